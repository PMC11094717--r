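test_that("rigorous distance factor equals quadrature of its defining integral", {
  th <- thermo_context()
  expect_equal(z_distance_chen(1, 3, th), oracle_z_true("distance", 1, 3, th),
               tolerance = 1e-10)
  set.seed(7)
  for (i in 1:30) {
    K <- runif(1, 0.5, 100); r0 <- runif(1, 2, 8)
    expect_equal(z_distance_chen(K, r0, th),
                 oracle_z_true("distance", K, r0, th), tolerance = 1e-10)
  }
  # stiff/far-from-origin limit: the RRHO approximations become exact; the
  # leading A1 error is sigma^2/r0^2 = kT/(2 K r0^2)
  dev50 <- abs(z_distance_chen(50, 8, th) / z_distance_rrho(50, 8, th) - 1)
  dev5e4 <- abs(z_distance_chen(5e4, 8, th) / z_distance_rrho(5e4, 8, th) - 1)
  expect_lt(dev50, 1e-4)
  expect_lt(dev5e4, 1e-6)
  # r0 -> 0 limit: half-Gaussian second moment sqrt(pi) / (4 (beta K)^{3/2})
  a <- th$beta * 2
  expect_equal(z_distance_chen(2, 1e-12, th), sqrt(pi) / (4 * a^1.5),
               tolerance = 1e-10)
})

test_that("rigorous angle factor is the Gaussian-damped sine identity", {
  th <- thermo_context()
  # ratio to the RRHO factor is exactly exp(-1/(4 beta K)), whatever theta0
  for (K in c(0.5, 1, 7, 40)) {
    for (t0 in deg2rad(c(30, 89.73, 150))) {
      expect_equal(z_angle_chen(K, t0, th) / z_angle_rrho(K, t0, th),
                   exp(-1 / (4 * th$beta * K)), tolerance = 1e-14)
    }
  }
  # against quadrature of sin(theta) exp(-beta K (theta-theta0)^2) over
  # a +/- 12 sigma window (the (-inf, inf) integral, truncated)
  K <- 40; t0 <- deg2rad(89.73)
  sigma <- thermal_sigma(K, th)
  q <- pracma::quadgk(function(x) sin(x) * exp(-th$beta * K * (x - t0)^2),
                      t0 - 12 * sigma, t0 + 12 * sigma, tol = 1e-13)
  expect_equal(z_angle_chen(K, t0, th), q, tolerance = 1e-8)
  # K -> infinity: converges to the RRHO value
  expect_equal(z_angle_chen(1e6, deg2rad(70), th) / z_angle_rrho(1e6, deg2rad(70), th),
               1, tolerance = 1e-6)
})

test_that("rigorous dihedral factor integrates one full period", {
  th <- thermo_context()
  expect_equal(z_dihedral_chen(1, th), oracle_z_true("dihedral", 1, 0, th),
               tolerance = 1e-10)
  # erf argument >> 3: indistinguishable from the infinite-limit Gaussian
  expect_equal(z_dihedral_chen(20, th), z_dihedral_rrho(20, th),
               tolerance = 1e-12)
  # strictly below the RRHO value while erf(pi sqrt(beta K)) < 1 is
  # resolvable at double precision
  for (K in c(0.5, 1, 2)) expect_lt(z_dihedral_chen(K, th), z_dihedral_rrho(K, th))
  for (K in c(0.5, 1, 2, 5, 50))
    expect_lte(z_dihedral_chen(K, th), z_dihedral_rrho(K, th))
})

test_that("exact angle integral agrees with (0, pi) quadrature everywhere", {
  th <- thermo_context()
  # the primary contract: oracle equality over randomized safe draws
  set.seed(11)
  for (i in 1:100) {
    K <- runif(1, 0.5, 100)
    t0 <- runif(1, deg2rad(20), deg2rad(160))
    expect_equal(z_angle_exact(K, t0, th), oracle_z_true("angle", K, t0, th),
                 tolerance = 1e-10)
  }
  # EXTR angles: measurably different from the infinite-limit form
  z_ex <- z_angle_exact(1, deg2rad(22.5), th)
  expect_equal(z_ex, oracle_z_true("angle", 1, deg2rad(22.5), th),
               tolerance = 1e-10)
  expect_gt(abs(z_ex - z_angle_chen(1, deg2rad(22.5), th)) / z_ex, 0.01)
  # near 90 degrees at large K all three angle forms coincide (the
  # exact/RRHO gap is the exp(-1/(4 beta K)) factor, ~3e-5 at K = 5000)
  z1 <- z_angle_exact(5000, pi / 2, th)
  expect_equal(z1, z_angle_chen(5000, pi / 2, th), tolerance = 1e-12)
  expect_equal(z1, z_angle_rrho(5000, pi / 2, th), tolerance = 1e-4)
  # mid-range targets, K >= 10: infinite-limit and exact forms agree tightly
  for (t0 in deg2rad(c(80, 90, 100))) {
    for (K in c(10, 40, 100)) {
      expect_equal(z_angle_chen(K, t0, th), z_angle_exact(K, t0, th),
                   tolerance = 1e-6)
    }
  }
})

test_that("exact angle integral stays stable for very stiff restraints", {
  th <- thermo_context()
  for (K in c(1e3, 1e4, 1e5)) {
    z <- z_angle_exact(K, deg2rad(89.73), th)
    expect_true(is.finite(z) && z > 0)
    expect_equal(z, oracle_z_true("angle", K, deg2rad(89.73), th),
                 tolerance = 1e-9)
  }
})

test_that("set-level rigorous and exact partitions share distance/dihedral factors", {
  th <- thermo_context()
  extr <- table1_sets("EXTR")[[1]]
  z_ch <- z_rest_chen(extr, th)
  z_ex <- z_rest_exact(extr, th)
  expect_identical(z_ch$scheme, "chen")
  expect_identical(z_ex$scheme, "exact")
  expect_identical(z_ch$z[["r"]], z_ex$z[["r"]])
  expect_identical(z_ch$z[["phi_B"]], z_ex$z[["phi_B"]])
  expect_false(isTRUE(all.equal(z_ch$z[["theta_A"]], z_ex$z[["theta_A"]])))

  # all schemes coincide in the stiff-restraint limit
  stiff <- make_harmonic_set(K_r = 1e4, r0 = 3.48, K_theta = 1e4,
                             theta_A0 = 89.73, theta_B0 = 124.14, K_phi = 1e4)
  dA <- c(delta_a_rest(z_rest_rrho(stiff, th), th),
          delta_a_rest(z_rest_chen(stiff, th), th),
          delta_a_rest(z_rest_exact(stiff, th), th),
          delta_a_rest(z_rest_numeric(stiff, th), th))
  expect_lt(max(dA) - min(dA), 1e-3)

  fb <- restraint_set("fb", r = restraint("distance", 2, 3, "flat_bottom", 0.25),
                      theta_A = extr$theta_A, theta_B = extr$theta_B,
                      phi_A = extr$phi_A, phi_B = extr$phi_B, phi_C = extr$phi_C)
  expect_error(z_rest_chen(fb, th), "flat-bottom")
  expect_error(z_rest_exact(fb, th), "flat-bottom")
})
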