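test_that("restraint constructors enforce domains and units", {
  expect_error(restraint("distance", -1, 3), "force_constant")
  expect_error(restraint("distance", 1, 0), "distance target")
  expect_error(restraint("angle", 1, 0), "angle target")
  expect_error(restraint("angle", 1, 180), "angle target")
  expect_error(restraint("dihedral", 1, -180), "dihedral target")
  expect_error(restraint("distance", 1, 3, half_width = -0.1), "half_width")
  expect_silent(restraint("dihedral", 1, 180))

  # degrees in, radians stored
  th <- restraint("angle", 2, 90)
  expect_equal(th$target, pi / 2)

  # 1/2-convention force constants are halved on input
  expect_equal(restraint("distance", 2, 3, half_factor = TRUE)$force_constant, 1)
})

test_that("restraint sets fix one distance, two angles, three dihedrals", {
  set <- make_harmonic_set()
  expect_s3_class(set, "restraint_set")
  expect_error(restraint_set("bad", r = restraint("angle", 1, 90),
                             theta_A = set$theta_A, theta_B = set$theta_B,
                             phi_A = set$phi_A, phi_B = set$phi_B,
                             phi_C = set$phi_C),
               "must be a distance restraint")
  expect_error(restraint_set("bad", r = set$r, theta_A = set$theta_A,
                             theta_B = "not a restraint", phi_A = set$phi_A,
                             phi_B = set$phi_B, phi_C = set$phi_C),
               "must be a restraint object")
})

test_that("potential energy follows U = K (x - x0)^2 with no half factor", {
  r <- restraint("distance", 1, 3)
  expect_identical(potential_energy(r, 3), 0)
  # a 1 A displacement at K = 1 kcal/(mol A^2) costs exactly 1 kcal/mol
  expect_equal(potential_energy(r, 4), 1)
  expect_equal(potential_energy(r, 2), 1)

  fb <- restraint("distance", 2, 3, "flat_bottom", half_width = 0.5)
  expect_identical(potential_energy(fb, 3.4), 0)
  expect_equal(potential_energy(fb, 4.5), 2 * 1.0^2)

  # zero half width makes flat-bottom identical to harmonic
  fb0 <- restraint("distance", 2, 3, "flat_bottom", half_width = 0)
  x <- seq(0.5, 6, by = 0.25)
  expect_identical(potential_energy(fb0, x),
                   potential_energy(restraint("distance", 2, 3), x))

  # dihedral displacements are wrapped into (-pi, pi]
  d <- restraint("dihedral", 1, 170)
  expect_equal(potential_energy(d, deg2rad(-170)), deg2rad(20)^2)
})

test_that("standard volume matches the Avogadro-number definition", {
  expect_equal(signif(standard_volume(1), 3), 1660)
  expect_equal(standard_volume(1), 1e27 / 6.02214076e23)
  expect_equal(standard_volume(2), standard_volume(1) / 2)
  expect_equal(standard_volume(0.5), 2 * standard_volume(1))
  expect_error(standard_volume(0), "mol/L")
  th <- thermo_context()
  expect_gt(th$V0, 1660); expect_lt(th$V0, 1661)
  expect_error(thermo_context(temperature = -1), "temperature")
})

test_that("thermal sigma is the Boltzmann-Gaussian standard deviation", {
  expect_equal(round(thermal_sigma(1), 2), 0.55)
  expect_equal(thermal_sigma(4), thermal_sigma(1) / 2)
  expect_error(thermal_sigma(0), "force constant")

  # second moment of the normalized Boltzmann density, by quadrature
  th <- thermo_context()
  for (K in c(1, 20, 75)) {
    f <- function(x) exp(-th$beta * K * x^2)
    win <- 15 * sqrt(th$kT / (2 * K))  # covers the Gaussian support
    norm <- pracma::quadgk(f, -win, win, tol = 1e-13)
    m2 <- pracma::quadgk(function(x) x^2 * f(x), -win, win, tol = 1e-13) / norm
    expect_equal(thermal_sigma(K, th), sqrt(m2), tolerance = 1e-8)
    expect_equal(thermal_sigma(K, th), sqrt(th$kT / (2 * K)))
  }
})

test_that("safety report flags targets near coordinate boundaries", {
  th <- thermo_context()
  expect_identical(nrow(safety_report(table1_sets("CL1")[[1]], th)), 0L)

  extr <- safety_report(table1_sets("EXTR")[[1]], th)
  expect_setequal(extr$coordinate, c("theta_A", "theta_B"))

  # r0 = 3 A at K = 1 clears the 5 sigma ~ 2.75 A margin to r = 0
  soft <- make_harmonic_set(K_r = 1, r0 = 3)
  expect_false("r" %in% safety_report(soft, th)$coordinate)
  expect_true("r" %in% safety_report(make_harmonic_set(K_r = 1, r0 = 2), th)$coordinate)

  # threshold is configurable
  expect_gt(nrow(safety_report(soft, th, n_sigma = 8)), 0)
})

test_that("config files round-trip bit-identically", {
  set <- make_harmonic_set(K_r = pi, r0 = sqrt(2) * 3, K_theta = exp(1),
                           theta_A0 = 67.123456789, theta_B0 = 110.987654321,
                           K_phi = 1 / 3, phi0 = c(-12.5, 0.1, 179.99))
  th <- thermo_context(temperature = 298.15)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_restraint_config(set, th, path)
  back <- read_restraint_config(path)
  expect_identical(back$set, set)
  expect_identical(back$thermo$temperature, th$temperature)

  fb <- restraint_set("fb",
    r = restraint("distance", 2, 3, "flat_bottom", 0.25),
    theta_A = restraint("angle", 10, 80, "flat_bottom", 5),
    theta_B = restraint("angle", 10, 100, "flat_bottom", 5),
    phi_A = restraint("dihedral", 5, 0, "flat_bottom", 10),
    phi_B = restraint("dihedral", 5, 0, "flat_bottom", 10),
    phi_C = restraint("dihedral", 5, 0, "flat_bottom", 10))
  write_restraint_config(fb, th, path)
  expect_identical(read_restraint_config(path)$set, fb)

  expect_error(read_restraint_config(file.path(tempdir(), "nope.yaml")),
               "not found")
})

test_that("degree/radian conversion is exact at right angles and involutive", {
  expect_identical(deg2rad(0), 0)
  expect_identical(deg2rad(90), pi / 2)
  expect_identical(deg2rad(180), pi)
  expect_identical(rad2deg(pi), 180)
  x <- seq(-179, 179, by = 7.3)
  expect_equal(rad2deg(deg2rad(x)), x, tolerance = 1e-15)

  w <- wrap_dihedral(c(0, pi, -pi, 3 * pi / 2, -3 * pi / 2, 2 * pi))
  expect_equal(w, c(0, pi, pi, -pi / 2, pi / 2, 0))
})

test_that("bundled fixtures carry the documented parameters", {
  sets <- table1_sets()
  expect_named(sets, c("L1A-5", "L1A-F", "CL1", "CL1/SCH", "EXTR"))
  extr <- sets$EXTR
  expect_equal(extr$r$force_constant, 1)
  expect_equal(extr$r$target, 3)
  expect_equal(rad2deg(extr$theta_A$target), 22.5)
  expect_equal(rad2deg(extr$theta_B$target), 157.5)
  sch <- sets$`CL1/SCH`
  expect_equal(sch$r$force_constant, 1)
  expect_equal(sch$theta_A$force_constant, 40)
  expect_equal(sch$r$target, sets$CL1$r$target)
  expect_error(table1_sets("NOPE"), "unknown restraint set")
})
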