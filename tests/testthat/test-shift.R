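test_that("zero shell reduces exactly to the bare-sphere polarizability", {
  s <- coated_sphere()
  eps0 <- trap_constants$eps0
  eps <- trap_constants$eps_silica
  r <- s$core_radius
  expect_identical(polarizability(s),
                   4 * pi * eps0 * r^3 * (eps - 1) / (eps + 2))
})

test_that("a shell of core permittivity is a bigger bare sphere", {
  t <- 5e-9
  coated <- coated_sphere(shell_thickness = t,
                          shell_eps = trap_constants$eps_silica,
                          shell_density = trap_constants$rho_silica)
  bare <- coated_sphere(core_radius = 75e-9 + t)
  expect_equal(polarizability(coated), polarizability(bare),
               tolerance = 1e-12)
  expect_equal(coated$mass, bare$mass, tolerance = 1e-12)
})

test_that("polarizability grows monotonically with shell thickness", {
  al <- vapply(seq(0, 2e-9, length.out = 9), function(t)
    polarizability(coated_sphere(shell_thickness = t, shell_eps = 3,
                                 shell_density = 1400)), numeric(1))
  expect_true(all(diff(al) > 0))
})

test_that("trap frequency depends on the particle only through alpha/m", {
  fld <- trap_field()
  f_small <- trap_frequency(coated_sphere(core_radius = 50e-9), fld)
  f_big <- trap_frequency(coated_sphere(core_radius = 100e-9), fld)
  # alpha and m both scale with volume: size cancels
  expect_equal(f_small, f_big, tolerance = 1e-12)
  # doubling alpha at fixed mass scales f by sqrt(2)
  s <- coated_sphere()
  f0 <- trap_frequency(s, fld)
  f2 <- trap_frequency(list(alpha = 2 * polarizability(s), mass = s$mass),
                       fld)
  expect_equal(f2 / f0, sqrt(2), tolerance = 1e-12)
})

test_that("the bare reference sphere sits in the simulator's frequency band", {
  f0 <- trap_frequency(coated_sphere(), trap_field())
  expect_gt(f0, 100e3)
  expect_lt(f0, 180e3)
})

test_that("monolayer shift behaves at its limits", {
  expect_identical(monolayer_shift(molecule("adenine"), coverage = 0), 0)
  # approximately linear in coverage when dilute
  d1 <- monolayer_shift(molecule("adenine"), coverage = 0.01)
  d2 <- monolayer_shift(molecule("adenine"), coverage = 0.02)
  expect_equal(d2 / d1, 2, tolerance = 0.02)
  expect_error(monolayer_shift(molecule("adenine"),
                               sphere = coated_sphere(shell_thickness = 1e-9,
                                                      shell_eps = 2,
                                                      shell_density = 1000)),
               "bare")
})

test_that("single-molecule comparison is antisymmetric and zero on equals", {
  a <- molecule("oligo_25A"); b <- molecule("oligo_25T")
  expect_identical(single_molecule_shift(a, a), 0)
  expect_equal(single_molecule_shift(a, b), -single_molecule_shift(b, a))
})

test_that("perturbative shift matches the differentiated full model", {
  # independent routes: analytic dilute-coverage derivative vs the full
  # core-shell formula at small coverage
  for (name in c("adenine", "thymine")) {
    mol <- molecule(name)
    n_mono <- 4 * pi * coated_sphere()$core_radius^2 / mol$footprint
    numeric_d <- monolayer_shift(mol, coverage = 1e-6) / (1e-6 * n_mono)
    expect_equal(single_molecule_shift_one(mol), numeric_d,
                 tolerance = 0.01)
  }
})

test_that("rayleigh-regime violations are flagged", {
  expect_warning(polarizability(coated_sphere(core_radius = 400e-9)),
                 "quasi-static")
})

test_that("shift report reproduces the study's model estimates", {
  rep <- shift_report()
  expect_equal(unname(rep$monolayer_shift_hz["adenine"]), 1000,
               tolerance = 0.1)
  expect_gt(rep$monolayer_shift_hz["adenine"], rep$monolayer_shift_hz["thymine"])
  expect_equal(rep$single_strand_difference_hz, 30e-3, tolerance = 0.5)
})
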