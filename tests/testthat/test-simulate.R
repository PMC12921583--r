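test_that("simulated axis obeys equipartition", {
  m <- particle_mass(75e-9, 1850)
  om0 <- 2 * pi * 5e4
  g0 <- 2 * pi * 3e3
  theory <- kB * 300 / (m * om0^2)
  vs <- vapply(1:6, function(s)
    var(simulate_axis(om0, g0, m, 300, duration = 0.5, sample_rate = 5e5,
                      seed = s)), numeric(1))
  expect_lt(abs(mean(vs) / theory - 1), 0.05)
})

test_that("zero temperature gives the zero trajectory", {
  x <- simulate_axis(2 * pi * 5e4, 2 * pi * 3e3, 1e-18, 0,
                     duration = 0.01, sample_rate = 1e6, seed = 1)
  expect_identical(x, numeric(10000))
})

test_that("traces are bit-identical for identical seed and parameters", {
  a <- simulate_axis(2 * pi * 4e4, 2 * pi * 3e3, 3e-18, 300, 0.05, 1e6, 7)
  b <- simulate_axis(2 * pi * 4e4, 2 * pi * 3e3, 3e-18, 300, 0.05, 1e6, 7)
  expect_identical(a, b)
  tr1 <- synthesize_trace(particle_spec(), trap_params(), 0.05, 1e6, seed = 9)
  tr2 <- synthesize_trace(particle_spec(), trap_params(), 0.05, 1e6, seed = 9)
  expect_identical(tr1$samples, tr2$samples)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulate_axis(2 * pi * 5e4, 1, 1e-18, 300, -1, 1e6, 1),
               "positive")
  expect_error(simulate_axis(2 * pi * 3e5, 2 * pi * 3e3, 1e-18, 300,
                             0.1, 1e6, 1), "undersampled")
  expect_error(simulate_axis(2 * pi * 5e4, 2 * pi * 3e3, 1e-18, 300,
                             1e-4, 1e6, 1), "100 oscillation periods")
})

test_that("trace PSD integrates to the equipartition variance", {
  # Parseval: total one-sided power equals the signal variance, which the
  # exact update pins to kB T / (m omega0^2)
  m <- particle_mass(75e-9, 1850)
  om0 <- 2 * pi * 5e4
  x <- simulate_axis(om0, 2 * pi * 3e3, m, 300, 0.5, 5e5, seed = 3)
  psd <- estimate_psd(list(samples = x, sample_rate = 5e5),
                      segment_length = 2^13)
  expect_lt(abs(sum(psd$power) * psd$df / (kB * 300 / (m * om0^2)) - 1), 0.05)
})

test_that("zero conversion factors and zero noise give a silent detector", {
  tp <- trap_params(conv = c(0, 0, 0), noise_floor = 0)
  tr <- synthesize_trace(particle_spec(), tp, 0.02, 1e6, seed = 1)
  expect_identical(tr$samples, numeric(20000))
})

test_that("gas damping and radius are exact inverses", {
  g0 <- damping_rate(75e-9, 350, 300)
  expect_equal(radius_from_damping(g0, 350, 300), 75e-9, tolerance = 1e-12)
  r <- radius_from_damping(2e4, 350, 300)
  expect_equal(damping_rate(r, 350, 300), 2e4, tolerance = 1e-12)
})

test_that("overlapping peaks raise the metadata flag", {
  tp <- trap_params(f1 = 40e3, f2 = 41e3, f3 = 140e3)
  expect_warning(
    tr <- synthesize_trace(particle_spec(), tp, 0.02, 1e6, seed = 1),
    "3 linewidths")
  expect_true(tr$metadata$overlap_warning)
})

test_that("cohort generation is deterministic with the declared layout", {
  cl <- cohort_classes("three_class")
  expect_length(cl, 3)
  expect_identical(cl[[1]]$freq_offsets, c(0, 0, 0))
  co1 <- generate_cohort(2, classes = cl, duration = 0.02, seed = 5)
  co2 <- generate_cohort(2, classes = cl, duration = 0.02, seed = 5)
  expect_equal(nrow(co1$manifest), 6)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$traces[[3]]$samples, co2$traces[[3]]$samples)
  expect_error(generate_cohort(2, classes = list(), duration = 0.02),
               "empty class list")
  # class offsets applied to the ground truth
  expect_equal(co1$manifest$f1_true[co1$manifest$class == "25A_1000uM"] -
                 co1$manifest$f1_true[co1$manifest$class == "standard"],
               rep(1006, 2))
})

test_that("trace CSV round-trips samples and metadata", {
  tr <- synthesize_trace(particle_spec(), trap_params(), 0.01, 1e6, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
  expect_equal(back$sample_rate, tr$sample_rate)
  expect_identical(back$metadata$class_label, "standard")
  unlink(f)
})
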