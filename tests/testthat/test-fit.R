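test_that("fitting the model to its own noiseless curve recovers A, B, C", {
  A <- 8e12; B <- 2 * pi * 120e3; C <- 2 * pi * 3e3
  psd <- model_psd_estimate(A, B, C)
  fit <- fit_lorentzian(psd, c(100e3, 140e3))
  expect_lt(abs(fit$A / A - 1), 1e-3)
  expect_lt(abs(fit$B / B - 1), 1e-3)
  expect_lt(abs(fit$C / C - 1), 1e-3)
  expect_true(fit$converged)
})

test_that("a noise floor nuisance does not bias the peak parameters", {
  A <- 8e12; B <- 2 * pi * 120e3; C <- 2 * pi * 3e3
  floor_v <- 4 * pi * model_psd(B, A, B, C) * 1e-3
  psd <- model_psd_estimate(A, B, C, floor = floor_v)
  fit <- fit_lorentzian(psd, c(100e3, 140e3))
  expect_lt(abs(fit$B / B - 1), 1e-3)
  expect_lt(abs(fit$C / C - 1), 2e-3)
  expect_equal(fit$noise_floor, floor_v, tolerance = 0.05)
})

test_that("simulated traces give back the trap parameters", {
  tr <- fixture_trace()
  fit <- fixture_fit()
  truth_f <- tr$metadata$f_true
  truth_g <- tr$metadata$gamma0_true
  for (i in 1:3) {
    expect_lt(abs(fit$fits[[i]]$B / (2 * pi) / truth_f[i] - 1), 0.005)
    expect_lt(abs(fit$fits[[i]]$C / truth_g - 1), 0.10)
  }
  expect_lt(abs(fit$radius[["f1"]] / tr$metadata$radius_true - 1), 0.10)
  expect_lt(abs(fit$gamma / tr$metadata$conv_true[1] - 1), 0.10)
})

test_that("conversion factor inverts the thermal amplitude exactly", {
  m <- particle_mass(75e-9, 1850)
  gam_true <- 1e6
  C <- 2 * pi * 3e3
  A <- gam_true^2 * kB * 300 * C / (pi * m)
  fit <- list(A = A, C = C)
  expect_equal(conversion_factor(fit, m, 300), gam_true, tolerance = 1e-12)
  # gamma scales as sqrt(A)
  expect_equal(conversion_factor(list(A = 2 * A, C = C), m, 300),
               sqrt(2) * gam_true, tolerance = 1e-12)
  expect_error(conversion_factor(fit, -1, 300))
})

test_that("radius estimate follows its scaling laws", {
  r0 <- radius_from_damping(2e4, 350, 300)
  expect_equal(radius_from_damping(4e4, 350, 300), r0 / 2)
  expect_equal(radius_from_damping(2e4, 700, 300), 2 * r0)
  expect_error(radius_from_damping(-1, 350))
  expect_error(radius_from_damping(2e4, 0))
  # continuum-regime configurations are flagged
  expect_warning(radius_from_damping(2e4, 5e4, 300), "Knudsen")
})

test_that("spherical mass arithmetic", {
  expect_equal(particle_mass(75e-9, 1850), 3.27e-18, tolerance = 1e-3)
  expect_identical(particle_mass(0, 1850), 0)
  expect_equal(particle_mass(150e-9, 1850) / particle_mass(75e-9, 1850), 8)
})

test_that("a peakless window is rejected or flagged", {
  set.seed(4)
  x <- rnorm(2e5, sd = 1e-3)
  psd <- estimate_psd(list(samples = x, sample_rate = 1e6),
                      segment_length = 4096)
  res <- tryCatch(fit_lorentzian(psd, c(100e3, 140e3)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "converge")
  } else {
    expect_false(res$converged)
  }
})

test_that("trap_fit methods are coherent", {
  fit <- fixture_fit()
  co <- coef(fit)
  expect_equal(dim(co), c(3, 3))
  expect_true(all(co > 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.trap_fit")
  expect_equal(nrow(s$peaks), 3)
  pred <- predict(fit)
  expect_length(pred, length(fit$psd$frequency))
  expect_true(all(pred > 0))
  # prediction matches the measured PSD at the f1 resonance within the
  # estimator noise
  i0 <- which.min(abs(fit$psd$frequency - fit$fits$f1$B / (2 * pi)))
  band <- (i0 - 3):(i0 + 3)
  expect_lt(abs(mean(pred[band]) / mean(fit$psd$power[band]) - 1), 0.25)
  expect_true(all(is.finite(residuals(fit))))
  expect_output(print(fit), "radius")
})
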