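# Shared fixtures, built once per test run.

kB <- 1.380649e-23

# a cached short trace + fit so several test files can reuse them
.fixture_env <- new.env()

fixture_trace <- function() {
  if (is.null(.fixture_env$trace))
    .fixture_env$trace <- synthesize_trace(particle_spec(), trap_params(),
                                           duration = 0.25,
                                           sample_rate = 1e6, seed = 42)
  .fixture_env$trace
}

fixture_fit <- function() {
  if (is.null(.fixture_env$fit))
    .fixture_env$fit <- trap_fit(fixture_trace(), segment_length = 2^13)
  .fixture_env$fit
}

# synthetic PSD object carrying an exact model curve (optionally plus a
# flat floor), for fitting-its-own-model tests
model_psd_estimate <- function(A, B, C, floor = 0, fs = 1e6, nbin = 2048) {
  f <- (0:(nbin - 1)) * (fs / 2) / nbin
  p <- 4 * pi * model_psd(pmax(2 * pi * f, 1e-9), A, B, C) + floor
  structure(list(frequency = f, power = p, df = f[2] - f[1],
                 n_segments = 1,
                 settings = list(segment_length = 2 * nbin, overlap = 0,
                                 window_name = "hann", sample_rate = fs),
                 metadata = list()),
            class = "psd_estimate")
}

# feature tables with controllable class separation: k classes, p noise
# features plus one informative feature shifted by `sep` per class step
make_table <- function(n_per_class, k = 3, p = 4, sep = 0, seed = 1) {
  set.seed(seed)
  n <- n_per_class * k
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  cls <- rep(seq_len(k), each = n_per_class)
  X[, 1] <- X[, 1] + sep * (cls - 1)
  d <- as.data.frame(X)
  d$class <- factor(paste0("c", cls))
  d
}

# quick pipeline: cohort of short traces -> feature table
cohort_features <- function(classes, n_per_class, seed,
                            duration = 0.25, radius_cv = 0.05) {
  co <- generate_cohort(n_per_class, classes = classes,
                        radius_cv = radius_cv, duration = duration,
                        sample_rate = 1e6, seed = seed)
  fits <- lapply(co$traces, function(tr) trap_fit(tr, segment_length = 2^13))
  assemble_features(fits)
}

# two-sided quadrature of the spectral model, split around the resonance so
# the adaptive rule cannot miss the narrow peak
quad_lorentz <- function(A, B, C) {
  f <- function(om) model_psd(om, A, B, C)
  2 * (integrate(f, 0, 0.9 * B, rel.tol = 1e-11)$value +
         integrate(f, 0.9 * B, 1.1 * B, rel.tol = 1e-11)$value +
         integrate(f, 1.1 * B, 100 * B, rel.tol = 1e-11)$value)
}
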