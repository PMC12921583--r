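## Lorentzian peak fitting, detector calibration and radius/mass estimation.

#' Mass of a spherical particle
#'
#' `(4/3) pi r^3 rho`.
#'
#' @param radius particle radius (m).
#' @param density material density (kg/m^3).
#' @return mass (kg).
#' @examples
#' particle_mass(75e-9, 1850)   # ~3.27e-18 kg
#' @export
particle_mass <- function(radius, density) {
  stopifnot(all(radius >= 0), all(density > 0))
  4 / 3 * pi * radius^3 * density
}

#' Kinetic-regime gas damping rate and its radius inversion
#'
#' In the kinetic (free-molecular) regime the residual-gas damping of a
#' sphere of radius `r` at pressure `P` is
#' \deqn{\Gamma_0 = 0.619 \frac{9\pi}{\sqrt 2}
#'   \frac{\eta_{air} d^2}{\rho k_B T_0} \frac{P_{gas}}{r},}
#' so the radius follows from the fitted Lorentzian width `C = Gamma0` as
#' `r = 0.619 (9 pi / sqrt 2) (eta d^2 / (rho kB T0)) P / C`. The two
#' functions are exact inverses of each other.
#'
#' `radius_from_damping` flags (with a warning) configurations where the
#' Knudsen number `lambda_mfp / r` drops below 10, outside the kinetic
#' regime the formula assumes.
#'
#' @param radius sphere radius (m).
#' @param C fitted damping rate Gamma0 (rad/s).
#' @param pressure gas pressure (Pa).
#' @param temperature gas temperature (K).
#' @param density particle material density (kg/m^3).
#' @param eta_air gas dynamic viscosity (Pa s).
#' @param d_air effective gas molecule diameter (m).
#' @return `damping_rate`: Gamma0 (rad/s); `radius_from_damping`: radius
#'   (m).
#' @examples
#' g0 <- damping_rate(75e-9, 350, 300)
#' radius_from_damping(g0, 350, 300)   # 75e-9, round trip
#' @export
damping_rate <- function(radius, pressure, temperature = 300,
                         density = trap_constants$rho_silica,
                         eta_air = trap_constants$eta_air,
                         d_air = trap_constants$d_air) {
  stopifnot(radius > 0, pressure > 0, temperature > 0)
  kB <- trap_constants$kB
  0.619 * (9 * pi / sqrt(2)) * eta_air * d_air^2 /
    (density * kB * temperature) * pressure / radius
}

#' @rdname damping_rate
#' @export
radius_from_damping <- function(C, pressure, temperature = 300,
                                density = trap_constants$rho_silica,
                                eta_air = trap_constants$eta_air,
                                d_air = trap_constants$d_air) {
  if (any(C <= 0)) stop("damping rate C must be positive")
  if (any(pressure <= 0)) stop("pressure must be positive")
  kB <- trap_constants$kB
  r <- 0.619 * (9 * pi / sqrt(2)) * eta_air * d_air^2 /
    (density * kB * temperature) * pressure / C
  # mean free path lambda = kB T / (sqrt(2) pi d^2 P); kinetic regime needs
  # Knudsen = lambda / r >> 1
  lambda <- kB * temperature / (sqrt(2) * pi * d_air^2 * pressure)
  if (any(lambda / r < 10))
    warning("Knudsen number < 10: outside the kinetic-regime validity of ",
            "the damping model")
  r
}

#' Detector conversion factor from a fitted peak
#'
#' Inverts the thermal amplitude `A = gamma^2 kB T0 Gamma0 / (pi m)` of the
#' Lorentzian fit:
#' \deqn{\gamma = \sqrt{A \pi m / (C k_B T_0)}}
#' giving the displacement-to-voltage conversion factor in V/m, which
#' converts the measured PSD (V^2/Hz) to displacement units (m^2/Hz).
#'
#' @param fit a `peak_fit` (or any list with elements `A` and `C`).
#' @param mass particle mass (kg).
#' @param temperature equilibrium temperature (K).
#' @return conversion factor gamma (V/m).
#' @export
conversion_factor <- function(fit, mass, temperature = 300) {
  stopifnot(mass > 0, temperature > 0)
  A <- fit$A; C <- fit$C
  stopifnot(A > 0, C > 0)
  kB <- trap_constants$kB
  sqrt(A * pi * mass / (C * kB * temperature))
}

#' Fit the Lorentzian spectral model to one peak window
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of [model_psd()] plus an additive white noise-floor
#' nuisance term to the PSD inside a frequency window. The one-sided
#' density in V^2/Hz is converted to the two-sided angular-frequency scale
#' (division by 4 pi) so the fitted `A`, `B`, `C` are on the natural
#' (rad/s) scale of the model. Weights are proportional to `1/model`
#' (refreshed each evaluation), i.e. a relative-error criterion that treats
#' the decades of dynamic range across the peak evenly. `A`, `B`, `C` are
#' parameterized on the log scale; the noise floor is bounded below by 0.
#'
#' Initialization is derivative-free and deterministic: `B` from the peak
#' bin, `C` from the half-maximum width, `A` from the peak height.
#'
#' @param psd a [estimate_psd()] result.
#' @param window a window from [find_peaks()] (list with `lo`, `hi` in Hz;
#'   `label`, `f_peak` optional), or `c(lo, hi)` in Hz.
#' @param max_iter maximum LM iterations.
#' @return object of class `"peak_fit"`: `A`, `B`, `C` (rad/s scale),
#'   `noise_floor` (V^2/Hz, one-sided), `se` (approximate standard errors
#'   of A, B, C), `covariance` (3x3), `rss`, `converged`, `window`,
#'   `label`, `n_bins`, and `flags` (character vector; e.g. width
#'   exceeding the window).
#' @examples
#' tr <- synthesize_trace(particle_spec(), trap_params(),
#'                        duration = 0.1, sample_rate = 1e6, seed = 5)
#' psd <- estimate_psd(tr, segment_length = 8192)
#' w <- find_peaks(psd)[[1]]
#' fit_lorentzian(psd, w)
#' @export
fit_lorentzian <- function(psd, window, max_iter = 200) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (is.numeric(window)) window <- list(label = "peak", lo = window[1],
                                         hi = window[2],
                                         f_peak = mean(window))
  sel <- psd$frequency >= window$lo & psd$frequency <= window$hi
  if (sum(sel) < 10) stop("need at least 10 frequency bins in the window")
  f <- psd$frequency[sel]
  y <- psd$power[sel] / (4 * pi)   # one-sided V^2/Hz -> two-sided in omega
  om <- 2 * pi * f

  # deterministic initial guesses
  ipk <- which.max(y)
  B0 <- om[ipk]
  half <- y[ipk] / 2
  above <- range(which(y > half))
  C0 <- max(om[above[2]] - om[above[1]], 2 * pi * 2 * psd$df)
  A0 <- y[ipk] * B0^2 * C0^2
  D0 <- max(stats::median(y[y < half]), min(y[y > 0]) , 0)

  resid_fn <- function(par) {
    A <- exp(par[1]); B <- exp(par[2]); C <- exp(par[3]); D <- par[4]
    m <- A / ((B^2 - om^2)^2 + om^2 * C^2) + D
    (y - m) / sqrt(pmax(m, .Machine$double.xmin))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(log(A0), log(B0), log(C0), D0),
                       fn = resid_fn,
                       lower = c(-Inf, -Inf, -Inf, 0),
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, maxfev = 4000)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5, 9)) {
    stop(sprintf(
      "Lorentzian fit did not converge in window [%.1f, %.1f] kHz (init A=%.3g B=%.3g C=%.3g; %s)",
      window$lo / 1e3, window$hi / 1e3, A0, B0, C0,
      if (is.null(fit)) "LM error" else fit$message))
  }
  par <- fit$par
  A <- exp(par[1]); B <- exp(par[2]); C <- exp(par[3]); D <- max(par[4], 0)
  rss <- sum(fit$fvec^2)
  dof <- max(length(y) - 4, 1)
  # covariance of (logA, logB, logC, D) from the LM hessian ~ 2 J'J,
  # mapped to (A, B, C) by the delta method
  cov3 <- matrix(NA_real_, 3, 3)
  se <- rep(NA_real_, 3)
  covp <- tryCatch(2 * solve(fit$hessian) * rss / dof, error = function(e) NULL)
  if (!is.null(covp)) {
    J <- diag(c(A, B, C))
    cov3 <- J %*% covp[1:3, 1:3] %*% J
    se <- sqrt(pmax(diag(cov3), 0))
  }
  flags <- character(0)
  width_hz <- C / (2 * pi)
  if (width_hz > (window$hi - window$lo))
    flags <- c(flags, "width_exceeds_window")
  if (B / (2 * pi) < window$lo || B / (2 * pi) > window$hi)
    flags <- c(flags, "centre_outside_window")
  structure(list(label = window$label %||% "peak", A = A, B = B, C = C,
                 noise_floor = 4 * pi * D, se = se, covariance = cov3,
                 rss = rss, converged = length(flags) == 0,
                 window = c(lo = window$lo, hi = window$hi),
                 n_bins = length(y), flags = flags),
            class = "peak_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Peak %s: f0 = %.4f kHz, Gamma0/2pi = %.4f kHz%s\n",
              x$label, x$B / 2e3 / pi, x$C / 2e3 / pi,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  cat(sprintf("  A = %.4g  (se: A %.2g, B %.2g, C %.2g rad/s)\n",
              x$A, x$se[1], x$se[2], x$se[3]))
  invisible(x)
}

#' Fit the full three-peak spectral model of one particle
#'
#' The central fitting routine of the package: estimates the PSD of a
#' detector trace, locates the three motional peaks (f1 < f2 < f3),
#' fits a Lorentzian to each, and runs the calibration chain:
#' radius from the f1 damping width (kinetic-regime gas damping), mass
#' from the radius assuming a spherical particle of the configured
#' density, and detector conversion factor from the f1 amplitude via
#' equipartition. A radius estimate is derived from every peak's width
#' (they are repeated measurements of the same damping rate).
#'
#' @param trace a `trap_trace`, or an already-computed `psd_estimate`.
#' @param pressure_mbar gas pressure (mbar); defaults to the trace
#'   metadata.
#' @param temperature equilibrium temperature (K); defaults to metadata,
#'   else 300 K.
#' @param density particle material density (kg/m^3).
#' @param n_peaks number of motional peaks expected.
#' @param reference_peak which peak's fit feeds the radius/mass/gamma
#'   chain (default `"f1"`).
#' @param segment_length,overlap,window_name PSD settings (see
#'   [estimate_psd()]).
#' @param ... passed to [find_peaks()].
#' @return object of class `"trap_fit"`: list with `psd`, `fits` (list of
#'   `peak_fit`), `radius` (named per peak, m), `mass` (kg), `gamma`
#'   (V/m), `reference_peak`, `settings`, `metadata`.
#' @examples
#' tr <- synthesize_trace(particle_spec(), trap_params(),
#'                        duration = 0.25, sample_rate = 1e6, seed = 11)
#' fit <- trap_fit(tr)
#' fit
#' coef(fit)
#' @export
trap_fit <- function(trace, pressure_mbar = NULL, temperature = NULL,
                     density = trap_constants$rho_silica, n_peaks = 3,
                     reference_peak = "f1",
                     segment_length = 2^14, overlap = 0.5,
                     window_name = "hann", ...) {
  psd <- if (inherits(trace, "psd_estimate")) trace
  else estimate_psd(trace, segment_length, overlap, window_name)
  md <- psd$metadata %||% list()
  pressure_mbar <- pressure_mbar %||% md$pressure_mbar %||%
    stop("pressure_mbar not given and absent from trace metadata")
  temperature <- temperature %||% md$temperature %||% 300

  windows <- find_peaks(psd, n_peaks = n_peaks, ...)
  fits <- lapply(windows, function(w) fit_lorentzian(psd, w))
  names(fits) <- vapply(fits, `[[`, "", "label")

  pressure <- pressure_mbar * 100
  radius <- vapply(fits, function(f)
    radius_from_damping(f$C, pressure, temperature, density = density),
    numeric(1))
  ref <- fits[[reference_peak]]
  r_ref <- radius[[reference_peak]]
  mass <- particle_mass(r_ref, density)
  gam <- conversion_factor(ref, mass, temperature)

  structure(list(psd = psd, fits = fits, radius = radius, mass = mass,
                 gamma = gam, reference_peak = reference_peak,
                 settings = list(pressure_mbar = pressure_mbar,
                                 temperature = temperature,
                                 density = density,
                                 segment_length = psd$settings$segment_length,
                                 overlap = psd$settings$overlap,
                                 window_name = psd$settings$window_name),
                 metadata = md),
            class = "trap_fit")
}

#' @export
print.trap_fit <- function(x, ...) {
  cat("Three-peak thermal-oscillator fit\n")
  for (f in x$fits)
    cat(sprintf("  %s: f0 = %8.3f kHz  width = %6.3f kHz  A = %.3e%s\n",
                f$label, f$B / 2e3 / pi, f$C / 2e3 / pi, f$A,
                if (f$converged) "" else "  [flagged]"))
  cat(sprintf("  radius (from %s width): %.1f nm   mass: %.3e kg   gamma: %.3e V/m\n",
              x$reference_peak, x$radius[[x$reference_peak]] * 1e9, x$mass,
              x$gamma))
  invisible(x)
}

#' @export
coef.trap_fit <- function(object, ...) {
  out <- t(vapply(object$fits, function(f) c(A = f$A, B = f$B, C = f$C),
                  numeric(3)))
  out
}

#' @export
summary.trap_fit <- function(object, ...) {
  tab <- data.frame(
    peak = names(object$fits),
    f0_khz = vapply(object$fits, function(f) f$B / 2e3 / pi, 0),
    width_khz = vapply(object$fits, function(f) f$C / 2e3 / pi, 0),
    A = vapply(object$fits, function(f) f$A, 0),
    radius_nm = unname(object$radius) * 1e9,
    converged = vapply(object$fits, function(f) f$converged, TRUE),
    row.names = NULL)
  structure(list(peaks = tab, mass = object$mass, gamma = object$gamma,
                 reference_peak = object$reference_peak,
                 settings = object$settings),
            class = "summary.trap_fit")
}

#' @export
print.summary.trap_fit <- function(x, ...) {
  cat("Three-peak thermal-oscillator fit\n\n")
  print(x$peaks, digits = 5)
  cat(sprintf("\nmass %.4g kg, gamma %.4g V/m (reference peak %s, %g mbar, %g K)\n",
              x$mass, x$gamma, x$reference_peak, x$settings$pressure_mbar,
              x$settings$temperature))
  invisible(x)
}

#' @export
predict.trap_fit <- function(object, frequency = NULL, ...) {
  frequency <- frequency %||% object$psd$frequency
  om <- 2 * pi * frequency
  tot <- numeric(length(om))
  for (f in object$fits) tot <- tot + model_psd(om, f$A, f$B, f$C)
  floor_v <- mean(vapply(object$fits, `[[`, 0, "noise_floor"))
  4 * pi * tot + floor_v   # back to one-sided V^2/Hz
}

#' @export
residuals.trap_fit <- function(object, ...) {
  unlist(lapply(object$fits, function(f) {
    sel <- object$psd$frequency >= f$window["lo"] &
      object$psd$frequency <= f$window["hi"]
    y <- object$psd$power[sel]
    m <- 4 * pi * model_psd(2 * pi * object$psd$frequency[sel],
                            f$A, f$B, f$C) + f$noise_floor
    stats::setNames((y - m) / m, NULL)
  }))
}

#' Plot a fitted spectrum
#'
#' One panel per motional peak (the layout of the study's PSD comparison
#' figures): measured PSD with the fitted Lorentzian overlaid. Pass several
#' fits (via `extra`) to compare particles/classes in the same panels.
#'
#' @param x a `trap_fit`.
#' @param extra optional named list of further `trap_fit` objects drawn in
#'   other colours.
#' @param col colours (data first, then overlays).
#' @param ... passed to `plot`.
#' @export
plot.trap_fit <- function(x, extra = NULL, col = c("grey25", "red",
                                                   "blue", "purple"), ...) {
  all_fits <- c(list(x), extra)
  op <- graphics::par(mfrow = c(1, length(x$fits)),
                      mar = c(4, 4, 2, 0.6))
  on.exit(graphics::par(op))
  for (i in seq_along(x$fits)) {
    lab <- names(x$fits)[i]
    lo <- min(vapply(all_fits, function(ft) ft$fits[[i]]$window["lo"], 0))
    hi <- max(vapply(all_fits, function(ft) ft$fits[[i]]$window["hi"], 0))
    ylim <- NULL
    for (j in seq_along(all_fits)) {
      ft <- all_fits[[j]]
      sel <- ft$psd$frequency >= lo & ft$psd$frequency <= hi &
        ft$psd$power > 0
      if (j == 1) {
        graphics::plot(ft$psd$frequency[sel] / 1e3, ft$psd$power[sel],
                       type = "l", log = "y", col = col[j], main = lab,
                       xlab = "Frequency (kHz)",
                       ylab = if (i == 1) expression(PSD ~ (V^2/Hz)) else "",
                       ...)
      } else {
        graphics::lines(ft$psd$frequency[sel] / 1e3, ft$psd$power[sel],
                        col = col[(j - 1) %% length(col) + 1])
      }
      fgrid <- seq(lo, hi, length.out = 400)
      graphics::lines(fgrid / 1e3,
                      4 * pi * model_psd(2 * pi * fgrid, ft$fits[[i]]$A,
                                         ft$fits[[i]]$B, ft$fits[[i]]$C) +
                        ft$fits[[i]]$noise_floor,
                      col = col[(j - 1) %% length(col) + 1], lty = 2)
    }
  }
  invisible(x)
}
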