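## Langevin simulator: exact discrete-time sampling of the damped thermal
## harmonic oscillator, single-channel detector synthesis, cohort generation.

#' Trap and detector parameters
#'
#' Describes one optical trap + detection channel: the three motional
#' frequencies (z, x, y read out as the spectral peaks f1 < f2 < f3 of a
#' single detector channel), the gas damping rate, the particle mass, the
#' environment temperature, the per-axis displacement-to-voltage conversion
#' factors, the white detector-noise floor and the gas pressure.
#'
#' If `gamma0` is omitted it is derived from `radius` and `pressure_mbar`
#' through the kinetic-regime gas-damping relation (see
#' [damping_rate()]); if `mass` is omitted it is derived from `radius` and
#' `density`.
#'
#' @param f1,f2,f3 motional frequencies (Hz) of the z, x, y axes. Must be
#'   strictly increasing.
#' @param pressure_mbar gas pressure (mbar).
#' @param temperature environment temperature (K).
#' @param radius particle radius (m), used to derive `gamma0` and `mass`.
#' @param density particle material density (kg/m^3).
#' @param gamma0 damping rate Gamma0 (rad/s); derived from pressure and
#'   radius when `NULL`.
#' @param mass particle mass (kg); derived from radius and density when
#'   `NULL`.
#' @param conv conversion factors (V/m), length 3 (z, x, y).
#' @param noise_floor one-sided white detector noise density (V^2/Hz).
#' @param eta_air,d_air gas viscosity (Pa s) and effective molecule
#'   diameter (m) used when deriving `gamma0`.
#' @return an object of class `"trap_params"` (a list with elements
#'   `omega0` (rad/s, length 3), `gamma0`, `mass`, `temperature`, `conv`,
#'   `noise_floor`, `pressure` (Pa), `pressure_mbar`, `radius`, `density`).
#' @examples
#' trap_params()                      # 40/120/140 kHz at 3.5 mbar, 300 K
#' trap_params(f1 = 5e4, gamma0 = 2 * pi * 3e3)
#' @export
trap_params <- function(f1 = 40e3, f2 = 120e3, f3 = 140e3,
                        pressure_mbar = 3.5, temperature = 300,
                        radius = trap_constants$radius_default,
                        density = trap_constants$rho_silica,
                        gamma0 = NULL, mass = NULL,
                        conv = c(1e6, 8e5, 6e5), noise_floor = 1e-9,
                        eta_air = trap_constants$eta_air,
                        d_air = trap_constants$d_air) {
  f <- c(f1, f2, f3)
  if (any(f <= 0)) stop("motional frequencies must be positive")
  if (any(diff(f) <= 0)) stop("frequencies must satisfy f1 < f2 < f3")
  if (pressure_mbar <= 0 || temperature < 0 || radius <= 0 || density <= 0)
    stop("pressure, radius and density must be positive; temperature non-negative")
  pressure <- pressure_mbar * 100  # mbar -> Pa
  if (is.null(gamma0))
    gamma0 <- damping_rate(radius, pressure, temperature, density = density,
                           eta_air = eta_air, d_air = d_air)
  if (is.null(mass)) mass <- particle_mass(radius, density)
  stopifnot(gamma0 > 0, mass > 0, length(conv) == 3, noise_floor >= 0)
  structure(list(omega0 = 2 * pi * f, gamma0 = gamma0, mass = mass,
                 temperature = temperature, conv = conv,
                 noise_floor = noise_floor, pressure = pressure,
                 pressure_mbar = pressure_mbar, radius = radius,
                 density = density),
            class = "trap_params")
}

#' @export
print.trap_params <- function(x, ...) {
  cat("Trap parameters\n")
  cat(sprintf("  f1/f2/f3     %.3f / %.3f / %.3f kHz\n", x$omega0[1] / 2e3 / pi,
              x$omega0[2] / 2e3 / pi, x$omega0[3] / 2e3 / pi))
  cat(sprintf("  Gamma0/2pi   %.3f kHz  (%.2f mbar, %g K)\n",
              x$gamma0 / 2e3 / pi, x$pressure_mbar, x$temperature))
  cat(sprintf("  mass         %.4g kg  (r = %.1f nm)\n", x$mass, x$radius * 1e9))
  cat(sprintf("  conv (V/m)   %s;  noise floor %g V^2/Hz\n",
              paste(format(x$conv, digits = 3), collapse = ", "), x$noise_floor))
  invisible(x)
}

#' Particle description for cohort generation
#'
#' A particle template: radius, material density, a class label (e.g.
#' `"standard"`, `"25A_1000uM"`, `"25T_1000uM"`) and the per-axis
#' trap-frequency offsets (Hz) that encode the effect of a surface coating
#' on the polarizability-to-mass ratio. Offsets must be zero for the
#' unfunctionalized `"standard"` class.
#'
#' @param radius particle radius (m).
#' @param density material density (kg/m^3).
#' @param class_label class of the particle (character scalar).
#' @param freq_offsets numeric length 3 (or scalar, recycled): frequency
#'   offsets (Hz) added to f1, f2, f3.
#' @return an object of class `"particle_spec"`.
#' @examples
#' particle_spec()
#' particle_spec(class_label = "25A_1000uM", freq_offsets = 1010)
#' @export
particle_spec <- function(radius = trap_constants$radius_default,
                          density = trap_constants$rho_silica,
                          class_label = "standard",
                          freq_offsets = c(0, 0, 0)) {
  stopifnot(radius > 0, density > 0, is.character(class_label))
  if (length(freq_offsets) == 1) freq_offsets <- rep(freq_offsets, 3)
  stopifnot(length(freq_offsets) == 3)
  if (identical(class_label, "standard") && any(freq_offsets != 0))
    stop("freq_offsets must be 0 for class 'standard'")
  structure(list(radius = radius, density = density,
                 class_label = class_label, freq_offsets = freq_offsets,
                 mass = particle_mass(radius, density)),
            class = "particle_spec")
}

## Exact one-step transition of the damped oscillator (x, v) over dt:
## M = exp(A dt) for A = [[0, 1], [-omega0^2, -gamma0]], written with
## complex Omega so the under- and over-damped branches share one formula.
.osc_transition <- function(omega0, gamma0, dt) {
  Om <- sqrt(as.complex(omega0^2 - gamma0^2 / 4))
  e <- exp(-gamma0 * dt / 2)
  cO <- Re(cos(Om * dt))
  sO <- if (abs(Om) > 0) Re(sin(Om * dt) / Om) else dt
  matrix(c(e * (cO + gamma0 / 2 * sO), e * sO,
           -e * omega0^2 * sO,         e * (cO - gamma0 / 2 * sO)),
         2, 2, byrow = TRUE)
}

#' Simulate one motional axis of a trapped particle
#'
#' Draws a stationary sample path of the thermally driven damped harmonic
#' oscillator
#' \deqn{\ddot x + \Gamma_0 \dot x + \omega_0^2 x = \sqrt{2 k_B T_0 \Gamma_0 / m}\,\xi(t)}
#' whose displacement power spectral density is the Lorentzian thermal
#' spectrum used by the fitting stage. The update is the exact discrete-time
#' transition of the (x, v) Gaussian process: the one-step mean is
#' `exp(A dt)` and the one-step covariance is `S - M S M'` with `S` the
#' stationary (equipartition) covariance, so the sampled path has exactly
#' the continuous-time marginals at any step size (no integrator bias).
#'
#' @param omega0 natural angular frequency (rad/s).
#' @param gamma0 damping rate (rad/s).
#' @param mass particle mass (kg).
#' @param temperature bath temperature (K). `0` yields the zero path.
#' @param duration trace length (s); must cover at least 100 oscillation
#'   periods.
#' @param sample_rate sampling rate (Hz); must exceed `4 * omega0 / 2 pi`.
#' @param seed integer seed; the trace is a deterministic function of it.
#' @return numeric vector of displacements (m), length
#'   `round(duration * sample_rate)`.
#' @examples
#' m <- particle_mass(75e-9, 1850)
#' x <- simulate_axis(2 * pi * 5e4, 2 * pi * 3e3, m, 300,
#'                    duration = 0.05, sample_rate = 1e6, seed = 1)
#' var(x)                       # ~ kB T / (m omega0^2)
#' @export
simulate_axis <- function(omega0, gamma0, mass, temperature,
                          duration, sample_rate, seed) {
  if (duration <= 0 || sample_rate <= 0)
    stop("duration and sample_rate must be positive")
  if (omega0 <= 0 || gamma0 <= 0 || mass <= 0)
    stop("omega0, gamma0 and mass must be positive")
  if (temperature < 0) stop("temperature must be non-negative")
  if (sample_rate <= 4 * omega0 / (2 * pi))
    stop("undersampled configuration: sample_rate must exceed 4 * omega0/2pi ",
         "to keep the resonance clear of the Nyquist frequency")
  if (duration < 100 * 2 * pi / omega0)
    stop("duration must cover at least 100 oscillation periods")
  n <- round(duration * sample_rate)
  if (temperature == 0) return(numeric(n))

  kB <- trap_constants$kB
  dt <- 1 / sample_rate
  M <- .osc_transition(omega0, gamma0, dt)
  Sx <- kB * temperature / (mass * omega0^2)
  Sv <- kB * temperature / mass
  # one-step covariance Q = S - M S M' (S diagonal at stationarity)
  Q11 <- Sx - (M[1, 1]^2 * Sx + M[1, 2]^2 * Sv)
  Q12 <-    - (M[1, 1] * M[2, 1] * Sx + M[1, 2] * M[2, 2] * Sv)
  Q22 <- Sv - (M[2, 1]^2 * Sx + M[2, 2]^2 * Sv)
  L11 <- sqrt(max(Q11, 0))
  L21 <- if (L11 > 0) Q12 / L11 else 0
  L22 <- sqrt(max(Q22 - L21^2, 0))

  set.seed(seed)
  w1 <- stats::rnorm(n); w2 <- stats::rnorm(n)
  u1 <- L11 * w1
  u2 <- L21 * w1 + L22 * w2
  x1 <- stats::rnorm(1, 0, sqrt(Sx))
  v1 <- stats::rnorm(1, 0, sqrt(Sv))
  if (n == 1) return(x1)
  x2 <- M[1, 1] * x1 + M[1, 2] * v1 + u1[1]
  if (n == 2) return(c(x1, x2))
  # positions alone follow an ARMA(2,1) recursion driven by the 2-D noise;
  # stats::filter runs it in C
  phi1 <- M[1, 1] + M[2, 2]
  phi2 <- -(M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1])
  k <- 3:n
  innov <- u1[k - 1] + M[1, 2] * u2[k - 2] - M[2, 2] * u1[k - 2]
  xs <- stats::filter(innov, c(phi1, phi2), method = "recursive",
                      init = c(x2, x1))
  c(x1, x2, as.numeric(xs))
}

#' Synthesize a single-channel detector trace
#'
#' Builds the voltage signal of one detection channel carrying all three
#' motional peaks: each axis is simulated independently (with the damping
#' rate derived from the particle's radius and the trap pressure), scaled by
#' its conversion factor, summed, and additive white Gaussian detector noise
#' of the configured one-sided floor is added. Class-dependent frequency
#' offsets from the particle spec are applied to the trap frequencies.
#'
#' @param particle a [particle_spec()].
#' @param trap a [trap_params()]. Its `mass`, `gamma0` and `radius` are
#'   overridden by the particle's radius (damping re-derived at the trap
#'   pressure).
#' @param duration trace length (s).
#' @param sample_rate sampling rate (Hz).
#' @param seed integer seed (deterministic per-axis subseeds are derived
#'   from it).
#' @return an object of class `"trap_trace"`: list with `samples` (V),
#'   `sample_rate`, `duration`, and `metadata` (pressure_mbar, temperature,
#'   class label, seed, ground-truth frequencies, damping, radius, mass,
#'   conversion factors, overlap flag).
#' @examples
#' tr <- synthesize_trace(particle_spec(), trap_params(),
#'                        duration = 0.05, sample_rate = 1e6, seed = 7)
#' tr
#' @export
synthesize_trace <- function(particle, trap, duration = 1,
                             sample_rate = 1e6, seed = 1) {
  stopifnot(inherits(particle, "particle_spec"), inherits(trap, "trap_params"))
  omega0 <- trap$omega0 + 2 * pi * particle$freq_offsets
  if (any(diff(omega0) <= 0))
    stop("frequency offsets reorder the peaks; f1 < f2 < f3 required")
  gamma0 <- damping_rate(particle$radius, trap$pressure, trap$temperature,
                         density = particle$density)
  mass <- particle$mass
  overlap <- min(diff(sort(omega0))) < 3 * gamma0
  if (overlap)
    warning("motional peaks closer than 3 linewidths; fits may be degenerate")

  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1, 4)
  n <- round(duration * sample_rate)
  volts <- numeric(n)
  for (ax in 1:3) {
    if (trap$conv[ax] == 0) next
    x <- simulate_axis(omega0[ax], gamma0, mass, trap$temperature,
                       duration, sample_rate, subseeds[ax])
    volts <- volts + trap$conv[ax] * x
  }
  if (trap$noise_floor > 0) {
    set.seed(subseeds[4])
    volts <- volts + stats::rnorm(n, 0, sqrt(trap$noise_floor * sample_rate / 2))
  }
  structure(list(
    samples = volts, sample_rate = sample_rate, duration = n / sample_rate,
    metadata = list(pressure_mbar = trap$pressure_mbar,
                    temperature = trap$temperature,
                    class_label = particle$class_label, seed = seed,
                    f_true = omega0 / (2 * pi), gamma0_true = gamma0,
                    radius_true = particle$radius, mass_true = mass,
                    density = particle$density, conv_true = trap$conv,
                    noise_floor = trap$noise_floor,
                    overlap_warning = overlap)),
    class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Detector trace: %d samples @ %g MHz (%.3g s), class '%s'\n",
              length(x$samples), x$sample_rate / 1e6, x$duration,
              md$class_label))
  cat(sprintf("  truth: f = %s kHz, Gamma0/2pi = %.3f kHz, r = %.1f nm\n",
              paste(sprintf("%.2f", md$f_true / 1e3), collapse = "/"),
              md$gamma0_true / 2e3 / pi, md$radius_true * 1e9))
  invisible(x)
}

#' Default particle-class templates for the two study designs
#'
#' Returns the class templates used by [generate_cohort()] for the two
#' experiment layouts: `"three_class"` (standard, 25A and 25T at 1000 uM
#' binding-agent concentration) and `"concentration"` (25T at 100, 500, 750
#' and 1000 uM). The frequency offsets come from the coating model of
#' [monolayer_shift()]: a full adenine monolayer shifts the trap frequency
#' by about +1.01 kHz and a thymine monolayer by about +0.71 kHz on the
#' default 75 nm sphere; the concentration series scales the thymine offset
#' by a Langmuir coverage curve c/(c + 300 uM).
#'
#' @param experiment `"three_class"` or `"concentration"`.
#' @return list of [particle_spec()] templates.
#' @export
cohort_classes <- function(experiment = c("three_class", "concentration")) {
  experiment <- match.arg(experiment)
  shift_A <- 1006   # Hz, full adenine monolayer (see monolayer_shift)
  shift_T <- 709    # Hz, full thymine monolayer
  if (experiment == "three_class") {
    list(particle_spec(class_label = "standard"),
         particle_spec(class_label = "25A_1000uM", freq_offsets = shift_A),
         particle_spec(class_label = "25T_1000uM", freq_offsets = shift_T))
  } else {
    conc <- c(100, 500, 750, 1000)
    cov <- conc / (conc + 300)    # Langmuir adsorption isotherm
    lapply(seq_along(conc), function(i)
      particle_spec(class_label = sprintf("25T_%duM", conc[i]),
                    freq_offsets = shift_T * cov[i]))
  }
}

#' Generate a cohort of simulated detector traces
#'
#' Draws `n_per_class` particles per class template, dispersing each
#' particle's radius around its template value with the given coefficient
#' of variation (truncated at 3 sigma to keep radii positive), applies the
#' class frequency offsets, and synthesizes one detector trace per particle.
#' The whole cohort is a deterministic function of `seed`.
#'
#' @param n_per_class particles per class (scalar or one per class).
#' @param classes list of [particle_spec()] templates (default: the
#'   three-class study design, see [cohort_classes()]).
#' @param radius_cv coefficient of variation of the particle radius within
#'   a class, in `[0, 0.5]`.
#' @param trap a [trap_params()] shared by the cohort.
#' @param duration,sample_rate trace settings passed to
#'   [synthesize_trace()].
#' @param seed master seed.
#' @return list with `traces` (list of `trap_trace`) and `manifest`
#'   (data.frame: index, class, seed, true radius (m), true f1/f2/f3 (Hz)).
#' @examples
#' co <- generate_cohort(2, duration = 0.05, seed = 3)
#' co$manifest
#' @export
generate_cohort <- function(n_per_class, classes = cohort_classes(),
                            radius_cv = 0.1, trap = trap_params(),
                            duration = 1, sample_rate = 1e6, seed = 1) {
  if (length(classes) == 0) stop("empty class list")
  stopifnot(all(n_per_class >= 1), radius_cv >= 0, radius_cv <= 0.5)
  n_per_class <- rep_len(n_per_class, length(classes))
  total <- sum(n_per_class)
  set.seed(seed)
  trace_seeds <- sample.int(.Machine$integer.max - 1, total)
  # radius draws: truncated normal, |z| <= 3
  z <- stats::rnorm(total)
  z[abs(z) > 3] <- 3 * sign(z[abs(z) > 3])

  traces <- vector("list", total)
  rows <- vector("list", total)
  i <- 0
  for (ci in seq_along(classes)) {
    tmpl <- classes[[ci]]
    for (k in seq_len(n_per_class[ci])) {
      i <- i + 1
      r <- tmpl$radius * (1 + radius_cv * z[i])
      p <- particle_spec(radius = r, density = tmpl$density,
                         class_label = tmpl$class_label,
                         freq_offsets = tmpl$freq_offsets)
      traces[[i]] <- synthesize_trace(p, trap, duration, sample_rate,
                                      seed = trace_seeds[i])
      rows[[i]] <- data.frame(index = i, class = tmpl$class_label,
                              seed = trace_seeds[i], radius_true = r,
                              f1_true = traces[[i]]$metadata$f_true[1],
                              f2_true = traces[[i]]$metadata$f_true[2],
                              f3_true = traces[[i]]$metadata$f_true[3])
    }
  }
  list(traces = traces, manifest = do.call(rbind, rows))
}

#' Write / read a detector trace as CSV
#'
#' Two-column CSV (`time_s`, `voltage_V`); metadata is carried in `#`
#' comment header lines as `key=value` pairs.
#'
#' @param trace a `trap_trace`.
#' @param path file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `trap_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  md <- trace$metadata
  hdr <- c(sprintf("# sample_rate=%.10g", trace$sample_rate),
           sprintf("# pressure_mbar=%.10g", md$pressure_mbar),
           sprintf("# temperature_K=%.10g", md$temperature),
           sprintf("# class_label=%s", md$class_label),
           sprintf("# seed=%d", md$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,voltage_V", con)
  t <- (seq_along(trace$samples) - 1) / trace$sample_rate
  writeLines(sprintf("%.9g,%.9g", t, trace$samples), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  md <- stats::setNames(as.list(vals), keys)
  d <- utils::read.csv(path, comment.char = "#")
  sr <- as.numeric(md$sample_rate)
  structure(list(samples = d$voltage_V, sample_rate = sr,
                 duration = nrow(d) / sr,
                 metadata = list(
                   pressure_mbar = as.numeric(md$pressure_mbar),
                   temperature = as.numeric(md$temperature_K),
                   class_label = md$class_label,
                   seed = as.integer(md$seed))),
            class = "trap_trace")
}
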