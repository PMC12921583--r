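## Core-shell polarizability model of the trap-frequency shift caused by a
## molecular coating on a levitated dielectric nanosphere.

#' Coated dielectric nanosphere
#'
#' A silica core of radius `core_radius` optionally wrapped in a uniform
#' dielectric shell (the molecular coating). Zero shell thickness reduces
#' exactly to the bare sphere. Any salt layer from the binding agent is
#' deliberately not modelled.
#'
#' @param core_radius core radius (m).
#' @param core_density core density (kg/m^3).
#' @param core_eps core relative permittivity at the trapping wavelength.
#' @param shell_thickness shell thickness (m), >= 0.
#' @param shell_density shell density (kg/m^3).
#' @param shell_eps shell relative permittivity (> 1 for a dielectric).
#' @return object of class `"coated_sphere"` with the fields above plus
#'   `mass` (core + shell, kg).
#' @examples
#' coated_sphere()                          # bare 75 nm silica sphere
#' coated_sphere(shell_thickness = 4e-10, shell_eps = 3.1,
#'               shell_density = 1470)
#' @export
coated_sphere <- function(core_radius = trap_constants$radius_default,
                          core_density = trap_constants$rho_silica,
                          core_eps = trap_constants$eps_silica,
                          shell_thickness = 0, shell_density = 0,
                          shell_eps = 1) {
  stopifnot(core_radius > 0, core_density > 0, shell_thickness >= 0)
  if (core_eps <= 1 || shell_eps < 1)
    stop("permittivities must exceed 1 for a dielectric (shell may be 1 only when empty)")
  if (shell_thickness > 0 && shell_density < 0)
    stop("shell_density must be non-negative")
  R <- core_radius + shell_thickness
  shell_mass <- 4 / 3 * pi * (R^3 - core_radius^3) * shell_density
  structure(list(core_radius = core_radius, core_density = core_density,
                 core_eps = core_eps, shell_thickness = shell_thickness,
                 shell_density = shell_density, shell_eps = shell_eps,
                 outer_radius = R,
                 mass = particle_mass(core_radius, core_density) + shell_mass),
            class = "coated_sphere")
}

#' Optical trap field
#'
#' The focused Gaussian beam forming the trap: wavelength (1550 nm in this
#' experiment), optical power and focal waist. The transverse intensity
#' curvature at the focus sets the harmonic trap stiffness.
#'
#' The default power (0.43 W at 1.0 um waist) places the bare 75 nm silica
#' sphere's transverse frequency near 140 kHz, consistent with the
#' simulator's default f3.
#'
#' @param wavelength laser wavelength (m).
#' @param power optical power (W).
#' @param waist focal beam waist (m).
#' @return object of class `"trap_field"`.
#' @export
trap_field <- function(wavelength = 1550e-9, power = 0.43, waist = 1.0e-6) {
  stopifnot(wavelength > 0, power > 0, waist > 0)
  structure(list(wavelength = wavelength, power = power, waist = waist),
            class = "trap_field")
}

#' Quasi-static polarizability of a (coated) nanosphere
#'
#' Clausius-Mossotti polarizability of a core-shell sphere in the Rayleigh
#' (quasi-static) regime:
#' \deqn{\alpha = 4\pi\varepsilon_0 R^3
#'  \frac{(\varepsilon_2-1)(\varepsilon_1+2\varepsilon_2)
#'        + f(\varepsilon_1-\varepsilon_2)(1+2\varepsilon_2)}
#'       {(\varepsilon_2+2)(\varepsilon_1+2\varepsilon_2)
#'        + f(\varepsilon_1-\varepsilon_2)(2\varepsilon_2-2)}}
#' with core permittivity `eps1`, shell permittivity `eps2`, outer radius
#' `R` and core volume fraction `f = (r/R)^3`. At zero shell thickness this
#' is exactly the bare-sphere form `4 pi eps0 r^3 (eps-1)/(eps+2)`.
#'
#' @param sphere a [coated_sphere()].
#' @param wavelength trapping wavelength (m), used only for the Rayleigh
#'   validity check (`R < wavelength / 10`; a warning is raised
#'   otherwise).
#' @return polarizability alpha (SI, C m^2/V).
#' @examples
#' polarizability(coated_sphere())
#' @export
polarizability <- function(sphere, wavelength = 1550e-9) {
  stopifnot(inherits(sphere, "coated_sphere"))
  if (sphere$outer_radius > wavelength / 10)
    warning("sphere is not small compared to the wavelength; ",
            "quasi-static polarizability is approximate")
  eps0 <- trap_constants$eps0
  e1 <- sphere$core_eps; e2 <- sphere$shell_eps
  R <- sphere$outer_radius
  if (sphere$shell_thickness == 0)
    return(4 * pi * eps0 * R^3 * (e1 - 1) / (e1 + 2))
  f <- (sphere$core_radius / R)^3
  num <- (e2 - 1) * (e1 + 2 * e2) + f * (e1 - e2) * (1 + 2 * e2)
  den <- (e2 + 2) * (e1 + 2 * e2) + f * (e1 - e2) * (2 * e2 - 2)
  4 * pi * eps0 * R^3 * num / den
}

#' Transverse trap frequency of a sphere in a Gaussian focus
#'
#' In the harmonic approximation at the focus, the transverse spring
#' constant is `k = 2 alpha I0 / (c eps0 w0^2)` with on-axis intensity
#' `I0 = 2 P / (pi w0^2)`, so
#' \deqn{\omega_0 = \sqrt{\frac{4 \alpha P}{\pi c \varepsilon_0 w_0^4 m}}.}
#' The frequency depends on the particle only through its
#' polarizability-to-mass ratio alpha/m: in the Rayleigh regime both scale
#' with the volume, which is why a molecular coating shifts the frequency
#' through alpha/m rather than through mass alone.
#'
#' @param sphere a [coated_sphere()] (or a list with `alpha` and `mass` to
#'   bypass the polarizability computation).
#' @param field a [trap_field()].
#' @return trap frequency omega0 / 2 pi (Hz).
#' @examples
#' trap_frequency(coated_sphere(), trap_field())   # ~140 kHz
#' @export
trap_frequency <- function(sphere, field = trap_field()) {
  stopifnot(inherits(field, "trap_field"))
  alpha <- if (!is.null(sphere$alpha)) sphere$alpha
  else polarizability(sphere, field$wavelength)
  mass <- sphere$mass
  if (mass <= 0) stop("mass must be positive")
  cst <- trap_constants
  omega2 <- 4 * alpha * field$power /
    (pi * cst$c0 * cst$eps0 * field$waist^4 * mass)
  sqrt(omega2) / (2 * pi)
}

## shell description of a (partial) monolayer of `mol` at fractional
## coverage: thickness from the molecular volume and footprint; shell
## permittivity from the Clausius-Mossotti relation at the in-layer number
## density scaled by coverage.
.monolayer_shell <- function(mol, coverage = 1) {
  stopifnot(coverage >= 0, coverage <= 1)
  V <- mol$mass / mol$density
  t <- V / mol$footprint
  N <- coverage / (mol$footprint * t)
  cm <- 4 * pi / 3 * N * mol$alpha_vol
  if (cm >= 1) stop("unphysical monolayer: Clausius-Mossotti factor >= 1")
  eps2 <- (1 + 2 * cm) / (1 - cm)
  rho2 <- coverage * mol$mass / (mol$footprint * t)
  list(thickness = t, eps = eps2, density = rho2)
}

#' Trap-frequency shift from a molecular monolayer
#'
#' Frequency shift `f(coated) - f(bare)` when the sphere is coated with a
#' (partial) monolayer of the given molecule. The layer thickness is the
#' molecular volume divided by the adsorption footprint; the shell
#' permittivity follows from the Clausius-Mossotti relation at the
#' in-layer number density (scaled by coverage), and the shell mass is the
#' number of adsorbed molecules times the molecular mass. Zero coverage
#' returns exactly 0.
#'
#' With the default constants a full adenine monolayer on the 75 nm
#' reference sphere shifts the trap frequency by about +1 kHz.
#'
#' @param mol a [molecule()] (typically `molecule("adenine")` or
#'   `molecule("thymine")`).
#' @param sphere the bare reference [coated_sphere()].
#' @param field a [trap_field()].
#' @param coverage fractional monolayer coverage in `[0, 1]`.
#' @return frequency shift Delta f (Hz), signed.
#' @examples
#' monolayer_shift(molecule("adenine"))    # ~ +1 kHz
#' @export
monolayer_shift <- function(mol, sphere = coated_sphere(),
                            field = trap_field(), coverage = 1) {
  stopifnot(inherits(mol, "molecule"), inherits(sphere, "coated_sphere"))
  if (sphere$shell_thickness != 0)
    stop("reference sphere must be bare (zero shell)")
  if (coverage == 0) return(0)
  sh <- .monolayer_shell(mol, coverage)
  coated <- coated_sphere(core_radius = sphere$core_radius,
                          core_density = sphere$core_density,
                          core_eps = sphere$core_eps,
                          shell_thickness = sh$thickness,
                          shell_density = sh$density,
                          shell_eps = sh$eps)
  trap_frequency(coated, field) - trap_frequency(sphere, field)
}

#' Single-molecule frequency shift and two-molecule comparison
#'
#' `single_molecule_shift_one()` gives the perturbative frequency shift
#' from one adsorbed molecule:
#' \deqn{\Delta f = \frac{f_0}{2}\left(\frac{\alpha_{mol}}{\alpha}
#'   - \frac{m_{mol}}{m}\right),}
#' the first-order change of `f propto sqrt(alpha/m)`.
#' `single_molecule_shift()` returns the difference between the shifts of
#' two molecules on the same particle — e.g. one 25-mer deoxyadenosine
#' strand (`molecule("oligo_25A")`) against one 25-mer deoxythymidine
#' strand, which on the default 75 nm sphere differs by about 30 mHz. It
#' is antisymmetric in its two arguments and zero for identical
#' molecules.
#'
#' @param mol,mol_a,mol_b [molecule()] descriptors.
#' @param sphere the bare reference [coated_sphere()].
#' @param field a [trap_field()].
#' @return frequency shift (Hz).
#' @examples
#' single_molecule_shift(molecule("oligo_25A"), molecule("oligo_25T"))
#' @export
single_molecule_shift <- function(mol_a, mol_b, sphere = coated_sphere(),
                                  field = trap_field()) {
  single_molecule_shift_one(mol_a, sphere, field) -
    single_molecule_shift_one(mol_b, sphere, field)
}

#' @rdname single_molecule_shift
#' @export
single_molecule_shift_one <- function(mol, sphere = coated_sphere(),
                                      field = trap_field()) {
  stopifnot(inherits(mol, "molecule"), inherits(sphere, "coated_sphere"))
  if (sphere$shell_thickness != 0)
    stop("reference sphere must be bare (zero shell)")
  eps0 <- trap_constants$eps0
  alpha <- polarizability(sphere, field$wavelength)
  f0 <- trap_frequency(sphere, field)
  # dilute-coverage derivative of the core-shell polarizability: one
  # molecule in a vanishing-density layer of its monolayer thickness t.
  # With G(e2) the core-shell Clausius-Mossotti factor, the per-molecule
  # polarizability is 4 pi eps0 R^3 G'(1) de2/dn, where de2/dn =
  # alpha_vol / (r^2 t). G'(1) carries the local-field enhancement of the
  # polarized core at its surface; it vanishes with the shell volume.
  r <- sphere$core_radius
  t <- mol$mass / mol$density / mol$footprint
  R <- r + t
  f <- (r / R)^3
  e1 <- sphere$core_eps
  num  <- 3 * f * (e1 - 1)
  den  <- 3 * (e1 + 2)
  dnum <- (e1 + 2) + f * (2 * e1 - 5)
  dden <- (e1 + 8) + 2 * f * (e1 - 1)
  Gp <- (dnum * den - num * dden) / den^2
  dalpha_dn <- 4 * pi * eps0 * R^3 * Gp * mol$alpha_vol / (r^2 * t)
  f0 / 2 * (dalpha_dn / alpha - mol$mass / sphere$mass)
}

#' Frequency-shift scenario report
#'
#' Evaluates the bare trap frequency and the coating scenarios of the
#' study (adenine and thymine monolayers; one 25A strand vs one 25T
#' strand) for a given sphere and field.
#'
#' @param sphere the bare reference [coated_sphere()].
#' @param field a [trap_field()].
#' @return list: `bare_frequency_hz`, `monolayer_shift_hz` (named, adenine
#'   and thymine), `single_strand_difference_hz`.
#' @export
shift_report <- function(sphere = coated_sphere(), field = trap_field()) {
  list(bare_frequency_hz = trap_frequency(sphere, field),
       monolayer_shift_hz = c(
         adenine = monolayer_shift(molecule("adenine"), sphere, field),
         thymine = monolayer_shift(molecule("thymine"), sphere, field)),
       single_strand_difference_hz = single_molecule_shift(
         molecule("oligo_25A"), molecule("oligo_25T"), sphere, field))
}
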