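## Physical constants (2019 SI) and material defaults shared across the package.

#' Physical constants used throughout the package
#'
#' A named list of SI constants and the material/gas defaults assumed by the
#' simulator, the calibration chain and the frequency-shift model. All values
#' are configurable through the function arguments that consume them; this
#' list only fixes the defaults in one place.
#'
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{eps0}{Vacuum permittivity, F/m.}
#'   \item{c0}{Speed of light, m/s.}
#'   \item{N_avogadro}{Avogadro constant, 1/mol.}
#'   \item{eta_air}{Dynamic viscosity of air at 300 K, Pa s.}
#'   \item{d_air}{Effective diameter of an air molecule, m.}
#'   \item{rho_silica}{Density of amorphous (fumed) silica, kg/m^3.}
#'   \item{eps_silica}{Relative permittivity of fused silica at 1550 nm
#'     (n = 1.44).}
#'   \item{radius_default}{Nominal particle radius, m.}
#' }
#'
#' @export
trap_constants <- list(
  kB          = 1.380649e-23,
  eps0        = 8.8541878128e-12,
  c0          = 299792458,
  N_avogadro  = 6.02214076e23,
  eta_air     = 1.81e-5,
  d_air       = 0.372e-9,
  rho_silica  = 1850,
  eps_silica  = 1.44^2,
  radius_default = 75e-9
)

## Molecule table for the frequency-shift model. Polarizability volumes
## (alpha / 4 pi eps0, in m^3) and crystal densities are literature values for
## the isolated bases; the 2'-deoxynucleoside-5'-monophosphates add a common
## sugar-phosphate backbone contribution, and the 25-mer strands are built
## additively from 25 nucleotides minus 24 condensation waters.
.molecule_table <- local({
  Da <- 1e-3 / 6.02214076e23       # kg per g/mol
  backbone_alpha <- 17.0e-30        # deoxyribose-phosphate, m^3
  m_h2o <- 18.02 * Da
  base <- list(
    adenine = list(mass = 135.13 * Da, alpha_vol = 15.0e-30,
                   density = 1470, footprint = 0.35e-18),
    thymine = list(mass = 126.11 * Da, alpha_vol = 12.5e-30,
                   density = 1460, footprint = 0.35e-18)
  )
  nt <- list(
    dAMP = list(mass = 331.22 * Da, alpha_vol = base$adenine$alpha_vol + backbone_alpha,
                density = 1600, footprint = 0.60e-18),
    dTMP = list(mass = 322.21 * Da, alpha_vol = base$thymine$alpha_vol + backbone_alpha,
                density = 1600, footprint = 0.60e-18)
  )
  oligo <- list(
    oligo_25A = list(mass = 25 * nt$dAMP$mass - 24 * m_h2o,
                     alpha_vol = 25 * nt$dAMP$alpha_vol,
                     density = 1600, footprint = 25 * nt$dAMP$footprint),
    oligo_25T = list(mass = 25 * nt$dTMP$mass - 24 * m_h2o,
                     alpha_vol = 25 * nt$dTMP$alpha_vol,
                     density = 1600, footprint = 25 * nt$dTMP$footprint)
  )
  c(base, nt, oligo)
})

#' Molecule descriptor for the frequency-shift model
#'
#' Returns a descriptor (name, molecular mass in kg, polarizability volume in
#' m^3, bulk density in kg/m^3, adsorption footprint in m^2) either from the
#' built-in table or constructed from the supplied values.
#'
#' Built-in names: `"adenine"`, `"thymine"` (free bases), `"dAMP"`, `"dTMP"`
#' (deoxynucleotides), `"oligo_25A"`, `"oligo_25T"` (25-mer single strands,
#' additive in their nucleotides).
#'
#' @param name molecule name; either one of the built-ins or a label for a
#'   custom molecule.
#' @param mass molecular mass (kg); required for custom molecules.
#' @param alpha_vol polarizability volume (m^3), i.e. alpha / (4 pi eps0).
#' @param density bulk density of the condensed molecule (kg/m^3).
#' @param footprint surface area occupied by one adsorbed molecule (m^2).
#' @return an object of class `"molecule"`.
#' @examples
#' molecule("adenine")
#' molecule("custom", mass = 2e-25, alpha_vol = 1.4e-29,
#'          density = 1500, footprint = 3e-19)
#' @export
molecule <- function(name, mass = NULL, alpha_vol = NULL,
                     density = NULL, footprint = NULL) {
  if (name %in% names(.molecule_table)) {
    m <- .molecule_table[[name]]
    if (!is.null(mass)) m$mass <- mass
    if (!is.null(alpha_vol)) m$alpha_vol <- alpha_vol
    if (!is.null(density)) m$density <- density
    if (!is.null(footprint)) m$footprint <- footprint
  } else {
    if (is.null(mass) || is.null(alpha_vol) || is.null(density) ||
        is.null(footprint))
      stop("unknown molecule '", name,
           "': supply mass, alpha_vol, density and footprint", call. = FALSE)
    m <- list(mass = mass, alpha_vol = alpha_vol, density = density,
              footprint = footprint)
  }
  stopifnot(m$mass > 0, m$alpha_vol > 0, m$density > 0, m$footprint > 0)
  structure(c(list(name = name), m), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("Molecule:", x$name, "\n")
  cat(sprintf("  mass       %.4g kg (%.2f Da)\n", x$mass, x$mass / 1.66053907e-27))
  cat(sprintf("  alpha_vol  %.4g m^3\n", x$alpha_vol))
  cat(sprintf("  density    %.4g kg/m^3\n", x$density))
  cat(sprintf("  footprint  %.4g m^2\n", x$footprint))
  invisible(x)
}
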