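# Physical constants (CODATA 2018) and the unit registry.
#
# Internal unit system: atomic units for energy (Hartree) and length (Bohr),
# masses in unified atomic mass units (amu), dipoles in atomic units (e*a0).
# Conversions happen only at package boundaries (file readers/writers, user
# facing reports).

#' CODATA 2018 physical constants
#'
#' A named list of the SI-valued physical constants every conversion factor in
#' the package is derived from. Exposed so that tests and scripts can perform
#' independent dimensional-analysis cross-checks against the very same source
#' values.
#'
#' @format Named list with elements
#'   \describe{
#'     \item{year}{constant-set year (2018)}
#'     \item{c}{speed of light in vacuum, m/s (exact)}
#'     \item{h}{Planck constant, J s (exact)}
#'     \item{N_A}{Avogadro constant, 1/mol (exact)}
#'     \item{e}{elementary charge, C (exact)}
#'     \item{eps0}{vacuum electric permittivity, F/m}
#'     \item{a0}{Bohr radius, m}
#'     \item{E_h}{Hartree energy, J}
#'     \item{amu}{unified atomic mass unit, kg}
#'     \item{m_e}{electron mass, kg}
#'     \item{cal}{thermochemical calorie, J (exact by definition)}
#'   }
#' @export
codata_constants <- list(
  year = 2018L,
  c    = 299792458,
  h    = 6.62607015e-34,
  N_A  = 6.02214076e23,
  e    = 1.602176634e-19,
  eps0 = 8.8541878128e-12,
  a0   = 5.29177210903e-11,
  E_h  = 4.3597447222071e-18,
  amu  = 1.66053906660e-27,
  m_e  = 9.1093837015e-31,
  cal  = 4.184
)

# Derived factors used throughout the pipeline. All traced to codata_constants.
.k <- codata_constants
.const <- list(
  bohr_to_angstrom = .k$a0 * 1e10,
  hartree_to_kcalmol = .k$E_h * .k$N_A / (.k$cal * 1000),
  au_dipole_to_debye = .k$e * .k$a0 / (1e-21 / .k$c),
  # sqrt(eigenvalue) -> wavenumber: eigenvalues of the mass-weighted FCM come
  # out in E_h / (a0^2 amu); converting to SI angular terms and dividing by
  # 2*pi*c gives reciprocal centimeters.
  sqrt_eig_to_rcm = sqrt(.k$E_h / (.k$a0^2 * .k$amu)) / (2 * pi * .k$c * 100),
  # |dmu/dQ|^2 -> km/mol for dmu/dQ in e / sqrt(amu): N_A e^2/(12 eps0 c^2 amu)
  dmudq2_to_kmmol = .k$N_A * .k$e^2 / (12 * .k$eps0 * .k$c^2 * .k$amu) / 1000,
  rcm_to_kcalmol = .k$h * .k$c * 100 * .k$N_A / (.k$cal * 1000)
)
rm(.k)

#' Spectroscopic conversion constants derived from CODATA 2018
#'
#' @return Named list:
#' \describe{
#'   \item{sqrt_eig_to_rcm}{multiply \code{sqrt(|eigenvalue|)} of the
#'     mass-weighted force-constant matrix (in Eh/(a0^2 amu)) by this to get
#'     the wavenumber in 1/cm (about 5140.5).}
#'   \item{dmudq2_to_kmmol}{multiply the squared normal-mode dipole derivative
#'     (in (e/sqrt(amu))^2) by this to get the integral absorption coefficient
#'     in km/mol (about 974.9).}
#'   \item{rcm_to_kcalmol}{energy of one wavenumber unit in kcal/mol.}
#' }
#' @export
spectroscopy_constants <- function() {
  .const[c("sqrt_eig_to_rcm", "dmudq2_to_kmmol", "rcm_to_kcalmol")]
}

# Unit registry: every unit carries a dimension tag and a factor to the
# internal base unit of that dimension (bohr / hartree / amu / au dipole).
.unit_registry <- local({
  u <- list()
  add <- function(name, dim, to_base) u[[name]] <<- list(dim = dim, to_base = to_base)
  add("bohr",     "length", 1)
  add("angstrom", "length", 1 / .const$bohr_to_angstrom)
  add("m",        "length", 1e10 / .const$bohr_to_angstrom)
  add("hartree",  "energy", 1)
  add("kcal/mol", "energy", 1 / .const$hartree_to_kcalmol)
  add("kj/mol",   "energy", 1 / (.const$hartree_to_kcalmol * codata_constants$cal))
  add("rcm",      "energy", .const$rcm_to_kcalmol / .const$hartree_to_kcalmol)
  add("amu",           "mass", 1)
  add("electron_mass", "mass", codata_constants$m_e / codata_constants$amu)
  add("kg",            "mass", 1 / codata_constants$amu)
  add("au_dipole", "dipole", 1)
  add("debye",     "dipole", 1 / .const$au_dipole_to_debye)
  u
})

#' Names of all registered units
#' @return Character vector of unit names accepted by [convert_units()].
#' @export
registered_units <- function() names(.unit_registry)

#' Convert a value between registered units
#'
#' Both units must belong to the same dimension (length, energy, mass or
#' dipole). `rcm` (reciprocal centimeters) is registered as an energy unit via
#' E = h c nu-tilde. Round trips are identities to at least 12 significant
#' digits because all factors derive from one CODATA constant set.
#'
#' @param value numeric vector.
#' @param from,to unit names; see [registered_units()].
#' @return `value` expressed in `to` units.
#' @examples
#' convert_units(1, "angstrom", "bohr")
#' convert_units(627.5094740631, "kcal/mol", "hartree")
#' @export
convert_units <- function(value, from, to) {
  uf <- .unit_registry[[from]]
  ut <- .unit_registry[[to]]
  if (is.null(uf) || is.null(ut)) {
    stop("unregistered unit(s): ",
         paste(setdiff(c(from, to), registered_units()), collapse = ", "),
         call. = FALSE)
  }
  if (uf$dim != ut$dim) {
    stop(sprintf("incompatible dimensions: '%s' is %s, '%s' is %s",
                 from, uf$dim, to, ut$dim), call. = FALSE)
  }
  value * (uf$to_base / ut$to_base)
}

# Standard atomic weights (IUPAC 2021 abridged). One mass per element, no
# isotopes. Covers the element set of typical organic/drug-like molecules.
.atomic_masses <- c(
  H  = 1.008,    He = 4.002602,
  Li = 6.94,     Be = 9.0121831, B  = 10.81,    C  = 12.011,
  N  = 14.007,   O  = 15.999,    F  = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815384,  Si = 28.085,
  P  = 30.973761998, S = 32.06,  Cl = 35.45,    Ar = 39.95,
  K  = 39.0983,  Ca = 40.078,
  Br = 79.904,   I  = 126.90447
)

#' Standard atomic weight of an element
#'
#' @param symbol character vector of element symbols (case sensitive, e.g.
#'   `"Cl"`). At minimum H, C, N, O, F, P, S, Cl and Br are supported.
#' @return numeric vector of masses in amu.
#' @examples
#' atomic_mass("H")
#' atomic_mass(c("C", "O"))
#' @export
atomic_mass <- function(symbol) {
  m <- .atomic_masses[symbol]
  if (anyNA(m)) {
    bad <- unique(symbol[is.na(m)])
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

#' Element symbols with a registered atomic mass
#' @return Character vector of supported element symbols.
#' @export
supported_elements <- function() names(.atomic_masses)
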