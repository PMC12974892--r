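#' Physical constants and unit conversion
#'
#' All internal computation in emler is done in Hartree atomic units
#' (bohr, hartree, elementary charge); file and user-facing interfaces use
#' angstrom, kcal/mol and elementary charge, following molecular-dynamics
#' conventions.
#'
#' @name emler-units
#' @keywords internal
NULL

# CODATA-style fixed constants used throughout the package.
BOHR_TO_ANGSTROM <- 0.52917721092
HARTREE_TO_KCALMOL <- 627.509474

# Boltzmann constant in kcal/mol/K.
KB_KCALMOL <- 0.0019872041

# Acceleration conversion: force [kcal/mol/A] over mass [amu] -> [A/fs^2].
ACC_KCALMOL_A_AMU <- 4.184e-4

.unit_table <- list(
  bohr = c(length = 1),
  angstrom = c(length = 1 / 0.52917721092),
  hartree = c(energy = 1),
  `kcal/mol` = c(energy = 1 / 627.509474),
  e = c(charge = 1)
)

#' Convert between the package's supported units
#'
#' Supported units are `"bohr"`, `"angstrom"` (alias `"A"`), `"hartree"`,
#' `"kcal/mol"` and `"e"`. Conversion is only defined between units of the
#' same dimension; round trips are exact to better than 1e-12 relative.
#'
#' @param value numeric vector to convert.
#' @param from,to unit names.
#' @return converted numeric vector.
#' @examples
#' convert_units(1, "hartree", "kcal/mol")
#' convert_units(1, "bohr", "angstrom")
#' @export
convert_units <- function(value, from, to) {
  norm <- function(u) {
    u <- tolower(u)
    if (u %in% c("a", "ang", "angstrom", "å")) u <- "angstrom"
    if (!u %in% names(.unit_table)) {
      stop("unknown unit: '", u, "' (supported: ",
           paste(names(.unit_table), collapse = ", "), ")", call. = FALSE)
    }
    u
  }
  from <- norm(from)
  to <- norm(to)
  fu <- .unit_table[[from]]
  tu <- .unit_table[[to]]
  if (names(fu) != names(tu)) {
    stop("incompatible units: '", from, "' (", names(fu), ") and '",
         to, "' (", names(tu), ")", call. = FALSE)
  }
  value * (fu[[1]] / tu[[1]])
}
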