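## Element data used throughout: atomic numbers, covalent radii (Angstrom),
## and the valence model that backs bond-order perception.

.ELEMENTS <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
           "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
           "Ga", "Ge", "As", "Se", "Br", "Kr", "Rh", "Pd", "Ag", "I",
           "Pt", "Au")
  z <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
         11, 12, 13, 14, 15, 16, 17, 18, 19, 20,
         21, 22, 23, 24, 25, 26, 27, 28, 29, 30,
         31, 32, 33, 34, 35, 36, 45, 46, 47, 53,
         78, 79)
  ## Pyykko/Atsumi single-bond covalent radii (rounded)
  rcov <- c(0.32, 0.46, 1.33, 1.02, 0.85, 0.75, 0.71, 0.63, 0.64, 0.67,
            1.55, 1.39, 1.26, 1.16, 1.11, 1.03, 0.99, 0.96, 1.96, 1.71,
            1.48, 1.36, 1.34, 1.22, 1.19, 1.16, 1.11, 1.10, 1.12, 1.18,
            1.24, 1.21, 1.21, 1.16, 1.14, 1.17, 1.25, 1.20, 1.28, 1.33,
            1.23, 1.24)
  data.frame(symbol = sym, Z = z, rcov = rcov, stringsAsFactors = FALSE)
})

.TRANSITION_METALS <- c("Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu",
                        "Zn", "Rh", "Pd", "Ag", "Pt", "Au")

#' Atomic number of an element symbol
#' @param symbol character vector of element symbols (e.g. "C", "Co").
#' @return integer vector of atomic numbers.
#' @examples atomicNumber(c("H", "Co"))
#' @export
atomicNumber <- function(symbol) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(i)) stop("unknown element symbol: ",
                     paste(symbol[is.na(i)], collapse = ", "))
  .ELEMENTS$Z[i]
}

.covalentRadius <- function(symbol) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(i)) stop("unknown element symbol: ",
                     paste(symbol[is.na(i)], collapse = ", "))
  .ELEMENTS$rcov[i]
}

.isMetal <- function(symbol) symbol %in% .TRANSITION_METALS

## Allowed (sum of bond orders -> formal charges) per main-group element.
## Each entry: named list, names = bond-order sum, values = integer vector of
## admissible formal charges at that valence. Radicals (odd electron on an
## atom) are excluded by default; allowRadicals adds charge-0 entries one
## below/above the normal valence.
.VALENCE_TABLE <- list(
  H  = list(`0` = c(-1L, 1L), `1` = 0L),
  B  = list(`3` = 0L, `4` = -1L),
  C  = list(`3` = c(-1L, 1L), `4` = 0L),
  N  = list(`2` = -1L, `3` = 0L, `4` = 1L),
  O  = list(`1` = -1L, `2` = 0L, `3` = 1L),
  P  = list(`3` = 0L, `4` = 1L, `5` = 0L),
  S  = list(`1` = -1L, `2` = 0L, `3` = 1L, `4` = 0L, `6` = 0L),
  F  = list(`0` = -1L, `1` = 0L),
  Cl = list(`0` = -1L, `1` = 0L, `2` = 1L),
  Br = list(`0` = -1L, `1` = 0L, `2` = 1L),
  I  = list(`0` = -1L, `1` = 0L, `2` = 1L)
)

## maximum order a single bond between two elements may take in perception
.maxBondOrder <- function(e1, e2) {
  multi <- c("C", "N", "O", "S", "P")
  if (e1 %in% multi && e2 %in% multi) 3L else 1L
}
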