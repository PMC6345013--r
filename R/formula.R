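# Elemental formulas in Hill notation (integer counts, no embedded charges).

ATOMIC_WEIGHTS <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Na = 22.990, K = 39.098, Fe = 55.845, Mg = 24.305, Ca = 40.078,
  Cl = 35.45, Zn = 65.38, Mn = 54.938, Cu = 63.546, Se = 78.971
)

#' Parse an elemental formula
#'
#' Parses a Hill-notation elemental formula such as `"C23H38N7O17P3S"` into a
#' named integer vector of element counts. Only integer counts are supported;
#' charge is never embedded in the formula and is stored separately on the
#' metabolite.
#'
#' @param formula A single formula string. The empty string (or `NA`) denotes
#'   an unknown formula and yields an empty vector.
#' @return A named integer vector of element counts (possibly empty).
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("HO4P")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("`formula` must be a single string")
  if (is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (paste(pieces, collapse = "") != formula) {
    stop("unparseable formula string: '", formula, "'")
  }
  elems <- sub("[0-9]*$", "", pieces)
  counts <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                              sub("^[A-Za-z]+", "", pieces), "1"))
  out <- tapply(counts, elems, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Molar mass of a formula
#'
#' @param formula Formula string (Hill notation).
#' @return Molar mass in g/mmol (i.e. g/mol divided by 1000), the unit used
#'   for biomass coefficients. `NA` for an empty formula.
#' @examples
#' molar_mass("C6H14O6") # mannitol, ~0.18217 g/mmol
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(NA_real_)
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0L) {
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(ATOMIC_WEIGHTS[names(counts)] * counts) / 1000
}
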