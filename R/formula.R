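#' Standard atomic masses used throughout the package
#'
#' A single fixed table of atomic masses (g/mol) keeps every elemental
#' computation in the package consistent. Values follow the conventional
#' abridged standard atomic weights.
#'
#' @format Named numeric vector, element symbol -> g/mol.
#' @export
atomic_masses <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06,
  P = 30.974, Fe = 55.845, Mg = 24.305, K = 39.098, Na = 22.990,
  Ca = 40.078, Cl = 35.45, Zn = 65.38, Mn = 54.938, Cu = 63.546
)

#' Parse a chemical formula string into element counts
#'
#' Accepts formulas with fractional subscripts such as the elemental biomass
#' composition `"C3.69H6.76O2.66N0.25S0.010"`. An `NA` or empty string
#' returns `NULL`, the explicit "no formula" flag carried by pseudo-species
#' (salts, biomass aggregates, bookkeeping protons).
#'
#' @param x Formula string, e.g. `"C6H12O6"`.
#' @return Named numeric vector element -> count, or `NULL` for pseudo-species.
#' @export
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C3.69H6.76O2.66N0.25S0.010")
parse_formula <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  if (is.numeric(x)) stop("formula must be a string, not numeric")
  x <- as.character(x)[1L]
  if (is.na(x) || !nzchar(trimws(x))) return(NULL)
  x <- gsub("[[:space:]]", "", x)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x, perl = TRUE)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(x)) {
    stop(sprintf("cannot parse formula '%s'", x))
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(ct == "", 1, suppressWarnings(as.numeric(ct)))
  if (anyNA(ct)) stop(sprintf("cannot parse formula '%s'", x))
  out <- tapply(ct, el, sum)
  structure(as.numeric(out), names = names(out))
}

#' Deparse element counts back into a formula string
#' @param counts Named numeric vector element -> count.
#' @return Character scalar (`NA` for `NULL` input).
#' @export
deparse_formula <- function(counts) {
  if (is.null(counts)) return(NA_character_)
  counts <- counts[counts != 0]
  if (!length(counts)) return("")
  ord <- c(intersect(c("C", "H", "O", "N", "S", "P"), names(counts)),
           sort(setdiff(names(counts), c("C", "H", "O", "N", "S", "P"))))
  paste0(ord, ifelse(counts[ord] == 1, "", format(counts[ord], trim = TRUE,
                                                  scientific = FALSE)),
         collapse = "")
}

#' Number of carbon atoms in a formula
#' @param formula Formula string or parsed count vector.
#' @return Carbon count (0 when carbon absent), NA for pseudo-species.
#' @export
carbon_count <- function(formula) {
  f <- if (is.character(formula) || is.null(formula) ||
           (length(formula) == 1L && is.na(formula))) parse_formula(formula)
       else formula
  if (is.null(f)) return(NA_real_)
  if ("C" %in% names(f)) unname(f[["C"]]) else 0
}

#' Molar mass of a formula
#' @param formula Formula string or parsed count vector.
#' @return g/mol.
#' @export
molar_mass <- function(formula) {
  f <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(f)) stop("cannot compute a molar mass for a species without formula")
  unknown <- setdiff(names(f), names(atomic_masses))
  if (length(unknown)) {
    stop(sprintf("no atomic mass tabulated for element(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  sum(f * atomic_masses[names(f)])
}

#' Molar mass per mole of carbon
#'
#' Mass of one C-mole of a compound: the molar mass divided by the carbon
#' subscript. For the elemental biomass composition of *Fibrobacter
#' succinogenes* S85, C3.69H6.76O2.66N0.25S0.010, this evaluates to about
#' 26.4 g per mol of carbon (the published value is 26.401 g/mol_C; the
#' fixed atomic-mass table reproduces it to within 0.2%).
#'
#' @param formula Formula string or parsed count vector; must contain carbon.
#' @return g per mol of carbon.
#' @export
#' @examples
#' molar_mass_per_carbon("C3.69H6.76O2.66N0.25S0.010")
molar_mass_per_carbon <- function(formula) {
  f <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(f)) stop("species has no formula")
  nc <- if ("C" %in% names(f)) f[["C"]] else 0
  if (nc <= 0) stop("formula contains no carbon; mass per C-mole undefined")
  molar_mass(f) / nc
}

#' Elemental composition of biomass used for unit conversions
#'
#' The elemental composition of *F. succinogenes* S85 biomass,
#' C3.69H6.76O2.66N0.25S0.010, and the derived mass per C-mole used to
#' convert between molar (C-mol) and gram biomass bookkeeping.
#' @export
biomass_formula <- "C3.69H6.76O2.66N0.25S0.010"

#' @rdname biomass_formula
#' @export
biomass_g_per_mol_c <- 26.401
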