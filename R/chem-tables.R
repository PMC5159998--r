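# Monoisotopic atomic constants and amino-acid residue compositions.
# These tables back every mass computed by the package; nothing else in the
# code base carries numeric mass constants.

# CODATA/IUPAC monoisotopic masses, Da.
.ATOMIC_MASSES <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 5.48579909e-4

# Residue composition = amino acid minus one water.
.RESIDUE_COMPOSITIONS <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1)
)

.WATER <- c(H = 2, O = 1)

#' Monoisotopic atomic masses
#'
#' Returns the table of monoisotopic atomic masses (Da) used throughout the
#' package, covering C, H, N, O and S.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @seealso [mass_constants()] for the proton, hydrogen-atom and electron
#'   masses.
#' @export
#' @examples
#' atomic_masses()
atomic_masses <- function() .ATOMIC_MASSES

#' Charge-carrier and electron mass constants
#'
#' @return Named numeric vector with elements `proton`, `hydrogen` (neutral H
#'   atom) and `electron`, all in Da.
#' @export
mass_constants <- function() {
  c(
    proton = .PROTON_MASS,
    hydrogen = unname(.ATOMIC_MASSES["H"]),
    electron = .ELECTRON_MASS
  )
}

#' Residue elemental compositions
#'
#' Elemental composition (amino acid minus one water) for each of the 20
#' proteinogenic residues, keyed by one-letter code.
#'
#' @return Named list of named integer vectors (element -> atom count).
#' @export
#' @examples
#' residue_compositions()[["G"]] # glycine residue, C2H3NO
residue_compositions <- function() .RESIDUE_COMPOSITIONS

#' Residue monoisotopic masses
#'
#' @return Named numeric vector of the 20 residue masses in Da
#'   (e.g. Gly 57.02146).
#' @export
residue_masses <- function() {
  vapply(.RESIDUE_COMPOSITIONS, monoisotopic_mass, numeric(1))
}

# ---- elemental composition arithmetic ---------------------------------------

.as_composition <- function(x) {
  if (length(x) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("an elemental composition must be a named vector of atom counts")
  }
  storage.mode(x) <- "double"
  x
}

#' Add (or subtract) elemental compositions
#'
#' Element-wise `a + coef * b`. Compositions are named integer vectors
#' (element symbol -> count). Subtraction that would drive any count below
#' zero is an error unless `allow_negative = TRUE` (used internally for
#' modification deltas, which are signed).
#'
#' @param a,b Named numeric vectors of atom counts.
#' @param coef Multiplier applied to `b` (use `-1` to subtract).
#' @param allow_negative Permit negative counts in the result?
#' @return Named numeric vector of atom counts.
#' @export
#' @examples
#' comp_add(c(C = 2, H = 3, N = 1, O = 1), c(H = 2, O = 1))
comp_add <- function(a, b, coef = 1, allow_negative = FALSE) {
  a <- .as_composition(a)
  b <- .as_composition(b)
  elements <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(elements)), elements)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + coef * b
  if (!allow_negative && any(out < 0)) {
    bad <- names(out)[out < 0]
    stop(
      "composition arithmetic produced a negative count for element(s): ",
      paste(bad, collapse = ", ")
    )
  }
  out[out != 0]
}

#' Format an elemental composition as a formula string
#'
#' Hill-like order: C first, then H, then the remaining elements
#' alphabetically. Unit counts are printed without a digit.
#'
#' @param comp Named numeric vector of non-negative atom counts.
#' @return Single formula string, e.g. `"C39H56N8O16"`.
#' @export
#' @examples
#' format_formula(c(C = 39, H = 56, N = 8, O = 16))
format_formula <- function(comp) {
  comp <- .as_composition(comp)
  comp <- comp[comp != 0]
  if (any(comp < 0)) stop("cannot format a composition with negative counts")
  elements <- names(comp)
  rest <- sort(setdiff(elements, c("C", "H")))
  ordered <- c(intersect(c("C", "H"), elements), rest)
  counts <- comp[ordered]
  paste0(ordered, ifelse(counts == 1, "", format(counts, trim = TRUE)),
         collapse = "")
}

#' Parse a formula string into an elemental composition
#'
#' @param x Formula string such as `"C39H56N8O16"`.
#' @return Named numeric vector of atom counts.
#' @export
#' @examples
#' parse_formula("C34H52N8O20")
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L || sum(nchar(tokens)) != nchar(x)) {
    stop("cannot parse formula string: '", x, "'")
  }
  elements <- sub("[0-9]+$", "", tokens)
  counts <- as.numeric(sub("^[A-Za-z]+", "", tokens))
  counts[is.na(counts)] <- 1
  out <- tapply(counts, elements, sum)
  stats::setNames(as.numeric(out), names(out))
}
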