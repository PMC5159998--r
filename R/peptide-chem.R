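# Mass arithmetic for linear and head-to-tail cyclic peptides.

#' Define a composition-level peptide modification
#'
#' Modifications are site-agnostic: only the net elemental delta matters.
#' Deltas may be signed (tryptathionine removes two hydrogens).
#'
#' @param name Modification name.
#' @param delta Named numeric vector of signed atom-count changes.
#' @param max_per_peptide Maximum copies allowed on one peptide.
#' @return A `peptide_mod` object.
#' @export
#' @examples
#' peptide_mod("methylation", c(C = 1, H = 2), max_per_peptide = 2)
peptide_mod <- function(name, delta, max_per_peptide = 1L) {
  stopifnot(is.character(name), length(name) == 1L)
  delta <- .as_composition(delta)
  max_per_peptide <- as.integer(max_per_peptide)
  stopifnot(max_per_peptide >= 1L)
  structure(
    list(name = name, delta = delta, max_per_peptide = max_per_peptide),
    class = "peptide_mod"
  )
}

#' @rdname peptide_mod
#' @details `mod_hydroxylation()` adds one oxygen (+15.994915 Da), at most
#'   four per peptide, by analogy with the amatoxins and phallotoxins which
#'   carry up to four hydroxylations. `mod_tryptathionine()` removes two
#'   hydrogens (-2.015650 Da), the net change of forming the Trp-Cys
#'   cross-bridge.
#' @export
mod_hydroxylation <- function() {
  peptide_mod("hydroxylation", c(O = 1), max_per_peptide = 4L)
}

#' @rdname peptide_mod
#' @export
mod_tryptathionine <- function() {
  peptide_mod("tryptathionine", c(H = -2), max_per_peptide = 1L)
}

# Normalise the `mods` argument: a list whose elements are either
# `peptide_mod` objects (count 1) or `list(mod, count)` pairs.
.normalise_mods <- function(mods) {
  if (length(mods) == 0L) return(list())
  lapply(mods, function(m) {
    if (inherits(m, "peptide_mod")) {
      list(mod = m, count = 1L)
    } else if (is.list(m) && length(m) == 2L) {
      names(m) <- c("mod", "count")
      stopifnot(inherits(m$mod, "peptide_mod"))
      m$count <- as.integer(m$count)
      m
    } else {
      stop("each modification must be a peptide_mod or a list(mod, count) pair")
    }
  })
}

.split_residues <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("peptide sequence must be non-empty")
  residues <- strsplit(seq, "", fixed = TRUE)[[1]]
  known <- names(.RESIDUE_COMPOSITIONS)
  bad <- which(!(residues %in% known))
  if (length(bad) > 0L) {
    stop(
      "unknown residue code '", residues[bad[1]], "' at position ", bad[1],
      " of '", seq, "'"
    )
  }
  residues
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions over the sequence: a linear peptide gains one
#' water (its termini), a head-to-tail cyclic peptide does not. Modifications
#' are applied as composition-level deltas.
#'
#' @param seq Amino-acid sequence (standard one-letter codes).
#' @param topology `"cyclic"` (head-to-tail macrocycle, the default here
#'   since mature MSDIN products are cyclic) or `"linear"`.
#' @param mods List of modifications: `peptide_mod` objects or
#'   `list(mod, count)` pairs. Counts above `max_per_peptide` are an error.
#' @return Named numeric vector of atom counts.
#' @export
#' @examples
#' format_formula(peptide_composition("ISDPTAYP", "cyclic",
#'   mods = list(list(mod_hydroxylation(), 3))))
peptide_composition <- function(seq, topology = c("cyclic", "linear"),
                                mods = list()) {
  topology <- match.arg(topology)
  residues <- .split_residues(seq)
  if (length(residues) < 2L && topology == "cyclic") {
    stop("a cyclic peptide needs at least 2 residues")
  }
  comp <- stats::setNames(numeric(0), character(0))
  for (r in residues) comp <- comp_add(comp, .RESIDUE_COMPOSITIONS[[r]])
  if (topology == "linear") comp <- comp_add(comp, .WATER)
  for (m in .normalise_mods(mods)) {
    if (m$count > m$mod$max_per_peptide) {
      stop(
        "modification '", m$mod$name, "' count ", m$count,
        " exceeds max_per_peptide ", m$mod$max_per_peptide
      )
    }
    if (m$count > 0L) comp <- comp_add(comp, m$mod$delta, coef = m$count)
  }
  comp
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Named numeric vector of atom counts.
#' @return Mass in Da. The empty composition has mass 0.
#' @export
#' @examples
#' monoisotopic_mass(c(H = 2, O = 1)) # water, 18.010565
monoisotopic_mass <- function(comp) {
  comp <- .as_composition(comp)
  if (length(comp) == 0L) return(0)
  unknown <- setdiff(names(comp), names(.ATOMIC_MASSES))
  if (length(unknown) > 0L) {
    stop(
      "element(s) absent from the atomic mass table: ",
      paste(unknown, collapse = ", ")
    )
  }
  sum(comp * .ATOMIC_MASSES[names(comp)])
}

#' m/z of a protonated ion
#'
#' `(neutral_mass + charge * adduct) / charge`. The default adduct is the
#' proton mass (1.007276 Da); `convention = "h-atom"` uses the neutral
#' hydrogen-atom mass instead (the two differ by the electron mass,
#' about 0.7 ppm at m/z 800 -- both conventions occur in the literature's
#' printed 4-decimal values).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (vectorised).
#' @param charge Integer charge state, >= 1.
#' @param convention `"proton"` or `"h-atom"`.
#' @return m/z value(s).
#' @export
#' @examples
#' mz_protonated(821.41121) # cyclo(SFFFPVP), z = 1
mz_protonated <- function(neutral_mass, charge = 1L,
                          convention = c("proton", "h-atom")) {
  convention <- match.arg(convention)
  charge <- as.integer(charge)
  if (length(charge) != 1L || is.na(charge) || charge < 1L) {
    stop("charge must be a single integer >= 1")
  }
  adduct <- if (convention == "proton") .PROTON_MASS else .ATOMIC_MASSES[["H"]]
  (neutral_mass + charge * adduct) / charge
}

#' Relative mass error in parts per million
#'
#' `|observed - theoretical| / theoretical * 1e6`. Reports are conventionally
#' rounded to one decimal; full precision is returned here.
#'
#' @param observed,theoretical m/z values (vectorised; recycled).
#' @return Absolute ppm error(s).
#' @export
#' @examples
#' ppm_error(822.4218, 822.4190) # ~3.4 ppm
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  abs(observed - theoretical) / theoretical * 1e6
}
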