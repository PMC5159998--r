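# Core-region statistics: lengths, observed-vs-expected amino acid usage,
# hydrophobic bias, and between-species core overlap.

#' A labelled set of core peptides
#'
#' @param cores Character vector of core sequences.
#' @param label Set label (e.g. a species name).
#' @param dedupe Collapse to unique core strings?
#' @return A `core_set` list.
#' @export
core_set <- function(cores, label = "cores", dedupe = FALSE) {
  stopifnot(is.character(cores))
  for (core in cores) .split_residues(core)
  if (dedupe) cores <- unique(cores)
  structure(list(label = label, cores = cores, dedupe = dedupe),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("Core set '", x$label, "': ", length(x$cores), " cores",
      if (x$dedupe) " (deduplicated)", "\n", sep = "")
  invisible(x)
}

#' Length summary of a core set
#'
#' @param cs A [core_set()].
#' @return List: `n`, `mean`, `mode` (smallest modal length on ties),
#'   `min`, `max`.
#' @export
#' @examples
#' length_stats(core_set(c("IWGIGC", "AWLATCPX", "ISDPTAYP", "FFFPPFFIPP")))
length_stats <- function(cs) {
  stopifnot(inherits(cs, "core_set"))
  if (length(cs$cores) == 0L) stop("empty core set")
  lens <- nchar(cs$cores)
  tab <- table(lens)
  modes <- as.integer(names(tab)[tab == max(tab)])
  list(n = length(lens), mean = mean(lens), mode = min(modes),
       min = min(lens), max = max(lens))
}

#' Observed vs expected amino-acid usage in core regions
#'
#' Observed counts pool all residues across the set's cores (duplicates per
#' the set's dedupe flag). Expected counts distribute the same total over
#' the supplied background. The background for the "expected" side of such
#' comparisons is not standardised; the default is uniform (1/20), and any
#' user-supplied distribution (e.g. proteome-wide frequencies) may be given
#' instead. The background id is recorded on the result.
#'
#' @param cs A [core_set()].
#' @param background `"uniform"` or a named numeric distribution over the 20
#'   amino acids summing to 1 (tolerance 1e-6).
#' @param exclude_terminal Drop the last residue of each core (the conserved
#'   POPB transpeptidation Pro) from the counts? Default `FALSE`: the
#'   terminal Pro is part of the mature cyclic product.
#' @return Data frame: aa, observed, expected, ratio; attribute
#'   `background_id`.
#' @export
aa_bias <- function(cs, background = "uniform", exclude_terminal = FALSE) {
  stopifnot(inherits(cs, "core_set"))
  aas <- names(.RESIDUE_COMPOSITIONS)
  if (identical(background, "uniform")) {
    bg <- stats::setNames(rep(1 / 20, 20L), aas)
    bg_id <- "uniform"
  } else {
    bg <- background[aas]
    if (any(is.na(bg))) stop("background must cover all 20 amino acids")
    if (abs(sum(bg) - 1) > 1e-6) stop("background must sum to 1")
    bg_id <- "user-supplied"
  }
  cores <- cs$cores
  if (exclude_terminal) cores <- substr(cores, 1L, nchar(cores) - 1L)
  residues <- unlist(strsplit(cores, "", fixed = TRUE), use.names = FALSE)
  observed <- table(factor(residues, levels = aas))
  total <- sum(observed)
  expected <- bg * total
  out <- data.frame(
    aa = aas,
    observed = as.integer(observed),
    expected = as.numeric(expected),
    ratio = ifelse(expected > 0, as.integer(observed) / as.numeric(expected),
                   NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "background_id") <- bg_id
  attr(out, "label") <- cs$label
  out
}

#' Default hydrophobicity classes
#'
#' Aliphatic and aromatic side chains (plus Gly, Cys, Pro) are classed
#' hydrophobic; the remainder polar/charged. Overridable in
#' [hydrophobic_bias()].
#'
#' @return Named character vector aa -> class.
#' @export
default_aa_classes <- function() {
  hydrophobic <- c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W")
  aas <- names(.RESIDUE_COMPOSITIONS)
  stats::setNames(
    ifelse(aas %in% hydrophobic, "hydrophobic", "polar/charged"), aas)
}

#' Aggregate amino-acid bias by hydrophobicity class
#'
#' @param bt A bias table from [aa_bias()].
#' @param classes Named character vector mapping every amino acid to a
#'   class; see [default_aa_classes()].
#' @return List: `table` (class, observed, expected, ratio) and
#'   `direction`, the class (if any) with observed/expected ratio > 1.
#' @export
hydrophobic_bias <- function(bt, classes = default_aa_classes()) {
  missing_aa <- setdiff(bt$aa, names(classes))
  if (length(missing_aa) > 0L) {
    stop("unclassified residue(s): ", paste(missing_aa, collapse = ", "))
  }
  cls <- classes[bt$aa]
  obs <- tapply(bt$observed, cls, sum)
  exp_ <- tapply(bt$expected, cls, sum)
  tab <- data.frame(
    class = names(obs),
    observed = as.numeric(obs),
    expected = as.numeric(exp_),
    ratio = as.numeric(obs) / as.numeric(exp_),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab, direction = tab$class[tab$ratio > 1])
}

#' Shared and species-specific cores between two sets
#'
#' Exact string intersection of two (deduplicated) core sets, as used to ask
#' which predicted cyclic peptides two genomes hold in common.
#'
#' @param a,b [core_set()] objects (deduplicated internally).
#' @return List: `shared`, `unique_to_a`, `unique_to_b` plus their counts.
#' @export
#' @examples
#' compare_sets(
#'   core_set(c("IWGIGCNP", "AWLVDCP", "ISDPTAYP", "SFFFPVP"), "Ap"),
#'   core_set(c("IWGIGCNP", "AWLVDCP", "ISDPTAYP", "IIFEPIIP"), "Ab"))$n_shared
compare_sets <- function(a, b) {
  stopifnot(inherits(a, "core_set"), inherits(b, "core_set"))
  ua <- unique(a$cores)
  ub <- unique(b$cores)
  shared <- intersect(ua, ub)
  list(
    shared = shared,
    unique_to_a = setdiff(ua, ub),
    unique_to_b = setdiff(ub, ua),
    n_shared = length(shared),
    n_unique_to_a = length(setdiff(ua, ub)),
    n_unique_to_b = length(setdiff(ub, ua))
  )
}

#' Observed vs expected scatter plot of a bias table
#'
#' Mirrors the standard observed-against-expected presentation with the
#' identity (slope = 1, no bias) line, points coloured by hydrophobicity
#' class. Requires ggplot2.
#'
#' @param bt A bias table from [aa_bias()].
#' @param classes Named class map, see [default_aa_classes()].
#' @return A ggplot object.
#' @export
plot_aa_bias <- function(bt, classes = default_aa_classes()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_aa_bias requires the ggplot2 package")
  }
  bt$class <- classes[bt$aa]
  ggplot2::ggplot(bt, ggplot2::aes(x = expected, y = observed,
                                   colour = class, label = aa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_text() +
    ggplot2::labs(x = "Expected count", y = "Observed count",
                  colour = NULL,
                  title = attr(bt, "label")) +
    ggplot2::theme_minimal()
}
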