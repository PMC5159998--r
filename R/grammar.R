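# MSDIN precursor grammar: partition into leader/core/follower and validate
# against the POPB processing rules.

#' Grammar of MSDIN precursor peptides
#'
#' MSDIN precursors are 33-37 aa: a 10-aa leader ending in Pro (the POPB
#' cleavage site), a variable 6-10-aa core that becomes the mature cyclic
#' peptide (usually ending in Pro, the transpeptidation site), and a 17-aa
#' follower whose strong consensus ends Leu-Cys. Leaders start with the
#' canonical "MSDIN" or a single-residue variant of it.
#'
#' @param leader_len,follower_len,core_min,core_max Segment lengths (aa).
#' @param canonical_leader5 The canonical first five leader residues.
#' @param leader5_variants Single-mismatch leader starts observed in
#'   annotated genes.
#' @param max_leader_mismatches Hamming distance to `canonical_leader5` below
#'   which an unlisted leader is still called `near-variant`.
#' @param terminal_residues Residues accepted at the precursor C-terminus
#'   (Cys is canonical; Ser substitutes in several genes).
#' @param penultimate_residue Expected residue before the terminus (Leu).
#' @return A `grammar_config` list; `precursor_min`/`precursor_max` are
#'   derived from the segment lengths.
#' @export
grammar_config <- function(leader_len = 10L,
                           follower_len = 17L,
                           core_min = 6L,
                           core_max = 10L,
                           canonical_leader5 = "MSDIN",
                           leader5_variants = c("MSDMN", "MSDVN", "MSDIK",
                                                "MSEIN", "MSDTN", "MSNIN"),
                           max_leader_mismatches = 1L,
                           terminal_residues = c("C", "S"),
                           penultimate_residue = "L") {
  cfg <- list(
    leader_len = as.integer(leader_len),
    follower_len = as.integer(follower_len),
    core_min = as.integer(core_min),
    core_max = as.integer(core_max),
    canonical_leader5 = canonical_leader5,
    leader5_variants = leader5_variants,
    max_leader_mismatches = as.integer(max_leader_mismatches),
    terminal_residues = terminal_residues,
    penultimate_residue = penultimate_residue
  )
  cfg$precursor_min <- cfg$leader_len + cfg$core_min + cfg$follower_len
  cfg$precursor_max <- cfg$leader_len + cfg$core_max + cfg$follower_len
  structure(cfg, class = "grammar_config")
}

#' Partition a precursor into leader, core and follower
#'
#' The split is arithmetic: leader = first `leader_len` residues, follower =
#' last `follower_len`, core = remainder. Partition succeeds iff the implied
#' core length is within `[core_min, core_max]`; on failure the (possibly
#' non-positive) computed core length is still reported, which is how
#' coreless MSDIN-like loci surface.
#'
#' @param seq Precursor amino-acid sequence.
#' @param cfg A [grammar_config()].
#' @return An `msdin_precursor` list: `raw`, `ok`, `core_length`, and (when
#'   `ok`) `leader`, `core`, `follower`.
#' @export
#' @examples
#' p <- partition_precursor(paste0("MSDINATRLP", "IWGIGCNP", "CVGDDVNRLLC"))
#' p$ok # FALSE: 29 aa is outside the 33-37 window
partition_precursor <- function(seq, cfg = grammar_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  core_length <- n - cfg$leader_len - cfg$follower_len
  ok <- core_length >= cfg$core_min && core_length <= cfg$core_max
  out <- list(
    raw = seq,
    ok = ok,
    core_length = as.integer(core_length),
    leader = NA_character_,
    core = NA_character_,
    follower = NA_character_
  )
  if (ok) {
    out$leader <- substr(seq, 1L, cfg$leader_len)
    out$core <- substr(seq, cfg$leader_len + 1L, cfg$leader_len + core_length)
    out$follower <- substr(seq, n - cfg$follower_len + 1L, n)
  }
  structure(out, class = "msdin_precursor")
}

#' @export
print.msdin_precursor <- function(x, ...) {
  if (x$ok) {
    cat("MSDIN precursor (", nchar(x$raw), " aa): ",
        x$leader, " | ", x$core, " | ", x$follower, "\n", sep = "")
  } else {
    cat("MSDIN-like sequence (", nchar(x$raw),
        " aa): partition failed, implied core length ", x$core_length,
        "\n", sep = "")
  }
  invisible(x)
}

.hamming5 <- function(x, target) {
  xm <- strsplit(x, "", fixed = TRUE)
  tv <- strsplit(target, "", fixed = TRUE)[[1]]
  vapply(xm, function(ch) sum(ch[seq_along(tv)] != tv), numeric(1))
}

# Vectorised classification of 5-mer leader starts.
.classify_leader5 <- function(first5, cfg) {
  cls <- rep("divergent", length(first5))
  d <- .hamming5(first5, cfg$canonical_leader5)
  d[is.na(d)] <- Inf
  cls[d <= cfg$max_leader_mismatches] <- "near-variant"
  cls[first5 %in% cfg$leader5_variants] <- "listed-variant"
  cls[first5 == cfg$canonical_leader5] <- "canonical"
  cls
}

#' Classify a 10-aa leader by its first five residues
#'
#' @param leader A 10-residue leader sequence.
#' @param cfg A [grammar_config()].
#' @return One of `"canonical"`, `"listed-variant"`, `"near-variant"`,
#'   `"divergent"`. Residues 6-10 never influence the class.
#' @export
#' @examples
#' classify_leader("MSDINATRLP") # canonical
#' classify_leader("MSGINAARLP") # near-variant (1 mismatch, unlisted)
classify_leader <- function(leader, cfg = grammar_config()) {
  stopifnot(is.character(leader), length(leader) == 1L)
  if (nchar(leader) != cfg$leader_len) {
    stop("leader must be exactly ", cfg$leader_len, " residues, got ",
         nchar(leader))
  }
  .classify_leader5(substr(leader, 1L, 5L), cfg)
}

#' Does a core have tryptathionine potential?
#'
#' The Trp-Cys cross-bridge of the amatoxins and phallotoxins requires at
#' least one Trp and one Cys in the core.
#'
#' @param core Core sequence(s); vectorised.
#' @return Logical vector.
#' @export
#' @examples
#' tryptathionine_potential(c("AWLAECP", "SFFFPIP"))
tryptathionine_potential <- function(core) {
  if (any(!nzchar(core))) stop("core must be non-empty")
  grepl("W", core, fixed = TRUE) & grepl("C", core, fixed = TRUE)
}

#' Validate a partitioned precursor against the POPB processing rules
#'
#' Flags the features POPB processing depends on: the leader-terminal Pro
#' (cleavage), the core-terminal Pro (transpeptidation; retained in the
#' product), the terminal Cys -- or its observed substitute Ser -- and the
#' penultimate Leu. `processable` requires both Pro residues, an accepted
#' terminal residue, and an in-window length.
#'
#' @param p An `msdin_precursor` with `p$ok == TRUE` (see
#'   [partition_precursor()]).
#' @param cfg A [grammar_config()].
#' @return One-row data frame of flags plus `leader_class`.
#' @export
validate_precursor <- function(p, cfg = grammar_config()) {
  stopifnot(inherits(p, "msdin_precursor"))
  if (!p$ok) stop("cannot validate a precursor whose partition failed")
  n <- nchar(p$raw)
  terminal <- substr(p$raw, n, n)
  penult <- substr(p$raw, n - 1L, n - 1L)
  leader_end <- substr(p$leader, cfg$leader_len, cfg$leader_len)
  core_end <- substr(p$core, nchar(p$core), nchar(p$core))
  length_ok <- n >= cfg$precursor_min && n <= cfg$precursor_max
  terminal_cys <- terminal == "C"
  terminal_ser <- terminal == "S"
  leader_end_pro <- leader_end == "P"
  core_end_pro <- core_end == "P"
  data.frame(
    leader_class = classify_leader(p$leader, cfg),
    leader_end_pro = leader_end_pro,
    core_end_pro = core_end_pro,
    terminal_cys = terminal_cys,
    terminal_ser = terminal_ser,
    penultimate_leu = penult == cfg$penultimate_residue,
    length_ok = length_ok,
    tryptathionine_potential = tryptathionine_potential(p$core),
    processable = leader_end_pro && core_end_pro &&
      terminal %in% cfg$terminal_residues && length_ok,
    stringsAsFactors = FALSE
  )
}

#' Validate a FASTA file of precursor proteins
#'
#' Reads an amino-acid FASTA, partitions and validates every record, and
#' optionally writes a TSV report (one row per precursor). Sequences outside
#' the length window are reported as MSDIN-like with `partition_ok = FALSE`
#' and `NA` flags rather than dropped.
#'
#' @param path Input FASTA of precursor proteins.
#' @param cfg A [grammar_config()].
#' @param out Optional path for the TSV report.
#' @return Data frame: id, length, partition_ok, core_length, leader, core,
#'   follower and all validation flags.
#' @export
validate_fasta <- function(path, cfg = grammar_config(), out = NULL) {
  seqs <- read_fasta(path, type = "AA")
  rows <- lapply(seq_along(seqs), function(i) {
    p <- partition_precursor(seqs[[i]], cfg)
    base <- data.frame(
      id = names(seqs)[i],
      length = nchar(p$raw),
      partition_ok = p$ok,
      core_length = p$core_length,
      leader = p$leader,
      core = p$core,
      follower = p$follower,
      stringsAsFactors = FALSE
    )
    if (p$ok) {
      cbind(base, validate_precursor(p, cfg))
    } else {
      flags <- validate_precursor(partition_precursor(
        strrep("A", cfg$precursor_min), cfg), cfg)
      flags[1L, ] <- NA
      cbind(base, flags)
    }
  })
  report <- do.call(rbind, rows)
  if (!is.null(out)) write_tsv(report, out)
  report
}
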