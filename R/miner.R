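# Deterministic six-frame miner for the two-exon MSDIN gene structure:
# ATG + leader motif seed, then enumeration of single-intron gene models
# (52-58 bp, GT/GC..AG, interrupting the fourth codon from the end, stop
# codon included in the count).

.CODON_TABLE <- Biostrings::GENETIC_CODE

#' Translate a DNA string with the standard genetic code
#'
#' Trailing bases short of a codon are ignored; codons containing N (or any
#' non-ACGT base) translate to `"X"`. Stops are `"*"`.
#'
#' @param dna DNA string.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_dna("ATGTCTGATATCAATTAA") # MSDIN*
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(dna, starts, starts + 2L)
  aa <- .CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param dna DNA string over A, C, G, T, N.
#' @return Reverse-complemented string.
#' @export
revcomp_dna <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Intron model for MSDIN genes
#'
#' All confirmed MSDIN genes carry a single 52-58 bp spliceosomal intron
#' interrupting the fourth codon from the end of the coding sequence
#' (counting the stop codon), with a GT donor (GC in a minority of genes)
#' and an AG acceptor.
#'
#' @param min_len,max_len Intron length bounds (bp).
#' @param donors Accepted donor dinucleotides; `"GT"` is canonical.
#' @param acceptor Acceptor dinucleotide.
#' @param interrupted_codon_from_end Which codon from the CDS end (stop
#'   included) the intron interrupts.
#' @return An `intron_model` list.
#' @export
intron_model <- function(min_len = 52L, max_len = 58L,
                         donors = c("GT", "GC"), acceptor = "AG",
                         interrupted_codon_from_end = 4L) {
  stopifnot(min_len <= max_len, length(donors) >= 1L)
  structure(
    list(
      min_len = as.integer(min_len),
      max_len = as.integer(max_len),
      donors = donors,
      acceptor = acceptor,
      interrupted_codon_from_end = as.integer(interrupted_codon_from_end)
    ),
    class = "intron_model"
  )
}

#' Miner configuration
#'
#' @param grammar A [grammar_config()].
#' @param intron An [intron_model()].
#' @param allow_phase0 Also enumerate models where the intron falls cleanly
#'   between the third- and fourth-from-last codons (phase 0)? Interrupted
#'   phases (1, 2) are preferred in scoring.
#' @param require_terminal_LC Keep only models whose precursor ends Leu-Cys?
#' @param min_score Minimum model score retained by [mine_genome()].
#' @return A `miner_config` list.
#' @export
miner_config <- function(grammar = grammar_config(),
                         intron = intron_model(),
                         allow_phase0 = TRUE,
                         require_terminal_LC = FALSE,
                         min_score = 0) {
  structure(
    list(
      grammar = grammar,
      intron = intron,
      allow_phase0 = isTRUE(allow_phase0),
      require_terminal_LC = isTRUE(require_terminal_LC),
      min_score = min_score
    ),
    class = "miner_config"
  )
}

# Columns of the gene-model data frame, in stable report order.
.MODEL_COLUMNS <- c(
  "scaffold", "strand", "start", "end",
  "exon1_start", "exon1_end", "intron_start", "intron_end",
  "exon2_start", "exon2_end", "donor", "acceptor", "intron_len", "phase",
  "precursor", "leader", "core", "follower", "leader_class",
  "leader_end_pro", "core_end_pro", "terminal_cys", "terminal_ser",
  "penultimate_leu", "length_ok", "tryptathionine_potential", "processable",
  "terminal_lc", "score"
)

.empty_models <- function() {
  out <- data.frame(
    scaffold = character(0), strand = character(0),
    start = integer(0), end = integer(0),
    exon1_start = integer(0), exon1_end = integer(0),
    intron_start = integer(0), intron_end = integer(0),
    exon2_start = integer(0), exon2_end = integer(0),
    donor = character(0), acceptor = character(0),
    intron_len = integer(0), phase = integer(0),
    precursor = character(0), leader = character(0), core = character(0),
    follower = character(0), leader_class = character(0),
    leader_end_pro = logical(0), core_end_pro = logical(0),
    terminal_cys = logical(0), terminal_ser = logical(0),
    penultimate_leu = logical(0), length_ok = logical(0),
    tryptathionine_potential = logical(0), processable = logical(0),
    terminal_lc = logical(0), score = numeric(0),
    stringsAsFactors = FALSE
  )
  out[, .MODEL_COLUMNS]
}

#' Seed positions for MSDIN gene models
#'
#' Scans all six frames (both strands) for ATG codons whose in-frame
#' translation yields a 10-aa leader window whose first five residues are
#' not `divergent` under [classify_leader()]. This deterministic motif scan
#' replaces permissive homology search as the sensitivity lever.
#'
#' @param seq Scaffold DNA string (A/C/G/T/N, upper case).
#' @param cfg A [miner_config()].
#' @return Data frame: `strand`, `pos` (1-based ATG position on the
#'   strand-oriented sequence), `fwd_pos` (the same position mapped to the
#'   forward strand), `frame`, `leader`, `leader_class`.
#' @export
six_frame_seeds <- function(seq, cfg = miner_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  len <- nchar(seq)
  leader_nt <- 3L * cfg$grammar$leader_len
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_dna(seq)
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    hits <- hits[hits + leader_nt - 1L <= len]
    if (length(hits) == 0L) next
    windows <- substring(s, hits, hits + leader_nt - 1L)
    aa <- matrix("", nrow = length(windows), ncol = cfg$grammar$leader_len)
    for (j in seq_len(cfg$grammar$leader_len)) {
      codons <- substring(windows, 3L * (j - 1L) + 1L, 3L * j)
      col <- .CODON_TABLE[codons]
      col[is.na(col)] <- "X"
      aa[, j] <- col
    }
    leaders <- apply(aa, 1L, paste, collapse = "")
    first5 <- substr(leaders, 1L, 5L)
    cls <- .classify_leader5(first5, cfg$grammar)
    keep <- cls != "divergent" & !grepl("*", first5, fixed = TRUE)
    if (!any(keep)) next
    pos <- hits[keep]
    out[[strand]] <- data.frame(
      strand = strand,
      pos = pos,
      fwd_pos = if (strand == "+") pos else len - pos + 1L,
      frame = (pos - 1L) %% 3L + 1L,
      leader = leaders[keep],
      leader_class = cls[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(
      strand = character(0), pos = integer(0), fwd_pos = integer(0),
      frame = integer(0), leader = character(0),
      leader_class = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Map an interval on the strand-oriented sequence to forward coordinates.
.to_forward <- function(a, b, strand, len) {
  if (strand == "+") c(a, b) else c(len - b + 1L, len - a + 1L)
}

#' Enumerate candidate gene models at one seed
#'
#' For each candidate precursor length N in the grammar window and each
#' intron phase, tries every intron length in the model's range: exon 1 is
#' the first N-3 codons plus `phase` nucleotides, the intron must start with
#' an accepted donor and end with the acceptor, and exon 2 supplies the rest
#' of the interrupted codon plus the final three codons (the stop included).
#' A model is kept when the spliced CDS has no internal stop, ends in a stop,
#' contains no N, and its translation partitions under the grammar.
#'
#' @param scaffold_id Scaffold name carried into the models.
#' @param seq Scaffold DNA string.
#' @param seed One row of [six_frame_seeds()] output (data frame or list).
#' @param cfg A [miner_config()].
#' @return Data frame of gene models (possibly empty), forward-strand
#'   1-based inclusive coordinates, features in transcript order.
#' @export
enumerate_gene_models <- function(scaffold_id, seq, seed,
                                  cfg = miner_config()) {
  len <- nchar(seq)
  strand <- seed$strand[1]
  s <- if (strand == "+") seq else revcomp_dna(seq)
  pos <- seed$pos[1]
  g <- cfg$grammar
  im <- cfg$intron
  phases <- if (cfg$allow_phase0) 0:2 else 1:2
  rows <- list()
  for (N in g$precursor_min:g$precursor_max) {
    for (p in phases) {
      exon1_len <- 3L * (N - 3L) + p
      ds <- pos + exon1_len
      if (ds + im$min_len + 11L - p > len + 1L) next
      donor <- substr(s, ds, ds + 1L)
      if (!(donor %in% im$donors)) next
      for (L in im$min_len:im$max_len) {
        acc <- substr(s, ds + L - 2L, ds + L - 1L)
        if (acc != im$acceptor) next
        exon2_len <- 12L - p
        e2s <- ds + L
        e2e <- e2s + exon2_len - 1L
        if (e2e > len) next
        intron_seq <- substr(s, ds, ds + L - 1L)
        if (grepl("N", intron_seq, fixed = TRUE)) next
        cds <- paste0(substr(s, pos, pos + exon1_len - 1L),
                      substr(s, e2s, e2e))
        if (grepl("N", cds, fixed = TRUE)) next
        aa <- translate_dna(cds)
        if (substr(aa, N + 1L, N + 1L) != "*") next
        prec <- substr(aa, 1L, N)
        if (grepl("*", prec, fixed = TRUE) ||
            grepl("X", prec, fixed = TRUE)) next
        part <- partition_precursor(prec, g)
        if (!part$ok) next
        flags <- validate_precursor(part, g)
        e1 <- .to_forward(pos, pos + exon1_len - 1L, strand, len)
        it <- .to_forward(ds, ds + L - 1L, strand, len)
        e2 <- .to_forward(e2s, e2e, strand, len)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(
            scaffold = scaffold_id, strand = strand,
            start = min(e1, e2), end = max(e1, e2),
            exon1_start = e1[1], exon1_end = e1[2],
            intron_start = it[1], intron_end = it[2],
            exon2_start = e2[1], exon2_end = e2[2],
            donor = donor, acceptor = acc,
            intron_len = L, phase = p,
            precursor = prec, leader = part$leader, core = part$core,
            follower = part$follower,
            stringsAsFactors = FALSE
          ),
          flags,
          data.frame(
            terminal_lc = substr(prec, N - 1L, N) == "LC",
            score = NA_real_,
            stringsAsFactors = FALSE
          )
        )
      }
    }
  }
  if (length(rows) == 0L) return(.empty_models())
  out <- do.call(rbind, rows)
  out <- out[, .MODEL_COLUMNS]
  out$score <- score_models(out)
  out
}

#' Score gene models
#'
#' Deterministic additive score; higher is more MSDIN-like. Weights: GT
#' donor 1.0 (GC 0.5); terminal Leu-Cys 1.0; core-terminal Pro 0.5; leader
#' class canonical 1.5 / listed-variant 1.0 / near-variant 0.5; intron
#' length 0.5 minus 0.05 per bp away from 55; interrupted intron phase
#' (1 or 2) 0.25.
#'
#' @param models Gene-model data frame.
#' @return Numeric vector of scores.
#' @export
score_models <- function(models) {
  if (nrow(models) == 0L) return(numeric(0))
  leader_w <- c(canonical = 1.5, `listed-variant` = 1.0,
                `near-variant` = 0.5, divergent = 0)
  ifelse(models$donor == "GT", 1.0, 0.5) +
    ifelse(models$terminal_lc, 1.0, 0) +
    ifelse(models$core_end_pro, 0.5, 0) +
    unname(leader_w[models$leader_class]) +
    (0.5 - 0.05 * abs(models$intron_len - 55)) +
    ifelse(models$phase %in% 1:2, 0.25, 0)
}

# Greedy same-strand overlap resolution: best score first; ties broken by
# longer exon 1, then leftmost start.
.resolve_overlaps <- function(models) {
  if (nrow(models) <= 1L) return(models)
  exon1_len <- abs(models$exon1_end - models$exon1_start) + 1L
  ord <- order(-models$score, -exon1_len, models$start)
  models <- models[ord, , drop = FALSE]
  kept <- logical(nrow(models))
  for (i in seq_len(nrow(models))) {
    ok <- TRUE
    if (any(kept)) {
      k <- which(kept)
      same <- models$scaffold[k] == models$scaffold[i] &
        models$strand[k] == models$strand[i]
      if (any(same)) {
        k <- k[same]
        overlap <- models$start[k] <= models$end[i] &
          models$end[k] >= models$start[i]
        ok <- !any(overlap)
      }
    }
    kept[i] <- ok
  }
  models[kept, , drop = FALSE]
}

#' Mine a set of scaffolds for MSDIN gene models
#'
#' Runs [six_frame_seeds()] and [enumerate_gene_models()] over every
#' scaffold, scores all models, resolves same-strand overlaps by score
#' (opposite-strand overlaps are both kept), and returns the surviving
#' models ranked by score. Deterministic for fixed input and configuration.
#'
#' @param scaffolds Named character vector of DNA sequences, a
#'   `DNAStringSet`, or a path to a genome FASTA file.
#' @param cfg A [miner_config()].
#' @return Gene-model data frame (see [enumerate_gene_models()] for the
#'   coordinate conventions), ranked by decreasing score.
#' @export
mine_genome <- function(scaffolds, cfg = miner_config()) {
  if (is.character(scaffolds) && length(scaffolds) == 1L &&
      file.exists(scaffolds)) {
    scaffolds <- read_fasta(scaffolds, type = "DNA")
  }
  if (inherits(scaffolds, "DNAStringSet")) {
    scaffolds <- stats::setNames(as.character(scaffolds), names(scaffolds))
  }
  if (length(scaffolds) == 0L) stop("no scaffolds supplied")
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds)))) {
    stop("scaffolds must be named")
  }
  all_models <- list()
  for (id in names(scaffolds)) {
    seq <- toupper(scaffolds[[id]])
    seeds <- six_frame_seeds(seq, cfg)
    if (nrow(seeds) == 0L) next
    models <- lapply(seq_len(nrow(seeds)), function(i) {
      enumerate_gene_models(id, seq, seeds[i, , drop = FALSE], cfg)
    })
    models <- do.call(rbind, models)
    if (nrow(models) > 0L) all_models[[id]] <- models
  }
  if (length(all_models) == 0L) return(.empty_models())
  models <- do.call(rbind, c(all_models, list(make.row.names = FALSE)))
  models <- models[models$score >= cfg$min_score, , drop = FALSE]
  if (cfg$require_terminal_LC) {
    models <- models[models$terminal_lc, , drop = FALSE]
  }
  models <- .resolve_overlaps(models)
  models <- models[order(-models$score, models$scaffold, models$start), ,
                   drop = FALSE]
  rownames(models) <- NULL
  models
}

#' Summarise mined models: unique cores and per-scaffold clusters
#'
#' Gene copies are counted as "unique" by identical core sequence (set
#' `by = "precursor"` for full-precursor uniqueness).
#'
#' @param models Gene-model data frame from [mine_genome()].
#' @param by `"core"` (default) or `"precursor"`.
#' @return List: `total` models, `unique` count, `core_table` (data frame of
#'   core, n_loci, loci) and `per_scaffold` cluster counts.
#' @export
#' @examples
#' dedupe_and_cluster(data.frame(
#'   scaffold = c("s1", "s1", "s2", "s2"), strand = "+",
#'   start = c(1, 900, 1, 900), end = c(200, 1100, 200, 1100),
#'   core = c("AWLATCP", "AWLATCP", "AWLATCP", "IWGIGCNP")))
dedupe_and_cluster <- function(models, by = c("core", "precursor")) {
  by <- match.arg(by)
  if (nrow(models) == 0L) {
    return(list(
      total = 0L, unique = 0L,
      core_table = data.frame(core = character(0), n_loci = integer(0),
                              loci = character(0), stringsAsFactors = FALSE),
      per_scaffold = data.frame(scaffold = character(0),
                                n_models = integer(0),
                                stringsAsFactors = FALSE)
    ))
  }
  key <- models[[by]]
  locus <- paste0(models$scaffold, ":", models$start, "-", models$end,
                  "(", models$strand, ")")
  core_table <- do.call(rbind, lapply(split(seq_len(nrow(models)), key),
    function(idx) {
      data.frame(
        core = models$core[idx[1]],
        n_loci = length(idx),
        loci = paste(locus[idx], collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  rownames(core_table) <- NULL
  per_scaffold <- as.data.frame(table(scaffold = models$scaffold),
                                stringsAsFactors = FALSE)
  names(per_scaffold) <- c("scaffold", "n_models")
  list(
    total = nrow(models),
    unique = length(unique(key)),
    core_table = core_table[order(-core_table$n_loci, core_table$core), ],
    per_scaffold = per_scaffold
  )
}

#' Compare mined models with a truth annotation
#'
#' Exact-coordinate evaluation: a mined model is a true positive when a
#' truth record matches its scaffold, strand and all six exon/intron
#' coordinates.
#'
#' @param models Mined gene-model data frame.
#' @param truth Truth data frame with the same coordinate columns.
#' @return List with `sensitivity`, `precision`, `n_true`, `n_mined`,
#'   `n_matched`.
#' @export
evaluate_mining <- function(models, truth) {
  key <- function(d) {
    paste(d$scaffold, d$strand, d$exon1_start, d$exon1_end,
          d$intron_start, d$intron_end, d$exon2_start, d$exon2_end,
          sep = "|")
  }
  mk <- key(models)
  tk <- key(truth)
  n_matched <- sum(tk %in% mk)
  list(
    sensitivity = if (nrow(truth) > 0) n_matched / nrow(truth) else NA_real_,
    precision = if (nrow(models) > 0) sum(mk %in% tk) / nrow(models)
                else NA_real_,
    n_true = nrow(truth),
    n_mined = nrow(models),
    n_matched = n_matched
  )
}
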