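# Seeded generators for grammar-conformant precursors, intron-containing
# genes, genome scaffolds with truth annotations, and noisy peak lists.
# These emulate the study conditions the mined assemblies would provide:
# GC ~48% background, 6-10-aa cores with mode 8, Pro/Ile/Phe-enriched core
# composition, 52-58 bp introns with a GC donor minority.

#' Default core amino-acid frequencies
#'
#' Pro/Ile/Phe-enriched, depleted in charged and polar residues, mirroring
#' the composition bias of annotated core regions.
#'
#' @return Named numeric distribution over the 20 amino acids (sums to 1).
#' @export
default_core_aa_freqs <- function() {
  c(P = 0.15, I = 0.12, F = 0.12, L = 0.09, V = 0.08, A = 0.07, G = 0.06,
    S = 0.05, T = 0.04, W = 0.03, C = 0.03, Y = 0.03,
    M = 0.02, N = 0.02, Q = 0.02, D = 0.02, E = 0.02,
    H = 0.01, K = 0.01, R = 0.01)
}

#' Default leader pool
#'
#' Ten-residue leaders ending in Pro: the canonical MSDIN start plus the
#' listed single-residue variants, on the common "...ATRLP" leader body.
#'
#' @return Character vector of 10-aa leaders.
#' @export
default_leader_pool <- function() {
  paste0(c("MSDIN", "MSDMN", "MSDVN", "MSDIK", "MSEIN", "MSDTN", "MSNIN"),
         "ATRLP")
}

#' Simulation configuration
#'
#' The defaults define the study conditions used throughout the test suite:
#' 20 scaffolds of 50 kb at GC 0.48 carrying 30 planted genes, core lengths
#' 6-10 with mode 8, introns 52-58 bp with 85% GT / 15% GC donors, MS1 peak
#' lists with 2 ppm Gaussian mass noise and 200 uniform decoy peaks.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_scaffolds,scaffold_len,gc_fraction Background scaffold settings.
#' @param n_genes Number of genes planted across the scaffolds.
#' @param core_length_weights Named weights over core lengths 6-10.
#' @param core_aa_distribution Residue distribution for core positions
#'   before the forced terminal Pro.
#' @param leader_pool Pool of 10-aa leaders (each must end in Pro).
#' @param intron_len_range Intron length bounds (bp).
#' @param donor_weights Named weights over donor dinucleotides.
#' @param intron_phase_weights Named weights over intron phases 1 and 2
#'   (the intron truly interrupts the fourth-from-last codon).
#' @param ppm_noise_sd Gaussian m/z noise, ppm.
#' @param n_decoy_peaks Uniform decoy peaks added to generated peak lists.
#' @param min_gene_spacing Minimum bp between planted genes on a scaffold.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 20L,
                       scaffold_len = 50000L,
                       gc_fraction = 0.48,
                       n_genes = 30L,
                       core_length_weights = c(`6` = 0.10, `7` = 0.20,
                                               `8` = 0.40, `9` = 0.20,
                                               `10` = 0.10),
                       core_aa_distribution = default_core_aa_freqs(),
                       leader_pool = default_leader_pool(),
                       intron_len_range = c(52L, 58L),
                       donor_weights = c(GT = 0.85, GC = 0.15),
                       intron_phase_weights = c(`1` = 0.5, `2` = 0.5),
                       ppm_noise_sd = 2,
                       n_decoy_peaks = 200L,
                       min_gene_spacing = 500L) {
  stopifnot(
    abs(sum(core_length_weights) - 1) < 1e-9,
    abs(sum(core_aa_distribution) - 1) < 1e-9,
    abs(sum(donor_weights) - 1) < 1e-9,
    abs(sum(intron_phase_weights) - 1) < 1e-9,
    all(substr(leader_pool, 10L, 10L) == "P")
  )
  structure(
    list(
      seed = as.integer(seed),
      n_scaffolds = as.integer(n_scaffolds),
      scaffold_len = as.integer(scaffold_len),
      gc_fraction = gc_fraction,
      n_genes = as.integer(n_genes),
      core_length_weights = core_length_weights,
      core_aa_distribution = core_aa_distribution,
      leader_pool = leader_pool,
      intron_len_range = as.integer(intron_len_range),
      donor_weights = donor_weights,
      intron_phase_weights = intron_phase_weights,
      ppm_noise_sd = ppm_noise_sd,
      n_decoy_peaks = as.integer(n_decoy_peaks),
      min_gene_spacing = as.integer(min_gene_spacing)
    ),
    class = "sim_config"
  )
}

.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

.sample_aa <- function(n, dist) {
  sample(names(dist), n, replace = TRUE, prob = dist)
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Reverse genetic code: aa -> codons (stops under "*").
.SYNONYMOUS_CODONS <- split(names(.CODON_TABLE), unname(.CODON_TABLE))

#' Generate grammar-conformant precursor peptides
#'
#' Leader drawn from the pool (ends Pro), core length drawn from the weight
#' table with a forced terminal Pro, follower of 15 uniform residues plus
#' the consensus Leu-Cys ending. Every output partitions and validates as
#' processable.
#'
#' @param cfg A [sim_config()].
#' @param n Number of precursors.
#' @param seed Seed for this call; pass `NULL` to draw from the current RNG
#'   stream (used internally by the higher-level generators).
#' @return Character vector of precursor sequences (33-37 aa).
#' @export
generate_precursor <- function(cfg = sim_config(), n = 1L, seed = cfg$seed) {
  .maybe_seed(seed)
  aas <- names(.RESIDUE_COMPOSITIONS)
  vapply(seq_len(n), function(i) {
    leader <- sample(cfg$leader_pool, 1L)
    core_len <- as.integer(sample(names(cfg$core_length_weights), 1L,
                                  prob = cfg$core_length_weights))
    core <- paste0(
      paste(.sample_aa(core_len - 1L, cfg$core_aa_distribution),
            collapse = ""),
      "P"
    )
    follower <- paste0(paste(sample(aas, 15L, replace = TRUE),
                             collapse = ""), "LC")
    paste0(leader, core, follower)
  }, character(1))
}

#' Encode a precursor as an intron-containing gene
#'
#' Back-translates the precursor (uniform synonymous codon choice, random
#' stop codon) and inserts a single intron of drawn length, donor and phase
#' into the fourth codon from the end (stop included). Re-splicing and
#' translating the result reproduces the precursor exactly.
#'
#' @param precursor Precursor amino-acid sequence.
#' @param cfg A [sim_config()].
#' @param seed Seed for this call; `NULL` to draw from the current stream.
#' @return List: `dna`, `exon1_len`, `intron_len`, `exon2_len`, `phase`,
#'   `donor`, `precursor`, `core` (via the grammar partition).
#' @export
generate_gene <- function(precursor, cfg = sim_config(), seed = NULL) {
  .maybe_seed(seed)
  residues <- .split_residues(precursor)
  codons <- vapply(residues, function(a) {
    opts <- .SYNONYMOUS_CODONS[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  stop_codon <- sample(.SYNONYMOUS_CODONS[["*"]], 1L)
  cds <- paste(c(codons, stop_codon), collapse = "")
  n_aa <- length(residues)
  phase <- as.integer(sample(names(cfg$intron_phase_weights), 1L,
                             prob = cfg$intron_phase_weights))
  intron_len <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]),
                       1L)
  donor <- sample(names(cfg$donor_weights), 1L, prob = cfg$donor_weights)
  interior <- .random_dna(intron_len - 4L, cfg$gc_fraction)
  intron <- paste0(donor, interior, "AG")
  # fourth codon from the CDS end (stop included) is codon n_aa - 2
  exon1_len <- 3L * (n_aa - 3L) + phase
  exon1 <- substr(cds, 1L, exon1_len)
  exon2 <- substr(cds, exon1_len + 1L, nchar(cds))
  part <- partition_precursor(precursor)
  list(
    dna = paste0(exon1, intron, exon2),
    exon1_len = exon1_len,
    intron_len = intron_len,
    exon2_len = nchar(exon2),
    phase = phase,
    donor = donor,
    precursor = precursor,
    core = part$core
  )
}

#' Generate genome scaffolds with planted MSDIN genes
#'
#' Builds i.i.d. background scaffolds at the configured GC fraction and
#' plants `n_genes` generated genes on random strands at non-overlapping
#' positions at least `min_gene_spacing` bp apart. The truth table uses the
#' same columns and coordinate conventions as [mine_genome()] output, so
#' sensitivity and precision are directly computable.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed; `NULL` to draw from the current stream.
#' @return List: `scaffolds` (named character vector) and `truth` (gene
#'   model data frame).
#' @export
generate_scaffolds <- function(cfg = sim_config(), seed = cfg$seed) {
  .maybe_seed(seed)
  ids <- sprintf("scaffold_%03d", seq_len(cfg$n_scaffolds))
  scaffolds <- stats::setNames(
    vapply(ids, function(i) .random_dna(cfg$scaffold_len, cfg$gc_fraction),
           character(1)),
    ids
  )
  occupied <- stats::setNames(
    rep(list(data.frame(start = integer(0), end = integer(0))), length(ids)),
    ids
  )
  truth_rows <- list()
  for (k in seq_len(cfg$n_genes)) {
    precursor <- generate_precursor(cfg, 1L, seed = NULL)
    gene <- generate_gene(precursor, cfg, seed = NULL)
    glen <- nchar(gene$dna)
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      sc <- sample(ids, 1L)
      pos <- sample.int(cfg$scaffold_len - glen - 200L, 1L) + 100L
      occ <- occupied[[sc]]
      if (nrow(occ) == 0L ||
          all(pos > occ$end + cfg$min_gene_spacing |
              pos + glen - 1L < occ$start - cfg$min_gene_spacing)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place gene ", k, " after 200 attempts; ",
           "reduce n_genes or enlarge scaffolds")
    }
    strand <- sample(c("+", "-"), 1L)
    insert <- if (strand == "+") gene$dna else revcomp_dna(gene$dna)
    scaffolds[[sc]] <- paste0(
      substr(scaffolds[[sc]], 1L, pos - 1L),
      insert,
      substr(scaffolds[[sc]], pos + glen, cfg$scaffold_len)
    )
    occupied[[sc]] <- rbind(occupied[[sc]],
                            data.frame(start = pos, end = pos + glen - 1L))
    e1 <- c(1L, gene$exon1_len)
    it <- c(gene$exon1_len + 1L, gene$exon1_len + gene$intron_len)
    e2 <- c(it[2] + 1L, glen)
    offset <- function(iv) {
      if (strand == "+") pos + iv - 1L else pos + glen - rev(iv)
    }
    e1f <- offset(e1); itf <- offset(it); e2f <- offset(e2)
    part <- partition_precursor(precursor)
    flags <- validate_precursor(part)
    row <- cbind(
      data.frame(
        scaffold = sc, strand = strand,
        start = pos, end = pos + glen - 1L,
        exon1_start = e1f[1], exon1_end = e1f[2],
        intron_start = itf[1], intron_end = itf[2],
        exon2_start = e2f[1], exon2_end = e2f[2],
        donor = gene$donor, acceptor = "AG",
        intron_len = gene$intron_len, phase = gene$phase,
        precursor = precursor, leader = part$leader, core = part$core,
        follower = part$follower,
        stringsAsFactors = FALSE
      ),
      flags,
      data.frame(
        terminal_lc = TRUE, score = NA_real_, stringsAsFactors = FALSE
      )
    )
    truth_rows[[k]] <- row[, .MODEL_COLUMNS]
  }
  truth <- if (length(truth_rows) == 0L) {
    .empty_models()
  } else {
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  }
  truth$score <- score_models(truth)
  list(scaffolds = scaffolds, truth = truth)
}

#' Generate a noisy peak list for a set of cyclic peptides
#'
#' MS1 mode emits one peak per peptide at its theoretical singly protonated
#' m/z perturbed by Gaussian ppm noise, plus uniform decoy peaks over the
#' observed m/z range. MS2 mode emits the full cyclic b-ion ladder of a
#' single peptide, perturbed the same way.
#'
#' @param peptides Character vector of cyclic peptide sequences, or a
#'   numeric vector of theoretical m/z values (MS1 only).
#' @param cfg A [sim_config()] (uses `ppm_noise_sd` and `n_decoy_peaks`).
#' @param level `"MS1"` or `"MS2"`.
#' @param seed Seed; `NULL` to draw from the current stream.
#' @return Data frame (`mz`, `intensity`) sorted by m/z, with attributes
#'   `level` and `truth` (data frame of true and noisy m/z per peak).
#' @export
generate_peaklist <- function(peptides, cfg = sim_config(),
                              level = c("MS1", "MS2"), seed = cfg$seed) {
  level <- match.arg(level)
  .maybe_seed(seed)
  if (level == "MS1") {
    true_mz <- if (is.numeric(peptides)) {
      peptides
    } else {
      vapply(peptides, function(s) {
        mz_protonated(monoisotopic_mass(peptide_composition(s, "cyclic")))
      }, numeric(1))
    }
    labels <- if (is.character(peptides)) peptides else
      sprintf("mz_%.4f", true_mz)
  } else {
    stopifnot(is.character(peptides), length(peptides) == 1L)
    frags <- fragment_ladder(peptides)$fragments
    true_mz <- frags$mz
    labels <- frags$residues
  }
  noisy <- true_mz * (1 + stats::rnorm(length(true_mz),
                                       sd = cfg$ppm_noise_sd) * 1e-6)
  decoys <- if (cfg$n_decoy_peaks > 0L) {
    stats::runif(cfg$n_decoy_peaks,
                 min(true_mz) * 0.95, max(true_mz) * 1.05)
  } else {
    numeric(0)
  }
  mz <- c(noisy, decoys)
  pl <- data.frame(
    mz = mz,
    intensity = stats::runif(length(mz), 1e4, 1e6)
  )
  ord <- order(pl$mz)
  pl <- pl[ord, , drop = FALSE]
  rownames(pl) <- NULL
  attr(pl, "level") <- level
  attr(pl, "truth") <- data.frame(
    peptide = labels, true_mz = true_mz, noisy_mz = noisy,
    stringsAsFactors = FALSE
  )
  pl
}
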