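# Builds small synthetic scaffolds with known planted genes and checks that
# mining recovers them at exact coordinates.

plant_gene <- function(gene_dna, flank = 300, seed = 7, strand = "+") {
  set.seed(seed)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  insert <- if (strand == "+") gene_dna else revcomp_dna(gene_dna)
  list(
    seq = paste0(bg(flank), insert, bg(flank)),
    gene_start = flank + 1L,
    gene_end = flank + nchar(gene_dna)
  )
}

test_that("a planted gene is recovered with exact coordinates", {
  cfg <- sim_config(seed = 21)
  prec <- generate_precursor(cfg)
  gene <- generate_gene(prec, cfg, seed = 22)
  sc <- plant_gene(gene$dna)
  models <- mine_genome(c(test_scaffold = sc$seq))
  expect_equal(nrow(models), 1L)
  expect_equal(models$precursor, prec)
  expect_equal(models$exon1_start, sc$gene_start)
  expect_equal(models$exon1_end, sc$gene_start + gene$exon1_len - 1L)
  expect_equal(models$intron_len, gene$intron_len)
  expect_equal(models$phase, gene$phase)
  expect_equal(models$exon2_end, sc$gene_end)
  expect_equal(models$donor, gene$donor)
  expect_true(models$processable)
})

test_that("seeds appear at the planted ATG on both strands", {
  cfg <- sim_config(seed = 31)
  gene <- generate_gene(generate_precursor(cfg), cfg, seed = 32)
  fwd <- plant_gene(gene$dna, strand = "+")
  seeds <- six_frame_seeds(fwd$seq)
  plus <- seeds[seeds$strand == "+", ]
  expect_true(fwd$gene_start %in% plus$pos)

  rev <- plant_gene(gene$dna, strand = "-")
  seeds_rev <- six_frame_seeds(rev$seq)
  minus <- seeds_rev[seeds_rev$strand == "-", ]
  # on the oriented (reverse-complement) sequence the ATG is at the same
  # offset as on the forward planting, since the flanks are equal length
  expect_true(rev$gene_start %in% minus$pos)
  expect_equal(minus$fwd_pos[minus$pos == rev$gene_start],
               nchar(rev$seq) - rev$gene_start + 1L)
  # an all-N scaffold has no seeds
  expect_equal(nrow(six_frame_seeds(strrep("N", 500))), 0L)
})

test_that("mutating the donor dinucleotide kills the gene model", {
  cfg <- sim_config(seed = 41)
  prec <- generate_precursor(cfg)
  gene <- generate_gene(prec, cfg, seed = 42)
  expect_equal(gene$donor, "GT")
  broken <- paste0(
    substr(gene$dna, 1, gene$exon1_len), "GA",
    substr(gene$dna, gene$exon1_len + 3L, nchar(gene$dna))
  )
  sc <- plant_gene(broken)
  expect_equal(nrow(mine_genome(c(s = sc$seq))), 0L)
})

test_that("GC donors are recovered and scored below GT donors", {
  cfg <- sim_config(seed = 51)
  prec <- generate_precursor(cfg)
  gene <- generate_gene(prec, cfg, seed = 57)
  expect_equal(gene$donor, "GT")
  gc_version <- paste0(
    substr(gene$dna, 1, gene$exon1_len), "GC",
    substr(gene$dna, gene$exon1_len + 3L, nchar(gene$dna))
  )
  m_gt <- mine_genome(c(s = plant_gene(gene$dna)$seq))
  m_gc <- mine_genome(c(s = plant_gene(gc_version)$seq))
  expect_equal(nrow(m_gc), 1L)
  expect_equal(m_gc$donor, "GC")
  expect_equal(m_gc$precursor, prec)
  expect_lt(m_gc$score, m_gt$score)
})

test_that("mining a reverse-complemented scaffold mirrors the models", {
  sim <- generate_scaffolds(sim_config(seed = 61, n_scaffolds = 2,
                                       scaffold_len = 12000, n_genes = 5))
  for (id in names(sim$scaffolds)) {
    seq <- sim$scaffolds[[id]]
    fwd <- mine_genome(stats::setNames(seq, id))
    rev <- mine_genome(stats::setNames(revcomp_dna(seq), id))
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd) == 0L) next
    L <- nchar(seq)
    mirror <- function(d) {
      key <- paste(
        ifelse(d$strand == "+", "-", "+"),
        L - d$exon1_end + 1L, L - d$exon1_start + 1L,
        L - d$intron_end + 1L, L - d$intron_start + 1L,
        L - d$exon2_end + 1L, L - d$exon2_start + 1L,
        d$precursor, sep = "|")
      sort(key)
    }
    fwd_key <- sort(paste(fwd$strand, fwd$exon1_start, fwd$exon1_end,
                          fwd$intron_start, fwd$intron_end,
                          fwd$exon2_start, fwd$exon2_end, fwd$precursor,
                          sep = "|"))
    expect_equal(mirror(rev), fwd_key)
  }
})

test_that("mined models respect splice validity and the intron rules", {
  sim <- generate_scaffolds(sim_config(seed = 71, n_scaffolds = 3,
                                       scaffold_len = 15000, n_genes = 8))
  models <- mine_genome(sim$scaffolds)
  expect_gt(nrow(models), 0L)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    expect_gte(m$intron_len, 52L)
    expect_lte(m$intron_len, 58L)
    seq <- sim$scaffolds[[m$scaffold]]
    extract <- function(a, b) substr(seq, a, b)
    if (m$strand == "+") {
      cds <- paste0(extract(m$exon1_start, m$exon1_end),
                    extract(m$exon2_start, m$exon2_end))
      intron <- extract(m$intron_start, m$intron_end)
    } else {
      cds <- revcomp_dna(paste0(extract(m$exon2_start, m$exon2_end),
                                extract(m$exon1_start, m$exon1_end)))
      intron <- revcomp_dna(extract(m$intron_start, m$intron_end))
    }
    expect_true(substr(intron, 1, 2) %in% c("GT", "GC"))
    expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    expect_equal(nchar(cds) %% 3, 0)
    aa <- translate_dna(cds)
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_equal(substr(aa, 1, nchar(aa) - 1), m$precursor)
    expect_true(partition_precursor(m$precursor)$ok)
  }
})

test_that("scores are deterministic and reward canonical features", {
  sim <- generate_scaffolds(sim_config(seed = 81, n_scaffolds = 2,
                                       scaffold_len = 10000, n_genes = 4))
  models <- mine_genome(sim$scaffolds)
  expect_equal(score_models(models), models$score)
  m <- models[1, ]
  worse <- m
  worse$terminal_lc <- FALSE
  expect_lt(score_models(worse), score_models(m))
  worse2 <- m
  worse2$leader_class <- "near-variant"
  expect_lt(score_models(worse2), score_models(m))
})

test_that("dedupe_and_cluster counts total vs unique cores and clusters", {
  models <- data.frame(
    scaffold = c("s1", "s1", "s2", "s3"), strand = "+",
    start = c(1, 1000, 1, 1), end = c(200, 1200, 200, 200),
    core = c("AWLATCP", "AWLATCP", "AWLATCP", "IWGIGCNP"),
    precursor = "x", stringsAsFactors = FALSE
  )
  s <- dedupe_and_cluster(models)
  expect_equal(s$total, 4L)
  expect_equal(s$unique, 2L)
  expect_equal(s$core_table$n_loci[s$core_table$core == "AWLATCP"], 3L)
  expect_equal(s$per_scaffold$n_models[s$per_scaffold$scaffold == "s1"], 2L)
  empty <- dedupe_and_cluster(models[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(empty$unique, 0L)
})

test_that("mining rejects an empty scaffold set", {
  expect_error(mine_genome(character(0)), "no scaffolds")
  expect_error(mine_genome(c("ACGT")), "named")
})
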