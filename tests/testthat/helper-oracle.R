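# Independent oracle data for the chemistry tests: full molecular formulas
# of the 20 proteinogenic amino acids (free amino acids, i.e. residue plus
# one water), entered by hand from standard tables. The package's own
# residue table is never consulted here.

AA_MOLECULAR_FORMULAS <- list(
  A = c(C = 3, H = 7, N = 1, O = 2),
  R = c(C = 6, H = 14, N = 4, O = 2),
  N = c(C = 4, H = 8, N = 2, O = 3),
  D = c(C = 4, H = 7, N = 1, O = 4),
  C = c(C = 3, H = 7, N = 1, O = 2, S = 1),
  E = c(C = 5, H = 9, N = 1, O = 4),
  Q = c(C = 5, H = 10, N = 2, O = 3),
  G = c(C = 2, H = 5, N = 1, O = 2),
  H = c(C = 6, H = 9, N = 3, O = 2),
  I = c(C = 6, H = 13, N = 1, O = 2),
  L = c(C = 6, H = 13, N = 1, O = 2),
  K = c(C = 6, H = 14, N = 2, O = 2),
  M = c(C = 5, H = 11, N = 1, O = 2, S = 1),
  F = c(C = 9, H = 11, N = 1, O = 2),
  P = c(C = 5, H = 9, N = 1, O = 2),
  S = c(C = 3, H = 7, N = 1, O = 3),
  T = c(C = 4, H = 9, N = 1, O = 3),
  W = c(C = 11, H = 12, N = 2, O = 2),
  Y = c(C = 9, H = 11, N = 1, O = 3),
  V = c(C = 5, H = 11, N = 1, O = 2)
)

# Brute-force per-atom tally: n free amino acids condensed with loss of
# (n - 1) waters for a linear peptide, n waters for a head-to-tail cycle.
oracle_peptide_composition <- function(seq, topology = "linear") {
  residues <- strsplit(seq, "")[[1]]
  tally <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (r in residues) {
    f <- AA_MOLECULAR_FORMULAS[[r]]
    tally[names(f)] <- tally[names(f)] + f
  }
  n_water <- if (topology == "linear") length(residues) - 1 else
    length(residues)
  tally["H"] <- tally["H"] - 2 * n_water
  tally["O"] <- tally["O"] - n_water
  tally[tally != 0]
}

random_peptides <- function(n, len_range = c(5, 12)) {
  aas <- names(AA_MOLECULAR_FORMULAS)
  vapply(seq_len(n), function(i) {
    paste(sample(aas, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# Compare two compositions as sets of non-zero counts.
expect_same_composition <- function(a, b) {
  a <- a[a != 0]
  b <- b[b != 0]
  expect_setequal(names(a), names(b))
  expect_equal(a[sort(names(a))], b[sort(names(a))])
}
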