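test_that("atomic and residue tables satisfy their sanity anchors", {
  m <- atomic_masses()
  expect_true(all(m > 0))
  k <- mass_constants()
  expect_equal(unname(k["hydrogen"] - k["proton"]), 5.49e-4,
               tolerance = 1e-5 / 5.49e-4)
  rc <- residue_compositions()
  expect_length(rc, 20L)
  for (comp in rc) {
    expect_true(all(comp[c("C", "H", "N")] >= 1))
  }
  expect_equal(unname(residue_masses()["G"]), 57.02146, tolerance = 1e-4 / 57)
})

test_that("peptide compositions match the published and trivial formulas", {
  tri_oh <- peptide_composition("ISDPTAYP", "cyclic",
                                mods = list(list(mod_hydroxylation(), 3)))
  expect_equal(format_formula(tri_oh), "C39H56N8O16")
  expect_equal(format_formula(peptide_composition("GG", "linear")),
               "C4H8N2O3")
  # the unmodified cycloamanide E ring
  expect_equal(format_formula(peptide_composition("SFFFPVP", "cyclic")),
               "C45H55N7O8")
})

test_that("monoisotopic masses reproduce printed values", {
  expect_equal(monoisotopic_mass(parse_formula("C39H56N8O16")), 892.3814,
               tolerance = 5e-4 / 892)
  expect_equal(monoisotopic_mass(c(H = 2, O = 1)), 18.010565,
               tolerance = 1e-5 / 18)
  expect_equal(monoisotopic_mass(setNames(numeric(0), character(0))), 0)
})

test_that("protonated m/z supports both charge-carrier conventions", {
  ivg <- monoisotopic_mass(peptide_composition("IVGILGLP", "cyclic"))
  expect_equal(mz_protonated(ivg, 1, "proton"), 763.5076,
               tolerance = 8e-4 / 763)
  sff <- monoisotopic_mass(peptide_composition("SFFFPVP", "cyclic"))
  expect_equal(mz_protonated(sff, 1, "h-atom"), 822.4190,
               tolerance = 8e-4 / 822)
  expect_equal(mz_protonated(0, 1, "proton"), 1.007276,
               tolerance = 1e-6)
  # doubly charged ion of a neutral mass M: (M + 2 p) / 2
  expect_equal(mz_protonated(1000, 2), (1000 + 2 * 1.00727646688) / 2)
})

test_that("ppm errors reproduce the printed discrepancies", {
  sff_mz <- mz_protonated(
    monoisotopic_mass(peptide_composition("SFFFPVP", "cyclic")),
    convention = "h-atom")
  expect_equal(ppm_error(822.4218, sff_mz), 3.4, tolerance = 0.05 / 3.4)
  ivg_mz <- mz_protonated(
    monoisotopic_mass(peptide_composition("IVGILGLP", "cyclic")))
  expect_equal(ppm_error(763.5118, ivg_mz), 5.5, tolerance = 0.05 / 5.5)
  expect_equal(ppm_error(500.123, 500.123), 0)
})

test_that("invalid inputs fail with informative errors", {
  expect_error(peptide_composition("PEPTIDEZ"), "Z.*position 8")
  expect_error(peptide_composition(""), "non-empty")
  expect_error(mz_protonated(100, 0), "charge")
  expect_error(ppm_error(100, 0), "theoretical")
  expect_error(monoisotopic_mass(c(C = 1, Xe = 2)), "Xe")
  expect_error(
    peptide_composition("AWLATCP", mods = list(list(mod_hydroxylation(), 5))),
    "exceeds max_per_peptide")
  # tryptathionine on two glycines would need hydrogens that are not there
  expect_error(comp_add(c(C = 2), c(H = 2), coef = -1), "negative")
})

test_that("linear minus cyclic is exactly one water", {
  set.seed(42)
  for (seq in random_peptides(200)) {
    lin <- peptide_composition(seq, "linear")
    cyc <- peptide_composition(seq, "cyclic")
    expect_same_composition(comp_add(lin, cyc, coef = -1), c(H = 2, O = 1))
    expect_equal(monoisotopic_mass(lin) - monoisotopic_mass(cyc),
                 monoisotopic_mass(c(H = 2, O = 1)))
  }
})

test_that("mass is additive over compositions", {
  a <- peptide_composition("IWGIGCNP", "cyclic")
  b <- parse_formula("C7H5NO3S")
  expect_equal(monoisotopic_mass(comp_add(a, b)),
               monoisotopic_mass(a) + monoisotopic_mass(b),
               tolerance = 1e-9)
})

test_that("modification deltas have the expected masses", {
  base <- peptide_composition("AWLATCP", "cyclic")
  oh <- peptide_composition("AWLATCP", "cyclic",
                            mods = list(mod_hydroxylation()))
  expect_equal(monoisotopic_mass(oh) - monoisotopic_mass(base), 15.994915,
               tolerance = 1e-5 / 16)
  tt <- peptide_composition("AWLATCP", "cyclic",
                            mods = list(mod_tryptathionine()))
  expect_equal(monoisotopic_mass(tt) - monoisotopic_mass(base), -2.015650,
               tolerance = 1e-5 / 2)
})

test_that("compositions agree with the per-atom oracle on all homodipeptides", {
  for (aa in names(AA_MOLECULAR_FORMULAS)) {
    seq <- strrep(aa, 2)
    expect_same_composition(peptide_composition(seq, "linear"),
                            oracle_peptide_composition(seq, "linear"))
    expect_same_composition(peptide_composition(seq, "cyclic"),
                            oracle_peptide_composition(seq, "cyclic"))
  }
})

test_that("cyclic mass is invariant under rotation of the sequence", {
  seq <- "ISDPTAYP"
  n <- nchar(seq)
  ref <- monoisotopic_mass(peptide_composition(seq, "cyclic"))
  for (r in seq_len(n - 1)) {
    rot <- paste0(substr(seq, r + 1, n), substr(seq, 1, r))
    expect_equal(monoisotopic_mass(peptide_composition(rot, "cyclic")), ref)
  }
})

test_that("formula strings round-trip through parse and format", {
  for (f in c("C39H56N8O16", "C34H52N8O20", "H2O", "C45H55N7O8S")) {
    expect_equal(format_formula(parse_formula(f)), f)
  }
  expect_error(parse_formula("not a formula"), "parse")
})
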