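test_that("candidate enumeration counts hydroxylation and bridge variants", {
  plain <- candidate_masses("SFFFPVP")
  expect_equal(nrow(plain), 5L) # 0-4 hydroxylations, no W/C for the bridge
  bridged <- candidate_masses("IWGIGCNP")
  expect_equal(nrow(bridged), 10L)
  expect_equal(sum(bridged$tryptathionine), 5L)
  tri <- candidate_masses("ISDPTAYP")
  expect_equal(tri$neutral_mass[tri$n_hydroxyl == 3 & !tri$tryptathionine],
               892.3814, tolerance = 5e-4 / 892)
  expect_true(all(plain$mz > plain$neutral_mass))
  expect_error(candidate_masses("ISDPTAYB"), "ISDPTAYB")
  expect_error(candidate_masses(character(0)), "no cores")
})

test_that("peak matching accepts close peaks and rejects the 68 ppm case", {
  cands_h <- candidate_masses("SFFFPVP", convention = "h-atom")
  hit <- match_peaks(data.frame(mz = 822.4218, intensity = 1), cands_h,
                     tol_ppm = 10)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_hydroxyl, 0L)
  expect_equal(abs(hit$ppm), 3.4, tolerance = 0.05 / 3.4)

  # the observed m/z 892.3201 compound is ~68 ppm from trihydroxylated
  # cyclo(ISDPTAYP) and must not match at 10 ppm
  tri <- candidate_masses("ISDPTAYP")
  miss <- match_peaks(data.frame(mz = 892.3201, intensity = 1), tri,
                      tol_ppm = 10)
  expect_equal(nrow(miss), 0L)

  exact <- match_peaks(data.frame(mz = tri$mz[1], intensity = 1), tri)
  expect_equal(exact$ppm[exact$is_best], 0)
  expect_error(match_peaks(data.frame(mz = 1, intensity = 1), tri[0, ]),
               "empty candidate")
})

test_that("matches at a loose tolerance contain matches at a tight one", {
  cands <- candidate_masses(c("SFFFPVP", "ISDPTAYP", "IWGIGCNP"))
  set.seed(9)
  peaks <- data.frame(
    mz = cands$mz * (1 + rnorm(nrow(cands), sd = 6) * 1e-6),
    intensity = 1
  )
  key <- function(m) paste(m$peak_mz, m$candidate_mz)
  tight <- match_peaks(peaks, cands, tol_ppm = 4)
  loose <- match_peaks(peaks, cands, tol_ppm = 12)
  expect_true(all(key(tight) %in% key(loose)))
  expect_gt(nrow(loose), nrow(tight))
})

test_that("the cyclic ladder enumerates all n(n-1) fragments", {
  ladder <- fragment_ladder("SFFFPVP")
  expect_equal(nrow(ladder$fragments), 42L)
  gg <- fragment_ladder("GG")
  expect_equal(gg$fragments$mz, c(58.0287, 58.0287), tolerance = 1e-3 / 58)
  expect_error(fragment_ladder("SFFFPVP", topology = "linear"), "cyclic")
})

test_that("sequential-loss arithmetic holds: losing Val leaves the Val mass", {
  ladder <- fragment_ladder("SFFFPVP")
  frags <- ladder$fragments
  six <- frags[frags$length == 6 & !grepl("V", frags$residues), ]
  expect_equal(nrow(six), 1L)
  expect_equal(ladder$precursor_mz - six$mz, 99.0684,
               tolerance = 1e-3 / 99)
})

test_that("ladders are rotation invariant as m/z multisets", {
  seq <- "IVGILGLP"
  ref <- sort(fragment_ladder(seq)$fragments$mz)
  for (r in 1:7) {
    rot <- paste0(substr(seq, r + 1, 8), substr(seq, 1, r))
    expect_equal(sort(fragment_ladder(rot)$fragments$mz), ref)
  }
})

test_that("complementary fragments partition the full ring mass", {
  ladder <- fragment_ladder("AWLATCP")
  n <- ladder$n
  frags <- ladder$fragments
  proton <- mass_constants()["proton"]
  ring_sum <- ladder$precursor_mz - proton
  for (s in seq_len(n)) {
    for (k in seq_len(n - 1)) {
      a <- frags$mz[frags$start == s & frags$length == k] - proton
      comp_start <- (s + k - 1) %% n + 1
      b <- frags$mz[frags$start == comp_start & frags$length == n - k] -
        proton
      expect_equal(unname(a + b), unname(ring_sum), tolerance = 1e-9)
    }
  }
})

test_that("MS/MS annotation computes backbone coverage", {
  ladder <- fragment_ladder("SFFFPVP")
  full <- data.frame(mz = ladder$fragments$mz, intensity = 1)
  ann <- annotate_msms(full, "SFFFPVP", tol_ppm = 5)
  expect_equal(ann$coverage, 1)
  expect_true(ann$full_coverage)
  expect_equal(ann$n_matched, 42L)

  # removing every peak mass observable from ring-opening boundary 1
  # breaks full coverage (repeated residues make some fragment masses
  # degenerate, so peaks are dropped by m/z, not by fragment identity)
  n <- ladder$n
  b_before <- (ladder$fragments$start - 2) %% n + 1
  b_after <- (ladder$fragments$start + ladder$fragments$length - 2) %% n + 1
  banned <- ladder$fragments$mz[b_before == 1 | b_after == 1]
  keep <- !(ladder$fragments$mz %in% banned)
  partial <- data.frame(mz = ladder$fragments$mz[keep], intensity = 1)
  ann2 <- annotate_msms(partial, "SFFFPVP", tol_ppm = 5)
  expect_lt(ann2$coverage, 1)
  expect_false(ann2$full_coverage)

  empty <- annotate_msms(data.frame(mz = numeric(0), intensity = numeric(0)),
                         "SFFFPVP")
  expect_equal(empty$coverage, 0)
  expect_equal(empty$n_matched, 0L)
})
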