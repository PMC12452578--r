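test_that("digest applies the KP rule, acid both-sides rule and filters", {
  # trypsin: K followed by P is protected, so AAKPGGR stays intact
  d <- digest("AAKPGGRAA", "trypsin", max_missed = 0)
  expect_equal(d$sequence, "AAKPGGR")
  expect_equal(d$missed_sites, 0L)
  # acid cleaves on both sides of D (length filter relaxed to observe all)
  d2 <- digest("GGDGG", "acid", max_missed = 0, len_range = c(1L, 40L))
  expect_setequal(d2$sequence, c("GG", "D"))
  expect_equal(sort(paste0(d2$start, "-", d2$end)),
               c("1-2", "3-3", "4-5"))
  expect_error(digest("AAKBB", "trypsin"), "position 4")
  expect_error(digest("AAA", "trypsin", max_missed = -1), "max_missed")
})

test_that("digestion equals exhaustive enumeration on random sequences", {
  set.seed(71)
  for (rep in 1:25) {
    p <- random_protein(sample(20:80, 1))
    mode <- sample(c("trypsin", "acid"), 1)
    mm <- sample(0:3, 1)
    got <- sort(digest(p, mode, max_missed = mm)$sequence)
    expect_equal(got, oracle_digest(p, mode, mm),
                 label = sprintf("rep %d (%s, mm=%d)", rep, mode, mm))
  }
})

test_that("peptide masses are additive over the residue table", {
  # glycine: residue 57.02146 + water + proton
  expect_equal(peptide_mass("G"), 57.02146 + 18.010565 + 1.007276,
               tolerance = 1e-6)
  expect_equal(peptide_mass("AG") - peptide_mass("G"), 71.03711,
               tolerance = 1e-6)
  set.seed(72)
  for (rep in 1:10) {
    a <- random_protein(sample(3:15, 1))
    b <- random_protein(sample(3:15, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565 - 1.007276,
                 tolerance = 1e-9)
  }
  expect_equal(peptide_mass("CC", cys_fixed_mod = "carbamidomethyl") -
                 peptide_mass("CC"), 2 * 57.02146, tolerance = 1e-6)
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("AB"), "position 2")
})

test_that("matching is self-consistent at zero noise and degrades smoothly", {
  tpl <- fx_template()
  mat <- tpl$kappa$mature_protein
  theo <- digest(mat, "trypsin", chain = "light")
  clean <- peak_list(theo$mh_mono, rep(1, nrow(theo)), "clean", "trypsin")
  fp <- match_peaks(clean, theo, tol_ppm = 100,
                    chain_lengths = list(light = nchar(mat)))
  expect_equal(nrow(fp$matches), nrow(clean$peaks))
  expect_true(all(abs(fp$matches$error_ppm) < 1e-9))
  expect_equal(fp$coverage_fraction, 1.0)

  # empty peak list: coverage 0, all CDR assignments false
  cd <- cdr_spans(mat, "light", tpl$kappa$cdr3_aa,
                  cdr1 = c(27, 32), cdr2 = c(50, 56))
  empty <- peak_list(numeric(0), numeric(0), "empty", "trypsin")
  fp0 <- match_peaks(empty, theo, tol_ppm = 100, cdrs = cd,
                     chain_lengths = list(light = nchar(mat)))
  expect_equal(fp0$coverage_fraction, 0)
  expect_false(any(fp0$cdr_assignments$assigned))

  # coverage non-decreasing in tolerance and in max_missed
  cfg <- fixture_config(seed = 3, mz_jitter_ppm = 40, n_noise_peaks = 0)
  sim <- simulate_spectrum(mat, "trypsin", cfg, chain = "light")
  cov_tol <- vapply(c(10, 50, 100, 200), function(tol)
    match_peaks(sim$peaks, theo, tol_ppm = tol,
                chain_lengths = list(light = nchar(mat)))$coverage_fraction, 0)
  expect_true(all(diff(cov_tol) >= 0))
  cov_mm <- vapply(0:3, function(mm)
    match_peaks(sim$peaks, digest(mat, "trypsin", max_missed = mm,
                                  chain = "light"),
                tol_ppm = 100,
                chain_lengths = list(light = nchar(mat)))$coverage_fraction, 0)
  expect_true(all(diff(cov_mm) >= 0))
})

test_that("simulated spectra recover attainable coverage, lost to dropout", {
  tpl <- fx_template()
  mat <- tpl$kappa$mature_protein
  theo <- digest(mat, "acid", chain = "light")
  cfg0 <- fixture_config(seed = 5, peak_dropout = 0, mz_jitter_ppm = 0,
                         n_noise_peaks = 0)
  sim0 <- simulate_spectrum(mat, "acid", cfg0, chain = "light")
  fp0 <- match_peaks(sim0$peaks, theo, tol_ppm = 100,
                     chain_lengths = list(light = nchar(mat)))
  # zero-noise coverage equals the digest's attainable maximum (residues in
  # no 4-40 aa fragment -- e.g. aspartate-free stretches over 40 aa -- are
  # unreachable by construction); oracle union computed directly
  mask <- logical(nchar(mat))
  for (k in seq_len(nrow(theo))) mask[theo$start[k]:theo$end[k]] <- TRUE
  expect_equal(fp0$coverage_fraction, mean(mask))
  expect_gt(fp0$coverage_fraction, 0.5)
  covs <- vapply(c(0, 0.5, 0.95), function(dr) {
    cfg <- fixture_config(seed = 5, peak_dropout = dr, mz_jitter_ppm = 0,
                          n_noise_peaks = 0)
    sim <- simulate_spectrum(mat, "acid", cfg, chain = "light")
    match_peaks(sim$peaks, theo, tol_ppm = 100,
                chain_lengths = list(light = nchar(mat)))$coverage_fraction
  }, 0)
  expect_true(all(diff(covs) <= 0))
  expect_lt(covs[3], covs[1])
})

test_that("cdr_spans validates spans and locates the CDR3 automatically", {
  tpl <- fx_template()
  mat <- tpl$kappa$mature_protein
  cd <- cdr_spans(mat, "light", tpl$kappa$cdr3_aa)
  expect_equal(cd$end_aa - cd$start_aa + 1L, nchar(tpl$kappa$cdr3_aa))
  expect_equal(unname(unlist(
    cd[cd$label == "CDR3", c("start_aa", "end_aa")])),
    tpl$kappa$cdr_spans_aa$CDR3)
  expect_error(cdr_spans(mat, "light", tpl$kappa$cdr3_aa, cdr1 = c(30, 20)),
               "end < start")
  expect_error(cdr_spans(mat, "light", tpl$kappa$cdr3_aa,
                         cdr1 = c(1, 5000)), "outside")
  # adjacent non-overlapping spans accepted; overlap rejected
  ok <- cdr_spans(mat, "light", tpl$kappa$cdr3_aa, cdr1 = c(10, 20),
                  cdr2 = c(21, 30))
  expect_equal(nrow(ok), 3L)
  expect_error(cdr_spans(mat, "light", tpl$kappa$cdr3_aa, cdr1 = c(10, 22),
                         cdr2 = c(21, 30)), "overlap")
})
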