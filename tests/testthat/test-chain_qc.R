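test_that("annotate_orf finds the leader ORF and flags forced stops", {
  set.seed(31)
  # ATG GCT TAA + downstream coding: stop at codon 3
  downstream <- random_dna(60)
  orf <- annotate_orf(paste0("ATGGCTTAA", downstream))
  expect_true(orf$premature_stop)
  expect_equal(orf$stop_position_aa, 3L)
  expect_true(orf$leader_detected)
  expect_equal(substring(orf$protein, 1, 2), "MA")

  # productive fixture kappa transcript: no premature stop
  tpl <- fx_template()
  kappa_amp <- substring(tpl$kappa$mrna, tpl$kappa$read_region[1],
                         tpl$kappa$read_region[2])
  orf_k <- annotate_orf(kappa_amp)
  expect_false(orf_k$premature_stop)
  expect_true(orf_k$leader_detected)

  # aberrant fixture kappa: junction frameshift -> early stop
  orf_ab <- annotate_orf(tpl$kappa$aberrant_read_region_seq)
  expect_true(orf_ab$premature_stop)

  expect_error(annotate_orf("ATGGCT"), "60")
})

test_that("annotate_orf protein equals brute-force codon translation", {
  tpl <- fx_template()
  for (chain in c("heavy", "kappa")) {
    amp <- substring(tpl[[chain]]$mrna, tpl[[chain]]$read_region[1],
                     tpl[[chain]]$read_region[2])
    orf <- annotate_orf(amp)
    frame_seq <- substring(amp, orf$start_nt)
    ref <- oracle_translate(frame_seq)
    ref <- sub("\\*.*$", "", ref)  # up to first stop
    expect_equal(orf$protein, ref, label = paste(chain, "protein"))
  }
})

test_that("flag_aberrant combines reference identity and ORF evidence", {
  tpl <- fx_template()
  ab_refs <- Filter(function(r) r$category == "aberrant_kappa",
                    tpl$references)
  # consensus equal to a bundled aberrant reference: identity 1.0
  fa <- flag_aberrant(ab_refs[[1]]$sequence, ab_refs)
  expect_true(fa$aberrant)
  expect_equal(fa$best_identity, 1.0)
  expect_true("reference_match" %in% fa$evidence)

  # productive fixture chain: below 0.95 to every aberrant reference
  kappa_amp <- substring(tpl$kappa$mrna, tpl$kappa$read_region[1],
                         tpl$kappa$read_region[2])
  fa2 <- flag_aberrant(kappa_amp, ab_refs)
  expect_false(fa2$aberrant)
  expect_lt(fa2$best_identity, 0.95)

  # monotone in min_identity: raising the threshold never flips FALSE->TRUE
  for (thr in c(0.90, 0.95, 0.99)) {
    fa_thr <- flag_aberrant(kappa_amp, ab_refs, min_identity = thr)
    expect_false(fa_thr$aberrant)
  }
  expect_error(flag_aberrant("ACGT", list()), "empty")
})

test_that("the eight-read kappa fixture flags exactly the aberrant cluster", {
  tpl <- fx_template()
  clusters <- fx_consensus("kappa")
  ab_refs <- Filter(function(r) r$category == "aberrant_kappa",
                    tpl$references)
  flags <- vapply(clusters, function(cl)
    flag_aberrant(cl$consensus, ab_refs)$aberrant, TRUE)
  expect_equal(sum(flags), 1L)
  expect_length(clusters[[which(flags)]]$members, 4L)
  expect_length(clusters[[which(!flags)]]$members, 4L)
})

test_that("compare_to_strain ranks references and maps codon differences", {
  tpl <- fx_template()
  strain_refs <- fx_strain_refs()
  sample_const <- substring(tpl$heavy$mrna, tpl$heavy$regions$const[1],
                            tpl$heavy$regions$const[2])
  cmp <- compare_to_strain(sample_const, strain_refs, aa_offset = 119L)
  expect_equal(cmp[[1]]$strain, "NOD")
  expect_equal(cmp[[1]]$n_nt_differences, 0L)
  expect_equal(nrow(cmp[[1]]$aa_differences), 0L)
  expect_equal(cmp[[2]]$strain, "C57BL/6J")
  expect_equal(cmp[[2]]$n_nt_differences, 2L)
  aa <- cmp[[2]]$aa_differences
  expect_equal(nrow(aa), 1L)
  expect_equal(aa$position_aa, 435L)
  expect_equal(aa$residue_sample, "G")
  expect_equal(aa$residue_ref, "V")
  # every aa difference maps to a nt difference within its codon
  codon_nt <- (aa$position_aa - 119L - 1L) * 3L + 1:3
  expect_true(all(cmp[[2]]$nt_differences$position_nt %in% codon_nt))

  # identity case
  self <- compare_to_strain(strain_refs[[1]]$sequence, strain_refs[1])
  expect_equal(self[[1]]$n_nt_differences, 0L)
})

test_that("compare_to_strain is symmetric under sample/reference swap", {
  tpl <- fx_template()
  strain_refs <- fx_strain_refs()
  a <- strain_refs[[1]]$sequence
  b <- strain_refs[[2]]$sequence
  ab <- compare_to_strain(a, strain_refs[2])[[1]]
  ba <- compare_to_strain(b, strain_refs[1])[[1]]
  expect_equal(ab$nt_differences$position_nt, ba$nt_differences$position_nt)
  expect_equal(ab$nt_differences$base_sample, ba$nt_differences$base_ref)
  expect_equal(ab$aa_differences$residue_sample, ba$aa_differences$residue_ref)
  expect_error(compare_to_strain("ACGT", list(
    reference_record("x", "ACGTACGT", "constant_region",
                     subclass_or_strain = "NOD"))), "50 nt")
})
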