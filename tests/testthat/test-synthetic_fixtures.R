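test_that("fixture generation is deterministic and validates its config", {
  t1 <- make_antibody_template(fixture_config(seed = 9))
  t2 <- make_antibody_template(fixture_config(seed = 9))
  expect_identical(t1$heavy$mrna, t2$heavy$mrna)
  expect_identical(t1$kappa$mrna, t2$kappa$mrna)
  r1 <- make_clone_reads(t1$kappa, fixture_config(seed = 9))
  r2 <- make_clone_reads(t2$kappa, fixture_config(seed = 9))
  expect_identical(vapply(r1$reads, `[[`, "", "sequence"),
                   vapply(r2$reads, `[[`, "", "sequence"))

  expect_error(fixture_config(subclass = "IgG9"), "subclass")
  expect_error(fixture_config(strain = "BALB/c"), "strain")
  expect_error(fixture_config(read_error_rate = 1.5), "probabilities")
  expect_error(fixture_config(n_reads_per_chain = 8, aberrant_fraction = 0.3),
               "integral")
})

test_that("templates follow the mRNA architecture with consistent truth", {
  tpl <- fx_template()
  for (chain in c("heavy", "kappa")) {
    t_ <- tpl[[chain]]
    # region bookkeeping tiles the mRNA
    expect_equal(t_$regions$leader[1], 1L)
    expect_equal(t_$regions$polyA[2], nchar(t_$mrna))
    # poly-A tail of 30 A
    expect_equal(substring(t_$mrna, t_$regions$polyA[1]),
                 strrep("A", 30))
    # mature protein is the in-frame translation V..constant, stop-free
    expect_false(grepl("*", t_$mature_protein, fixed = TRUE))
    # CDR3 embedded at the annotated position
    expect_equal(substring(t_$mrna, t_$regions$CDR3[1], t_$regions$CDR3[2]),
                 if (chain == "heavy") "GTCAGATACGGTGGTGGAGGGTTTGCTTAC"
                 else "CAGCAGTATCATAGTTACCCACGGACG")
  }
  expect_equal(nchar(tpl$heavy$mature_protein), 449L)
  expect_equal(tpl$strain_aa_position, 435L)
  # NOD vs C57BL/6J constant references differ only by the dinucleotide swap
  refs <- fx_strain_refs()
  seqs <- setNames(vapply(refs, `[[`, "", "sequence"),
                   vapply(refs, `[[`, "", "subclass_or_strain"))
  d <- which(strsplit(seqs[["NOD"]], "")[[1]] !=
               strsplit(seqs[["C57BL/6J"]], "")[[1]])
  expect_length(d, 2L)
  expect_equal(diff(d), 1L)
})

test_that("clone reads honour error rate and aberrant fraction", {
  tpl <- fx_template()
  # error rate 0: reads equal the template substring
  cfg0 <- fixture_config(seed = 2, read_error_rate = 0,
                         aberrant_fraction = 0)
  r0 <- make_clone_reads(tpl$heavy, cfg0)
  base <- substring(tpl$heavy$mrna, tpl$heavy$read_region[1],
                    tpl$heavy$read_region[2])
  expect_true(all(vapply(r0$reads, `[[`, "", "sequence") == base))
  expect_false(any(r0$truth$aberrant))

  # default kappa composition: 4 productive + 4 aberrant
  rk <- make_clone_reads(tpl$kappa, fixture_config(seed = 2))
  expect_length(rk$reads, 8L)
  expect_equal(sum(rk$truth$aberrant), 4L)
  ab_seq <- tpl$kappa$aberrant_read_region_seq
  for (i in which(rk$truth$aberrant))
    expect_equal(nchar(rk$reads[[i]]$sequence), nchar(ab_seq))
})

test_that("simulated spectra honour dropout, jitter and noise settings", {
  tpl <- fx_template()
  mat <- tpl$kappa$mature_protein
  theo <- digest(mat, "trypsin", chain = "light")
  # identity channel
  cfg0 <- fixture_config(seed = 4, peak_dropout = 0, mz_jitter_ppm = 0,
                         n_noise_peaks = 0)
  sim0 <- simulate_spectrum(mat, "trypsin", cfg0, chain = "light")
  expect_setequal(round(sim0$peaks$peaks$mz, 6), round(theo$mh_mono, 6))
  # total dropout leaves only the decoys
  cfg1 <- fixture_config(seed = 4, peak_dropout = 1, n_noise_peaks = 7)
  sim1 <- simulate_spectrum(mat, "trypsin", cfg1, chain = "light")
  expect_equal(nrow(sim1$truth), 0L)
  expect_equal(nrow(sim1$peaks$peaks), 7L)
  # seeded reproducibility
  simA <- simulate_spectrum(mat, "acid", fixture_config(seed = 6))
  simB <- simulate_spectrum(mat, "acid", fixture_config(seed = 6))
  expect_identical(simA$peaks$peaks, simB$peaks$peaks)
})

test_that("fixture outputs satisfy the package type invariants", {
  tpl <- fx_template()
  for (r in tpl$references) {
    expect_s3_class(r, "reference_record")
    expect_false(grepl("N", r$sequence, fixed = TRUE))
  }
  reads <- make_clone_reads(tpl$kappa, fixture_config(seed = 1))$reads
  ids <- vapply(reads, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0)
  sim <- simulate_spectrum(tpl$kappa$mature_protein, "acid",
                           fixture_config(seed = 1))
  expect_true(all(diff(sim$peaks$peaks$mz) > 0))
  expect_true(all(sim$peaks$peaks$mz > 0))
})
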