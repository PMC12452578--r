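test_that("derive_motifs finds unique windows and enforces preconditions", {
  # two references differing at one column: each gets unique k-mers
  base <- strsplit("ACGTACGTACGTCCGGAATTCCGGTTAA", "")[[1]]
  alt <- base; alt[14] <- "T"
  refs <- list(
    reference_record("c1", paste(base, collapse = ""), "CH1_exon",
                     subclass_or_strain = "IgG1"),
    reference_record("c2", paste(alt, collapse = ""), "CH1_exon",
                     subclass_or_strain = "IgG2a"))
  ms <- derive_motifs(refs)
  expect_true(all(c("IgG1", "IgG2a") %in% ms$subclass))
  # minimality: every reported motif is a minimal unique window
  expect_true(all(nchar(ms$motif) == 8))

  # duplicate reference sequences make uniqueness impossible
  dup <- list(refs[[1]],
              reference_record("c2", refs[[1]]$sequence, "CH1_exon",
                               subclass_or_strain = "IgG2a"))
  expect_error(derive_motifs(dup), "identical")
})

test_that("every bundled motif hits exactly one subclass reference", {
  motifs <- fx_motifs()
  ch1 <- fx_refs_of("CH1_exon")
  expect_true(all(table(motifs$subclass) >= 1))
  for (i in seq_len(nrow(motifs))) {
    hits <- vapply(ch1, function(r)
      grepl(motifs$motif[i], r$sequence, fixed = TRUE), TRUE)
    expect_equal(sum(hits), 1L, label = sprintf("motif %s", motifs$motif[i]))
    expect_equal(ch1[[which(hits)]]$subclass_or_strain, motifs$subclass[i])
  }
})

test_that("all five planted subclasses are recovered from their stubs", {
  motifs <- fx_motifs()
  for (sc in c("IgG1", "IgG2a", "IgG2b", "IgG2c", "IgG3")) {
    tpl <- fx_template(fixture_config(subclass = sc))
    stub <- substring(tpl$heavy$mrna, tpl$heavy$read_region[1],
                      tpl$heavy$read_region[2])
    expect_equal(call_isotype(stub, motifs)$subclass, sc,
                 label = sprintf("planted %s", sc))
  }
})

test_that("isotype is called from consensus and light chain from CL stub", {
  call_h <- call_isotype(fx_consensus("heavy")[[1]]$consensus, fx_motifs(),
                         fx_light_refs())
  expect_equal(call_h$subclass, "IgG2c")
  expect_equal(call_h$light_chain, "none")

  call_k <- call_isotype(fx_consensus("kappa")[[1]]$consensus, fx_motifs(),
                         fx_light_refs())
  expect_equal(call_k$light_chain, "kappa")

  # no CH1 stub: ambiguous with no coherent evidence
  set.seed(51)
  call_none <- call_isotype(random_dna(120), fx_motifs())
  expect_equal(call_none$subclass, "ambiguous")
  expect_false(any(call_none$evidence$coherent))
})

test_that("scan_primer_sites equals a brute-force minimum-Hamming search", {
  set.seed(52)
  for (rep in 1:10) {
    ref_seq <- random_dna(120)
    L <- sample(15:25, 1)
    role <- sample(c("RT", "vdj_specific"), 1)
    pr <- primer_record("p", random_dna(L), role)
    ref <- reference_record("ref", ref_seq, "CH1_exon",
                            subclass_or_strain = "IgG1")
    got <- scan_primer_sites(pr, list(ref))
    probe <- if (role == "RT") revcomp_test(pr$sequence) else pr$sequence
    pv <- strsplit(probe, "")[[1]]
    rv <- strsplit(ref_seq, "")[[1]]
    mins <- min(vapply(seq_len(120 - L + 1), function(o)
      sum(pv != rv[o:(o + L - 1)]), 0L))
    expect_equal(got$mismatches, mins, label = sprintf("replicate %d", rep))
  }
})

test_that("primer audit reproduces the per-subclass mismatch pattern", {
  ch1 <- fx_refs_of("CH1_exon")
  sc_of <- function(df) setNames(df$mismatches, df$subclass_or_strain)
  rt <- sc_of(scan_primer_sites(fx_primer("mIGG-RT"), ch1))
  expect_equal(rt[["IgG1"]], 0L)
  expect_equal(rt[["IgG2a"]], 0L)
  expect_equal(rt[["IgG2b"]], 0L)
  expect_equal(rt[["IgG2c"]], 0L)
  expect_equal(rt[["IgG3"]], 5L)
  pcr <- sc_of(scan_primer_sites(fx_primer("mIGG-PCR"), ch1))
  expect_equal(pcr[["IgG2b"]], 1L)
  expect_equal(pcr[["IgG3"]], 4L)
  expect_equal(pcr[["IgG1"]] + pcr[["IgG2a"]] + pcr[["IgG2c"]], 0L)
  # mismatch count always equals the number of reported positions
  all_rows <- scan_primer_sites(fx_primer("mIGG-PCR"), ch1)
  n_pos <- vapply(strsplit(all_rows$mismatch_positions, ","),
                  function(x) length(x[nzchar(x)]), 0L)
  expect_equal(all_rows$mismatches, n_pos)
})
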