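test_that("table junctions are recovered exactly from the fixture chains", {
  heavy_cons <- fx_consensus("heavy")[[1]]$consensus
  cdr3_h <- find_cdr3(heavy_cons, "heavy", fx_v_refs("heavy"),
                      fx_j_refs("heavy"))
  expect_equal(cdr3_h$cdr3_nt, "GTCAGATACGGTGGTGGAGGGTTTGCTTAC")
  expect_equal(cdr3_h$cdr3_aa, "VRYGGGGFAY")

  kappa_cl <- fx_consensus("kappa")
  ab_refs <- Filter(function(r) r$category == "aberrant_kappa",
                    fx_template()$references)
  productive <- which(!vapply(kappa_cl, function(cl)
    flag_aberrant(cl$consensus, ab_refs)$aberrant, TRUE))[1]
  cdr3_k <- find_cdr3(kappa_cl[[productive]]$consensus, "kappa",
                      fx_v_refs("kappa"), fx_j_refs("kappa"))
  expect_equal(cdr3_k$cdr3_nt, "CAGCAGTATCATAGTTACCCACGGACG")
  expect_equal(cdr3_k$cdr3_aa, "QQYHSYPRT")
  # span is a 0-based half-open interval over the CDR3
  expect_equal(diff(cdr3_k$span), nchar(cdr3_k$cdr3_nt))
})

test_that("planting arbitrary CDR3s between the anchors recovers them", {
  v <- fx_v_refs("heavy")[1]
  j <- fx_j_refs("heavy")
  set.seed(41)
  for (rep in 1:8) {
    len <- sample(seq(9, 60, by = 3), 1)
    cdr3 <- random_dna(len)
    tplseq <- paste0(v[[1]]$sequence, cdr3, j[[1]]$sequence)
    got <- find_cdr3(tplseq, "heavy", v, j)
    expect_equal(got$cdr3_nt, cdr3, label = sprintf("replicate %d", rep))
  }
})

test_that("find_cdr3 handles the reverse strand and missing anchors", {
  v <- fx_v_refs("kappa")
  j <- fx_j_refs("kappa")
  cdr3 <- "CAGCAGTATCATAGTTACCCACGGACG"
  tplseq <- paste0(v[[1]]$sequence, cdr3, j[[1]]$sequence)
  got <- find_cdr3(revcomp_test(tplseq), "kappa", v, j)
  expect_equal(got$cdr3_nt, cdr3)
  expect_equal(got$strand, "-")

  no_anchor <- list(reference_record("V0", v[[1]]$sequence, "germline_V"))
  expect_error(find_cdr3(tplseq, "kappa", no_anchor, j), "anchor")
})

test_that("assign_germline scores identity and reports co-best ties", {
  set.seed(42)
  ref <- random_dna(200)
  refs <- list(reference_record("self", ref, "germline_V"))
  res <- assign_germline(ref, refs)
  expect_equal(res$identity_pct, 100.0)

  # 2 substitutions over 200 aligned nt -> 99.0%
  mut <- strsplit(ref, "")[[1]]
  mut[50] <- setdiff(c("A", "C", "G", "T"), mut[50])[1]
  mut[150] <- setdiff(c("A", "C", "G", "T"), mut[150])[1]
  res2 <- assign_germline(paste(mut, collapse = ""), refs)
  expect_equal(res2$identity_pct, 99.0)

  # exact tie: two identical references both reported as top
  refs3 <- list(reference_record("a1", ref, "germline_V"),
                reference_record("a2", ref, "germline_V"),
                reference_record("far", random_dna(200), "germline_V"))
  res3 <- assign_germline(ref, refs3)
  expect_equal(sort(res3$id[res3$top]), c("a1", "a2"))
  # brute-force check of the tie: identities computed pairwise agree
  expect_equal(res3$identity_pct[res3$id == "a1"],
               res3$identity_pct[res3$id == "a2"])
  expect_error(assign_germline(ref, list()), "empty")
})

test_that("germline identity is invariant to list order and strand", {
  heavy_cons <- fx_consensus("heavy")[[1]]$consensus
  refs <- c(fx_v_refs("heavy"), fx_refs_of("germline_J")[1])
  r1 <- assign_germline(heavy_cons, refs)
  r2 <- assign_germline(heavy_cons, rev(refs))
  expect_equal(r1, r2)
  r3 <- assign_germline(revcomp_test(heavy_cons), refs, orient = TRUE)
  expect_equal(r3$identity_pct, r1$identity_pct)
})

test_that("annotate_chain assembles calls with fixture-true values", {
  ann <- annotate_chain(fx_consensus("heavy")[[1]]$consensus, "heavy",
                        v_refs = fx_v_refs("heavy"),
                        j_refs = fx_j_refs("heavy"),
                        d_refs = fx_refs_of("germline_D"))
  expect_true(ann$productive)
  # both co-best V alleles and both D alleles reported
  expect_match(ann$v_call, "IGHV-2\\*01")
  expect_match(ann$v_call, "IGHV2-6-8\\*01")
  expect_match(ann$d_call, "IGHD-1\\*01")
  expect_match(ann$d_call, "IGHD-1\\*02")
  expect_equal(ann$j_call, "IGHJ3*01")
  # 4 planted substitutions over 294 aligned nt
  expect_equal(ann$total_identity_pct, 100 * 290 / 294, tolerance = 1e-6)
  expect_equal(ann$cdr3_aa, "VRYGGGGFAY")
})
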