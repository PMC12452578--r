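test_that("step 1 reports the fixture truth for both chains", {
  s1 <- fx_step1()
  h <- s1$chains$heavy
  expect_length(h$clusters, 1L)
  expect_equal(h$flagged_read_pct, 0)
  expect_equal(h$isotype$subclass, "IgG2c")
  expect_equal(h$annotation$cdr3_nt, "GTCAGATACGGTGGTGGAGGGTTTGCTTAC")
  expect_true(h$annotation$productive)
  expect_false(is.null(h$primer))

  k <- s1$chains$kappa
  expect_length(k$clusters, 2L)
  expect_equal(k$flagged_read_pct, 50)
  expect_equal(k$annotation$cdr3_nt, "CAGCAGTATCATAGTTACCCACGGACG")
  expect_error(run_step1(list(), fx_template()$references), "named list")
  expect_error(run_step1(list(kappa = list()), fx_template()$references),
               "heavy")
})

fx_step2 <- function() {
  if (!is.null(.fixture_cache$s2)) return(.fixture_cache$s2)
  tpl <- fx_template()
  cfg <- fixture_config(seed = 1)
  mat_h <- tpl$heavy$mature_protein
  mat_k <- tpl$kappa$mature_protein
  cd <- rbind(
    cdr_spans(mat_h, "heavy", tpl$heavy$cdr3_aa,
              tpl$heavy$cdr_spans_aa$CDR1, tpl$heavy$cdr_spans_aa$CDR2),
    cdr_spans(mat_k, "light", tpl$kappa$cdr3_aa,
              tpl$kappa$cdr_spans_aa$CDR1, tpl$kappa$cdr_spans_aa$CDR2))
  # fixture spectra constructed to cover five of the six CDRs: peptides
  # fully containing heavy CDR2 are withheld
  mk_peaks <- function(mode) {
    theo <- rbind(digest(mat_h, mode, chain = "heavy"),
                  digest(mat_k, mode, chain = "light"))
    drop <- theo$chain == "heavy" &
      theo$start <= tpl$heavy$cdr_spans_aa$CDR2[1] &
      theo$end >= tpl$heavy$cdr_spans_aa$CDR2[2]
    surv <- theo[!drop, ]
    peak_list(surv$mh_mono, rep(50, nrow(surv)), paste0("fx-", mode), mode)
  }
  s2 <- run_step2(fx_step1(),
                  list(heavy = const_reads(tpl$heavy, cfg),
                       kappa = const_reads(tpl$kappa, cfg)),
                  tpl$references,
                  peaks = list(trypsin = mk_peaks("trypsin"),
                               acid = mk_peaks("acid")),
                  cdr_span_table = cd)
  .fixture_cache$s2 <- s2
  s2
}

test_that("step 2 assembles full-length chains and verifies 5 of 6 CDRs", {
  tpl <- fx_template()
  mat_h <- tpl$heavy$mature_protein
  mat_k <- tpl$kappa$mature_protein
  s2 <- fx_step2()
  # assembly reproduces the template's mature chains without internal stops
  expect_identical(s2$assembly$heavy$mature, mat_h)
  expect_identical(s2$assembly$kappa$mature, mat_k)
  expect_false(s2$assembly$heavy$orf$premature_stop)

  # NOD-derived fixture ranks NOD first with a perfect match
  expect_equal(s2$strain_comparison[[1]]$strain, "NOD")
  expect_equal(s2$strain_comparison[[1]]$n_nt_differences, 0L)
  expect_equal(s2$strain_comparison[[2]]$aa_differences$position_aa, 435L)

  # fingerprint verdict: exactly the five covered CDRs assigned
  ca <- s2$fingerprint$cdr_assignments
  expect_equal(sum(ca$assigned), 5L)
  expect_false(ca$assigned[ca$chain == "heavy" & ca$label == "CDR2"])

  expect_error(run_step2(list(), list()), "run_step1")
})

test_that("the JSON report round-trips with the documented structure", {
  s2 <- fx_step2()
  f <- withr::local_tempfile(fileext = ".json")
  report_to_json(s2, f)
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  schema <- jsonlite::fromJSON(
    system.file("schema", "workflow_report_schema.json",
                package = "sangermab"),
    simplifyVector = FALSE)
  for (key in schema$required)
    expect_true(!is.null(parsed[[key]]), label = paste("report key", key))
  expect_equal(parsed$step, 2L)
  expect_equal(parsed$chains$heavy$isotype$subclass, "IgG2c")
  expect_equal(parsed$chains$kappa$flagged_read_pct, 50)
})
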