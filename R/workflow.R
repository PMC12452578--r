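# Two-step workflow orchestration. Step 1 turns variable-region clone
# reads into per-chain consensus, QC, V-(D-)J annotation, a DNA-level
# isotype call and a CDR3-anchored primer. Step 2 adds the constant-region
# consensus, strain comparison, full-length assembly and MALDI fingerprint
# verification.

#' Run step 1: variable-region sequencing analysis
#'
#' For each chain read set: cluster reads, call per-cluster consensus,
#' flag aberrant clusters, annotate the best productive cluster (CDR3 +
#' germline calls), call the isotype from the heavy consensus, and design
#' the CDR3-anchored forward primer. A failure in one chain does not abort
#' the others.
#'
#' @param reads_by_chain Named list (`heavy`, `kappa`, and/or `lambda`) of
#'   read lists; heavy plus at least one light chain required.
#' @param references List of [reference_record()] objects (germline V/D/J,
#'   CH1 exons, light constant regions, aberrant kappa references).
#' @param primers List of [primer_record()] objects (unused by the
#'   computation itself but echoed into the report).
#' @param identity_threshold Clustering threshold (default 0.99).
#' @param tm_range,len_range Primer-design constraints.
#' @return A `workflow_report` (partial) with per-chain entries: clusters,
#'   QC flags, `chain_annotation`, `isotype_call` (heavy), `primer_spec`.
#' @export
run_step1 <- function(reads_by_chain, references, primers = list(),
                      identity_threshold = 0.99,
                      tm_range = c(55, 65), len_range = c(15, 40)) {
  if (!length(reads_by_chain) || is.null(names(reads_by_chain)))
    abort_validation("reads_by_chain must be a named list of read sets")
  if (!"heavy" %in% names(reads_by_chain))
    abort_validation("a heavy-chain read set is required")
  cat_of <- function(cat) Filter(function(r) r$category == cat, references)
  v_refs <- cat_of("germline_V"); d_refs <- cat_of("germline_D")
  j_refs <- cat_of("germline_J"); ab_refs <- cat_of("aberrant_kappa")
  ch1_refs <- cat_of("CH1_exon")
  light_refs <- Filter(function(r)
    r$subclass_or_strain %in% c("kappa", "lambda") ||
      grepl("^IgLC", r$subclass_or_strain %||% ""), cat_of("constant_region"))
  motifs <- if (length(ch1_refs) >= 2L) derive_motifs(ch1_refs) else NULL
  chains <- list()
  for (chain in names(reads_by_chain)) {
    res <- tryCatch({
      reads <- reads_by_chain[[chain]]
      if (!length(reads)) stop("no reads for chain ", chain)
      clusters <- cluster_reads(reads, identity_threshold)
      qc <- lapply(clusters, function(cl) {
        if (length(ab_refs)) flag_aberrant(cl$consensus, ab_refs)
        else list(aberrant = annotate_orf(cl$consensus)$premature_stop,
                  evidence = "premature_stop", orf = annotate_orf(cl$consensus))
      })
      flagged <- vapply(qc, `[[`, TRUE, "aberrant")
      n_flagged_reads <- sum(vapply(which(flagged), function(i)
        length(clusters[[i]]$members), 0L))
      n_reads <- length(reads)
      best <- which(!flagged)[1]
      ann <- iso <- prim <- NULL
      if (!is.na(best)) {
        ctype <- if (chain == "heavy") "heavy" else chain
        ann <- annotate_chain(clusters[[best]]$consensus, ctype,
                              v_refs = v_refs, j_refs = j_refs,
                              d_refs = if (chain == "heavy") d_refs else NULL)
        if (chain == "heavy" && !is.null(motifs))
          iso <- call_isotype(ann$sequence, motifs, light_refs)
        prim <- design_cdr3_primer(
          ann, ann$sequence, tm_range = tm_range, len_range = len_range,
          name = sprintf("%s_VDJ-PCR", chain))
      }
      list(chain = chain, clusters = clusters, qc = qc,
           n_reads = n_reads, n_flagged_reads = n_flagged_reads,
           flagged_read_pct = 100 * n_flagged_reads / n_reads,
           annotation = ann, isotype = iso, primer = prim,
           error = NULL)
    }, error = function(e) list(chain = chain, error = conditionMessage(e)))
    chains[[chain]] <- res
  }
  failed <- vapply(chains, function(x) !is.null(x$error) ||
                     is.null(x$annotation), TRUE)
  if (all(failed))
    abort_validation(paste(
      "all chains failed QC/annotation:",
      paste(vapply(chains, function(x) x$error %||% "no productive cluster", ""),
            collapse = "; ")))
  structure(list(step = 1L, chains = chains,
                 primers_in = primers,
                 version = as.character(utils::packageVersion("sangermab")),
                 params = list(identity_threshold = identity_threshold,
                               tm_range = tm_range, len_range = len_range)),
            class = "workflow_report")
}

#' Run step 2: constant regions, assembly and fingerprint verification
#'
#' Builds per-chain constant-region consensus from the step-2 clone reads,
#' compares the heavy constant region against strain references, assembles
#' the full-length coding sequence (step-1 variable consensus up to the
#' CDR3 joined with the constant-amplicon consensus from the CDR3 onward),
#' translates the mature chains, and verifies CDRs against MALDI peak
#' lists.
#'
#' @param step1 Report from [run_step1()]; must contain CDR3 annotations.
#' @param constant_reads_by_chain Named list of constant-amplicon read
#'   sets.
#' @param references Reference bundle (needs `constant_region` strain
#'   records for the heavy comparison).
#' @param peaks Optional named list of [peak_list()] objects to match
#'   (pooled into one fingerprint).
#' @param cdr_span_table Optional [cdr_spans()]-style data frame covering
#'   all six CDRs (user-supplied CDR1/2 spans; CDR3 spans from step 1).
#' @param tol_ppm Fingerprint matching tolerance.
#' @param identity_threshold Clustering threshold for constant reads.
#' @return The completed `workflow_report` with `assembly` (per-chain
#'   coding DNA + mature protein), `strain_comparison`, and
#'   `fingerprint`.
#' @export
run_step2 <- function(step1, constant_reads_by_chain, references,
                      peaks = NULL, cdr_span_table = NULL, tol_ppm = 100,
                      identity_threshold = 0.99) {
  if (!inherits(step1, "workflow_report") || step1$step != 1L)
    abort_validation("step1 must be a run_step1() report")
  strain_refs <- Filter(function(r)
    r$category == "constant_region" &&
      !(r$subclass_or_strain %in% c("kappa", "lambda")) &&
      !grepl("^IgLC", r$subclass_or_strain %||% ""), references)
  assembly <- list(); strain_cmp <- NULL
  for (chain in names(constant_reads_by_chain)) {
    s1 <- step1$chains[[chain]]
    if (is.null(s1) || is.null(s1$annotation))
      abort_validation(sprintf(
        "step1 report lacks a CDR3 annotation for chain '%s'", chain))
    ann <- s1$annotation
    clusters <- cluster_reads(constant_reads_by_chain[[chain]],
                              identity_threshold)
    const_cons <- clusters[[1]]$consensus
    # the constant amplicon starts at the CDR3-anchored primer
    cdr3_at <- find_all(ann$cdr3_nt, const_cons)
    if (length(cdr3_at) != 1L)
      abort_validation(sprintf(
        "CDR3 not found uniquely in the %s constant consensus", chain))
    # assemble: step-1 consensus up to (excluding) CDR3 + constant consensus
    full <- paste0(substring(ann$sequence, 1L, ann$cdr3_span_nt[1]),
                   substring(const_cons, cdr3_at))
    # expected chain length (leader + V-(D-)J + constant) from the best
    # constant reference, so the natural stop upstream of the 3' UTR is not
    # mistaken for a premature one
    const_refs_chain <- if (chain == "heavy") strain_refs else
      Filter(function(r)
        r$category == "constant_region" &&
          (r$subclass_or_strain %in% chain ||
             (chain == "lambda" && grepl("^IgLC", r$subclass_or_strain))),
        references)
    expected_aa <- NULL
    if (length(const_refs_chain)) {
      vdj_nt <- (ann$cdr3_span_nt[2] - ann$v_start_nt + 1L) +
        j_length_aa(ann) * 3L
      const_nt <- max(vapply(const_refs_chain, function(r)
        nchar(r$sequence), 0L))
      expected_aa <- (ann$v_start_nt - 1L + vdj_nt + const_nt) %/% 3L
    }
    orf <- annotate_orf(full, expected_length_aa = expected_aa)
    mature_start_aa <- (ann$v_start_nt - orf$start_nt) %/% 3L + 1L
    mature <- substring(orf$protein, mature_start_aa)
    if (chain == "heavy" && length(strain_refs)) {
      vdj_aa <- (ann$cdr3_span_nt[2] - ann$v_start_nt + 1L) %/% 3L +
        j_length_aa(ann)
      const_start <- find_constant_start(full, ann)
      sample_const <- substring(full, const_start)
      sample_const <- substring(sample_const, 1L,
                                nchar(sample_const) -
                                  nchar(sample_const) %% 3L)
      strain_cmp <- compare_to_strain(
        trim_to_ref(sample_const, strain_refs), strain_refs,
        aa_offset = vdj_aa)
    }
    assembly[[chain]] <- list(coding_dna = full, orf = orf, mature = mature,
                              cdr3_aa = ann$cdr3_aa)
  }
  fp <- NULL
  if (!is.null(peaks)) {
    theo <- do.call(rbind, lapply(names(assembly), function(chain) {
      lab <- if (chain == "heavy") "heavy" else "light"
      rbind(digest(assembly[[chain]]$mature, "trypsin", chain = lab),
            digest(assembly[[chain]]$mature, "acid", chain = lab))
    }))
    chain_lengths <- stats::setNames(
      vapply(names(assembly), function(chain)
        nchar(assembly[[chain]]$mature), 0L),
      vapply(names(assembly), function(chain)
        if (chain == "heavy") "heavy" else "light", ""))
    fps <- lapply(peaks, function(pk)
      match_peaks(pk, theo[theo$cleavage_mode == pk$cleavage_mode, ,
                           drop = FALSE],
                  tol_ppm = tol_ppm, cdrs = cdr_span_table,
                  chain_lengths = as.list(chain_lengths)))
    # pool matches across spectra (trypsin + acid) into one overall verdict
    pooled <- do.call(rbind, lapply(fps, `[[`, "matches"))
    fp <- pooled_fingerprint(pooled, cdr_span_table,
                             as.list(chain_lengths), tol_ppm)
    fp$per_spectrum <- fps
  }
  out <- step1
  out$step <- 2L
  out$assembly <- assembly
  out$strain_comparison <- strain_cmp
  out$fingerprint <- fp
  out
}

# coverage and CDR verdicts over matches pooled from several spectra
pooled_fingerprint <- function(matches, cdrs, chain_lengths, tol_ppm) {
  covered <- 0L
  for (cc in names(chain_lengths)) {
    len <- chain_lengths[[cc]]
    if (len == 0L) next
    mask <- logical(len)
    sub <- matches[matches$chain == cc, , drop = FALSE]
    for (k in seq_len(nrow(sub))) mask[sub$start[k]:sub$end[k]] <- TRUE
    covered <- covered + sum(mask)
  }
  total <- sum(unlist(chain_lengths))
  cdr_assign <- NULL
  if (!is.null(cdrs)) {
    cdr_assign <- cdrs
    cdr_assign$assigned <- FALSE
    cdr_assign$peptides <- ""
    for (i in seq_len(nrow(cdr_assign))) {
      sub <- matches[matches$chain == cdr_assign$chain[i] &
                       matches$start <= cdr_assign$start_aa[i] &
                       matches$end >= cdr_assign$end_aa[i], , drop = FALSE]
      if (nrow(sub)) {
        cdr_assign$assigned[i] <- TRUE
        cdr_assign$peptides[i] <- paste(unique(sub$sequence), collapse = ";")
      }
    }
  }
  structure(list(matches = matches,
                 coverage_fraction = if (total > 0) covered / total else 0,
                 cdr_assignments = cdr_assign, tol_ppm = tol_ppm),
            class = "fingerprint_result")
}

# aa length of the J segment downstream of the CDR3 in the annotated query
j_length_aa <- function(ann) {
  # J runs from the anchor codon to the start of the constant region; in
  # the annotation the span is bounded by frame: count codons from the
  # CDR3 end to the first constant codon via the stored J call length
  # (fallback: 11 for heavy, 10 for light)
  if (!is.null(ann$j_length_aa)) return(ann$j_length_aa)
  if (ann$chain_type == "heavy") 11L else 10L
}

# first nt of the constant region = CDR3 end + J length + 1
find_constant_start <- function(full, ann) {
  cdr3_at <- find_all(ann$cdr3_nt, full)[1]
  cdr3_at + nchar(ann$cdr3_nt) + j_length_aa(ann) * 3L
}

# clip a sample constant sequence to the reference length (drops UTR tail)
trim_to_ref <- function(sample_const, refs) {
  L <- max(vapply(refs, function(r) nchar(r$sequence), 0L))
  substring(sample_const, 1L, min(nchar(sample_const), L))
}

#' Serialise a workflow report to JSON
#'
#' @param report A `workflow_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  x <- report_to_list(report)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 6, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

report_to_list <- function(report) {
  chains <- lapply(report$chains, function(ch) {
    if (!is.null(ch$error)) return(list(chain = ch$chain, error = ch$error))
    ann <- ch$annotation
    list(
      chain = ch$chain,
      n_reads = ch$n_reads,
      n_clusters = length(ch$clusters),
      cluster_sizes = vapply(ch$clusters, function(cl) length(cl$members), 0L),
      flagged_read_pct = ch$flagged_read_pct,
      annotation = if (!is.null(ann)) list(
        chain_type = ann$chain_type, v_call = ann$v_call,
        d_call = ann$d_call, j_call = ann$j_call,
        total_identity_pct = ann$total_identity_pct,
        cdr3_nt = ann$cdr3_nt, cdr3_aa = ann$cdr3_aa,
        productive = ann$productive),
      isotype = if (!is.null(ch$isotype)) list(
        subclass = ch$isotype$subclass, light_chain = ch$isotype$light_chain),
      primer = if (!is.null(ch$primer)) list(
        name = ch$primer$name, sequence = ch$primer$sequence,
        tm_celsius = ch$primer$tm_celsius,
        gc_fraction = ch$primer$gc_fraction, anchor = ch$primer$anchor))
  })
  out <- list(tool = "sangermab", version = report$version,
              step = report$step, params = report$params, chains = chains)
  if (!is.null(report$strain_comparison))
    out$strain_comparison <- lapply(report$strain_comparison, function(sc)
      list(strain = sc$strain, reference_id = sc$reference_id,
           n_nt_differences = sc$n_nt_differences,
           aa_differences = sc$aa_differences))
  if (!is.null(report$assembly))
    out$assembly <- lapply(report$assembly, function(a)
      list(mature_length_aa = nchar(a$mature), cdr3_aa = a$cdr3_aa,
           premature_stop = a$orf$premature_stop))
  if (!is.null(report$fingerprint))
    out$fingerprint <- list(
      coverage_pct = 100 * report$fingerprint$coverage_fraction,
      n_matches = nrow(report$fingerprint$matches),
      cdr_assignments = report$fingerprint$cdr_assignments)
  out
}

#' @export
print.workflow_report <- function(x, ...) {
  cat(sprintf("<workflow_report> step %d, chains: %s\n", x$step,
              paste(names(x$chains), collapse = ", ")))
  for (ch in x$chains) {
    if (!is.null(ch$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", ch$chain, ch$error))
    } else {
      cat(sprintf("  %s: %d reads -> %d cluster(s), %.0f%% reads flagged aberrant\n",
                  ch$chain, ch$n_reads, length(ch$clusters),
                  ch$flagged_read_pct))
    }
  }
  invisible(x)
}
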