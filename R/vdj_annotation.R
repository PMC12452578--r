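# Lightweight V-(D-)J annotation: CDR3 junction localisation by anchor
# projection from the best-scoring germline references, and germline gene
# assignment by plain global-alignment percent identity. This deliberately
# does not reproduce a full immunogenetics aligner's composite scoring;
# identity values are descriptive.

#' Assign germline genes by alignment identity
#'
#' Every reference is fitted into the query (reference end-to-end inside a
#' local window of the query) and scored as percent identity over the
#' aligned reference span. All references tied within `tie_margin`
#' percentage points of the best score are reported, which reproduces the
#' common situation where several alleles are co-best matches. When
#' `orient = TRUE` both strands of the query are scored and the better one
#' is kept, since reads from plasmid sequencing may come in either
#' orientation.
#'
#' @param consensus Query DNA (consensus transcript).
#' @param refs Non-empty list of [reference_record()] germline references of
#'   one category.
#' @param tie_margin Ties within this many percentage points of the best
#'   are all reported (default 0.1).
#' @param orient Score both strands of the query (default `TRUE`).
#' @return A data frame ranked by descending identity with columns `id`,
#'   `identity_pct`, `strand`, `top` (logical: within the tie margin).
#' @export
assign_germline <- function(consensus, refs, tie_margin = 0.1, orient = TRUE) {
  if (!length(refs)) abort_validation("empty reference set")
  rows <- lapply(refs, function(r) {
    fit <- fit_identity(r$sequence, consensus, orient = orient)
    data.frame(id = r$id, identity_pct = 100 * fit$identity,
               strand = fit$strand)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$identity_pct, df$id), , drop = FALSE]
  df$top <- df$identity_pct >= max(df$identity_pct) - tie_margin
  rownames(df) <- NULL
  df
}

#' Locate the CDR3 junction by germline anchor projection
#'
#' The CDR3 is defined IMGT-style as the codons strictly between the
#' conserved second cysteine of framework 3 (carried by the V segment) and
#' the conserved J anchor (tryptophan for heavy chains,
#' phenylalanine/tryptophan for light chains). Rather than searching for
#' sequence motifs -- which fails on mutated frameworks -- the best-scoring
#' V and J references are aligned to the query and their annotated anchor
#' codon positions projected onto it.
#'
#' @param consensus Query DNA containing an in-frame V region.
#' @param chain_type `"heavy"`, `"kappa"` or `"lambda"`.
#' @param v_refs,j_refs Non-empty germline reference lists whose records
#'   carry `anchor` positions (see [reference_record()]).
#' @param orient Try both query strands (default `TRUE`).
#' @return List with `cdr3_nt`, `cdr3_aa` (`NA` unless length is a codon
#'   multiple), `span` (0-based half-open nt interval in the oriented
#'   query), `strand`, `v_id`, `j_id`, and the oriented `query`.
#' @export
find_cdr3 <- function(consensus, chain_type = c("heavy", "kappa", "lambda"),
                      v_refs, j_refs, orient = TRUE) {
  chain_type <- match.arg(chain_type)
  if (!length(v_refs) || !length(j_refs))
    abort_validation("empty reference set")
  no_anchor <- function(rr) any(vapply(rr, function(r) is.na(r$anchor), TRUE))
  if (no_anchor(v_refs) || no_anchor(j_refs))
    abort_validation("V/J references must carry anchor positions")
  vfits <- lapply(v_refs, function(r) fit_identity(r$sequence, consensus, orient))
  vbest <- which.max(vapply(vfits, `[[`, 0, "identity"))
  vfit <- vfits[[vbest]]
  query <- vfit$query
  # J is fitted on the strand chosen by the V fit
  jfits <- lapply(j_refs, function(r) fit_identity(r$sequence, query, orient = FALSE))
  jbest <- which.max(vapply(jfits, `[[`, 0, "identity"))
  jfit <- jfits[[jbest]]
  v_anchor <- v_refs[[vbest]]$anchor
  j_anchor <- j_refs[[jbest]]$anchor
  # query position of the last base of the conserved Cys codon
  cys_end <- project_position(vfit$aln, v_anchor + 2L)
  # query position of the first base of the J anchor codon
  j_start <- project_position(jfit$aln, j_anchor)
  if (is.na(cys_end) || is.na(j_start) || j_start <= cys_end + 1L)
    stop(sprintf(paste0(
      "junction not resolvable: V anchor -> %s, J anchor -> %s ",
      "(V '%s' identity %.1f%%, J '%s' identity %.1f%%)"),
      cys_end, j_start, v_refs[[vbest]]$id, 100 * vfit$identity,
      j_refs[[jbest]]$id, 100 * jfit$identity))
  cdr3_nt <- substring(query, cys_end + 1L, j_start - 1L)
  cdr3_aa <- if (nchar(cdr3_nt) %% 3L == 0L) translate_dna(cdr3_nt) else NA_character_
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
       span = c(cys_end, j_start - 1L),  # 0-based half-open
       strand = vfit$strand,
       v_id = v_refs[[vbest]]$id, j_id = j_refs[[jbest]]$id,
       query = query)
}

#' Annotate a consensus chain (germline calls + CDR3 + productivity)
#'
#' Convenience wrapper assembling a `chain_annotation`: top V/(D)/J calls
#' (co-best matches joined by `", "`), percent identity of the V region,
#' the CDR3 at nucleotide and amino-acid level, and a productivity flag
#' (in-frame CDR3 and no premature stop).
#'
#' @param consensus Consensus DNA of one chain.
#' @param chain_type `"heavy"`, `"kappa"` or `"lambda"`.
#' @param v_refs,j_refs Germline references with anchors.
#' @param d_refs Germline D references (heavy chains only; D calls are made
#'   by fitting each D segment into the CDR3).
#' @return A `chain_annotation` list: `chain_type`, `v_call`, `d_call`,
#'   `j_call`, `total_identity_pct`, `cdr3_nt`, `cdr3_aa`, `cdr3_span_nt`,
#'   `productive`, `v_start_nt` (query position where the V region starts;
#'   mature-chain numbering starts here), `sequence` (oriented query).
#' @export
annotate_chain <- function(consensus, chain_type = c("heavy", "kappa", "lambda"),
                           v_refs, j_refs, d_refs = NULL) {
  chain_type <- match.arg(chain_type)
  cdr3 <- find_cdr3(consensus, chain_type, v_refs, j_refs)
  query <- cdr3$query
  vg <- assign_germline(query, v_refs, orient = FALSE)
  jg <- assign_germline(query, j_refs, orient = FALSE)
  d_call <- ""
  if (chain_type == "heavy" && length(d_refs) && nchar(cdr3$cdr3_nt) >= 6L) {
    dg <- assign_germline(cdr3$cdr3_nt, d_refs, orient = FALSE)
    d_call <- paste(dg$id[dg$top], collapse = ", ")
  }
  orf <- annotate_orf(query)
  productive <- !orf$premature_stop && nchar(cdr3$cdr3_nt) %% 3L == 0L
  # V region start on the query: subject start of the best V fit
  vbest_ref <- v_refs[[match(vg$id[1], vapply(v_refs, `[[`, "", "id"))]]
  vfit <- fit_identity(vbest_ref$sequence, query, orient = FALSE)
  v_start <- Biostrings::start(Biostrings::subject(vfit$aln))
  structure(list(
    chain_type = chain_type,
    v_call = paste(vg$id[vg$top], collapse = ", "),
    d_call = d_call,
    j_call = paste(jg$id[jg$top], collapse = ", "),
    total_identity_pct = vg$identity_pct[1],
    cdr3_nt = cdr3$cdr3_nt,
    cdr3_aa = cdr3$cdr3_aa,
    cdr3_span_nt = cdr3$span,
    productive = productive,
    v_start_nt = v_start,
    j_length_aa = nchar(j_refs[[match(cdr3$j_id,
      vapply(j_refs, `[[`, "", "id"))]]$sequence) %/% 3L,
    sequence = query
  ), class = "chain_annotation")
}

#' @export
print.chain_annotation <- function(x, ...) {
  cat(sprintf("<chain_annotation> %s%s\n  V: %s (%.1f%%)\n%s  J: %s\n  CDR3: %s (%s)\n",
              x$chain_type, if (x$productive) " [productive]" else " [NOT productive]",
              x$v_call, x$total_identity_pct,
              if (nzchar(x$d_call)) sprintf("  D: %s\n", x$d_call) else "",
              x$j_call, x$cdr3_nt, x$cdr3_aa))
  invisible(x)
}
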