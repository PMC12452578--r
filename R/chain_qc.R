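# Productive-vs-aberrant decisions for consensus transcripts. Hybridoma
# fusion partners frequently carry a non-productive kappa transcript with a
# frameshift at the V-J junction and a premature termination codon; such
# chains must be recognised and excluded before annotation.

#' Annotate the open reading frame of a consensus transcript
#'
#' All three forward frames are translated. Frames whose first ATG falls
#' within the first `atg_window` nucleotides are preferred -- a full-length
#' antibody transcript begins with the secretion leader, so its initiator
#' ATG is the 5'-most start codon -- and among them the frame with the
#' 5'-most ATG wins; only when no frame has an ATG in the window does the
#' frame with the longest stop-free stretch from the frame start win, with
#' `leader_detected = FALSE`.
#'
#' A stop codon is called *premature* when it interrupts the reading frame
#' before `premature_frac` (default 0.9) of the expected chain length; the
#' expected length defaults to the remaining coding capacity of the
#' consensus itself and can be supplied from a best-matching reference via
#' `expected_length_aa`. A transcript whose best open stretch is shorter
#' than 30 aa in every frame is reported with `premature_stop = TRUE`
#' ("likely aberrant").
#'
#' @param consensus DNA string, length >= 60 nt.
#' @param start_policy `"require_atg"` (default) or `"frame_start"`.
#' @param atg_window Window (nt, from the 5' end) in which the initiator ATG
#'   must start.
#' @param expected_length_aa Optional expected mature+leader chain length in
#'   amino acids, typically from the best-matching reference.
#' @param premature_frac Fraction of the expected length before which a stop
#'   is premature.
#' @return An `orf_report`: `frame_offset` (0/1/2), `protein`,
#'   `premature_stop`, `stop_position_aa` (1-based codon index of the stop,
#'   counted from the selected start; `NA` if none), `leader_detected`,
#'   `start_nt` (1-based position of the selected start codon).
#' @export
annotate_orf <- function(consensus,
                         start_policy = c("require_atg", "frame_start"),
                         atg_window = 90L,
                         expected_length_aa = NULL,
                         premature_frac = 0.9) {
  start_policy <- match.arg(start_policy)
  consensus <- normalize_dna(consensus, label = "consensus", allow_n = TRUE)
  if (nchar(consensus) < 60L)
    abort_validation("consensus shorter than 60 nt")
  best <- NULL
  for (off in 0:2) {
    frame_seq <- substring(consensus, off + 1L)
    aa <- translate_dna(frame_seq)
    if (!nchar(aa)) next
    aav <- strsplit(aa, "")[[1]]
    starts <- which(aav == "M")
    start_codon <- NA_integer_
    leader <- FALSE
    if (start_policy == "require_atg") {
      ok <- starts[(off + (starts - 1L) * 3L + 1L) <= atg_window]
      if (length(ok)) { start_codon <- ok[1]; leader <- TRUE }
    }
    if (is.na(start_codon)) start_codon <- 1L
    rest <- aav[start_codon:length(aav)]
    stop_idx <- which(rest == "*")
    open_len <- if (length(stop_idx)) stop_idx[1] - 1L else length(rest)
    cand <- list(frame_offset = off, start_codon = start_codon,
                 leader = leader, open_len = open_len,
                 start_nt_abs = off + (start_codon - 1L) * 3L + 1L,
                 rest = rest, stop_idx = if (length(stop_idx)) stop_idx[1] else NA_integer_)
    better <- if (is.null(best)) TRUE
      else if (cand$leader != best$leader) cand$leader
      else if (cand$leader) cand$start_nt_abs < best$start_nt_abs
      else cand$open_len > best$open_len
    if (better) best <- cand
  }
  avail_codons <- length(best$rest)
  expected <- expected_length_aa %||% avail_codons
  premature <- FALSE
  if (!is.na(best$stop_idx) && best$stop_idx <= premature_frac * expected)
    premature <- TRUE
  if (best$open_len < 30L) {
    premature <- TRUE
    message("annotate_orf: open stretch < 30 aa in every frame; likely aberrant")
  }
  protein <- paste(best$rest[seq_len(best$open_len)], collapse = "")
  structure(list(
    frame_offset = best$frame_offset,
    protein = protein,
    premature_stop = premature,
    stop_position_aa = best$stop_idx,
    leader_detected = best$leader,
    start_nt = best$frame_offset + (best$start_codon - 1L) * 3L + 1L
  ), class = "orf_report")
}

#' Flag an aberrant (non-productive) consensus chain
#'
#' A consensus is flagged aberrant when its global-alignment identity to any
#' bundled known non-functional reference reaches `min_identity`, or when
#' [annotate_orf()] reports a premature stop codon. Raising `min_identity`
#' can therefore never convert a non-flagged chain into a flagged one.
#'
#' @param consensus DNA string.
#' @param aberrant_refs Non-empty list of [reference_record()] objects of
#'   category `aberrant_kappa`.
#' @param min_identity Identity threshold for the reference branch
#'   (default 0.95).
#' @param orf Optional precomputed [annotate_orf()] report.
#' @return List with `aberrant` (logical), `evidence`
#'   (`"reference_match"`, `"premature_stop"`, both, or none),
#'   `best_match_id`, `best_identity`, and the `orf` report.
#' @export
flag_aberrant <- function(consensus, aberrant_refs, min_identity = 0.95,
                          orf = NULL) {
  if (!length(aberrant_refs)) abort_validation("aberrant_refs is empty")
  ids <- vapply(aberrant_refs, `[[`, "", "id")
  idents <- vapply(aberrant_refs, function(r)
    pairwise_identity(consensus, r$sequence), 0)
  best <- which.max(idents)
  orf <- orf %||% annotate_orf(consensus)
  evidence <- character(0)
  if (idents[best] >= min_identity) evidence <- c(evidence, "reference_match")
  if (orf$premature_stop) evidence <- c(evidence, "premature_stop")
  list(aberrant = length(evidence) > 0L,
       evidence = evidence,
       best_match_id = ids[best],
       best_identity = unname(idents[best]),
       orf = orf)
}

#' Compare a sequenced constant region against strain references
#'
#' The sample is globally aligned against every `constant_region` reference;
#' references are ranked by ascending nucleotide difference count.
#' Amino-acid differences are derived by codon-aligned translation (frame 1
#' of the supplied constant sequences) and are reported 1-based in the
#' assembled mature (leaderless) chain: `aa_offset` gives the number of
#' amino acids preceding the constant region in the mature chain, so a
#' constant-region codon `i` is mature-chain position `aa_offset + i`.
#'
#' @param sample_constant Sequenced constant-region DNA (frame 1 = first
#'   constant codon).
#' @param refs List of [reference_record()] objects with category
#'   `constant_region`; each must be >= 50 nt.
#' @param aa_offset Amino acids preceding the constant region in the mature
#'   chain (typically the V-(D-)J length); default 0 reports positions
#'   within the constant region itself.
#' @return List of `strain_comparison` objects ranked by ascending
#'   nucleotide differences. Each carries `strain` (reference label),
#'   `reference_id`, `nt_differences` (data frame: `position_nt` 1-based in
#'   the sample, `base_sample`, `base_ref`), `aa_differences` (data frame:
#'   `position_aa` mature-chain numbering, `residue_sample`, `residue_ref`),
#'   and `identity`.
#' @export
compare_to_strain <- function(sample_constant, refs, aa_offset = 0L) {
  refs <- Filter(function(r) identical(r$category, "constant_region"), refs)
  if (!length(refs)) abort_validation("no constant_region references supplied")
  short <- vapply(refs, function(r) nchar(r$sequence) < 50L, TRUE)
  if (any(short))
    abort_validation(sprintf("reference '%s' shorter than 50 nt",
                             refs[[which(short)[1]]]$id))
  out <- lapply(refs, function(r) {
    aln <- align_global(sample_constant, r$sequence)
    d <- alignment_differences(aln)
    nt <- if (nrow(d$substitutions)) {
      data.frame(position_nt = d$substitutions$pos_pattern,
                 base_sample = substring(sample_constant,
                                         d$substitutions$pos_pattern,
                                         d$substitutions$pos_pattern),
                 base_ref = substring(r$sequence,
                                      d$substitutions$pos_subject,
                                      d$substitutions$pos_subject))
    } else {
      data.frame(position_nt = integer(0), base_sample = character(0),
                 base_ref = character(0))
    }
    aa <- codon_differences(sample_constant, r$sequence, aln, aa_offset)
    structure(list(strain = r$subclass_or_strain, reference_id = r$id,
                   nt_differences = nt, n_nt_differences = nrow(nt) + d$n_gap_columns,
                   aa_differences = aa, identity = alignment_identity(aln)),
              class = "strain_comparison")
  })
  out[order(vapply(out, `[[`, 0L, "n_nt_differences"))]
}

# Codon-aligned aa differences; only codons aligned without gaps on either
# side are compared.
codon_differences <- function(sample, ref, aln, aa_offset) {
  s <- aln_strings(aln)
  p <- strsplit(s$pattern, "")[[1]]
  q <- strsplit(s$subject, "")[[1]]
  pi <- 0L; qi <- 0L
  # sample codon index -> ref positions of its three bases (NA if gapped)
  map <- integer(nchar(sample)); map[] <- NA_integer_
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (q[k] != "-") qi <- qi + 1L
    if (p[k] != "-" && q[k] != "-") map[pi] <- qi
  }
  n_codon <- nchar(sample) %/% 3L
  rows <- list()
  for (ci in seq_len(n_codon)) {
    ii <- (ci - 1L) * 3L + 1:3
    rr <- map[ii]
    if (any(is.na(rr)) || any(diff(rr) != 1L)) next
    cs <- substring(sample, ii[1], ii[3])
    cr <- substring(ref, rr[1], rr[3])
    if (cs == cr) next
    as_ <- translate_dna(cs); ar <- translate_dna(cr)
    if (as_ != ar)
      rows[[length(rows) + 1L]] <- data.frame(
        position_aa = aa_offset + ci, residue_sample = as_, residue_ref = ar)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(position_aa = integer(0), residue_sample = character(0),
                  residue_ref = character(0))
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("<orf_report> frame +%d, %d aa%s%s\n", x$frame_offset,
              nchar(x$protein),
              if (x$premature_stop) sprintf(", PREMATURE STOP at aa %s",
                                            x$stop_position_aa) else "",
              if (x$leader_detected) ", leader ATG" else ""))
  invisible(x)
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("<strain_comparison> vs %s (%s): %d nt diff, %d aa diff\n",
              x$strain, x$reference_id, x$n_nt_differences,
              nrow(x$aa_differences)))
  invisible(x)
}
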