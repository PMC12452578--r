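# Pairwise alignment layer. All alignments in the package run through these
# wrappers so that one scoring scheme (match +1, mismatch -1, gap open -2,
# gap extend -1) is used everywhere. Scores come from Biostrings'
# Needleman-Wunsch implementation; identity is matches / aligned columns.

align_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# Global (end-to-end) alignment of two DNA strings.
align_global <- function(a, b) {
  Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = align_submat(), gapOpening = 2, gapExtension = 1)
}

# Pattern aligned end-to-end inside a locally chosen window of the subject
# (fit alignment); used to place a short reference segment onto a longer
# consensus.
align_fit <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "global-local",
    substitutionMatrix = align_submat(), gapOpening = 2, gapExtension = 1)
}

aln_strings <- function(aln) {
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)))
}

# Fraction of identical aligned columns (gaps count as columns).
alignment_identity <- function(aln) {
  s <- aln_strings(aln)
  p <- strsplit(s$pattern, "")[[1]]
  q <- strsplit(s$subject, "")[[1]]
  sum(p == q & p != "-") / length(p)
}

# Global-alignment identity between two sequences, in [0, 1].
pairwise_identity <- function(a, b) {
  alignment_identity(align_global(a, b))
}

# Identity of `ref` fitted into `query` (matches / aligned pattern columns),
# plus subject coordinates of the fit. Both strands are scored when
# `orient = TRUE` and the better one is kept.
fit_identity <- function(ref, query, orient = FALSE) {
  fit1 <- align_fit(ref, query)
  id1 <- alignment_identity(fit1)
  if (orient) {
    rc <- revcomp(query)
    fit2 <- align_fit(ref, rc)
    id2 <- alignment_identity(fit2)
    if (id2 > id1)
      return(list(aln = fit2, identity = id2, strand = "-", query = rc))
  }
  list(aln = fit1, identity = id1, strand = "+", query = query)
}

# Ends-free (overlap) alignment: identity over the aligned window plus the
# number of aligned pattern columns; used when only a fragment of the
# pattern is expected to be present in the query (e.g. a constant-region
# stub on a variable-region amplicon).
overlap_identity <- function(pattern, subject) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "overlap",
    substitutionMatrix = align_submat(), gapOpening = 2, gapExtension = 1)
  s <- aln_strings(aln)
  p <- strsplit(s$pattern, "")[[1]]
  q <- strsplit(s$subject, "")[[1]]
  ncol_aln <- length(p)
  list(identity = if (ncol_aln) sum(p == q & p != "-") / ncol_aln else 0,
       overlap = ncol_aln)
}

# Map a pattern position (1-based, in the unaligned pattern) to the subject
# position it is aligned to. Returns NA if the pattern position sits in a
# subject gap or outside the aligned region.
project_position <- function(aln, pattern_pos) {
  s <- aln_strings(aln)
  p <- strsplit(s$pattern, "")[[1]]
  q <- strsplit(s$subject, "")[[1]]
  p_start <- Biostrings::start(Biostrings::pattern(aln))
  q_start <- Biostrings::start(Biostrings::subject(aln))
  pi <- p_start - 1L
  qi <- q_start - 1L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (q[k] != "-") qi <- qi + 1L
    if (p[k] != "-" && pi == pattern_pos) {
      if (q[k] == "-") return(NA_integer_)
      return(qi)
    }
  }
  NA_integer_
}

# Column-level differences of a global alignment: substitution positions in
# both coordinate systems. Gap columns are reported separately.
alignment_differences <- function(aln) {
  s <- aln_strings(aln)
  p <- strsplit(s$pattern, "")[[1]]
  q <- strsplit(s$subject, "")[[1]]
  pi <- 0L; qi <- 0L
  subs <- list(); gaps <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (q[k] != "-") qi <- qi + 1L
    if (p[k] == "-" || q[k] == "-") {
      gaps <- gaps + 1L
    } else if (p[k] != q[k]) {
      subs[[length(subs) + 1L]] <- c(pos_pattern = pi, pos_subject = qi)
    }
  }
  list(
    substitutions = if (length(subs)) {
      m <- do.call(rbind, subs)
      data.frame(pos_pattern = m[, 1], pos_subject = m[, 2])
    } else data.frame(pos_pattern = integer(0), pos_subject = integer(0)),
    n_gap_columns = gaps)
}
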