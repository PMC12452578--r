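# DNA-level isotyping. The CH1 exon of mouse IgG subclasses is highly
# conserved yet carries short subclass-specific stretches; because the
# variable-region RT-PCR primers anneal inside CH1, every variable-region
# amplicon automatically contains these discriminative motifs, so the IgG
# subclass can be read off the same Sanger consensus that yields the V
# region. This matters most for IgG2c (produced by C57BL/6 and NOD mice),
# which is hard to distinguish from IgG2a at the protein level.

#' Derive subclass-discriminative motifs from aligned CH1 references
#'
#' The CH1 exon references (one per subclass) are column-aligned and every
#' minimal-length window unique to one subclass is reported. A window of
#' length `k` (within `k_range`) is *unique* when it occurs as a substring
#' of its own subclass reference and of no other subclass reference;
#' *minimal* means it contains no shorter unique window of the same
#' subclass.
#'
#' @param ch1_refs One [reference_record()] of category `CH1_exon` per
#'   subclass; all pairwise alignable.
#' @param k_range Window length interval (default `c(8, 20)`).
#' @return A `motif_set`: data frame with `subclass`, `motif`, `offset`
#'   (1-based alignment column of the window start) plus an
#'   `alignment_length` attribute.
#' @export
derive_motifs <- function(ch1_refs, k_range = c(8L, 20L)) {
  ch1_refs <- Filter(function(r) identical(r$category, "CH1_exon"), ch1_refs)
  if (length(ch1_refs) < 2L)
    abort_validation("need CH1_exon references for at least two subclasses")
  subclasses <- vapply(ch1_refs, `[[`, "", "subclass_or_strain")
  if (anyDuplicated(subclasses))
    abort_validation("more than one CH1 reference per subclass")
  seqs <- vapply(ch1_refs, `[[`, "", "sequence")
  if (anyDuplicated(seqs))
    abort_validation(sprintf(
      "identical CH1 sequences for subclasses %s: no unique window exists",
      paste(subclasses[duplicated(seqs) | duplicated(seqs, fromLast = TRUE)],
            collapse = ", ")))
  names(seqs) <- subclasses
  # alignment offsets: equal-length references are already columnar;
  # otherwise each sequence is fitted to the longest one
  aln_len <- max(nchar(seqs))
  col_of <- lapply(seqs, function(s) seq_len(nchar(s)))
  if (length(unique(nchar(seqs))) > 1L) {
    backbone <- seqs[[which.max(nchar(seqs))]]
    col_of <- lapply(seqs, function(s) {
      if (identical(s, backbone)) return(seq_len(nchar(s)))
      aln <- align_global(s, backbone)
      vapply(seq_len(nchar(s)), function(i) {
        p <- project_position(aln, i)
        if (is.na(p)) 0L else p
      }, 0L)
    })
  }
  rows <- list()
  for (sc in subclasses) {
    own <- seqs[[sc]]
    others <- seqs[setdiff(subclasses, sc)]
    uniq <- list()
    for (k in seq(k_range[1], k_range[2])) {
      if (k > nchar(own)) break
      for (i in seq_len(nchar(own) - k + 1L)) {
        w <- substring(own, i, i + k - 1L)
        if (!any(vapply(others, function(o) grepl(w, o, fixed = TRUE), TRUE)))
          uniq[[length(uniq) + 1L]] <- list(motif = w, start = i)
      }
    }
    if (!length(uniq))
      abort_validation(sprintf(
        "subclass %s has no unique window of length %d-%d",
        sc, k_range[1], k_range[2]))
    # minimality: drop windows containing a shorter unique window
    motifs <- vapply(uniq, `[[`, "", "motif")
    keep <- vapply(seq_along(uniq), function(i) {
      !any(nchar(motifs) < nchar(motifs[i]) &
             vapply(motifs, function(m) grepl(m, motifs[i], fixed = TRUE), TRUE))
    }, TRUE)
    for (i in which(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        subclass = sc, motif = uniq[[i]]$motif,
        offset = col_of[[sc]][uniq[[i]]$start])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alignment_length") <- aln_len
  class(out) <- c("motif_set", class(out))
  out
}

#' Call mouse IgG subclass and light-chain class at the DNA level
#'
#' Motifs are scanned as exact matches on both strands of the consensus
#' (exact because they live in highly conserved CH1 sequence and the query
#' is a consensus, not a raw read). Because the minimal unique windows can
#' be as short as 8 nt, an isolated exact hit can occur by chance anywhere
#' on a several-hundred-nt amplicon; a subclass therefore counts as
#' *supported* only when at least `min_coherent` of its motif hits are
#' positionally coherent -- same strand and the same implied CH1 placement
#' (`hit position - motif offset`). The subclass with exclusive coherent
#' support is returned; zero or two-plus supported subclasses yield
#' `"ambiguous"`. Light-chain class is assigned by best ends-free
#' constant-region identity against `light_refs` (the amplicon carries
#' only a CL stub, so the overlap must reach `light_min_overlap` columns).
#'
#' @param consensus Consensus DNA (variable-region amplicon including the
#'   CH1 stub for heavy chains, or the CL stub for light chains).
#' @param motifs A [derive_motifs()] result.
#' @param light_refs Optional list of `constant_region` references labelled
#'   `"kappa"` / `"lambda"` (or `IgLC1..4` for lambda subtypes).
#' @param light_min_identity Identity below which no light-chain class is
#'   called (default 0.80).
#' @param light_min_overlap Minimum aligned overlap (nt) for a light-chain
#'   call (default 60).
#' @param min_coherent Minimum number of positionally coherent motif hits
#'   for subclass support (default 2).
#' @return An `isotype_call`: `subclass`, `light_chain`
#'   (`"kappa"`/`"lambda"`/`"none"`), `evidence` (data frame of matched
#'   motifs with positions, strand and coherence flag), `light_identity`.
#' @export
call_isotype <- function(consensus, motifs, light_refs = NULL,
                         light_min_identity = 0.80,
                         light_min_overlap = 60L, min_coherent = 2L) {
  consensus <- normalize_dna(consensus, "consensus", allow_n = TRUE)
  rc <- revcomp(consensus)
  hits <- list()
  for (i in seq_len(nrow(motifs))) {
    m <- motifs$motif[i]
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") consensus else rc
      pos <- find_all(m, subj)
      for (p in pos)
        hits[[length(hits) + 1L]] <- data.frame(
          subclass = motifs$subclass[i], motif = m, position = p,
          strand = strand, implied_start = p - (motifs$offset[i] - 1L))
    }
  }
  evidence <- if (length(hits)) do.call(rbind, hits) else
    data.frame(subclass = character(0), motif = character(0),
               position = integer(0), strand = character(0),
               implied_start = integer(0))
  evidence$coherent <- logical(nrow(evidence))
  supported <- character(0)
  for (sc in unique(evidence$subclass)) {
    ii <- which(evidence$subclass == sc)
    key <- paste(evidence$strand[ii], evidence$implied_start[ii])
    tab <- table(key)
    if (max(tab) >= min_coherent) {
      supported <- c(supported, sc)
      evidence$coherent[ii[key == names(tab)[which.max(tab)]]] <- TRUE
    }
  }
  subclass <- if (length(supported) == 1L) supported else "ambiguous"
  light_chain <- "none"
  light_identity <- NA_real_
  if (length(light_refs)) {
    lids <- vapply(light_refs, `[[`, "", "subclass_or_strain")
    fits <- lapply(light_refs, function(r) {
      f1 <- overlap_identity(r$sequence, consensus)
      f2 <- overlap_identity(r$sequence, rc)
      if (f2$identity * (f2$overlap >= light_min_overlap) >
          f1$identity * (f1$overlap >= light_min_overlap)) f2 else f1
    })
    ok <- vapply(fits, function(f) f$overlap >= light_min_overlap, TRUE)
    idents <- vapply(fits, `[[`, 0, "identity")
    idents[!ok] <- 0
    b <- which.max(idents)
    if (idents[b] >= light_min_identity) {
      light_chain <- if (grepl("^IgLC|lambda", lids[b])) "lambda" else "kappa"
      light_identity <- idents[b]
    }
  }
  structure(list(subclass = subclass, light_chain = light_chain,
                 evidence = evidence, light_identity = light_identity),
            class = "isotype_call")
}

#' Audit a primer binding site against reference sequences
#'
#' The primer -- or its reverse complement for antisense roles (`RT`,
#' `PCR`) -- is slid ungapped across each reference; the offset minimising
#' the Hamming mismatch count is reported together with the mismatch
#' positions (1-based within the primer, counted from its 5' end). The
#' search is ungapped because primer-site evaluation is positional mismatch
#' counting, and an indel in a primer site would abort annealing anyway.
#'
#' @param primer A [primer_record()]; length must not exceed the reference
#'   length.
#' @param refs List of [reference_record()] objects.
#' @return Data frame with one row per reference: `primer`, `reference_id`,
#'   `subclass_or_strain`, `offset` (1-based start of the best window on
#'   the reference), `mismatches`, `mismatch_positions`
#'   (comma-joined), `orientation` (`sense`/`antisense`).
#' @export
scan_primer_sites <- function(primer, refs) {
  antisense <- primer$role %in% c("RT", "PCR")
  probe <- if (antisense) revcomp(primer$sequence) else primer$sequence
  L <- nchar(probe)
  pv <- strsplit(probe, "")[[1]]
  rows <- lapply(refs, function(r) {
    if (L > nchar(r$sequence))
      abort_validation(sprintf("primer '%s' longer than reference '%s'",
                               primer$name, r$id))
    rv <- strsplit(r$sequence, "")[[1]]
    n_off <- length(rv) - L + 1L
    best_mm <- L + 1L; best_off <- 1L; best_pos <- integer(0)
    for (o in seq_len(n_off)) {
      mmv <- which(pv != rv[o:(o + L - 1L)])
      if (length(mmv) < best_mm) {
        best_mm <- length(mmv); best_off <- o; best_pos <- mmv
      }
    }
    # map positions on the scanned probe back to primer 5'->3' coordinates
    primer_pos <- if (antisense) sort(L + 1L - best_pos) else best_pos
    data.frame(primer = primer$name, reference_id = r$id,
               subclass_or_strain = r$subclass_or_strain,
               offset = best_off, mismatches = best_mm,
               mismatch_positions = paste(primer_pos, collapse = ","),
               orientation = if (antisense) "antisense" else "sense")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.isotype_call <- function(x, ...) {
  cat(sprintf("<isotype_call> subclass %s, light chain %s (%d motif hits)\n",
              x$subclass, x$light_chain, nrow(x$evidence)))
  invisible(x)
}
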