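# Protein-level CDR verification by peptide mass fingerprinting: in-silico
# trypsin and dilute-sulfuric-acid digestion of the assembled antibody
# chains, monoisotopic [M+H]+ mass computation, and ppm-tolerant matching
# against MALDI-TOF peak lists. Reflector-mode MALDI observes singly
# protonated monoisotopic masses; no fixed cysteine modification is applied
# by default (the wet protocol omits alkylation).

MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_CARBAMIDOMETHYL <- 57.02146

check_protein <- function(protein, label = "protein") {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    abort_validation(sprintf("%s: empty sequence", label))
  ch <- strsplit(protein, "")[[1]]
  bad <- which(!(ch %in% AA_ALPHABET))
  if (length(bad))
    abort_validation(sprintf("%s: nonstandard residue '%s' at position %d",
                             label, ch[bad[1]], bad[1]))
  ch
}

#' Monoisotopic [M+H]+ mass of a peptide
#'
#' Sum of residue monoisotopic masses plus water (18.010565 Da) plus one
#' proton (1.007276 Da).
#'
#' @param sequence Peptide over the 20 standard residues.
#' @param cys_fixed_mod `"none"` (default; the reference protocol omits
#'   alkylation) or `"carbamidomethyl"` (+57.02146 Da per cysteine).
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, cys_fixed_mod = c("none", "carbamidomethyl")) {
  cys_fixed_mod <- match.arg(cys_fixed_mod)
  ch <- check_protein(sequence, "peptide")
  m <- sum(MONO_RESIDUE_MASS[ch]) + MASS_WATER + MASS_PROTON
  if (cys_fixed_mod == "carbamidomethyl")
    m <- m + MASS_CARBAMIDOMETHYL * sum(ch == "C")
  unname(m)
}

# 0-based cut positions (cut after residue i) for a cleavage mode.
cleavage_sites <- function(ch, mode) {
  n <- length(ch)
  if (mode == "trypsin") {
    # after K or R, except before P
    idx <- which(ch[-n] %in% c("K", "R") & ch[-1] != "P")
  } else {
    # dilute acid: both sides of aspartate (X-D and D-X bonds)
    after_d <- which(ch[-n] == "D")
    before_d <- which(ch[-1] == "D")
    idx <- sort(unique(c(after_d, before_d)))
  }
  idx
}

#' In-silico proteolytic / acid digestion
#'
#' Trypsin cleaves after `K` or `R` except when followed by `P`; dilute
#' sulfuric acid cleaves on both sides of aspartate (`X-D` and `D-X`
#' bonds). Every fragment spanning at most `max_missed` internal sites is
#' emitted, then a residue-length filter (default 4-40) is applied --
#' shorter fragments fall into the MALDI matrix region and longer ones
#' outside the reflector window. Acid hydrolysis is deliberately partial,
#' hence its higher default missed-site allowance.
#'
#' @param protein Parent chain over the 20 standard residues.
#' @param mode `"trypsin"` or `"acid"`.
#' @param max_missed Maximum internal (missed) sites per fragment; default
#'   2 for trypsin, 5 for acid.
#' @param len_range Residue-length filter applied after enumeration.
#' @param chain Chain label stored on each peptide (`"heavy"`/`"light"`).
#' @param cys_fixed_mod Passed to [peptide_mass()].
#' @return Data frame of theoretical peptides: `sequence`, `start`, `end`
#'   (1-based inclusive in the parent), `chain`, `missed_sites`, `mh_mono`,
#'   `cleavage_mode`.
#' @export
digest <- function(protein, mode = c("trypsin", "acid"), max_missed = NULL,
                   len_range = c(4L, 40L), chain = "heavy",
                   cys_fixed_mod = "none") {
  mode <- match.arg(mode)
  if (is.null(max_missed)) max_missed <- if (mode == "acid") 5L else 2L
  if (max_missed < 0L) abort_validation("max_missed must be >= 0")
  ch <- check_protein(protein)
  n <- length(ch)
  sites <- cleavage_sites(ch, mode)
  bounds <- c(0L, sites, n)          # fragment boundaries (cut after index)
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < len_range[1] || len > len_range[2]) next
      pep <- substring(protein, s, e)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, start = s, end = e, chain = chain,
        missed_sites = j - i,
        mh_mono = peptide_mass(pep, cys_fixed_mod),
        cleavage_mode = mode)
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), chain = character(0),
                      missed_sites = integer(0), mh_mono = numeric(0),
                      cleavage_mode = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalise and validate CDR spans for fingerprint assignment
#'
#' CDR1/CDR2 boundaries are not called from DNA by this package; they are
#' user-supplied amino-acid spans. The CDR3 span is derived automatically
#' from a chain annotation (its amino-acid sequence is located in the
#' mature chain).
#'
#' @param mature_protein Mature (leaderless) chain sequence.
#' @param chain Chain label (`"heavy"`/`"light"`).
#' @param cdr3_aa CDR3 amino-acid sequence (from annotation); located
#'   exactly once in `mature_protein`.
#' @param cdr1,cdr2 Optional `c(start, end)` 1-based inclusive spans.
#' @return Data frame `label`, `chain`, `start_aa`, `end_aa`, sorted by
#'   start; overlapping or out-of-range spans raise a validation error.
#' @export
cdr_spans <- function(mature_protein, chain, cdr3_aa, cdr1 = NULL, cdr2 = NULL) {
  n <- nchar(mature_protein)
  occ <- gregexpr(cdr3_aa, mature_protein, fixed = TRUE)[[1]]
  if (occ[1] == -1L) abort_validation("CDR3 not found in mature chain")
  if (length(occ) > 1L) abort_validation("CDR3 occurs more than once in mature chain")
  spans <- list(CDR3 = c(as.integer(occ), as.integer(occ) + nchar(cdr3_aa) - 1L))
  if (!is.null(cdr1)) spans$CDR1 <- as.integer(cdr1)
  if (!is.null(cdr2)) spans$CDR2 <- as.integer(cdr2)
  for (lab in names(spans)) {
    sp <- spans[[lab]]
    if (length(sp) != 2L || sp[2] < sp[1])
      abort_validation(sprintf("%s: span end < start", lab))
    if (sp[1] < 1L || sp[2] > n)
      abort_validation(sprintf("%s: span outside chain (1-%d)", lab, n))
  }
  df <- data.frame(label = names(spans), chain = chain,
                   start_aa = vapply(spans, `[`, 0L, 1),
                   end_aa = vapply(spans, `[`, 0L, 2))
  df <- df[order(df$start_aa), , drop = FALSE]
  for (i in seq_len(nrow(df) - 1L))
    if (nrow(df) > 1L && df$end_aa[i] >= df$start_aa[i + 1L])
      abort_validation(sprintf("spans %s and %s overlap",
                               df$label[i], df$label[i + 1L]))
  rownames(df) <- NULL
  df
}

#' Match MALDI peaks against theoretical peptides
#'
#' Each peak is assigned to the theoretical peptide minimising the absolute
#' ppm error, provided it is within `tol_ppm`; a peak matches at most one
#' peptide while a peptide may explain several peaks. Sequence coverage is
#' the union of matched peptide spans over the total residues (concatenated
#' chains). A CDR is *assigned* only when at least one matched peptide
#' fully contains its span -- partial overlap does not count.
#'
#' @param peaks A [peak_list()].
#' @param theoreticals Data frame from [digest()] (rows from several
#'   digests/chains may be combined with `rbind`).
#' @param tol_ppm Matching tolerance in ppm (default 100, typical for an
#'   externally calibrated reflector MALDI-TOF).
#' @param cdrs Optional span table from [cdr_spans()] (rows for both chains
#'   may be combined).
#' @param chain_lengths Optional named vector of parent-chain lengths used
#'   as the coverage denominator; defaults to `max(end)` per chain in
#'   `theoreticals`.
#' @return A `fingerprint_result`: `matches` (data frame `mz`, `sequence`,
#'   `start`, `end`, `chain`, `missed_sites`, `cleavage_mode`, `mh_mono`,
#'   `error_ppm`), `coverage_fraction`, `cdr_assignments` (data frame
#'   `label`, `chain`, `assigned`, `peptides`).
#' @export
match_peaks <- function(peaks, theoreticals, tol_ppm = 100, cdrs = NULL,
                        chain_lengths = NULL) {
  if (tol_ppm <= 0) abort_validation("tol_ppm must be > 0")
  mz <- peaks$peaks$mz
  matches <- list()
  if (length(mz) && nrow(theoreticals)) {
    for (i in seq_along(mz)) {
      err <- (mz[i] - theoreticals$mh_mono) / theoreticals$mh_mono * 1e6
      j <- which.min(abs(err))
      if (abs(err[j]) <= tol_ppm) {
        row <- theoreticals[j, , drop = FALSE]
        row$mz <- mz[i]
        row$error_ppm <- err[j]
        matches[[length(matches) + 1L]] <- row
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    cbind(theoreticals[0, , drop = FALSE],
          data.frame(mz = numeric(0), error_ppm = numeric(0)))
  rownames(matches) <- NULL
  chains <- unique(c(theoreticals$chain, if (!is.null(cdrs)) cdrs$chain))
  if (is.null(chain_lengths)) {
    chain_lengths <- vapply(chains, function(cc) {
      e <- theoreticals$end[theoreticals$chain == cc]
      if (length(e)) max(e) else 0L
    }, 0L)
  }
  covered <- 0L
  for (cc in names(chain_lengths)) {
    len <- chain_lengths[[cc]]
    if (len == 0L) next
    mask <- logical(len)
    sub <- matches[matches$chain == cc, , drop = FALSE]
    for (k in seq_len(nrow(sub)))
      mask[sub$start[k]:sub$end[k]] <- TRUE
    covered <- covered + sum(mask)
  }
  total <- sum(unlist(chain_lengths))
  coverage <- if (total > 0) covered / total else 0
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
  structure(list(matches = matches, coverage_fraction = coverage,
                 cdr_assignments = cdr_assign, tol_ppm = tol_ppm),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("<fingerprint_result> %d matched peaks, coverage %.1f%%",
              nrow(x$matches), 100 * x$coverage_fraction))
  if (!is.null(x$cdr_assignments))
    cat(sprintf(", CDRs assigned %d/%d", sum(x$cdr_assignments$assigned),
                nrow(x$cdr_assignments)))
  cat("\n")
  invisible(x)
}
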