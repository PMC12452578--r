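# CDR3-anchored primer design and in-silico 3' RACE amplicon prediction.
# The constant regions of an antibody chain are amplified between a forward
# primer planted on the clone-specific CDR3 junction and a universal
# oligo(dT)-anchor adaptor at the poly-A tail.

# Nearest-neighbour duplex parameters (unified set, 1 M NaCl reference
# state): dH in kcal/mol, dS in cal/(mol K). Keyed by the sense-strand
# dinucleotide; each step and its reverse complement share one entry.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
NN_EQUIV <- c(TT = "AA", TG = "CA", AC = "GT", AG = "CT", TC = "GA", CC = "GG",
              AA = "AA", AT = "AT", TA = "TA", CA = "CA", GT = "GT",
              CT = "CT", GA = "GA", CG = "CG", GC = "GC", GG = "GG")
# duplex initiation with a terminal G.C vs A.T pair
NN_INIT_GC <- c(dh = 0.1, ds = -2.8)
NN_INIT_AT <- c(dh = 2.3, ds = 4.1)

#' Nearest-neighbour melting temperature
#'
#' Two-state nearest-neighbour thermodynamics with the unified duplex
#' parameter set; entropy is salt-corrected by
#' `dS + 0.368 * (n-1) * ln([Na+])` and the duplex transition temperature
#' is `Tm = 1000*dH / (dS_corrected + R * ln(C/4)) - 273.15` with
#' `R = 1.987 cal/(mol K)`. Defaults: 50 mM monovalent salt, 250 nM total
#' primer. By construction `Tm(s) == Tm(revcomp(s))`.
#'
#' @param sequence DNA, length >= 8, no `N`.
#' @param primer_nM Total primer concentration (nM).
#' @param na_mM Monovalent cation concentration (mM).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(sequence, primer_nM = 250, na_mM = 50) {
  s <- normalize_dna(sequence, "primer", allow_n = TRUE)
  if (grepl("N", s, fixed = TRUE))
    abort_validation("melting_temperature: N not allowed")
  n <- nchar(s)
  if (n < 8L) abort_validation("melting_temperature: sequence shorter than 8 nt")
  steps <- substring(s, 1:(n - 1L), 2:n)
  key <- NN_EQUIV[steps]
  dh <- sum(NN_DH[key])
  ds <- sum(NN_DS[key])
  for (end in c(substring(s, 1, 1), substring(s, n, n))) {
    init <- if (end %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds_corr <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- primer_nM * 1e-9
  tm_k <- (1000 * dh) / (ds_corr + 1.987 * log(ct / 4))
  tm_k - 273.15
}

#' Design the CDR3-anchored forward primer
#'
#' The primer's 5' end is fixed at the CDR3 start -- the junction is what
#' makes the primer clone-specific -- and its 3' end is trimmed into the
#' CDR3 or extended into FR4/J to satisfy the melting-temperature and
#' length windows. The full CDR3 is preferred; candidates are examined in
#' order of increasing deviation from the CDR3 length. Uniqueness of the
#' anchor and of the designed primer in the template is enforced.
#'
#' @param annotation A `chain_annotation` (needs `cdr3_nt`).
#' @param template Template DNA (e.g. the consensus mRNA) in which the
#'   CDR3 occurs exactly once.
#' @param tm_range Acceptable melting-temperature window in Celsius
#'   (default `c(55, 65)`).
#' @param len_range Acceptable primer length window (default `c(15, 40)`).
#' @param name Primer name.
#' @return A `primer_spec`: `name`, `sequence`, `tm_celsius`,
#'   `gc_fraction`, `anchor` (binding-locus description), `start_nt`
#'   (1-based template position), `role = "vdj_specific"`.
#' @export
design_cdr3_primer <- function(annotation, template,
                               tm_range = c(55, 65), len_range = c(15, 40),
                               name = "VDJ-PCR") {
  cdr3 <- annotation$cdr3_nt
  if (is.null(cdr3) || !nzchar(cdr3)) abort_validation("annotation lacks cdr3_nt")
  template <- normalize_dna(template, "template", allow_n = TRUE)
  occ <- find_all(cdr3, template)
  if (length(occ) == 0L)
    abort_validation("CDR3 not found in template")
  if (length(occ) > 1L)
    abort_validation(sprintf("non-unique anchor: CDR3 occurs %d times in template",
                             length(occ)))
  start <- occ[1]
  lens <- seq(len_range[1], len_range[2])
  lens <- lens[start + lens - 1L <= nchar(template)]
  if (!length(lens)) abort_validation("template too short for any primer length")
  lens <- lens[order(abs(lens - nchar(cdr3)), lens)]  # prefer full CDR3
  failures <- character(0)
  for (L in lens) {
    cand <- substring(template, start, start + L - 1L)
    if (grepl("N", cand, fixed = TRUE)) next
    tm <- melting_temperature(cand)
    if (tm < tm_range[1] || tm > tm_range[2]) {
      failures <- c(failures, sprintf("len %d: Tm %.1f outside [%g, %g]",
                                      L, tm, tm_range[1], tm_range[2]))
      next
    }
    if (length(find_all(cand, template)) != 1L) {
      failures <- c(failures, sprintf("len %d: not unique in template", L))
      next
    }
    return(structure(list(
      name = name, sequence = cand, tm_celsius = tm,
      gc_fraction = gc_fraction(cand),
      anchor = sprintf("CDR3, nt %d-%d of template", start, start + L - 1L),
      start_nt = start, role = "vdj_specific"), class = "primer_spec"))
  }
  abort_validation(paste0("no primer satisfies constraints:\n  ",
                          paste(utils::head(failures, 5), collapse = "\n  ")))
}

#' Predict the 3' RACE amplicon on an mRNA template
#'
#' cDNA is primed at the poly-A tail by an oligo(dT) anchor adaptor; PCR
#' then runs between the CDR3-anchored forward primer and the adaptor. The
#' reverse product boundary is the 5' end of the poly-A tract plus the
#' anchor adaptor length, so
#' `product_length = (polyA_start - forward_start) + nchar(anchor)`.
#' Poly-A detection requires >= 10 consecutive `A` within the final 50 nt.
#'
#' @param forward A `primer_spec` (must bind the template exactly once).
#' @param template_mrna mRNA-sense DNA ending in a poly-A tract.
#' @param anchor_primer [primer_record()] of the oligo(dT) anchor adaptor;
#'   its full length (adaptor plus dT stretch) enters the product length.
#' @param regions Optional named list of 1-based `c(start, end)` template
#'   intervals (e.g. `CH1`, `hinge`, `CH2`, `CH3`, `3UTR`); region labels
#'   overlapped by the product are reported in `covers`.
#' @return An `amplicon_prediction`: `forward`, `anchor_primer`,
#'   `product_length_nt`, `covers`, `forward_start`, `polyA_start`.
#' @export
predict_amplicon <- function(forward, template_mrna, anchor_primer,
                             regions = NULL) {
  template_mrna <- normalize_dna(template_mrna, "template", allow_n = TRUE)
  n <- nchar(template_mrna)
  tail_start <- max(1L, n - 49L)
  tail_seq <- substring(template_mrna, tail_start, n)
  m <- regexpr("A{10,}", tail_seq)
  if (m == -1L) abort_validation("not a 3' RACE template: no poly-A tract")
  polyA_start <- tail_start + as.integer(m) - 1L
  occ <- find_all(forward$sequence, template_mrna)
  if (length(occ) != 1L)
    abort_validation(sprintf("forward primer binds template %d times (need 1)",
                             length(occ)))
  fwd_start <- occ[1]
  if (fwd_start >= polyA_start)
    abort_validation("forward primer lies inside/after the poly-A tract")
  product <- (polyA_start - fwd_start) + nchar(anchor_primer$sequence)
  covers <- character(0)
  if (length(regions)) {
    for (lab in names(regions)) {
      iv <- regions[[lab]]
      if (iv[1] <= polyA_start - 1L && iv[2] >= fwd_start)
        covers <- c(covers, lab)
    }
  }
  structure(list(forward = forward, anchor_primer = anchor_primer,
                 product_length_nt = product, covers = covers,
                 forward_start = fwd_start, polyA_start = polyA_start),
            class = "amplicon_prediction")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec> %s 5'-%s-3' (%d nt, Tm %.1f C, GC %.0f%%)\n  %s\n",
              x$name, x$sequence, nchar(x$sequence), x$tm_celsius,
              100 * x$gc_fraction, x$anchor))
  invisible(x)
}

#' @export
print.amplicon_prediction <- function(x, ...) {
  cat(sprintf("<amplicon_prediction> %d bp (%s -> polyA+%d-nt adaptor)%s\n",
              x$product_length_nt, x$forward$name,
              nchar(x$anchor_primer$sequence),
              if (length(x$covers)) paste0(", covers ",
                                           paste(x$covers, collapse = ", ")) else ""))
  invisible(x)
}
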