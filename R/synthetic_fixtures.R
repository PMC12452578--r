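# Deterministic synthetic fixtures with known ground truth. The sequences
# are synthetic but structurally faithful: correct anchor codons, exon
# order, motif-bearing CH1 stubs, primer binding sites with the documented
# per-subclass mismatch pattern, a strain-discriminating CH3 dinucleotide
# swap, and a planted aberrant kappa transcript with a V-J junction
# frameshift. Real curated sequences can be dropped in through the
# reference bundle at any time; nothing here requires a download.

REF_SEED <- 20250822L  # internal constant; reference bundle is fixed

# one fixed codon per amino acid (used for back-translation)
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")
# residues whose fixed codon tolerates any third-position base without
# creating a stop (codon does not start with TA or TG)
SAFE_AA <- c("G", "A", "S", "P", "V", "T", "L", "I", "N", "D", "Q", "K",
             "E", "H", "F", "R")

backtranslate <- function(protein) {
  paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = "")
}

# all sense codons per amino acid
CODON_LIST <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
})

# back-translation with codon choice randomised per position (drawn from
# the surrounding RNG stream); avoids the nucleotide-level coincidences a
# fixed codon table would create between unrelated regions that share
# short amino-acid runs
bt_rand <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- CODON_LIST[[a]]
    cs[sample.int(length(cs), 1L)]
  }, ""), collapse = "")
}

rand_protein <- function(n, aa_set = SAFE_AA) {
  paste(sample(aa_set, n, replace = TRUE), collapse = "")
}

# substitute the third base of codon `idx` with the next base in A<C<G<T order
mutate_third <- function(nt, idx) {
  pos <- idx * 3L
  cur <- substring(nt, pos, pos)
  nxt <- c(A = "C", C = "G", G = "A", T = "C")[[cur]]
  paste0(substring(nt, 1L, pos - 1L), nxt, substring(nt, pos + 1L))
}

#' Fixture configuration
#'
#' Defaults describe the emulated study conditions: eight Sanger clone
#' reads per chain, half of the kappa reads derived from an aberrant
#' transcript, an IgG2c antibody of NOD constant-region background, a
#' per-base substitution error typical of trimmed Sanger reads, and mild
#' MALDI peak dropout/jitter/noise.
#'
#' @param seed Integer master seed; identical seed + config gives
#'   byte-identical fixtures.
#' @param n_reads_per_chain Reads per chain.
#' @param read_error_rate Per-base substitution probability.
#' @param aberrant_fraction Fraction of kappa reads from the aberrant
#'   transcript; `aberrant_fraction * n_reads_per_chain` must be integral.
#' @param subclass Heavy-chain subclass (`IgG1`, `IgG2a`, `IgG2b`, `IgG2c`,
#'   `IgG3`).
#' @param strain Constant-region strain background (`C57BL/6J` or `NOD`).
#' @param peak_dropout Probability a theoretical peak is lost.
#' @param mz_jitter_ppm Gaussian m/z jitter (ppm).
#' @param n_noise_peaks Uniform decoy peaks added per spectrum.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_reads_per_chain = 8L,
                           read_error_rate = 0.002,
                           aberrant_fraction = 0.5,
                           subclass = "IgG2c", strain = "NOD",
                           peak_dropout = 0.1, mz_jitter_ppm = 15,
                           n_noise_peaks = 10L) {
  probs <- c(read_error_rate, aberrant_fraction, peak_dropout)
  if (any(probs < 0 | probs > 1))
    abort_validation("probabilities must be in [0, 1]")
  if (!subclass %in% c("IgG1", "IgG2a", "IgG2b", "IgG2c", "IgG3"))
    abort_validation(sprintf("unknown subclass '%s'", subclass))
  if (!strain %in% c("C57BL/6J", "NOD"))
    abort_validation(sprintf("unknown strain '%s'", strain))
  nab <- aberrant_fraction * n_reads_per_chain
  if (abs(nab - round(nab)) > 1e-9)
    abort_validation("aberrant_fraction * n_reads_per_chain must be integral")
  structure(list(seed = as.integer(seed),
                 n_reads_per_chain = as.integer(n_reads_per_chain),
                 read_error_rate = read_error_rate,
                 aberrant_fraction = aberrant_fraction,
                 subclass = subclass, strain = strain,
                 peak_dropout = peak_dropout,
                 mz_jitter_ppm = mz_jitter_ppm,
                 n_noise_peaks = as.integer(n_noise_peaks)),
            class = "fixture_config")
}

# Table-derived CDR3 junctions planted by default
FIXTURE_CDR3_HEAVY_NT <- "GTCAGATACGGTGGTGGAGGGTTTGCTTAC"
FIXTURE_CDR3_KAPPA_NT <- "CAGCAGTATCATAGTTACCCACGGACG"

#' Synthetic reference bundle and primer set
#'
#' Builds the fixed reference sequences every other fixture derives from:
#' germline V/(D)/J mini-references with annotated CDR3 anchor codons, CH1
#' exon references for the five mouse IgG subclasses (each carrying a
#' subclass-specific motif block plus RT/PCR primer binding sites with the
#' documented per-subclass mismatch pattern: the RT site is exact in IgG1,
#' IgG2a, IgG2b and IgG2c but carries 5 mismatches in IgG3; the PCR site is
#' exact in IgG1, IgG2a and IgG2c, carries 1 mismatch in IgG2b and 4 in
#' IgG3), full heavy constant regions for the C57BL/6J and NOD strains
#' (differing only by a TG/GT dinucleotide swap in CH3 that exchanges
#' valine for glycine), kappa and lambda constant regions, a synthetic
#' aberrant kappa transcript, and the primer table (chain-specific RT/PCR
#' primers, the universal ISPCR adaptor, the template-switch oligo and the
#' oligo(dT)-ISPCR anchor).
#'
#' @return List with `references` (list of [reference_record()]),
#'   `primers` (list of [primer_record()]), and `parts` (internal building
#'   blocks used by [make_antibody_template()]).
#' @export
synthetic_references <- function() {
  with_seed(REF_SEED, {
    leader_heavy_aa <- "MGWSCIILFLVATATGVHS"          # 19 aa secretion leader
    leader_kappa_aa <- "METDTLLLWVLLLWVPGSTG"         # 20 aa
    v_heavy_nt <- bt_rand(paste0(rand_protein(97L), "C"))  # 98 aa, FR3 Cys last
    v_kappa_nt <- bt_rand(paste0(rand_protein(94L), "C"))  # 95 aa
    j_heavy_nt <- backtranslate("WGQGTSVTVSS")        # 11 aa, J-Trp first
    j_kappa_nt <- backtranslate("FGGTKLEIKR")         # 10 aa, J-Phe first
    d_nt <- "TACGGTGGTGGAGGG"                         # sits inside heavy CDR3

    # CH1: 98 aa scaffold back-translated once (shared columns), aa 21-27
    # motif block (subclass-specific nt), aa 34-41 PCR primer site,
    # aa 81-88 RT primer site (per-subclass third-position mismatches)
    ch1_scaffold_nt <- bt_rand(rand_protein(98L))
    motif_blocks <- list(IgG1 = "APGSAAQ", IgG2a = "EPRGPTI",
                         IgG2b = "KPGDTTH", IgG2c = "ERKSPAI",
                         IgG3 = "NGGTSED")
    block_nt <- lapply(motif_blocks, bt_rand)
    ch1_nt <- lapply(names(motif_blocks), function(sc) {
      nt <- paste0(substring(ch1_scaffold_nt, 1L, 20L * 3L),
                   block_nt[[sc]],
                   substring(ch1_scaffold_nt, 27L * 3L + 1L))
      if (sc == "IgG2b") nt <- mutate_third(nt, 37L)             # 1 mm, PCR site
      if (sc == "IgG3") {
        for (ci in c(35L, 37L, 39L, 41L)) nt <- mutate_third(nt, ci)  # 4 mm, PCR
        for (ci in c(81L, 83L, 85L, 86L, 88L)) nt <- mutate_third(nt, ci)  # 5 mm, RT
      }
      nt
    })
    names(ch1_nt) <- names(motif_blocks)

    # strain-discriminating codon: constant codon 316 = CH3 codon 93,
    # glycine GGT (NOD) vs valine GTG (C57BL/6J) -- a TG/GT dinucleotide swap
    ch3_aa <- strsplit(rand_protein(107L), "")[[1]]
    ch3_aa[93] <- "G"
    ch3_nod_nt <- bt_rand(paste(ch3_aa, collapse = ""))
    p <- 92L * 3L
    ch3_nod_nt <- paste0(substring(ch3_nod_nt, 1, p), "GGT",
                         substring(ch3_nod_nt, p + 4L))
    ch3_c57_nt <- paste0(substring(ch3_nod_nt, 1, p), "GTG",
                         substring(ch3_nod_nt, p + 4L))
    tail_heavy_nt <- paste0(bt_rand(rand_protein(15L)),   # hinge
                            bt_rand(rand_protein(110L)))  # CH2
    const_heavy <- list(
      "NOD" = paste0(ch1_nt[["IgG2c"]], tail_heavy_nt, ch3_nod_nt),
      "C57BL/6J" = paste0(ch1_nt[["IgG2c"]], tail_heavy_nt, ch3_c57_nt))

    # light constant regions; kappa carries exact RT/PCR sites at the same
    # codon offsets as CH1
    cl_kappa_nt <- bt_rand(rand_protein(107L))
    cl_lambda_nt <- bt_rand(rand_protein(106L))

    # primers: RT/PCR are antisense; sites are codon blocks 34-41 / 81-88
    site <- function(nt, from_codon, to_codon)
      substring(nt, (from_codon - 1L) * 3L + 1L, to_codon * 3L)
    primers <- list(
      primer_record("mIGG-RT", revcomp(site(ch1_nt[["IgG1"]], 81L, 88L)), "RT"),
      primer_record("mIGG-PCR", revcomp(site(ch1_nt[["IgG1"]], 34L, 41L)), "PCR"),
      primer_record("mIGK-RT", revcomp(site(cl_kappa_nt, 81L, 88L)), "RT"),
      primer_record("mIGK-PCR", revcomp(site(cl_kappa_nt, 34L, 41L)), "PCR"),
      primer_record("mIGL-PCR", revcomp(site(cl_lambda_nt, 34L, 41L)), "PCR"),
      primer_record("ISPCR", "AAGCAGTGGTATCAACGCAGAGT", "PCR"),
      primer_record("TSO", "AAGCAGTGGTATCAACGCAGAGTACATGGG", "template_switch"),
      primer_record("AOligo-dT-ISPCR",
                    paste0("AAGCAGTGGTATCAACGCAGAGT",
                           strrep("T", 30L)), "oligo_dT_anchor"))

    # aberrant kappa: distinct V, junction with a 1-nt deletion that shifts
    # J + CL out of frame; junk junction chosen (deterministically) so that
    # a stop codon appears within 20 codons of the junction
    ab_v_nt <- bt_rand(paste0(rand_protein(94L), "C"))
    leader_kappa_nt <- backtranslate(leader_kappa_aa)
    kappa_pcr_end <- 41L * 3L
    ab_read <- NULL
    for (try in 1:100) {
      junk <- paste(sample(c("A", "C", "G", "T"), 26L, replace = TRUE),
                    collapse = "")
      cand <- paste0(leader_kappa_nt, ab_v_nt, junk, j_kappa_nt,
                     substring(cl_kappa_nt, 1L, kappa_pcr_end))
      aa <- translate_dna(cand)
      junction_codon <- (nchar(leader_kappa_nt) + nchar(ab_v_nt)) %/% 3L
      stop_idx <- which(strsplit(aa, "")[[1]] == "*")
      if (length(stop_idx) && any(stop_idx > junction_codon &
                                  stop_idx <= junction_codon + 25L) &&
          !any(stop_idx <= junction_codon)) {
        ab_read <- cand
        break
      }
    }
    if (is.null(ab_read))
      stop("internal: could not construct aberrant kappa fixture")

    refs <- c(
      list(
        reference_record("IGHV-2*01", v_heavy_nt, "germline_V",
                         anchor = nchar(v_heavy_nt) - 2L),
        reference_record("IGHV2-6-8*01", v_heavy_nt, "germline_V",
                         anchor = nchar(v_heavy_nt) - 2L),
        reference_record("IGHD-1*01", d_nt, "germline_D"),
        reference_record("IGHD-1*02", d_nt, "germline_D"),
        reference_record("IGHJ3*01", j_heavy_nt, "germline_J", anchor = 1L),
        reference_record("IGKV4-61*01", v_kappa_nt, "germline_V",
                         anchor = nchar(v_kappa_nt) - 2L),
        reference_record("IGKJ*01", j_kappa_nt, "germline_J", anchor = 1L)),
      lapply(names(ch1_nt), function(sc)
        reference_record(paste0("CH1-", sc), ch1_nt[[sc]], "CH1_exon",
                         subclass_or_strain = sc)),
      list(
        reference_record("IGHG2c-C57BL6J", const_heavy[["C57BL/6J"]],
                         "constant_region", subclass_or_strain = "C57BL/6J"),
        reference_record("IGHG2c-NOD", const_heavy[["NOD"]],
                         "constant_region", subclass_or_strain = "NOD"),
        reference_record("IGKC", cl_kappa_nt, "constant_region",
                         subclass_or_strain = "kappa"),
        reference_record("IGLC1", cl_lambda_nt, "constant_region",
                         subclass_or_strain = "IgLC1"),
        reference_record("aberrant-kappa-synthetic", ab_read,
                         "aberrant_kappa")))

    parts <- list(
      leader_heavy_nt = backtranslate(leader_heavy_aa),
      leader_kappa_nt = leader_kappa_nt,
      v_heavy_nt = v_heavy_nt, v_kappa_nt = v_kappa_nt,
      j_heavy_nt = j_heavy_nt, j_kappa_nt = j_kappa_nt,
      ch1_nt = ch1_nt, tail_heavy_nt = tail_heavy_nt,
      ch3_nt = list("NOD" = ch3_nod_nt, "C57BL/6J" = ch3_c57_nt),
      const_heavy = const_heavy, cl_kappa_nt = cl_kappa_nt,
      cl_lambda_nt = cl_lambda_nt,
      aberrant_kappa_read_region = ab_read,
      kappa_pcr_end_codon = 41L, heavy_pcr_end_codon = 41L)
    list(references = refs, primers = primers, parts = parts)
  })
}

# deterministic UTR free of poly-A tracts and primer/CDR3 collisions
make_utr <- function(len) {
  repeat {
    u <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    if (!grepl("AAAAAA", u, fixed = TRUE)) return(u)
  }
}

#' Build full antibody mRNA templates with ground truth
#'
#' Each template follows the natural architecture
#' `leader + V-(D-)J + constant exons + 3' UTR + poly-A(30)`. Table-style
#' CDR3 junctions are embedded by default. The 3' UTR lengths are fixed so
#' that the predicted 3' RACE amplicons are 1299 nt (heavy constant) and
#' 600 nt (kappa constant), matching the reported ~1300/~600 bp products.
#'
#' @param config A [fixture_config()].
#' @param cdr3_heavy_nt,cdr3_kappa_nt CDR3 junctions to embed (codon
#'   multiples).
#' @return List with `heavy` and `kappa` template descriptions (`mrna`,
#'   `regions`, `read_region`, `mature_protein`, `cdr_spans_aa`,
#'   `expected_amplicon_nt`, plus the aberrant kappa fields), `references`,
#'   `primers`, `config`.
#' @export
make_antibody_template <- function(config = fixture_config(),
                                   cdr3_heavy_nt = FIXTURE_CDR3_HEAVY_NT,
                                   cdr3_kappa_nt = FIXTURE_CDR3_KAPPA_NT) {
  stopifnot(inherits(config, "fixture_config"))
  if (nchar(cdr3_heavy_nt) %% 3L || nchar(cdr3_kappa_nt) %% 3L)
    abort_validation("CDR3 lengths must be codon multiples")
  bundle <- synthetic_references()
  p <- bundle$parts
  # plant somatic mutations in the sample V regions (third positions), so
  # germline identity is (294-4)/294 = 98.6% (heavy), (285-2)/285 = 99.3%
  # (kappa) -- the flavour of a hypermutated clone
  v_heavy_sample <- Reduce(mutate_third, c(20L, 40L, 60L, 80L),
                           accumulate = FALSE, init = p$v_heavy_nt)
  v_kappa_sample <- Reduce(mutate_third, c(25L, 65L),
                           accumulate = FALSE, init = p$v_kappa_nt)
  const_h <- paste0(p$ch1_nt[[config$subclass]], p$tail_heavy_nt,
                    p$ch3_nt[[config$strain]])
  utr_h <- with_seed(REF_SEED + 7L, make_utr(190L))
  utr_k <- with_seed(REF_SEED + 8L, make_utr(166L))
  polyA <- strrep("A", 30L)

  assemble <- function(leader, v, cdr3, j, const, utr) {
    segs <- c(leader = leader, V = v, CDR3 = cdr3, J = j, const = const,
              stop = "TAA", UTR3 = utr, polyA = polyA)
    mrna <- paste(segs, collapse = "")
    ends <- cumsum(nchar(segs))
    starts <- c(1L, utils::head(ends, -1) + 1L)
    regions <- Map(function(s, e) c(s, e), starts, ends)
    names(regions) <- names(segs)
    list(mrna = mrna, regions = regions)
  }

  h <- assemble(p$leader_heavy_nt, v_heavy_sample, cdr3_heavy_nt,
                p$j_heavy_nt, const_h, utr_h)
  k <- assemble(p$leader_kappa_nt, v_kappa_sample, cdr3_kappa_nt,
                p$j_kappa_nt, paste0(p$cl_kappa_nt, ""), utr_k)

  # split heavy constant region labels for amplicon 'covers'
  ch <- h$regions$const
  h$regions$CH1 <- c(ch[1], ch[1] + 98L * 3L - 1L)
  h$regions$hinge <- c(h$regions$CH1[2] + 1L, h$regions$CH1[2] + 15L * 3L)
  h$regions$CH2 <- c(h$regions$hinge[2] + 1L, h$regions$hinge[2] + 110L * 3L)
  h$regions$CH3 <- c(h$regions$CH2[2] + 1L, ch[2])

  pcr_end <- function(regions, codon) regions$const[1] + codon * 3L - 1L
  h$read_region <- c(1L, pcr_end(h$regions, p$heavy_pcr_end_codon))
  k$read_region <- c(1L, pcr_end(k$regions, p$kappa_pcr_end_codon))

  mature <- function(t_) {
    cds <- substring(t_$mrna, t_$regions$V[1], t_$regions$const[2])
    translate_dna(cds)
  }
  h$mature_protein <- mature(h)
  k$mature_protein <- mature(k)
  h$cdr3_aa <- translate_dna(cdr3_heavy_nt)
  k$cdr3_aa <- translate_dna(cdr3_kappa_nt)
  # mature-chain CDR spans: CDR3 follows the V segment; CDR1/2 spans are
  # fixture conventions for the MS module
  v_len_h <- nchar(p$v_heavy_nt) %/% 3L
  v_len_k <- nchar(p$v_kappa_nt) %/% 3L
  h$cdr_spans_aa <- list(CDR1 = c(26L, 33L), CDR2 = c(51L, 58L),
                         CDR3 = c(v_len_h + 1L,
                                  v_len_h + nchar(cdr3_heavy_nt) %/% 3L))
  k$cdr_spans_aa <- list(CDR1 = c(27L, 32L), CDR2 = c(50L, 56L),
                         CDR3 = c(v_len_k + 1L,
                                  v_len_k + nchar(cdr3_kappa_nt) %/% 3L))
  h$expected_amplicon_nt <- (h$regions$polyA[1] - h$regions$CDR3[1]) + 53L
  k$expected_amplicon_nt <- (k$regions$polyA[1] - k$regions$CDR3[1]) + 53L
  h$chain <- "heavy"; k$chain <- "kappa"
  k$aberrant_read_region_seq <- p$aberrant_kappa_read_region
  # aa position (mature heavy numbering) of the strain-discriminating codon
  strain_pos <- v_len_h + nchar(cdr3_heavy_nt) %/% 3L +
    nchar(p$j_heavy_nt) %/% 3L + 316L
  list(heavy = h, kappa = k, references = bundle$references,
       primers = bundle$primers, config = config,
       strain_aa_position = strain_pos)
}

#' Simulate Sanger clone reads from a template
#'
#' `n_reads_per_chain` reads are sampled from the template's step-1
#' amplicon region with iid substitution errors. For a kappa template, an
#' `aberrant_fraction` of the reads derive instead from the planted
#' aberrant transcript (distinct V segment, 1-nt deletion at the V-J
#' junction, premature stop).
#'
#' @param template One chain element of [make_antibody_template()] output
#'   (`$heavy` or `$kappa`).
#' @param config The [fixture_config()].
#' @return List with `reads` (list of [nucleotide_read()]) and `truth`
#'   (data frame `id`, `aberrant`).
#' @export
make_clone_reads <- function(template, config = fixture_config()) {
  chain <- template$chain
  n <- config$n_reads_per_chain
  n_ab <- if (chain == "kappa" && !is.null(template$aberrant_read_region_seq))
    as.integer(round(config$aberrant_fraction * n)) else 0L
  base_seq <- substring(template$mrna, template$read_region[1],
                        template$read_region[2])
  prefix <- substring(chain, 1, 1)
  seed_off <- if (chain == "heavy") 101L else 202L
  with_seed(config$seed + seed_off, {
    reads <- vector("list", n)
    truth <- data.frame(id = character(n), aberrant = logical(n))
    for (i in seq_len(n)) {
      ab <- i > n - n_ab
      src <- if (ab) template$aberrant_read_region_seq else base_seq
      chv <- strsplit(src, "")[[1]]
      err <- which(stats::runif(length(chv)) < config$read_error_rate)
      for (e in err) {
        alt <- setdiff(c("A", "C", "G", "T"), chv[e])
        chv[e] <- sample(alt, 1L)
      }
      id <- sprintf("%s%02d", prefix, i)
      reads[[i]] <- nucleotide_read(id, paste(chv, collapse = ""),
                                    chain_hint = chain)
      truth$id[i] <- id
      truth$aberrant[i] <- ab
    }
    list(reads = reads, truth = truth)
  })
}

#' Simulate a MALDI peak list from an in-silico digest
#'
#' The protein is digested, each theoretical peak survives with probability
#' `1 - peak_dropout`, surviving m/z values are jittered by
#' `N(0, mz_jitter_ppm)`, and `n_noise_peaks` uniform decoys are added over
#' the observed m/z range.
#'
#' @param protein Parent chain sequence.
#' @param mode `"trypsin"` or `"acid"`.
#' @param config The [fixture_config()].
#' @param chain Chain label for the digest.
#' @param seed_offset Added to `config$seed` so several spectra per run
#'   stay independent.
#' @return List with `peaks` (a [peak_list()]) and `truth` (data frame of
#'   surviving theoretical peptides).
#' @export
simulate_spectrum <- function(protein, mode = c("trypsin", "acid"),
                              config = fixture_config(), chain = "heavy",
                              seed_offset = 303L) {
  mode <- match.arg(mode)
  theo <- digest(protein, mode, chain = chain)
  with_seed(config$seed + seed_offset, {
    keep <- stats::runif(nrow(theo)) >= config$peak_dropout
    surv <- theo[keep, , drop = FALSE]
    mz <- surv$mh_mono *
      (1 + stats::rnorm(nrow(surv), 0, config$mz_jitter_ppm) * 1e-6)
    intensity <- stats::runif(nrow(surv), 20, 100)
    if (config$n_noise_peaks > 0L) {
      rng <- if (length(mz)) range(mz) else c(500, 3500)
      noise_mz <- stats::runif(config$n_noise_peaks, rng[1], rng[2])
      mz <- c(mz, noise_mz)
      intensity <- c(intensity, stats::runif(config$n_noise_peaks, 5, 20))
    }
    list(peaks = peak_list(mz, intensity,
                           source_label = sprintf("simulated-%s-%s", chain, mode),
                           cleavage_mode = mode),
         truth = surv)
  })
}
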