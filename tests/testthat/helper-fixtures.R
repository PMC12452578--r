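# Shared fixture cache: the synthetic reference bundle and default template
# are deterministic, so they are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fx_template <- function(config = NULL) {
  if (is.null(config)) {
    if (is.null(.fixture_cache$tpl))
      .fixture_cache$tpl <- make_antibody_template(fixture_config(seed = 1))
    return(.fixture_cache$tpl)
  }
  make_antibody_template(config)
}

fx_refs_of <- function(category) {
  Filter(function(r) r$category == category, fx_template()$references)
}

fx_primer <- function(name) {
  ps <- fx_template()$primers
  ps[[which(vapply(ps, `[[`, "", "name") == name)]]
}

fx_motifs <- function() {
  if (is.null(.fixture_cache$motifs))
    .fixture_cache$motifs <- derive_motifs(fx_refs_of("CH1_exon"))
  .fixture_cache$motifs
}

fx_light_refs <- function() {
  Filter(function(r)
    r$subclass_or_strain %in% "kappa" | grepl("^IgLC", r$subclass_or_strain),
    fx_refs_of("constant_region"))
}

fx_strain_refs <- function() {
  Filter(function(r) r$subclass_or_strain %in% c("NOD", "C57BL/6J"),
         fx_refs_of("constant_region"))
}

fx_v_refs <- function(chain) {
  pref <- if (chain == "heavy") "IGHV" else "IGKV"
  Filter(function(r) startsWith(r$id, pref), fx_refs_of("germline_V"))
}

fx_j_refs <- function(chain) {
  pref <- if (chain == "heavy") "IGHJ" else "IGKJ"
  Filter(function(r) startsWith(r$id, pref), fx_refs_of("germline_J"))
}

# step-1 consensus per chain, cached (clustering 8 reads costs a few
# pairwise alignments)
fx_consensus <- function(chain) {
  key <- paste0("cons_", chain)
  if (is.null(.fixture_cache[[key]])) {
    tpl <- fx_template()
    reads <- make_clone_reads(tpl[[chain]], fixture_config(seed = 1))$reads
    .fixture_cache[[key]] <- cluster_reads(reads)
  }
  .fixture_cache[[key]]
}

# independent oracle: standard-code translation via seqinr when available,
# else a literal codon-table lookup written without the package's helper
oracle_translate <- function(dna) {
  if (requireNamespace("seqinr", quietly = TRUE)) {
    aa <- seqinr::translate(strsplit(tolower(dna), "")[[1]])
    return(paste(aa, collapse = ""))
  }
  tab <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3L
  paste(vapply(seq_len(n), function(i)
    tab[[substring(dna, 3 * i - 2, 3 * i)]], ""), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# reverse complement written independently of the package helper
revcomp_test <- function(x) {
  ch <- rev(strsplit(x, "")[[1]])
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch], collapse = "")
}

# independent digestion oracle: enumerate boundaries by rule, then every
# consecutive run of fragments
oracle_digest <- function(protein, mode, max_missed, len_range = c(4L, 40L)) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  cuts <- c()
  for (i in seq_len(n - 1)) {
    cut <- if (mode == "trypsin") {
      ch[i] %in% c("K", "R") && ch[i + 1] != "P"
    } else {
      ch[i] == "D" || ch[i + 1] == "D"
    }
    if (cut) cuts <- c(cuts, i)
  }
  bounds <- c(0L, cuts, n)
  out <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(length(bounds) - 1, i + max_missed)) {
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      if (e - s + 1L >= len_range[1] && e - s + 1L <= len_range[2])
        out <- c(out, substring(protein, s, e))
    }
  }
  sort(out)
}

# cached step-1 run on the default fixture
fx_step1 <- function() {
  if (!is.null(.fixture_cache$s1)) return(.fixture_cache$s1)
  tpl <- fx_template()
  cfg <- fixture_config(seed = 1)
  s1 <- run_step1(
    list(heavy = make_clone_reads(tpl$heavy, cfg)$reads,
         kappa = make_clone_reads(tpl$kappa, cfg)$reads),
    tpl$references, tpl$primers)
  .fixture_cache$s1 <- s1
  s1
}

# constant-amplicon clone reads for step 2
const_reads <- function(t_, cfg) {
  tt <- t_
  tt$read_region <- c(t_$regions$CDR3[1], t_$regions$polyA[2])
  tt$aberrant_read_region_seq <- NULL
  make_clone_reads(tt, cfg)$reads
}

random_protein <- function(n) paste(
  sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, TRUE), collapse = "")
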