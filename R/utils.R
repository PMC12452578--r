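# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T")
DNA_ALPHABET_READ <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

CHAIN_TYPES <- c("heavy", "kappa", "lambda", "unknown")
REFERENCE_CATEGORIES <- c(
  "germline_V", "germline_D", "germline_J",
  "CH1_exon", "constant_region", "aberrant_kappa"
)
PRIMER_ROLES <- c("RT", "PCR", "template_switch", "oligo_dT_anchor", "vdj_specific")
CLEAVAGE_MODES <- c("trypsin", "acid")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Codon-table translation; incomplete trailing codons are dropped. Stop codons
# appear as "*".
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  codons <- substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

is_dna <- function(x, allow_n = TRUE) {
  alph <- if (allow_n) DNA_ALPHABET_READ else DNA_ALPHABET_STRICT
  all(strsplit(x, "", fixed = TRUE)[[1]] %in% alph)
}

gc_fraction <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  sum(ch %in% c("G", "C")) / length(ch)
}

# All start offsets (1-based) of `pattern` in `subject`, exact match.
find_all <- function(pattern, subject) {
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substring(subject, from), fixed = TRUE)
    if (hit == -1L) break
    out <- c(out, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  out
}

abort_parse <- function(msg) stop(structure(
  class = c("sangermab_parse_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

abort_validation <- function(msg) stop(structure(
  class = c("sangermab_validation_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))
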