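#' Construct a single Sanger clone read
#'
#' A `nucleotide_read` holds one Sanger read of a cloned antibody chain
#' amplicon. Sequences are stored uppercase over the alphabet `A,C,G,T,N`;
#' `N` encodes a Sanger base-calling ambiguity and is tolerated in reads but
#' never in curated reference records.
#'
#' @param id Read label, unique within a read set.
#' @param sequence DNA string; lowercase input is uppercased, `U` mapped to `T`.
#' @param chain_hint One of `"heavy"`, `"kappa"`, `"lambda"`, `"unknown"`.
#' @return An object of class `nucleotide_read`.
#' @export
nucleotide_read <- function(id, sequence, chain_hint = "unknown") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_dna(sequence, label = id, allow_n = TRUE)
  chain_hint <- match.arg(chain_hint, CHAIN_TYPES)
  structure(list(id = id, sequence = sequence, chain_hint = chain_hint),
            class = "nucleotide_read")
}

#' Construct a curated reference record
#'
#' Reference records carry germline segments, CH1 exons, constant regions or
#' known non-functional (aberrant) kappa chains. The `category` decides which
#' downstream module may consume the record. Germline V and J records may
#' carry an `anchor`: the 1-based position of the first nucleotide of the
#' conserved anchor codon (second cysteine of FR3 for V; J-tryptophan /
#' J-phenylalanine for J) used to project the CDR3 junction onto a query.
#'
#' @param id Record label.
#' @param sequence DNA, `N` not allowed (references are curated).
#' @param category One of `"germline_V"`, `"germline_D"`, `"germline_J"`,
#'   `"CH1_exon"`, `"constant_region"`, `"aberrant_kappa"`.
#' @param subclass_or_strain Optional subclass (e.g. `"IgG2c"`) or strain
#'   (e.g. `"NOD"`) label; required for `CH1_exon` and `constant_region`.
#' @param anchor Optional anchor codon start (see Details).
#' @return An object of class `reference_record`.
#' @export
reference_record <- function(id, sequence, category,
                             subclass_or_strain = NA_character_,
                             anchor = NA_integer_) {
  category <- match.arg(category, REFERENCE_CATEGORIES)
  sequence <- normalize_dna(sequence, label = id, allow_n = FALSE)
  if (category %in% c("CH1_exon", "constant_region") && is.na(subclass_or_strain))
    abort_validation(sprintf(
      "reference '%s': category '%s' requires a subclass/strain label",
      id, category))
  structure(list(id = id, sequence = sequence, category = category,
                 subclass_or_strain = as.character(subclass_or_strain),
                 anchor = as.integer(anchor)),
            class = "reference_record")
}

#' Construct a primer record
#'
#' @param name Primer name.
#' @param sequence DNA 5'->3'.
#' @param role One of `"RT"`, `"PCR"`, `"template_switch"`,
#'   `"oligo_dT_anchor"`, `"vdj_specific"`. `RT` and `PCR` primers are
#'   reverse (antisense) primers by convention; the rest anneal in sense
#'   orientation.
#' @return An object of class `primer_record`.
#' @export
primer_record <- function(name, sequence, role) {
  role <- match.arg(role, PRIMER_ROLES)
  sequence <- normalize_dna(sequence, label = name, allow_n = FALSE)
  structure(list(name = name, sequence = sequence, role = role),
            class = "primer_record")
}

#' Construct a MALDI peak list
#'
#' Peaks are stored sorted by ascending m/z; duplicate m/z values are merged
#' by intensity sum.
#'
#' @param mz Numeric vector of m/z values (Da), all positive.
#' @param intensity Non-negative intensities (arbitrary units).
#' @param source_label Free-text provenance label.
#' @param cleavage_mode `"trypsin"` or `"acid"`.
#' @return An object of class `peak_list` with a `peaks` data frame.
#' @export
peak_list <- function(mz, intensity, source_label = "",
                      cleavage_mode = c("trypsin", "acid")) {
  cleavage_mode <- match.arg(cleavage_mode)
  if (length(mz) != length(intensity))
    abort_validation("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(mz <= 0))
    abort_validation("m/z values must be positive finite numbers")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    abort_validation("intensities must be non-negative")
  if (length(mz)) {
    agg <- tapply(intensity, mz, sum)
    mz <- as.numeric(names(agg))
    intensity <- as.numeric(agg)
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(peaks = data.frame(mz = mz, intensity = intensity),
                 source_label = source_label, cleavage_mode = cleavage_mode),
            class = "peak_list")
}

# Uppercase, map U->T, validate alphabet with a position-reporting error.
normalize_dna <- function(sequence, label = "?", allow_n = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("u", "t", sequence)
  s <- toupper(chartr("U", "T", s))
  if (!nzchar(s))
    abort_validation(sprintf("record '%s': empty sequence", label))
  alph <- if (allow_n) DNA_ALPHABET_READ else DNA_ALPHABET_STRICT
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% alph))
  if (length(bad))
    abort_parse(sprintf("record '%s': illegal character '%s' at position %d",
                        label, ch[bad[1]], bad[1]))
  s
}

#' Read Sanger clone reads from a FASTA file
#'
#' Sequences are uppercased and `U` mapped to `T`; characters outside
#' `A,C,G,T,N` raise a parse error naming the record and position. The FASTA
#' description after the first whitespace is stored in the read but ignored
#' by all downstream logic.
#'
#' @param path FASTA file.
#' @param chain_hint Chain hint applied to every read.
#' @return List of [nucleotide_read()] objects.
#' @export
read_fasta <- function(path, chain_hint = "unknown") {
  recs <- parse_fasta_file(path)
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    abort_validation(sprintf("duplicate read id '%s' in %s",
                             ids[duplicated(ids)][1], path))
  lapply(recs, function(r) {
    rd <- nucleotide_read(r$id, r$sequence, chain_hint)
    attr(rd, "description") <- r$description
    rd
  })
}

#' Read curated references from a FASTA file
#'
#' Record metadata is parsed from `key=value` tokens in the FASTA description
#' (keys: `category`, `subclass`, `strain`, `anchor`). A `category` argument
#' overrides/supplies the category for all records.
#'
#' @param path FASTA file.
#' @param category Optional category applied to all records.
#' @return List of [reference_record()] objects.
#' @export
read_reference_fasta <- function(path, category = NULL) {
  recs <- parse_fasta_file(path)
  lapply(recs, function(r) {
    kv <- parse_kv(r$description)
    cat <- category %||% kv[["category"]]
    if (is.null(cat))
      abort_validation(sprintf("reference '%s': no category given", r$id))
    reference_record(
      r$id, r$sequence, cat,
      subclass_or_strain = kv[["subclass"]] %||% kv[["strain"]] %||% NA_character_,
      anchor = as.integer(kv[["anchor"]] %||% NA_integer_))
  })
}

parse_kv <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(list())
  toks <- strsplit(desc, "[[:space:]]+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  out <- list()
  for (t in toks) {
    p <- strsplit(t, "=", fixed = TRUE)[[1]]
    out[[p[1]]] <- p[2]
  }
  out
}

# Minimal-structure FASTA reader; per-character validation and error wording
# are this package's contract, so records are kept as raw strings here.
parse_fasta_file <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort_parse(sprintf("no records in %s", path))
  hdr <- grepl("^>", lines)
  if (!hdr[1]) abort_parse(sprintf("%s is not FASTA (no '>' header)", path))
  idx <- cumsum(hdr)
  recs <- lapply(split(seq_along(lines), idx), function(ii) {
    h <- sub("^>", "", lines[ii[1]])
    id <- sub("[[:space:]].*$", "", h)
    desc <- if (grepl("[[:space:]]", h)) sub("^[^[:space:]]+[[:space:]]+", "", h) else ""
    seqs <- if (length(ii) > 1) paste(gsub("[[:space:]]", "", lines[ii[-1]]), collapse = "") else ""
    if (!nzchar(id)) abort_parse(sprintf("unnamed record in %s", path))
    if (!nzchar(seqs)) abort_parse(sprintf("record '%s': empty sequence", id))
    list(id = id, description = desc, sequence = seqs)
  })
  unname(recs)
}

#' Write reads or references to FASTA
#'
#' @param x List of [nucleotide_read()] / [reference_record()] objects, or a
#'   named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    seqs <- unname(x)
    descs <- rep("", length(x))
  } else {
    ids <- vapply(x, function(r) r$id %||% r$name, "")
    seqs <- vapply(x, `[[`, "", "sequence")
    descs <- vapply(x, function(r) attr(r, "description") %||% "", "")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    hdr <- if (nzchar(descs[i])) paste0(">", ids[i], " ", descs[i]) else paste0(">", ids[i])
    writeLines(hdr, con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a MALDI peak list from two-column text
#'
#' Accepts whitespace- or comma-delimited `m/z intensity` rows; lines starting
#' with `#` are treated as comments. Peaks are sorted ascending by m/z and
#' duplicate m/z values merged by intensity sum.
#'
#' @param path Peak-list text file.
#' @param mode Cleavage mode the spectrum derives from (`"trypsin"`/`"acid"`).
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, mode = c("trypsin", "acid")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  mz <- numeric(0); it <- numeric(0)
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    if (length(f) < 2L)
      abort_parse(sprintf("%s line %d: expected two columns", path, i))
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (any(is.na(v)))
      abort_parse(sprintf("%s line %d: non-numeric field", path, i))
    if (v[1] <= 0)
      abort_validation(sprintf("%s line %d: non-positive m/z", path, i))
    mz <- c(mz, v[1]); it <- c(it, v[2])
  }
  peak_list(mz, it, source_label = basename(path), cleavage_mode = mode)
}

#' Write a peak list as two-column text
#' @param x A [peak_list()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s (%s)", x$source_label, x$cleavage_mode), con)
  writeLines(sprintf("%.6f %.6g", x$peaks$mz, x$peaks$intensity), con)
  invisible(path)
}

#' Read a primer table (TSV/CSV with columns name, sequence, role)
#'
#' @param path Delimited text file; the delimiter (tab or comma) is sniffed
#'   from the header line. A header row is optional.
#' @return List of [primer_record()] objects (empty list, with a warning, for
#'   an empty file).
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) {
    warning(sprintf("empty primer table: %s", path))
    return(list())
  }
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  # drop a header row: recognised by a non-sequence second column
  first <- trimws(rows[[1]])
  if (length(first) >= 2 &&
      !grepl("^[ACGTUNacgtun]+$", first[2])) rows <- rows[-1]
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    if (length(f) < 3L)
      abort_parse(sprintf("%s row %d: expected columns name, sequence, role", path, i))
    if (!(f[3] %in% PRIMER_ROLES))
      abort_validation(sprintf("%s row %d ('%s'): unknown role '%s'",
                               path, i, f[1], f[3]))
    out[[i]] <- primer_record(f[1], f[2], f[3])
  }
  out
}

#' Write a primer table as TSV
#' @param primers List of [primer_record()] or [primer_spec] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("name\tsequence\trole", con)
  for (p in primers)
    writeLines(paste(p$name, p$sequence, p$role %||% "vdj_specific", sep = "\t"), con)
  invisible(path)
}

#' @export
print.nucleotide_read <- function(x, ...) {
  cat(sprintf("<nucleotide_read> %s [%s] %d nt\n", x$id, x$chain_hint,
              nchar(x$sequence)))
  invisible(x)
}

#' @export
print.reference_record <- function(x, ...) {
  cat(sprintf("<reference_record> %s (%s%s) %d nt\n", x$id, x$category,
              if (!is.na(x$subclass_or_strain)) paste0(", ", x$subclass_or_strain) else "",
              nchar(x$sequence)))
  invisible(x)
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s (%s): %d peaks, m/z %.1f-%.1f\n", x$source_label,
              x$cleavage_mode, nrow(x$peaks),
              if (nrow(x$peaks)) min(x$peaks$mz) else NA,
              if (nrow(x$peaks)) max(x$peaks$mz) else NA))
  invisible(x)
}
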