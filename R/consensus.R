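# Clustering of near-identical Sanger clone reads and majority-vote
# consensus calling. Clone reads of a single transcript differ only by
# sequencing error, while genuinely distinct transcripts (e.g. a productive
# and an aberrant kappa variant) must end up in separate clusters.

IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

#' Cluster clone reads by pairwise global-alignment identity
#'
#' Single-linkage clustering: two reads are linked when their global
#' alignment identity (identical columns / alignment columns) is at least
#' `identity_threshold`. Clusters are ordered by size descending, ties by
#' the lexicographically smallest member id; members within a cluster are
#' sorted by id so the result is invariant to input order.
#'
#' @param reads List of [nucleotide_read()] objects (>= 1).
#' @param identity_threshold Linkage threshold in (0.5, 1]. The default 0.99
#'   keeps reads of one transcript together (Sanger substitution error is
#'   well below 1%) while splitting transcripts that differ by a junction
#'   frameshift or a different V segment.
#' @return List of `read_cluster` objects, each with `members`, `consensus`
#'   and per-column `support`.
#' @export
cluster_reads <- function(reads, identity_threshold = 0.99) {
  if (!length(reads)) abort_validation("no reads")
  if (identity_threshold <= 0.5 || identity_threshold > 1)
    abort_validation("identity_threshold must be in (0.5, 1]")
  ids <- vapply(reads, `[[`, "", "id")
  if (anyDuplicated(ids)) abort_validation("duplicate read ids")
  n <- length(reads)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (find(i) == find(j)) next
      id_ij <- pairwise_identity(reads[[i]]$sequence, reads[[j]]$sequence)
      if (id_ij >= identity_threshold) parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- unname(split(seq_len(n), comp))
  clusters <- lapply(groups, function(ii) {
    members <- reads[ii][order(ids[ii])]
    prof <- consensus_profile(members)
    structure(list(members = members, consensus = prof$consensus,
                   support = prof$support),
              class = "read_cluster")
  })
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  first_id <- vapply(clusters, function(cl) cl$members[[1]]$id, "")
  clusters[order(-sizes, first_id)]
}

#' Majority-vote consensus of a read cluster
#'
#' Members are aligned progressively (pairwise) to the longest member, which
#' defines the column space; reads are near-identical so full MSA machinery
#' is unnecessary. Per column the strict-majority base is emitted; exact
#' ties between concrete bases are emitted as the covering IUPAC ambiguity
#' code; columns where gaps hold the majority are deleted. `N` in a member
#' never wins a vote: `N` votes are discarded and the most frequent concrete
#' base is used (an all-`N` column emits `N`).
#'
#' @param cluster A `read_cluster` (or plain list of reads).
#' @return Consensus DNA string (possibly with IUPAC ambiguity codes).
#' @export
call_consensus <- function(cluster) {
  members <- if (inherits(cluster, "read_cluster")) cluster$members else cluster
  if (!length(members)) abort_validation("empty cluster")
  consensus_profile(members)$consensus
}

# Shared implementation: returns consensus string plus per-emitted-column
# support (fraction of members agreeing with the emitted base).
consensus_profile <- function(members) {
  n <- length(members)
  seqs <- vapply(members, `[[`, "", "sequence")
  if (n == 1L)
    return(list(consensus = seqs[1], support = rep(1, nchar(seqs[1]))))
  # deterministic backbone: longest member, ties by smallest id
  ids <- vapply(members, `[[`, "", "id")
  ord <- order(-nchar(seqs), ids)
  backbone <- seqs[ord[1]]
  L <- nchar(backbone)
  # base votes per backbone column; insertions relative to the backbone are
  # keyed by (backbone position, insertion offset)
  votes <- matrix(0L, nrow = 5, ncol = L,
                  dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  ins <- new.env(parent = emptyenv())
  add_ins <- function(pos, off, base, who) {
    key <- paste0(pos, ".", off)
    cur <- if (!is.null(ins[[key]])) ins[[key]] else character(0)
    cur[who] <- base
    ins[[key]] <- cur
  }
  bvec <- strsplit(backbone, "")[[1]]
  for (col in seq_len(L)) {
    b <- bvec[col]
    if (b %in% rownames(votes)) votes[b, col] <- votes[b, col] + 1L
  }
  for (m in seq_along(members)) {
    if (m == ord[1]) next
    aln <- align_global(seqs[m], backbone)
    s <- aln_strings(aln)
    p <- strsplit(s$pattern, "")[[1]]   # member
    q <- strsplit(s$subject, "")[[1]]   # backbone
    qi <- 0L; off <- 0L
    for (k in seq_along(p)) {
      if (q[k] != "-") { qi <- qi + 1L; off <- 0L }
      if (q[k] == "-") {
        off <- off + 1L
        if (p[k] != "-") add_ins(qi, off, p[k], as.character(m))
      } else {
        base <- if (p[k] == "-") "-" else p[k]
        if (base %in% c("A", "C", "G", "T", "-"))
          votes[base, qi] <- votes[base, qi] + 1L
        # N votes are dropped entirely
      }
    }
  }
  out <- character(0); supp <- numeric(0)
  emit <- function(counts, n_total) {
    bases <- counts[c("A", "C", "G", "T")]
    gaps <- counts["-"]
    if (gaps * 2L > n_total) return(NULL)          # gap-majority column deleted
    if (sum(bases) == 0L) return(list(base = "N", support = 0))
    top <- max(bases)
    tied <- sort(names(bases)[bases == top])
    base <- IUPAC_FROM_SET[paste(tied, collapse = "")]
    list(base = unname(base), support = top / n_total)
  }
  emit_ins <- function(col) {
    off <- 1L
    repeat {
      key <- paste0(col, ".", off)
      if (is.null(ins[[key]])) break
      basev <- ins[[key]]
      counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, "-" = n - length(basev))
      for (b in basev) if (b %in% names(counts)) counts[b] <- counts[b] + 1L
      e <- emit(counts, n)
      if (!is.null(e)) { out <<- c(out, e$base); supp <<- c(supp, e$support) }
      off <- off + 1L
    }
  }
  emit_ins(0L)  # member bases 5' of the backbone
  for (col in seq_len(L)) {
    e <- emit(votes[, col], n)
    if (!is.null(e)) { out <- c(out, e$base); supp <- c(supp, e$support) }
    emit_ins(col)
  }
  list(consensus = paste(out, collapse = ""), support = supp)
}

#' @export
print.read_cluster <- function(x, ...) {
  cat(sprintf("<read_cluster> %d reads, consensus %d nt, mean support %.3f\n",
              length(x$members), nchar(x$consensus), mean(x$support)))
  invisible(x)
}
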