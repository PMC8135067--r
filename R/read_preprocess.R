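## Read cleaning: PCR-duplicate removal by prefix identity + whole-read
## similarity, then adapter trimming and mean-quality filtering.

#' Whole-read similarity between two sequences
#'
#' For equal-length reads, similarity is positional identity: the fraction of
#' positions carrying the same non-N base. For unequal lengths a global
#' alignment (match = 1, mismatch and gap = 0) is used and similarity is
#' matches / alignment length. `N` never matches, not even another `N`.
#'
#' @param a,b nucleotide strings (A/C/G/T/N).
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' read_similarity("ACGT", "ACGA")  # 0.75
#' @export
read_similarity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop_invalid("read_similarity: sequences must be non-empty")
  if (nchar(a) == nchar(b)) {
    ia <- utf8ToInt(a); ib <- utf8ToInt(b)
    n_code <- utf8ToInt("N")
    sum(ia == ib & ia != n_code) / length(ia)
  } else {
    similarity_aligned(a, b)
  }
}

## unequal lengths: global alignment identity via Biostrings
similarity_aligned <- function(a, b) {
  mat <- matrix(0, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                         c("A", "C", "G", "T", "N")))
  diag(mat) <- 1
  mat["N", "N"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0
  )
  ## alignment length including gap columns (end gaps included)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / len
}

#' PCR-duplicate test for a read pair
#'
#' Two reads are PCR duplicates when (i) their first 10 bases are identical
#' (case-insensitive; `N` never matches) and (ii) the entire reads exhibit
#' strictly more than 90% similarity as computed by [read_similarity()].
#'
#' @param a,b nucleotide strings, each at least `prefix_len` bases.
#' @param prefix_len length of the exact-identity prefix (default 10).
#' @param min_similarity strict lower similarity bound (default 0.90).
#' @return logical scalar.
#' @export
is_pcr_duplicate <- function(a, b, prefix_len = 10L, min_similarity = 0.90) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < prefix_len || nchar(b) < prefix_len)
    stop_invalid(sprintf("is_pcr_duplicate: reads must be >= %d nt", prefix_len))
  pa <- utf8ToInt(substr(a, 1L, prefix_len))
  pb <- utf8ToInt(substr(b, 1L, prefix_len))
  n_code <- utf8ToInt("N")
  if (!all(pa == pb & pa != n_code)) return(FALSE)
  read_similarity(a, b) > min_similarity
}

#' Remove PCR duplicates from a read set
#'
#' Reads are bucketed by their exact `prefix_len`-mer prefix; within each
#' bucket, pairs satisfying [is_pcr_duplicate()] are merged by single linkage.
#' The first-seen read of each cluster is kept as representative.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @inheritParams is_pcr_duplicate
#' @return list with `kept` (data.frame of retained reads), `report` (a
#'   `dedup_report`: n_input, n_kept, n_removed_duplicates, clusters), and
#'   `cluster` (integer cluster index per input read, in input order).
#' @export
deduplicate_reads <- function(reads, prefix_len = 10L, min_similarity = 0.90) {
  check_reads(reads)
  seqs <- toupper(reads$sequence)
  n <- length(seqs)
  if (n > 0L && any(nchar(seqs) < prefix_len))
    stop_invalid(sprintf("deduplicate_reads: all reads must be >= %d nt", prefix_len))

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  buckets <- split(seq_len(n), substr(seqs, 1L, prefix_len))
  for (idx in buckets) {
    if (length(idx) < 2L) next
    ## prefixes containing N never satisfy the prefix condition
    if (grepl("N", substr(seqs[idx[1L]], 1L, prefix_len), fixed = TRUE)) next
    for (k in seq_along(idx)[-1L]) {
      for (j in seq_len(k - 1L)) {
        i1 <- idx[j]; i2 <- idx[k]
        if (find(i1) == find(i2)) next
        if (read_similarity(seqs[i1], seqs[i2]) > min_similarity)
          union2(i1, i2)
      }
    }
  }

  root <- if (n) vapply(seq_len(n), find, integer(1)) else integer(0)
  cluster <- match(root, unique(root))
  keep <- !duplicated(cluster)
  kept <- reads[keep, , drop = FALSE]
  row.names(kept) <- NULL

  clusters <- lapply(split(seq_len(n), cluster)[order(unique(cluster))],
                     function(ii) list(kept_read_id = reads$read_id[ii[1L]],
                                       removed_read_ids = reads$read_id[ii[-1L]]))
  clusters <- unname(Filter(function(cl) length(cl$removed_read_ids) > 0, clusters))
  report <- structure(
    list(n_input = n, n_kept = sum(keep),
         n_removed_duplicates = n - sum(keep), clusters = clusters),
    class = "dedup_report"
  )
  list(kept = kept, report = report, cluster = cluster)
}

#' @export
print.dedup_report <- function(x, ...) {
  cat("PCR-duplicate removal report\n")
  cat(sprintf("  input reads:        %d\n", x$n_input))
  cat(sprintf("  kept reads:         %d\n", x$n_kept))
  cat(sprintf("  removed duplicates: %d (in %d clusters)\n",
              x$n_removed_duplicates, length(x$clusters)))
  invisible(x)
}

#' Adapter trimming and mean-quality filtering
#'
#' The cleaning criteria beyond duplicate removal are not standardized in this
#' pipeline's source protocol; the defaults here (3' exact adapter-prefix
#' match with minimum overlap 5, mean Phred >= 20) are package choices and are
#' recorded in every run log.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param adapter adapter sequence, or `NULL` to skip trimming.
#' @param min_mean_q minimum mean Phred score for a read to be kept.
#' @param min_overlap minimum 3' overlap with the adapter start to trim.
#' @return list with `kept` (trimmed, filtered reads) and counts
#'   `n_trimmed`, `n_removed_quality`.
#' @export
filter_reads <- function(reads, adapter = NULL, min_mean_q = 20,
                         min_overlap = 5L) {
  check_reads(reads)
  seqs <- reads$sequence
  quals <- reads$quality
  n_trimmed <- 0L

  if (!is.null(adapter)) {
    if (!nzchar(adapter)) stop_invalid("adapter must be non-empty when given")
    adapter <- toupper(adapter)
    for (i in seq_along(seqs)) {
      s <- toupper(seqs[i]); L <- nchar(s)
      ## longest suffix of the read equal to a prefix of the adapter
      max_ov <- min(L, nchar(adapter))
      hit <- 0L
      if (max_ov >= min_overlap) {
        for (ov in seq(max_ov, min_overlap)) {
          if (substr(s, L - ov + 1L, L) == substr(adapter, 1L, ov)) {
            hit <- ov
            break
          }
        }
      }
      if (hit > 0L) {
        seqs[i] <- substr(seqs[i], 1L, L - hit)
        quals[i] <- substr(quals[i], 1L, L - hit)
        n_trimmed <- n_trimmed + 1L
      }
    }
  }

  keep <- if (length(seqs)) mean_phred(quals) >= min_mean_q else logical(0)
  kept <- data.frame(read_id = reads$read_id[keep], sequence = seqs[keep],
                     quality = quals[keep], stringsAsFactors = FALSE)
  list(kept = kept, n_trimmed = n_trimmed,
       n_removed_quality = sum(!keep))
}
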