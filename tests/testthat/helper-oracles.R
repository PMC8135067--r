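# Independent brute-force oracles, implemented from first principles and
# deliberately not sharing code with the package internals they check.

# All-pairs single-linkage PCR-duplicate partition: for every pair, test the
# rule verbatim (first 10 bases identical, N never matching; whole-read
# positional identity strictly above 0.90), then take connected components.
oracle_dedup_partition <- function(seqs, prefix_len = 10, min_sim = 0.90) {
  n <- length(seqs)
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pref <- substr(toupper(seqs), 1, prefix_len)
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      if (pref[i] != pref[j]) next
      if (grepl("N", pref[i], fixed = TRUE)) next
      si <- chars[[i]]; sj <- chars[[j]]
      sim <- sum(si == sj & si != "N") / max(length(si), length(sj))
      if (sim > min_sim) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  match(root, unique(root))  # canonical labels in first-seen order
}

# Exhaustive ancestor walk on a raw edge list (child -> parent).
oracle_ancestors <- function(edges, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    parents <- edges$parent[edges$child %in% frontier]
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  sort(seen)
}

# Shortest path length to a root by breadth-first search on the edge list.
oracle_level <- function(edges, root, term) {
  if (term == root) return(0L)
  level <- 0L
  frontier <- term
  repeat {
    level <- level + 1L
    frontier <- unique(edges$parent[edges$child %in% frontier])
    if (!length(frontier)) return(NA_integer_)
    if (root %in% frontier) return(level)
  }
}

random_reads_df <- function(seqs) {
  data.frame(
    read_id = sprintf("r%04d", seq_along(seqs)),
    sequence = seqs,
    quality = vapply(nchar(seqs), function(L) strrep("I", L), character(1)),
    stringsAsFactors = FALSE
  )
}
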