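## Comparative GO enrichment: per-set term frequencies, the pseudo-count
## regularized signed score, the display filter and graph export.

#' Frequency of a GO term within a gene set
#'
#' Fraction of the set's genes annotated (after true-path closure) to the
#' term.
#'
#' @param gene_set character vector of gene ids.
#' @param term a term id.
#' @param ann_closed closed annotation list (see [propagate_annotations()]).
#' @return fraction in `[0, 1]`.
#' @export
term_frequency <- function(gene_set, term, ann_closed) {
  if (!length(gene_set)) stop_invalid("gene_set must be non-empty")
  hits <- vapply(gene_set, function(g) term %in% ann_closed[[g]], logical(1))
  mean(hits)
}

#' Signed pseudo-count regularized enrichment score
#'
#' `score = log2((freq_A + pseudo) / (freq_B + pseudo))`: positive when the
#' term is more frequent among set-A (mutant-specific) genes, negative for
#' set B, zero at equal frequencies, and exactly antisymmetric under swapping
#' the sets. The pseudo-count is a small fixed constant keeping the score
#' finite when a term is absent from one set.
#'
#' @param freq_a,freq_b term frequencies in the two gene sets.
#' @param pseudo pseudo-count, > 0 (default 0.01).
#' @param base logarithm base (default 2; the score scale all thresholds in
#'   this package assume).
#' @return signed score(s).
#' @examples
#' enrichment_score(0.30, 0.05)  # about 2.37
#' @export
enrichment_score <- function(freq_a, freq_b, pseudo = 0.01, base = 2) {
  if (pseudo <= 0) stop_invalid("pseudo-count must be > 0")
  ## difference of logs, so swapping the sets negates the score exactly
  log(freq_a + pseudo, base = base) - log(freq_b + pseudo, base = base)
}

#' Compare two gene sets over every GO term
#'
#' Computes, for each term of the DAG, its frequency in each gene set (after
#' closing the annotations if needed), the signed enrichment score, the GO
#' level, and the display attributes of [filter_display()].
#'
#' @param dag a `go_dag`.
#' @param ann annotation list (closed or not; closed if `propagate = TRUE`).
#' @param set_a,set_b disjoint gene-id vectors (A = mutant-specific set;
#'   positive scores mean enriched in A).
#' @param pseudo pseudo-count (default 0.01).
#' @param propagate close the annotations up the DAG first (default TRUE).
#' @param min_level,score_band display-filter parameters, see
#'   [filter_display()].
#' @return data.frame (class `enrichment_result`) with columns `term_id`,
#'   `name`, `namespace`, `level`, `n_genes_a`, `n_genes_b`, `freq_a`,
#'   `freq_b`, `score`, `node_size`, `displayed`.
#' @export
enrich_compare <- function(dag, ann, set_a, set_b, pseudo = 0.01,
                           propagate = TRUE, min_level = 2,
                           score_band = 1.2) {
  if (!length(set_a) || !length(set_b))
    stop_invalid("both gene sets must be non-empty")
  if (length(intersect(set_a, set_b)))
    stop_invalid("gene sets must be disjoint")
  if (propagate && !isTRUE(attr(ann, "closed")))
    ann <- propagate_annotations(dag, ann)
  terms <- dag$terms$id

  count_hits <- function(set) {
    tab <- table(unlist(ann[intersect(set, names(ann))], use.names = FALSE))
    n <- stats::setNames(integer(length(terms)), terms)
    n[names(tab)] <- as.integer(tab)
    n
  }
  n_a <- count_hits(set_a)
  n_b <- count_hits(set_b)
  res <- data.frame(
    term_id = terms,
    name = dag$terms$name,
    namespace = dag$terms$namespace,
    level = go_level(dag, terms),
    n_genes_a = as.integer(n_a),
    n_genes_b = as.integer(n_b),
    freq_a = n_a / length(set_a),
    freq_b = n_b / length(set_b),
    stringsAsFactors = FALSE
  )
  res$score <- enrichment_score(res$freq_a, res$freq_b, pseudo)
  res <- filter_display(res, min_level = min_level, score_band = score_band)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Zero-size display filter for the enrichment graph view
#'
#' A term is displayed iff its GO level is at least `min_level` and its score
#' lies outside the open band `(-score_band, score_band)` (band endpoints are
#' displayed). Non-displayed terms stay in the graph as zero-sized nodes;
#' displayed terms get `node_size` = number of genes from either set carrying
#' the term.
#'
#' @param results data.frame with `level`, `score`, `n_genes_a`, `n_genes_b`.
#' @param min_level minimum displayed level (default 2).
#' @param score_band half-width of the masked score band (default 1.2).
#' @return `results` with `displayed` and `node_size` columns set.
#' @export
filter_display <- function(results, min_level = 2, score_band = 1.2) {
  if (score_band < 0) stop_invalid("score_band must be >= 0")
  displayed <- results$level >= min_level & abs(results$score) >= score_band
  results$displayed <- displayed
  results$node_size <- ifelse(displayed,
                              as.numeric(results$n_genes_a + results$n_genes_b),
                              0)
  results
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GO enrichment over %d terms (%d displayed)\n",
              nrow(x), sum(x$displayed)))
  shown <- x[x$displayed, c("term_id", "name", "level", "score", "node_size")]
  if (nrow(shown)) {
    shown <- shown[order(-abs(shown$score)), ]
    print(utils::head(as.data.frame(shown), 10), row.names = FALSE)
  }
  invisible(x)
}

#' Export an enrichment graph for Cytoscape
#'
#' Writes one GraphML graph restricted to a namespace, with per-node `score`
#' (positive = set A = red end of a diverging palette, negative = set B =
#' blue), `node_size`, `level` and `displayed` attributes, and 'is_a' edges.
#'
#' @param dag a `go_dag`.
#' @param results an `enrichment_result` (may be missing terms; absent terms
#'   get score 0 and node_size 0).
#' @param namespace one of the DAG's namespaces.
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(dag, results, namespace, path) {
  if (!namespace %in% dag$terms$namespace)
    stop_invalid(sprintf("unknown namespace '%s'", namespace))
  ids <- dag$terms$id[dag$terms$namespace == namespace]
  edges <- dag$edges[dag$edges$child %in% ids & dag$edges$parent %in% ids, ]
  m <- match(ids, results$term_id)
  verts <- data.frame(
    name = ids,
    label = dag$terms$name[match(ids, dag$terms$id)],
    score = ifelse(is.na(m), 0, results$score[m]),
    node_size = ifelse(is.na(m), 0L, results$node_size[m]),
    level = go_level(dag, ids),
    displayed = ifelse(is.na(m), FALSE, results$displayed[m]),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
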