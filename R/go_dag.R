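## Gene Ontology 'is_a' DAG: OBO 1.2 ingestion, level computation and
## true-path annotation closure.

new_go_dag <- function(terms, edges) {
  ## terms: data.frame(id, name, namespace); edges: data.frame(child, parent)
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms[, "id", drop = FALSE]
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    stop_format(paste0("is_a cycle detected involving terms: ",
                       paste(sort(cyc), collapse = ", ")))
  }
  unknown <- setdiff(edges$parent, terms$id)
  if (length(unknown))
    stop_format(paste0("unknown parent id(s): ", paste(unknown, collapse = ", ")))
  ## roots: terms with no outgoing is_a edge, one per namespace
  root_ids <- terms$id[!(terms$id %in% edges$child)]
  roots <- stats::setNames(root_ids,
                           terms$namespace[match(root_ids, terms$id)])
  structure(list(terms = terms, edges = edges, roots = roots, graph = g),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO 'is_a' DAG: %d terms, %d edges\n",
              nrow(x$terms), nrow(x$edges)))
  for (ns in names(x$roots))
    cat(sprintf("  %s root: %s\n", ns, x$roots[[ns]]))
  invisible(x)
}

#' Parse an OBO 1.2 ontology into an 'is_a' DAG
#'
#' Only `is_a` edges are retained; `relationship:` lines and obsolete terms
#' are dropped. Cycles and references to undefined parents are format errors.
#'
#' @param path OBO file path.
#' @return a `go_dag`: term table (`id`, `name`, `namespace`), edge table
#'   (`child`, `parent`), namespace `roots`, and the underlying igraph.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  idx <- which(lines == "[Term]")
  if (!length(idx)) stop_format("no [Term] stanzas found")
  ends <- c(idx[-1L] - 1L, length(lines))
  ids <- names <- nss <- character(0)
  ch <- pa <- character(0)
  for (k in seq_along(idx)) {
    block <- lines[idx[k]:ends[k]]
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name: ", block, value = TRUE)[1])
    ns <- sub("^namespace: *", "", grep("^namespace: ", block, value = TRUE)[1])
    parents <- sub("^is_a: *([^ !]+).*$", "\\1",
                   grep("^is_a: ", block, value = TRUE))
    ids <- c(ids, id)
    names <- c(names, if (is.na(nm)) id else nm)
    nss <- c(nss, if (is.na(ns)) "biological_process" else ns)
    ch <- c(ch, rep(id, length(parents)))
    pa <- c(pa, parents)
  }
  if (!all(pa %in% ids))
    stop_format(paste0("unknown parent id(s): ",
                       paste(unique(pa[!(pa %in% ids)]), collapse = ", ")))
  new_go_dag(
    data.frame(id = ids, name = names, namespace = nss,
               stringsAsFactors = FALSE),
    data.frame(child = ch, parent = pa, stringsAsFactors = FALSE)
  )
}

#' Write a `go_dag` as OBO 1.2
#'
#' @param dag a `go_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(dag$edges$parent, dag$edges$child)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    writeLines("[Term]", con)
    writeLines(sprintf("id: %s", t$id), con)
    writeLines(sprintf("name: %s", t$name), con)
    writeLines(sprintf("namespace: %s", t$namespace), con)
    for (p in by_child[[t$id]])
      writeLines(sprintf("is_a: %s", p), con)
    writeLines("", con)
  }
  invisible(path)
}

#' GO level of a term
#'
#' Level is the shortest 'is_a' path length from the term's namespace root
#' (the root itself is level 0).
#'
#' @param dag a `go_dag`.
#' @param term term id(s).
#' @return integer vector of levels.
#' @export
go_level <- function(dag, term) {
  if (!all(term %in% dag$terms$id))
    stop_invalid(paste0("unknown term(s): ",
                        paste(setdiff(term, dag$terms$id), collapse = ", ")))
  d <- igraph::distances(dag$graph, v = term, to = dag$roots,
                         mode = "out")
  lev <- apply(d, 1L, min)
  as.integer(lev[term])
}

## all is_a ancestors (excluding the term itself), as a named list
go_ancestors <- function(dag, terms = dag$terms$id) {
  res <- igraph::ego(dag$graph, order = nrow(dag$terms), nodes = terms,
                     mode = "out")
  stats::setNames(lapply(seq_along(res), function(i)
    setdiff(names(res[[i]]), terms[i])), terms)
}

#' Propagate annotations up the 'is_a' graph (true-path closure)
#'
#' Every gene annotated to a term becomes annotated to all of that term's
#' ancestors. Idempotent.
#'
#' @param dag a `go_dag`.
#' @param ann named list: gene id -> character vector of term ids.
#' @return annotation list of the same shape, ancestor-complete, with
#'   attribute `closed = TRUE`.
#' @export
propagate_annotations <- function(dag, ann) {
  used <- unique(unlist(ann, use.names = FALSE))
  bad <- setdiff(used, dag$terms$id)
  if (length(bad))
    stop_invalid(paste0("annotation uses unknown term(s): ",
                        paste(bad, collapse = ", ")))
  anc <- go_ancestors(dag, used)
  out <- lapply(ann, function(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE)))))
  attr(out, "closed") <- TRUE
  out
}

#' Read a gene-to-GO annotation TSV
#'
#' Two columns: gene id, then comma-joined GO term ids.
#'
#' @param path TSV path.
#' @return named list gene id -> character vector of term ids
#'   (`closed` attribute FALSE).
#' @export
read_annotations <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("gene_id", "terms"))
  out <- stats::setNames(strsplit(x$terms, ",", fixed = TRUE), x$gene_id)
  attr(out, "closed") <- FALSE
  out
}

#' Write a gene-to-GO annotation TSV
#' @param ann named list gene -> term ids. @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(
    data.frame(gene_id = names(ann),
               terms = vapply(ann, paste, "", collapse = ","),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
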