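write_obo_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

diamond_dag <- function() {
  # root -> a -> t (short arm, length 2); root -> b -> c -> d -> t (length 4)
  parse_obo(write_obo_text(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: a", "namespace: biological_process",
    "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: b", "namespace: biological_process",
    "is_a: GO:1", "",
    "[Term]", "id: GO:4", "name: c", "namespace: biological_process",
    "is_a: GO:3", "",
    "[Term]", "id: GO:5", "name: d", "namespace: biological_process",
    "is_a: GO:4", "",
    "[Term]", "id: GO:6", "name: t", "namespace: biological_process",
    "is_a: GO:2", "is_a: GO:5", ""
  )))
}

test_that("OBO parsing keeps is_a edges, drops obsolete terms, flags cycles", {
  dag <- parse_obo(write_obo_text(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: child",
    "namespace: biological_process", "is_a: GO:1 ! root", ""
  )))
  expect_identical(nrow(dag$terms), 2L)
  expect_identical(nrow(dag$edges), 1L)
  expect_identical(unname(dag$roots), "GO:1")

  dag2 <- parse_obo(write_obo_text(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:9", "name: gone", "is_obsolete: true", ""
  )))
  expect_identical(dag2$terms$id, "GO:1")

  expect_error(parse_obo(write_obo_text(c(
    "[Term]", "id: GO:1", "name: a", "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "is_a: GO:1", ""
  ))), class = "ovatome_format_error")
  expect_error(parse_obo(write_obo_text(c(
    "[Term]", "id: GO:1", "name: a", "is_a: GO:7", ""
  ))), class = "ovatome_format_error")
})

test_that("synthetic OBO round-trips with identical term and edge counts", {
  gw <- sim_go_world(sim_config(seed = 4))
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(gw$dag, path)
  dag2 <- parse_obo(path)
  expect_identical(nrow(dag2$terms), nrow(gw$dag$terms))
  expect_identical(nrow(dag2$edges), nrow(gw$dag$edges))
  expect_setequal(paste(dag2$edges$child, dag2$edges$parent),
                  paste(gw$dag$edges$child, gw$dag$edges$parent))
})

test_that("parsed DAG matches the obonet reference parser", {
  gw <- sim_go_world(sim_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(gw$dag, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import obonet; g = obonet.read_obo('", path, "');",
    "print(g.number_of_nodes(), g.number_of_edges())"
  ))), stdout = TRUE)
  counts <- as.integer(strsplit(out, " ")[[1]])
  expect_identical(counts, c(nrow(gw$dag$terms), nrow(gw$dag$edges)))
})

test_that("GO level is the shortest is_a path from the namespace root", {
  dag <- diamond_dag()
  expect_identical(go_level(dag, "GO:1"), 0L)
  expect_identical(go_level(dag, "GO:2"), 1L)
  expect_identical(go_level(dag, "GO:6"), 2L)  # min(2, 4) on the diamond
  expect_error(go_level(dag, "GO:99"), class = "ovatome_invalid_input")

  # agrees with a breadth-first oracle on a random DAG
  gw <- sim_go_world(sim_config(seed = 12))
  root <- unname(gw$dag$roots[1])
  for (t in sample(gw$dag$terms$id, 10)) {
    expect_identical(go_level(gw$dag, t),
                     oracle_level(gw$dag$edges, root, t))
  }
})

test_that("annotation closure adds exactly the is_a ancestors, idempotently", {
  dag <- diamond_dag()
  ann <- list(g_root = "GO:1", g_deep = "GO:5", g_t = "GO:6")
  closed <- propagate_annotations(dag, ann)
  expect_identical(closed$g_root, "GO:1")
  expect_setequal(closed$g_deep, c("GO:5", "GO:4", "GO:3", "GO:1"))
  expect_setequal(closed$g_t, c("GO:6", "GO:2", "GO:5", "GO:4", "GO:3", "GO:1"))
  expect_identical(propagate_annotations(dag, closed)[], closed[])
  expect_error(propagate_annotations(dag, list(g = "GO:77")),
               class = "ovatome_invalid_input")

  # equals the exhaustive ancestor-walk oracle on a random world
  gw <- sim_go_world(sim_config(seed = 5))
  closed2 <- propagate_annotations(gw$dag, gw$ann)
  for (g in sample(names(gw$ann), 8)) {
    want <- sort(unique(c(gw$ann[[g]],
                          unlist(lapply(gw$ann[[g]], oracle_ancestors,
                                        edges = gw$dag$edges)))))
    expect_identical(closed2[[g]], want)
  }
})

test_that("term frequency counts closed annotations over the gene set", {
  dag <- diamond_dag()
  genes <- sprintf("g%02d", 1:10)
  ann <- stats::setNames(rep(list(character(0)), 10), genes)
  for (g in genes[1:3]) ann[[g]] <- "GO:5"
  closed <- propagate_annotations(dag, ann)
  expect_identical(term_frequency(genes, "GO:5", closed), 0.3)
  expect_identical(term_frequency(genes, "GO:6", closed), 0)
  expect_identical(term_frequency(genes, "GO:1", closed), 0.3)  # closure
  expect_error(term_frequency(character(0), "GO:5", closed),
               class = "ovatome_invalid_input")
})

test_that("enrichment score: zero at equality, antisymmetric, monotone", {
  expect_identical(enrichment_score(0.4, 0.4), 0)
  expect_equal(enrichment_score(0.30, 0.05, pseudo = 0.01), 2.369234,
               tolerance = 1e-6)
  for (fa in c(0, 0.2, 0.9)) {
    for (fb in c(0, 0.35, 1)) {
      expect_identical(enrichment_score(fa, fb), -enrichment_score(fb, fa))
    }
  }
  f <- seq(0, 1, by = 0.05)
  s <- enrichment_score(f, 0.3)
  expect_true(all(diff(s) > 0))
  expect_error(enrichment_score(0.1, 0.1, pseudo = 0),
               class = "ovatome_invalid_input")
})

test_that("closure makes term frequency monotone along is_a paths", {
  gw <- sim_go_world(sim_config(seed = 17))
  closed <- propagate_annotations(gw$dag, gw$ann)
  for (i in sample(nrow(gw$dag$edges), 20)) {
    child <- gw$dag$edges$child[i]
    parent <- gw$dag$edges$parent[i]
    expect_gte(term_frequency(gw$set_a, parent, closed),
               term_frequency(gw$set_a, child, closed))
  }
})

test_that("display filter zero-sizes shallow terms and the masked score band", {
  res <- data.frame(
    level = c(1, 4, 3, 2, 5),
    score = c(3.0, 0.5, -1.3, 1.2, -1.2),
    n_genes_a = c(4, 9, 10, 3, 2),
    n_genes_b = c(1, 2, 7, 5, 0)
  )
  out <- filter_display(res)
  expect_identical(out$displayed, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(out$node_size, c(0, 0, 17, 8, 2))
})

test_that("planted terms are recovered with the right sign and display flag", {
  gw <- sim_go_world(sim_config(seed = 3))
  res <- enrich_compare(gw$dag, gw$ann, gw$set_a, gw$set_b)
  m <- merge(gw$truth, as.data.frame(res), by = "term_id")
  expect_true(all(m$displayed))
  want_sign <- ifelse(m$direction == "up_in_mutant", 1, -1)
  expect_identical(sign(m$score), want_sign)
  # swapping the sets negates every score exactly
  res_sw <- enrich_compare(gw$dag, gw$ann, gw$set_b, gw$set_a)
  expect_equal(res_sw$score, -res$score)
  expect_error(enrich_compare(gw$dag, gw$ann, gw$set_a, gw$set_a),
               class = "ovatome_invalid_input")
})

test_that("GraphML export carries node attributes and round-trips", {
  gw <- sim_go_world(sim_config(seed = 6))
  res <- enrich_compare(gw$dag, gw$ann, gw$set_a, gw$set_b)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(gw$dag, res, "biological_process", path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_identical(as.integer(igraph::vcount(g)), nrow(gw$dag$terms))
  expect_identical(as.integer(igraph::ecount(g)), nrow(gw$dag$edges))
  expect_true(all(c("score", "node_size", "level", "displayed") %in%
                    igraph::vertex_attr_names(g)))
  # zero-sized nodes stay in the graph rather than being removed
  expect_identical(sum(igraph::V(g)$node_size > 0), sum(res$displayed))
  expect_error(export_graph(gw$dag, res, "made_up", tempfile()),
               class = "ovatome_invalid_input")
})
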