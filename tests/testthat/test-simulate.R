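test_that("configs reject contradictory settings", {
  expect_error(sim_config(read_length = 10), class = "ovatome_invalid_config")
  expect_error(sim_config(duplicate_rate = 1.2),
               class = "ovatome_invalid_config")
  expect_error(sim_config(planted_fold = 1), class = "ovatome_invalid_config")
  expect_error(sim_config(n_genes = 10, n_up_mutant = 8, n_up_wildtype = 8),
               class = "ovatome_invalid_config")
  expect_error(sim_config(dag_depth = 2), class = "ovatome_invalid_config")
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 123)
  expect_identical(sim_read_set(cfg), sim_read_set(cfg))
  expect_identical(sim_expression_pair(cfg), sim_expression_pair(cfg))
  expect_identical(sim_go_world(cfg)$truth, sim_go_world(cfg)$truth)
  expect_identical(sim_ovary_section(cfg), sim_ovary_section(cfg))
  expect_identical(sim_ct_table(cfg), sim_ct_table(cfg))
})

test_that("read sets plant duplicates that pass and near-misses that fail", {
  cfg <- sim_config(seed = 1, n_unique_reads = 50, duplicate_rate = 0.5)
  rs <- sim_read_set(cfg)
  reads <- rs$reads
  expect_false(any(is.na(reads$cluster)))
  seed_of <- function(cl) reads$sequence[reads$role == "seed" &
                                           reads$cluster == cl][1]
  for (i in which(reads$role == "duplicate")) {
    expect_true(is_pcr_duplicate(reads$sequence[i],
                                 seed_of(reads$cluster[i])))
  }
  # near-miss reads violate exactly one condition against their source seed
  near <- reads[reads$role == "near_miss", ]
  for (i in seq_len(nrow(near))) {
    sims <- vapply(reads$sequence[reads$role == "seed"],
                   read_similarity, numeric(1), b = near$sequence[i])
    src <- which.max(sims)
    seed_seq <- reads$sequence[reads$role == "seed"][src]
    prefix_ok <- substr(seed_seq, 1, 10) == substr(near$sequence[i], 1, 10)
    sim_ok <- max(sims) > 0.90
    expect_identical(prefix_ok + sim_ok, 1L)  # exactly one condition holds
    expect_false(is_pcr_duplicate(near$sequence[i], seed_seq))
  }
})

test_that("duplicate_rate 0 yields singleton clusters only", {
  rs <- sim_read_set(sim_config(seed = 2, duplicate_rate = 0,
                                n_unique_reads = 80))
  expect_identical(nrow(rs$reads), 80L)
  expect_identical(max(table(rs$reads$cluster)), 1L)
})

test_that("total reads and clustered fraction track duplicate_rate", {
  r <- 0.5
  totals <- frac <- numeric(30)
  for (s in seq_len(30)) {
    rs <- sim_read_set(sim_config(seed = s, n_unique_reads = 400,
                                  duplicate_rate = r, n_go_terms = 60))
    reads <- rs$reads[rs$reads$role != "near_miss", ]
    totals[s] <- nrow(reads)
    sizes <- table(reads$cluster)
    frac[s] <- mean(reads$cluster %in% names(sizes)[sizes >= 2])
  }
  # expected total = n_unique * (1 + rate); clustered fraction = rate
  expect_lt(abs(mean(totals) - 400 * (1 + r)),
            3 * stats::sd(totals) / sqrt(30))
  expect_lt(abs(mean(frac) - r), 3 * stats::sd(frac) / sqrt(30))
})

test_that("expression truth labels honour the planted design", {
  none <- sim_expression_pair(sim_config(seed = 3, n_up_mutant = 0,
                                         n_up_wildtype = 0))
  expect_true(all(none$truth$label %in% c("unchanged", "not_expressed")))
  low <- none$truth$fpkm_mut_true <= 5 & none$truth$fpkm_wt_true <= 5
  expect_identical(none$truth$label == "not_expressed", low)

  ep <- sim_expression_pair(sim_config(seed = 7, planted_fold = 4))
  up <- ep$truth[ep$truth$label == "up_in_mutant", ]
  expect_true(all(up$fpkm_mut_true / up$fpkm_wt_true >= 4))
  expect_true(all(up$fpkm_mut_true > 5))
  # the FPKM > 5 call is exercised on both sides of the threshold
  expect_gt(sum(ep$truth$label == "not_expressed"), 0)
  expect_gt(sum(ep$truth$label == "unchanged"), 0)
  expect_true(all(ep$counts$count_mut >= 0))
  expect_true(all(ep$counts$count_mut == round(ep$counts$count_mut)))
})

test_that("go worlds are acyclic, single-rooted, with deep planted terms", {
  for (s in c(5, 23)) {
    gw <- sim_go_world(sim_config(seed = s))
    expect_true(igraph::is_dag(gw$dag$graph))
    expect_length(gw$dag$roots, 1L)
    expect_true(all(go_level(gw$dag, gw$truth$term_id) >= 2L))
    expect_length(intersect(gw$set_a, gw$set_b), 0L)
    # planted frequency margin holds on the closed annotations
    closed <- propagate_annotations(gw$dag, gw$ann)
    for (k in seq_len(nrow(gw$truth))) {
      t <- gw$truth$term_id[k]
      fa <- term_frequency(gw$set_a, t, closed)
      fb <- term_frequency(gw$set_b, t, closed)
      if (gw$truth$direction[k] == "up_in_mutant") expect_gt(fa, fb)
      else expect_gt(fb, fa)
    }
  }
})

test_that("uniform annotations give near-zero mean enrichment", {
  gw <- sim_go_world(sim_config(seed = 31, n_planted_up = 0,
                                n_planted_down = 0))
  res <- enrich_compare(gw$dag, gw$ann, gw$set_a, gw$set_b)
  expect_lt(mean(abs(res$score)), 0.5)
  expect_lt(abs(mean(res$score)), 0.2)
})

test_that("ovary sections honour stage counts, area, and the cv warning", {
  sec <- sim_ovary_section(sim_config(seed = 5, n_follicles_per_stage =
                                        c(I = 200L, II = 150L, III = 30L),
                                      section_area = 5.0))
  s <- summarize_section(sec$follicles, sec$area_mm2)
  expect_identical(s$n_total, 380L)
  expect_identical(s$density_total, 380 / 5.0)
  expect_identical(as.integer(table(sec$follicles$stage_true)[c("I", "II", "III")]),
                   c(200L, 150L, 30L))

  empty <- sim_ovary_section(sim_config(seed = 5, n_follicles_per_stage =
                                          c(I = 0L, II = 0L, III = 0L)))
  expect_identical(nrow(empty$follicles), 0L)
  expect_warning(sim_ovary_section(sim_config(seed = 5, diameter_cv = 0.4)),
                 "misassignment")
})

test_that("section density example: 380 follicles over 5 mm2 gives 76/mm2", {
  sec <- sim_ovary_section(sim_config(seed = 5, n_follicles_per_stage =
                                        c(I = 200L, II = 150L, III = 30L),
                                      section_area = 5.0))
  s <- summarize_section(sec$follicles, sec$area_mm2)
  expect_identical(s$density_total, 76)
})
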