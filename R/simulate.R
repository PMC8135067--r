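## Synthetic-data generators. Every pipeline input can be produced with
## known ground truth, so downstream recovery is exactly scorable.

#' Simulation configuration
#'
#' One seed fans out into independent substreams per generator, so each
#' generator is bit-reproducible on its own. Defaults describe the study
#' conditions the pipeline targets: single-end 101-nt reads, libraries of
#' tens of millions of mapped fragments, follicle stages centred at 50/70/100
#' um, and fold changes planted safely above the 2-fold call threshold.
#'
#' @param seed integer master seed.
#' @param read_length read length in nt (>= 11).
#' @param n_unique_reads number of distinct library molecules.
#' @param duplicate_rate expected PCR-duplicate copies per unique read, in
#'   `[0, 1]`; also the expected fraction of reads sitting in clusters of
#'   size >= 2 (see the methods vignette for the construction).
#' @param n_genes number of genes in the expression table.
#' @param n_up_mutant,n_up_wildtype planted differential genes per direction.
#' @param planted_fold planted true FPKM fold change, > 1.
#' @param total_mapped mapped fragments per condition library.
#' @param dispersion negative-binomial dispersion of fragment counts.
#' @param n_go_terms,dag_depth GO DAG size and maximum depth (depth >= 3).
#' @param n_planted_up,n_planted_down GO terms planted as enriched in the
#'   mutant-specific / wildtype-specific gene set.
#' @param planted_freq_hi,planted_freq_lo planted term frequencies in the
#'   enriched vs depleted set.
#' @param background_rate per-term background annotation probability.
#' @param n_set_genes genes per condition-specific gene set.
#' @param n_follicles_per_stage named integer vector (stages I, II, III).
#' @param section_area section area in mm2.
#' @param diameter_cv coefficient of variation of follicle diameters.
#' @param ct_noise_sd replicate Ct noise SD in cycles.
#' @param n_ct_replicates qPCR replicates per (sample, gene).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       read_length = 101L,
                       n_unique_reads = 200L,
                       duplicate_rate = 0.25,
                       n_genes = 500L,
                       n_up_mutant = 40L,
                       n_up_wildtype = 40L,
                       planted_fold = 4,
                       total_mapped = 2e7,
                       dispersion = 0.02,
                       n_go_terms = 60L,
                       dag_depth = 4L,
                       n_planted_up = 3L,
                       n_planted_down = 3L,
                       planted_freq_hi = 0.35,
                       planted_freq_lo = 0.05,
                       background_rate = 0.1,
                       n_set_genes = 120L,
                       n_follicles_per_stage = c(I = 160L, II = 159L, III = 35L),
                       section_area = 5.52,
                       diameter_cv = 0.05,
                       ct_noise_sd = 0.2,
                       n_ct_replicates = 3L) {
  cfg <- as.list(environment())
  if (cfg$read_length < 11L)
    stop_invalid("read_length must be >= 11 (the 10-base prefix rule would dominate the whole read)",
                 class = "ovatome_invalid_config")
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate > 1)
    stop_invalid("duplicate_rate must be in [0, 1]",
                 class = "ovatome_invalid_config")
  if (cfg$planted_fold <= 1)
    stop_invalid("planted_fold must exceed 1",
                 class = "ovatome_invalid_config")
  if (cfg$n_up_mutant + cfg$n_up_wildtype > cfg$n_genes)
    stop_invalid("planted genes exceed n_genes",
                 class = "ovatome_invalid_config")
  if (cfg$dag_depth < 3L)
    stop_invalid("dag_depth must be >= 3", class = "ovatome_invalid_config")
  if (cfg$section_area <= 0)
    stop_invalid("section_area must be > 0", class = "ovatome_invalid_config")
  counts <- c(cfg$n_unique_reads, cfg$n_genes, cfg$n_go_terms,
              cfg$n_set_genes, cfg$n_follicles_per_stage, cfg$n_ct_replicates)
  if (any(counts < 0)) stop_invalid("counts must be >= 0",
                                    class = "ovatome_invalid_config")
  class(cfg) <- "sim_config"
  cfg
}

random_seq <- function(n, L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

mutate_at <- function(seq, positions) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions)
    s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

#' Simulate a read set with planted PCR-duplicate clusters
#'
#' Each unique read becomes a duplicated cluster seed with probability
#' `duplicate_rate^2`; flagged seeds receive `1 + Poisson(1/rate - 1)` extra
#' copies, so both the expected total read count, `n_unique * (1 + rate)`,
#' and the expected fraction of reads in clusters of size >= 2 (= rate) hold.
#' Copies keep the first 10 bases exact and mutate few enough later bases to
#' stay strictly above 90% identity. Each duplicated cluster also plants one
#' near-miss read violating exactly one of the two duplicate conditions
#' (alternating: one mismatching base inside the prefix, or enough mismatches
#' after it to drop similarity to <= 0.90).
#'
#' @param cfg a [sim_config()].
#' @return list with `reads` (data.frame: read_id, sequence, quality,
#'   cluster, role in seed/duplicate/near_miss) and `truth` (the same
#'   columns; the cluster column is the ground-truth partition).
#' @export
sim_read_set <- function(cfg) with_seed(derive_seed(cfg$seed, 1L), {
  L <- cfg$read_length
  u <- cfg$n_unique_reads
  r <- cfg$duplicate_rate
  base <- random_seq(u, L)
  k_max <- max(0L, floor((L - 1) / 10))          # mutations keeping > 0.90
  k_miss <- ceiling(L / 10)                      # mutations forcing <= 0.90

  seqs <- base
  cluster <- seq_len(u)
  role <- rep("seed", u)
  next_cluster <- u + 1L
  miss_type <- 0L
  for (i in seq_len(u)) {
    if (r > 0 && stats::runif(1) < r^2) {
      n_copies <- 1L + stats::rpois(1L, 1 / r - 1)
      for (cpy in seq_len(n_copies)) {
        k <- sample(0:k_max, 1L)
        pos <- if (k > 0L) sample((11L):L, k) else integer(0)
        seqs <- c(seqs, mutate_at(base[i], pos))
        cluster <- c(cluster, i)
        role <- c(role, "duplicate")
      }
      ## one near-miss per duplicated cluster, alternating violation type
      miss_type <- miss_type + 1L
      if (miss_type %% 2L == 1L) {
        nm <- mutate_at(base[i], sample(1:10, 1L))        # prefix fails
      } else if (L - 10L >= k_miss) {
        nm <- mutate_at(base[i], sample(11L:L, k_miss))   # similarity fails
      } else {
        nm <- mutate_at(base[i], sample(1:10, 1L))
      }
      seqs <- c(seqs, nm)
      cluster <- c(cluster, next_cluster)
      next_cluster <- next_cluster + 1L
      role <- c(role, "near_miss")
    }
  }
  n <- length(seqs)
  ord <- sample.int(n)                           # shuffle library order
  quals <- vapply(seq_len(n), function(i)
    intToUtf8(sample(63:73, L, replace = TRUE)), character(1))  # Q30-Q40
  reads <- data.frame(
    read_id = sprintf("read_%05d", seq_len(n)),
    sequence = seqs[ord],
    quality = quals,
    cluster = match(cluster[ord], unique(cluster[ord])),
    role = role[ord],
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = reads[, c("read_id", "cluster", "role")])
})

#' Simulate a two-condition expression table with planted fold changes
#'
#' True FPKM values are log-normal with a deliberate band of genes straddling
#' the FPKM > 5 expression threshold; planted genes get a true fold change of
#' `planted_fold` in the chosen direction with the high side comfortably
#' expressed. Fragment counts are negative-binomial around the expected
#' fragments for each true FPKM (RNA-seq counts are overdispersed; mean
#' `fpkm * length_kb * total_mapped / 1e6`, dispersion `cfg$dispersion`).
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (gene_id, length_nt, count_mut, count_wt) and
#'   `truth` (gene_id, length_nt, fpkm_mut_true, fpkm_wt_true, label).
#' @export
sim_expression_pair <- function(cfg) with_seed(derive_seed(cfg$seed, 2L), {
  n <- cfg$n_genes
  gene_id <- sprintf("gene_%04d", seq_len(n))
  length_nt <- sample(500:5000, n, replace = TRUE)

  base <- stats::rlnorm(n, meanlog = log(8), sdlog = 1.2)
  n_border <- round(0.1 * n)                 # exercise both sides of FPKM > 5
  if (n_border > 0)
    base[seq_len(n_border)] <- stats::runif(n_border, 3, 8)

  idx <- sample.int(n)                       # planted genes drawn at random
  up_mut <- idx[seq_len(cfg$n_up_mutant)]
  up_wt <- idx[cfg$n_up_mutant + seq_len(cfg$n_up_wildtype)]
  ## planted genes need a base level whose high side is clearly expressed
  planted_base <- function(k) exp(stats::runif(k, log(1.5), log(50)))
  base[up_mut] <- planted_base(length(up_mut))
  base[up_wt] <- planted_base(length(up_wt))

  fpkm_mut <- base
  fpkm_wt <- base
  fpkm_mut[up_mut] <- base[up_mut] * cfg$planted_fold
  fpkm_wt[up_wt] <- base[up_wt] * cfg$planted_fold

  label <- rep("unchanged", n)
  label[pmax(fpkm_mut, fpkm_wt) <= 5] <- "not_expressed"
  label[up_mut] <- "up_in_mutant"
  label[up_wt] <- "up_in_wildtype"

  draw <- function(fpkm) {
    mu <- fpkm * (length_nt / 1000) * (cfg$total_mapped / 1e6)
    stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
  }
  counts <- data.frame(gene_id = gene_id, length_nt = length_nt,
                       count_mut = draw(fpkm_mut), count_wt = draw(fpkm_wt),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id, length_nt = length_nt,
                      fpkm_mut_true = fpkm_mut, fpkm_wt_true = fpkm_wt,
                      label = label, stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
})

#' Simulate a GO world: DAG, annotations, gene sets and planted enrichment
#'
#' Builds a single-namespace (biological_process) random 'is_a' DAG of
#' `n_go_terms` terms with depth capped at `dag_depth` (15% of terms gain a
#' second parent). Two disjoint gene sets are annotated with a uniform
#' per-term background; planted terms (leaf terms at level >= 2, so closure
#' cannot dilute them) are annotated directly at frequency
#' `planted_freq_hi` in their enriched set and `planted_freq_lo` in the
#' other.
#'
#' @param cfg a [sim_config()].
#' @return list with `dag` (a `go_dag`), `ann` (direct annotations),
#'   `set_a`, `set_b` (gene-id vectors; A = mutant-specific), and `truth`
#'   (data.frame: term_id, direction, freq_planted_hi, freq_planted_lo).
#' @export
sim_go_world <- function(cfg) with_seed(derive_seed(cfg$seed, 3L), {
  nt <- cfg$n_go_terms
  ids <- sprintf("GO:%07d", seq_len(nt))
  depth <- integer(nt); depth[1L] <- 0L
  child <- parent <- character(0)
  for (i in 2:nt) {
    ok <- which(depth[seq_len(i - 1L)] < cfg$dag_depth)
    p <- ok[sample.int(length(ok), 1L)]
    child <- c(child, ids[i]); parent <- c(parent, ids[p])
    depth[i] <- depth[p] + 1L
    if (depth[i] >= 2L && stats::runif(1) < 0.15) {
      ## extra is_a parent at a strictly shallower depth keeps it a DAG
      ok2 <- setdiff(which(depth[seq_len(i - 1L)] < depth[i]), p)
      if (length(ok2)) {
        p2 <- ok2[sample.int(length(ok2), 1L)]
        child <- c(child, ids[i]); parent <- c(parent, ids[p2])
      }
    }
  }
  dag <- new_go_dag(
    data.frame(id = ids,
               name = c("root", sprintf("term %d", 2:nt)),
               namespace = "biological_process", stringsAsFactors = FALSE),
    data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  )

  set_a <- sprintf("gene_mut_%03d", seq_len(cfg$n_set_genes))
  set_b <- sprintf("gene_wt_%03d", seq_len(cfg$n_set_genes))
  genes <- c(set_a, set_b)
  ann <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    hit <- ids[-1L][stats::runif(nt - 1L) < cfg$background_rate]
    ann[[g]] <- hit
  }

  ## plant on leaf terms at level >= 2: leaves have no descendants, so
  ## closure of background annotations below them cannot wash the signal out
  lev <- go_level(dag, ids)
  n_desc <- vapply(
    igraph::ego(dag$graph, order = nt, nodes = ids, mode = "in"),
    length, integer(1)) - 1L
  cand <- ids[lev >= 2L & n_desc == 0L]
  n_plant <- cfg$n_planted_up + cfg$n_planted_down
  if (length(cand) < n_plant)
    stop_invalid("DAG too small to host the planted terms at level >= 2",
                 class = "ovatome_invalid_config")
  ## planted terms must be pairwise unrelated on the DAG, else closure of one
  ## planted term would contaminate the frequencies of its planted ancestor
  anc <- go_ancestors(dag, cand)
  planted <- character(0)
  for (t in sample(cand)) {
    if (length(planted) == n_plant) break
    related <- any(planted %in% anc[[t]]) ||
      any(vapply(planted, function(q) t %in% anc[[q]], logical(1)))
    if (!related) planted <- c(planted, t)
  }
  if (length(planted) < n_plant)
    stop_invalid("could not place pairwise-unrelated planted terms; increase n_go_terms",
                 class = "ovatome_invalid_config")
  up <- planted[seq_len(cfg$n_planted_up)]
  down <- planted[cfg$n_planted_up + seq_len(cfg$n_planted_down)]

  ## planting clears a term's background hits first so the direct planted
  ## frequencies are exact in both sets
  for (t in up) {
    ann <- lapply(ann, setdiff, y = t)                 # clear background
    for (g in sample(set_a, round(cfg$planted_freq_hi * length(set_a))))
      ann[[g]] <- union(ann[[g]], t)
    for (g in sample(set_b, round(cfg$planted_freq_lo * length(set_b))))
      ann[[g]] <- union(ann[[g]], t)
  }
  for (t in down) {
    ann <- lapply(ann, setdiff, y = t)
    for (g in sample(set_b, round(cfg$planted_freq_hi * length(set_b))))
      ann[[g]] <- union(ann[[g]], t)
    for (g in sample(set_a, round(cfg$planted_freq_lo * length(set_a))))
      ann[[g]] <- union(ann[[g]], t)
  }
  attr(ann, "closed") <- FALSE
  truth <- data.frame(
    term_id = c(up, down),
    direction = rep(c("up_in_mutant", "up_in_wildtype"),
                    c(length(up), length(down))),
    freq_planted_hi = rep(cfg$planted_freq_hi, n_plant),
    freq_planted_lo = rep(cfg$planted_freq_lo, n_plant),
    stringsAsFactors = FALSE
  )
  list(dag = dag, ann = ann, set_a = set_a, set_b = set_b, truth = truth)
})

#' Simulate one ovary section with stage-structured diameters
#'
#' Diameters are normal around the nominal stage means (50, 70, 100 um) with
#' coefficient of variation `diameter_cv`, truncated at 1 um. If the
#' configured cv makes the stage distributions overlap enough that the
#' default classifier would misassign more than 20% of follicles, a warning
#' (not an error) is emitted.
#'
#' @param cfg a [sim_config()].
#' @return list with `follicles` (follicle_id, diameter_um, stage_true),
#'   `area_mm2`, and `truth` (stage counts).
#' @export
sim_ovary_section <- function(cfg) with_seed(derive_seed(cfg$seed, 4L), {
  means <- c(I = 50, II = 70, III = 100)
  counts <- cfg$n_follicles_per_stage
  if (is.null(names(counts)) || !all(names(counts) %in% names(means)))
    stop_invalid("n_follicles_per_stage must be named with stages I/II/III",
                 class = "ovatome_invalid_config")
  if (cfg$diameter_cv > 0) {
    ## expected misassignment under the default 60/85 um boundaries
    mis <- c(stats::pnorm(60, 50, 50 * cfg$diameter_cv, lower.tail = FALSE),
             stats::pnorm(60, 70, 70 * cfg$diameter_cv) +
               stats::pnorm(85, 70, 70 * cfg$diameter_cv, lower.tail = FALSE),
             stats::pnorm(85, 100, 100 * cfg$diameter_cv))
    w <- counts[names(means)]; w[is.na(w)] <- 0
    if (sum(w) > 0 && sum(mis * w) / sum(w) > 0.2)
      warning("stage diameter distributions overlap: expected misassignment exceeds 20%")
  }
  stage <- rep(names(counts), counts)
  d <- pmax(1, stats::rnorm(length(stage), means[stage],
                            means[stage] * cfg$diameter_cv))
  follicles <- data.frame(
    follicle_id = sprintf("fol_%04d", seq_along(stage)),
    diameter_um = d,
    stage_true = stage,
    stringsAsFactors = FALSE
  )
  list(follicles = follicles, area_mm2 = cfg$section_area,
       truth = as.list(counts))
})

#' Simulate a qPCR Ct table with known delta-delta-Ct ground truth
#'
#' The reference gene sits near Ct 20 and targets near Ct 24 in the
#' calibrator; each target's test-sample Ct is shifted by its true ddCt.
#' Replicates get independent normal noise of SD `ct_noise_sd` cycles.
#'
#' @param cfg a [sim_config()].
#' @param ddct_true named numeric vector of true ddCt per target gene.
#' @param reference reference gene name.
#' @return list with `ct` (long data.frame sample/gene/ct) and `truth`
#'   (gene, ddct_true, rq_true).
#' @export
sim_ct_table <- function(cfg,
                         ddct_true = c(ces1 = 0.585, pkcb = 0.678,
                                       mlh3 = -1.07),
                         reference = "GAPDH") {
  with_seed(derive_seed(cfg$seed, 5L), {
    reps <- cfg$n_ct_replicates
    sd <- cfg$ct_noise_sd
    rows <- list()
    add <- function(sample, gene, mu)
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, gene = gene,
        ct = stats::rnorm(reps, mu, sd), stringsAsFactors = FALSE)
    add("wildtype", reference, 20)
    add("mutant", reference, 20)
    for (g in names(ddct_true)) {
      add("wildtype", g, 24)
      add("mutant", g, 24 + ddct_true[[g]])
    }
    list(ct = do.call(rbind, rows),
         truth = data.frame(gene = names(ddct_true),
                            ddct_true = unname(ddct_true),
                            rq_true = 2^(-unname(ddct_true)),
                            stringsAsFactors = FALSE))
  })
}
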