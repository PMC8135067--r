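# ovatome

Comparative ovary transcriptomics and follicle morphometry for two-condition
studies in the ascidian *Ciona intestinalis* — typically a neuropeptide-gene
knockout versus wildtype.

When a mutant ovary is profiled against a wildtype one without replicates,
the analysis rests on a handful of simple, sharply defined rules rather than
on statistical testing. `ovatome` implements that rule set end to end, with
a synthetic-data module that generates every input with known ground truth
so the whole pipeline is testable offline:

- **PCR-duplicate removal** from single-end reads: two reads are duplicates
  iff their first 10 bases are identical and the whole reads show strictly
  more than 90% similarity; clusters are closed by single linkage and the
  first-seen read is kept.
- **Expression quantification**: FPKM = count × 10⁹ / (length_nt ×
  total_mapped); a gene is *expressed* iff FPKM > 5 (strict), and among
  genes expressed in either condition a gene is *up in the mutant* iff
  FPKM_mut / FPKM_wt > 2, *up in the wildtype* iff the ratio is < 0.5.
- **Comparative GO enrichment** on the 'is_a' ontology graph: after
  true-path closure, each term gets the signed score
  `log2((f_A + c) / (f_B + c))`, where `f_X` is the term's annotation
  frequency in condition-specific gene set X and `c` is a fixed pseudo-count
  (default 0.01). Terms at GO level < 2 (shortest is_a path from the root)
  or with a score strictly inside (−1.2, 1.2) are rendered as zero-sized
  nodes; graphs export to Cytoscape-importable GraphML.
- **Follicle morphometry**: stage I/II/III classification from diameter
  (nominal 50/70/100 μm; midpoint boundaries 60 and 85 μm), and per-section
  occupancy — total and stage-III follicles per mm², stage-III proportion,
  and between-genotype fold ratios.
- **ΔΔCt relative quantification** with a reference gene (e.g. GAPDH) and a
  calibrator sample: RQ = 2^(−ΔΔCt), replicate spread propagated to a
  standard error.

## Worked example

Follicle morphometry from section counts and areas (wildtype: 354 follicles
of which 35 stage III over 5.52 mm²; mutant: 476 / 7 over 4.30 mm²):

```r
library(ovatome)
wt  <- summarize_section(data.frame(stage = rep(c("I","II","III"), c(160,159,35))),
                         area_mm2 = 5.52)
mut <- summarize_section(data.frame(stage = rep(c("I","II","III"), c(300,169,7))),
                         area_mm2 = 4.30)
wt
#> Ovary section summary
#>   area:               5.52 mm2
#>   follicles:          354 (I: 160, II: 159, III: 35)
#>   total density:      64.1 follicles/mm2
#>   stage III density:  6.34 follicles/mm2
#>   stage III fraction: 9.9%
compare_sections(mut, wt)
#>         quantity          a         b     ratio ratio_1dp
#> 1  density_total 110.697674 64.130435 1.7261332       1.7
#> 2 density_stage3   1.627907  6.340580 0.2567442       0.3
#> 3    prop_stage3   1.470588  9.887006 0.1487395       0.1
```

The mutant ovary packs ~1.7× more follicles per mm² but only a quarter of
the stage-III density: early follicles accumulate while post-vitellogenic
ones are depleted.

GO enrichment on a synthetic world with six planted terms (A = the
mutant-specific gene set; positive scores are mutant-enriched):

```r
gw  <- sim_go_world(sim_config(seed = 3))
res <- enrich_compare(gw$dag, gw$ann, gw$set_a, gw$set_b)
res
#> GO enrichment over 60 terms (8 displayed)
#>     term_id    name level     score node_size
#>  GO:0000026 term 26     4  2.584963        48
#>  GO:0000027 term 27     4  2.584963        48
#>  GO:0000031 term 31     3 -2.584963        48
#>  ...
```

The six planted terms surface at |score| = log2(0.36/0.06) ≈ 2.58 with the
planted sign; masked terms stay in the exported graph as zero-sized nodes.

Relative expression by ΔΔCt (target Ct 25 vs 24, reference flat at 20):

```r
ct <- data.frame(sample = rep(c("mutant","wildtype"), each = 2),
                 gene = rep(c("ces1","GAPDH"), 2), ct = c(25, 20, 24, 20))
fold_report(delta_delta_ct(ct, "ces1"))
#>   gene  rq fold direction          label
#> 1 ces1 0.5    2     lower 2.0-fold lower
```

An end-to-end demo over all-synthetic inputs (FASTQ → dedup → FPKM calls →
GO graphs → morphometry → ΔΔCt) with a deterministic run manifest:

```r
run_demo(seed = 42, out_dir = "demo")   # or: inst/bin/ovatome demo --seed 42 --out demo
```

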