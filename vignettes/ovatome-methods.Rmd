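---
title: "Methods: the rules behind the ovatome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the rules behind the ovatome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovatome)
```

`ovatome` re-implements, as a tested and reusable pipeline, the
computational procedures used to compare the ovary of a neuropeptide-gene
knockout ascidian with a wildtype one: read cleaning, threshold-based
expression calls, a comparative GO enrichment score, follicle morphometry
and ΔΔCt quantification. This vignette explains each rule, its assumptions,
the tunable parameters, and the design decisions taken where the procedure
left a genuine choice open.

## PCR-duplicate removal

Two single-end reads are PCR duplicates iff

1. their first 10 bases are identical (case-insensitive; an `N` never
   matches, not even another `N`), and
2. the entire reads exhibit strictly more than 90% similarity.

For equal-length reads — the common case in a fixed-cycle single-end
library — similarity is positional identity: matching non-`N` positions
divided by the read length. For unequal lengths (e.g. after trimming) a
global alignment (match = 1, mismatch/gap = 0) is used and similarity is
matches over alignment length including end gaps. Both readings are
symmetric; the equal-length one is the cheapest faithful interpretation of
"whole-read similarity" for a fixed-length library.

Boundary semantics matter and are strict on both sides: a similarity of
exactly 0.90 is **not** a duplicate, and a single mismatch anywhere in the
10-base prefix vetoes the pair regardless of a 100/101 overall identity.
`deduplicate_reads()` buckets reads by their exact 10-mer prefix (the
prefix condition makes buckets exact, not heuristic), applies the pair rule
within buckets, closes clusters by single linkage, and keeps the first-seen
read of each cluster. The suite checks this implementation against a
brute-force all-pairs oracle applying the two conditions verbatim.

Duplicate removal runs on raw, untrimmed reads; adapter trimming and
quality filtering come after. The original protocol does not state this
ordering, nor its adapter/quality criteria, so `filter_reads()` exposes
them as configuration (3' exact adapter-prefix match with minimum overlap
5; mean Phred ≥ 20) and every pipeline run logs the thresholds actually
applied. No reverse-complement logic is used: the rule as stated carries no
strand component for a single-end, orientation-fixed library.

## Expression calls

`compute_fpkm()` is plain FPKM, `count × 10⁹ / (length_nt ×
total_mapped)`, on annotated transcript lengths — no effective-length
correction. The library size defaults to the column sum of the supplied
count table; whether the original "total mapped reads" counted all mapped
reads or only those on the gene set is unstated, and the column sum is the
reproducible choice given only a count table.

All thresholds are strict inequalities:

- *expressed*: FPKM > 5 (so FPKM = 5 exactly is not expressed);
- *up in mutant*: expressed in at least one condition and
  FPKM_mut/FPKM_wt > 2;
- *up in wildtype*: ratio < 0.5;
- otherwise *unchanged*; genes expressed in neither condition are
  *not expressed* and excluded from the ratio universe.

The comparison universe is genes expressed in **at least one** condition:
the filtering step precedes the ratio but the combination rule is not
spelled out, and the one-side reading keeps on/off genes — the
biologically interesting extreme — in the comparison, with the zero
denominator handled as the limiting ratio (+∞, hence up in the non-zero
condition). With the threshold pair (2, 0.5) the two directions are
mutually exclusive by construction.

## Comparative GO enrichment

The ontology is the 'is_a' DAG only: `parse_obo()` keeps `is_a` edges from
OBO 1.2, drops obsolete terms, ignores other relationship types, and
refuses cycles. *GO level* is the shortest is_a path from the namespace
root — the cheapest well-defined reading of the level notion used by the
display rule.

Annotations are closed upward by the true-path rule before frequencies are
computed (`propagate_annotations()`); whether the original analysis
propagated is unstated, so closure is the default and can be disabled
(`propagate = FALSE`). The per-term score between the two
condition-specific gene sets A (mutant) and B (wildtype) is

```
score(t) = log2( (f_A(t) + c) / (f_B(t) + c) )
```

where `f_X(t)` is the fraction of set X's genes carrying term t and `c` is
a fixed pseudo-count, default 0.01. The exact original functional form is
not recoverable from its description (only the frequency symbols, the fixed
pseudo-count, a signed ±1.2 display band and a red/blue diverging rendering
are documented); the signed log2 frequency ratio is the simplest form
consistent with all four, and the implementation computes it as a
difference of logs so swapping the sets negates the score exactly. The
log base is a parameter, so an alternative convention can be swapped
without touching callers.

The display rule: a term is drawn iff its level is ≥ 2 **and** its score
lies outside the open band (−1.2, 1.2) — band endpoints are displayed.
Masked terms remain in the exported GraphML as zero-sized nodes rather than
being removed, preserving the graph topology for Cytoscape; displayed nodes
carry the number of annotated genes (A ∪ B) as `node_size` and the signed
score for the colour scale.

## Follicle morphometry

Stages I–III follicles have nominal diameters of approximately 50, 70 and
100 μm; stage IV follicles are ovulated and absent from sections. Since
only the nominal sizes are given, the classifier uses their midpoints —
60 μm between I/II and 85 μm between II/III — half-open upward (60 μm is
stage II, 85 μm stage III). `summarize_section()` reports counts, total and
stage-III densities per mm², and the stage-III percentage, with report
values rounded half-up to the precision conventionally printed (two
decimals for the stage-III density, one elsewhere); raw values are always
retained. One known discrepancy is documented rather than matched: from the
published mutant counts, 7/476 = 1.47%, which rounds to 1.5%, while the
source table prints 1.4% — whether that value was truncated or derived from
different raw numbers is unknowable. The package standardizes on
"follicles/mm²" where the source mixes "oocytes/mm²" and "follicles/mm²".

## ΔΔCt

Classic ΔΔCt with amplification efficiency fixed at 2: replicate Ct values
are averaged per (sample, gene), ΔCt subtracts the reference gene within
each sample, ΔΔCt subtracts the calibrator sample, and RQ = 2^(−ΔΔCt).
Replicate standard deviations propagate to a standard error on ΔΔCt as the
root sum of the four cell-mean variances. `fold_report()` restates RQ as a
fold ≥ 1 plus a direction, with the reciprocal exact. No significance test
is attached: the source protocol reports one without naming it, so none is
guessed.

## The synthetic-data generators

The generators define the conditions under which the pipeline is exercised;
they are first-class, tested code, not fixtures.

**Reads** (`sim_read_set()`): 101-nt single-end reads (the protocol also
mentions paired-end reads in one place; the single-end reading is used and
the contradiction simply noted), random A/C/G/T, Phred 30–40. Each unique
read becomes a duplicated cluster seed with probability `rate²`, and
flagged seeds draw `1 + Poisson(1/rate − 1)` extra copies. This
construction makes two things hold simultaneously in expectation: the total
read count is `n_unique × (1 + rate)` and the fraction of reads lying in
clusters of size ≥ 2 equals `rate`. Copies keep the 10-base prefix exact
and mutate at most ⌊(L−1)/10⌋ later positions, staying strictly above 90%
identity; every duplicated cluster also plants one *near-miss* read
violating exactly one condition (alternating: one mutated prefix base, or
⌈L/10⌉ mutations after the prefix, which lands at or below the 0.90
boundary), giving the deduplication tests discriminating cases on both
sides of each rule. Sequencing-error profiles and adapter chemistry are not
modelled.

**Expression** (`sim_expression_pair()`): true FPKM is log-normal
(meanlog log 8, sdlog 1.2) with 10% of genes drawn uniformly in [3, 8] so
the FPKM > 5 call is exercised on both sides; planted genes take a base
level log-uniform in [1.5, 50] times `planted_fold` on the high side, so
the up-regulated side is clearly expressed. Fragment counts are negative
binomial — the standard overdispersed model for RNA-seq counts — with mean
`fpkm × length_kb × total_mapped/10⁶` and dispersion 0.02, at a library
size of 2×10⁷ fragments per condition, echoing the tens-of-millions scale
of real single-lane libraries while keeping runtimes in seconds.

**GO world** (`sim_go_world()`): a random single-rooted tree of 60 terms
with depth capped at 4, where 15% of terms acquire a second, strictly
shallower parent (keeping the graph acyclic); background annotations at
rate 0.1 per term; planted terms are chosen among *leaf* terms at level
≥ 2 — leaves have no descendants, so upward closure of background
annotations cannot dilute the planted frequencies — and are annotated
deterministically at frequency 0.35 in the enriched set versus 0.05 in the
other, giving a planted score of log2(0.36/0.06) ≈ 2.58, comfortably
outside the ±1.2 band. Planted terms are pairwise unrelated on the DAG so
no planted term contaminates another through closure.

**Sections** (`sim_ovary_section()`): diameters are normal around the
50/70/100 μm stage means with cv 0.05 (at which the default classifier
recovers > 99% of truth stages); a cv large enough to push expected
misassignment above 20% triggers a warning, not an error. Default stage
counts (wildtype-like: 160/159/35 over 5.52 mm²) reproduce the published
totals of 354 follicles with 35 stage III; the I/II split is not published
and is a package choice.

**Ct tables** (`sim_ct_table()`): reference near Ct 20, targets near Ct 24,
true ΔΔCt shifts injected into the test sample, replicate noise normal with
SD 0.2 cycles over 3 replicates. The default true folds (≈1.5 lower, ≈1.6
lower, ≈2.1 higher) mirror the magnitude range typical of validation qPCR.

What passing these simulations shows — and what it does not: the pipeline
recovers *planted* signals whose generative assumptions it shares
(independent NB counts, uniform annotation background, normal diameter and
Ct noise). Real libraries add positional error profiles, mapping ambiguity,
annotation bias and inter-animal variability that the generators do not
emulate; dataset-scale figures from real sequencing runs (tens of millions
of reads, >18,000 expressed genes) require the external raw data and
databases and are deliberately out of scope for the test suite.

## Numerical and engineering choices

- All generators draw from per-generator substreams derived from one master
  seed, so any stage can be regenerated independently and bit-identically;
  the pipeline manifest records the seed and the MD5 digest of every output,
  and re-running with the same config reproduces identical digests.
- Report rounding is half-up (`round_half_up()`), matching how bench tables
  are conventionally printed, and raw values are always kept alongside.
- Zero denominators: expression ratios use the limiting-value rule above;
  section fold ratios report NA ("undefined") rather than erroring; an
  empty section has zero densities and an explicitly flagged undefined
  stage-III proportion.
- Invalid inputs raise classed conditions (`ovatome_invalid_input`,
  `ovatome_invalid_config`, `ovatome_format_error`) so callers and the CLI
  can distinguish user error from bugs; config validation reports all
  violations at once.
- Problem sizes in the test suite (read sets up to ~500 reads, 500-gene
  tables, 60-term ontologies, 25–50 seeded fixtures, 100–200 ΔΔCt
  simulations) are chosen so the full suite and the acceptance script each
  run in well under a minute on one CPU while keeping every Monte-Carlo
  check's standard error far from its acceptance margin.

## Known limitations

- The enrichment score's exact original form (log base, where the
  pseudo-count enters) is reconstructed, not transcribed; the pseudo-count
  magnitude (0.01) is a package default, exposed as a parameter.
- The duplicate rule is sequence-only: coordinate-based duplicate marking,
  UMIs and paired-end logic are out of scope.
- No statistical differential-expression testing (no dispersion estimation,
  no p-values) — the threshold rules are the method under study; for
  replicated designs use a dedicated DE framework instead.
- `length_nt` is the annotated transcript length; isoform-level
  quantification is not attempted.
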