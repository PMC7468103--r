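# mdtnet

Cancer cells frequently switch which transcript isoform of a gene is the
most highly expressed one. When the newly dominant isoform encodes a
protein that has lost the domains through which it binds its partners, the
switch silently removes protein–protein interactions from the cell's
network. `mdtnet` is an R toolkit for detecting such **cancer-specific
most-dominant-transcript (cMDT) switches** from bulk transcript-level TPM
matrices and for scoring their network impact. It is aimed at computational
cancer biologists who have transcript quantifications for a tumor cohort
and a matched normal cohort, plus standard annotation resources (a scored
protein interaction edge list, per-protein domain annotations, a physical
domain–domain interaction table, and per-isoform protein sequences).

## Method

**Isoform-specific interaction network.** Functional edges with combined
score ≥ 0.9 are kept. An edge is *physical* when its two proteins carry
domain instances whose family pair occurs in the physical domain–domain
interaction table. For every alternative isoform, each physical interaction
of its gene's canonical protein *persists* if the exact amino-acid sequence
of at least one supporting domain instance occurs verbatim in the isoform,
and is *lost* otherwise.

**MDT and cMDT.** In sample *s*, the most dominant transcript (MDT) of a
gene is the top-expressed transcript *t* with

```
TPM(t, s) ≥ 2 · TPM(t₂, s)   and   TPM(t, s) ≥ floor
```

where *t₂* is the second-ranked transcript and the floor is 2 TPM in tumor
samples and 0.2 TPM in normals. With relative expression
`r(t, s) = TPM(t, s) / Σ_g TPM(·, s)` (the within-gene share), a tumor MDT
is *cancer-specific* when (1) its transcript is never an MDT in the normal
compendium, (2) its gene has an MDT in ≥ 50 % of matched normals, (3) the
exact two-sided sign test of its relative expression against the matched
normal cohort gives Benjamini–Hochberg q < 0.01 within the cancer type, and
(4) its relative expression exceeds the normal-cohort median.

**Impact scoring.** Lost interactions are attributed per sample and cMDT;
each protein gets a network density score
`NDS(a) = deg(a) + Σ_{s=1..3} Σ_b 2^{-s} · deg(b) · score(b, parent(b))`
over its breadth-first neighbourhood, mapped to a relative rank in [0, 1];
distances to cancer-census genes come from a multi-source BFS with a
seeded expressed-protein control (Wilcoxon rank-sum); per-sample disrupted
subnetworks (connected components) are tested for gene-set enrichment with
a hypergeometric test against the isoform-network universe. A
Wilcoxon-based cis-mutation association test and a Spearman load
correlation complete the pipeline.

## Worked example

The package ships a seeded generator that emits a complete toy study with
known ground truth (planted switches, deleted domains, cis mutations):

```r
library(mdtnet)
w <- generate_world(synthetic_config(seed = 7), dir = "world7")
res <- run_pipeline(file.path("world7", "config.yaml"), "out7")
t(res$summary)
```

```
cancer_type                   "ToyCancer"
n_tumor_samples               "10"
n_normal_samples              "20"
n_cmdt_calls                  "98"
n_unique_cmdt                 "10"
median_cmdt_per_sample        "10"
total_disrupted_ppi           "117"
mean_disrupted_ppi_per_sample "11.7"
```

Ten genes carry a planted switch; 98 of the 100 expected (sample ×
transcript) cMDT calls are recovered, each tumor sample carries a median of
10 cMDT, and the 117 lost interactions attributed across the 10-sample
cohort give a mean of 11.7 disrupted interactions per sample. The lost-edge
set equals the generator's truth table exactly, and all planted
cis-mutation associations are significant at q ≤ 0.01:

```r
st <- res$network$statuses
setequal(paste(st$isoform_id, st$partner_protein)[st$status == "lost"],
         paste(w$truth$lost_edges$isoform_id,
               w$truth$lost_edges$partner_protein))
#> TRUE
```

A thin CLI wrapper is available at `inst/cli/mdtnet.R`
(`simulate`, `run-all`).

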