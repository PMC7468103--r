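---
title: "Detecting cancer-specific dominant-transcript switches and their network impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cancer-specific dominant-transcript switches and their network impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most genes express one predominant ("most dominant") transcript isoform in
normal tissue. Disturbed splicing regulation in tumors can hand dominance
to an alternative isoform whose protein lacks interaction domains, so the
switch removes edges from the protein–protein interaction network even
though gene-level expression looks unchanged. `mdtnet` detects these
switches from transcript-level TPM matrices and quantifies the network
damage. This vignette documents the model, its assumptions, the tunable
parameters, and the numerical choices the implementation makes.

## Isoform-specific interaction network

Functional interaction edges arrive as a scored edge list. Two score
dialects are accepted (integers 0–999 or reals in [0, 1]); any score above
1 switches the file to the integer dialect and scores are divided by 1000
once at load. Only high-confidence edges (combined score ≥ `min_score`,
default 0.9) enter the network. Before anything else, protein sequences
backing the network are cross-checked against the annotation proteome and
any protein whose sequence is not byte-identical in both sources is
discarded — sequence coordinates from one source must not be applied to a
different sequence from the other.

An edge is *physical* when the two proteins carry domain instances whose
family pair occurs in the physical domain–domain interaction table, in
either orientation; all supporting instance pairs are recorded. For every
alternative isoform we then ask, per physical edge of its gene's canonical
protein: does the exact amino-acid sequence of at least one supporting
domain instance (on the isoform's side of the edge) occur verbatim in the
isoform? If yes the interaction persists, otherwise it is lost.

Three design points were genuinely open and are resolved as follows:

* **Any-instance persistence.** An interaction supported by several domain
  instances persists when *any* one of them survives; the matched instances
  are recorded for auditing. Requiring all instances would conflate partial
  interface erosion with complete loss.
* **Only the isoform's own side is tested**; the partner is assumed
  canonical. Per-isoform status must be independent of what the partner
  expresses in any particular sample — joint effects are a per-sample
  question answered downstream.
* **Exact substring matching, no alignment.** A single substituted residue
  inside a domain span counts as loss. This is deliberately conservative
  and fast; a mismatch-tolerant mode is out of scope. Domain annotations
  are taken as given; no de-novo domain scanning is performed.

## MDT and cancer-specific MDT

Per gene and sample, transcripts are ranked by TPM; missing values are
treated as 0 at load. The top transcript is the MDT when its TPM is at
least `dominance_fold` (default 2) times the second-ranked TPM and at least
the role-specific floor: `min_tpm_tumor` = 2 TPM (the background ceiling of
transcripts, such as olfactory receptors, that should not be expressed in
the profiled tissue) and `min_tpm_normal` = 0.2 TPM, ten-fold lower so that
weak but consistent normal dominance still blocks a spurious
cancer-specific call. Exactly tied top TPMs fail the fold rule, so ties
never produce an MDT.

*Relative expression* of transcript *t* in sample *s* is TPM(t, s) divided
by the summed TPM of all transcripts of *t*'s gene in *s*. It is the only
definition bounded in [0, 1] that supports comparing a sample's value with
a per-transcript cohort median; it is undefined when the gene is silent,
and undefined values are excluded everywhere.

A tumor MDT becomes a cMDT when all four criteria hold:

1. its transcript is never an MDT in any sample of the normal compendium
   (default scope; a matched-cohort-only scope is available);
2. its gene has an MDT — of any transcript identity — in at least 50 % of
   matched normal samples, i.e. the gene shows stable dominance behaviour
   that the tumor sample deviates from;
3. the sign test on its relative expression against the matched normals is
   significant after BH adjustment (q < `q_cmdt`, default 0.01), with one
   BH family per cancer type covering **all** tested tumor MDT of that
   type;
4. its relative expression exceeds the median of the transcript's defined
   relative expressions over all matched normal samples (not only those
   where the gene had an MDT — using all defined values keeps the median
   well-defined for genes with unstable dominance).

The sign test counts matched normal samples with strictly lower and
strictly higher relative expression; exact ties drop out of both counts,
standard sign-test practice. The two-sided p-value is the exact
minimum-likelihood binomial probability at p = 0.5 (identical to
`binom.test`); a doubled-tail variant is available behind a flag. Zero
informative normals give p = 1.

## Impact scoring

**Disruption mapping** joins cMDT calls to the status table: every lost
physical edge of the called isoform becomes one record per sample, and the
per-call percentage lost is reported; genes without any network edge are
flagged as having no interaction data rather than silently scored 0.

**Network density score.** For protein *a*,

$$\mathrm{NDS}(a) = \deg(a) + \sum_{s=1}^{3} \sum_{b \in L_s}
\frac{1}{2^{s}}\,\deg(b)\,\mathrm{score}(b, \mathrm{parent}(b)),$$

where \(L_s\) is the set of nodes first reached at breadth-first depth
*s*. Each node contributes once, at its shortest depth — the defining sum
is ambiguous between per-node and per-path accounting, and the visit-once
reading is the only one that is finite on cyclic graphs and matches "an
interactor being *s* nodes apart". When several parents at depth *s − 1*
exist, the lexicographically smallest parent id supplies the edge score,
making the score deterministic. Scores enter on the 0–1 scale. Raw NDS
values are mapped to relative ranks: ascending order, rank position
divided by *N* − 1, ties sharing the mean of their positions.

**Census proximity** is a multi-source BFS from the census proteins
present in the graph; the proximity graph uses all high-confidence
functional edges, not only physical ones. The random control draws, with a
seeded generator, proteins that are expressed (≥ 2 TPM in at least one
cohort sample) and whose gene has ≥ 2 annotated isoforms — the same
eligibility the query set has by construction — and compares distance
distributions with a two-sided Wilcoxon rank-sum test.

**Enrichment.** The disrupted edges of one sample form a graph whose
connected components are the disrupted subnetworks — the minimal structure
in which interactions "overlap in one or both partners". Each component is
tested per gene set with a hypergeometric upper tail against the proteins
of the isoform-specific network as universe, BH-adjusted across terms
within the component; only the most significant term is kept (ties broken
by smallest term id). Components with no protein in the universe are
skipped with a message.

## Cis-mutation association

Within one cancer type, a sample is *Mutated* for a transcript when its
gene carries at least one variant in a cis region (promoter core, promoter
domain, 5′UTR, coding sequence, splice site, 3′UTR — the full six-class
list is used; all six appear in the region annotation model). Runs of
adjacent same-sample SNVs are merged into MNVs before overlap; indels
never merge; a variant overlapping several functional regions yields one
record per region. Transcripts with ≥ `min_mutated` (default 5) mutated
samples, a non-empty wildtype group, expression in both groups and
non-zero variance are tested with a two-sided Wilcoxon rank-sum test
(exact when both groups have ≤ 8 tie-free values, normal approximation
with continuity and tie correction otherwise), BH-adjusted within the
cancer type at `q_assoc` = 0.01. Per-sample cMDT load versus variant load
uses Spearman correlation with average ranks.

## The synthetic world

The generator emits every input the pipeline reads, with truth tables for
every planted signal, under one seed. Its defaults are the package's
standard study conditions: 50 genes with 2–3 isoforms, 10 tumor versus 20
matched normal samples, 20 % of genes carrying a planted switch, a
relative-expression gap of 0.6 between cohorts, lognormal abundance noise
with σ = 0.25, edge density 0.04 between canonical proteins, domains of
8–15 residues, and 3 genes with a planted 10× cis-mutation expression
shift in 6 tumor samples. The 10 vs 20 cohort keeps the whole test suite
and the acceptance script within interactive runtimes while leaving the
sign test ample resolution (smallest attainable p with 20 informative
normals ≈ 2 × 10⁻⁶).

Construction guarantees make truth exact rather than probabilistic:

* every physical edge is supported by exactly one fresh domain-family pair,
  and each alternative isoform is the canonical sequence with whole-domain
  (or inert-domain) deletions, so the lost-edge set is known by
  construction; the generator verifies that a deleted domain's sequence
  does not recur elsewhere in the isoform and aborts otherwise;
* domain sequences are unique random draws over the amino-acid alphabet,
  so substring tests cannot collide accidentally;
* planted switch genes give the alternative transcript a (1 + gap)/2 = 0.8
  within-gene share in tumors and (1 − gap)/2 = 0.2 in normals, with the
  canonical transcript taking 90 % of the remainder; TPM values are the
  gene's lognormal base level times these shares times lognormal noise,
  renormalized per sample to TPM semantics (planted mutation fold changes
  are applied before renormalization);
* a config whose gap cannot clear the two-fold dominance rule
  (gap ≤ 1/3) or whose noise exceeds the gap is rejected before emission.

What the generator does **not** emulate: read-level quantification error,
correlated splicing programs across genes, annotation incompleteness,
partial domain truncation, tumor purity and subclonality. Passing the
recovery tests therefore demonstrates correctness of the statistical
machinery under its stated model, not performance on real cohorts.

## Numerical choices and limitations

* BH q-values are computed per cancer type; cohorts are never pooled.
* Degenerate inputs are explicit: silent genes give undefined relative
  expression, empty normal cohorts and empty census sets are errors,
  transcripts without protein ids simply have no network statuses.
* Edge lists are canonicalized (smaller id first, duplicates collapsed to
  the maximum score), so results are independent of input row order; the
  pipeline is a pure function of config + seed and reruns are
  byte-identical.
* The per-cohort disruption summary (total, cohort size, mean per sample)
  is exact arithmetic; `inst/extdata/disrupted_ppi_cohorts.tsv` ships one
  published-scale example table for it.
* Known limitations: persistence is sequence-identity based and blind to
  conformational effects; the NDS depth-3 horizon and halving decay are
  conventions, not fitted; enrichment treats components independently even
  when produced by the same cMDT.
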