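---
title: "Splicing-aware interactome rewiring: models, parameters and design choices"
author: "spliceRewire developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-aware interactome rewiring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceRewire)
library(data.table)
```

# The model

## Joint PPI/DDI networks

A protein–protein interaction (PPI) network alone cannot say *why* two
proteins interact, and therefore cannot say whether an isoform that lost a
domain still interacts. `spliceRewire` represents the interactome as a set of
*annotated edges*: each unordered protein pair carries a list of evidence
items that could mediate the contact —

* `ddi_experimental`: a domain pair from an experimentally validated
  domain–domain interaction (DDI) template list, attached to edge (p, q)
  whenever one domain occurs on p and the other on q;
* `ddi_predicted`: the same attachment rule for predicted DDIs, gated by a
  gold/silver/bronze confidence tier filter;
* `dmi`: a domain on one endpoint binding a short linear motif (a protein
  coordinate span) on the other;
* `residue`: interface residue positions on both endpoints, from co-resolved
  structures.

Edges with no evidence are kept separately as *unannotated*; they are
invisible to the enrichment test (below). Evidence orientation is preserved
(which domain sits on which endpoint), homodimers attach each unordered
domain pair once, and a predicted DDI identical to an experimental template
is stored once, as experimental — predictions are *additional* annotation,
never a duplicate.

## DDI prediction from PPI co-occurrence

The prediction follows the co-occurrence idea: a domain pair that keeps
showing up on opposite ends of PPIs, across several independent interaction
databases, is likely a real DDI. Per resource $r$:

$$s_r(a,b) = \frac{n_r(a,b)}{\sqrt{m_r(a)\, m_r(b)}}$$

with $n_r(a,b)$ the number of PPIs carrying $a$ and $b$ on opposite
endpoints (each PPI contributing at most once per pair) and $m_r(d)$ the
number of PPIs with $d$ on at least one endpoint. This cosine normalization
is bounded in $[0,1]$, symmetric, and penalizes promiscuous domains. The
combined score is a reliability-weighted mean over **all** configured
resources, $S = \sum_r w_r s_r / \sum_r w_r$, so that a pair supported by
several resources outranks one supported by a single resource at equal
per-resource score; a resource that never saw the pair contributes 0.

The weights are integers searched at random (default 10 000 draws from
$[1,100]^{|R|}$, one seeded generator, draws in sorted-resource-name order).
For every draw the score threshold is *calibrated*: candidate thresholds are
the distinct observed scores, and the returned threshold maximizes F1
against a ground-truth DDI list, ties broken toward the smaller threshold
(more recall at equal F1). Tiers are then: **gold** — above threshold with
support from ≥ 2 resources; **silver** — above threshold, single resource;
**bronze** — within a factor 2 below threshold; these operationalize tier
names that the upstream literature uses without a formal definition.

By default precision/recall are computed over the scored candidate universe:
a truth pair whose domains never co-occur in any resource cannot be found by
any threshold and is not counted as a false negative. The alternative
convention (count all truth pairs) is available via
`count_unscored_truth = TRUE`.

## Coordinate lifting and affected features

All internal genomic coordinates are 1-based inclusive (GTF convention);
rMATS 0-based starts and BED starts get +1 on read. Amino acid $i$ covers
coding nucleotides $3i-2 \ldots 3i$ counted 5'→3' along the spliced CDS;
`protein_to_genomic()` returns the footprint as maximal genomic runs in
ascending order, spanning splice junctions where codons do.
`genomic_to_protein()` is its inverse: the minimal amino-acid interval
covering the CDS intersection, so a single-nucleotide overlap with a codon
maps to that codon. The round trip is the identity on valid inputs and every
footprint has exactly $3 \times$ the amino-acid span in nucleotides — both
are enforced by property tests over randomized transcript models on both
strands.

A feature is *affected* by an exon-skipping event iff its genomic footprint
intersects the event's exon by **≥ 1 nucleotide** on a transcript of the
event's gene. There is deliberately no reading-frame or in-frame check: the
input contract is coordinate overlap, nothing more. Events map through every
transcript of the gene whose exon set intersects the event, not only a
canonical transcript. Transcripts without an in-frame CDS are kept for exon
overlap but excluded from protein-coordinate lifting (with a warning).

An evidence item is *lost* iff it references an affected domain on the
corresponding endpoint (DDI kinds), an affected motif span (DMI), or at
least one affected residue position (residue). An edge is *rewired* iff it
loses at least one item; the sign of delta-PSI is reported but does not gate
the derivation — increased inclusion and increased skipping are both
treated as rewiring, since either changes the isoform population.

## Edge-level enrichment

With $N$ annotated edges, $K$ incident to a pathway, $n$ rewired and $k$
rewired-and-incident, the raw p-value is the inclusive upper tail
$P(X \ge k)$ of the hypergeometric distribution, adjusted by
Benjamini–Hochberg across all testable pathways; pathways with $K = 0$ are
excluded *before* correction and reported as untestable. Results are ranked
by $-\log_{10}(p_\mathrm{adj})$ (the ranking score is a monotone transform
of adjusted significance; the upstream tools sort by an equivalent score
without defining it). The universe is the annotated edges only: unannotated
PPIs can never be detected as rewired, so including them would only deflate
p-values.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `dpsi_min` | 0.05 | PSI difference | the threshold used for rMATS case analyses in the upstream literature; comparisons are inclusive |
| `p_max` | 0.05 | probability | ditto; for Whippet/MAJIQ input the "significance" is 1 − posterior probability so one threshold semantics covers all dialects (a documented convention, not the tools' own) |
| `tier_filter` | none | — | predicted DDIs are opt-in; enlarging the filter can only add evidence (monotonicity is test-enforced) |
| `n_iter` | 10 000 | draws | weight-search budget |
| weight range | [1, 100] | integer | the searched reliability weights |
| cluster cutoff | 0.05 | adjusted p | node inclusion in the pathway-cluster graph; links are Jaccard > 0 over contributing genes |

# The synthetic data generator

`simulate_interactome()` emits a complete, internally consistent bundle *as
files* (GTF, TSVs, GMT), so the reader and CLI paths are exercised end to
end. Genes get 5 exons with lengths that are multiples of 3 (so every
exon-skipping isoform stays in frame, satisfying the generator's own
invariant that emitted CDSs are translatable), one protein and exactly one
domain occurrence per gene, and a planted truth DDI set from which a
configurable fraction of PPI edges is generated; each resource observes an
independent subsample. Junction-spanning codons are exercised by the test
helpers' randomized transcript models, whose exon lengths are *not*
multiples of 3.

Two interaction models are provided, because two different benchmarks need
two different stated worlds:

* **`shared_domains`** — domain types recur across proteins, so
  co-occurrence counts accumulate over edges. Used for the DDI-prediction
  benchmark. At noise 0 every candidate pair is a truth pair by
  construction (one domain per protein), so calibrated F1 = 1 exactly; at
  noise 0.2 false candidates appear with low co-occurrence scores. The
  benchmark world uses 60 genes / 12 domain types / 240 requested edges:
  at the small default (20 genes / 15 domains) most domain types have a
  single carrier and co-occurrence carries no signal, which would make the
  benchmark vacuous rather than hard.
* **`matched_pairs`** — every protein carries a private domain type and the
  truth edges form a perfect matching, so one splicing event disrupts
  exactly one annotated edge. Used for the enrichment benchmark: with
  enrichment factor 1, `plant_splice_events()` samples annotated edges
  uniformly without replacement, which *is* the null of the edge-level
  hypergeometric test, so the empirical type-I rate can be checked against
  nominal.

`plant_splice_events()` samples edges with weight equal to the enrichment
factor for target-pathway-incident edges (weight 1 otherwise), places a
significant event (|ΔPSI| = 0.2, p = 5·10⁻⁴ — comfortably past the default
thresholds) on a footprint segment of a supporting domain, and adds an equal
number of sub-threshold decoys (|ΔPSI| = 0.02, p = 0.5) on random exons.

When the requested truth-edge count exceeds the number of feasible
truth-generated pairs, the bundle is scaled down preserving the requested
truth/noise ratio rather than silently padding with noise.

**What a green test does and does not establish.** The generator emulates
coordinate consistency, multi-resource sampling, planted co-occurrence
signal and planted pathway signal. It does not emulate: real degree
distributions (hubs), multi-domain proteins in the generated bundles,
correlated resource errors, partial exon overlap of domains, isoform-specific
domain annotation, or identifier mapping noise. A green planted-signal test
establishes that the machinery recovers a signal it is pointed at under the
stated noise — not that real-data signals are of this kind or strength.

# Numerical and design choices

* **Enrichment-benchmark sizing.** The null-calibration world (220 genes,
  110 annotated edges, pathways of 40 genes, 15 events) was chosen in a
  design-phase pilot so that the discrete hypergeometric's achievable alpha
  lies near the nominal 0.05. With much smaller pathways the exact test is
  so conservative that the empirical type-I rate falls *below* the
  two-sided 99% binomial band around 0.05 — a calibration check can fail
  for being conservative, which is a property of discreteness, not an
  error. "The target attains the smallest adjusted p" is evaluated
  tie-tolerantly because BH step-up routinely flattens neighbouring
  adjusted values into exact ties.
* **Threshold boundaries.** All event-filter comparisons are inclusive
  (≥ `dpsi_min`, ≤ `p_max`); events exactly at threshold are kept.
* **Calibration ties** break toward the smallest threshold.
* **Degenerate inputs.** Empty PPI files read as empty collections with a
  warning; an all-false calibration errors as uncalibratable; pathways with
  K = 0 are untestable rather than p = 1; an event whose gene has no
  transcript model is counted as unmapped, not an error.
* **Determinism.** Every random operation takes an explicit seed; one
  seeded generator drives the weight search; the run metadata contains no
  timestamps, so identical configurations produce byte-identical outputs.
* **DMI loss rule.** A DMI item is lost through its motif span. The domain
  side is stored and participates in isoform views, but an affected domain
  on the domain side does not by itself mark the DMI lost — the motif is
  the splice-sensitive element being modelled.
* **Identifier policy.** All identifiers are opaque strings; no online
  lookups or symbol normalization. Inputs must arrive pre-mapped.

# Known limitations

* Only exon-skipping events are modelled; intron retention and alternative
  5'/3' splice sites are out of scope by input contract.
* Gain-of-inclusion events are treated symmetrically with skipping
  ("rewiring"), not as interaction gains.
* The DDI predictor reimplements the co-occurrence family of methods, not
  any published model's exact per-source probabilities; calibrated
  thresholds are meaningful only relative to the supplied ground truth.
* Whether an edge annotated *only* by DMI/residue evidence should count as
  "augmented" is convention-dependent; this package counts any evidence
  kind as annotation and reports per-kind counts so either convention can
  be recovered downstream.
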