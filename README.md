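# spliceRewire

Splicing-aware interactome rewiring analysis in R: joint PPI/DDI network
construction, domain–domain interaction (DDI) prediction from multi-resource
PPI co-occurrence, exon-to-domain genomic coordinate mapping, and edge-level
hypergeometric pathway enrichment.

## The problem

Alternative splicing changes the domain composition of proteins, and the
domain composition determines which partners a protein can bind. A
differential exon-skipping event can therefore *rewire* the protein–protein
interaction (PPI) network without changing gene-level expression at all.
Standard gene-set enrichment is blind to this: it asks which genes changed,
not which *interactions* were disrupted.

`spliceRewire` is for computational biologists who have a table of
differential exon-skipping events (rMATS, Whippet, MAJIQ, or a plain
BED-like list) and want to know which pathways lose interactions because of
them. The package:

1. builds a **joint PPI/DDI network**: each PPI edge is annotated with the
   domain-level evidence that can mediate it — experimental DDI templates,
   predicted DDIs (with gold/silver/bronze confidence tiers), domain–motif
   interactions (DMIs), and residue-level evidence;
2. **predicts DDIs** from how often domain types co-occur on the endpoints
   of PPIs across several interaction databases, with reliability-weighted
   score combination and threshold calibration against a ground-truth DDI
   set;
3. **maps exon-skipping events onto protein features** by lifting protein
   coordinates (domains, motif spans, interface residues) to genomic
   coordinates through transcript models and intersecting them with the
   skipped exon;
4. runs an **edge-level hypergeometric enrichment test** over the rewired
   edges.

## The statistics in brief

**Edge-level enrichment.** Let `N` be the number of annotated edges in the
network, `K` the number of those incident to a pathway (an edge counts once
even if both endpoints are members), `n` the number of affected (rewired)
edges, and `k` the number of affected edges incident to the pathway. The
raw p-value is the upper-tail inclusive hypergeometric probability

    p = P(X >= k),  X ~ Hypergeometric(N, K, n)

adjusted across pathways by Benjamini–Hochberg; pathways are ranked by the
score `-log10(p_adj)`.

**DDI co-occurrence score.** For a resource `r`, a domain pair (a, b) gets
the cosine-style score

    s_r(a, b) = n_r(a, b) / sqrt(m_r(a) * m_r(b))

where `n_r(a, b)` counts PPIs with `a` on one endpoint and `b` on the other
and `m_r(d)` counts PPIs with `d` on at least one endpoint. Resource scores
are combined as a reliability-weighted mean `S = sum(w_r s_r) / sum(w_r)`;
the weights are found by randomized integer search (default 10 000 draws
from [1, 100]) maximizing F1 against the ground truth, and the confidence
threshold is calibrated on the same ground truth.

**Coordinate lifting.** Amino acid `i` of a protein covers coding
nucleotides `3i-2 .. 3i` counted 5'→3' along the spliced CDS; footprints may
span splice junctions and are returned as maximal genomic runs. A feature is
affected by an event iff its footprint intersects the skipped exon by at
least one nucleotide on a transcript of the event's gene.

## Worked example

Everything below runs offline on a synthetic fixture bundle (20 genes, 3 PPI
resources, a planted truth DDI set, 10 pathways):

```r
library(spliceRewire)

cfg    <- fixture_config(seed = 42)
bundle <- simulate_interactome(cfg, "demo_bundle")   # writes GTF/TSV/GMT files
events <- plant_splice_events(bundle)                # plants a splicing signal
ctx    <- plant_context(bundle)                      # readers + network build

ctx$network
#> <joint_network> 19 proteins; 30 annotated edge(s) (30 evidence items), 7 unannotated; tier filter: none

ev  <- read_splice_events(events$path, "generic_bed")
sig <- filter_events(ev, dpsi_min = 0.05, p_max = 0.05)   # 10 of 20 events pass

feats <- map_events_to_features(sig, ctx$models, ctx$dom_fp)
feats
#> <affected_features> 10 domain, 0 motif, 0 residue hits

aff <- derive_affected_edges(ctx$network, feats)
aff
#> <affected_edge_set> 17 affected edge(s), 17 lost evidence item(s)

stats <- network_characteristics(ctx$network, ctx$gsets, ctx$p2g)
enr   <- enrich_pathways(stats, aff, ctx$gsets, ctx$p2g)
enr$results[1:2, .(pathway_id, N, K, n, k, p_raw, p_adj)]
#>    pathway_id     N     K     n     k      p_raw     p_adj
#> 1:      PW001    30    18    17    13 0.04150030 0.2075015
#> 2:      PW004    30    16    17    12 0.03548226 0.2075015
```

Reading: of `N = 30` annotated edges, `n = 17` were rewired by significant
events; `k = 13` of those touch pathway PW001, which has `K = 18` incident
edges in total — an excess over the `n*K/N ≈ 10.2` expected by chance, with
raw hypergeometric p = 0.042 (not significant after BH on this tiny toy).

The same pipeline runs end to end from the command line:

```sh
exec/splicerewire simulate --out demo --seed 42 --events
exec/splicerewire run \
  --gtf demo/transcripts.gtf --domains demo/domains.tsv \
  --ppi R01=demo/ppi_R01.tsv,R02=demo/ppi_R02.tsv,R03=demo/ppi_R03.tsv \
  --ddi-templates demo/truth_ddis.tsv --events demo/events.tsv \
  --gene-sets demo/pathways.gmt --protein-to-gene demo/protein2gene.tsv \
  --out demo_results
```

writing `enrichment.tsv`, `affected_features.tsv`, `affected_edges.tsv`,
per-pathway detail tables, a pathway-cluster graph (TSV + JSON node-link)
and `run_metadata.json` with per-stage counts.

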