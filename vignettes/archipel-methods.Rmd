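---
title: "Methods: from checklists to biogeographic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from checklists to biogeographic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archipel)
```

## The problem

Oceanic archipelagos are classified into nested biogeographic ranks
(ecoregion, province, subprovince) from the species they share and the
species restricted to them. `archipel` implements the quantitative core of
that workflow for littoral marine faunas and floras: species-by-region
presence/absence checklists go in; dissimilarity-based dendrograms with
bootstrap support, optimal-cluster statistics, endemism and provincial
summaries come out. Every stage is also exercised by a synthetic checklist
generator with *known* planted structure, so the pipeline can be validated
end to end without access to any particular compilation of faunal records.

## Data model and filters

A checklist is a tibble: one row per species with taxon group, family,
genus, a depth range (m), status flags, an endemism annotation
(`endemic_scope`: blank, one region label, or plus-separated labels for
endemics shared between regions), and one strictly binary presence column
per region. Non-binary presence cells are rejected, never coerced:
abundance codes or "?" silently mapped to 0/1 are a classic source of
irreproducible matrices.

Two filters mirror standard littoral practice:

* **Depth** (`apply_depth_filter()`): a species is retained when its
  *shallow* depth limit lies at or above the chosen isobath. A species
  recorded at 10–300 m is reachable from the littoral zone, so the shallow
  limit — not the deep one — is what decides inclusion. The conventional
  thresholds are 50 m for gastropods and macroalgae and 200 m for coastal
  fishes, echinoderms, brachyurans and polychaetes, and
  `run_group_analysis()` applies them by taxon group. Species with missing
  depth are retained with a warning: curated checklists are usually
  pre-filtered by experts, and a missing metadata field must not silently
  delete a record.
* **Status** (`apply_status_filter()`): pelagic, bathypelagic, deep-water,
  exclusively anchialine, introduced and dubious records are removed, with
  per-flag counts logged.

Both filters are idempotent and commute, which the test suite checks as a
property over random checklists.

## Dissimilarity indices

For two regions with `a` shared species, `b` exclusive to the first and `c`
exclusive to the second, the package computes dissimilarity = 1 −
similarity for four classical binary indices:

| index | dissimilarity |
|---|---|
| Jaccard | \(1 - a/(a+b+c)\) |
| Sørensen | \(1 - 2a/(2a+b+c)\) |
| Ochiai | \(1 - a/\sqrt{(a+b)(a+c)}\) |
| Simpson | \(1 - a/(a+\min(b,c))\) |

Simpson is implemented in its turnover-only ("beta-sim") form — the
standard meaning of "Simpson dissimilarity" in the biogeography literature:
it ignores nestedness, so a fauna fully contained in another scores 0. The
ordering Simpson ≤ Sørensen ≤ Jaccard holds for every count triple (from
\(\min(b,c) \le b + c\)) and is asserted as a property test.

Degenerate pairs raise errors rather than adopting a silent convention: two
empty regions leave all four indices undefined, and a single empty region
leaves Ochiai and Simpson undefined. Real study regions are never empty, so
a zero-filled or one-filled convention would only mask data bugs. All
values are computed in full floating precision; rounding (half-up, one
decimal) happens exclusively at report time.

## Clustering and model selection

`agglomerate()` implements Lance–Williams agglomeration for UPGMA,
complete, centroid and Ward linkage. Numerical choices:

* **Ward variant.** Ward's criterion is applied to squared dissimilarities
  with merge heights reported back on the input scale — the Ward.D2
  convention. The tests verify exact height equality with
  `hclust(..., "ward.D2")`.
* **Centroid.** Centroid updates likewise operate on squared
  dissimilarities (`sqrt` at report time), matching
  `sqrt(hclust(d^2, "centroid")$height)`. Centroid linkage can produce
  height inversions; they are *retained* and flagged
  (`$inversions`), never repaired, and cophenetic distances use the actual
  merge heights.
* **Ties.** When two pairs share the minimal linkage value, the pair whose
  concatenated sorted leaf-label tuple sorts first is merged. This makes
  results independent of input row order (property-tested under random
  permutations). A positional tie rule (`tie_break = "order"`) exists for
  the bootstrap, below.

The best index × linkage combination is chosen by the cophenetic
correlation — the Pearson correlation between the original dissimilarities
and the tree's cophenetic distances (`select_model()`). Correlation ties
are broken by a documented, configurable preference:
UPGMA > complete > Ward > centroid, then
Jaccard > Sørensen > Simpson > Ochiai — average linkage and the most
widely used index first. On an exactly ultrametric matrix UPGMA is a fixed
point and the correlation is exactly 1, which doubles as a test oracle.

## Bootstrap node support

`bootstrap_support()` resamples species (matrix columns) with replacement —
the standard compositional bootstrap — rebuilding matrix and tree
`n_trees × n_iterations` times (default 100 × 100 = 10,000; the two knobs
exist because resampling designs are conventionally quoted as "trees per
iteration × iterations", and both are exposed). A node's support is 100 ×
the fraction of replicate trees containing the identical leaf-set
bipartition anywhere in the tree; support attaches to bipartitions, not
heights. The root bipartition is contained in every replicate, hence
always 100.

Each replicate randomizes leaf input order. Under the deterministic
label-based tie rule this would be a no-op, so replicates deliberately use
the positional tie rule: tied merges then resolve differently across
replicates, and tie artifacts wash out of the support values instead of
being votes for one arbitrary resolution. A replicate whose resampled
matrix empties a region (undefined index) is discarded and counted; more
than 10% discarded aborts with a diagnostic, since supports from heavily
censored replicate sets are not comparable.

## How many clusters?

Two criteria, both computed on cuts of the dendrogram (`cut_tree()`, which
removes the k − 1 last merges; for centroid trees with inversions this is a
merge-order cut, which stays well defined):

* **Silhouette** (`silhouette_widths()`):
  \(s(i) = (b_i - a_i)/\max(a_i, b_i)\), with singleton clusters scored 0
  by convention.
* **Mantel** (`mantel_statistic()`): Pearson correlation between the
  dissimilarity upper triangle and a binary model matrix coding 1 for
  pairs in *different* clusters. This coding makes well-separated
  partitions score positively; the opposite coding only flips the sign.
  At k = n the model matrix is constant and the statistic undefined, so
  the Mantel scan stops at k = n − 1. Permutation p-values are
  intentionally omitted: the statistic is used to choose k, not to test a
  null.

`optimal_k()` scans k = 2..k_max, reports the full profile (no silent
skips) and returns the argmax, smallest k on ties.

## The provincial index

For the ten warm-water gastropod index families/subfamilies (Turbinellidae,
Modulidae, Conidae, Conorbidae, Muricinae, Fasciolariinae, Volutinae,
Olivinae, Cancellariinae, Plesiotritoninae), the Provincial Index Taxon is
the family's endemism percentage, PIT = 100·n/N. The Provincial Combined
Index averages the ten PIT values **with empty families contributing
zero** — the denominator stays 10. This is the only reading consistent
with published worked values: four occupied families scoring
(50 + 94.5 + 50 + 100) average to 29.5 only when divided by 10. The index
is undefined (reported "n.a.") only when *no* index family has any
species — distinct from the 0.0 of a region whose index families are
present but hold no endemics. Classification: > 50% provincial rank,
25–50% subprovincial, with both boundaries read inclusive for
subprovince (a stated "between 25% and 50%" band; the convention is
documented and configurable via `classify_provincial_status()`).

Subfamily-level index taxa are matched through a genus table
(`index_taxon_genera()`), replaceable by the caller. Endemism status always
comes from curated annotations, never inferred from the presence matrix
alone: a matrix covers only the studied areas, and a species absent
elsewhere *in the matrix* may still occur outside it.

## Shared endemics

Endemics shared between two or more study archipelagos act like
synapomorphies: areas sharing restricted taxa are more closely related than
areas lacking them. `shared_endemics()` tabulates each such species'
archipelago set, the occupancy distribution (how many species span 2, 3,
4, ... archipelagos) and per-combination counts;
`shared_endemics_matrix()` turns the table back into a presence/absence
checklist so the archipelagos can be clustered on shared endemics alone
(conventionally Jaccard/UPGMA, as `run_shared_endemics_analysis()` does).
`checklist_from_combos()` expands printed combination counts into the same
structure, which is how published occupancy tables are re-analysed through
the identical code path.

## The synthetic world

`generate_checklist()` samples a checklist from a stated world: regions in
`k` true clusters; a cosmopolitan pool present everywhere; per-cluster
pools present in member regions with probability `p_within` (default 0.9)
and leaking elsewhere with probability `p_leak` (default 0.05);
single-region endemics; shared endemics on designated subsets; and a
detection probability (default 0.95) thinning every true presence. The
default world — 12 regions in 3 clusters, ~600 species — matches the
scale of real multi-archipelago littoral checklists (10–20 regions,
10²–10³ species per group). Presence is independent Bernoulli per cell:
no spatial autocorrelation beyond the block structure, which is the
simplest model consistent with what the analysis assumes. Ground truth
(partition + endemism annotations) is emitted in the exact annotation
format the endemism module consumes, so synthetic data exercises the same
I/O path as real data.

What a green test establishes, and what it does not: with `p_leak = 0` and
`detection = 1` the planted partition is provably recoverable, and the
acceptance suite demands exact recovery, k selection by both criteria, and
bootstrap support 100 on every planted clade. Real checklists add spatially
correlated sampling effort, taxonomic error and non-block structure that
this generator deliberately does not model; green synthetic tests validate
the *machinery*, not any empirical claim about a real fauna.

## Limitations

* Taxonomic name validation against online registries is out of scope;
  checklists are taken as curated.
* Newick round-tripping assumes monotone trees (centroid trees with
  inversions export fine but are not guaranteed to re-import to an
  identical merge order).
* The Mantel criterion is a greedy scan over tree cuts, not over all
  partitions.
* Reported percentages use half-up rounding to one decimal; other rounding
  conventions in published tables can differ in the last digit.
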