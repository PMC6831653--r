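# archipel

Multi-taxon marine island biogeography from presence/absence checklists.

`archipel` is for biogeographers asking whether a group of oceanic
archipelagos forms a coherent biogeographic unit: it takes
species-by-region checklists of littoral faunas and floras (coastal
fishes, echinoderms, gastropods, brachyurans, polychaetes, macroalgae, …)
and produces the quantitative evidence used to rank areas into ecoregions,
provinces and subprovinces.

The pipeline:

1. **Checklists** — strict binary presence/absence tibbles with depth,
   status and endemism metadata; depth filters (50 m isobath for
   gastropods/macroalgae, 200 m for the mobile groups) and status filters
   (pelagic, deep-water, anchialine, introduced, dubious records removed).
2. **Dissimilarity** — for region pairs with `a` shared species, `b` and
   `c` exclusives: Jaccard `1 − a/(a+b+c)`, Sørensen `1 − 2a/(2a+b+c)`,
   Ochiai `1 − a/√((a+b)(a+c))`, and turnover-only Simpson
   `1 − a/(a+min(b,c))`.
3. **Clustering** — UPGMA, complete, centroid and Ward (D2) linkage with a
   deterministic tie rule; the best index × linkage combination chosen by
   cophenetic correlation.
4. **Validation** — species-bootstrap node support (default 100 × 100
   replicates) on leaf-set bipartitions; optimal cluster number by mean
   silhouette width `s(i) = (b_i − a_i)/max(a_i, b_i)` and by the Mantel
   correlation between the distance matrix and a cluster model matrix.
5. **Endemism** — per-archipelago richness/endemism tables, the molluscan
   Provincial Index Taxa (`PIT = 100·n/N` over ten index families) and
   Provincial Combined Index (`PCT = Σ PIT/10`, >50% province, 25–50%
   subprovince), and shared-endemics occupancy/combination analysis with
   Jaccard/UPGMA clustering of the archipelagos on shared endemics alone.
6. **Synthetic data** — a generator with planted cluster structure,
   endemics and incomplete detection, returning ground truth in the same
   format, so the entire pipeline is testable without external data.

## Worked example

The Provincial Combined Index from published per-family counts for the
Cabo Verde archipelago (Modulidae 2 species / 1 endemic, Conidae 55/52,
Muricinae 2/1, Olivinae 1/1, the other six index families empty):

```r
library(archipel)
counts <- readr::read_tsv(
  system.file("extdata", "provincial_index_counts.tsv", package = "archipel"))
provincial_index_from_counts(subset(counts, region == "CAB")[-1], region = "CAB")
#> # Provincial Index - CAB
#>    family           n_species n_endemic   pit
#>  1 Turbinellidae            0         0  NA
#>  2 Modulidae                2         1  50
#>  3 Conidae                 55        52  94.5
#>  ...
#>  8 Olivinae                 1         1 100
#> Provincial Combined Index: 29.5% -> subprovince
```

Empty families contribute 0 to the average but the denominator stays 10:
(50 + 94.5 + 50 + 100)/10 = 29.5%, inside the 25–50% subprovincial band.

A full synthetic run — generate a 12-region checklist with 3 planted
clusters, filter, select the model, bootstrap, and pick k:

```r
cfg <- synthetic_config(seed = 7)
g   <- generate_checklist(cfg)
rep <- run_group_analysis(g$checklist, n_trees = 20, n_iterations = 10, seed = 7)
rep
#> # Group analysis: other
#>   stage       n_species
#> 1 input             620
#> 2 depth<=200m       591
#> 3 status            560
#> best model: jaccard / upgma (cophenetic r = 0.999)
#> optimal k: silhouette 3 (0.563), Mantel 3 (0.997)

recovery_report(g$truth$partition, rep$optimal_mantel$partition)
#>   exact  rand k_true k_inferred
#> 1 TRUE      1      3          3
```

The filter log shows 29 deep-water and 31 flagged species removed; both
cluster-number criteria recover the planted k = 3 and the partition matches
the ground truth exactly (Rand index 1). `autoplot(rep$tree)` draws the
dendrogram with bootstrap supports; `export_newick()` writes it with
supports as internal node labels.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance target from
scratch — the Cabo Verde Provincial Combined Index from the published
ten-family counts shipped in `inst/extdata/` — and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — implementation; `tests/testthat/` — unit, property and
  acceptance suites (all fixtures built in code or shipped as small TSVs)
- `inst/extdata/` — published count tables used as inputs; the gastropod
  combination file is marked `_synthetic` because only its marginals are
  published
- `vignettes/archipel-methods.Rmd` — the model, its assumptions, numerical
  conventions and limitations
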