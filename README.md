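# seloop

Connecting super-enhancers and broad H3K4me3 domains to their target
genes through chromatin interactions.

Two classes of cis-regulatory elements repeatedly mark cell-identity and
disease genes: **super-enhancers** — clusters of H3K27ac peaks with
exceptionally high aggregate signal — and **broad H3K4me3 domains** —
the widest promoter-mark peaks in a cell type. Whether either class
actually regulates a cancer gene cannot be read off linear distance
alone: enhancers loop over intervening genes to remote promoters.
`seloop` implements the full analysis that joins these layers: element
calling from ChIP-seq peaks, promoter-proximal/distal classification
against an annotation, replicate-reproducible ChIA-PET loops and
loop-mediated target-gene assignment, CAGE-based expression and
cell-type specificity, a merged SE/BD region taxonomy, and gene-set
enrichment statistics with housekeeping-gene subsampling controls.

It is written for computational biologists who have peak calls, loop
lists, and an annotation in standard formats (narrowPeak, gappedPeak,
bedGraph, BEDPE, GTF, TSV) and want a deterministic, fully tested,
tidyverse-native reimplementation of this workflow — every function
takes a data frame and returns a tibble.

## The methods in brief

* **Super-enhancer calling (ROSE-style).** H3K27ac peaks within 4 kb of
  each other are stitched (promoter peaks retained); each stitched
  region gets the input-corrected signal
  `∫ treatment − ∫ control` (rpm·bp). With signals sorted ascending as
  *y₁ ≤ … ≤ yₙ* and average slope *s = (yₙ − y₁)/n*, a line of slope
  *s* is slid through every point *(i, yᵢ)*; the tangent point is the
  one whose line leaves the fewest points strictly below it, and
  regions above *y*<sub>i\*</sub> are super-enhancers
  (`find_cutoff()`, exhaustive and deterministic).
* **Broad H3K4me3 domains.** Gapped peaks are trimmed to their block
  span; the top 5% by trimmed length are broad domains, the rest
  typical (`call_broad_domains()`).
* **Proximity.** An element within 4 kb (inclusive, edge-to-edge) of
  any retained TSS is proximal; small-RNA and artifact biotypes are
  excluded from the TSS set (`classify_proximity()`, `load_tss()`).
* **Loops and targets.** Loops found in both ChIA-PET replicates (both
  anchor pairs mutually overlapping, either orientation — the BEDTools
  `pairToPair` rule) are kept; genes with a TSS within 4 kb of the
  anchor opposite an element are its loop-mediated targets, with
  skipped-TSS counts quantifying "nearest gene" failures
  (`intersect_replicates()`, `loop_targets()`).
* **Expression specificity.** CAGE cluster expression is averaged
  within cell-type facets; specificity is
  `1 − entropy(X/ΣX)/log2(N)` over the `N` facets: 0 = ubiquitous,
  1 = single-facet (`facet_means()`, `specificity()`).
* **Taxonomy and enrichment.** Overlapping elements merge into regions
  classed SE_BD / SE_O / BD_O / O_O, split proximal/distal; pairwise
  class comparisons against tumor-suppressor, oncogene, cancer-census
  and housekeeping gene sets use Fisher's exact test with Holm–Šídák
  correction per panel, housekeeping counts entering as averaged
  500-gene subsamples, and the display score
  `sign(log OR)·(−log10 p)` (`build_taxonomy()`,
  `enrichment_matrix()`). `dunn_test()` provides the rank-based
  post-hoc comparison used for expression/specificity group contrasts.

A deterministic synthetic-data generator (`generate_fixture()`) plants
ground truth — SE peak clusters, length-skewed gapped peaks,
replicate-shared jittered loops, element→gene target pairs,
facet-structured expression, gene-set labels — so the entire pipeline
is testable end to end without downloads; `null_fixture()` randomises
the gene-set labels for type-I-error control.

## Worked example

```r
library(seloop)
library(dplyr)

bundle <- generate_fixture(fixture_config(seed = 1))
res <- run_analysis(bundle, analysis_facet = "K562",
                    hk_sample_size = 50, hk_reps = 200, seed = 1)

res$cutoff
#> Tangent-line super-enhancer cutoff
#>   regions: 202   cutoff: 3.753e+04 (index 187 of ascending sort)
#>   slope: 1.009e+04 signal/rank   super-enhancers: 15
```

202 stitched regions; the tangent of the ranked signal curve sits at
index 187, and the 15 regions above it — the planted clusters — are
called super-enhancers. `autoplot(res$cutoff)` draws the hockey-stick
rank curve with the cutoff.

```r
table(res$taxonomy$region_class, res$taxonomy$proximity)
#>         distal proximal
#>   BD_O       9       36
#>   O_O      189      882
#>   SE_BD      0        5
#>   SE_O       0       10

res$enrichment |>
  filter(panel == "proximal_proximity", class_a == "BD_O", class_b == "O_O")
#>   gene_set     a     b     c     d odds_ratio   p_value    p_adj signed_score
#> 1 TSG         15    21   117   765      4.67  0.0000413 0.000950        4.38
#> 2 OG           5    31    89   793      1.44  0.405     1.000           0.393
#> 3 CCG          7    29   125   757      1.46  0.339     0.999           0.470
#> 4 HKG          2    34    50   832      0.979 1         1               0
```

The 2×2 cells are regions hitting / not hitting each gene set for the
two classes. The fixture plants a 5× tumor-suppressor rate at genes in
broad-domain-only sites, and exactly that comparison lights up
(OR 4.7, adjusted p = 9.5×10⁻⁴, positive signed score); the other sets
stay at the null, and `autoplot(res$enrichment)` renders the signed
heat map. Recovery against the planted truth:

```r
evaluate_recovery(list(se = filter(res$enhancers, is_super) |>
                         mutate(element_id = region_id),
                       broad = filter(res$domains, is_broad),
                       targets = res$se_targets[c("element_id", "gene_id")]),
                  bundle$manifest)
#>   stage           n_planted n_called n_recovered recall   fdp
#> 1 super_enhancers        15       15          15      1 0
#> 2 broad_domains          50       50          50      1 0
#> 3 loop_targets           30       38          30      1 0.211
```

All planted elements and target pairs are recovered; the extra called
targets are genuine incidental loop–TSS overlaps, not errors (the test
suite verifies them against a brute-force oracle). The file-based
entry point `run_pipeline()` (or `inst/scripts/run-pipeline.R` from a
shell) runs the same stages from narrowPeak/bedGraph/gappedPeak/BEDPE/
GTF/TSV inputs and writes one TSV per stage plus a JSON run manifest.

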