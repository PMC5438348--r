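---
title: "seloop: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seloop: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seloop)
library(dplyr)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, the numerical conventions, and what the synthetic test bed can
and cannot show about real data.

## Coordinate and interval conventions

All intervals are 0-based, half-open (BED convention), carried as
tibble columns `chrom`, `start`, `end`. GTF input (1-based, inclusive)
is converted on read. The overlap engine behind `overlap_query()`,
`merge_within()` and every downstream operation is the IRanges interval
tree; the package's contribution is the analysis logic, not interval
arithmetic. Two conventions are load-bearing and deliberately uniform
across the package:

* **"Within W" is an inclusive edge-to-edge distance.** Merging joins
  intervals whose gap is `<= W` (so a gap of exactly 4 000 merges, and
  `merge_within(gap = 0)` joins overlapping and book-ended intervals);
  proximity calls an element proximal when the gap to a TSS is
  `<= 4000`, with distance 0 for a TSS inside the element. A TSS one
  base past the window (gap 4 001) is distal — the boundary is tested
  explicitly.
* **Strand is ignored for overlap** and used only to derive TSS
  positions: the `start` of a `+` transcript, the last base of a `-`
  transcript.

## Super-enhancer calling

H3K27ac peaks stitched within 4 kb (`stitch_peaks()`) form candidate
regions. Peaks inside promoter regions are retained — large fractions
of super-enhancers are promoter-proximal, and removing promoter peaks
before stitching hides exactly the elements of interest. Region signal
is the integral of rpm-normalised coverage (value x covered bases) of
treatment minus control; net signal is not floored at zero, negative
regions simply rank last. Results are rank-invariant to any global
scale factor on the tracks, so whether the coverage is read counts or
rpm density only changes units, never the call set.

The super/typical boundary is the tangent of the scaled rank curve.
`find_cutoff()` fixes the algorithm as a discrete, exhaustive search:
sort signals ascending, take the mean slope `s = (y_n - y_1)/n`, slide
a line of slope `s` through every point `(i, y_i)`, and choose the
point whose line leaves the fewest points strictly below it (ties to
the largest index, i.e. the highest cutoff). This is deterministic,
scale-covariant, and oracle-checkable — the test suite compares it
against an independent O(n^2) line search on hundreds of random
vectors. A flat signal vector is degenerate by definition: the cutoff
is the maximum and nothing is super. Rank ties are broken by
`(chrom, start)` so repeated runs are bit-identical.

## Broad H3K4me3 domains

Gapped peaks are trimmed to the span from the start of the first block
to the end of the last block; "size" is this trimmed length. We read
"trimming the flanking broad regions" as restriction to the block
span, not removal of the internal linkers — the internal gaps are part
of a domain's extent, and the ranking axis is the domain's footprint.
The top `ceil(0.05 n)` by trimmed length are broad. Length ties at the
boundary are broken by `(chrom, start)` so that exactly `k` domains
are broad; `rank_by_length(ties = "all")` switches to the
all-ties-promoted policy if a caller prefers it.

## Loops and target genes

Replicate reproducibility uses the `pairToPair` rule: a loop is kept
when some loop in the other replicate overlaps it on both anchors by
at least one base, in either anchor orientation; output carries
replicate-1 coordinates. Anchors are canonically ordered on ingest.

Loop-mediated targets use the same 4 kb TSS window as proximity
classification: one proximity notion throughout, since using a
different window for anchors than for promoters would make
"proximal" and "looped-to" incomparable. The element centre is
`floor((start + end)/2)`; `skipped_tss_count` counts distinct retained
TSS *positions* strictly between centre and target TSS (identical
positions collapse, so a gene with two transcript isoforms at one
promoter is one skipped site).

Two confounder controls mirror the analysis practice: category sizes
are equalised before comparing involvement rates
(`extension_control()`: each element grows by the difference between
its category's mean size and the largest category mean, split half per
side, clipped at position 0 — post-extension means agree within one
base), and interaction counts can be normalised per unit of occupancy
signal (`normalize_by_signal()`, undefined for non-positive signal).

## Expression and specificity

Facet expression is the arithmetic mean over the facet's samples.
Specificity is `1 - entropy(X/sum(X))/log2(N)` with entropy in bits
and `0 log 0 = 0`; base 2 matches the `log2(N)` normaliser, making the
score exactly 0 for uniform and 1 for one-hot vectors. All-zero rows
are reported missing (`NA`), never 0 or 1 — a silent cluster is
neither ubiquitous nor specific. The enhancer-RNA call requires a
bidirectional cluster with expression above zero and at least
`tpm_threshold` in the analysis facet; the default threshold 0 means
"any positive expression", the weakest defensible notion of
transcribed.

## Taxonomy and enrichment

Element calls merge transitively by overlap into regions classed
SE_BD / SE_O / BD_O / O_O by member kinds (typical elements never
change the class). The three marker classes are proximal when they
contain a proximal SE or proximal BD member; O_O regions are proximal
when any member is. Note `merge_within(gap = 0)` also joins book-ended
elements; exact adjacency has measure zero in real coordinates and
keeping one merge semantics package-wide was preferred over a special
case.

Each enrichment panel (distal-looping, proximal-looping,
proximal-proximity) builds 2x2 tables of regions hitting / not hitting
a gene set for every pair of classes. Denominators follow the panel:
looping panels count only regions involved in interactions, the
proximity panel counts all (proximal) regions. The Fisher p-value is
the standard two-sided hypergeometric sum (delegated to
`stats::fisher.test`); the odds ratio is the sample OR `ad/bc`, which
is what the signed display score needs a sign from, not the
conditional MLE. Holm–Šídák (`1 - (1-p)^(m-i+1)` step-down, running
maximum, cap at 1) is applied per panel across all of its comparisons.
The signed score is `sign(log10 OR) x (-log10 p)` on the raw p-value,
with the adjusted p carried alongside; log base 10 affects only the
display scale, never the sign.

Housekeeping genes are a control set an order of magnitude larger than
the cancer sets, so their counts enter as the average over repeated
500-gene subsamples (without replacement, 1 000 repetitions at real
catalog scale), rounded half-up because Fisher's test needs integer
cells. `hk_average_counts()` is deterministic given its seed and
restores the caller's RNG state. `dunn_test()` implements the
rank-based post-hoc z statistic with the standard tie correction and
no internal multiplicity adjustment; `holm_sidak()` can be layered on
top when a family of pairwise contrasts is reported together.

## The synthetic test bed

`generate_fixture()` builds a two-chromosome (10 Mb each) miniature of
the real inputs, deterministic given the seed, with one RNG stream per
file type (peaks, gapped peaks, genes, loops, expression) so adding a
component never perturbs the others. The default configuration *is*
the study condition of the test suite and acceptance script; it was
fixed once, before freezing, as follows:

* **H3K27ac**: 200 background peaks (widths 400–1200 bp, heights
  log-normal, meanlog log 20, sdlog 0.3) and 15 planted super-enhancer
  clusters of 5 constituents (gaps 0.5–3 kb, well inside the 4 kb
  stitch window) at 12x background height. The multiplier and
  background spread were calibrated jointly so the rank curve is a
  genuine hockey stick: the discrete tangent rule places the cutoff at
  the top of the background only when the mean slope (max signal / n)
  exceeds the spacing between the top background order statistics;
  with a heavier background tail or a weaker multiplier the cutoff
  slides a few ranks into the background and the planted/called
  correspondence the suite asserts would be meaningless. Control
  coverage is 5–25% of treatment.
* **H3K4me3**: 1 000 gapped peaks, trimmed lengths log-normal
  (meanlog log 2500, sdlog 0.7, clamped to 0.6–80 kb), 1–3 blocks,
  200–800 bp flanks; the 5 longest broad domains are centred on
  planted super-enhancers to create SE_BD regions, all other domains
  are placed away from SE neighbourhoods so the planted class
  structure is exact.
* **Genes**: one gene per planted SE (TSS inside the cluster span) and
  one per domain with probability 0.85 — the same probability for
  broad and typical domains, deliberately: region classes then have
  the same genes-per-region structure, so under randomised labels the
  enrichment panels are genuinely null (a class with systematically
  more genes per region would show "enrichment" with random labels and
  no test could pass a type-I check honestly). Plus 80 unanchored
  genes and 12 structural-RNA genes exercising the biotype exclusion.
  Base gene-set rates: TSG 0.10, OG 0.10, CCG 0.12, housekeeping 0.35;
  the planted effect multiplies the TSG rate by 5 at genes in
  broad-only sites. `null_fixture()` draws every gene at base rates.
* **Loops**: 240 per replicate, 70% shared, anchors 0.8–1.5 kb jittered
  by at most 200 bp between replicates — enough that replicate
  intersection is non-trivial, small enough (less than half an anchor
  width) that every shared loop must survive. Two planted loops per SE
  run from the cluster to a gene TSS 30 kb–1 Mb away, present in both
  replicates, so planted target recall should be exactly 1.
* **CAGE**: 12 facets x 3 samples; promoter clusters at every coding
  TSS (housekeeping genes near-uniform across facets, others one-hot
  leaning), bidirectional eRNA clusters at every planted SE (analysis
  facet) and at 15% of background peaks (random facet).
* **Enrichment controls at fixture scale**: the housekeeping catalog
  here is ~120 genes, so the subsampling control runs at 50 genes x
  200 repetitions; the 500 x 1000 defaults apply to real,
  3800-gene-scale catalogs.

What passing on this bed shows — and what it does not: the fixtures
have clean rpm tracks, isolated planted clusters, exact block
structure, and label noise only where planted. They validate the
*logic* (stitching, cutoff geometry, pairToPair matching, window
arithmetic, test statistics, multiplicity handling, determinism), not
robustness to mappability artifacts, copy-number-distorted coverage,
anchor-calling errors, or annotation incompleteness in real data.
Problem sizes (20 recovery seeds, 100–200 null fixtures) were chosen
to give stable Monte-Carlo estimates at desk scale.

## Numerical and degenerate-input conventions

* `find_cutoff()` on < 2 signals, empty gene-set tables, groups of
  size 0 in `dunn_test()`, and a control set smaller than the
  subsample size are validation errors, not silent results.
* Flat signal vectors yield zero super-enhancers; an empty TSS set
  classifies everything distal with a warning; genes missing from an
  expression table count as inactive with a warning; a
  nearest-active distance with no active gene is `NA`; the
  false-discovery proportion of an empty call set is `NA` (0/0), not 0.
* Recovery matching uses 50% reciprocal overlap for intervals and
  exact identifiers for element-to-gene pairs.
* The only stochastic steps in the whole pipeline are housekeeping
  subsampling and fixture generation; both take explicit seeds, and
  `run_pipeline()` output is byte-identical across runs given the same
  inputs and seed.

## Known limitations

* The tangent cutoff is sensitive to the upper tail of the typical-
  enhancer signal distribution by construction; on data without a
  clear inflection it will place the boundary conservatively high
  (flat curves yield no super-enhancers at all).
* Hi-C style loop lists can be consumed as BEDPE through the same
  operations, but contact-matrix processing, loop significance models
  and peak calling are out of scope; peaks and loops are inputs.
* The leukemia-associated subset of the census catalog is extracted by
  case-insensitive substring keywords (default: leukaemia, leukemia,
  AML, CML, ALL, CLL) over the tumour-type text; curated catalogs with
  free-text tumour types may need the keyword list adjusted (note
  "ALL" as a substring can match unrelated phrases in some catalogs).
* `specificity()` treats facets symmetrically; it does not model
  nested facet ontologies or sample-size differences between facets
  beyond the within-facet mean.
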