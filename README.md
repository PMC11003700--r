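# regquad

Integrative ChIP-seq/RNA-seq regulatory classification and drug-synergy
scoring for R.

## The problem

When a transcription factor (TF) such as an amplified oncogenic driver
binds thousands of sites genome-wide, the mechanistic questions are
*where* it acts and *what happens* to the genes it touches: which peaks
sit in active promoters (H3K4me3 + H3K27ac) versus distal enhancers
(H3K4me1 + H3K27ac), which cofactors co-occupy each element type,
whether losing the TF moves promoter-bound and enhancer-bound targets
in different directions, and whether drugging two of its cofactors at
once is synergistic. regquad packages that entire workflow — aimed at
computational biologists who have peak calls, coverage tracks, a gene
model and a differential-expression (DE) table, and want the
integrative classification reproducibly scripted.

## What it computes

* **Signal matrices and metagenes** — per-peak binned coverage around
  peak centers (±3 kb, 10 bp bins; per-base mean per bin), accumulated
  peak-center scores (±500 bp), column-mean metagene profiles, and
  percent summit changes between conditions.
* **Chromatin-state segmentation** — deterministic k-means (k = 2) over
  per-mark-standardized signal matrices, clusters labeled
  promoter-like/enhancer-like by the H3K4me3:H3K4me1 score ratio.
* **Positional annotation** — exclusive promoter/distal classes against
  strand-aware −1 kb..+100 bp promoter windows, nearest-TSS gene
  assignment, 5 kb distance binning, 1-decimal percentage reporting.
* **Peak-set overlap** — ChIP-peak overlap with "min" connected-peaks
  semantics: components of the bipartite ≥1 bp overlap graph, counted
  as Σ min(|A\_i|, |B\_i|), plus per-category breakdowns.
* **Super-enhancers** — distal (> 2.5 kb from TSS) H3K27ac peaks
  stitched within 12.5 kb, ranked by input-subtracted signal, cut where
  the tangent slope of the unit-scaled rank curve reaches 1.
* **Regulatory quadrants** — bound element class (promoter/enhancer)
  crossed with DE direction (|FC| ≥ 1.5, padj < 0.05); dual-bound genes
  count in both element tallies and are reported separately.
* **Occupancy binning** — kd/ctrl peak-center ratios binned down
  (≤ 1/1.2), stable (within 1.1-fold), up (≥ 1.2), with the uncovered
  bands reported as unclassified; chi-square comparison of class
  distributions.
* **Bliss synergy** — checkerboard viability matrices scored as
  observed − expected inhibition, E(a,b) = e\_a + e\_b − e\_a·e\_b, in
  percentage points; average in (−10, 10] additive, > 10 synergistic.
* **Synthetic regulome generator** — a two-chromosome toy genome with
  planted peak classes, quadrants, occupancy categories,
  super-enhancers and Bliss excess, byte-reproducible from one seed,
  so the full pipeline is testable offline.

## Worked example

Generate a synthetic dataset and run the whole pipeline from its config:

```r
library(regquad)
sim <- simulate_regulome(synth_config(), seed = 1, out_dir = "demo")
rep <- run_pipeline("demo/config.yaml")

rep$quadrants$counts
#>   element_class direction count percentage
#> 1      promoter      down    65       92.9
#> 2      enhancer      down     5        8.3
#> 3      promoter        up     5        7.1
#> 4      enhancer        up    55       91.7
```

Of the 120 DE genes, all 120 are TF-bound and 10 are bound at both
element types — so promoter-bound targets are overwhelmingly
down-regulated after knockdown while enhancer-bound targets go up,
exactly the planted design (60 promoter-down, 50 enhancer-up, 10 dual).
The other stages report:

```r
rep$super_enhancers
#> $n_stitched [1] 60   $n_super [1] 9

rep$occupancy
#> $down [1] 30   $stable [1] 30

round(rep$tf_summit_decrease_pct, 1)
#> [1] 49.2

bliss_score(sim$dose$synergistic)
#> Bliss synergy: average score 13.88 (synergistic) over 16 combination cells
```

The 60 stitched distal regions include the 6 planted 6×-amplitude
clusters (all called super, plus a few borderline regions above the
inflection); the cofactor-B occupancy bins recover the planted 30 down
/ 30 stable split; the TF metagene summit drops by ~50% after
knockdown; and the planted 15-point Bliss excess scores ~14 under 3%
viability noise. Percentage reporting works on plain counts too:

```r
class_fractions(c(promoter = 9299), 19707)
#>      class count percentage
#> 1 promoter  9299       47.2
```

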