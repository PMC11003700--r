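---
title: "Methods: integrative regulatory classification and synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative regulatory classification and synergy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regquad)
```

# The analysis

regquad implements the integrative ChIP-seq/RNA-seq workflow used to ask
how a transcription factor (TF) regulates its direct targets: does it
act at promoters or at distal enhancers, which cofactors does it
recruit at each element type, and does losing it move the bound genes
up or down? The pipeline runs in the order

1. **Signal quantification** — binned coverage matrices around TF peak
   centers (`compute_matrix`), accumulated peak-center scores
   (`peak_center_score`), metagene profiles (`metagene`) and
   between-condition summit changes (`summit_change`).
2. **Chromatin-state segmentation** — k-means over the concatenated,
   per-mark-standardized matrices of H3K4me3, H3K4me1 and H3K27ac
   (`classify_tf_peaks`), with clusters labeled promoter-like or
   enhancer-like from the H3K4me3:H3K4me1 peak-center score ratio.
3. **Positional annotation** — exclusive promoter/distal assignment
   against strand-aware −1 kb..+100 bp promoter windows plus
   nearest-TSS gene mapping (`annotate_peaks`), and 5 kb near-TSS
   distance binning.
4. **Cofactor overlap** — min-linkage connected-component overlap
   counting between peak sets (`find_overlaps`): components of the
   bipartite ≥1 bp-overlap graph, counted as
   $\sum_i \min(|A_i|, |B_i|)$.
5. **Super-enhancers** — TSS-exclusion (> 2.5 kb), 12.5 kb stitching,
   input-subtracted signal ranking, and an inflection cutoff where the
   tangent slope of the unit-scaled rank curve reaches 1
   (`call_supers`).
6. **Regulatory quadrants** — the cross of bound element class
   (promoter / enhancer) with differential-expression direction after
   TF knockdown (`build_quadrants`); a gene bound at both element types
   counts in both tallies, and the dual-bound count is reported
   explicitly because the two element tallies overlap.
7. **Occupancy binning** — cofactor peak-center signal ratios between
   conditions, binned down / stable / up (`bin_occupancy_change`).
8. **Bliss synergy** — checkerboard viability matrices scored against
   the independence expectation $e_a + e_b - e_a e_b$ (`bliss_score`).

# Conventions and key parameters

All coordinates are BED-style 0-based half-open `[start, end)`; a
minus-strand TSS is `end - 1`. All thresholds live in one place,
`analysis_config()`:

* DE calls: $|FC| \ge 1.5$ (inclusive; immaterial for continuous data
  but deterministic) **and** adjusted $p < 0.05$ (strict). Fold changes
  use the signed-linear convention (−x means 1/x; no-change is +1).
* Promoter window: −1000..+100 bp of the TSS, mirrored about the TSS on
  the minus strand, clipped at 0.
* Signal matrices: ±3 kb flanks, 10 bp bins, anchored at the called
  summit when present, else the interval midpoint. A bin's value is the
  per-base **mean** of the track over the bin (not the sum), so the
  peak-center "accumulated" score is a sum of bin means — this pins the
  oracle arithmetic exactly. Tracks are treated as already normalized
  (bamCoverage-style RPKM bedGraphs); an explicit `normalize = "rpkm"`
  mode rescales raw-count tracks by bin length and library size.
  Flanks beyond the covered genome are zero-filled so all rows have
  equal width.
* Occupancy bins, ratio $r = \mathrm{kd}/\mathrm{ctrl}$: down when
  $r \le 1/1.2$, up when $r \ge 1.2$, stable when $1/1.1 < r < 1.1$.
  The bands $(1/1.2, 1/1.1]$ and $[1.1, 1.2)$ are genuinely uncovered
  by those three rules; they are reported as `unclassified` rather than
  silently absorbed.
* Synergy classification: average excess in $(-10, 10]$ additive,
  $> 10$ synergistic, $\le -10$ antagonistic (the lower tail is not
  named by the three-bin convention's source; antagonistic is the
  natural completion).
* Percentages are reported to one decimal (round-half-up via `round`),
  matching the field's reporting style.

# Numerical choices

**Coverage integrals.** Tracks are stored as sorted non-overlapping
steps with implicit zero gaps; bin values come from an exact
prefix-integral (`findInterval` on step starts), so `compute_matrix`
agrees with a naive per-base accumulation to 1e−9 — the test suite
enforces this on random instances.

**Deterministic k-means.** `kmeans_segment` seeds the first center with
a single seeded draw, picks remaining centers by greedy farthest-point,
then runs Lloyd iterations to convergence. Results are bit-stable for a
fixed seed. If fewer than k distinct rows exist, all points go to
cluster 1 (no crash, documented degenerate contract). Per-mark feature
blocks are standardized column-wise (zero-variance columns become 0)
because the marks have very different dynamic ranges; without this the
largest-amplitude mark dominates the metric.

**Cluster labeling.** Promoter-like = higher
$\bar s_{K4me3} / (\bar s_{K4me1} + \varepsilon)$ with
$\varepsilon = 10^{-8}$; exact ratio ties leave clusters unlabeled
rather than guessing.

**Super-enhancer cutoff.** The published description — a cutoff "where
the tangent slope = 1" on the rank-ordered, unit-scaled signal curve —
needs a concrete estimator. A finite-difference slope scan is fragile:
when the two top regions have nearly equal signal, the one-sided slope
at the top rank falls below 1 and the scan terminates empty, and exact
plateaus (ties) behave the same way. regquad therefore uses the
geometric definition directly: for the convex ranked curve, the line of
slope 1 slid up from below touches it at
$\arg\min_i (\tilde y_i - \tilde x_i)$ (scaled signal minus scaled
rank), which is exactly where the numerical slope crosses 1; rank ties
resolve to the higher rank, and regions strictly above the cutoff
signal are super. A flat curve has no tangent point and no supers;
fewer than two regions are all typical. An independent brute-force
tangent scan validates this on 1 000+ random signal vectors, and the
super set is upward-closed by construction.

**Overlap semantics.** "min" connected-peaks counting is implemented as
union-find over the bipartite overlap graph (pairwise hits detected
with GenomicRanges); the component table preserves the full membership
so alternative counts (e.g. merged-interval counts) can be recomputed.
The category report divides by the A-side peaks that belong to any
component.

**Nearest-TSS ties** break toward the smaller TSS coordinate and then
the gene identifier, making `annotate_peaks` invariant to gene-list
order. Nearest-gene assignment is per chromosome; a peak on a
chromosome without genes is distal with `NA` gene.

# The synthetic regulome

`simulate_regulome()` generates the study conditions every recovery
test runs under: two ~1.4 Mb chromosomes, 200 genes at 14 kb spacing
with the TSS pinned 1 kb into each slot; 60 promoter-bound genes
(planted −2-fold down on TF loss), 50 enhancer-bound genes (+2-fold
up), 10 dual-bound, and 80 unbound fillers with $|FC| < 1.2$ (ten of
them with large fold changes but non-significant adjusted p, to
exercise the p-value rule). Enhancers sit 6 kb downstream of their TSS
— beyond the 5 kb near-TSS bin and the 2.5 kb super-enhancer
exclusion. Coverage is Gaussian bumps (sd 150 bp, truncated at ±3 sd,
10 bp steps) with log-normal per-peak amplitude spread (sd 0.3) and
per-bin noise (sd 0.15); knockdown multiplies TF amplitudes by 0.5 and
cofactor A by 0.95 (planted 50% / 5% summit decreases). Cofactor A
covers 70% of TF promoter peaks; cofactor B is enhancer-restricted with
planted occupancy categories (half 1.5×-down, half stable, 3% per-peak
amplitude noise — the calibration condition for the ≥ 0.98 recovery
check). Six super-enhancer clusters (three constituents, 6× amplitude)
are planted in the intergenic space next to selected enhancer-bound
hosts; each stitches with the host's own enhancer into one super
region, and sits > 11 kb from every TF peak so signal matrices are
unaffected. Dose checkerboards use fixed Hill single agents over doses
0–3 with a uniform planted Bliss excess and 3% multiplicative
viability noise. A single master seed fans out into named per-output
RNG streams, so regenerating with the same seed is byte-identical and
adding an output type never perturbs the others.

At `noise_scale = 0` the pipeline must recover every planted label
exactly — the tests assert this. At the default noise the suite checks
averages over 20 generations: cluster-label accuracy ≥ 0.95, quadrant
recall and precision ≥ 0.95, occupancy-category recovery ≥ 0.98, and
Bliss excess recovered within ±0.5 points over 200 replicate
checkerboards for planted 5/15/25-point excesses.

What the generator does **not** emulate: read-level sampling noise and
mappability artifacts, peak-calling uncertainty (peak sets are exact),
copy-number and input biases, correlated biological replicate
structure, overlapping genes and alternative TSSs, and realistic
genome sequence. Passing recovery tests therefore demonstrates that the
pipeline's arithmetic and decision rules are correct under controlled
signal/noise, not that any particular real dataset will separate as
cleanly.

# Problem sizes

The routine test suite runs reduced designs (60-gene regulomes) plus
1 000+ randomized oracle instances per interval operation and finishes
in about a minute; the acceptance checks use the full 200-gene design
over 20 seeds and 500 simulated checkerboards, a few minutes in total.
These sizes were chosen so the planted effects dominate sampling error
by a comfortable margin while the whole suite stays quick to iterate
on.

# Known limitations

* Sub-classification of enhancers (active vs weak/poised) is not
  attempted — only mean profiles per cluster are reported.
* The synergy scorer reproduces the plain Bliss excess average;
  baseline correction and response-surface smoothing offered by
  interactive tools are out of scope, so scores can differ from theirs
  on noisy matrices.
* `overlap_by_category` percentages depend on the chosen denominator
  side; the component table is exported so other conventions can be
  recomputed.
* The positional annotator implements only the promoter/distal split
  and nearest-TSS mapping, not a full genic taxonomy
  (exon/intron/UTR) or regulatory-domain association rules.
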