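---
title: "Aligning and comparing complexome profiles with gelwarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning and comparing complexome profiles with gelwarp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelwarp)
```

## The model

Complexome profiling yields, per sample, a matrix of non-negative
intensities with proteins in rows and gel slices in columns. The slice axis
is ordinal (apparent molecular mass changes monotonically along it) but not
calibrated: different gels shift and stretch relative to one another, and
labs cut anywhere from a few dozen to a few hundred slices. gelwarp treats
cross-gel comparison as a sequence-alignment problem on the slice axis,
followed by a curve-comparison problem per protein.

### Multi-dimensional dynamic time warping

The local cost between slice `x` of one sample and slice `y` of another is
the L1 distance over the shared protein roster,
`d(x, y) = Σ_i |x_i − y_i|`. Pooling all proteins makes the alignment
"multi-dimensional": abundant proteins carry the strongest signal and
dominate the warp, which is intended — they are also the most reliably
quantified. The accumulated cost follows the unconstrained classic
recursion with moves diagonal, gap-in-one-side, gap-in-other-side, both
endpoints anchored. The global cost (accumulated cost at the end point)
contains no gap penalty, so it measures profile difference independently of
how much warping was needed — which is why it doubles as the dissimilarity
for clustering samples.

Choices the recursion leaves open, fixed here deterministically:

* **Tie-break** among equal-cost predecessors: diagonal first, then the
  predecessor along the first argument's axis, then the second's. This
  favors the fewest insertions and makes every run reproducible. Costs are
  compared exactly (no epsilon): local costs are sums of absolute
  differences of the same doubles, so equal optima really are bit-equal.
* **No warping window, no step weights**: profiles have at most a few
  hundred slices, so the full O(n²·p) table is cheap (pure R, ~1 s for nine
  60-slice samples of 100 proteins) and a window would only risk clipping a
  genuine shift.

### Progressive multiple alignment

All pairwise global costs are clustered by single linkage into a guide
tree; ties pick the pair with the smallest original sample index. Merges
follow the tree bottom-up. To align two alignments, the local cost at an
aligned position pair is the *average* local cost over all cross sample
pairs; already-inserted (repeated) positions contribute their repeated
values, i.e. the warped matrices are used as-is. At each merge the side
containing the lowest original sample index is the first DTW argument, so
the result is invariant to input order up to row order.

A gap inserted into a sample is realized by repeating the preceding slice's
intensities. Consequences used as invariants throughout the test suite:
deleting a sample's inserted positions recovers its normalized input
bit-exactly ("de-warp identity"), and the aligned length equals each
sample's original slice count plus its insertion count. A gap before the
first slice cannot occur with anchored endpoints; the code still handles it
(by repeating the first slice) defensively.

### Normalization

Each sample is scaled by one scalar so the summed intensity over the
analysis roster is equal across samples. The common target defaults to the
mean of the raw totals — scale-preserving, so outputs stay in the input's
order of magnitude — with a `fixed` alternative. Harmonization zero-fills
proteins missing from a sample *before* normalizing (zero rows do not
change sums), and the zero rows mean presence/absence differences are
visible to the DTW cost rather than silently dropped. Note one consequence
explored in the tests: a pure per-gel intensity factor is cancelled exactly
only when both lanes carry the same total mass; a duplicated slice adds
mass, so after normalization a small residual cost remains — proportional
to the duplicated slice's share of the lane total.

### Hausdorff distance on rescaled curves

Aligned per-protein curves are compared as discrete point sets, one point
`(position, intensity)` per aligned position (no interpolation — the data
are sets of coordinates, not continuous traces). Because raw intensities
dwarf the slice axis, each protein's curves are first multiplied by
`w·L / M_i`, where `L` is the aligned length and `M_i` the protein's
maximum over *all* samples compared (not per group). `w = 1` yields a
square plane; `w = 0.25` weighs migration (mass) shifts 4-fold over
abundance shifts. Both settings are worth running: per-protein results
differ slightly, and agreement of the affected complexes across `w` is a
useful robustness check — data-dependent, hence recommended rather than
asserted in the tests. All-zero proteins are left unchanged and score 0
everywhere.

The implemented distance is the *symmetric* Hausdorff distance
`max(h(A,B), h(B,A))`. A one-directional `h` is sometimes quoted as "the"
definition; the symmetric max is the standard metric (symmetry, identity,
triangle inequality — all property-tested against a brute-force
double-loop oracle).

### Hausdorff effect size

For groups of sizes `n₁, n₂` there are `B = n₁·n₂` between-group and
`W = C(n₁,2) + C(n₂,2)` within-group sample pairs; per protein,
`HES = mean(between d_H) / mean(within d_H)`. HES is symmetric under
swapping the group labels. Division-by-zero policy (explicit flags instead
of silent NaN): `mean_within = 0 < mean_between` gives `Inf`, ranked top,
flagged `infinite` (written to `.rnk` as 10× the largest finite score,
since GSEA needs finite values); both means zero gives `NA`, ranked bottom,
flagged `undefined`, omitted from `.rnk` and listed in a sidecar exclusion
file. Pairs where both curves are all-zero contribute 0 to the averages —
the literal reading of the definition. HES ties rank by protein id.

Enrichment statistics themselves (enrichment-score curves, NES, permutation
FDR) are deliberately out of scope: the package exports the `.rnk` ranking
and consumes GMT set files, plus a convenience `leading_edge_summary()`
that reports each complex's member ranks and top-k count.

## The synthetic-data generator

`generate_study()` is first-class, tested code, not a throwaway fixture. It
emulates the design the method targets: 4 cases and 5 controls (default) of
100 proteins over 60 slices, run on 3 gels assigned round-robin. Each
protein gets one Gaussian peak (center uniform in the middle 70% of the
lane; sigma 1.5–3 slices, the sharpness typical of resolved complexes;
height `10^U(3,6)`, spanning the orders of magnitude iBAQ covers). Noise is
multiplicative lognormal with unit mean and cv 0.1 — intensities are
positive and right-skewed — and cells drop out with probability 0.02,
emulating missed identifications; both defaults are deliberately small so
that failures indicate algorithmic bugs, not an overwhelmed signal. Gel
warps duplicate a few known slices (at 60 slices: none / slices 15, 40 /
slices 25, 50, scaling proportionally for other lane lengths) and apply
per-gel intensity factors 1 / 1.3 / 0.8 — shifts of a few slices, the
magnitude seen between real gels. The case effect shifts 10 chosen
proteins' peaks by +4 slices and scales them 3-fold, mirroring the
complex-mass plus abundance changes the effect size is meant to flag.

What the generator does *not* emulate: iBAQ physics and peptide
detectability, multi-peak distributions of proteins shared between
complexes, correlated noise within a gel, or realistic complex
stoichiometries. A green recovery test therefore establishes that the
algorithmic chain is correct and sensitive in a controlled world, not that
any particular biological dataset would rank the same proteins on top.

## Numerical and design notes

* Internally slice indices are R's 1-based columns; all reports
  (insertion tables, ranks) are 1-based as well.
* Empty cells in input files read as 0; explicit `NaN` becomes 0 with a
  warning count. Negative or non-numeric intensity cells are hard errors
  naming the offending cell.
* Duplicate rows per gene can be collapsed with `collapse_by=`, keeping
  the row with the highest total intensity.
* The guide tree is built by a hand-rolled single-linkage agglomeration
  rather than `stats::hclust` solely to guarantee the documented
  tie-break; single linkage cannot produce inversions, so heights are
  non-decreasing by construction.
* Determinism is a contract: identical inputs give byte-identical CSV/rnk
  outputs (tested), and every CLI run writes a `manifest.json` with the
  configuration, package version and input checksums for exact replay.
* xlsx input is supported when `readxl` is installed; outputs are CSV
  (no xlsx writer is available in the supported environment).

## Known limitations

* Samples are assumed to share the orientation of the slice axis; no
  reversal detection or mass calibration is attempted.
* The DTW is O(n²·p) per pair and the progressive stage aligns the warped
  matrices as-is without iterative refinement; for very many samples the
  guide-tree order increasingly determines the result.
* HES has no attached significance; inference is delegated to external
  preranked GSEA on the exported files.
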