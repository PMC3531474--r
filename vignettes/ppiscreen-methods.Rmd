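---
title: "Methods: scoring and comparing colony-array PPI screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and comparing colony-array PPI screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

This vignette documents the statistical model behind `ppiscreen`, the
choices made where the underlying assay leaves the analysis open, and
what the synthetic-data generator does and does not emulate.

## The measurement model

A DHFR-PCA cross reports an interaction as colony growth on
methotrexate. We treat the log10 colony size of replicate $r$ of a
cross between bait $i$ (MATa, F[1,2] fragment) and prey $j$ (MATα,
F[3]) in background $b$ as

$$\log_{10} s_{ijbr} = \beta_0 + \gamma_{ijb} + \delta_i + \delta_j + \varepsilon_{ijbr},$$

where $\beta_0$ is background growth common to all crosses,
$\gamma_{ijb} \ge 0$ is the interaction signal (zero for non-interacting
pairs), $\delta$ are per-strain mating-type biases (zero for most
strains, negative for the occasional problematic fusion), and
$\varepsilon \sim N(0, \sigma^2)$ is replicate noise, Gaussian on the
log scale because colony growth errors act multiplicatively.

The signal index of a cross averages the replicates before taking logs:

$$\mathrm{SI}_{ijb} = \log_{10}\left(\tfrac{1}{R}\sum_r s_{ijbr} + 1\right).$$

The pseudo-count of 1 (one pixel, on the raw-count scale) makes an
all-empty cross score exactly 0 and is negligible for any real colony.
Averaging sizes before the log follows the assay's readout — the mean of
triplicate colonies is the quantity tracked plate to plate; taking logs
first would instead estimate the geometric mean and would be undefined
at zero colonies.

## Quantifying plates

Colonies are segmented with a single global threshold per plate, the
midpoint of a deterministic two-class split of the intensity histogram
(two-means, the Ridler–Calvard fixed point). Per-cell thresholds would
react to local lighting but also to the colony itself; a plate-wide
threshold keeps size differences between cells meaningful. Colony size
is the **count** of foreground pixels in the cell window — area, not
integrated intensity, which is also available (`measure = "intensity"`)
but makes no claim of equivalence. Sizes are normalized by the median
nonzero colony of the plate, which removes plate-to-plate scale (pinning
pressure, camera distance) while leaving zeros at zero. Grid geometry is
supplied by configuration, not auto-detected: arrays are pinned by
robot, so geometry is known, and auto-detection failures are silent.

## Testability and design

Within one background, a protein pair has up to two tag orientations
(which protein carries the bait fragment). Pairs are coded `S`
(homomeric, one cross), `R` (both orientations available), `NR` (one
orientation), or untestable. In hybrid backgrounds the bait's species is
fixed by the hybrid's mating-type configuration, so the reciprocal of a
hybrid-1 cross is its tag-swapped cross in the same background, and the
species-swapped combination appears in hybrid 2.

Replicates of one cross are pinned at random positions subject to never
touching, with adjacency read as the 8-neighbourhood (a shared plate
edge or corner): neighbouring colonies compete for nutrients, and
diagonal contact is contact. Placement is rejection sampling with a
bounded retry count, seeded and reproducible; unused positions are
BORDER and enter no statistic.

## Strain-bias correction

Comparing one species with one hybrid, the strains on the tagged side
differ between the two backgrounds while the other side is shared, so a
biased strain shows up as a level offset in that strain's group of
shared crosses. The correction is conditional and per-strain: a group is
touched only when its between-background Pearson correlation is
significant at $\alpha = 0.001$ (the correlation, not the offset, is the
evidence that the group measures the same interactions on both sides);
then the side with the higher mean is shifted **down** by the mean
difference. Decreasing the unbiased side rather than raising the biased
one is deliberately conservative: it can push a weak signal into the
background but can never promote background noise into a call. The
correction is a mean shift only — with ~24 crosses per group a stable
slope estimate is not available, and a slope correction could not be
made decrease-only; an inverse-regression variant is available
(`method = "slope"`) without that guarantee. Applying the correction
twice changes nothing: the shift equalizes the group means, and the
correlation the gate tests is invariant under constant shifts.

Groups with fewer than 3 shared crosses cannot support a correlation
test and are skipped with a warning.

## Threshold and calling

Crosses between proteins of two unrelated complexes (SA values) are
taken as pure background; the calling threshold $t$ of a background is
the **maximum** SA value, estimated per background because hybrids need
not share the parents' background level. This construction fixes the
among-complex false-call rate at exactly zero and is conservative for
weak true interactions near $t$. A within-complex pair is called when
any tested orientation exceeds $t$; both-orientation support is reported
(`reciprocal` vs `single_orientation`) but not required, since tag
orientation can abolish a real interaction by steric interference.

## Divergence between backgrounds

After correction, an ordinary least-squares regression of one
background's SI on the other's is fitted over all shared crosses, and
the residuals are pooled. A pair is flagged at the smallest of
5% / 1% / 0.1% whose two-sided normal bound its residual (standardized
by the pooled residual SD) exceeds; an empirical-quantile variant is
available for heavy-tailed pools. Two-sided bounds are used because a
gain and a loss are equally interesting. Classification then separates
what calling sees from what the residuals support: an edge called in
only one background is "specific", but counts as a significant gain or
loss only when also flagged — near-threshold flips without residual
support are expected whenever a weak interaction sits near $t$ in both
backgrounds.

## The synthetic generator

`screen_truth()` fixes the study conditions: 24 proteins in two
complexes (15 + 9, mirroring a nuclear-pore-sized and an
RNA-polymerase-sized complex), species B missing 1 MATa and 7 MATα
strains (so the full design holds 1927 crosses), 40 true within-complex
edges with strengths drawn uniformly from 0.6–2.0 log10 units above a
background of $\beta_0 = 1.0$, replicate noise $\sigma = 0.1$ log10
units, and 2 bait-side strains biased by −0.4 log10 units. Colony sizes
are $\mathrm{round}(10^{\text{signal}})$ pixels. Where the assay itself
fixes no value (noise level, number of biased strains), these defaults
are one-time choices of a plausible screen regime — noise at the level
that reproduces replicate correlations of ~0.95–0.97, biases on the
bait side because that is the side whose strains differ in the
species-vs-hybrid comparisons the correction targets.

Simulated screens are generated on one common reference scale with no
plate effects, so their `normalized_size` equals `raw_size`; the plate
normalization path is exercised separately on rendered images, where
`render_plates()` draws each colony as a filled disk of nearest
achievable pixel area (rasterization error at most $4\lceil r\rceil + 4$
pixels).

What the generator does **not** emulate: spatial plate artefacts
(edge/gradient effects), colony-size saturation and nutrient
competition, non-Gaussian outliers (contamination, pinning failures),
correlated noise between neighbouring positions, and biases that differ
between backgrounds for the same strain. Tests passing on synthetic
screens therefore validate the estimators under the stated model, not
robustness to every laboratory failure mode.

## Numerical choices and degenerate inputs

* Flat (all-background) images threshold to "nothing above", giving
  size 0 everywhere; all-zero plates are an error at normalization.
* A pooled residual set smaller than 10 is refused rather than
  standardized.
* A numerically zero residual SD (identical backgrounds) yields zero
  standardized residuals, not division by machine noise.
* Constant replicate vectors make the Pearson correlation undefined;
  they are reported as `NA` with a warning, not silently dropped.
* Ties in calling are broken by the strict inequality `SI > t`: a pair
  exactly at the maximum SA value is not called.
* Problem sizes in the test suite (24-protein screens, 50-seed
  correction runs, 6-seed calibration pools) were chosen as the smallest
  sizes at which the stochastic properties under test are stable.

## Divergence-profile conventions

Pairwise divergence excludes columns with a gap in either sequence from
numerator and denominator; lineage-specific calls additionally require
all taxa gap-free in the column, so indels never masquerade as
substitutions. With only two outgroup taxa, a change shared by both
non-focal lineages is indistinguishable from a focal change and will be
attributed to the focal lineage; the generator therefore plants "shared"
changes as focal-plus-one-other, which the caller correctly rejects.
The polar set {R, N, D, C, Q, E, G, H, K, S, T, Y} vs nonpolar
{A, I, L, M, F, P, W, V} is the conventional partition and is
configurable. Domain coordinates are 1-based inclusive on the ungapped
reference sequence; window profiles truncate at sequence ends and divide
by the truncated width.

## Known limitations

* The max-SA threshold is sensitive to a single contaminated
  among-complex cross; with real data the SA pool should be inspected
  before trusting $t$.
* The normal bounds on pooled residuals assume approximate normality;
  use `method = "empirical"` when the pool is heavy-tailed.
* The mean-shift correction assumes the bias is a level effect; a
  strain whose bias scales with signal would need the slope variant.
* Comparability masking excludes pairs with missing strains from
  shared/specific accounting; no imputation is attempted.
```{r session}
sessionInfo()
```
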