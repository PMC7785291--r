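---
title: "Methods: enrichment scoring and imaging statistics for dynein-assembly organelles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment scoring and imaging statistics for dynein-assembly organelles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynapstats)
```

Multiciliated cells pre-assemble their axonemal dynein motors in
cytoplasmic, liquid-like organelles (DynAPs) before deploying them to
cilia. Studies of these organelles lean on three quantitative readouts:
affinity-purification mass-spectrometry (APMS) of tagged dynein subunits
scored by spectral counts against a GFP-only control; fluorescence recovery
after photobleaching (FRAP) to measure molecular exchange in and out of the
organelle; and two-channel confocal imaging quantified by Pearson
colocalization within organelle masks and by intensity profiles along the
normalized axoneme length. `dynapstats` implements all three, together with
a synthetic-data module that generates every input with known ground truth.

## Spectral-count enrichment model

One APMS experiment compares a bait pulldown ("expt") with a parallel
GFP-only pulldown ("ctrl") from the same clutch of embryos. After upstream
PSM assignment, the data reduce to per-protein spectral counts. Because the
*Xenopus laevis* proteome contains homeologous near-duplicates, proteins
are first collapsed into vertebrate-level orthology groups by summing PSMs
within each `(run, group)` (`collapse_to_groups()`; the mapping is consumed
as a table, never rebuilt). Replicate runs are pooled by summing counts
(`combine_runs()`); the statistical universe is the union of groups with at
least one PSM on either side, so every group has data and the count pair is
well defined.

For group $i$ out of $n$ groups, with per-side totals
$T_e = \sum_j \mathrm{PSM}_{j,expt}$ and $T_c$:

* **Fold-change** (pseudocounted, compositional):
  $$FC_i = \log_2\frac{(\mathrm{PSM}_{i,expt}+1)\,/\sum_j(\mathrm{PSM}_{j,expt}+1)}
  {(\mathrm{PSM}_{i,ctrl}+1)\,/\sum_k(\mathrm{PSM}_{k,ctrl}+1)}$$
  The +1 pseudocounts keep every value finite, including for groups seen on
  only one side.
* **Z statistic** (raw frequencies, no pseudocounts): with
  $f_i = \mathrm{PSM}_i/T$ per side and pooled frequency
  $f_{i,comb} = (\mathrm{PSM}_{i,expt}+\mathrm{PSM}_{i,ctrl})/(T_e+T_c)$,
  $$Z_i = \frac{f_{i,expt}-f_{i,ctrl}}
  {\sqrt{f_{i,comb}(1-f_{i,comb})/T_e+f_{i,comb}(1-f_{i,comb})/T_c}}.$$
  The deliberate asymmetry — pseudocounts in $FC$ but not in $Z$ — follows
  the standard spectral-count scoring convention this package reproduces.
  When $f_{i,comb}\in\{0,1\}$ the statistic is undefined; we set $Z=0$ and
  $p=1$, the conservative convention (this occurs only in a single-group
  universe).
* **p-value**: one-sided upper tail, $p_i = 1-\Phi(Z_i)$, since the
  question is enrichment in the bait pulldown, not depletion.
* **FDR**: Benjamini–Hochberg step-up across the groups of one experiment
  (delegated to `stats::p.adjust`).

`score_experiment()` composes these, ranks by $Z$ (ties broken by
fold-change, then group id, for fully deterministic output), flags the
bait's own group (retained as a positive control rather than removed), and
calls significance at $z \ge 1.645$, the one-sided standard-normal 95%
critical value. FDR is reported alongside but is not the default gate,
matching the practice of gating visualization on the Z threshold. Both
columns are written by `write_results()`, so users can filter on either.

Design choices made where the procedure was genuinely open:

* *Universe definition.* "Proteins considered" is taken as the union of
  groups observed in the pooled bait or pooled control runs — the largest
  set with any data. Groups absent from both sides carry no information and
  are excluded.
* *Replicate pooling.* Replicates are summed before any statistic is
  computed, treating the comparison as a single expt-vs-ctrl contrast; this
  matches designs with one bait run against two pooled control runs.
* *Edge export.* For spoke-diagram visualization, each significant non-bait
  prey becomes one bait–prey edge weighted by its log2 fold-change.

## FRAP model

A FRAP record consists of frame times, the bleached ROI intensity, an
unbleached reference intensity, and the index of the first post-bleach
frame (frames during the bleach pulse are excluded; the pulse itself is not
modeled). Processing is the standard double normalization: divide ROI by
reference frame-by-frame (removing shared acquisition photobleaching), then
scale so the pre-bleach mean is exactly 1.

Recovery is fit by least squares to a single exponential
$$I(t) = F + (P-F)\left(1-e^{-k\,(t-t_{bleach})}\right),$$
with the post-bleach floor $F$ fixed at the first post-bleach value and the
plateau $P$ and rate $k$ free — the model used by the common ImageJ FRAP
analysis scripts this pipeline mirrors. Derived quantities are the
half-time $t_{1/2}=\ln 2/k$ (an exact identity of every returned fit) and
the mobile fraction $M=(P-F)/(1-F)$, clamped to $[0,1]$. Fitting uses
Levenberg–Marquardt (`minpack.lm::nlsLM`) with deterministic
initialization: $k_0$ is the reciprocal of the time to half of the apparent
recovery and $P_0$ the mean of the last 10% of frames, with $k$ bounded to
$(10^{-4}, 10^3)\,\mathrm{s}^{-1}$ and a small fixed grid of rescaled $k_0$
retries before a diagnostic error. A post-bleach segment with zero variance
short-circuits to $M=0$ with an undefined rate (`NA`) rather than reporting
a spurious time constant. Traces are fit individually; curves can be
averaged afterwards if desired.

## Colocalization and axoneme profiles

Colocalization of two fluorescent labels is quantified per z-section as the
sample Pearson correlation of the two channels over the pixels of an
organelle ROI mask (`pearson_in_mask()`), and aggregated per cell as the
unweighted mean across usable sections (`cell_colocalization()`). Sections
whose mask holds fewer than two pixels or a zero-variance channel are
skipped and counted. Masks may be supplied (e.g. drawn elsewhere) or derived
automatically from the reference (red) channel by Otsu thresholding —
manual ROI drawing is not reproducible in code, so automation is the
documented default. Plain Pearson is used deliberately: no Costes
randomization and no Manders coefficients, because the target readout is a
Pearson R. Pooling pixels across sections before correlating is a
reasonable alternative aggregation; per-section averaging was chosen and is
the only mode implemented.

Axoneme quantification samples intensity along a user-traced polyline at
1-pixel arc-length steps, averaging across a 3-pixel perpendicular width
with bilinear interpolation on 0-based pixel centers
(`sample_profile()`), then forms the pointwise ratio of the signal channel
to a co-expressed membrane reference channel sampled along the same line
(`normalize_profile()`). The ratio interpretation of "normalizing against
membrane-RFP" is a pointwise division, not a global rescaling; the choice
is localized in one function so it can be swapped. No background
subtraction is applied before the ratio; the reference floor check guards
against dividing by background instead.

## Synthetic data: what it emulates and what it does not

`simulate_psm_experiment()` draws each run as a multinomial sample of fixed
depth over the group universe: control runs from background binding
propensities $w$, bait runs from $w$ re-weighted by the configured
enrichment factors. Fixed-depth (multinomial rather than Poisson) sampling
was chosen because conditioning on the total mirrors the compositional
normalization in the fold-change. Background abundances default to a
log-uniform distribution over two orders of magnitude, reflecting the wide
dynamic range of spectral counts. The generator captures sampling noise and
compositional competition; it does not emulate peptide-level effects
(protein length, detectability, shared peptides) or run-to-run batch
effects, so passing tests demonstrate the statistics are correctly
computed and calibrated under multinomial sampling — not that real
pulldowns satisfy those assumptions.

`simulate_frap_trace()` generates the exact single-exponential recovery
with a multiplicative acquisition-bleaching decay $e^{-bt}$ applied to both
recorded channels (default $b = 0.005\,\mathrm{s}^{-1}$, a modest ~25% loss
over a 60-s acquisition) plus additive Gaussian noise on both, at the
default acquisition geometry of 300 frames at 0.20-s intervals with a
10-frame baseline and an 80% bleach depth.

`simulate_foci_pair()` builds two-channel sections of Gaussian-blob foci.
Within each focus the two channels occupy lobes displaced to opposite sides
of the focus centre; the displacement shrinks linearly with the `overlap`
parameter, so `overlap = 1` gives identical sub-regions and `overlap = 0`
fully partitioned ones. Two generator constants — the maximal lobe
separation (3.2 px at lobe sigma 3 px) and the additive noise (sd 24 at
amplitude 200) — were calibrated once, before being frozen, so that the
per-cell Pearson R lands near the two empirical anchor values for full
(≈0.85) and partitioned (≈0.45) sub-structure overlap under default
settings. Sections are independent 2-D images (the analysis is
per-section); no microscope PSF or z-correlation is simulated.

`simulate_axoneme_image()` draws a straight horizontal axoneme with a
Gaussian cross-section (sigma 1.5 px), a uniform membrane-reference channel
along the full length, and a signal channel present only over the proximal
fraction of the length with a ~1-px logistic edge — emulating the
proximally restricted outer-dynein-arm signal seen after assembly-factor
knockdown.

All generators are bit-reproducible given their `seed` argument (seeding is
scoped with `withr::with_seed`, so the caller's RNG state is untouched).

## Numerical choices and problem sizes

* Results tables serialize real columns in scientific notation with six
  decimal digits, making round trips accurate to better than $10^{-6}$
  relative while keeping diffs stable.
* The test suite verifies the enrichment statistics against independent
  brute-force transcriptions on the complete enumeration of universes with
  up to 4 groups and per-side totals up to 12 (about 2.7 million
  universes), checks type-I-error calibration on 1,000 simulated null
  pulldown pairs of 200 groups at depth 10,000 (200,000 tests), bait
  recovery on 200 simulated pulldowns at depth 5,000 with 50-fold bait
  enrichment, FRAP parameter recovery on 100 noisy traces, and
  colocalization monotonicity across five overlap levels with 20 seeds
  each. These sizes keep Monte-Carlo standard errors well below the margins
  being asserted.
* Degenerate inputs are errors, not warnings: zero reference intensity in a
  FRAP trace, constant images under Otsu, zero-variance channels under a
  mask, conflicting orthogroup assignments, and non-integer or negative
  PSM counts all abort with messages naming the offending input.

## Known limitations

* The enrichment Z test treats pooled PSM counts as multinomial draws;
  overdispersion between biological replicates is not modeled (replicates
  are summed, not tested for consistency).
* The single-exponential FRAP model cannot represent two-component
  exchange; traces with distinctly biphasic recovery will fit the dominant
  component with inflated residuals.
* Line profiles assume the traced polyline stays on the axoneme; no
  automatic centerline extraction is provided.
* The foci generator's `overlap` scale is calibrated for the default
  geometry; changing lobe separation, radius, amplitude or noise rescales
  what a given `overlap` value means in Pearson terms.

## A worked example

```{r example}
sim <- simulate_psm_experiment(n_groups = 100, bait_enrichment = 50,
                               prey_enrichments = c(g042 = 12),
                               depth_expt = 5000, depth_ctrl = 5000,
                               seed = 7)
scores <- score_experiment(sim$psm, NULL, sim$pairing,
                           bait_label = "bait", bait_group_id = "g001")
glance(scores)
head(tidy(scores), 3)
```

The bait ranks first and the planted prey is recovered among the
significant groups; `autoplot(scores)` draws the corresponding
volcano-style view.
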