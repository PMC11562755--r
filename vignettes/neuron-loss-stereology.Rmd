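---
title: "Stereological quantification of DRG neuron loss: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereological quantification of DRG neuron loss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgstereo)
```

## The problem

Peripheral nerve injury kills a fraction of the sensory neurons whose axons
were cut, and the loss is biased toward small-diameter, nonpeptidergic
nociceptors. Quantifying this from histology is harder than it sounds:
counting labelled profiles in tissue sections over-counts large cells,
density is a misleading readout when the whole ganglion shrinks, and
subpopulation markers are transcriptionally downregulated after axotomy, so
naive marker counting confounds death with silencing. The workflow this
package implements answers those problems with design-based stereology
(an optical-dissector counting rule plus Cavalieri volume estimation),
distribution-level comparison of soma sizes, co-labelling proportions
against a retrograde tracer, and a cleared-tissue nuclear-volume pipeline —
together with a synthetic ganglion generator that provides known ground
truth for every one of those stages.

`drgstereo` is a simulation-first toolkit: every estimator can be run
against populations whose true size, composition and loss dynamics are
known exactly, so bias and variance are measurable rather than assumed.
The same functions accept equivalently structured tables derived from real
microscopy exports.

## The synthetic ganglion

A ganglion is an axis-aligned ellipsoid (default semi-axes 250 x 200 x 350
µm) containing `n` neurons (default 8000, the scale of a mouse L4 DRG)
placed uniformly at random. Each neuron gets:

* a **subpopulation** by multinomial draw. The default composition is
  30% Mrgprd+ nonpeptidergic, 30% CGRP+ peptidergic, 8% Trpm8+, 25%
  myelinated (Thy1-sampled) and 7% other.
* a **maximal soma cross-sectional area** from a lognormal moment-matched
  to the subpopulation's (mean, SD). Mrgprd somata use 361 +/- 138 µm²;
  myelinated afferents are larger (700 +/- 250 µm²). The lognormal gives
  the right-skewed, strictly positive size histograms characteristic of
  DRG somata. The soma is a sphere of radius `sqrt(area/pi)`.
* a **concentric spherical nucleus** with radius 0.45 x soma radius.
  Closed-form sphere-plane intersections make every downstream measurement
  analytically checkable.
* a **peripheral territory** (tibial 0.35 / peroneal 0.45 / sural 0.20).
  These fractions are not published quantities; they were chosen once so
  that spared nerve injury (which cuts the tibial and peroneal branches and
  spares the sural) axotomizes 80% of the ganglion, and they are
  configurable in every scenario file.

Somata are allowed to overlap (Poisson placement). All implemented
estimators operate per neuron, so overlap biases nothing; packing geometry
is deliberately not modelled.

**Injury** flags neurons in the axotomized territories and assigns each a
single survival quantile; a neuron is alive at day `d` if its quantile is
below its subpopulation's scheduled survival fraction at `d`. One draw per
neuron makes survivor sets nested over time by construction, and death is
instantaneous removal — the measurements model presence/absence, not dying
intermediates. Schedules are piecewise-linear in time and must be
non-increasing.

**Labelling** is independent Bernoulli per neuron: probability
`sensitivity` for members of the label's target set (a marker-defined
class, the axotomized or intact set, or a tracer territory), otherwise
`false_positive`. The shipped injury-reporter label uses 99.1% sensitivity
on axotomized neurons and a 4.6% false-positive rate, modelled as
independent leak; the FastBlue tracer labels tibial-territory neurons with
probability 0.97 irrespective of soma size.

### Scenario calibration

Scenario files (YAML, under `inst/extdata/scenarios/`) hold every
paper-derived default; code contains no scenario constants. Two designs
ship:

* `atf3_whole_drg` — whole-ganglion injury reporting. Subpopulation
  survival schedules are composition-weighted so whole-DRG axotomized
  survival is 1.00 / 0.45 / 0.41 / 0.39 at 7 / 14 / 28 / 56 days: a ~61%
  loss of reporter-positive neurons between weeks 1 and 8, concentrated in
  the small-diameter classes (Mrgprd survival 0.05 at 8 weeks, myelinated
  0.95). The weighting reproduces both the whole-DRG time course and the
  rightward shift of the surviving injured population's size distribution.
* `mrgd_fb_trans`, `mrgd_fb_crush`, `trpm8_fb`, `calca_fb`, `thy1_fb` —
  two-class tracer/co-labelling designs. Each is calibrated from a pair of
  proportions: the contralateral share `p_contra` of tracer-labelled
  neurons carrying the marker, and the ipsilateral share `p_ipsi` after
  injury. `calibrate_survival_ratio(p_contra, p_ipsi)` returns the odds
  ratio `rho = odds(p_ipsi)/odds(p_contra)`; simulating marker survival
  `s * rho` against non-marker survival `s` then yields `p_ipsi` among
  survivors for *any* base survival `s` — the observable proportion is
  invariant to `s`, so the non-marker 28-day survival (0.50) is a free
  realism choice. `rho` is recomputed from the proportions at load time,
  never stored. Each scenario is calibrated independently because the
  underlying experiments use different mouse lines; no single composition
  satisfies all printed proportions at once.

## Virtual sectioning and z-stacks

Cryosectioning is modelled in processed-tissue space: neuron z-coordinates
are rescaled by an axial shrinkage factor (default 0.85) before cutting.
Somata remain spheres — a documented simplification; counts are invariant
to it and all volumes are *apparent* volumes, which is also how the bench
protocol treats them (thickness is measured without optical correction and
never converted back).

Sections are half-open intervals `[z_lo, z_hi)` of nominal thickness 30 µm
tiling the tissue with a random phase offset uniform in `[0, thickness)` —
systematic uniform-random sampling, which is what makes the Cavalieri
estimator unbiased. A nucleus center exactly on a cut belongs to the
lower-index section; ties are impossible by construction. Sections go
serially onto 5 slides (`slide = index mod 5`) and one slide is chosen at
random for analysis, giving 4-5 analyzed sections from a default ganglion.

Each section's confocal stack has planes on the grid `z_lo + k * dz`
(default `dz` = 3 µm, configurable in the 2-3 µm range), from the upper cut
surface down to the deepest grid plane at or above the lower surface. When
the thickness is a multiple of `dz` the bottom frame lies *on* the lower
surface, so consecutive stacks share that physical level. This full-depth
grid matters: if stacks stopped strictly short of the lower surface, every
section would carry a `dz`-thick blind gap and the dissector would
systematically miss ~`dz/thickness` (10%) of nuclei. With the shared
boundary plane, a nucleus spanning a cut is visible in the top frame of the
lower section (hence excluded there) and at the bottom frame of the upper
section (hence counted there): each nucleus is counted exactly once, which
the test suite verifies against a brute-force per-nucleus oracle. Nuclei
smaller than the plane spacing could still fall between planes; at the
default geometry (nucleus diameters ~7-13 µm vs `dz` = 3 µm) this cannot
happen.

Two measurements are attached to each section, and both deliberately refer
to the **cell-containing** part of the section — the overlap of the section
with the tissue — because that is what the bench rules themselves measure:

* **Measured thickness**: the mean of the thickest and thinnest
  cell-containing readings, under multiplicative uniform local noise
  (default +/-10%). For interior sections this is the nominal thickness up
  to noise; for an end section it is the depth of tissue actually in it.
* **Cell-containing area**: the analytic ellipse cross-section
  `pi * a_x * a_y * (1 - (z_m/a_z)^2)` at the middle optical section of the
  cell-containing series (the grid plane nearest the center of the
  tissue-overlap, not of the wax).

End slivers with less than half a section's depth in tissue are not
collected at all (`min_cell_fraction = 0.5`): a rim of tissue thinner than
half the block advance is not recognizable or mountable as a ganglion
section. This matters quantitatively: if such slivers are admitted with
their near-zero midplane areas, the per-section density `N_sec/(t*a)`
occasionally explodes (observed 4-30x outliers), destroying the estimator's
variance; excluding them removes less than 0.1% of the tissue volume.

## The stereological estimators

Per analyzed section: `V_sec = t * a` and `N_v = N_sec / V_sec`, where
`N_sec` is the optical-dissector count — distinct neurons whose nucleus is
visible on at least one plane but **not** in the top frame, each counted at
most once. Densities are averaged across the analyzed sections
(`N_v_bar`); the pooled alternative `sum(N_sec)/sum(V_sec)` is available
(`pooled = TRUE`) but off by default, matching the per-section-then-average
presentation of the bench method.

The ganglion volume uses the Cavalieri principle,
`V_DRG = a_bar * t_bar * l`, with `l` the **dimensionless count** of
sections collected across all slides — the product only has volume units if
`l` is a count, and "collected" means sections showing a cell-containing
region at their midplane. Under that definition `t * sum(a_i)` is exactly
the midpoint systematic-sampling estimate of the ellipsoid volume, which is
unbiased under the random phase; admitting empty-midplane sections into `l`
while excluding them from `a_bar` would inflate the product by their ratio.

Finally `N_DRG = N_v_bar * V_DRG`. At the default configuration the
package's test suite demonstrates a mean recovery ratio of 0.99 with a
per-replicate CV of ~9% over 200 simulated ganglia, invariance of counts to
axial shrinkage (0.6-1.0), and exact x8 volume scaling under doubled linear
dimensions.

Sections excluded for missing cell-containing regions reduce the analyzed
set; partial end-sections that are collected contribute their (genuinely
smaller) measured thickness and midplane area like any other section.

## Size distributions, proportions, spots

**Soma sizes.** A neuron's measured size is its largest optical-section
profile, `max over planes of pi*(r^2 - (z - z_c)^2)`, sampled only for
neurons with a visible nucleus on the analyzed slide. Distributions are
compared with a two-sample Kolmogorov-Smirnov test whose `D` is computed
exactly by scanning ECDF differences at the pooled order statistics (exact
under ties). The p-value uses the asymptotic Kolmogorov distribution with
effective size `n_x*n_y/(n_x+n_y)` — the convention of mainstream software
at these sample sizes (null rejection rate 0.044 at n = 200/200 in the
suite's calibration) — with a seeded permutation alternative for small
samples. Samples are pooled across simulated animals, reproducing the
pooled-neurons (pseudo-replicated) comparison design of the original
analyses; this is deliberate mimicry, not an endorsement, and a per-animal
stratified path is available by calling the test per animal.

**Co-labelling proportions.** Reference cells (e.g. FastBlue-positive with
a visible nucleus anywhere in the section — no top-frame exclusion and no
stereological correction, by design) are enumerated blind to the marker
channel; `colabel_proportion()` preserves those two-pass semantics, and the
suite checks that shuffling the marker column cannot change reference
counts. Per-animal percentages feed `summarize_groups()` (mean +/- SEM,
paired deltas). One systematic effect deserves note: profile-based sampling
sees a neuron in proportion to its nuclear diameter, so classes with
smaller nuclei are slightly under-represented (simulated contralateral
Mrgprd share ~14.3% against a ground-truth 15%). The bench protocol's
stated rationale — similar nuclear sizes across classes — holds only
approximately here because nuclei scale with somata; the effect is well
inside the tolerances of every calibrated readout.

**Cleared-tissue spots.** Imaris-style spot tables are filtered with strict
bounds (volume < 5 µm³ or > 2000 µm³ removed; boundary values pass, per the
verbatim filter definition) and binned with inclusive upper bounds (small
<= 258 µm³ < medium <= 400 µm³ < large), 258 being stated as an *upper
bound* of identified small nuclei and 400 a distribution midpoint. Both
boundary conventions are configurable. A realism caveat: with the fixed
nucleus:soma ratio of 0.45, simulated Mrgprd nuclear volumes (~400 µm³)
sit above the empirical 258 µm³ small-nucleus bound — nuclear allometry in
real DRG is weaker than proportional. Spot binning is therefore validated
against brute-force oracles, not against the empirical bin occupancies.

## The statistical toolkit

The inference functions mirror the analyses the quantification feeds:
paired t tests, one-way ANOVA with Tukey HSD, and a two-way mixed
(split-plot) repeated-measures ANOVA decomposed by explicit least squares —
between-subjects effects tested against the subject-within-group stratum,
within and interaction effects against the within-subjects error.
Sphericity is assumed (uncorrected RM ANOVA, as reported in this
literature). Unbalanced between-group sizes use unweighted-means (Type
III-equivalent) sums of squares and are flagged; incomplete within-subject
data is refused rather than imputed. Every F and p is checked in the test
suite against `stats::aov` with an `Error(subject)` stratum on randomized
balanced designs, and zero-SS effects report F = 0 by convention. Posttest
families are declared, never inferred: Tukey over between-group means, or
Sidak (`p_adj = 1 - (1-p)^m`) over an explicit comparison list with a
declared family size, using the pooled between-at-within error with
Satterthwaite df.

Normality gating uses Shapiro-Wilk (Royston's approximation, n 3-5000).
Power analysis assumes a two-sided two-sample t test: the smallest integer
`n >= 2` with noncentral-t power (noncentrality `d*sqrt(n/2)`, df `2n-2`)
at or above the target. The test family is a modelling choice — the
original calculation names only software and an effect size of 4.81 — and
this choice reproduces the published group size of 3 at that effect size
(and the classical n = 17 at d = 1).

## Numerical choices and reproducibility

* Problem sizes: ganglia of 8000 neurons; calibrated readouts use 20 seeds;
  the unbiasedness suite uses 200 replicates; null calibrations use 2000
  replicates at n = 200 (KS) and n = 20 (Shapiro-Wilk). These sizes put
  Monte-Carlo error comfortably inside every stated tolerance.
* All randomness flows from explicit integer seeds; stages derive
  independent child seeds (`derive_seed`) so that, e.g., relabelling does
  not perturb placement. Identical `(config, seed)` reproduces ganglia,
  section series and scenario summaries bit-for-bit, and every scenario
  output embeds a configuration hash and the package version.
* Strict inequalities define profile visibility (`|z - z_c| < r`); a plane
  tangent to a sphere sees nothing, and a midplane at the pole has zero
  area without warning (the section outside the tissue warns).
* Survival schedules are linearly interpolated between scheduled days and
  held constant beyond the last day.

## What passing the simulations does and does not show

The generator reproduces the statistical structure the estimators rely on:
uniform placement in a convex volume, right-skewed class-specific size
distributions, subpopulation-biased loss with a 1-8 week time course,
imperfect reporters and a territory-restricted tracer, shrinkage,
serial 1-in-5 collection and discrete optical planes. It does not model
non-neuronal expansion after injury, vascular or satellite structures,
irregular ganglion shape, anisotropic somata, optical blur or
depth-dependent detection loss. Passing tests therefore certify the
*estimators* — their bias, variance and boundary behavior under known
truth — not the biology of any particular dataset; on real images,
segmentation quality and the blunt, irregular shape of an actual ganglion
will dominate the residual error budget.
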