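---
title: "Meta-analytic homotopic connectivity: model, estimator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic homotopic connectivity: model, estimator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homokappa)
```

## The problem

Homotopic connectivity (HC) is the functional coupling between a brain
region and its mirror twin in the opposite hemisphere. From resting-state
fMRI it is usually measured with voxel-mirrored homotopic connectivity
(VMHC): the Pearson correlation between each voxel's BOLD time series and
that of its mirror voxel across the midsagittal plane, Fisher
z-transformed and averaged over subjects. `homokappa` implements a
*meta-analytic* counterpart (MHC): instead of time series it consumes a
corpus of published activation peak coordinates ("foci"), asks how often
mirror-region pairs are *co-activated* across experiments, and scores each
homotopic pair with Patel's kappa. The package also ships the machinery to
compare an MHC map against a VMHC map voxel by voxel.

## From foci to an activation matrix

**Modeled activation (MA).** Each experiment contributes a set of foci in
stereotaxic space (Talairach or MNI; MNI collections are converted with
the pluggable icbm2tal affine constant sets in `icbm_transform()`). Around
every focus an isotropic 3-D Gaussian probability kernel is placed:

$$g(d) = \frac{V_{\text{voxel}}}{(2\pi)^{3/2}\sigma^3}
  \exp\!\left(-\frac{d^2}{2\sigma^2}\right),
  \qquad \sigma = \frac{\mathrm{FWHM}}{\sqrt{8\ln 2}},$$

where $d$ is the focus-to-voxel distance in mm. Foci of one experiment
combine by probabilistic union, $MA = 1 - \prod_f (1 - g_f)$, so MA values
stay in $[0, 1)$; the same union across experiments gives an ALE map. The
default FWHM of 10 mm gives a Gaussian cloud whose effective extent is
about 12 mm around the focus, the typical spatial uncertainty of
coordinate-based meta-analytic data; a subject-count-based per-experiment
FWHM can be substituted by passing a different `kernel_spec()` per call.
Kernels are truncated at 5$\sigma$, which changes no value by more than
$10^{-5}$ of the peak (checked numerically in the test suite) and bounds
the cost of map construction.

**Midline offset adjustment.** A focus near the midline spreads modeled
activation into the opposite hemisphere, which would fabricate
co-activation of midline pairs. Within a 24-mm band along the midline
(half-width 12 mm), the contribution of a focus to voxels in the *opposite*
hemisphere is attenuated by a weight $w(|x|)$ that is 0 on the midline and
reaches 1 at the band edge. The attenuation's exact functional form is a
genuinely open design point: we default to the linear ramp
$w = |x|/12$ and also ship an inverse-distance mode
$w(d) = (1/\varepsilon - 1/d)\,/\,(1/\varepsilon - 1/12)$ (clamped to
$[0,1]$, $\varepsilon = 1$ mm), an affine function of $1/d$ that still
satisfies $w(12) = 1$ and monotonicity — a raw $1 - c/d$ form cannot reach
1 at the band edge. The adjustment is applied per focus at the MA level,
before any region aggregation, because that is where cross-hemisphere
leakage arises. The mode in use is recorded in provenance.

**The 20 % rule.** Given a symmetric parcellation, experiment $e$
activates region $r$ when at least a fraction $t$ (default 0.20, boundary
inclusive) of $r$'s voxels are MA-significant. "Significant" defaults to
*any positive MA under the truncated kernel* — the simplest predicate
under which the 0 % threshold variant ("a single active voxel drives the
region") is meaningful; an absolute MA cutoff is available via
`sig_cutoff`. Stacking experiments yields the binary N x M activation
matrix.

## Patel's kappa

For a homotopic pair $(a, b)$ the four joint activation states have
probabilities $\theta_1 = P(a{=}1, b{=}1)$, $\theta_2 = P(a{=}1, b{=}0)$,
$\theta_3 = P(a{=}0, b{=}1)$, $\theta_4 = P(a{=}0, b{=}0)$, estimated from
the matrix columns. With $E = (\theta_1{+}\theta_2)(\theta_1{+}\theta_3)$
the expected co-activation under independence,

$$\kappa = \frac{\theta_1 - E}
  {D\,(\max(\theta_1) - E) + (1 - D)\,(E - \min(\theta_1))},$$

where $\max(\theta_1) = \min(\theta_1{+}\theta_2,\,\theta_1{+}\theta_3)$,
$\min(\theta_1) = \max(0,\, 2\theta_1{+}\theta_2{+}\theta_3-1)$ and
$D = 1\{\theta_1 \ge E\}$. The denominator is the attainable range of
$\theta_1$ on the relevant side of independence, so $\kappa \in [-1, 1]$,
with 1 at maximal attainable co-activation, 0 at exact independence and
$-1$ at maximal avoidance. When a region is never or always active the
range collapses and kappa is undefined: the package returns a flagged
`NA`, never 0, because 0 means independence rather than "unestimable".

**Significance.** Under a flat prior the posterior of
$(\theta_1..\theta_4)$ is Dirichlet(counts + 1). `kappa_significance()`
draws `n_mc` samples (default 10 000), computes kappa per draw, and
reports $P(\kappa > e \mid \text{data})$; a pair is significant when that
probability reaches the credibility level (default 0.95, $e = 0$). All
draws are seeded and reproducible; degenerate draws are skipped and
counted, and a result with more than half skipped is flagged unreliable.

## Parcellations

The reference workflow uses a symmetrized anatomical atlas on a 2-mm
mirror-closed grid (every brain voxel has an exact on-grid mirror; the
midline is the world plane $x = 0$). `symmetrize_atlas()` offers two
policies — *intersection* (a voxel keeps its label only if its mirror
carries the same label; conservative, invents no tissue, the default) and
*left-dominant* (the left hemisphere is mirrored onto the right). The
right choice depends on the atlas in hand, so both are shipped and
the choice is logged in provenance.

As size-bias controls, `homogeneous_parcellation()` rebuilds each region
from equal-size random parcels of exactly *k* voxels (at whole-brain
2-mm scale, k = 997 gives ~128 reasonably large volumes and k = 250 gives
~512 reasonably small ones; the package works at any k >= 8). Parcels are
grown 6-connected by seeded random region growing — contiguous parcels are
the sensible default for a spatial control, but a non-contiguous mode
exists for sensitivity checks. Growth is
boundary-first (seeds and accretions prefer free voxels with the fewest
unassigned neighbours), which lets dense packings complete; remainder
voxels (region size mod k) are merged into an adjacent parcel of the same
region by default — silently dropping tissue would bias coverage — and the
enlarged parcels are reported. Only the left hemisphere is grown; the
partition is mirrored, so homotopic pairs stay voxel-exact.

## The VMHC arm and the comparison machinery

`vmhc()` implements the core: per in-mask voxel, the Pearson correlation
with the mirror voxel's series, $z = \operatorname{atanh}(r)$ with $|r|$
clipped at $1 - 10^{-7}$ (and the clip counted), no smoothing before or
after. Preprocessing (realignment, nuisance regression, symmetric-template
normalisation) is out of scope: the function consumes preprocessed data.
Individual z maps average with `group_average()` (missing values excluded
per voxel, counts tracked). An external VMHC map is co-registered onto the
MHC grid by nearest-neighbour (values are statistics, not intensities).

For comparing the two maps over a shared brain mask:

- `map_correlation()` — the global Pearson r (non-brain voxels excluded);
- `vcc()` — leave-one-voxel-out contribution to correlation: each voxel
  pair is removed and $r$ recomputed via exact sufficient-statistic
  downdating (equal to naive recomputation to $10^{-12}$, property-tested);
  the differences $r_{\text{global}} - r_{-i}$ are then normalized. The
  published method says only "normalized": we z-score over the mask, which
  preserves the sign convention (positive = convergence-driving);
- `difference_map()` — both maps z-scored over the mask (kappa and Fisher
  z live on different scales) and subtracted, MHC minus VMHC;
- `threshold_to_roi()` (strict `> cutoff`, intersectable with manual
  masks) and `domain_enrichment()` — a binomial z against the all-domain
  base rate, $z_d = (k_d - n_d p_0)/\sqrt{n_d p_0 (1-p_0)}$. The exact
  statistic of the proprietary behavioral-analysis service is not public;
  the binomial z reproduces its ranking logic testably and is labelled as
  such.

## Synthetic generators: what they emulate and what they do not

Every estimator stage is validated against generators with known truth:

- `gen_synthetic_atlas()` — mirrored spherical parcels on a deterministic
  lattice; exact pair geometry.
- `gen_coactivation_experiments()` — per experiment and pair, one of the
  four joint states is drawn with probabilities $(\theta_1..\theta_4)$;
  each active region receives foci placed uniformly over its voxel
  centres. This is precisely the Bernoulli model kappa estimates, so
  closed-form $\kappa(\theta)$ is ground truth.
- `gen_rest_timeseries()` — mirror-pair series from a shared Gaussian
  factor plus independent noise, mixing chosen so the pair's population
  correlation equals the planted rho; optional AR(1) temporal structure.

The generators are deliberately idealised: foci are independent across
pairs and uniform within regions, no spatial autocorrelation between
pairs, no hemodynamics, motion or physiological noise, and the co-activation
structure is exactly Bernoulli. Passing tests therefore demonstrate the
*estimator's* correctness and calibration under its own model — not that
real activation corpora satisfy that model. Conclusions about real data
still require the robustness checks (threshold variants, atlas variants)
the package exposes.

## Numerical choices and degenerate inputs

- All computation is double precision; NIfTI storage is float32 (standard
  practice; round-trip error is at float32 eps scale).
- MA/ALE unions are computed in log space (`log1p`/`expm1`) for accuracy
  near 0 and capped strictly below 1.
- Warn if the kernel peak $V_{\text{voxel}}/((2\pi)^{3/2}\sigma^3)$
  reaches 1 (kernel under-resolved for the voxel size).
- Mirror closure is verified (tolerance $10^{-6}$ mm) before any
  mirroring; non-closed grids are rejected with advice to resample.
- Cluster-level ALE inference redraws each experiment's foci uniformly in
  the mask (counts preserved), forms clusters at the pooled
  $1 - p$ score quantile (default $p = 0.001$), and keeps observed
  clusters with empirical max-size p-value $\le \alpha$ (default 0.05,
  1000 permutations — the standard cluster-level defaults).
- Degenerate marginals give flagged `NA` kappa; constant time series give
  `NA` at both pair ends; zero-variance maps refuse to z-score.
- Foci falling outside the grid after space conversion are dropped with a
  logged count (clamping would fabricate peri-surface activation).

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run the full pipeline at sizes a
laptop handles comfortably, chosen once as representative study
conditions: estimator recovery on a 4-mm mirror-closed 14 x 14 x 32 grid
with 8 spherical pairs (radius 6 mm, centres 36 mm apart so inter-region
gaps exceed the truncated kernel radius; FWHM 8 mm; one focus per active
region), 2000 experiments per replicate, 100 replicates per theta;
calibration on 500 independent pairs of 200 experiments with 10 000
posterior draws each; VMHC recovery at T = 2000 on a 2-mm 20^3 grid;
threshold stability on 800 experiments over 6 pairs spanning weak to
strong co-activation, with regions (radius 10 mm) larger than the kernel
extent so that per-focus coverage straddles the 40 % rule and the
threshold variants genuinely differ. Whole-brain atlases at 2 mm run the same code paths
unchanged.

## Known limitations

- MHC is region-based by design (statistical power over spatial detail);
  it inherits the parcellation's resolution and any anatomical
  asymmetries erased by symmetrization.
- The midline adjustment's functional form is a modelling choice; both
  shipped forms agree at the band edges but differ inside the band.
- Kappa is undefined for never/always-active regions — rare at corpus
  scale, common in tiny collections; such pairs are reported, flagged,
  and excluded from maps rather than imputed.
- The behavioral enrichment statistic is a transparent binomial stand-in
  for a proprietary service's statistic, suitable for ranking and
  synthetic validation, not for numerical comparison with that service.
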