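---
title: "Dynamic texture parameter analysis of DSC-MRI time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic texture parameter analysis of DSC-MRI time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtpa)
```

## The problem

Dynamic susceptibility contrast enhanced (DSCE) MRI acquires a rapid EPI
image series while a gadolinium bolus passes the cerebral vasculature. The
contrast agent transiently shortens T2*, darkening perfused tissue; where
the blood–brain barrier is disrupted (enhancing lesions), leaked agent also
shortens T1 and *raises* the late signal above baseline. Classical perfusion
quantification (CBV/CBF/MTT) deconvolves the concentration curves against an
arterial input function and needs explicit pharmacokinetic leakage
correction. This package implements an alternative that avoids any
pharmacokinetic model: it tracks the evolution of *histogram-based texture
statistics* of baseline-difference images through the bolus passage, and
asks whether tissue classes (enhancing lesions EL, non-enhancing lesions
NEL, normal-appearing white matter NAWM) separate in that feature space.

## Pipeline

Given a 4D series $S_k(x)$ ($k$ = time index) the pipeline is:

1. **Coil-load normalization.** All voxel intensities are divided by
   $f = \bar S_0(\mathrm{ref}) / C_\mathrm{ideal}$, where the reference
   region is a user-drawn NAWM contour on the first steady-state image.
   Default $C_\mathrm{ideal} = 100$; the choice cancels from every group
   statistic because all tissues share the factor.
2. **Difference images.** $D_k(x) = S_0(x) - S_k(x)$. Positive values mean
   susceptibility signal drop (agent in the vasculature, intact barrier);
   negative values mean enhancement above baseline (leakage).
3. **Phase segmentation.** The reference-region concentration curve
   $C(t) = -\tfrac{1}{TE}\,\ln\!\big(\bar S_t / \bar S_0\big)$ is smoothed
   with a width-3 moving average; baseline mean $\mu$ and SD $\sigma$ are
   estimated from pre-peak samples below 10% of the maximum; the time of
   arrival (TOA) is the first index above $\mu + 3\sigma$ sustained for two
   samples; the peak is the global maximum; the post-peak minimum is the
   first interior local minimum. These landmarks partition the time axis
   into baseline (BLP), inflow (IFP), outflow (OFP) and reperfusion (RPP)
   periods: $[1,\mathrm{TOA})$, $[\mathrm{TOA}, t_{peak}]$,
   $(t_{peak}, t_{min}]$, $(t_{min}, t_{end}]$ — a half-open scheme chosen
   so the four intervals always partition the axis, which interval
   averaging requires.
4. **Cardiac-output normalization.** The trapezoidal area $A$ under the
   reference-region difference curve over IFP∪OFP is fixed to
   $AUC_\mathrm{ref} = 200$ by dividing the whole difference series by
   $g = A / 200$. Cardiac ejection differences scale the delivered bolus,
   so fixing this area makes interval-averaged difference statistics
   comparable across examinations. The correction is applied to the
   difference series (and everything derived from it); the raw-signal map
   keeps only the coil normalization.
5. **Texture parameter maps (TPMs).** Eight time-resolved maps: the
   coil-normalized raw series (ORIG), the difference series (DIFF), and six
   sliding-kernel maps of DIFF — local mean (AVER), population variance
   (VARI), standard deviation (STDEV), skewness (SKEW), excess kurtosis
   (KURT, zero for Gaussian intensities) and variance-of-variance (VAVA).
6. **TOI statistics.** For every user region and every map, six region
   statistics (mean, stdev, var, vava, skew, kurt) per time point, averaged
   per interval: a 6 × 4 grid per (region, map), i.e. 72 parameter cells
   per map over three tissue classes and 8 × 72 = 576 over the battery.
7. **Group testing.** Per (map, statistic, interval) cell: a one-way ANOVA
   gate at $p < 0.05$, then the three pairwise Wilcoxon rank-sum tests with
   Benjamini–Hochberg correction.

## Kernel texture maps

All kernel maps use **population** (divide-by-$n$) central moments over a
$w \times w$ in-plane neighbourhood, computed exactly via summed-area
tables on globally centred powers (the suite checks agreement with a brute
force per-voxel loop to $10^{-10}$ relative). Kernels never cross slice
boundaries: with 5 mm slices a through-plane neighbourhood would be
strongly anisotropic. The border band of half-width $(w-1)/2$ is marked
invalid rather than padded, and invalid voxels are excluded from region
statistics.

The default kernel is $w = 3$, the smallest meaningful window; $w = 5$ is
exercised in the tests. Larger kernels trade spatial resolution for SNR —
particularly for SKEW and KURT, whose sampling noise at $n = 9$ is large.
This trade-off motivates the kernel-free mode (`direct_toi_texture()`),
which pools all TOI voxels per time point instead of mapping local
statistics.

Two choices deserve justification:

* **VAVA as a second pass.** The local variance is itself a stochastic
  quantity, so it has a variance: VAVA is the local variance *of the VARI
  map*, computed with the same kernel (invalid border of width $w-1$).
  Unlike VARI, this two-pass map is not an edge detector: a sharp edge
  yields a locally constant (high) variance, hence low VAVA. The
  within-kernel closed form $m_4 - m_2^2$ — which is edge-sensitive — is
  available via `vava_mode = "closed_form"`. At the region level (a flat
  set of values with no second spatial pass available) the closed form is
  the natural analogue and is what `region_statistics()` uses.
* **Degeneracy handling.** SKEW and KURT are undefined on near-constant
  neighbourhoods; where $m_2 \le 10^{-12} (\text{dynamic range})^2$ they
  are marked *undetermined*, never zero-filled. Noise-free baseline
  difference images are the canonical case. Undetermined values propagate
  as explicit flags, are dropped from interval averages (with the
  contributing time-point count recorded) and excluded from group tests.

## The statistical battery

The texture parameters are not normally distributed, so the ANOVA is used
only as a liberal gate — a deliberate fidelity-over-optimality choice — and
inference rests on the nonparametric pairwise tests. The Wilcoxon
implementation enumerates all $\binom{n+m}{n}$ assignments of the pooled
mid-ranks when $n + m \le 12$ (a permutation-exact test, valid under ties)
and otherwise uses the normal approximation with tie-corrected variance and
continuity correction. The step-up FDR adjustment defaults to the per-cell
family (the three pairwise tests of one cell), the smallest family
consistent with reporting three adjusted columns per cell; per-map (72
tests) and global (576) scopes are configurable. The count summary reports
the expected false-positive count $576 \times 0.05 = 28.8$ as the yardstick
against which an observed significance count should be judged.

## The synthetic phantom

No public DSCE dataset accompanies this method, so the package ships a
generator whose defaults *are* the study conditions used by the tests and
the acceptance script. Per voxel of tissue $\tau$:

$$S(t, x) = B(x)\,e^{-TE\,c_\tau(t)} + \ell_\tau \int_0^t c_\tau \,dt'
  + \varepsilon(t, x)$$

* Grid 96 × 96, one slice, 40 time points at TE 47 ms / TR 1440 ms (the
  1.5 T protocol timing). Single-slice phantoms mirror the per-slice
  contour analysis of real examinations.
* $B(x)$: baseline 400 (arbitrary units) plus a Gaussian texture field,
  SD 40 (10% spatial heterogeneity) in NAWM/NEL and 80 in EL — enhancing
  lesions carry four times the texture variance.
* $c_\tau(t)$: gamma-variate ($\alpha = 3$, $\beta = 1.5$ time indices,
  peak concentration $7.6\times10^{-3}$ such that $TE \cdot c \approx 0.36$,
  a ~30% peak signal drop) plus a delayed, broader recirculation bump (20%
  amplitude, +10 indices, $\beta$ doubled) that produces the interior
  post-peak minimum the phase detector looks for. EL boluses arrive ~1.4
  indices earlier and 20% stronger (acute hyperperfusion); NEL amplitude is
  75% of NAWM (mild hypoperfusion).
* Leakage: an additive cumulative-uptake term, *not* a pharmacokinetic
  model — only the sign and monotonicity of late enhancement need
  emulating. The EL default $\ell = 500$ makes late enhancement ~10% of
  baseline, enough to dominate the residual susceptibility depression so
  the reperfusion-period difference mean is negative — the defining
  enhancing-lesion signature. More leakage lowers the
  $\Delta$TPM-DIFF = RPP − IFP marker monotonically, which is what lets it
  grade barrier disruption on a continuous scale.
* Noise: additive Gaussian, SD 8 (baseline SNR 50). At this SNR magnitude
  MRI's Rician noise is indistinguishable from Gaussian, and the additive
  form keeps the ground truth analytic.
* Regions: 37 NAWM, 27 EL and 29 NEL disc regions (radius 3, 29 voxels) on
  a regular lattice with classes interleaved, plus a separate 12 × 12 NAWM
  reference square — the same region counts as the study grid the battery
  is designed around.

The null configuration (`phantom_null_config()`) keeps the geometry and
labels but gives every class the NAWM parameters, so any significant test
is a false positive; the suite verifies that the mean raw
significant-test count per 576-test battery stays inside the 99% binomial
band around 28.8.

**What the phantom does not emulate:** anatomy (no gray matter, vessels or
CSF), partial-volume effects, EPI distortion, motion, spatially correlated
noise, and between-region parameter variability within a class (all EL
discs share one parameter set, so between-region spread reflects only the
texture field and noise). Passing tests therefore demonstrate that the
pipeline recovers the designed statistical structure at realistic SNR — not
that the specific significance patterns will reproduce on clinical data.

## Numerical choices and degenerate inputs

* Time indices are 1-based; the baseline index defaults to the first image
  and is configurable for acquisitions with non-steady-state lead-in
  frames.
* The AUC uses the trapezoidal rule at unit (time-index) spacing, endpoints
  inclusive; the normalization divides by the quotient $A/AUC_\mathrm{ref}$
  so the post-condition $A' = AUC_\mathrm{ref}$ holds exactly.
* Phase detection on a flat or never-arriving curve is a hard error ("no
  bolus detected"); if reperfusion never dips, the final time point becomes
  the RPP and the outflow period is shortened by one (with a warning), so
  every interval stays non-empty.
* A concentration curve requires strictly positive region means; zeros are
  a hard error rather than silent clipping.
* Polygon TOIs are rasterised on voxel centers (0-based coordinates) with
  the even-odd rule, boundary-inclusive, so an integer-vertex rectangle
  keeps its corner voxels; the suite checks every voxel against an
  exhaustive point-in-polygon oracle.
* Report files carry 12 significant digits; write → read → write is
  byte-identical, and every configuration value and detected landmark is
  echoed as header lines so a run is reproducible from its outputs.

## Problem sizes used by the test suite

The suite and the acceptance script regenerate everything from code: the
kernel-map oracle comparison uses 50 random 64 × 64 images at $w \in \{3,
5\}$; phase recovery, null calibration and effect recovery each use 100
seeded phantoms at the default study conditions; the monotone-leakage check
uses 10 seeds × 3 leakage levels. These sizes give the rate estimates a
resolution of one percentage point while keeping a full run in the
minutes range on a single core.

## Known limitations

* 2D kernels only; a true 3D neighbourhood would need isotropic voxels.
* The ANOVA gate assumes exchangeable groups and is used despite
  non-normality (by design, see above); at small region counts the gate,
  not the Wilcoxon tests, limits power.
* Only histogram-based textures are implemented — no gradient,
  co-occurrence, run-length, autoregressive or wavelet families.
* No motion correction, registration, or vendor private-tag handling; no
  automatic lesion segmentation (regions are user-supplied).
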