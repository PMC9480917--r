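---
title: "Mapping fingertip tuning with efficiency-optimized event-related designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fingertip tuning with efficiency-optimized event-related designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

## The problem

Somatosensory and motor cortex map the body topographically: adjacent
fingertips activate adjacent patches of cortex. fMRI studies of this
somatotopy have mostly used phase-encoded (cyclic, predictable) stimulation,
which localizes well but cannot characterize each voxel's full tuning
profile, or slow event-related (ER) designs, which can but are statistically
inefficient. This package implements the computational chain needed to do
both jobs with an efficiency-optimized *fast* ER design: sequence generation
and selection, forward simulation of somatotopic BOLD data, the
phase-encoded Fourier analysis, a two-step GLM for fingertip response
estimation, Gaussian population-receptive-field (pRF) fitting, and ROI-level
tuning and cortical-magnification summaries. Every stage runs on simulated
data with known ground truth, so the whole pipeline is testable end to end.

## Stimulation designs

All designs place events on a TR grid (TR = 2 s) in 252-s runs:

* **Fast ER**: 126 consecutive events — 18 stimulation events per fingertip
  plus 36 null events — randomized in six blocks of 21 events, each block
  holding exactly six nulls and three events per fingertip. The mean
  stimulation onset-to-onset interval is 2.8 s.
* **Slow ER**: 30 events (six per fingertip) with onset-to-onset gaps drawn
  uniformly from 4–12 s in 2-s steps (mean 8 s), no immediate fingertip
  repeats. Draws that do not fit in the run are rejected and redrawn, which
  biases the realized mean ITI slightly (~1%) below 8 s.
* **Phase-encoded**: each fingertip stimulated for 4 s in somatotopic order,
  a 20-s cycle repeated nine times, in thumb-to-pinky and pinky-to-thumb
  directions.

Two further fast-ER variants exist for efficiency comparisons: a *fully
randomized* variant (same event multiset shuffled over the whole run) and a
*no-null* variant (the 90 stimulation events on consecutive TRs with the
null events and their scan time removed).

## Design efficiency

For contrast matrices $C_i$ and design matrix $X$, the package scores a
design by the reciprocal of the mean contrast-variance trace,

$$E = \left[\frac{1}{K}\sum_{i=1}^{K} \mathrm{Tr}\!\left(C_i (X^\top X)^{-1}
C_i^\top\right)\right]^{-1},$$

under unit-variance white noise — higher is better. Three summaries are
reported: *detection* (five fingertip-vs-baseline contrasts on the
canonical-HRF design), *HRF estimation* (per-fingertip selection contrasts
on the FIR design), and *difference detection* (the ten pairwise fingertip
contrasts on the canonical design).

Two conventions matter for the absolute scale, and both were design
decisions:

* **Regressors approximate continuous-time convolution integrals.** Events
  are unit-area impulses (indicator × TR), the canonical HRF is normalized
  to unit integral, and FIR regressors are unit-area deltas. With these
  units the FIR-based HRF-estimation efficiency has no free scale at all,
  which pins the convention; the canonical rows then need no further
  calibration factor.
* **A baseline (intercept) column is modelled.** This is what makes the
  no-null variant collapse: with every TR stimulated, the five regressors
  sum to a near-constant that is collinear with the baseline, so individual
  fingertip betas become nearly unidentifiable while pairwise differences —
  insensitive to the common mode — survive. Without an intercept the
  collapse disappears entirely, which is inconsistent with how these
  variants behave in practice. `design_efficiencies(..., intercept =)`
  exposes the switch.

`optimize_fast_er()` draws sequences, scores detection efficiency with a
precomputed Toeplitz convolution operator, and keeps the top *k*. Selecting
the best 20 of 50,000 draws raises mean detection efficiency by roughly a
third over the random-draw mean.

A known limitation: under this (white-noise OLS) efficiency model,
block-randomized and fully randomized fast ER sequences are nearly
equivalent — the balanced 21-event blocks change the mean efficiencies by
only a few percent, and no filtering, autocorrelation weighting, or
normalization variant we examined separates them much further. Reports that
block randomization per se substantially increases detection efficiency are
therefore not reproduced by this implementation; the ordering
selected > random fast > slow and the collapse of the no-null variant are.

## Hemodynamics

The canonical HRF is a difference of gamma densities with modes at 6 s
(response) and 16 s (undershoot) and a 6:1 peak ratio, sampled at the TR
over 40 s. Gamma densities use shape = delay + 1 and scale = 1 s so the mode
lands exactly on the stated delay. The temporal derivative regressor is the
first difference of the sampled HRF — a finite-difference proxy consistent
with the TR grid. Sub-TR stimulus structure is not modelled: events are
TR-locked by design.

## The synthetic patch and forward model

`make_somatotopic_patch()` lays out a 40 × 40 voxel grid with parallel area
bands (BA3b, BA1, BA2, post-BA2 on the "postcentral" side; BA4a, BA6 on the
"precentral" side; background elsewhere; about 600 responsive voxels by
default). Within each band, pRF centers increase linearly along the
somatotopic axis across the full 0.5–5.5 fingertip range; band-mean tuning
widths increase BA3b (0.8) → BA1 (1.5) → BA2 (3) → post-BA2 (20, nearly
flat) and BA4a (1) → BA6 (8), reproducing the narrow-to-broad gradient as
ground truth. Voxelwise sigma gets lognormal jitter (SD 0.15); amplitudes
are Gaussian around 2.5 response units (SD 0.3). In regressor units an
isolated event peaks at ≈ 0.39, so the default amplitude corresponds to a
peak response near 0.97% signal change — the ~1% scale typical of fingertip
stimulation at high field.

`simulate_run()` builds each voxel's clean percent-signal response as
amplitude × Gaussian tuning × the fingertip regressors, adds low-frequency
drift (random discrete-cosine components below 0.01 Hz, coefficient SD 0.5%)
and white noise (default SD 1.5% per TR, a realistic single-voxel level for
1.5-mm voxels), and expresses the result around a baseline of 1000 units.
Noise is white by construction, matching the homoscedastic OLS analysis; no
spatial noise correlation, physiological noise or motion is simulated, so
passing tests demonstrate correctness of the computational chain, not
robustness to every real-data artifact. For phase-encoded runs
`steady_state = TRUE` switches to circular convolution: cyclic stimulation
is observed in steady state, which is also what makes the phase analysis
exact. An optional per-voxel HRF delay jitter (uniform, ± a configurable
number of seconds) exercises the delay-compensation step; it is off by
default. Response nonlinearity (saturation) is deliberately not simulated —
the analysis assumes linearity, and the simulation inverts exactly the
assumptions the analysis makes.

One consequence of the percent-signal-change convention is worth noting:
converting by the run mean divides each voxel by $1 + \bar c/100$, where
$\bar c$ is the voxel's mean clean response over the run (a fraction of a
percent). Noiseless round-trip tests account for this factor; it is the
same, usually ignored, bias present in any %-change analysis.

## Phase-encoded analysis

Forward and reverse runs are combined by circularly shifting the forward
run back $k$ TRs and the reverse run back $k+1$ TRs followed by array
time-reversal, then averaging. Any response delay enters the two directions
with opposite signs and cancels exactly in the averaged phase, so a voxel
preferring fingertip $i$ lands on phase $(2i-1)\pi/5$ — exactly, for any
delay, on noiseless data. The index conventions (reversal mapping sample
$n \mapsto -n-1$, combined index $k-n$) were fixed by requiring this
exactness; the shift $k \in \{1, 2\}$ only keeps the combined amplitude
high (it compensates the integer part of the delay).

Per voxel, the phase and coherence of the 0.05-Hz Fourier component are
computed (coherence = amplitude at the stimulation frequency relative to
the root-sum-square over all nonzero frequencies). Under Gaussian noise,
squared coherence is the $R^2$ of a sine-plus-cosine regression, giving the
F statistic $F = (C^2/2)/((1-C^2)/(n-3))$ with $(2, n-3)$ degrees of
freedom. Familywise error across voxels is controlled with Hochberg's
step-up ("stagewise Bonferroni") procedure; the step-up FDR procedure used
for ER maps is Benjamini–Hochberg. Both call `stats::p.adjust` and are
tested against brute-force implementations of the step-up rules.

Suprathreshold voxels are binned into five $2\pi/5$-wide phase bins centered
on the exact fingertip phases; per bin, 4-connected clusters are extracted
and the largest is kept if the cluster centroids progress monotonically
along the somatotopic axis (out-of-order clusters are dropped, mirroring
the exclusion of isolated out-of-order representations).

## Two-step GLM

Step one deconvolves each voxel's response with a 20-point FIR basis per
fingertip (40 s coverage), giving five 20-point response estimates per
voxel. The participant-average HRF averages these over each fingertip
region's voxels, keeps each region's dominant-fingertip response (dominance
= the region's phase bin), averages across the five regions and normalizes
to unit integral. Step two fits one amplitude per fingertip per voxel using
that HRF as the canonical kernel. On noiseless data this round trip is
exact to solver precision for both designs.

Fitting is homoscedastic voxelwise OLS without prewhitening (the simulated
noise is white; no autocorrelation model is estimated), with per-run
intercept columns after concatenation and convolution restarting at run
boundaries. Contrast families: one-sided preference ($e_i - \frac14\sum_{j
\ne i} e_j$) and activation ($e_i$) t maps, a main-effect F test (any
difference between fingertips, used to threshold pRF center maps) and an
any-positive F test (any nonzero response, used to threshold pRF width maps
and define responsive ROIs). The hemodynamic delay proxy is the ratio of
the temporal-derivative beta to the canonical beta at the voxel's preferred
fingertip; larger ratios mean shorter delays, and the sign convention is
fixed by simulation (an HRF advanced by one TR yields positive ratios).

## pRF fitting and ROI tuning

Each voxel's five-point tuning curve is fitted with a Gaussian over
fingertip index (free amplitude, center in [0.5, 5.5], spread at most 30
fingertip units; FWHM = sigma × 2√(2 ln 2) ≈ 2.355 sigma). The fit screens
a deterministic center × sigma start grid (centers 1–5 in 0.5 steps; sigmas
0.3, 1, 3, 10, 30) with closed-form amplitudes and refines the three best
starts with bounded Levenberg–Marquardt, which avoids the local minima of
naive single-start fits at negligible cost. A free amplitude is used
because the response estimates are unnormalized percent signal change. Flat
positive curves correctly drive sigma to its bound — a genuinely flat voxel
has unbounded width.

ROI tuning curves recenter each voxel's five responses on its preferred
fingertip — estimated from the *phase-encoded* data, independent of the ER
responses — and average per offset, giving nine points over offsets −4..+4.
Independent recentering is unbiased for untuned voxels; recentering on the
same data's argmax manufactures a spurious peak (the circularity bias),
which `analysis/04_circularity_bias.R` demonstrates. The ROI Gaussian is
centered at offset zero (the curves are recentered by construction) in two
variants: a design-comparison variant with a non-positive offset parameter
(absorbing below-baseline responses), and an ROI variant with the spread
bounded below at 0.4 fingertip units (minimum FWHM ≈ 0.94) and no upper
bound, so flat associative-area curves can report arbitrarily large widths.

Cortical magnification distances take, per fingertip ROI, the center line
perpendicular to the somatotopic axis, and report for consecutive ROIs the
mean nearest-vertex 4-connected grid geodesic (symmetrized over the two
directions), in voxel-spacing units — parallel aligned lines $d$ voxels
apart are exactly $d$ spacings apart.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains all stages on the default patch: three phase runs
per direction (the localizer aggregates runs across sessions), four fast
and four slow ER runs, 0.01-Hz high-pass filtering and percent-signal-change
conversion, phase mapping with Hochberg correction, the two-step GLM,
FDR-thresholded pRF maps and per-band ROI tuning. One top-level seed fans
out to per-stage child seeds through a fixed linear-congruential derivation
(`child_seed`), so every result is bit-reproducible given the config. The
default run finishes in seconds on one CPU; the efficiency table uses 1,000
draws per design plus one 50,000-draw selection (~20 s). These sizes were
chosen so the full analysis suite runs in minutes while keeping Monte-Carlo
error well inside the tolerances the tests assert.

## Known limitations

* The efficiency model does not reproduce a block-vs-full randomization
  advantage (see above); the affected comparisons are documented rather
  than tuned away.
* The no-null variant's FIR design is rank deficient on its 90-TR run
  (90 rows, 101 columns) and falls back to a pseudoinverse with a warning.
* The synthetic patch is a flat grid: no cortical folding, surface
  geometry, atlas uncertainty, or spatially correlated noise. Geodesics are
  grid geodesics, not mesh geodesics.
* Group-level inference (across participants) is out of scope; all
  analyses are within-"participant" on simulated data.
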