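---
title: "Sarcomere morphometry from SHG striation images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sarcomere morphometry from SHG striation images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcomorph)
```

## The measurement problem

Second-harmonic-generation (SHG) microscopy images unstained striated muscle
label-free: the signal arises from the myosin thick filaments, so each
sarcomere appears as a *biperiodic* pattern — two bright A-band segments
split by the thin dark M-band, bounded by dark (SHG-silent) Z-discs. Three
distances characterise the resting sarcomere:

* **SL** — sarcomere length, Z-disc to Z-disc (the pattern period);
* **ABL** — intra-sarcomeric A-band length, the distance between the two
  A-band segments around the M-band;
* **TTIL** — thick–thin filament interaction length, the mean width (FWHM)
  of an A-band-related intensity peak.

`sarcomorph` measures all three automatically from single-channel TIFFs with
known pixel pitch (40 nm by default), and runs the paired cohort statistics
of a control-vs-IUGR study design on the results. A synthetic-data module
generates ground-truthed images and cohorts so that every stage is testable
against known truth.

## Generative profile model

Along a fiber's axis, the noise-free intensity is modelled as a periodic
train of Gaussian peak pairs:

$$
I(s) \;=\; B + C \sum_{j=0}^{n-1} \sum_{\pm}
\exp\!\left(-\frac{\bigl(s - m_j \mp \mathrm{ABL}/2\bigr)^2}{2\sigma^2}\right),
\qquad m_j = s_0 + (j + \tfrac12)\,\mathrm{SL},
$$

with $\sigma = \mathrm{TTIL} / (2\sqrt{2\ln 2})$ — one documented constant
converts the FWHM convention of TTIL to the Gaussian width, and the same
constant is used by the simulator and the fitter. Gaussian peaks are an
assumption (the shape of a diffraction-limited band is not otherwise
constrained); they make the autocorrelation analytic. Z-discs need no
explicit dark object: SHG arises from myosin, so the Z-disc is simply the
gap between periods. The pattern is rejected as degenerate if TTIL reaches
half the smaller inter-peak gap ($\min(\mathrm{ABL}, \mathrm{SL} -
\mathrm{ABL})/2$), where neighbouring peaks merge.

## The autocorrelation model and fit

The measurement chain per fiber is: structure-tensor orientation field →
ridge tracing along the field → 1-D profile extraction → normalized
autocorrelation (ACF) → bounded nonlinear least-squares fit of the analytic
ACF of the model above. The ACF of the mean-subtracted periodic train is,
up to normalization,

$$
R(\tau) \;\propto\; \sum_{k\in\mathbb{Z}} \;\sum_{d \in \{0,\,0,\,+\mathrm{ABL},\,-\mathrm{ABL}\}}
\exp\!\left(-\frac{(\tau - d - k\,\mathrm{SL})^2}{4\sigma^2}\right)
\;-\; \frac{8\sigma\sqrt{\pi}}{\mathrm{SL}},
$$

normalized to $R(0) = 1$: peaks of weight 2 at lags $k\,\mathrm{SL}$ and of
weight 1 at $k\,\mathrm{SL} \pm \mathrm{ABL}$, all of width $\sigma\sqrt2$,
on a small negative DC offset. Because `model_acf()` is exactly the ACF of
the simulator's profile, simulator and fitter share a single generative
model; recovery on synthetic data therefore tests the pipeline, not a
modelling mismatch.

Key numerical choices:

* **ACF estimator.** `compute_acf()` uses the standard biased ($1/n$)
  estimator, which keeps values in $[-1, 1]$; the triangular Bartlett taper
  $1 - \ell/n$ it imposes is multiplied into the model during fitting
  rather than divided out of the data (dividing would amplify noise at long
  lags).
* **Noise handling.** White photon/read noise contributes to the ACF only
  at lag 0, so lags below `fit_lag_min_um` (0.12 µm) are excluded, and a
  free amplitude absorbs the fraction of profile variance taken by noise; a
  free offset absorbs slow envelope leakage. Five parameters are fitted:
  SL, ABL, TTIL, amplitude, offset.
* **Bounds and initialisation.** SL ∈ [1.0, 2.5] µm, ABL ∈ [0.4, 1.2] µm,
  TTIL ∈ [0.04, 0.2] µm bracket all the reference group means with margin.
  SL is initialised at the highest local ACF maximum inside the SL bounds
  (the satellite peaks at ABL and SL−ABL lie below 1 µm for physiological
  geometry), ABL at SL/2.15, TTIL at 0.1 µm. Levenberg–Marquardt
  (`minpack.lm::nls.lm`) runs to a relative cost change of 1e−8 or 500
  iterations. An ACF without an off-zero peak yields a *flagged*
  non-converged fit, never a silent drop.
* **Profile sampling.** Profiles are resampled at constant arc-length pitch
  equal to the pixel pitch with Catmull–Rom cubic interpolation. Bilinear
  interpolation (available as `profile_interp = "bilinear"`) adds
  ≈ pitch²/6 ≈ 267 nm² of axial variance at 45° orientation, biasing TTIL by
  about +7 nm; the Catmull–Rom kernel has zero second moment and preserves
  peak widths, so the default avoids a deconvolution correction. Transverse
  averaging over ±3 px boosts SNR and, for straight fibers, does not blur
  the axial pattern.

## Orientation estimation and tracing

Striations run perpendicular to the fiber axis, so the dominant
gradient-energy direction of a structure tensor *is* the axis. The tensor
is integrated over a Gaussian window of 400 nm (10 px); coherence
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ masks isotropic regions
(constant images give coherence 0 and undefined angles). Tracing seeds at
crests of a striation-free envelope (anisotropic smoothing: ~1 µm along the
dominant axis — attenuating the striation harmonics by ~10⁻³ — and 2 px
across), marches in 1 px steps along the local field angle with crest
re-centering, and stops at coherence < 0.2, envelope below 25 % of the seed
value, or the border. Traces shorter than 5 expected periods (5 × 1.7 µm)
are discarded so the ACF always spans several informative periods;
overlapping traces of one ridge keep the longer member. Tracing uses no
randomness and is deterministic given image and field.

## The quality rule and cohort statistics

The SL/ABL ratio is a physiological quality check: fitted fibers with ratio
**strictly above 2.25** are excluded (a ratio of exactly 2.25 is kept), as
the typical biperiodic pattern is lost above that value. The rule is
applied per fiber — the conservative superset — and the per-image mean
ratio is also reported against the same threshold, since the granularity of
"sample" is not fixed by the study description.

QC-passing fibers are averaged per heart (unweighted fiber → heart
aggregation, SDs with the n−1 denominator; fiber → image → heart averaging
would weight images equally instead and is deliberately not the default —
the hierarchy is shallow and fiber counts per image are similar). Group
contrasts are run both as a paired two-sided t-test on within-pair
differences and as a classical one-way ANOVA, each labelled in the output,
with significance at p < 0.05. Degenerate inputs (numerically constant
differences) are flagged rather than erroring, with t = 0, p = 1 when the
common difference is zero.

## What the synthetic cohorts emulate

`cohort_spec()` describes a paired two-group cohort by heart-level
distributions of SL, the SL/ABL ratio and TTIL; `reference_cohorts()` ships
the four study-group configurations (fetal/adult × control/IUGR: e.g. fetal
control SL 1.658 ± 0.094 µm, ABL 0.772 ± 0.044 µm, TTIL 0.104 ± 0.006 µm).
Three design choices matter:

* **SL–ABL coupling.** The reported per-heart ratio SD (0.02–0.03) is an
  order of magnitude smaller than independent SL and ABL draws would give
  (≈ 0.17), so hearts are drawn in (SL, ratio, TTIL) coordinates and ABL is
  derived as SL/ratio.
* **Pairing.** Paired hearts share a litter effect giving a between-pair
  correlation of 0.5 by default — a realistic value for littermates, and
  consistent with a paired design that reaches p < 0.05 at n = 7 for a
  0.127 µm SL effect. It is configurable (`pair_cor`).
* **Conditioning on summaries (`match_moments`).** The reported group means
  *are* the empirical means of the 7 real hearts per group. When the goal
  is to test whether the pipeline recovers the configured group mean, the
  drawn heart values are affinely standardised so the sample mean and SD
  equal the configured ones exactly; otherwise a ±0.02 µm recovery check
  would be dominated by the sampling noise of 7 hearts (SE ≈ 0.036 µm for
  fetal SL), not by measurement error. Studies of sampling variation (e.g.
  the power of the paired t-test across seeds) set `match_moments = FALSE`.

Within a heart, fibers jitter around the heart mean with configurable SDs
(defaults 0.05 µm SL, 0.05 ratio, 0.004 µm TTIL — the within/between
variance split is not derivable from group summaries, so these are stated
choices, not claims about the real animals). Fibers are straight, parallel,
oriented at 45° (the acquisition convention), spanning the image chord;
~8–15 fibers and on the order of 200 sarcomeres per image. Noise is Poisson
photon noise at a realistic photon-starved budget (peak ≈ 30 photons above
a background of 2) plus Gaussian read noise (SD 1.5); the `noise` level
scales the photon budget by 1/noise² (exposure scaling). Under these
defaults the single-fiber errors measured by the test suite sit comfortably
inside the 20 nm accuracy benchmark for SL and ABL and 10 nm for TTIL.

What the generator does **not** emulate — and hence what passing tests do
not show about real tissue: curved or crossing fibers, spatially varying
background and depth-dependent attenuation, polarization dependence of SHG,
detector artefacts, contraction-state variation within a fiber, and any
optical transfer beyond the Gaussian peak shape itself. Recovery on these
synthetics validates the algorithmic chain, not robustness to every real
acquisition artefact.

## Ranked-list gene-set scan

The microarray arm consumes an already-ranked gene list (most up-regulated
first; the ranking statistic is treated as an opaque key, ties broken by
gene id). Annotations are first propagated up the GO DAG — a gene annotated
to a term is annotated to every ancestor up to the root; cycles are an
error naming the cycle. `partition_scan()` then slides `n_partitions`
(default 30, configurable; the original tool's setting is not documented)
evenly spaced rank cuts along the list and tests each term × cut 2×2 table
(annotated vs not × above vs below) with a two-sided Fisher exact test,
reporting the one-sided over-representation tail as well.
Benjamini–Hochberg adjustment is applied across **all term × partition
tests jointly** (a stated choice — the reference tool's family definition
is unknown), and each term is summarised by its minimum adjusted p and the
partition attaining it.

The simulated enrichment block annotates 1.6 % of the top half and 0.69 %
of the bottom half of the list. At a list length of 20 000 — the order of a
whole-genome expression array — those fractions give counts (160 vs 69)
whose Fisher p is far below 0.001, matching the regime the method is meant
to detect; at only 2 000 genes the same fractions give counts of 16 vs 7,
which no exact test can call significant (p ≈ 0.09). The acceptance checks
therefore run the block detection at n = 20 000.

## Problem sizes and reproducibility

The test suite and the acceptance script use deliberately scaled study
sizes chosen to exercise every stage while keeping runs desk-sized: 512 px
(20.5 µm) images, 8 fibers per image, 3 images per heart, 7 hearts per
group, 50 seeded single-fiber images for the error distribution, 100 seeds
for the power study (run on ground truth plus measurement noise rather than
rendered pixels, since only heart-level variation matters there), and
n = 20 000 for the gene-list scan. All randomness flows from explicit
integer seeds; identical spec + seed reproduces images bit-for-bit.

## Known limitations

* Per-fiber averages only: no per-sarcomere length maps, no contraction
  modelling.
* The tracer assumes locally straight, non-branching, non-crossing fibers
  in a single plane.
* Parity with the original acquisition-side implementation is not claimed —
  only recovery of ground truth on the shared generative model.
* Differential-expression fitting (e.g. limma) is out of scope; the
  gene-set module starts from a ranked list.
* Which of the paired t-test vs ANOVA produced each reported p in the
  original study is not stated; both are emitted, labelled, and no attempt
  is made to match printed p-values on real data.
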