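---
title: "Methods: Raman crystallinity of microcrystalline cellulose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman crystallinity of microcrystalline cellulose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanci)
library(dplyr)
```

## The measurement problem

Microcrystalline cellulose (MCC) is a semi-crystalline excipient whose
crystallinity index (%CI, the mass percentage of crystalline material)
varies between suppliers and batches and influences tabletability and
water sorption.  `ramanci` implements a Raman-spectroscopic determination
of %CI built on the 380/1096 cm^-1 band-intensity ratio: the 380 cm^-1
band (a low-frequency skeletal/packing mode) is sensitive to crystalline
order, while the 1096 cm^-1 C--O--C backbone stretch is present in both
crystalline and amorphous cellulose and acts as the internal reference.
Because a semi-crystalline spectrum superposes crystalline and amorphous
contributions, the amorphous part is first subtracted using a reference
spectrum of ball-milled (amorphized) material, and the resulting ratio is
mapped to %CI through a linear calibration anchored in powder X-ray
diffraction.

The package provides four layers, each usable on its own:

1. **Pre-processing** — anchor-point baseline and SNV normalization.
2. **Univariate 380-method** — amorphous reference, band ratio, built-in
   and user-fitted calibration lines, Segal PXRD crystallinity.
3. **Latent-variable models** — NIPALS PCA and PLS1 with batch-grouped
   cross-validation, for instrument comparison and direct multivariate
   %CI prediction.
4. **A synthetic generator** — spectra and diffractograms with known
   crystalline fraction, so the full pipeline is testable end to end.

## Pre-processing

Fluorescence background is removed by subtracting a piecewise-linear
baseline through the spectrum's intensities at nine fixed anchors (1500,
1200, 952, 857, 743, 632, 550, 260, 200 cm^-1).  Anchor intensities are
read by linear interpolation when an anchor falls between grid points;
beyond the outermost anchors the baseline continues flat, avoiding
extrapolation blow-up on spectra that extend past the anchor range.  The
corrected intensity is exactly zero at every anchor that lies on the
sampling grid; for off-grid anchors the cancellation is exact in the
anchor read-off but only approximate when the corrected trace is
re-interpolated across the baseline's kink (instrument grids are integer
cm^-1 in practice, where the distinction vanishes).

Intensity scale differences between spectra are removed by the standard
normal variate (SNV): each spectrum is centered to mean zero and scaled
to unit *sample* standard deviation (divisor `n - 1`; any consistent
divisor choice rescales all spectra identically) over the full stored
axis.  The order is fixed — baseline first, then SNV — so that SNV
standardizes the residual chemical signal rather than the fluorescence.
Baseline subtraction is invariant to any additive background that is
piecewise linear over the anchors, and SNV to any multiplicative gain;
together these are exactly the nuisance terms the acquisition model
introduces.

## The 380-method

With pre-processed spectra, the crystallinity-sensitive ratio is

$$ r = \frac{I_{380} - I_{380,am}}{I_{1096} - I_{1096,am}}, $$

where the `am` values come from the amorphous reference.  Band
intensities are read as the maximum over a ±5 cm^-1 window by default
(robust to small calibration shifts between instruments); `half_window =
0` reads the exact interpolated band-center value.  The reference is an
averaged milled spectrum (`build_amorphous_reference()`), which also
records the mean ± sd of its band intensities; the published averaged
values for the two probe heads are available via
`published_amorphous_reference()`.

One step of the published procedure is ambiguous: the amorphous spectrum
is "equalized at 857 cm^-1" to the sample before subtraction.  We
implement this as a single scalar rescaling of the whole reference
spectrum matching the sample at 857 cm^-1 (`scale_to_match()`), with an
option to disable it.  Note that on baselined spectra 857 cm^-1 is an
anchor, so after SNV the value there is `-mean/sd`; the scaling therefore
matches the spectra's SNV offsets rather than a chemical band.  For the
synthetic validation studies the scaling is disabled (see below).

The ratio maps to %CI through a line in the classical calibration
direction, `r = m · %CI + c`, inverted for prediction as
`%CI = (r - c)/m`.  Three published lines are built in: `ORIGINAL`
(`m = 0.0065`, `c = 0.0286`, from the original FT-Raman work), `MR`
(`m = 0.005`, `c = -0.134`) and `PHAT` (`m = 0.005`, `c = -0.129`), the
latter two being instrument-specific corrections obtained from a blend
calibration against PXRD.  `fit_calibration()` reproduces that
procedure: ordinary least squares of ratio on reference %CI (the
classical direction matches the printed algebraic form of the published
equations; inverse regression is available for sensitivity analysis).
Predictions are deliberately *not* clipped to [0, 100]: a negative %CI
diagnoses a sample more amorphous than the reference.

The PXRD reference is the Segal peak-height index,
`%CI = 100 (I200 - Iam)/I200`, with `I200` the mean count over the
crystalline 200 reflection window (22.55–22.65° 2θ) and `Iam` over the
amorphous window (18.65–18.75° 2θ).  Both windows are closed intervals
over grid points; a window catching no grid point is an error rather
than a nearest-point fallback.  The index is returned on the percent
scale so it is commensurate with the Raman %CI.

## Latent-variable models

`nipals_pca()` implements mean-centered NIPALS with deflation:
components are extracted one at a time, convergence is declared when the
relative change of the score vector falls below `tol` (default `1e-9`),
and each loading's largest-magnitude element is made positive so fitted
models are reproducible.  Explained calibration variance per component
is the component sum of squares over the total centered sum of squares.
Cross-validated ("validation") variance uses segment-wise PRESS: each
held-out segment is projected onto loadings fitted on the remainder, and
`100 (1 - PRESS_k / SS0)` is reported cumulatively per component count.

Cross-validation segments are *batch-grouped*
(`grouped_segments()`): all spectra of a batch — from both probes — stay
in one segment, which prevents the leakage that ordinary random folds
would create between replicate spectra.  Any segment count up to the
number of groups is supported, with whole groups assigned round-robin;
the default is one segment per batch.  (The published analysis used 29
segments for 30 batches without stating which two batches were merged;
we support the count but default to the unambiguous one-per-batch.)

`pls1_fit()` is the standard univariate NIPALS-PLS sequence
(`w ∝ X'y`, `t = Xw`, deflation by `p` and `q`); for a univariate
response this is algebraically equivalent to the kernel algorithm used
by commercial chemometrics software, which is the contract the tests
enforce (equality with an independently coded SIMPLS oracle, and
convergence to the ordinary least-squares projection at full rank).
Spectra enter mean-centered but unscaled — they are already
SNV-normalized, and autoscaling would inflate baseline noise; X
variables are restricted to 1500–250 cm^-1 at matrix-assembly time
(`spectra_matrix()`), the window the models were designed for.
Per-factor RMSEC, bias and explained variance are kept for every factor
count; validation statistics are computed either by grouped CV
(`segments`) or on a caller-supplied held-out batch split — both are
exposed because the two notions of "validation variance" differ and
should not be conflated.  `select_factors()` defaults to the
first-minimum rule: the smallest factor count beyond which RMSECV stops
improving by more than 2% relative.

`regression_metrics()` defines explained variance as
`100 (1 - Var(residual)/Var(reference))` with sample variances — a pure
constant offset therefore still "explains" 100% of the variance and
shows up in the bias term instead, matching chemometrics reporting
conventions.

## The synthetic generator

`synth_config()` fixes a stylized but physically structured model of the
measurement:

* **Components.** A 23-band crystalline component (1096 cm^-1 strongest,
  380 cm^-1 nearly as strong at 0.95) and an amorphous component with
  the same centers broadened 1.8× at 0.55× amplitude.  The amorphous
  380 cm^-1 band is nearly absent (0.06) — the packing mode has no
  amorphous counterpart — and its nominal 1096 amplitude is small
  (0.05), with the amorphous intensity near 1096 cm^-1 carried by the
  broadened neighbouring bands.  Real amorphous cellulose retains more
  1096 intensity than this; the attenuation is deliberate, keeping the
  subtracted-ratio calibration well conditioned at the noise level the
  validation studies prescribe.  Band shapes are Gaussian by default
  (Lorentzian and pseudo-Voigt are available).
* **Acquisition nuisances.** A gentle upward quadratic fluorescence
  background (deliberately *not* piecewise-linear over the anchors, so
  baseline removal is approximate and exactness tests use zero
  background), a per-spectrum log-normal gain (`sdlog = 0.1`) that SNV
  must remove, and additive Gaussian noise with sd equal to 1% of the
  clean spectrum's maximum.
* **Probe response.** Per-probe multipliers on the two marker bands
  (MR 1.00/1.00, PhAT 0.80/1.15), reproducing the observed direction of
  inter-probe differences — lower 380, higher 1096 for the wide-area
  probe — which is what makes the two instruments separable by PCA and
  what motivates instrument-specific calibration lines.
* **Interface order-nonlinearity.** With an *exact* two-endmember
  mixture and the fraction-0 spectrum as reference, the 857-matched
  subtraction removes the amorphous contribution perfectly and the
  380/1096 ratio becomes independent of composition — an idealized
  two-phase world is the one place the 380-method cannot work, and real
  spectra escape it only because semi-crystalline cellulose is not a
  binary mixture.  The generator models the leading deviation: chains at
  crystal–amorphous interfaces scatter like ordered cellulose at the
  backbone bands but not at the packing band, so the crystalline
  380 cm^-1 band contributes with weight `chi (1 - kappa (1 - chi))`
  instead of `chi` (`order_nonlinearity`, default `kappa = 1`, i.e. an
  approximately quadratic response).  The deviation from linear mixing
  is exactly `-kappa chi (1 - chi) g380(nu)`, vanishing at both
  endmembers; setting `kappa = 0` restores exact mixing linearity, and
  both regimes are asserted by the test suite.  With the default, the
  subtracted ratio is affine through zero in the crystalline fraction —
  precisely the premise of the linear calibration.
* **Diffractograms.** 2θ 10–30° in 0.01° steps: crystalline Gaussian
  reflections at 14.9°, 16.4° and 22.7° (FWHM 1.5°), an amorphous halo
  (FWHM 8°) centered at 20.65° — between the two Segal windows, in line
  with the published position of the amorphous cellulose halo maximum
  (the classical 18.7° read-off is the inter-peak minimum, not the halo
  center) — a small constant instrument baseline, and Gaussian noise
  with `sd = sqrt(max(counts, 1))` as a Poisson stand-in.  The halo
  amplitude is normalized so that its mean over the amorphous window
  equals the crystalline pattern's mean over the 200 window; together
  with the symmetric halo placement this makes the Segal read-off of a
  blend linear in the mass fraction, which is what lets blend fractions
  serve as "theoretical %CI" in the calibration design.
* **Batch panels.** `synth_batch_panel()` draws per-batch crystalline
  fractions uniformly from 0.45–0.90 (a realistic span for commercial
  MCC around the typical ~60–80 %CI), applies per-batch band-position
  jitter (≤1 cm^-1) and 3% log-normal amplitude jitter, and measures
  each batch with MR triplicates and PhAT duplicates (150 spectra for
  30 batches).

Every generator output is a pure function of (configuration, arguments,
seed); multi-spectrum generators derive per-spectrum seeds from the
master seed through a fixed sub-seed draw.

**Generator-matched analysis settings.**  The synthetic calibration and
recovery studies read band intensities at the exact centers
(`half_window = 0`; the generator's bands sit exactly on the grid, so
the window maximum would only add noise-induced positive bias) and use
the unscaled subtraction (`scale_at_857 = FALSE`; on an exact-endmember
reference the 857-matched subtraction is perfectly efficient and
destroys the composition signal, as explained above).  The defaults —
window maximum and 857-scaling — remain the recommended settings for
real instrument data, where calibration shifts and imperfect references
are the dominant concerns.

**What passing the synthetic studies does and does not show.**  They
demonstrate that the pipeline's algebra, normalization and calibration
logic are correct and numerically stable under gain, background, noise
and probe effects of realistic magnitude; that the Segal and Raman
branches agree when the generator's ground truth says they must; and
that the latent-variable models recover composition and probe structure.
They do not validate the spectroscopic model itself against real
cellulose — band assignments, the interface response, and the amorphous
component here are stylized — so instrument-specific calibration against
diffraction data remains mandatory for real samples, exactly as the
published method prescribes.

## Numerical choices and degenerate inputs

* Axes are always stored ascending; descending files are reversed on
  read, and duplicate axis values are rejected as upstream data errors
  rather than averaged.
* Resampling is linear, matching the linear-interpolation baseline and
  avoiding spline ringing; no extrapolation, ever.
* NIPALS convergence: relative score change below `1e-9` (default),
  with a clear error naming the component on non-convergence;
  nearly-degenerate eigenvalue pairs may need a larger `max_iter`.
* Degenerate inputs fail loudly with specific messages: constant
  spectra in SNV, zero reference intensity at the 857 match point, a
  sample indistinguishable from the reference at 1096 cm^-1
  (|denominator| < 1e-12), all-equal reference %CI in calibration,
  empty Segal windows, non-positive `I200`.
* Batch aggregation uses mean ± sample sd (sd = 0 for a single
  replicate); failed replicates are excluded with a warning count, never
  silently dropped.

## Validation problem sizes

The shipped test suite and acceptance script run at desk scale: the
seven-fraction blend series with 3 replicates per blend plus 10 milled
reference spectra; 30-batch two-probe panels (150 spectra of 1301
points); 50 random matrices up to 20×50 for the PCA/SVD oracle; 100
generated spectra for the pre-processing property suite.  These sizes
were chosen to exercise every code path with comfortable statistical
margins while keeping a full run in the order of seconds.

## Known limitations

* The 380-method's precision degrades as samples approach the amorphous
  reference (the subtracted denominator shrinks toward zero); predictions
  for nearly amorphous samples carry large variance, which the
  replicate sd makes visible.
* JCAMP-DX support covers AFFN `(X++(Y..Y))` tables only; compressed
  (DIFDUP/SQZ) encodings are rejected with a message.
* The built-in calibrations and published amorphous reference values are
  instrument-specific; applying them to spectra from other instruments
  gives relative, not absolute, crystallinity.
* Segal peak-height crystallinity is itself an approximation (peak
  decomposition and Rietveld methods are out of scope here); the Raman
  %CI inherits whatever bias the diffraction reference carries.
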