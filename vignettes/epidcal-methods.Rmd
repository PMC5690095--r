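---
title: "Portal-dose calibration, off-axis profile correction and gamma QA with epidcal"
author: "epidcal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Portal-dose calibration, off-axis profile correction and gamma QA with epidcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidcal)
```

## The problem

An electronic portal imaging device (EPID) mounted opposite the linac head
can serve as a dosimeter: a measured fluence image of a treatment field is
compared against a treatment-planning prediction, and the comparison is
summarized by gamma-index pass rates. Two detector effects corrupt the
comparison on amorphous-silicon panels mounted on a support arm:

1. **Arm backscatter.** Radiation scattered off the support arm adds signal
   on the gantry side of the panel. Because the flood-field calibration is
   acquired with a large open beam, it embeds *more* backscatter than a
   small treatment field does; after flood correction a small field
   therefore *under*-responds on the gantry side, by a couple of percent.
   The effect is two-dimensional and asymmetric.
2. **Off-axis over-response.** Relative to the prediction, the measured
   signal grows with off-axis distance, reaching on the order of ten
   percent beyond 20 cm. Unlike the backscatter, this effect is close to
   radially symmetric, which makes it correctable within a prediction
   model that assumes a radially symmetric response.

`epidcal` implements the measurement-side workflow that addresses the
second effect: the standard dark-field/flood-field/CU calibration chain, a
one-dimensional polynomial correction to the diagonal beam profile used in
that chain, a gamma-index comparator to quantify the benefit, and a
parametric EPID simulator so the whole loop can be exercised and verified
without access to a linac.

## The calibration chain

A raw portal image is processed as

$$I_{\mathrm{cal}} = \frac{I_{\mathrm{raw}} - D}{F - D}\,
  \overline{(F - D)}\; \cdot\; P(r)\; \cdot\; k_{\mathrm{CU}},$$

where $D$ is the dark field (background signal), $F$ the flood field (an
open-beam acquisition that divides out both detector sensitivity and beam
nonuniformity), $P(r)$ the diagonal beam profile that restores the beam
"horns" the flood correction removed, and $k_{\mathrm{CU}}$ the scale
factor that makes the central axis of a 100 MU, 10 × 10 cm² reference
delivery read exactly 1.0 calibrated unit (CU). The rescaling by the mean
of $F - D$ keeps the flood correction dimension-preserving. The
central-axis readout is a bilinear interpolation at the exact beam-axis
point, which falls *between* pixels on the even-dimensioned 512 × 384
panel — there is no centre pixel to read.

A vendor-style two-dimensional correction map can replace the $P(r)$ step
(`apply2DCorrection()`); the package treats such maps as opaque
multiplicative inputs and does not parse any proprietary format.

## The 1D profile correction

The correction is derived from one large open field (38 × 28 cm², roughly
the largest field of interest):

1. Process the measured acquisition with the uncorrected calibration and
   produce the matching predicted image.
2. Extract the diagonal profile of both images from the panel centre
   (`extractDiagonalProfile()`), sampled once per pixel pitch.
3. Form the ratio $\rho(r)$ of measured to predicted profiles, both
   renormalized to 1 at the central axis (`computeRatio()`).
4. Fit $\rho(r) - 1$ with an ordinary least-squares polynomial over a fit
   window, giving the correction factor $c(r)$ (`fitCorrection()`).
5. Divide the calibration beam profile by $1 + c(r)$ and renormalize at
   the central axis (`applyProfileCorrection()`); recalibrate the CU
   scale with the corrected profile.

Three named modes bundle the constants (`deriveCorrection()`):

| mode | order | fit window (cm) | applied to (cm) |
|---|---|---|---|
| `inhouse_large` | 4 | 0 – 22 | 22 |
| `inhouse_20x20` | 4 | 0 – 11 | 14 |
| `bailey` | 1 | 10 – 25 | 25 |

The quartic is fitted only up to ~22 cm because beyond that radius the
measured/predicted ratio of a large field no longer follows a quartic; the
20 × 20 variant fits to 11 cm and applies to 14 cm, the maximal diagonal of
a 20 × 20 cm² field, with the correction set *exactly to zero* beyond the
application radius. That hard cutoff is intentional and leaves a step in
the corrected profile; an optional linear taper band (`taperCm`) is
available but off by default.

Design choices worth knowing:

* **Ratio orientation.** The ratio is defined as measured/predicted and
  applied by division, so an over-responding detector has its calibration
  profile reduced. Sources differ on which way round the ratio is quoted;
  both the orientation and the apply style are arguments, and the two
  conventions are mutually consistent (dividing by a fit of $\rho$ equals
  multiplying by a fit of $1/\rho$ up to polynomial truncation).
* **Fit target.** The fit is of $\rho - 1$, not $\rho$, so the
  zero-correction case is the zero polynomial and near-identity behaviour
  is numerically clean. The design matrix is built in the scaled variable
  $r / r_{\mathrm{fit,max}}$ and coefficients are rescaled back, keeping
  the quartic fit well conditioned; a noiseless polynomial ratio is
  recovered to machine precision with $R^2 = 1$ exactly.
* **$R^2$ convention.** When the total variance in the window is zero,
  $R^2$ is defined as 1 if the residuals are all zero and 0 otherwise.
* **Diagonal direction.** The profile is sampled along the panel-diagonal
  ray (36.9° on the 40 × 30 cm panel, 45° on a square panel). A literal
  45° ray would leave the 30-cm-tall panel at r = 21.2 cm, making a 22 cm
  fit window impossible; the panel diagonal reaches the 25 cm
  half-diagonal. The two opposing rays can be averaged (`symmetrize`),
  but by default a single ray toward the gantry-side corner is used, so
  the derived correction embeds whatever asymmetry that ray sees — the
  1D method's inherent approximation, kept visible on purpose.

## The gamma comparator

`gammaIndex()` computes the Low-style gamma index: for each reference
pixel, the minimum over nearby evaluated-image positions of
$\sqrt{d^2/\Delta d^2 + \delta D^2/\Delta D^2}$, with the prediction as
the reference by QA convention. The search covers a disc of
`searchRadiusFactor` × Δd (default 3 × 3 mm), sampled every
Δd/`searchSubsample` (default 0.3 mm) with bilinear interpolation, visited
in order of increasing distance so the search can stop as soon as the
distance term alone exceeds the best gamma so far. Dose differences are
normalized globally to the reference maximum by default (central-axis and
local-dose variants are flags). Pixels below the low-dose threshold are
excluded; ties at γ = 1 pass.

The vendor configuration behind published pass-rate tables (normalization
point, threshold, search resolution) is generally not printed, so these
defaults are documented assumptions, not a reconstruction of any
particular product. `gammaOracle()` is an independent plain-R exhaustive
search on a 50-per-Δd grid with no shortcuts, used as ground truth in the
tests; the fast search's offset grid is a subset of the oracle's, so the
fast gamma can never undercut the oracle. The two agree to 0.02 in the
gentle-gradient regime where in-field portal data live; near steep dose
gradients *any* pair of search discretizations diverges more than that,
which is a property of discretized gamma itself, not of this
implementation.

## The simulator

Every input the workflow needs is generated synthetically
(`simulateRaw()`, `simulatePredicted()`, `makeCalibrationInputs()`):

$$\mathrm{raw} = \left[\,F\,P(r)\,\rho(r)\,S(x,y)\,\tfrac{\mathrm{MU}}{100}
  + B(x,y)\,\mathrm{cov}(F) + D(x,y)\,\right](1 + \epsilon),$$

with $F$ the field fluence (3 mm linear penumbra, 0.5% jaw-transmission
floor, open/split/pyramid patterns), $P$ an even-polynomial horn profile,
$\rho$ the residual radial over-response, $S$ a smooth seeded sensitivity
map (±3%), $B$ the arm-backscatter map, $D$ the dark pattern and
$\epsilon$ 0.2% per-pixel Gaussian noise. The prediction surrogate is
simply $F\,P(r)$, noise-free — a radially symmetric model, exactly the
assumption whose violation the corrections address.

Parameter choices, made once against the published effect magnitudes:

* **Over-response** $\rho(r) = 1 - 1.004\times10^{-4} r^2 +
  6.3\times10^{-7} r^4$: dips to −0.4% near 9 cm and rises to +9.9% at
  22 cm — the reported range of the correction factor.
* **Backscatter** $B(y) = a\,\sqrt{y/\ell}$ (clipped at 1) on the gantry
  half only, with amplitude $a = 0.03$ and reach $\ell = 15$ cm, scaled by
  the fraction of the panel the field covers, so the flood embeds more
  backscatter than any smaller field. With these defaults a flood-corrected
  10 × 10 cm² field under-responds by 1–1.5% near its gantry-side edge and
  an 18 × 18 field by about 2%, reproducing the reported 2–3% scale for
  square fields under 20 × 20 cm². The concave rise was chosen over a
  linear one because a linear ramp with the same amplitude and reach puts
  the sub-20-cm asymmetry below 1%, short of the documented magnitude; the
  true arm kernel shape is not published, only these magnitudes anchor it.
* **Flood semantics.** $\rho$ is defined as the *residual* response the
  flood correction cannot remove (the field-spectrum versus flood-spectrum
  response difference), so the simulated flood acquisition carries horns,
  sensitivity, backscatter and dark signal but not $\rho$. Were $\rho$
  included in the flood, it would divide out of every field image and the
  off-axis discrepancy the correction exists for could never be observed —
  contrary to how flood-calibrated panels behave in practice.
* **Noise streams.** All randomness is seeded; each acquisition uses the
  noise seed plus a per-acquisition stream offset, so repeated runs are
  bit-identical while dark, flood and field frames carry independent
  noise.

What the simulator does *not* model: Monte-Carlo transport, energy
spectra, MLC leaf effects, arc-delivery dynamics, panel sag, ghosting,
frame averaging, dose-rate effects, non-square pixels, or any vendor's
actual backscatter kernel. Passing tests on this synthetic data
demonstrate that the algorithms are implemented correctly and that the
workflow behaves as described under the stated effect magnitudes — not
that any specific clinical pass rate will be reproduced on real hardware.

## Verification strategy and problem sizes

The test-suite checks, at the sizes they run at:

* analytic pixel-pitch, radial-map and interpolation identities on small
  grids and the full 512 × 384 panel;
* the CU round trip (CAX of the processed reference = 1.0 CU to 1e−9) on
  the full panel under arbitrary simulator settings;
* exact quartic recovery and the $R^2$ conventions; a noisy (0.1%
  multiplicative) quartic ratio sampled at pixel pitch over 0–22 cm keeps
  $R^2 \ge 0.999$;
* parameter recovery: with backscatter off and noise off, the derived
  $c(r)$ matches the injected $\rho - 1$ to 0.1 percentage points across
  the window (noise-free isolates the derivation: under the default 0.2%
  pixel noise the window-edge fit error is noise-limited near 0.2 pp);
  with full noise, recovery holds to 0.5 pp and the corrected open-field
  ratio is flat to 0.5% (1.2 cm moving average);
* gamma closed forms (uniform 2.9%/6% scalings, a step edge shifted by
  exactly Δd), invariances (common rescaling, criterion monotonicity) and
  oracle equivalence on 100 seeded random 16 × 16 pairs;
* qualitative pass-rate trends on the default study conditions: the
  corrected calibration beats the uncorrected one on the 5–28 cm square
  suite, and the 20 × 20-mode calibration collapses on split fields whose
  half-extents exceed 10 cm (the corrected area is smaller than the
  field, and outside its flood area the calibration is meaningless) —
  mirroring the failure mode that motivates using the large-field mode
  for general QA.

Experiments default to a 10% low-dose threshold — the usual convention for
field comparisons, and necessary here because without it the out-of-field
area dominates every pass rate. `gammaIndex()` itself defaults to
evaluating all pixels.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig()                       # the default study conditions
uncorr <- runExperiment(experimentSpec("uncorrected", config = cfg))
corr   <- runExperiment(experimentSpec("inhouse_40x30", config = cfg))
rbind(uncorr$summary, corr$summary)
```

The derived correction itself:

```{r corr, eval = FALSE}
built <- buildCalibration("inhouse_40x30", cfg)
built$correction
```

## Known limitations

* The 1D correction is radially symmetric by construction and cannot fix
  the 2D backscatter asymmetry; the simulator reproduces exactly this
  residual (the corrected small-field images still show the gantry-side
  deficit).
* The hard cutoff of the 20 × 20 mode produces a profile step at 14 cm;
  fields extending beyond it are corrected only partially, and beyond the
  20 × 20 flood area not calibrated at all.
* Gamma pass rates depend on unpublished vendor configuration choices;
  absolute agreement with any published table is out of scope, and only
  qualitative orderings are asserted.
* DICOM input is not implemented; images travel as headered CSV matrices.
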