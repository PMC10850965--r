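---
title: "Methods: extraction-free digital image colorimetry for well-strip assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extraction-free digital image colorimetry for well-strip assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its signal model

wellcolor implements the image-analysis half of an extraction-free
colorimetric assay for urea in cosmetic formulations. The wet chemistry is
simple: methyl red is dispersed in the formulation, sodium hypochlorite is
added, and the hypochlorous acid it releases bleaches the dye. Urea competes
for the free chlorine (forming chloramines, much weaker oxidants), so the
*residual* dye colour increases with urea content. The treated formulation
is loaded into microstrip wells, photographed once with a smartphone inside
a white lightbox, and the photograph is the measurement.

The quantity the package extracts from a photograph is, per well, the mean
intensity of a colour channel over a circular region of interest (ROI) at
the well centre. Within the assay's linear dynamic range the channel signal
$y$ is modelled as affine in the urea mass fraction $c$ (% w/w):

$$ y = \alpha + \beta\,c, \qquad c_\mathrm{lo} \le c \le c_\mathrm{hi}. $$

The characterised response in an oil-in-water emulsion (the package's
defaults, on the 0–255 intensity scale) is

| channel    | $\beta$ (per % w/w) | $\alpha$ | linear range (% w/w) |
|------------|--------------------:|---------:|----------------------|
| blue       | −3.009              | 128.19   | 2.5–30.0             |
| saturation | +4.185              | 79.49    | 2.5–30.0             |
| red        | −0.255              | 187.04   | 8.1–30.0             |
| green      | −0.452              | 171.90   | 8.1–30.0             |

Below ~2.5 % w/w the proportionality is lost (the free chlorine fully
bleaches the dye regardless), which drives two design points throughout the
package: the calibration module trims the low-concentration end first, and
standard addition never extrapolates to zero.

## Colour statistics (0–255 HSB, per-pixel averaging)

RGB triplets convert to hue/saturation/brightness with all three outputs on
0–255, the convention of ImageJ's HSB stack (hue 0–255 maps to 0–360°).
The intercept 79.49 and slope 4.185 of the saturation response only make
sense on that scale.

Per-well HSB statistics are the means of the *per-pixel* H, S and B values,
not the conversion of the mean RGB colour. The distinction matters: a field
of fully saturated pixels of mixed hue has per-pixel mean saturation 255,
while its mean colour can be grey. Per-pixel averaging is also what makes
the signal robust to the hue of the residual dye (red vs orange wells
calibrate equally well).

Hue is averaged arithmetically, not circularly. Hue is excluded a priori
from analytical-channel selection (it has no usable linear dependence on
analyte here), so the simplification is harmless; it is a documented
limitation should hue ever be pressed into analytical service near the
0°/360° wrap.

Channel means are kept fractional; rounding happens only in report
formatting.

## Well localisation and artifact masking

Wells sit on a known strip, so localisation is a configured grid refined by
an intensity-weighted centroid of $255-\mathrm{brightness}$ within a search
window of half the pitch, with the shift bounded to ±0.25 pitch. This is
deterministic, testable, and sufficient for a rigid microstrip; free circle
detection would add failure modes without adding accuracy. Coordinates are
1-based (row, col) from the top-left, matching R's array indexing.

The ROI is a disc of default radius 25 px (area ≈ 1963 px², inside the
1500–2200 px² band the assay was characterised with) at the refined centre,
deliberately clear of the reflective strip material at the well edges.

Glare and bubbles are masked per pixel: a pixel is excluded if its
brightness reaches 250 (specular clipping) or if any channel deviates from
the ROI channel median by more than $3.5 \times 1.4826 \times \mathrm{MAD}$.
The 1.4826 factor makes the MAD a consistent Gaussian sigma estimate, so
ordinary pixel noise survives (expected exclusion well under 2%) while
compact artifacts, which are gross outliers against a ~2000-pixel ROI, are
removed. A zero MAD (uniform field) disables that channel's criterion
rather than masking everything. Wells with more than 30% of their ROI
masked are rejected outright: beyond that the central area is no longer
representative, and one bad well must not silently bias a calibration.
Fewer than 100 usable pixels is a degenerate ROI and an error.

## Calibration

`fit_line()` is ordinary least squares (via `lm`) with
$R^2 = 1 - SSE/SST$; weighted or robust variants are out of scope because
the assay's validation was defined against OLS.

`determine_linear_range()` makes the linear range an explicit, reproducible
decision rather than a judgement call: fit all standards, back-calculate
each one against the fit, and while $R^2 < 0.98$ or any standard's
back-calculation bias exceeds 15%, drop the endpoint concentration and
refit — the low end first, the high end only when the low end already
passes. Both documented failure modes of the assay are low-end failures
(clipping below 2.5 % w/w; a +34% back-calculation error at the lower
limit in a matrix-effect study), which fixes the trimming order. The 15%
default separates the accepted (±10.2%) from the rejected (+34%)
back-calculation outcomes and is the conventional acceptance at the lower
limit of quantification. Replicate standards enter the fit individually;
replicates at an endpoint concentration are dropped together, since
dropping one of them would not change the candidate range. Blanks are never
fit points — zero concentration lies outside any reported linear range —
but remain in observation tables as diagnostics.

`select_channel()` encodes the published channel choice as a rule: among
candidate channels with $R^2 \ge 0.98$, restrict to those whose linear
range spans the widest interval, then take the largest $|\beta|$
(sensitivity). On the characterised fits this selects saturation, with blue
the runner-up.

`back_calculate()` inverts the line and flags estimates outside the linear
range beyond a tolerance of 10% of the respective endpoint. The band is
anchored to the endpoints rather than the range width so that a
zero-concentration estimate is always flagged against a 2.5–30 range; a
width-based band would accept it.

## Quantification

Direct quantification averages replicate signals, then inverts the
same-photo calibration curve.

The standard-addition estimator is the assay's modified form. Classical
standard addition extrapolates the addition line $y = a + bx$ to the
zero-analyte signal, which is invalid here because linearity does not reach
zero. Instead, a reference standard at $c_\mathrm{ref} > 2.5$ % w/w in the
same matrix is photographed in the same image, and

$$ \hat c_0 = c_\mathrm{ref} + \frac{a - y_\mathrm{ref}}{b}. $$

Under a shared in-range linear response ($y = \alpha + \beta(c_0 + x)$,
$y_\mathrm{ref} = \alpha + \beta c_\mathrm{ref}$, $\beta = b$) the formula
is exact for either sign of $\beta$, and with $c_\mathrm{ref} = 0$,
$y_\mathrm{ref} = \alpha$ it reduces to the classical estimator — both are
property-tested. An unspiked ($x=0$) aliquot is included in the fit when
present: it is a valid point under the model and improves the intercept.
Replicate reference wells are averaged. The estimate is flagged when
$\hat c_0$ falls below the linear-range floor or the addition fit's $R^2$
is poor, and an extrapolation flag is raised when
$\hat c_0 + \max x_i$ exceeds the upper limit.

Accuracy is reported as percent bias, $100(\hat c - c)/c$, computed from
full-precision estimates (rounding to two decimals, as printed reports do,
changes third-decimal bias digits). Intermediate precision is the CV%,
$100\,s/\bar x$ with the sample ($n-1$) standard deviation — the standard
choice for validation at $n$ of 3–8. Per-level bias uses the mean of the
replicate estimates.

## The synthetic plate simulator

Real photographs of this assay are not distributable, so the simulator is
a first-class module providing ground truth for every pipeline stage. It is
parameterised directly by the per-channel response lines above rather than
by chloramine kinetics: no rate constants are published, and the only
mechanistic consequence that matters downstream — loss of proportionality
below 2.52 % w/w — is reproduced by clipping the concentration into the
linear window before evaluating the line (a configurable `clip_lo`, since a
higher oxidant dose widens the window; this is represented qualitatively
only). HSB behaviour is emergent from the rendered RGB, not separately
parameterised; that the rendered saturation–concentration relation comes
out linear ($R^2 \ge 0.98$) is a property test, consistent with the
characterised saturation fit, not an input.

Noise enters in three places, chosen to reproduce the two behaviours the
assay documents:

* per-pixel Gaussian noise (sd 6 intensity units) — averaged to ~0.14
  units by a 1963-pixel ROI, hence nearly irrelevant, which is exactly why
  ROIs of this size are used;
* a per-well multiplicative gain (sd 0.01) — local illumination and
  loading variation, the dominant error source for a single well;
* a per-photo run gain (sd 0.05) shared by all wells — the reason
  standards and samples *must* share a photo; in-photo calibration cancels
  it, and a property test verifies that inflating it tenfold barely moves
  the recovered CV.

Run and well gains are truncated to [0.75, 1.25], modelling the camera's
automatic brightness adjustment: auto-exposure corrects scene-level
illumination outside a window around its metering target, keeping the
brightest content below specular clipping and the darkest quantifiable.
Without this, large simulated gains would either push the red channel
(intercept 187) into the 8-bit ceiling — turning whole wells into "glare" —
or compress the blue span into quantisation noise, neither of which a real
auto-exposed photograph exhibits.

Artifacts are parametric: glare is a disc forced to 255, a bubble is a
darkened ring. They exist to exercise the masking rules; photorealism
(vignetting fields, specular BRDFs, emulsion texture) is a non-goal, as is
time-dependent colour fading — the 30-minute capture window is metadata.
Both artifact probabilities default to 0 because the capture protocol is
designed to avoid them; tests switch them on explicitly. The background is
a fixed near-white (248, 245, 242), the strip plastic, which provides the
dark-well contrast the centroid refinement relies on. Rendering quantises
to 8 bits per pixel after noise, like the camera. All randomness flows from
one mandatory seed; identical inputs are bit-identical, which the test
suite and downstream determinism checks depend on.

What passing simulator-based tests does and does not show: they validate
the *pipeline* — geometry, masking, statistics, calibration algebra,
estimator exactness, error propagation through in-photo calibration — under
a noise model whose structure (not just magnitude) matches the assay's
documented behaviour. They cannot validate the chemistry, matrix effects
beyond the encoded response lines, illumination gradients across a strip
(not modelled; partially absorbed by in-photo calibration), or camera
processing such as local tone mapping.

## Study sizes and numerical choices

The validation-study generator defaults to the characterised QC levels
{6.03, 10.07, 18.13, 23.32, 27.21, 30.03} % w/w with seven in-photo
standards {2.52, …, 30.03}. The package's own acceptance checks use 8 runs
for the accuracy study (48 QC measurements) and 7 runs for intermediate
precision at 6.03 % w/w, matching the replication of the original
validation; each run is an independent photo with a fresh run gain.

Degenerate inputs are errors, not warnings: flat responses (SST = 0),
fewer than 3 calibration points, a zero slope at back-calculation or
standard addition, all-masked ROIs, and plate-map/layout mismatches. The
addition levels used in simulated spiked runs, {0, 5, 10, 15} % w/w, are a
package choice (the original spiking levels are not published). 16-bit
images are linearly rescaled to 0–255 at load with a note. Quantisation
bounds appear in tests as 0.5 intensity units on a well mean and
0.5/|β| ≈ 0.17 % w/w on a back-calculated concentration.

## Known limitations

* Arithmetic (non-circular) hue averaging, as discussed.
* No flat-field/illumination-gradient correction; the capture protocol
  (lightbox, wells away from directly under the LEDs) plus in-photo
  calibration is assumed to handle mild gradients.
* No colour management (ICC), white balance, RAW decoding, or perspective
  correction; input is an 8-bit RGB raster taken plan-view.
* No uncertainty propagation onto the standard-addition estimate; the
  assay reports replicate CVs instead.
* The linear-range trimming criterion is this package's explicit,
  configurable procedure; published range endpoints for this assay were
  stated without an algorithm, so agreement is by outcome, not by
  construction.
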