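---
title: "Methods: quantifying spheroid microarray histology with spharray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spheroid microarray histology with spharray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spharray)
```

# The measurement problem

A spheroid microarray embeds up to 66 fixed spheroids (6 rows × 11
columns, the last column holding marker wells) at a common depth in an
agarose block, so one paraffin section carries every condition of an
experiment. Three quantitative questions follow from that design, and this
package answers each of them:

1. **How much of each spheroid is positive for a marker?** Brightfield
   images of hematoxylin (H) + DAB immunohistochemistry must be unmixed
   into per-stain signals and summarised as percent positive area
   (cytoplasmic markers) or percent positive nuclei (nuclear markers).
2. **Do the spheroids really lie in one plane?** The embedding-depth
   dispersion is measured with plastic beads sectioned along each mold
   row.
3. **Is the readout good enough to screen with?** Assay quality is judged
   with a robust Z′-factor, and dose–response experiments are fitted with
   a four-parameter logistic (4PL) curve.

# Stain model

## Optical density and colour deconvolution

Transmitted light obeys Beer–Lambert: co-localised stains add in optical
density, not in intensity. Each channel of an 8-bit RGB pixel is therefore
transformed as

$$OD_c = -\log_{10}\!\big(\max(I_c, 1) / I_0\big),$$

with the incident intensity $I_0 = 255$ by default (configurable for
flat-field-corrected input). Intensities below 1 are clamped to 1 so the
transform stays finite on saturated dark pixels.

A stain system is a 3×3 matrix $V$ whose rows are unit-norm OD vectors —
hematoxylin, DAB, and a residual completed as their normalised cross
product so the matrix is always invertible for non-collinear stains. The
per-pixel stain densities are $c = (V^\top)^{-1} od$. The shipped default
vectors are the published Ruifrok–Johnston H-DAB pair
(H = (0.650, 0.704, 0.286), DAB = (0.268, 0.570, 0.776)); the staining
chemistry of a given laboratory may warrant measured vectors, which can be
supplied through `stain_system()` or the config file. Negative deconvolved
densities arising from noise are deliberately retained so that downstream
thresholds see the raw signal; only QC rendering clips at zero.

## Quantisation and the accuracy of the round trip

`synthesize_rgb()` is the exact forward model (used by the fixture
generators) and rounds to 8-bit integers, as an acquisition device would.
That rounding sets the accuracy floor of deconvolution: at intensity $I$
the OD quantisation step is about $0.5/(I\ln 10)$ per channel, and the
stain-matrix inverse amplifies channel errors by up to its maximum
absolute row sum (≈ 2.8 for the default H-DAB system). In practice the
round trip `deconvolve(rgb_to_od(synthesize_rgb(x)))` recovers densities
within 0.01 OD only while channel ODs stay below roughly 0.6 (intensities
above ~60); near 2 OD the same bound is ~0.2. The test suite asserts both
regimes explicitly, and the linear-algebra inverse itself is validated to
1e-9 at the OD level, where no quantisation intervenes.

# IHC quantification

## Thresholding policy

The hematoxylin (tissue/nuclei) plane is thresholded automatically with
the iterative-intermeans (isodata) rule — tissue against a white
background is reliably bimodal. The DAB plane is different: a negative
section contains *no* DAB mode, so any automatic two-class rule will
bisect noise and hallucinate positivity. Analysts calibrate the DAB cutoff
on positive and negative control sections; the package mirrors that with
a fixed DAB threshold, default 0.2 OD, logged (like every threshold) into
the results table. Both channels accept `isodata`, `otsu` or `fixed`
modes per run.

## Cytoplasmic readout

Percent positive area = $100\,|DAB \cap tissue|/|tissue|$. Intersecting
with the tissue mask treats extratissular DAB as artefact and bounds the
ratio by 100; it also makes the readout monotone non-increasing in the DAB
threshold, a property the tests verify. Masks are cleaned by a 3×3
despeckle and a radius-2 opening before measurement.

## Nuclear readout

Nuclei masks pass through despeckle → median (radius 2) → minimum/maximum
opening (radius 2, disk element — the stated "2 px" filters do not name a
shape, and a disk is the isotropic choice) → watershed on the negated
Euclidean distance transform with 1-px h-maxima suppression (to prevent
over-segmentation of mildly lumpy nuclei) → connected components →
minimum-area filter. The minimum nuclear area defaults to 20 µm² — a
deliberately permissive floor that removes debris while keeping compressed
nuclei; it is a required, always-logged parameter because the appropriate
value depends on magnification and cell type.

Two denominator conventions exist for percent positive nuclei because
strong DAB deposition can quench the hematoxylin counterstain:

* `"union"` (default): total nuclei counted on the H ∪ DAB mask, ratio
  capped at 100;
* `"h-only"`: the literal DAB-count over H-count ratio, uncapped.

Both are available so that results can be reported under either reading;
the mode is recorded in every result object.

## Illumination correction and cropping

Manual-microscope images often carry smooth illumination gain. With a
recorded blank field the image is divided by the (optionally smoothed)
blank and rescaled to the blank's channel median; without one, the gain is
estimated from the image itself by a large-radius Gaussian blur (default
σ = min(H, W)/8 — large enough that tissue structure does not leak into
the gain estimate). The estimate is least reliable within ~σ of the frame
border, which the tests acknowledge by checking interior flatness.
`crop_to_content()` reproduces the minimum-projection-then-crop step: the
darkest projection over the stack is thresholded and the joint bounding
box returned, with a full-frame fallback (flagged) for blank stacks.

# Embedding-depth analysis

Bead cross-section images are thresholded (isodata), despeckled, opened
(radius 2), and particles above 10,000 µm² are kept — debris and partial
sections are smaller. Each bead's lower edge is the bounding-box top plus
height in physical units, i.e. the depth of its bottom-most occupied row
at the calibrated 25 µm/px. Per mold row, the common plane is the median
lower edge; deviations from it are pooled across rows and experiments and
summarised with a histogram in 50-µm bins centred on zero, the IQR, and
the 10th/90th percentiles. Quantiles use linear interpolation between
order statistics (R type 7), the package's fixed choice since no
alternative rule is dictated by the data. Rows are assumed levelled at
acquisition; a per-image rotation angle in the manifest covers images
scanned in quarter-turn orientations.

# Screening statistics

## Robust Z′

$$Z' = 1 - \frac{3\,(\mathrm{MAD}_s + \mathrm{MAD}_c)}
                {|\tilde{x}_s - \tilde{x}_c|}$$

with medians $\tilde x$ and median absolute deviations per group. Per the
robust-statistics convention, MADs are scaled by 1.4826 by default so they
estimate a normal SD; an unscaled mode (`mad_scale = 1`) is provided
because published robust Z′ values do not always state their scaling, and
the choice is logged with the result. An assay is `"acceptable"` iff
Z′ > 0.5, strictly. Z′ is invariant under common positive affine
transforms of both groups and is undefined (an error, not NA) when the
medians coincide.

## 4PL dose–response

$$y = bottom + \frac{top - bottom}{1 + (x/IC_{50})^{hill}}$$

fitted on log10 dose by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), with the IC50 parameterised as log10(IC50) so its
Wald 95% CI respects positivity. The bottom plateau can be constrained to
zero — conventional when the response is known to vanish at saturating
dose — and the constrained fit's residual sum of squares can only exceed
the unconstrained one, which the tests assert. Zero-dose (untreated
control) points are offset to a configurable dose floor, by default one
decade below the smallest nonzero dose, since a log-dose model cannot
represent zero exactly. Wald intervals were chosen over profile likelihood
as the default for speed and because they match common fitting software;
at the noise levels of the validation (5% of the top plateau over 9
doses) their empirical coverage is ≥ 90% in the seeded Monte-Carlo test.

# Array tools

Spot-to-well assignment maps each detected centroid to the nearest grid
node, leaves centroids farther than a tolerance (default 0.45 × pitch)
unassigned, and resolves well conflicts by smallest residual — strict one
spot per well, except optionally in marker columns, which legitimately
hold multiple spheroids. When requested, the grid origin is re-estimated
from the centroid cloud (midrange initialisation, then median-offset
refinement), making assignment invariant to global slide translation. The
well pitch is config-mandatory for physical-unit work: it is a property of
the mold and is not derivable from images alone.

`sections_in_center_band(d, f, t) = floor(2 f d / t)` counts contiguous
sections of thickness $t$ in the band extending a fraction $f$ of the
diameter above and below a sphere's midline (50 for a 500-µm spheroid,
20% band, 4-µm sections). `plan_workflow()` expresses the economics: one
array block replaces `n_conditions` separately embedded blocks, an
`n_conditions`-fold saving in sectioning and staining consumables.

# Synthetic fixtures: what they emulate and what they do not

Every generator is a pure function of its spec and seed (bit-reproducible,
and the caller's RNG state is untouched).

* `render_section()` renders nuclei as hematoxylin-absorbing disks
  (positives additionally DAB-absorbing), or a tissue disk with a
  concentric DAB-positive region of prescribed area fraction, through the
  exact forward Beer–Lambert model, then applies an optional smooth radial
  gain field and additive Gaussian intensity noise (default σ = 2 of 255 —
  the order of sensor noise in well-exposed brightfield). Nucleus
  placement uses rejection sampling with a minimum centre distance
  (default 2.5 radii, guaranteeing non-touching disks); a touching-pair
  mode places pairs at a controlled separation for watershed validation.
* `render_bead_rows()` renders dark beads (500-µm radius at 25 µm/px, the
  reference imaging geometry) with planted lower-edge deviations snapped
  to the pixel grid. Beads are drawn with a small flattened contact facet
  at the planted lower edge — physically, centrifuged beads rest against
  the well bottom — so the planted edge is well-defined under the
  median/opening filters; a mathematically ideal circle ends in a 1-px tip
  that any speck-removal filter legitimately erodes.
* `simulate_assay_signal()` draws location-scale normal groups with a
  prescribed fraction of gross outliers (default 10%, displaced by 10
  spreads), the situation that motivates the robust Z′. Defaults emulate
  a strongly expressed nuclear marker (n = 23 per group, sample median
  91, spread 11).
* `simulate_dose_response()` generates 4PL responses on the default
  9-dose grid spanning 0.01–300 µM. Nine doses cannot span that range in
  exact half-log steps (4.48 decades over 8 intervals); the grid is
  geometric with a ~0.56 log10 step, the closest realisation of the
  stated design.

These fixtures validate the *algorithms*, not the biology: they contain no
staining heterogeneity, no touching tissue folds, no hematoxylin
aggregates, no paraffin texture, and only radially smooth illumination
bias. Passing tests therefore demonstrate correct measurement of what is
in the image, not robustness to every histological artefact; fixed DAB
thresholds in particular still require control-section calibration on real
material.

# Numerical choices and degenerate inputs

* Isodata is implemented as iterative intermeans on raw values
  (tolerance 1e-7); constant rasters raise a degenerate-threshold error
  directing the user to fixed mode rather than returning an arbitrary cut.
* Masks compare as `map >= threshold`; rectangles and index ranges are
  1-based and inclusive, the R convention.
* Empty tissue masks, empty detections, identical medians, and constant
  responses raise informative errors instead of NA propagation.
* Batch runs process files in sorted-filename order, log per-file
  failures without aborting, and echo the resolved configuration to the
  output directory; re-running an identical configuration reproduces the
  results CSV byte for byte.
* Problem sizes in the test suite (512² px fields with ~55 nuclei, 60
  single-pair watershed renders, 1000 8×8 round-trip fields, 100
  Monte-Carlo fits) were chosen as the smallest sizes at which each
  property is cleanly observable.

# Known limitations

* The 3×3 linear model cannot unmix more than three co-localised stains,
  and crossover between H and DAB vectors grows with deviation from the
  published vectors; measured vectors are recommended for quantitative
  work on unusual chromogen lots.
* Watershed with 1-px h-maxima suppression splits near-circular nuclei
  reliably at centre separations ≥ ~1.6 radii but will under-split long
  fused clusters and may over-split strongly non-convex nuclei.
* The depth pipeline measures a lower *edge*, not a sphere fit; tilted or
  chipped beads bias their row plane.
* De-arraying assumes a rigid, unrotated grid (translation is estimated;
  rotation and shear are not).
* 8-bit quantisation bounds deconvolution accuracy as described above;
  densities beyond ~2 OD are effectively saturated.
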