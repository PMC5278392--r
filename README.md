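# spharray

Quantitative image analysis for spheroid microarray histology.

Spheroid microarrays embed up to 66 fixed spheroids — 6 rows by 11 columns,
one column reserved for marker wells — in a single agarose plane, so that
one paraffin section carries every condition of an experiment and can be
stained and imaged in a single pass. `spharray` implements the downstream
analysis for such arrays, from raw brightfield micrographs to screening
statistics, together with seeded, ground-truthed synthetic generators that
validate every pipeline end to end.

## What it computes

**Stain separation.** Brightfield RGB images of hematoxylin (H) + DAB
stained sections are converted to optical density per channel,
`OD_c = -log10(max(I_c, 1) / I0)`, and unmixed by Ruifrok–Johnston colour
deconvolution: with a 3×3 matrix `V` whose rows are the unit-norm OD
vectors of H, DAB and a residual stain, the per-pixel stain densities are
`c = (V^T)^{-1} · od`. The forward model (`synthesize_rgb()`) renders
density maps back to RGB, which is how the synthetic fixtures are built.

**IHC quantification.** Two readouts mirror standard practice:

* *cytoplasmic markers*: percent positive **area** = 100 · |DAB ∩ tissue| /
  |tissue|, with tissue from an automatic isodata threshold of the H plane
  and DAB from a fixed OD cutoff (default 0.2) calibrated as one would on
  positive/negative control sections;
* *nuclear markers*: percent positive **nuclei**, counting nuclei by
  despeckle → median (2 px) → min/max opening (2 px) → watershed on the
  Euclidean distance transform → minimum-area filter.

Each batch run writes a CSV row per image (thresholds included) and a QC
overlay with green tissue outlines and magenta positive-area outlines.

**Embedding-depth uniformity.** Bead cross-section images are thresholded
(isodata), filtered, and every particle's lower edge (bounding-box top +
height, scaled by μm/px) is measured; deviations from each row's median
plane are pooled and summarised with a 50-μm histogram, IQR and
10th/90th percentiles.

**Screening statistics.** The robust Z′-factor

    Z' = 1 − 3·(MAD_sample + MAD_control) / |median_sample − median_control|

with MADs optionally scaled by 1.4826, and the conventional acceptance rule
Z′ > 0.5 (strict). Dose–response data are fitted to the four-parameter
logistic `y = bottom + (top − bottom) / (1 + (x/IC50)^hill)` on log10 dose
(Levenberg–Marquardt, optional `bottom = 0` constraint, Wald 95% CI for
the IC50).

**Array tools.** Grid layout modelling, spot-to-well assignment
(de-arraying, with origin re-estimation and marker-well support), the
central-band section count `floor(2 · band · diameter / thickness)`, and
workflow-economics arithmetic (array vs separately embedded samples).

## Worked example

```r
library(spharray)

# a synthetic nuclear-stain section with known ground truth
r   <- render_section(section_spec(n_nuclei = 20, n_positive = 13, seed = 7))
res <- analyze_nuclear(r$image, pixel_size = 1)
print(res)
#> Nuclear stain: 65.00% positive (13 DAB+ / 20 nuclei, union mode)

# assay quality from simulated per-spheroid signals with 10% outliers
sig <- simulate_assay_signal(seed = 1)
z   <- robust_z_prime(sig$sample, sig$control)
cat(sprintf("Z-prime = %.3f (%s)\n", z, classify_assay(z)))
#> Z-prime = 0.554 (acceptable)

# dose-response fit with the bottom constrained to zero
d <- simulate_dose_response(top = 50, bottom = 0, ic50 = 0.9, hill = 1,
                            noise_sd = 2.5, seed = 1)
print(fit_4pl(d$dose, d$response, constrain_bottom_zero = TRUE))
#> 4PL fit: top 47.9, bottom 0 (constrained), IC50 1.13 uM (95% CI 0.871-1.47), hill 1.17

sections_in_center_band(500, 0.2, 4)   # sections in the central 20% band
#> [1] 50
print(plan_workflow(11, 6, 3))
#> Workflow: 11 conditions x 6 replicates; 11 blocks vs 1 array (11-fold saving); 33 vs 3 slides
```

The 20-nuclei section really contains 13 DAB-positive nuclei by
construction (`r$truth`), so the 65% readout is exact; the fitted IC50 of
1.13 μM sits inside its confidence interval around the generating value of
0.9 μM at 5% response noise.

## Command line

A thin CLI over the same functions ships in `inst/cli/spharray`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "spharray", package = "spharray"))')
Rscript "$CLI" quant-nuclei --in images/ --out results/
Rscript "$CLI" depth --manifest rows.csv --out depth/ --min-area 10000 --bin 50
Rscript "$CLI" fit-dr --in doses.csv --constrain-bottom
Rscript "$CLI" sections-calc --diameter 500 --band 0.2 --thickness 4
```

Subcommands: `quant-cyto`, `quant-nuclei`, `depth`, `zprime`, `fit-dr`,
`dearray`, `simulate`, `sections-calc`, `plan`. Configuration is a YAML
file (`--config`); the resolved configuration is echoed into every output
directory.

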