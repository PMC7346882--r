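# psrmorph

Automated histomorphometry of Picrosirius Red (PSR) stained ventricular
myocardium: per-pixel quantification of **collagen**, **fat** and **myocyte**
proportions of tissue area, with perivascular-collagen exclusion, equal-area
epicardial/endocardial partition, and multilevel statistics on the log scale.

The package is aimed at cardiac pathology groups who quantify myocardial
fibrosis and fatty infiltration from whole-section digital slides, and at
methodologists who need a fully testable stand-in for such a pipeline:
a synthetic-slide and clustered-study generator with exact ground truth is a
first-class part of the package.

## What it computes

On a PSR slide, collagen stains red, myocytes orange-yellow, and unstained
structures (fat vacuoles, vessel lumens, slide background) are near white.
The pipeline:

1. **Colour-band classification** — each pixel is labelled background,
   collagen or myocyte by configurable hue/saturation/value bands (RGB
   banding available); pixels in no band go to the nearest band centre, so
   the image is always fully partitioned.
2. **Morphological fat detection** — fat shares the unstained colour of
   background, so a vacuole is defined geometrically: an *enclosed*
   near-white component (not connected to the image border) with adipocyte
   plausible area and high solidity after closing.
3. **Vessel exclusion** — remaining enclosed unstained components of
   sufficient area are lumen candidates. Each is scored with an
   **elliptical score**: the intersection-over-union between the region and
   its moment-matched filled ellipse. Candidates scoring ≥ 0.4 are accepted
   as lumens, and their perivascular collagen cuff — collagen reachable
   geodesically from the lumen within the collagen label, up to 2× the
   equivalent lumen radius — is excluded from analyzable tissue, because
   vessel caliber varies strongly between samples. (The score is a
   documented reconstruction; the vendor formula behind the original
   analyses is unpublished.)
4. **Regional partition** — free-wall tissue is split 50:50 by area into
   epicardial and endocardial halves by ranking analyzable pixels on their
   Euclidean distance to the annotated epicardial surface and cutting at
   the median distance stratum. Septal samples (no epicardial surface) are
   quantified whole.
5. **Composition** — percentages of *analyzable* tissue (lumen and cuff
   pixels removed from numerator and denominator) per region, plus absolute
   tissue area in mm²; right ventricular free-wall samples are pooled by
   pixel count before analysis.
6. **Multilevel model** — per component, `log(value)` is modelled with
   cell-mean fixed effects for (location × region), optional sex/age/BMI
   covariates, and a per-heart random intercept (REML via lme4).
   Back-transformed estimates are geometric means with 95% Wald CIs;
   location contrasts are geometric-mean ratios
   `exp(est_a − est_b)` with Wald tests.

## Worked example

```r
library(psrmorph)

# a synthetic PSR slide with known truth: 15.2% collagen, 12% fat, 3 vessels
syn <- generate_slide(slide_spec(width_px = 512, height_px = 512,
                                 collagen_frac = 0.152, fat_frac = 0.12,
                                 n_vessels = 3, rng_seed = 42))
res <- process_slide(syn$slide, heart_id = "H01", location = "RV",
                     boundary = syn$truth$epicardial_boundary)
res$records[, c("region", "collagen_pct", "fat_pct", "myocyte_pct",
                "tissue_area_mm2")]
#>        region collagen_pct fat_pct myocyte_pct tissue_area_mm2
#> 1       total        14.23   12.15       73.62          0.8964
#> 2  epicardial        13.83   12.61       73.55          0.4479
#> 3 endocardial        14.62   11.69       73.69          0.4485
```

Total collagen reads 14.2%, not 15.2%: the three perivascular cuffs are true
collagen but are excluded from analyzable tissue, exactly as intended. The
three lumens were found with near-perfect elliptical scores:

```r
as.data.frame(res$lumens)
#>   centroid_row centroid_col area_px area_um2 score accepted
#> 1          153          241     996     3984 0.993     TRUE
#> 2          323          343    1069     4276 0.997     TRUE
#> 3          394          315    1656     6624 0.999     TRUE
```

On the statistics side, a simulated 29-heart study at the package's
reference composition recovers the right-ventricle vs septum collagen
contrast:

```r
tab <- generate_study(study_spec(rng_seed = 7))
fit <- fit_composition_mlm(tab, "collagen")
contrast_ratio(fit, "RV:total", "IVS:total")
#>   component numerator denominator ratio ci_low ci_high  p_value
#> 1  collagen  RV:total   IVS:total  1.75   1.58    1.94 4.64e-27
```

i.e. collagen is estimated ~1.75× higher in the RV than in the septum
(simulation truth 15.2/8.6 ≈ 1.77), with a 95% CI and Wald p-value from the
mixed-model covariance.

A thin command-line front end over the same functions lives in
`inst/cli/psrmorph.R` (subcommands `simulate`, `classify`, `exclude`,
`quantify`, `stats`, `all`).

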