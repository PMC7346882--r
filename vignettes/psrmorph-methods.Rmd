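---
title: "Methods: PSR morphometry and multilevel analysis in psrmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSR morphometry and multilevel analysis in psrmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrmorph)
```

# Scope and model

psrmorph quantifies the composition of Picrosirius-Red (PSR) stained
ventricular myocardium — collagen, fat and myocyte percentages of analyzable
tissue area — from calibrated RGB section images, and analyses those
percentages across sampling locations with a multilevel model on the log
scale. This vignette documents the methodological choices: what each stage
assumes, which parameters matter, what the synthetic generators do and do
not emulate, and where the design was genuinely open.

# Pixel classification

PSR renders collagen fibres red against orange-yellow counterstained
myocytes; fat vacuoles, vessel lumens and slide background are unstained and
near white. Classification is by colour-band thresholds in
hue/saturation/value space (RGB banding is available as a dialect): hue
separates the red collagen family from the orange myocyte family far more
robustly than raw RGB, because staining intensity moves saturation and value
but barely moves hue.

The default bands are:

* background: saturation ≤ 0.25 and value ≥ 0.75 (any hue);
* collagen: hue in the red wedge [0.90, 1] ∪ [0, 0.055], saturation ≥ 0.30;
* myocyte: hue in the orange-yellow wedge [0.055, 0.25], saturation ≥ 0.30.

Overlaps are resolved by a fixed priority (background, collagen, myocyte),
and a pixel matching no band is assigned to the nearest band centre
(circular hue distance, weighted ×2 so a half-turn of hue counts as much as
a full swing of saturation or value). The nearest-centre fallback exists so
the class map always partitions the image — label counts are conserved
through every later stage, which is checked by the test suite.

**Calibration caveat.** The band defaults are tuned on this package's
synthetic slides, whose class colours are known Gaussian families. The
colour thresholds used by commercial analysis software on real scanned
slides are vendor-proprietary and unpublished; real-slide use therefore
*requires* explicit user calibration of the bands (`color_bands()`, or the
YAML config consumed by the pipeline). The package deliberately does not
pretend to ship portable stain thresholds.

# Fat detection

Fat cannot be separated from background by colour — both are unstained. It
is defined geometrically: a fat vacuole is an *enclosed* near-white
connected component, i.e. one that does not touch the image border, with

* area between `min_area` (60 µm²) and `max_area` (1100 µm²), an
  adipocyte-plausible window at the default 2 µm/px overview calibration;
* solidity (pixel count over convex-hull area) ≥ 0.85, measured after a
  morphological closing of radius 1 px that smooths rasterization noise.

Border-connected unstained regions — open clefts, slide margin — stay
background. Whether bordering unstained tissue clefts should ever count as
fat is not decidable from first principles; border connectivity is this
package's convention, stated here so users can audit it. The area window is
measured on the *original* component; the closing influences only the
solidity measurement, never which pixels are relabelled (label accounting
again).

# Vessel exclusion

Perivascular collagen is excluded from fibrosis quantification because
vessel caliber varies strongly between samples. Exclusion is driven by
lumen detection among the enclosed unstained components that remain after
fat detection (fat runs first on purpose: small round vacuoles would
otherwise score as excellent ellipses) and are at least `min_lumen_area`
(1600 µm²) — the size windows of fat and lumens are disjoint by default, so
the arbitration is stable.

**Elliptical score.** Each candidate region is scored with the
intersection-over-union between the region and its moment-matched filled
ellipse: the ellipse with the region's centroid, orientation from the
principal axis of the pixel covariance matrix, and semi-axes
$a = 2\sqrt{\lambda_1}$, $b = 2\sqrt{\lambda_2}$ from its eigenvalues — the
standard regionprops convention. For a region that is itself an ellipse
this fit reproduces it exactly (area and moments agree); for arbitrary
regions area- and moment-matching are over-determined, and the moments win.
The score is in [0, 1], equals 1 exactly for rasterized ellipses, is
invariant under translation and 90° rotation on the pixel grid, and
collapses to 0 by convention for degenerate (collinear) regions. Candidates
scoring ≥ `score_threshold` (0.4) are accepted. This score is a
*reconstruction*: it makes the published acceptance threshold operational,
but it is not the (unpublished) vendor formula. The implementation is
checked against a brute-force pixel-enumeration oracle to 10⁻⁹.

**Cuff reach.** The accepted lumen is relabelled `excluded_lumen`; collagen
reachable from it by geodesic dilation *within the collagen label* is
relabelled `excluded_perivascular`, up to a geodesic distance of
`cuff_reach_factor` (default 2.0) × the equivalent lumen radius
$\sqrt{A/\pi}$. Geodesic growth means the exclusion follows the cuff and
never jumps across myocytes to unrelated interstitial fibrosis; scaling the
reach with lumen size keeps the exclusion proportionate across calibers.
The dilation is 8-connected, so geodesic distance is measured in chessboard
steps — documented because it makes results bit-reproducible. Myocyte and
fat pixels are never relabelled, and overlapping reaches of nearby vessels
union without double counting (labels are exclusive).

# Epicardial/endocardial partition

The 50:50 split of free-wall tissue is implemented as an equal-area
distance-rank partition: every analyzable pixel gets its Euclidean distance
(pixel centres, exact distance transform) to the annotated epicardial
surface; pixels are ranked and the cut placed between distance strata as
close to the median as strata allow; the nearer half is epicardial. Among
the readings of a "50:50 categorization" (area split, wall-thickness
midline, manual annotation), the distance-rank split is the only one that
guarantees 50% of *area* on arbitrarily curved walls, which is why it is
the one implemented. Strata are never divided, so the two halves differ by
at most one stratum (one pixel row on a flat slab; ≪1% of area on realistic
curved walls). Septal samples carry a `whole_only` mask — the septum has no
epicardial surface.

Composition percentages then use analyzable tissue (collagen + fat +
myocyte after exclusions) as the denominator. Excluded pixels leave
numerator *and* denominator; keeping cuffs in the denominator would
silently deflate all three percentages. Pixel counts are carried in every
record so pooling is exact: epicardial + endocardial records pool to the
total record identically, and the three right ventricular free-wall samples
of a heart are pooled by pixel count before analysis. The right ventricular
outflow tract keeps its own location label but is grouped with RV for
analysis (only RV/IVS/LV-level results are reported by the reference
analysis; the grouping map is user-overridable).

# Multilevel model

Per component, `log(value)` is modelled as

$$\log y_{ij} = \mu_{\text{cell}(ij)} + x_{ij}^\top\beta + b_i +
\varepsilon_{ij},\quad b_i \sim N(0, \sigma^2_h),\;
\varepsilon_{ij} \sim N(0, \sigma^2_e)$$

with cell-mean fixed effects for each observed (location × region) cell,
optional heart-level covariates (sex, age, BMI), and a random intercept per
heart $b_i$ capturing the within-heart correlation of repeated samples.
Estimation is REML via lme4 (ML available). Conventions, chosen to match
the reference presentation and kept deliberately simple:

* Wald intervals with $z = 1.96$; no small-sample degrees-of-freedom
  correction at ~29 clusters. The Monte-Carlo suite measures the resulting
  CI coverage at ~93–94% rather than the nominal 95% — slightly
  anticonservative, as expected for cluster-level Wald inference, and
  within the accepted 92–98% validation band.
* Geometric means: $\exp(\hat\mu)$; ratios: $\exp(\hat\mu_a - \hat\mu_b)$
  with SE from the fixed-effect covariance. The ratio point estimate is
  identically the ratio of the two geometric means.
* Covariate handling: continuous covariates centred at their sample means,
  sex coded with male as reference, so cell estimates stay interpretable as
  log geometric means at reference covariates. Constant (collinear)
  covariates are an explicit error, checked before fitting.
* Zero values (possible for fat in the septum) have no log. Default:
  replace with half the smallest positive value of that component, with a
  warning and the replacement recorded in the fit object; a strict mode
  fails instead. This is transparent and auditable, not statistically
  innocent — users with many zeros should model presence/absence
  separately.
* Each component is fitted separately (no cross-component constraint, no
  compositional transform), and no multiple-testing adjustment is applied;
  both match the reference analysis style and are stated limitations.
* Singular fits (heart variance at the boundary, e.g. on noise-free data)
  are reported via a message and a flag, never masked.

# Synthetic generators

**Slides.** `generate_slide()` draws a rectangular tissue slab on a
near-white border, elliptical vessel lumens (semi-major 14–24 px, aspect
0.72–1) wrapped in constant-thickness collagen cuffs, enclosed circular fat
vacuoles (radius 4–9 px), and interstitial collagen specks placed until the
realized collagen pixel count matches the requested fraction exactly. Class
colours are Gaussian in RGB around documented centres (collagen strong red,
myocyte orange, unstained near white; SD 0.02–0.03). Ground truth is exact
by construction: `true_fracs` are realized pixel counts, and the acceptance
suite verifies them against independent mask counting. Geometry rules:
vacuoles and vessels never touch the tissue edge (enclosure is the fat
disambiguator, and cuffs must be complete), and interstitial collagen keeps
a 2 px gap from cuffs so perivascular and interstitial collagen are
distinct structures rather than one connected network. Unattainable
requests (vacuole packing, cuff collagen exceeding the collagen budget)
fail explicitly rather than silently truncating.

What the slides do *not* emulate: stain texture and fibre anisotropy,
staining-batch and scanner variation, mixed-colour boundary pixels beyond
Gaussian noise, partial vessels at section edges, and realistic wall
curvature (curved-wall partition is tested on analytic annuli instead).
Passing on synthetic slides therefore demonstrates the pipeline's
*mechanics* — thresholds, morphology, exclusion, accounting — not
performance on real histology, which depends on user calibration.

**Study tables.** `generate_study()` draws
`value = exp(log_mean + b_heart + covariate terms + residual)` per (heart,
location, region, component): log-normal within cells, correlated within
hearts through one shared intercept per heart. Default cell means are the
package's reference composition for structurally normal hearts
(`reference_composition()`, e.g. total collagen RV 15.2%, IVS 8.6%,
LV 9.5%). Defaults `heart_sd = 0.3` and `residual_sd = 0.2` (log scale) are
fixture choices giving within-heart correlation ~0.7 — the real within-heart
correlation magnitude is not documented anywhere; they are *not* estimates.
Sex is assigned as exactly `round(n × female_frac)` females (default 4/29,
minimum one of each sex): a pure Bernoulli draw would occasionally produce a
single-sex study (~1.3% at n=29) whose covariate design is accidentally
collinear, which is a property of the fixture, not of the estimator under
study. Ages and BMIs are Gaussian (32.1 ± 9.9 years, 28.7 ± 7.3 kg/m²),
matching a young-adult non-cardiac-death autopsy population.

# Numerical conventions and degenerate inputs

* Single RNG seed per generator call; RNG state is restored afterwards.
  Identical seed ⇒ bit-identical images, masks and tables; the pipeline
  stages themselves are deterministic.
* Lumen candidates are ordered by centroid (row, then column); ties in the
  partition are broken only between distance strata, never inside one.
* Ellipse rasterization uses pixel-centre membership with ≤ (boundary
  pixels count as inside); the same inequality is used in the score and in
  the generator, so self-consistency is exact.
* Degenerate inputs: empty images, non-RGB arrays, zero analyzable tissue,
  missing free-wall boundary annotations, collinear candidate regions, and
  invalid configuration values all fail with explicit messages before any
  expensive work; a configuration is validated in full before the first
  image is read.
* Fractions in composition records sum to 100 to 10⁻⁶ by construction
  (exhaustive, exclusive labels over the analyzable denominator).

# Validation problem sizes

The test-suite and acceptance-script sizes were chosen as the smallest
problems that still exercise every mechanism at realistic scale: twelve
1024² slides spanning collagen 5–20% and fat 0–12% for segmentation
recovery (tolerance ±1.5 percentage points; observed error is ~three orders
of magnitude smaller because class colours are well separated); 500
Monte-Carlo replicates of the 29-heart design for ratio recovery (±10%),
CI coverage (92–98%) and covariate type-I error (5% ± 2%); and 20+
constructed shapes for score-oracle equivalence at 10⁻⁹.

# Known limitations

* Colour thresholds are not portable to real scanners without calibration;
  no stain deconvolution or machine-learned classification is attempted.
* The elliptical score and the cuff-reach rule are reconstructions of an
  unpublished vendor method; the printed 0.4 threshold is honoured, but
  region-level agreement with that software cannot be verified.
* No vessel-wall segmentation: the exclusion is lumen + collagen cuff, not
  media/adventitia anatomy, and interstitial collagen inside the reach that
  touches the cuff is excluded with it.
* Wald/REML inference is mildly anticonservative at ~29 clusters (coverage
  ~93–94%); a user needing exact small-sample inference should bootstrap at
  the heart level.
* The equal-area split and the RVOT→RV grouping are documented conventions;
  other readings of the reference procedure exist and can be configured,
  but are not the defaults.
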