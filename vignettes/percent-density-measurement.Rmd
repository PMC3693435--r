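---
title: "Measuring percent mammographic density with a two-threshold pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring percent mammographic density with a two-threshold pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodensity)
```

## The measurement model

Percent mammographic density (PD) is the share of the projected breast area
occupied by radiographically dense (fibroglandular) tissue. Dense tissue
attenuates X-rays more than fat, so on a digital mammogram — with the
convention used throughout this package that *higher intensity means denser
tissue* — density measurement reduces to counting bright pixels inside the
breast:

$$\mathrm{PD} = \frac{DT}{DT + FT} \times 100,$$

where $DT$ and $FT$ are the dense- and fat-tissue pixel counts. The pipeline
obtains those counts from two intensity thresholds:

* **T1** separates background from object pixels. It is *proposed*
  automatically (Otsu's between-class-variance criterion over a 256-bin
  histogram of the full image) and may be overridden, mirroring the
  semi-automatic workflow in which a reader adjusts the proposal when labels
  or markers touch the breast. After thresholding, connected components are
  labelled and **only the largest component is kept as the breast**; all
  other objects (view labels, markers) are regions of non-interest and are
  discarded. Objects *connected* to the breast cannot be removed this way and
  are instead subtracted explicitly via invalidation masks, as is the
  pectoral muscle on mediolateral-oblique (MLO) views.
* **T2** separates fat from dense tissue inside the breast. It is always set
  manually (per image, in the session file): the fat/dense boundary is a
  reading judgement, not an image statistic. `t1 <= t2` is enforced so every
  dense pixel is also a breast pixel.

Two preprocessing steps condition the image before thresholding.

**Contrast/brightness normalization.** Assuming the least and most attenuating
tissues are present in every mammogram, a linear histogram stretch maps a low
and a high intensity percentile to 0 and 1. Percentiles are computed over
*nonzero* pixels so the black background (and dead pixels) cannot anchor the
map; the defaults are the 1st and 99th percentiles rather than the absolute
min/max, which makes the stretch robust to isolated outliers while remaining
configurable back to 0/100. A constant-foreground image is returned unchanged
with a warning rather than an error, since a degenerate histogram is a data
problem the batch run should survive.

**Breast-thickness brightness correction.** The compressed breast has roughly
constant thickness between the plates but thins toward the breast edge;
thicker regions attenuate more and therefore look brighter, so interior fat
can masquerade as dense tissue (and edge dense tissue as fat). The correction
multiplies each breast pixel by

$$K_{ij} = \alpha + (1 - \alpha)\, d_{ij}, \qquad \alpha \in [0, 1],$$

where $d_{ij}$ is the *within-row* relative distance from the chest-side
reference to the breast edge: $d = 0$ at the reference (the image border on
the chest side for craniocaudal views, the per-row pectoral boundary for MLO
views) and $d = 1$ at the outermost breast pixel of the row; rows whose edge
coincides with the reference take $d \equiv 1$. $K$ is affine in $d$ with
$K(0) = \alpha$ and $K(1) = 1$: $\alpha = 1$ is a bit-exact identity and
smaller $\alpha$ attenuates increasingly toward the chest side, flattening the
thickness gradient. The distance ramp is deliberately the only thickness
proxy: the correction formula consumes nothing else, physical thickness
reconstruction would require acquisition parameters (compression force, kVp)
that processed screening images do not carry, and a row-wise linear ramp is
exactly invertible, which makes the correction testable (below). The default
order of operations is stretch first, correct second; the correction is a
within-breast rescaling, so applying the global stretch first keeps the
percentile anchors interpretable. Correction is multiplicative because
attenuation with $K \le 1$ is a scaling of recorded brightness, not an offset.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t2` | none (required) | fat/dense intensity threshold in [0, 1], set per image |
| `t1` | Otsu proposal | background/object threshold in [0, 1] |
| `alpha` | 1 | thickness-correction strength; 1 = off, lower = stronger chest-side attenuation |
| `stretch` | (1, 99) | percentiles (over nonzero pixels) mapped to 0 and 1 |
| `connectivity` | 8 | pixel adjacency for component labelling; 8 is robust to thin skin-line connections, 4 available |
| `cutoffs` | (0, 10, 25, 50, 75) | PD cut-offs for categorical comparison (the Boyd scale) |

## Conventions and numerical choices

* **Foreground test at T1 is non-strict** (`>= t1`), and the **dense test at
  T2 is closed on the dense side** (`>= t2`): boundary pixels are assigned
  deterministically and the dense count is non-increasing in `t2` by
  construction.
* **Component ties** (two foreground objects of identical size) are broken in
  favour of the component containing the smallest `(row, column)` pixel in
  lexicographic order, so segmentation is deterministic.
* **Otsu plateaus.** When the histogram has an empty gap between modes the
  between-class criterion is flat across the gap; the proposal returns the
  lowest maximizing bin edge. Any threshold on the plateau induces the same
  classification.
* **Boyd boundaries.** The six Boyd categories (0%, <10%, 10–25%, 25–50%,
  50–75%, >75%) have overlapping printed labels, so a convention is needed:
  exactly 0 is its own category, the interior boundaries 10/25/50 are
  left-closed, and 75 belongs to 50–75% (forced by the strict ">75%" label).
  The generic binning in `categorize_cutoffs()` is purely left-closed — the
  natural reading of labels such as "7%–17%" and ">=29%" used for
  quartile-based risk categories — and therefore agrees with the Boyd
  assignment everywhere except at the exact values 0 and 75, where the Boyd
  scale's own outer labels dictate the special cases. Both conventions are
  documented on their functions; no single generic rule can reproduce both
  outer Boyd boundaries.
* **Percentiles** everywhere (histogram stretch, Bland–Altman P05/P95,
  per-category summaries) use the type-7 linear-interpolation definition,
  R's default.
* **Confidence intervals.** The CCC interval uses Lin's (1989) asymptotic
  variance of the Fisher z-transform, back-transformed; the weighted-kappa
  interval uses the Fleiss–Cohen–Everitt (1969) large-sample standard error.
  Both methods are recorded in the returned objects. Degenerate inputs are
  handled explicitly: CCC on two constant series is an error (agreement is
  undefined), kappa when both raters are constant on the same category
  returns `NA` with a warning (expected agreement is 1).
* **Missing readings** are dropped pairwise with a message giving the count,
  so each rater pair uses its own complete set.

## What the phantom generator emulates

Clinical mammograms cannot ship with a package, so every pipeline stage is
exercised on synthetic phantoms with exact ground truth. A phantom renders:

* a half-elliptical breast against the chest-side border (craniocaudal), or
  with a triangular pectoral wedge in the chest-top corner (MLO) whose
  per-row boundary is returned for the pipeline to use;
* dense tissue as random disks inside the breast, with the last disk clipped
  pixel-wise so the dense fraction of the breast equals the target *exactly*
  (to within one pixel of area) — exact ground truth is worth more for
  testing than anatomical realism;
* a simulated thickness falloff multiplying breast intensities by
  $\alpha_f / (\alpha_f + (1 - \alpha_f) d)$ — unchanged at the chest side,
  dimmed by the factor $\alpha_f$ at the edge. This profile is the algebraic
  reciprocal of the correction factor $K$, so correcting with
  $\alpha = \alpha_f$ restores a perfectly flat field (uniformly scaled by
  $\alpha_f$): after correction a single T2 classifies interior and
  near-edge tissue identically, with zero misclassified ground-truth pixels
  on a noiseless phantom. A linear falloff would only be approximately
  invertible; the reciprocal form turns the correction's purpose into a sharp,
  assertable property.
* off-breast label artifacts (disjoint bright disks in the margin beyond the
  breast) and optional i.i.d. Gaussian pixel noise, clipped to [0, 1].

Defaults were fixed once as the package's study conditions: 256 × 192 pixels,
craniocaudal view, intensity levels 0.06 (background), 0.50 (fat), 0.85
(dense) — near-black background, mid-grey fat and bright fibroglandular
tissue, as in a processed digital mammogram, with gaps wide enough that midway
thresholds (T1 = 0.28, T2 = 0.675) separate the classes exactly in the
noiseless case — dense fraction 0.20 (a typical screening value), two labels,
no falloff and no noise (so ground truth is exact unless a test opts in).
Identical spec and seed give a bit-identical phantom.

What phantoms do **not** model: X-ray scatter, the heel effect, parenchymal
texture, skin line and air gap, anatomical breast shape variation, or
vendor-specific processing. Passing the phantom suite therefore demonstrates
the *contracts* of the pipeline (thresholds, component selection, correction
algebra, exact counting), not clinical accuracy; on real images T2 and the
invalidation step remain reader judgements.

Simulated raters follow an additive model around a shared truth,
`clip(true + bias_r + N(0, sd_r), 0, 100)`. For two raters with equal noise
`s` around a truth of variance `v` the expected CCC is `v / (v + s^2)`, and
the mean pairwise difference equals the bias difference — closed forms the
test suite checks empirically. Clipping at 0 slightly shrinks an injected
bias when the truth range touches 0; the calibration tolerance (±0.15
percentage points on the mean difference) absorbs this.

## Problem sizes used by the tests and acceptance script

The automated checks run 50 phantoms across dense fractions 0.02–0.70
(noiseless with exact thresholds, and with noise sd 0.03 using the Otsu
proposal), 10 identity-correction phantoms, 10 falloff-inversion phantoms,
20 label-removal phantoms with 1–5 labels, 200 random oracle comparisons for
the CCC and weighted kappa (n ≤ 30, k ≤ 6), and one 5 000-image simulated
rater calibration — sizes chosen so the full suite completes in well under a
minute while every property is exercised across its parameter range.

## Known limitations

* No automatic pectoral-muscle detection: MLO pectoral exclusion requires a
  per-row boundary (or an invalidation mask) in the session file, matching
  the manual/interactive character of the original workflow.
* DICOM support is deliberately minimal: uncompressed little-endian transfer
  syntaxes, single-frame monochrome, rescale slope/intercept and photometric
  interpretation only. Compressed syntaxes raise an explicit error; convert
  such files to PNG upstream.
* The package measures area-based PD on 2-D projections; volumetric density
  and texture features are out of scope.
* Regression modelling of density determinants and case–control risk
  estimation are standard fits (`lme4::lmer`, `stats::glm`, `pROC`) on study
  data the package does not ship; the package's output CSV is shaped so such
  models can be fitted directly on it.
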