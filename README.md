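# mammodensity

Semi-automated measurement of **percent mammographic density (PD)** in
full-field digital mammograms, with the rater-agreement statistics used to
validate such tools and a synthetic phantom generator that makes the whole
pipeline testable without clinical images.

Mammographic density — the proportion of the breast occupied by
radiographically dense fibroglandular tissue — is one of the strongest known
risk factors for breast cancer and a standard phenotype in epidemiological
and screening studies. Visual scales (Wolfe, Tabár, BI-RADS, Boyd) are
subjective; computer-assisted thresholding gives a continuous, reproducible
measurement. This package is written for density readers and epidemiologists
who need batch, scriptable PD readings from digital mammograms and
reproducibility analyses across readers.

## The measurement

Pixels are classified by two intensity thresholds (intensities scaled to
[0, 1], higher = denser):

* **T1** — background vs object. Proposed by Otsu's criterion, user
  overridable. The largest connected foreground component is the breast;
  other objects (labels, markers) are discarded, and regions connected to the
  breast (e.g. the pectoral muscle on MLO views) are removed with
  invalidation masks or a per-row pectoral boundary.
* **T2** — fat vs dense tissue inside the breast, set manually per image.

Percent density is the dense share of the breast area:

    PD = DT / (DT + FT) * 100

Before thresholding, the image is conditioned by a percentile histogram
stretch and by a breast-thickness brightness correction that multiplies each
breast pixel by `K = alpha + (1 - alpha) * d`, where `d` is the within-row
relative distance from the chest wall (d = 0) to the breast edge (d = 1) and
`alpha` in [0, 1] is user-set; `alpha = 1` leaves the image unchanged. This
compensates for the thinning of the compressed breast toward its edge, which
otherwise makes thick interior regions look dense.

Agreement statistics included: Lin's concordance correlation coefficient
(with Fisher-z CI), Bland–Altman difference summaries (mean, empirical
P05/P95, limits of agreement), quadratic-weighted kappa for ordered
categories (Fleiss–Cohen–Everitt SE), and per-category PD distribution
summaries for comparison against visual scales.

## Worked example

```r
library(mammodensity)

# a synthetic mammogram with known 30% density, mild noise
ph <- generate_phantom(phantom_spec(true_dense_fraction = 0.30,
                                    noise_sd = 0.02, seed = 7))
m <- measure_pd(ph$image, t2 = 0.675, alpha = 1, normalize = FALSE)
m
#> Percent mammographic density: 30.0% (Boyd category 25-50%)
#>   dense 7325 px | fat 17093 px | t1 = 0.1406 | t2 = 0.6750
#>   breast 24418 px | alpha = 1.00
```

The Otsu proposal put T1 at 0.14 (between the dark background and the
breast), the manual T2 at 0.675 splits fat from dense tissue, and the
measured PD of 30.0% recovers the phantom's true dense fraction; the Boyd
category is the semiquantitative bin the reading falls in.

Agreement between two simulated readers of 200 images (reader 2 biased
−1.6 PD points, both with noise sd 3):

```r
truth <- runif(200, 0, 60)
rr <- simulate_raters(truth, rater_bias = c(0, -1.6), rater_sd = c(3, 3),
                      seed = 11)
lin_ccc(rr$rater_1, rr$rater_2)
#> Lin's concordance correlation: 0.972 (95% CI 0.963-0.978), n = 200
bland_altman(rr$rater_1, rr$rater_2)
#> Bland-Altman: mean difference +1.63 (P05 -4.54 to P95 +8.38), n = 200
weighted_kappa(categorize_boyd(rr$rater_1), categorize_boyd(rr$rater_2))
#> Quadratic-weighted kappa: 0.907 (95% CI 0.878-0.937), n = 200, k = 6
```

The mean difference recovers the injected bias, and the CCC of 0.97 matches
the additive-noise prediction `var(truth) / (var(truth) + sd^2)`.

For batches, `run_batch("session.yaml", out_csv = "results.csv")` processes a
YAML session file (one entry per image: path, view, T1 override, T2, alpha,
invalidation masks, pectoral boundary) with per-image error isolation, and
`run_agreement("readings.csv")` produces all pairwise CCC / Bland–Altman /
kappa summaries. A thin command-line driver with `density`, `agree` and
`phantom` subcommands is installed at
`system.file("cli", "mammodensity.R", package = "mammodensity")`.

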