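---
title: "Radiographic keel morphometry and damage associations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiographic keel morphometry and damage associations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keelmetry)
```

## Scope

Keel bone damage — deviations and fractures of the sternal carina — is
endemic in laying hens, and dissecting keels at the end of lay is the only
direct way to score it. `keelmetry` implements an on-farm alternative:
repeated radiography of live birds, with measurements of radiographic
optical density (tibiotarsal mid-shaft and cranial keel) and keel geometry
(length, mid-depth and their ratio), and the statistical machinery that
relates those longitudinal measurements to dissected-keel damage scores and
to pelvic dimensions. A synthetic layer (bone phantoms and simulated flocks)
makes every stage testable without any study data.

## Measurements on radiographs

All measurements start from keypoint annotations (a sidecar JSON file): a
line drawn across the tibiotarsal mid-shaft, a polyline along the keel from
the pila carinae to the keel tip, mid-depth and cranial-depth lines, an
anchor for the keel-density line, and an optional off-bone background
rectangle. The package deliberately contains no automatic segmentation; it
measures whatever is annotated, as an operator would in an on-screen tool.

**Wide-line profiles.** The density proxies are areas under wide-line
intensity profiles: at each 1 px step along the line's axis the profile
value is the average of the bilinearly interpolated image across the
perpendicular width (100 px for the tibiotarsal region, 25 px for the
keel). The perpendicular average is computed at 0.1 px sub-pixel spacing,
i.e. as a close approximation to the continuous width-average of the
bilinear interpolant. A coarser 1 px perpendicular sampling was considered
and rejected: on textured images it is a noticeably biased estimate of the
width-average, while the fine quadrature agrees with dense brute-force
sampling to about 1e-3 and leaves the closed-form cases (constant fields,
axis-aligned bands with edges on half-pixel boundaries) exact.

**AUC.** The profile's area under the curve uses the trapezoidal rule over
the sampled positions. Positions are in px, or in mm when the image carries
pixel spacing (DICOM PixelSpacing or a user-supplied fallback); the unit is
recorded in the output. Whether the original tooling summed raw values or
integrated is not observable from its outputs; the difference is O(step)
and the trapezoid is the self-consistent choice with the closed forms used
in testing.

**Tibiotarsal density.** The axis is the user's line across the mid-shaft,
so the axis length equals the drawn bone width and the measure scales with
bone width by construction. That is a property of the original measurement
protocol, not an accident, so the default preserves it; a width-normalized
variant (AUC divided by the drawn length) is available via
`widthNormalized = TRUE` for analyses that want a width-free proxy.

**Keel density.** A 10 mm line of width 25 px across the pila carinae. The
cranial ridge is used because it essentially never fractures, so the
measure is not inflated by callus over-mineralization. Realizing "10 mm"
requires pixel spacing; without metadata or a fallback the measurement
errors rather than silently guessing.

**Background correction.** When a background rectangle is annotated, the
median intensity of that rectangle times the profile's position span is
subtracted from the AUC (clamped at zero). The median is robust to stray
bright structures in the rectangle. This makes the density proxies
invariant to a uniform haze pedestal, which the phantom tests verify to
within 1%.

**Keel geometry.** Keel length is the arc length of a natural cubic spline
through the clicked centerline points, parameterized by chord length and
integrated with 1000-segment quadrature; the spline midpoint is the point at
half arc length. Mid-depth and cranial depth are the Euclidean lengths of
their annotation lines; the ratio `xlm = length / mid-depth` is the
geometry index (about 5 for an undamaged keel — e.g. a 10 cm keel with a
2 cm mid-depth). A warning is raised when the mid-depth line misses the
spline midpoint by more than 10 px. At week 16 the keel is only partly
ossified; those records carry an `ossified_only` flag.

**Photometric convention.** Images are canonicalized on load so that larger
values mean denser tissue; DICOM MONOCHROME1 sources are inverted as
`max - pixels`. Coordinates are 0-based, x = column, y = row, at pixel
centers.

## Dissected-keel scoring

Damage localization uses the three keel thirds (cranial, middle, caudal)
coded 0–7; the extent score is the number of affected thirds
(`localizationToExtent`, 0–3). Sizes are ordinal (0, <0.5 cm, ≥0.5 cm for
deviations; none/minimal/moderate-severe for callus); the fracture count is
0–4 with 4 meaning "at least four", stored as a censored flag consumed by
the count model. The validator enforces the protocol invariants
(localization 0 exactly when the size is 0, extents equal to the recoding,
censoring only at the cutoff). The headline damage prevalence counts
deviation-or-fracture; callus is tabulated separately.

## Correlation machinery

Ordinal scores are treated as discretized latent standard normals.
`polychoric` maximizes the multinomial likelihood of the contingency table
jointly over the latent correlation and both threshold vectors; `polyserial`
does the mixed continuous-ordinal analogue with the continuous margin
standardized by its ML moments. Standard errors come from the inverse
observed information (correlation diagonal, delta method through the
`atanh` parameterization). A two-step variant (margin thresholds first) is
available behind `twoStep = TRUE` for cross-checking; on 2x2 tables the
joint and two-step estimators coincide, which the tests exploit against an
independent grid-search tetrachoric oracle.

Numerical choices: rectangle probabilities come from a deterministic
bivariate-normal CDF (`bvnCdf`, exact to ~1e-14); cell probabilities are
floored at 1e-300 inside logs; thresholds are optimized on an unconstrained
scale (first threshold + log-increments) so ordering can never break;
estimates with |rho| above 0.9999 are capped and flagged as boundary, with
the standard error reported as NA rather than a fabricated number.

The longitudinal matrices across the seven measurement occasions (weeks 16,
29, 42, 55, 68; whole-body post-mortem PM; dissected-bone PMD) use Pearson
correlations with the large-sample standard error
`sqrt((1 - r^2) / (n - 2))`, pairwise-complete, with per-cell n reported
and cells under 3 pairs left empty. Live and post-mortem occasions are kept
as separate rows/columns and never pooled into one variable, because the
X-ray device was recalibrated between them and their means are not
comparable. Group comparisons of the ratio across score levels use one-way
ANOVA with Tukey's HSD at 0.05 and a compact letter display built by
insert-and-absorb over the non-significance graph.

## Regression models

The damage model per measurement occasion is

    y = b0 + b1 operator + b2 tibiotarsal + b3 keel + b4 xlm
        + b5 bodyweight + e

with the family chosen by the response: ordinary least squares for equally
spaced ordinal scores (treated as numeric, which is the protocol's own
reading), logistic regression for binary damage, and a right-censored
Poisson model for the fracture count. The censored Poisson log-likelihood
is, with censor point c,

    sum_{uncensored} log Pois(y_i; lambda_i)
      + sum_{censored} log P(Y >= c; lambda_i),    log lambda_i = x_i' b

maximized by BFGS from the uncensored Poisson start, with Wald standard
errors from the observed information. With no censored observations this is
exactly Poisson regression (the tests require log-likelihood agreement to
1e-9). The operator enters as a treatment-coded fixed effect (reference =
first level alphabetically) and is dropped with a warning when only one
scorer is present.

The pelvic model adds the pelvic x tibiotarsal interaction:

    y = b0 + b1 operator + b2 pelvic + b3 tibiotarsal
        + b4 pelvic * tibiotarsal + e

run separately for pelvic width (apex pubis to apex pubis), pelvic depth
(pubis to caudal keel end) and pelvic capacity (their product, validated
against the stored columns). Pelvic dimensions correlate about 0.65 with
body weight, so they are residualized on body weight by OLS and re-centered
at their original mean before entering the model; body weight is not added
again as a covariate, since residualization already removes the shared
variance and adding both would re-introduce near-collinearity. No
multiple-testing correction is applied across ages or responses (each model
is reported on its own terms); `p.adjust` can be applied downstream if a
family-wise summary is wanted.

## Synthetic phantoms

Phantoms are additive-attenuation images: a vertical tibiotarsal band and a
keel band of constant half-width along a centerline that runs straight down
the cranial ridge and bends caudally to the tip through a quadratic Bezier,
plus optional uniform haze and Gaussian noise. Additive attenuation (no
Beer-Lambert exponentiation) is the right target because every measurement
in the package is linear in intensity. Band edges sit on half-pixel
boundaries and the standard annotations extend a small margin past the
edges, so the trapezoidal AUC of the bilinear reconstruction equals the
analytic attenuation integral (level x band width) exactly; recovery errors
then measure noise and interpolation, not rendering artifacts. The phantom
truth record carries the centerline arc length (10^-4-resolution
quadrature), band widths and attenuation integrals. Recovery on randomized
batches is within 2% for geometry and 1% for the density integrals, and
test-retest correlations under 1 px annotation jitter exceed 0.9 — the same
qualitative property reported for human repeat measurements, checked as a
property rather than a number.

## Simulated flocks

`simulateFlock` draws one latent Gaussian system per bird:

* a dissected block over (deviation, fracture, callus liabilities, keel
  length, keel mid-depth) with the dissected-keel correlation structure
  (deviation–fracture 0.34, fracture–callus 0.79, fracture–mid-depth
  −0.33, ...); sizes arise by thresholding at the study's marginal
  frequencies (deviation 0.25/0.29/0.46, callus 0.17/0.41/0.42);
* fracture counts through a Gaussian copula over a Poisson(2) margin,
  right-censored at 4 ("at least four");
* extents drawn hierarchically given size — an extent liability correlated
  with the size liability, thresholded at the conditional extent
  frequencies, then a localization code of that extent drawn from the
  observed within-extent weights — so the recoding invariant holds by
  construction;
* radiographic anchors (keel density, tibiotarsal density, ratio) at the
  dissected-bone occasion, correlated with the damage liability, propagated
  backwards through the seven occasions as a nonstationary AR(1) whose
  adjacent correlations are the study's adjacent-age values (e.g. ratio
  week 55–68 at 0.90, keel density adjacencies near 0.8, tibiotarsal
  adjacencies low); the week-16 ratio mean is set low because the keel is
  only partly ossified there;
* pelvic width and depth correlated 0.65 with the final body weight
  (means 40.43 and 71.92 mm, sds 5.30 and 10.38 mm), capacity = width x
  depth, implying a mean capacity near 2936 mm^2.

Two generator quantities are not printed anywhere and were calibrated once,
at design time, against stated conditions: the extent-given-size loadings
(0.62/0.65/0.50) reproduce the size-extent polychoric correlations (0.89
for deviations), and the keel length/mid-depth moments (10.4 ± 0.8 cm,
2 ± 0.28 cm) put the ratio/mid-depth correlation near −0.88 with an
undamaged-keel ratio near 5. They are fixed defaults, not tuning knobs.

What the generator does **not** emulate: muscle/feather superimposition and
exposure drift (only uniform haze + white noise), operator disagreement in
scoring (operator labels are random, with no systematic effect unless one
is injected), missingness mechanisms other than missing-completely-at-
random corruption, and any real shape variation of keels beyond the
parametrized centerline family. Green tests on synthetic data therefore
validate the estimators and the pipeline plumbing under the model's own
assumptions; they do not certify measurement accuracy on real radiographs,
where annotation quality and imaging physics dominate.

## Cleaning and the pipeline

`mergeClean` inner-joins sources on bird id and excludes birds with a
missing id or missing values in the required columns, logging every
exclusion with a reason. Cleaning is analysis-scoped by default (a bird
missing only one occasion still contributes to other occasions through
pairwise-complete correlations); passing an explicit `required` set
reproduces a strict all-complete design. `runAll` is a pure function of
(data, config): it validates requested response names before computing,
writes the frequency, co-frequency, correlation, group-comparison and
coefficient tables plus a manifest, aborts with the stage name on any
failure (removing partial outputs), and produces byte-identical CSVs on
identical inputs.

## Problem sizes

The test suite simulates flocks of 300–8000 birds, 50-phantom recovery
batches, n = 10000 latent-correlation recoveries, 200-replicate coverage
runs for the regression families and 300-replicate Wald-coverage checks;
the acceptance script uses 8000 birds and 50 phantoms. These sizes put
Monte-Carlo noise well inside the asserted tolerances (e.g. ±0.02 on
proportions, ±0.03 on correlations at n = 10000) while keeping a full run
in the low minutes on one core.

## Known limitations

* The DICOM codec is intentionally minimal (uncompressed little-endian
  monochrome, pixel spacing, photometric interpretation); compressed or
  color transfer syntaxes are rejected with a clear error.
* Polychoric/polyserial standard errors are Wald-type and degrade near the
  boundary; boundary fits are flagged instead.
* Ordinal responses in the linear family are treated as equally spaced
  scores by design; no proportional-odds alternative is provided.
* Each measurement occasion is modeled separately; there is no joint
  longitudinal (mixed-effects) model across ages.
* The fracture-count copula reproduces latent correlations only
  approximately at small counts; the tests budget for that with the 0.05
  correlation tolerance.
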