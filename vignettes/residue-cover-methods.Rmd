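---
title: "Measuring crop residue cover: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crop residue cover: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescover)
```

## The measurement problem

Conservation agriculture counts a plot as adopting residue retention when
at least 30% of the soil surface is covered by organic material, and
graded statistics distinguish 30--60, 60--90 and >90% cover. Cover is
cheap to ask about and expensive to measure well: the reference protocol
is a line transect (a 30 m rope marked at 1 m intervals, read four times
from the field corners), while surveys rely on respondent or enumerator
percent estimates, visual-aid photo scales, drone photographs, or
satellite tillage indices. `rescover` implements all seven measurement
channels over a common synthetic ground truth, so their joint behaviour --
rank correlations, threshold misclassification, category false reporting,
and covariate-driven measurement error -- can be studied under controlled
and repeatable conditions.

Because the original field records of such experiments are typically not
public, the package's generator is calibrated to reproduce published
summary structure: record counts (197 households, 314 plots; 182 plots
with a drone estimate, 251 with a satellite estimate), the Spearman
correlation matrix of the seven methods, marginal summaries (benchmark
median 60%, a -30 point interviewee median gap, +2.5 points for
enumerator visits, -5 points for the drone method, 4% of plots above 90%
cover), and a 25% mean between-visit decay.

## The survey generator

### Dependence: a Gaussian copula on rank targets

Published results fix only the rank dependence of the seven measures, so
the generator uses the minimal completion: a Gaussian copula. For
continuous margins the copula parameter that yields a Spearman rank
correlation $\rho_s$ is the closed form

$$\rho = 2 \sin\!\left(\frac{\pi \rho_s}{6}\right),$$

implemented in `spearman_to_pearson()`. The visual-aid methods are
reported on a six-level photo scale, which compresses rank variation;
for those margins the parameter is instead found by bisection against a
common-random-numbers Monte Carlo evaluation of the post-discretization
Spearman (`calibrate_discretized_rho()`). Common random numbers make the
objective exactly monotone in the parameter, so bisection is reliable;
the routine reports the maximum attainable rank correlation when a
target exceeds what the discretization permits.

Two sampling modes exist deliberately:

* **bivariate mode** (`sample_copula_pair()`) draws one pair at a time
  with its exact (calibrated) parameter -- this is the mode whose
  dependence fidelity the package's acceptance checks assert;
* **full-matrix mode** (`simulate_survey()`) draws all seven measures
  jointly. The 7x7 latent matrix uses the closed-form link everywhere,
  with calibrated overrides for the two benchmark/visual-aid entries;
  calibrating all eleven discretized pairs jointly is not identified
  from pairwise targets alone, and the joint matrix exists to make
  plot records internally coherent, not to reproduce every pairwise
  entry exactly. The assembled matrix is passed through a Higham
  nearest-positive-definite projection (`nearest_pd_correlation()`,
  via `Matrix::nearPD`); the default matrix is already positive
  definite, so the projection is an identity there.

### Margins

The benchmark margin is a Beta distribution rescaled to $[0, 100]$ whose
shape parameters (3.1339, 2.1939) were solved once so that the median is
60 and $P(X > 90) = 0.04$; the support genuinely reaches 0 and 100. The
other continuous margins are rescalings pinned by their published median
offsets: interviewee 30, enumerator 32.5, satellite identical to the
benchmark. The drone margin is a separate Beta with total concentration
25 and median 55, reflecting the visibly compressed spread of
image-derived estimates. The six-level visual-aid scheme uses cut points
{10, 25, 40, 60, 80} and reported values {5, 17.5, 32.5, 50, 70, 90}: the
published photo levels are not printed anywhere, any monotone six-level
scheme is admissible, and this one brackets the 30% adoption threshold
so threshold analyses remain meaningful. The interviewee visual-aid
discretizes an interviewee-like underlying perception; the enumerator
visual-aid discretizes a benchmark-like one.

### The perception-error layer

Measurement-error regressions in this literature find that the
probability of misclassifying a plot at the 30% threshold rises with
field size and distance to the plot and falls with slope (sloped fields
offer a better viewing angle). The generator therefore perturbs the four
survey-reported measures with a perception error built from a covariate
index

$$g_i = 0.45\, z_{\log \text{field size}} + 0.30\, z_{\text{distance}}
  - 0.45\, [\text{slight slope}] - 0.90\, [\text{steep slope}],$$

centred to mean zero. Both the spread *and* the centre of the error move
with this index: measurement $m$ becomes
$\min(100, \max(0, m - \delta s_m g_i + \varepsilon_i))$ with
$\varepsilon_i \sim N(0, (\sigma s_m e^{0.3 g_i})^2)$, where $\delta = 5$
percent points, $\sigma = 6$ percent points and $s_m$ is a per-method
share (1.0, 0.5, 0.8, 0.4 for the four survey methods; on-site methods
are less error-prone). The systematic component is a deliberate model
choice: the interviewee margin's median (30) coincides with the adoption
threshold, so a purely symmetric noise scale moves classifications in
both directions at almost equal rates and its covariate signature on the
error outcome is statistically invisible at realistic sample sizes. A
directional component -- large, distant, flat fields are *under*-estimated
-- makes the documented sign pattern identifiable, which is exactly what
the package's sign-recovery checks assert (positive field size and
distance, negative slope, each $|t| > 2$ at 10,000 plots).

Two consequences are worth knowing. First, the benchmark and the two
instrument-derived measures carry no perception error. Second, the error
layer slightly lowers the survey-level rank correlations below the
copula targets (the benchmark/interviewee entry lands near 0.5 rather
than 0.60 at the default settings); bivariate mode is the mode that
reproduces the targets, and the two modes are separate API surfaces for
that reason.

### Counts, missingness and decay

Record counts are exact by construction: the first 117 households
contribute two plots and the remaining 80 one plot (only the totals are
published; this assignment is the simplest consistent one). Drone and
satellite estimates are missing completely at random with exact observed
counts 182 and 251 -- nothing in the published record identifies an
informative missingness mechanism, so none is modelled. Between-visit
decay (`apply_decay()`) multiplies each cover value by $1 - d$ with $d$
Beta-distributed (mean 0.25, sd 0.12 by default, matched by moments), so
second visits never exceed first visits and the mean proportional
reduction converges to the configured 25%.

## Synthetic imagery

`generate_field_scene()` rasterises random straw strokes (30 cm x 0.8 cm
by default, no anti-aliasing) onto a soil background until the counted
cover is within 1 percent point of the target, trimming the final stroke
pixel-by-pixel on overshoot -- ground truth is therefore exact by
counting, never estimated. Rendering uses per-soil-type colours (the
dark clay vertisol darkest), a common multiplicative illumination factor
per pixel (+/-10%) and small per-channel jitter (+/-3 counts). A single
`contrast` parameter interpolates the straw colour toward the scene's
soil colour: at 1 the two colour populations are disjoint in the
excess-green index, at 0 they are identical, and segmentation error
degrades continuously in between -- the package's stand-in for the
lighting and colour-cast failures that break excess-green segmentation
on real drone photographs.

The palette is deliberately structured so that the excess-green gap
survives per-channel contrast stretching: straw is much greener than
every soil, *bluer-than-straw* soils bound the blue channel, and straw
red sits inside the soil red range. A per-channel linear stretch
rescales each channel by the reciprocal of its range; if any channel is
narrow, its noise is amplified enormously, and a palette without this
structure loses the index separation after colour balance.

The default scene is 1024 x 768 pixels at 0.27 cm/pixel (a ~7.6 m x
5.7 m footprint, drone-like). The pipeline default is 320 x 240: on
these scenes the segmentation chain is resolution-invariant (the test
suite checks exact invariance under nearest-neighbour upsampling), and
the smaller default keeps a full 314-plot end-to-end run under a minute.

`render_spectral_scene()` builds the satellite stand-in on a 30 m grid:
`swir2 = swir1 * (1 - k * cover/100) * (1 + eps)` with `k = 0.4`, so the
tillage index is strictly increasing in cover absent noise, plus
multiplicative noise (`noise_sd = 0.15`) and an extra vertisol
perturbation (`0.06`) emulating the spectral effect of dark, moist clay.
The noise default was chosen by a one-off sweep so that the rank
correlation between true cover and the extracted scaled index on 251
plots sits near 0.55--0.6, the order of magnitude a satellite tillage
index achieves against a field benchmark; the test suite asserts only
the qualitative bound (> 0.5). Rasters are written as two-band 32-bit
float TIFF with the affine geotransform in a plain-text ESRI world file
(`.tfw`); values round-trip at single precision.

## The segmentation chain

`segment_cover()` composes four steps, each exposed separately:

1. `color_balance()` -- per-channel linear stretch saturating
   `floor(n * f/2)` pixels per tail (default `f = 0.007`, the common
   0.35%-per-tail default of desktop image tools); a constant channel is
   returned unchanged with a warning.
2. `excess_index()` -- signed `2G - R - B`, range $[-510, 510]$.
3. `binarize()` -- Otsu's threshold by exhaustive histogram search
   (deterministic, parameter-free; the published processing chain never
   states its cut, and a `fixed` threshold option can mimic any choice).
   The threshold convention is strict `>`, ties to soil: a direction had
   to be fixed and is documented rather than meaningful.
4. `cover_fraction()` -- residue pixels over total pixels.

One guard sits above Otsu: when the raw index's standard deviation falls
below 15 (an effectively uniform image -- all soil or all straw), Otsu
would split noise near 50/50, so the scene is classified wholesale by
the sign of its mean excess-green index. Homogeneous soil scenes measure
~6 index-sd units and homogeneous straw ~11 under the default renderer,
comfortably under the guard; any genuine two-class scene at usable
contrast measures far above it. The guard is bypassed with a fixed
threshold.

The degradation behaviour is asserted only qualitatively: mean absolute
segmentation error is non-decreasing as contrast falls. The package
deliberately does **not** claim to reproduce the negative drone-method
correlation observed in the field -- that arose from uncontrolled
acquisition conditions, not from the segmentation algorithm, and here it
enters only through the generator's dependence targets.

## The line transect

`lt_estimate()` lays a rope at each corner along the inward 45-degree
bisector; `read_transect()` samples the mask at the midpoints of the 30
one-metre intervals (0.5 m, 1.5 m, ...) and counts marks whose
containing cell is residue -- point sampling with no mark width, the
simplest reading of "look straight down above each mark". The field
estimate is the mean of the four per-transect percentages, hence always
a multiple of 100/120. On homogeneous masks each mark is an independent
Bernoulli draw, so the estimator is unbiased with standard error
$\sqrt{p(1-p)/120} \times 100$; the test suite verifies this at five
cover levels over 1,000 replicates each. Fields shorter than the rope
along the corner diagonal clip the transect with a warning and rescale
the marks to the available length -- the exact corner geometry of the
protocol is not fully specified anywhere, so placement is configurable
and the clipping behaviour is a documented convention.

## The tillage index

`compute_ndti()` is the standard normalized difference
$(\text{SWIR1} - \text{SWIR2}) / (\text{SWIR1} + \text{SWIR2})$ with
full parenthesisation -- the literal unparenthesised reading sometimes
seen in print is dimensionally nonsensical. Zero-sum pixels are flagged
invalid rather than producing numbers. `scale_ndti()` applies the fixed
affine map $(x + 1) \times 50$ to $[0, 100]$ -- no empirical calibration,
matching the uncalibrated use of the index this package emulates.
`extract_plot_value()` takes the single containing 30 m pixel by default
(mixed-pixel dilution is a documented limitation of that choice, not
corrected); a `mean3` mode averages the 3x3 block for users who prefer
smoothing, since published practice does not say which was used.

## The comparison framework

`spearman_matrix()` uses pairwise-complete observations (so
benchmark/drone cells use 182 plots and benchmark/satellite cells 251)
with average ranks for ties and a per-cell significance flag; all-tied
vectors yield an undefined correlation flagged rather than a number.
Adoption is classified inclusively (`>= 30`: "at least 30%" forces it),
and AQUASTAT bins are lower-inclusive half-open -- boundary handling is
never stated in the sources this emulates, so it is fixed and
documented. `fit_lpm()` is ordinary least squares on the binary error
outcome -- the linear probability model, with plain (non-robust) standard
errors by default and reference levels male head, teff residue, leptosol
soil, flat slope; household covariates enter only for the
interviewee-reported methods, mirroring how such error regressions are
reported. Coefficient magnitudes depend on covariate scaling choices
that published tables do not pin down, so the package asserts sign and
significance patterns on synthetic data, never magnitudes.

## Problem sizes and numerical checks

The package's calibrated-simulation checks use 500,000 draws per copula
pair (Monte Carlo standard error ~0.0014 on a Spearman estimate, against
a +/-0.01 assertion band) and 100,000 draws for the decay check;
bisection calibration uses 200,000 common-random-number draws per
evaluation with tolerance 0.003 and is cached per session. Property
suites use 50 segmentation scenes at 320 x 240, five cover levels x
1,000 transect replicates on 110 x 110 masks, exhaustive permutations of
1..6 against the rank-formula oracle, an explicit normal-equations
oracle for the regression, and 10,000 plots for sign recovery. These
sizes are the package's choices: large enough that every stochastic
assertion sits several standard errors inside its band, small enough to
run interactively.

## What passing tests do and do not show

The generator reproduces published *summary structure* -- dependence,
margins, counts, decay, sign patterns -- under a Gaussian copula with
independent perception noise. It does not model spatial autocorrelation
between plots, enumerator identity effects, informative missingness,
atmospheric effects, mixed pixels, or real acquisition failures; the
synthetic imagery has exactly two colour populations and no shadows,
orthomosaic seams or specular highlights. Field-study accuracy rates at
the 30% threshold (in the low-to-mid 80s for the better methods) and
error-regression coefficient magnitudes depend on unavailable field
data and are intentionally not asserted; what carries over to real data
is the machinery -- estimators, indices, confusion and category
accounting, regressions -- plus the qualitative facts built into the
generator, no more.
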