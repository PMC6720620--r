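---
title: "Classifying the savanna continuum with coupled NDVI and surface temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the savanna continuum with coupled NDVI and surface temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savannacover)
```

## The problem

Savannas are not a set of discrete covers but a continuum from open
grassland through shrubland to woodland. The structural classes share
species and differ mainly in woody-plant height and density, so their
spectral signatures overlap badly and conventional supervised classifiers
confuse them — in the wet-season assessment this package is built around, a
support vector machine reached only 34% overall accuracy on a three-class
savanna landscape.

Two continuous covariates do separate the classes when used *together*:

* **NDVI**, the normalized difference vegetation index,
  $v = (\rho_{NIR} - \rho_{red}) / (\rho_{NIR} + \rho_{red})$, a greenness
  proxy in $[-1, 1]$;
* **BBST**, blackbody surface temperature: brightness temperature obtained
  from the thermal band by inverting Planck's relation, with *no*
  emissivity correction (correcting for emissivity would require knowing
  the land cover, which is the thing being estimated).

Denser, taller vegetation is greener and — through evapotranspiration and
shading — cooler at overpass time. Woodland therefore occupies the
high-NDVI/low-BBST corner of the feature plane, grassland the
low-NDVI/high-BBST corner, and shrubland sits between, overlapping each
neighbour on either covariate alone but much less in the joint plane.

## The radiometric chain

Thermal digital numbers decode to spectral radiance by the linear rescale

$$L_\lambda = \frac{L_{max} - L_{min}}{Q_{max} - Q_{min}} (DN - Q_{min}) + L_{min},$$

and radiance to brightness temperature by

$$T = \frac{k_2}{\ln(k_1 / L_\lambda + 1)},$$

with $k_1, k_2$ the sensor's prelaunch calibration constants; Celsius is
kelvin minus 273.15. The constants live in image metadata and are required
inputs (`calibrationConstants()`) with no defaults; the synthetic generator
supplies a self-consistent Landsat-8-like set (`syntheticCalibration()`).
BBST is strictly increasing in radiance, so the chain is invertible —
`temperatureToDN()` is the exact inverse used by the generator, and the
package's tests exercise the round trip to sub-microkelvin error.

Two deliberate simplifications: no emissivity parameter is exposed (BBST is
the quantity of interest, by design), and BBST is computed from a single
configured thermal band — the sensor carries two and no defensible
combination rule exists, so none is invented.

## The rule-based classifier

A `RuleSet` holds, per class, an NDVI condition and a BBST condition (each
an interval or one-sided bound) plus a precedence order. The shipped
wet-season reference set (`referenceRuleSet()`, stored as JSON so the
thresholds are bit-exact inputs) is:

| class     | NDVI            | BBST (°C)        |
|-----------|-----------------|------------------|
| woodland  | > 0.41          | < 36.5           |
| grassland | < 0.36          | > 38.6           |
| shrubland | 0.28–0.51 incl. | 36.7–39.3 incl.  |

Three semantics are design choices worth stating:

* **Precedence.** The three boxes overlap (NDVI 0.30 at 39.0 °C satisfies
  both the grassland and the shrubland conditions) and leave gaps (NDVI
  0.45 at 36.6 °C matches nothing). `applyRules()` tests classes in a
  stated order — woodland, grassland, shrubland by default, configurable —
  and assigns the first full match; gap pixels get an explicit
  *unclassified* code rather than a forced class. This is deterministic
  and auditable; how the original mapping resolved overlaps is not
  documented, so first-match in the published listing order is our choice.
* **Boundary inclusivity.** One-sided bounds are strict ("higher than",
  "less than"), interval bounds inclusive ("between"), read literally from
  the published rules and preserved through serialization.
* **Unclassified handling.** `classProportions()` by default renormalizes
  over the three cover classes (the published percentages are three-class),
  with `includeUnclassified = TRUE` available; unclassified counts are
  reported in the pipeline log either way, because silent unclassified
  inflation is the classic failure mode of threshold classifiers.

### Rule induction

The original thresholds were read manually off the training-pixel scatter.
As a reproducible surrogate, `induceRules()` sets each class's conditions
to the empirical quantile interval $[q_{lo}, q_{hi}]$ of that class's
training pixels, default $[0.02, 0.98]$ — trimming 2% tails keeps a few
outlying pixels from inflating a box. With the default trim, each class's
*own-rule recall* (the share of its training pixels inside its own box,
`ruleRecall()`) is at least $1 - 4 \times 0.02 = 0.92$ by a union bound
over the two covariates' two tails. We define recall as box membership
rather than post-precedence assignment: precedence deliberately hands
contested pixels to the earlier class, so assignment-based recall of a
later class conflates box quality with the (separately documented)
precedence decision.

## Accuracy assessment

`errorMatrix()` cross-tabulates mapped against reference labels with rows
= mapped class and columns = reference class. Overall accuracy is
$100 \cdot \mathrm{tr}(M) / \sum M$; omission error of class $j$ is
column-wise, $100 (c_j - m_{jj}) / c_j$, and commission error row-wise —
the orientation is pinned down by the published table's own arithmetic
(its omission figures divide by column totals). Unclassified predictions
at reference sites are tallied aside and excluded from the 3×3 table,
which has no unclassified row. A zero row or column total yields `NA`,
never a fabricated 0 or 100. `svmBaseline()` (RBF kernel, unit-variance
scaling, fixed seed, via **e1071**) provides the generic supervised
comparison; it is a reproducible stand-in, not a replication of any
particular commercial implementation.

## Scale bridging and time series

To read a coarse (≈250 m) NDVI record through a fine (30 m) class map,
`aggregateClassMap()` labels each coarse cell with its modal fine class
*only if* that class holds at least a purity threshold (default 0.75) of
the cell's valid fine pixels; mixed cells are masked. The threshold lives
strictly above 0.5 so "modal" means "majority", and 0.75 makes each zone's
coarse NDVI attributable to one cover class while retaining most cells of
a patchy landscape. `zonalClassSeries()` then takes per-class means of
each seasonal raster over the zones.

Seasons partition months as MAM, JJA, SON, DJF. December is assigned to
the DJF of the *following* January–February, keeping each DJF contiguous
(the source record's convention is unstated; this is ours). Water years
run 1 October–30 September and are labelled by their ending September
year; `waterYearTotals()` drops any water year with a missing month —
with a warning — rather than summing eleven months, and reports anomalies
against the mean of complete years. Trends are ordinary least squares
(`stats::lm`): `linearTrend()` for a single series, and
`seasonalSeriesTrends()` regressing NDVI on year *with season as an
additive factor*, so the seasonal cycle cannot bias the yearly slope.

## The synthetic generator

No archive imagery ships with the package; every stage is exercised on
synthetic scenes whose statistical structure matches what the analysis
assumes.

**Fine scenes** (`generateScene()`). The class mosaic is a Gaussian white
noise field smoothed to a configurable patch scale (default 8 pixels) and
converted to classes by field rank, so realized class counts equal the
configured fractions up to integer rounding — grassland in the low-field
patches, woodland in the high. Default fractions are the published mapped
landscape shares (22.87 / 35.93 / 41.20%). Each pixel draws (NDVI, BBST)
from its class's generating box — defaults are uniform draws over the
published wet-season training ranges (woodland 0.40–0.68 and 32.5–36.4 °C;
shrubland 0.28–0.51 and 36.7–39.4 °C; grassland 0.18–0.38 and
38.6–41.3 °C; a truncated-normal family is available). Bands then *encode*
the draws: with a fixed brightness sum $s = \rho_{NIR} + \rho_{red}$
(default 0.6, a mid-range value for vegetated land), NDVI inverts to
$\rho_{NIR} = s(1+v)/2$, $\rho_{red} = s(1-v)/2$; the thermal DN is the
exact radiometric inverse of the drawn temperature. Full reflectance
spectra are not modelled because only NDVI and BBST feed the analysis.
Thermal DN are floating point by default so round trips are exact;
`quantizeDN = TRUE` emulates sensor quantization (sub-millidegree error at
16 bits). Training polygons are non-overlapping axis-aligned squares
(default six per class, 5×5 pixels, never smaller than 3×3 — the 90 m
field-sampling floor) placed inside pure-class patches.

Note the generating boxes are *not* the rule boxes: grassland NDVI runs to
0.38 while the grassland rule cuts at 0.36, woodland NDVI starts at 0.40
while its rule needs > 0.41, and the shrubland BBST range tops at 39.4 °C
against a 39.3 °C rule bound. Classifying a default synthetic scene with
the reference rules therefore leaves a few percent unclassified and swaps
a small fraction between grassland and shrubland — which is the realistic
regime, and still lands the three-class proportions within three
percentage points of the generating fractions.

**Coarse stacks** (`generateCoarseNdviSeries()`). Each coarse cell takes
the majority fine class; its value in year $t$ and season $s$ is
$b_{c,s} + \beta_c (t - t_0) + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$, clipped to $[-1, 1]$. Default baselines keep woodland >
shrubland > grassland in every season with a wet-season (DJF/MAM) peak and
dry-season (JJA) trough; default trends are mild declines steepest in
grassland ($\beta$ = −0.004, −0.002, −0.001 per year for grassland,
shrubland, woodland), the qualitative pattern of the 2000–2016 record, and
$\sigma$ defaults to 0.01 NDVI.

**Precipitation** (`generatePrecipSeries()`). Monthly totals follow a
strong November–April wet season; the monthly mean vector sums to 981 mm,
calibrated so that with the default −5 mm/yr decline the 2000–2016
water-year mean is the observed 941 mm (the trend's midpoint offset is
$-5 \times 16/2 = -40$). Monthly noise scales with the monthly mean
(`noiseSD` is the sd of an average month, default 25 mm): precipitation
variability grows with amount, and near-zero dry-season months must stay
near zero or the truncation of negative draws would bias annual totals
upward. Rows cover October of the year before the first water year through
September of the last, so every requested water year is complete.

What the generator does *not* emulate: atmospheric effects, cloud and gap
contamination, QA filtering of real 16-day composites, topography and the
rainfall gradient, mixed pixels inside training polygons, and spatial
autocorrelation of NDVI *within* a class patch. Passing tests therefore
demonstrate the correctness and internal consistency of the computational
chain under the assumed class-conditional structure — not classifier
performance on real imagery, where within-class texture and boundary
mixing would lower accuracy.

## Numerical choices and problem sizes

* Raster geometry is north-up with square cells only; pixel membership in
  polygons is pixel-center containment (deterministic, standard for
  training extraction, and consistent with ≥3×3 pure samples). Same-class
  polygon overlaps deduplicate; cross-class overlaps exclude the contested
  pixels with a logged count.
* Interval overlap between two classes is intersection length over the
  *shorter* interval's length, in $[0, 1]$ — 1 means the tighter class is
  nested, 0 means disjoint.
* Rasters interchange as ESRI ASCII Grid text files (plus GeoJSON for
  polygons and CSV manifests for stacks), keeping every artifact diffable
  and byte-reproducible; `runPipeline()` reruns with the same config and
  seed produce byte-identical tabular outputs.
* Test and validation sizes: the shared test fixture is a 128×128 scene;
  separability and proportion checks use 512×512 scenes (the smallest size
  at which mosaic sampling noise is comfortably below the ±3-point
  tolerance); trend recovery averages 50 generator seeds on a 12×12
  truth map over 2000–2016; the radiometric round trip samples 20 random
  calibration sets × 200 temperatures in [250, 330] K.

## Known limitations

The rule thresholds are image- and season-specific by construction; they
transfer to other dates only after re-deriving from training data
(`induceRules()`), and the package deliberately ships exactly one
published set. BBST is brightness temperature, not land-surface
temperature. The SVM baseline uses the synthetic bands plus NDVI and BBST,
not a full multi-band + transform feature stack. Published assessment
tables contain two internally inconsistent derived cells (a shrubland
omission and a grassland commission in the SVM panel that disagree with
their own matrix); the package reproduces the matrix-consistent values.
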