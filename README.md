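# savannacover

Savannas grade continuously from open grassland through shrubland to
woodland. The structural classes share woody species and differ mainly in
plant height and density, so their spectral signatures overlap and
conventional supervised classifiers confuse them badly. **savannacover**
implements the alternative that works on such landscapes: couple two
continuous covariates — the normalized difference vegetation index
(NDVI, a greenness proxy) and blackbody surface temperature (BBST,
brightness temperature from the thermal band, no emissivity correction) —
and classify with explicit IF–THEN box rules in the NDVI × BBST plane,
where woodland is green and cool, grassland sparse and hot, and shrubland
sits between. The package is aimed at remote-sensing ecologists and
protected-area analysts who need auditable, field-calibrated cover maps
and per-class vegetation trend series.

The core quantities:

* radiometric chain
  `L = (Lmax − Lmin)/(Qmax − Qmin) · (DN − Qmin) + Lmin`, then
  `T = k2 / ln(k1/L + 1)` (kelvin; Celsius = T − 273.15);
* `NDVI = (NIR − red) / (NIR + red)`;
* per-class rules such as *IF NDVI > 0.41 AND BBST < 36.5 °C THEN
  woodland*, applied in a stated precedence order with an explicit
  unclassified code for gap pixels;
* error-matrix accuracy: overall accuracy `100 · tr(M)/ΣM`, column-wise
  omission and row-wise commission errors;
* class-zonal seasonal NDVI series from a coarse composite stack, with
  ordinary-least-squares yearly trends, plus water-year (Oct–Sep)
  precipitation totals and anomalies.

A synthetic scene generator (patchy class mosaics, class-conditional
NDVI/BBST boxes, exact radiometric encoding, coarse seasonal stacks,
monthly precipitation) makes the entire chain testable without satellite
archives. Everything is S4 with validity checks; rasters interchange as
plain-text ESRI ASCII Grids, polygons as GeoJSON, tables as CSV.

## Worked example

```r
library(savannacover)

cfg <- pipelineConfig(scene = sceneConfig(rows = 128L, cols = 128L), seed = 42)
res <- runPipeline(cfg)

res$rules
#> RuleSet (precedence: woodland > grassland > shrubland)
#>   woodland   NDVI > 0.41;  BBST < 36.5 degC
#>   grassland  NDVI < 0.36;  BBST > 38.6 degC
#>   shrubland  NDVI >= 0.28 and <= 0.51;  BBST >= 36.7 and <= 39.3 degC

round(res$proportions, 2)
#> grassland shrubland  woodland
#>     25.54     32.93     41.53

res$errorMatrix
#> ErrorMatrix (rows = mapped, cols = reference)
#>            reference
#> mapped      woodland shrubland grassland
#>   woodland        63         0         0
#>   shrubland        0        58         0
#>   grassland        0        11        34
#> Overall accuracy: 93.37%  (8 unclassified site(s) excluded)

res$trends
#>       class slope_per_year      p_value
#> 1 grassland  -0.0040381205 1.019338e-71
#> 2 shrubland  -0.0020442561 6.161064e-50
#> 3  woodland  -0.0009681775 5.825441e-42
```

The pipeline generated a 128×128 synthetic scene with the default
landscape class fractions (22.87 / 35.93 / 41.20% grassland / shrubland /
woodland), decoded NDVI and BBST from the bands, classified with the
shipped wet-season reference rules, and assessed against the true mosaic
at 174 random sites. The mapped proportions sit within three points of the
generating fractions — the residual shift is real: the generating boxes
extend slightly past the rule thresholds, so some edge pixels go
unclassified or swap between grassland and shrubland. The confusion that
does occur is exactly the grass–shrub confusion the coupled approach is
designed to minimize, and the seasonal NDVI trends recover the generating
declines (−0.004, −0.002, −0.001 per year) with season-adjusted OLS.

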