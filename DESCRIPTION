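Package: savannacover
Title: Rule-Based Savanna Land-Cover Classification from Coupled NDVI and
    Surface Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying savanna landscapes along the
    grassland-shrubland-woodland continuum by coupling the normalized
    difference vegetation index (NDVI) with blackbody surface temperature
    (BBST) derived from thermal imagery. Implements the radiometric chain
    from quantized digital numbers to spectral radiance and brightness
    temperature, pixel extraction under labelled field polygons,
    induction and application of coupled NDVI-by-temperature box rules,
    error-matrix accuracy assessment with omission and commission errors,
    and class-zonal seasonal NDVI time series with ordinary least-squares
    trends and water-year precipitation bookkeeping. A synthetic scene
    generator emulating 30 m multispectral imagery and coarse 16-day NDVI
    composite stacks makes every stage testable without satellite
    archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
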