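#' Convert thermal digital numbers to spectral radiance
#'
#' Applies the standard linear radiometric rescaling
#' \deqn{L_\lambda = \frac{LMAX - LMIN}{QCALMAX - QCALMIN}(DN - QCALMIN) + LMIN}
#' per pixel. Nodata propagates; pixels whose rescaled radiance is
#' nonpositive (physically meaningless and fatal to the downstream
#' logarithm) are masked with a warning reporting their count.
#'
#' @param dn a \linkS4class{RasterGrid} of thermal digital numbers.
#' @param cal \linkS4class{CalibrationConstants} for the band.
#' @return A \linkS4class{RadianceGrid}.
#' @export
#' @examples
#' cal <- calibrationConstants(0.1, 22, 1, 65535, 774.8853, 1321.0789)
#' dn <- rasterGrid(matrix(c(1, 65535, 32768, NA), 2, 2))
#' gridValues(dnToRadiance(dn, cal))
dnToRadiance <- function(dn, cal) {
  stopifnot(is(dn, "RasterGrid"), is(cal, "CalibrationConstants"))
  validObject(cal)
  gain <- (cal@lmax - cal@lmin) / (cal@qcalmax - cal@qcalmin)
  l <- gain * (dn@values - cal@qcalmin) + cal@lmin
  bad <- !is.na(l) & l <= 0
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with nonpositive radiance masked as nodata")
    l[bad] <- NA_real_
  }
  rasterGrid(l, dn@xll, dn@yll, dn@cellsize, class = "RadianceGrid")
}

#' Convert spectral radiance to blackbody surface temperature
#'
#' Inverts Planck's blackbody relation with the two prelaunch calibration
#' constants,
#' \deqn{T = \frac{k_2}{\ln(k_1 / L_\lambda + 1)},}
#' giving brightness temperature with no emissivity correction (BBST). The
#' result is strictly increasing in radiance. Nonpositive radiance at an
#' unmasked pixel is masked with a warning rather than raising an error.
#'
#' @param radiance a \linkS4class{RadianceGrid} (or RasterGrid of radiance).
#' @param cal \linkS4class{CalibrationConstants}.
#' @param unit "kelvin" or "celsius"; Celsius is kelvin minus 273.15.
#' @return A \linkS4class{TemperatureGrid}.
#' @export
radianceToBBST <- function(radiance, cal, unit = c("kelvin", "celsius")) {
  stopifnot(is(radiance, "RasterGrid"), is(cal, "CalibrationConstants"))
  unit <- match.arg(unit)
  validObject(cal)
  l <- radiance@values
  bad <- !is.na(l) & l <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive-radiance pixel(s) masked in BBST")
    l[bad] <- NA_real_
  }
  t_k <- cal@k2 / log(cal@k1 / l + 1)
  v <- if (unit == "celsius") t_k - 273.15 else t_k
  rasterGrid(v, radiance@xll, radiance@yll, radiance@cellsize,
             class = "TemperatureGrid", unit = unit)
}

#' Convert a temperature grid between kelvin and Celsius
#'
#' @param temp a \linkS4class{TemperatureGrid}.
#' @param unit target unit.
#' @return A \linkS4class{TemperatureGrid} in the requested unit.
#' @export
convertTemperature <- function(temp, unit = c("celsius", "kelvin")) {
  unit <- match.arg(unit)
  if (temp@unit == unit) return(temp)
  off <- if (unit == "celsius") -273.15 else 273.15
  rasterGrid(temp@values + off, temp@xll, temp@yll, temp@cellsize,
             class = "TemperatureGrid", unit = unit)
}

#' Compute the normalized difference vegetation index
#'
#' NDVI = (NIR - red) / (NIR + red), a unitless greenness proxy in
#' [-1, 1]. Pixels where both bands are zero (undefined ratio) are masked
#' as nodata, as are pixels with nodata in either input.
#'
#' @param nir,red co-registered reflectance-like \linkS4class{RasterGrid}s.
#' @return An \linkS4class{NdviGrid}.
#' @export
#' @examples
#' nir <- rasterGrid(matrix(0.40))
#' red <- rasterGrid(matrix(0.10))
#' gridValues(computeNDVI(nir, red))  # 0.6
computeNDVI <- function(nir, red) {
  stopifnot(is(nir, "RasterGrid"), is(red, "RasterGrid"))
  checkCoregistered(nir, red)
  s <- nir@values + red@values
  v <- (nir@values - red@values) / s
  v[!is.na(s) & s == 0] <- NA_real_
  rasterGrid(v, nir@xll, nir@yll, nir@cellsize, class = "NdviGrid")
}

#' Scalar radiometric chain (single-pixel reference path)
#'
#' Evaluates DN -> radiance -> brightness temperature for scalar inputs
#' with plain arithmetic; used as the reference path the raster
#' implementation is compared against.
#'
#' @param dn scalar digital number.
#' @param cal \linkS4class{CalibrationConstants}.
#' @param unit "kelvin" or "celsius".
#' @return Scalar temperature.
#' @export
scalarBBST <- function(dn, cal, unit = c("kelvin", "celsius")) {
  unit <- match.arg(unit)
  l <- (cal@lmax - cal@lmin) / (cal@qcalmax - cal@qcalmin) *
    (dn - cal@qcalmin) + cal@lmin
  if (is.na(l) || l <= 0) return(NA_real_)
  t <- cal@k2 / log(cal@k1 / l + 1)
  if (unit == "celsius") t - 273.15 else t
}

#' Encode a temperature as a thermal digital number
#'
#' The inverse of the radiometric chain: computes the Planck radiance of a
#' blackbody at the given temperature and maps it back through the linear
#' DN rescaling. Used by the synthetic scene generator so that decoding a
#' generated scene recovers the drawn temperatures.
#'
#' @param t_celsius temperature(s) in Celsius.
#' @param cal \linkS4class{CalibrationConstants}.
#' @param quantize round the DN to integers (sensor-style quantization).
#' @return Digital number(s), same shape as \code{t_celsius}.
#' @export
temperatureToDN <- function(t_celsius, cal, quantize = FALSE) {
  t_k <- t_celsius + 273.15
  l <- cal@k1 / (exp(cal@k2 / t_k) - 1)
  dn <- (l - cal@lmin) / (cal@lmax - cal@lmin) *
    (cal@qcalmax - cal@qcalmin) + cal@qcalmin
  if (quantize) dn <- round(dn)
  dn
}
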