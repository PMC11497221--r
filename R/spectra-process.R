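#' Integration region
#'
#' @param lo,hi region bounds in x-units (ppm or nm), `lo < hi`.
#' @param label non-empty text label.
#' @return an object of class `region`.
#' @export
region <- function(lo, hi, label = sprintf("%g..%g", lo, hi)) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("'lo' and 'hi' must be finite numbers with lo < hi")
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be non-empty text")
  structure(list(lo = lo, hi = hi, label = label), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("Region '%s': [%g, %g]\n", x$label, x$lo, x$hi))
  invisible(x)
}

# ascending-x view of the samples inside a region
segment_in_region <- function(spec, reg, min_points) {
  ord <- order(spec$x)
  x <- spec$x[ord]; y <- spec$y[ord]
  if (reg$lo < x[1L] || reg$hi > x[length(x)])
    stop("region [", reg$lo, ", ", reg$hi, "] outside the spectrum x-range")
  keep <- x >= reg$lo & x <= reg$hi
  if (sum(keep) < min_points)
    stop("region '", reg$label, "' contains fewer than ", min_points,
         " samples")
  list(x = x[keep], y = y[keep])
}

#' Linear endpoint baseline correction over a region
#'
#' Subtracts the straight line through the region's two endpoint
#' intensities from the segment. This removes constant offsets and linear
#' slopes exactly; full baseline modeling is deliberately out of scope.
#'
#' @param spectrum a [spectrum()].
#' @param region a [region()] lying within the spectrum's x-range and
#'   containing at least 3 samples.
#' @return the corrected segment as a list with ascending `x` and `y`,
#'   plus the spectrum's `modality` and `timestamp` (class
#'   `spectrum_segment`).
#' @export
baseline_correct <- function(spectrum, region) {
  if (!inherits(spectrum, "spectrum")) stop("'spectrum' must be a spectrum")
  if (!inherits(region, "region")) stop("'region' must be a region")
  seg <- segment_in_region(spectrum, region, 3L)
  n <- length(seg$x)
  base <- seg$y[1L] + (seg$y[n] - seg$y[1L]) *
    (seg$x - seg$x[1L]) / (seg$x[n] - seg$x[1L])
  structure(list(x = seg$x, y = seg$y - base,
                 modality = spectrum$modality,
                 timestamp = spectrum$timestamp),
            class = "spectrum_segment")
}

#' Integrate a spectral region
#'
#' Trapezoidal area over the region's samples, optionally after linear
#' endpoint baseline correction. The x-axis orientation is handled so the
#' area of a positive peak is positive regardless of the descending-ppm
#' NMR convention.
#'
#' @param spectrum a [spectrum()].
#' @param region a [region()] with at least 2 samples inside it (3 when a
#'   baseline correction is requested).
#' @param baseline `"none"` or `"linear"`.
#' @return an object of class `integration_result`: list with `region`,
#'   `value`, `baseline_method`, `timestamp`.
#' @export
integrate_region <- function(spectrum, region, baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  if (!inherits(spectrum, "spectrum")) stop("'spectrum' must be a spectrum")
  if (!inherits(region, "region")) stop("'region' must be a region")
  seg <- if (baseline == "linear") baseline_correct(spectrum, region)
         else segment_in_region(spectrum, region, 2L)
  value <- pracma::trapz(seg$x, seg$y)
  structure(list(region = region, value = value,
                 baseline_method = baseline,
                 timestamp = spectrum$timestamp),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("Integral over '%s' [%g, %g]: %.6g (baseline: %s, t = %g min)\n",
              x$region$label, x$region$lo, x$region$hi, x$value,
              x$baseline_method, x$timestamp))
  invisible(x)
}

#' Conversion from peak integrals
#'
#' Conversion is the ratio of the product's integral to the summed
#' integrals of all related species (e.g. the tosyl methyl signal of the
#' sulfonamide over all tosyl derivatives combined). Small negative areas
#' from noise are clipped to zero first; the result is clipped to
#' \[0, 1\].
#'
#' @param product_area integral of the product region.
#' @param total_areas numeric vector of integrals over all related
#'   regions (including the product's).
#' @return conversion fraction in \[0, 1\].
#' @export
conversion_from_integrals <- function(product_area, total_areas) {
  if (!is.numeric(product_area) || length(product_area) != 1L ||
      !is.finite(product_area))
    stop("'product_area' must be a single finite number")
  if (!is.numeric(total_areas) || length(total_areas) < 1L ||
      any(!is.finite(total_areas)))
    stop("'total_areas' must be finite numbers")
  product_area <- max(product_area, 0)
  total <- sum(pmax(total_areas, 0))
  if (total <= 0)
    stop("no signal: total reference area is zero")
  min(max(product_area / total, 0), 1)
}

#' Absorbance at a wavelength
#'
#' Linear interpolation between the two bracketing samples of a UV-Vis
#' spectrum (works on any spectrum; x must cover the wavelength).
#'
#' @param spectrum a [spectrum()].
#' @param wavelength query x-value, within the spectrum's range.
#' @return interpolated y value (AU).
#' @export
absorbance_at <- function(spectrum, wavelength) {
  if (!inherits(spectrum, "spectrum")) stop("'spectrum' must be a spectrum")
  if (!is.numeric(wavelength) || length(wavelength) != 1L)
    stop("'wavelength' must be a single number")
  ord <- order(spectrum$x)
  x <- spectrum$x[ord]; y <- spectrum$y[ord]
  if (wavelength < x[1L] || wavelength > x[length(x)])
    stop("wavelength ", wavelength, " outside the spectrum range")
  stats::approx(x, y, xout = wavelength)$y
}

#' Recipe for turning spectra into a kinetic observable
#'
#' NMR conversion mode needs no calibration: integrals are directly
#' proportional to concentration, and the ratio cancels the response.
#' UV-Vis absorbance mode reports raw absorbance, or concentration when a
#' linear response factor (AU per mM) is supplied.
#'
#' @param mode `"conversion"` (NMR) or `"absorbance"` (UV-Vis).
#' @param product_region [region()] of the product signal (conversion mode).
#' @param total_regions list of [region()]s over all related signals,
#'   including the product's (conversion mode).
#' @param wavelength tracked wavelength in nm (absorbance mode).
#' @param calibration optional AU-per-mM response factor (absorbance mode).
#' @param species species name reported in calibrated absorbance mode.
#' @param baseline baseline method passed to [integrate_region()].
#' @return an object of class `trace_recipe`.
#' @export
trace_recipe <- function(mode = c("conversion", "absorbance"),
                         product_region = NULL, total_regions = NULL,
                         wavelength = NULL, calibration = NULL,
                         species = "analyte",
                         baseline = c("none", "linear")) {
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  if (mode == "conversion") {
    if (!inherits(product_region, "region"))
      stop("conversion mode needs a 'product_region'")
    if (!is.list(total_regions) || length(total_regions) < 1L ||
        !all(vapply(total_regions, inherits, logical(1), "region")))
      stop("conversion mode needs a list of 'total_regions'")
  } else {
    if (!is.numeric(wavelength) || length(wavelength) != 1L)
      stop("absorbance mode needs a 'wavelength'")
    if (!is.null(calibration) &&
        (!is.numeric(calibration) || calibration <= 0))
      stop("'calibration' must be a positive AU-per-mM factor")
  }
  structure(list(mode = mode, product_region = product_region,
                 total_regions = total_regions, wavelength = wavelength,
                 calibration = calibration, species = species,
                 baseline = baseline),
            class = "trace_recipe")
}

#' Kinetic observable from a time-ordered series of spectra
#'
#' Applies a [trace_recipe()] to each spectrum: conversion mode emits one
#' [conversion_from_integrals()] point per spectrum; absorbance mode
#' emits the tracked absorbance, converted to a concentration trace when
#' a calibration factor is available.
#'
#' @param spectra list of [spectrum()] objects sharing one modality, with
#'   strictly increasing timestamps. May be empty.
#' @param recipe a [trace_recipe()].
#' @return conversion mode: a `conversion_series` data frame
#'   (`time_min`, `conversion`); calibrated absorbance mode: a
#'   [conc_trace()]; uncalibrated: a data frame (`time_min`,
#'   `absorbance`).
#' @export
trace_from_spectra <- function(spectra, recipe) {
  if (!inherits(recipe, "trace_recipe")) stop("'recipe' must be a trace_recipe")
  if (!is.list(spectra))
    stop("'spectra' must be a list of spectrum objects")
  if (length(spectra) == 0L) {
    if (recipe$mode == "conversion")
      return(structure(data.frame(time_min = numeric(0),
                                  conversion = numeric(0)),
                       class = c("conversion_series", "data.frame")))
    return(data.frame(time_min = numeric(0), absorbance = numeric(0)))
  }
  if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("'spectra' must be a list of spectrum objects")
  mods <- vapply(spectra, `[[`, character(1), "modality")
  if (length(unique(mods)) > 1L)
    stop("mixed modalities in spectrum series")
  ts <- vapply(spectra, `[[`, numeric(1), "timestamp")
  if (length(ts) > 1L && any(diff(ts) <= 0))
    stop("spectrum timestamps must be strictly increasing")

  if (recipe$mode == "conversion") {
    conv <- vapply(spectra, function(s) {
      totals <- vapply(recipe$total_regions, function(r)
        integrate_region(s, r, recipe$baseline)$value, numeric(1))
      prod_a <- integrate_region(s, recipe$product_region,
                                 recipe$baseline)$value
      conversion_from_integrals(prod_a, totals)
    }, numeric(1))
    structure(data.frame(time_min = ts, conversion = conv),
              class = c("conversion_series", "data.frame"))
  } else {
    a <- vapply(spectra, absorbance_at, numeric(1),
                wavelength = recipe$wavelength)
    if (is.null(recipe$calibration))
      return(data.frame(time_min = ts, absorbance = a))
    conc <- matrix(pmax(a, 0) / recipe$calibration, ncol = 1L,
                   dimnames = list(NULL, recipe$species))
    conc_trace(ts, conc)
  }
}

#' @export
plot.conversion_series <- function(x, ..., xlab = "time (min)",
                                   ylab = "conversion") {
  graphics::plot(x$time_min, x$conversion, xlab = xlab, ylab = ylab,
                 ylim = c(0, 1), pch = 16, ...)
  invisible(x)
}
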