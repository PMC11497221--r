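#' Peak table for one species
#'
#' @param center peak center(s): ppm for NMR, nm for UV-Vis.
#' @param width half-width at half-maximum, same x-units as `center` (> 0).
#' @param response signal per mM: for NMR the peak's integral per mM
#'   (proportional to proton count), for UV-Vis the band's peak
#'   absorbance per mM per unit path. Must be >= 0.
#' @return a data frame with columns `center`, `width`, `response`.
#' @export
peak_table <- function(center, width, response) {
  df <- data.frame(center = center, width = width, response = response)
  if (any(!is.finite(as.matrix(df)))) stop("peak parameters must be finite")
  if (any(df$width <= 0)) stop("peak widths must be > 0")
  if (any(df$response < 0)) stop("peak responses must be >= 0")
  df
}

#' Spectral signature of a reaction mixture
#'
#' Maps species to the peaks they contribute to the rendered spectrum.
#' NMR peaks are Lorentzian with unit area scaled by `response * conc`;
#' UV-Vis bands are Gaussian with peak height `response * conc`
#' (Beer-Lambert, absorbances additive).
#'
#' @param peaks named list, one [peak_table()] per species.
#' @param modality `"nmr"` or `"uvvis"`.
#' @return an object of class `spectral_signature`.
#' @examples
#' spectral_signature(list(
#'   TsCl   = peak_table(2.46, 0.005, 3),
#'   TsNHAr = peak_table(2.36, 0.005, 3)), "nmr")
#' @export
spectral_signature <- function(peaks, modality = c("nmr", "uvvis")) {
  modality <- match.arg(modality)
  if (!is.list(peaks) || is.null(names(peaks)) || any(!nzchar(names(peaks))))
    stop("'peaks' must be a named list of peak tables")
  peaks <- lapply(peaks, function(p) {
    if (!is.data.frame(p) || !all(c("center", "width", "response") %in% names(p)))
      stop("each signature entry must be a peak_table()")
    peak_table(p$center, p$width, p$response)
  })
  structure(list(peaks = peaks, modality = modality),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("Spectral signature (%s): %d species\n",
              x$modality, length(x$peaks)))
  for (sp in names(x$peaks)) {
    p <- x$peaks[[sp]]
    cat(sprintf("  %s: %d peak(s) at %s\n", sp, nrow(p),
                paste(signif(p$center, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Measurement noise model
#'
#' Additive Gaussian noise with standard deviation `relative_sigma` times
#' the maximum noiseless signal of the spectrum, plus a constant baseline
#' offset. The realization is fully determined by `seed` and the spectrum
#' index, so identical (plan, seed) pairs give byte-identical spectra.
#'
#' @param relative_sigma Gaussian sd as a fraction of the max signal (>= 0).
#' @param baseline_drift constant baseline offset per spectrum (AU).
#' @param seed integer seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(relative_sigma = 0, baseline_drift = 0, seed = 1L) {
  if (!is.numeric(relative_sigma) || relative_sigma < 0)
    stop("'relative_sigma' must be >= 0")
  if (!is.numeric(baseline_drift) || !is.finite(baseline_drift))
    stop("'baseline_drift' must be finite")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  structure(list(relative_sigma = relative_sigma,
                 baseline_drift = baseline_drift,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# run expr with a private RNG stream; global .Random.seed untouched
with_private_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Single spectrum container
#'
#' @param x x-axis: strictly descending ppm for NMR, strictly ascending
#'   nm for UV-Vis (instrument conventions).
#' @param y intensities (arbitrary units) or absorbances (AU), same
#'   length as `x` (>= 2 points).
#' @param modality `"nmr"` or `"uvvis"`.
#' @param timestamp minutes since reaction start (>= 0).
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(x, y, modality = c("nmr", "uvvis"), timestamp = 0) {
  modality <- match.arg(modality)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 2L)
    stop("'x' and 'y' must be numeric vectors of equal length >= 2")
  d <- diff(x)
  if (modality == "nmr" && any(d >= 0))
    stop("NMR x-axis must be strictly descending (ppm)")
  if (modality == "uvvis" && any(d <= 0))
    stop("UV-Vis x-axis must be strictly ascending (nm)")
  if (!is.numeric(timestamp) || length(timestamp) != 1L || timestamp < 0)
    stop("'timestamp' must be a single number >= 0")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 modality = modality, timestamp = as.numeric(timestamp)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$modality == "nmr") "ppm" else "nm"
  cat(sprintf("%s spectrum, %d points, %g to %g %s, t = %g min\n",
              toupper(x$modality), length(x$x), x$x[1L],
              x$x[length(x$x)], unit, x$timestamp))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = NULL, ylab = NULL) {
  if (is.null(xlab))
    xlab <- if (x$modality == "nmr") "chemical shift (ppm)" else "wavelength (nm)"
  if (is.null(ylab))
    ylab <- if (x$modality == "nmr") "intensity (a.u.)" else "absorbance (AU)"
  xlim <- if (x$modality == "nmr") rev(range(x$x)) else range(x$x)
  graphics::plot(x$x, x$y, type = "l", xlim = xlim,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Render one spectrum from a concentration trace
#'
#' Produces the synthetic analytical observable at one time point of a
#' trace: each species contributes its signature peaks scaled linearly by
#' its concentration (NMR: unit-area Lorentzians scaled to integral =
#' response * conc; UV-Vis: Gaussian bands of height response * conc),
#' then seeded noise is applied. The noiseless region integral is thereby
#' exactly proportional to concentration.
#'
#' @param trace a [conc_trace()].
#' @param index time-point index into the trace (1-based).
#' @param signature a [spectral_signature()]; its species must all exist
#'   in the trace.
#' @param grid strictly ascending x-grid (ppm or nm). Must cover every
#'   peak center +/- 5 widths.
#' @param noise optional [noise_model()]; the per-spectrum noise stream
#'   is seeded with `noise$seed + index`.
#' @return a [spectrum()] with the trace's timestamp.
#' @export
render_spectrum <- function(trace, index, signature, grid, noise = NULL) {
  if (!inherits(trace, "conc_trace")) stop("'trace' must be a conc_trace")
  if (!inherits(signature, "spectral_signature"))
    stop("'signature' must be a spectral_signature")
  n <- length(trace$times)
  if (!is.numeric(index) || length(index) != 1L || index < 1 || index > n ||
      index != round(index))
    stop("'index' must be a valid time-point index")
  if (!is.numeric(grid) || length(grid) < 2L || any(diff(grid) <= 0))
    stop("'grid' must be strictly ascending with >= 2 points")
  absent <- setdiff(names(signature$peaks), colnames(trace$conc))
  if (length(absent))
    stop("signature species not present in trace: ",
         paste(absent, collapse = ", "))
  lo <- min(grid); hi <- max(grid)
  for (sp in names(signature$peaks)) {
    p <- signature$peaks[[sp]]
    if (any(p$center - 5 * p$width < lo) || any(p$center + 5 * p$width > hi))
      stop("peak of species '", sp, "' falls outside the grid (+/- 5 widths)")
  }

  y <- numeric(length(grid))
  for (sp in names(signature$peaks)) {
    conc <- trace$conc[index, sp]
    if (conc == 0) next
    p <- signature$peaks[[sp]]
    for (j in seq_len(nrow(p))) {
      if (signature$modality == "nmr") {
        g <- p$width[j]  # HWHM of the Lorentzian
        y <- y + p$response[j] * conc * (g / pi) / ((grid - p$center[j])^2 + g^2)
      } else {
        s <- p$width[j] / sqrt(2 * log(2))  # HWHM -> Gaussian sd
        y <- y + p$response[j] * conc * exp(-(grid - p$center[j])^2 / (2 * s^2))
      }
    }
  }

  if (!is.null(noise)) {
    if (!inherits(noise, "noise_model")) stop("'noise' must be a noise_model")
    ymax <- max(abs(y))
    y <- with_private_seed(noise$seed + as.integer(index), {
      y + stats::rnorm(length(y), sd = noise$relative_sigma * ymax)
    })
    y <- y + noise$baseline_drift
  }

  if (signature$modality == "nmr") {
    spectrum(rev(grid), rev(y), "nmr", trace$times[index])
  } else {
    spectrum(grid, y, "uvvis", trace$times[index])
  }
}
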