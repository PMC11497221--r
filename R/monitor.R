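#' Monitor configuration
#'
#' Parameters of the windowed plateau stop condition: acquisition
#' continues until the spread (max - min) of the `window` most recent
#' conversions falls to `threshold` or below, or `max_measurements` is
#' reached — the data-driven exit condition of a dynamically terminated
#' experiment. Both `window` and `threshold` are mandatory so a recorded
#' run is reproducible.
#'
#' @param window number of most-recent measurements compared (>= 2).
#' @param threshold maximum allowed spread, conversion units (> 0).
#' @param max_measurements hard cap on acquisitions (>= window).
#' @param interval_min minutes between acquisitions (> 0).
#' @param t0_min dead time before the first measurement (default 0).
#' @param mode `"conversion"` (the plateau test runs on the derived
#'   conversion value) or `"spectrum_linf"` (on the L-infinity distance
#'   between consecutive raw spectra).
#' @return an object of class `monitor_config`.
#' @export
monitor_config <- function(window, threshold, max_measurements,
                           interval_min, t0_min = 0,
                           mode = c("conversion", "spectrum_linf")) {
  mode <- match.arg(mode)
  if (!is.numeric(window) || length(window) != 1L || window < 2 ||
      window != round(window))
    stop("'window' must be an integer >= 2")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be > 0")
  if (!is.numeric(max_measurements) || length(max_measurements) != 1L ||
      max_measurements < window || max_measurements != round(max_measurements))
    stop("'max_measurements' must be an integer >= window")
  if (!is.numeric(interval_min) || length(interval_min) != 1L ||
      interval_min <= 0)
    stop("'interval_min' must be > 0")
  if (!is.numeric(t0_min) || length(t0_min) != 1L || t0_min < 0)
    stop("'t0_min' must be >= 0")
  structure(list(window = as.integer(window), threshold = threshold,
                 max_measurements = as.integer(max_measurements),
                 interval_min = interval_min, t0_min = t0_min,
                 mode = mode),
            class = "monitor_config")
}

#' Windowed plateau test
#'
#' `TRUE` iff at least `window` values exist and the spread (max - min)
#' of the most recent `window` values is at most `threshold` — the
#' while-loop exit condition of a monitored reaction step.
#'
#' @param values numeric vector of monitored values, oldest first.
#' @param window number of most-recent values compared (>= 2).
#' @param threshold maximum allowed spread (> 0).
#' @return logical.
#' @examples
#' plateau_reached(rep(0.95, 5), window = 5, threshold = 0.01)  # TRUE
#' @export
plateau_reached <- function(values, window, threshold) {
  if (!is.numeric(window) || length(window) != 1L || window < 2)
    stop("'window' must be >= 2")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be > 0")
  if (length(values) < window) return(FALSE)
  recent <- utils::tail(values, window)
  diff(range(recent)) <= threshold
}

#' In-process stream over a list of spectra
#'
#' Wraps a time-ordered list of spectra into the callable-stream
#' interface consumed by [run_monitor()]: each call yields the next
#' spectrum, then `NULL` on exhaustion.
#'
#' @param spectra list of [spectrum()] objects in time order.
#' @return a function of no arguments.
#' @export
spectrum_stream <- function(spectra) {
  if (!is.list(spectra) ||
      !all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("'spectra' must be a list of spectrum objects")
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(spectra)) NULL else spectra[[i]]
  }
}

#' Directory-watcher stream over spectrum files
#'
#' Yields spectra from CSV + JSON sidecar files in a directory, sorted
#' by their sidecar timestamps; files appearing between calls are picked
#' up, already-yielded files are not re-read. Returns `NULL` when no
#' unseen spectrum is available.
#'
#' @param path directory containing spectrum CSV files (see
#'   [write_spectrum()]).
#' @return a function of no arguments.
#' @export
dir_stream <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  seen <- character(0)
  function() {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    files <- setdiff(files, seen)
    files <- files[file.exists(vapply(files, sidecar_path, character(1)))]
    if (!length(files)) return(NULL)
    specs <- lapply(files, read_spectrum)
    ord <- order(vapply(specs, `[[`, numeric(1), "timestamp"))
    seen <<- c(seen, files[ord[1L]])
    specs[[ord[1L]]]
  }
}

#' Run the plateau-detection monitor over a spectrum stream
#'
#' Emulates the dynamic (while-loop) experiment step: after every
#' acquisition the spectrum is converted to its monitored value and the
#' windowed plateau test is applied; acquisition stops at the first
#' plateau or at `max_measurements`. In `"conversion"` mode the test
#' runs on the conversion derived via `recipe`; in `"spectrum_linf"`
#' mode it runs on the max-absolute difference between consecutive raw
#' spectra (a plateau needs `window - 1` consecutive small distances).
#'
#' @param stream a function yielding the next [spectrum()] or `NULL`
#'   (see [spectrum_stream()], [dir_stream()]), or a list of spectra.
#' @param recipe a conversion-mode [trace_recipe()] (ignored in
#'   `spectrum_linf` mode).
#' @param config a [monitor_config()].
#' @return an object of class `monitor_record`: `conversions` (data
#'   frame `time_min`, `conversion`; empty in `spectrum_linf` mode),
#'   `values` (the monitored series), `stopped_at` (number of
#'   measurements taken), `stop_reason` (`"plateau"` or
#'   `"max_reached"`), and the `config`.
#' @export
run_monitor <- function(stream, recipe, config) {
  if (!inherits(config, "monitor_config"))
    stop("'config' must be a monitor_config")
  if (is.list(stream)) stream <- spectrum_stream(stream)
  if (!is.function(stream)) stop("'stream' must be a function or a list")
  linf <- config$mode == "spectrum_linf"
  if (!linf && !inherits(recipe, "trace_recipe"))
    stop("conversion mode needs a trace_recipe")

  times <- numeric(0)
  vals <- numeric(0)      # monitored series (conversion or L-inf distance)
  conv <- numeric(0)
  prev <- NULL
  stop_reason <- "max_reached"
  taken <- 0L

  for (i in seq_len(config$max_measurements)) {
    s <- stream()
    if (is.null(s)) {
      if (taken < config$window)
        warning("stream exhausted before a full window of measurements")
      break
    }
    taken <- i
    times[i] <- s$timestamp
    if (linf) {
      if (!is.null(prev)) vals <- c(vals, max(abs(s$y - prev$y)))
      prev <- s
      hit <- length(vals) >= config$window - 1L &&
        all(utils::tail(vals, config$window - 1L) <= config$threshold)
    } else {
      totals <- vapply(recipe$total_regions, function(r)
        integrate_region(s, r, recipe$baseline)$value, numeric(1))
      prod_a <- integrate_region(s, recipe$product_region,
                                 recipe$baseline)$value
      conv[i] <- conversion_from_integrals(prod_a, totals)
      vals <- conv
      hit <- plateau_reached(vals, config$window, config$threshold)
    }
    if (hit) {
      stop_reason <- "plateau"
      break
    }
  }

  structure(list(conversions = data.frame(time_min = times,
                                          conversion = if (linf)
                                            rep(NA_real_, taken) else conv),
                 values = vals, stopped_at = taken,
                 stop_reason = stop_reason, config = config),
            class = "monitor_record")
}

#' @export
print.monitor_record <- function(x, ...) {
  cat(sprintf("Monitor record: %d measurement(s), stop reason: %s\n",
              x$stopped_at, x$stop_reason))
  if (x$stopped_at > 0 && x$stop_reason == "plateau")
    cat(sprintf("  final conversion: %.3f at t = %.2f min\n",
                utils::tail(x$conversions$conversion, 1L),
                utils::tail(x$conversions$time_min, 1L)))
  invisible(x)
}

#' @export
plot.monitor_record <- function(x, ..., xlab = "time (min)",
                                ylab = "conversion") {
  graphics::plot(x$conversions$time_min, x$conversions$conversion,
                 pch = 16, xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  if (x$stop_reason == "plateau")
    graphics::abline(v = utils::tail(x$conversions$time_min, 1L),
                     lty = 2, col = "grey40")
  invisible(x)
}
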