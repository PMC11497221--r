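# shared OLS backbone for the kinetic fits; r_squared defined as 1 for a
# zero-variance (perfectly flat) response so the invariant r2 <= 1 holds
ols_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  n <- length(y)
  se_slope <- if (n > 2) {
    s2 <- ssr / (n - 2)
    sqrt(s2 / sum((x - mean(x))^2))
  } else 0
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       stderr_slope = se_slope, r_squared = r2, fit = fit)
}

new_rate_fit <- function(ols, window, data, subclass = character(0)) {
  structure(list(slope = ols$slope, intercept = ols$intercept,
                 stderr_slope = ols$stderr_slope,
                 r_squared = ols$r_squared,
                 window = window, data = data, fit = ols$fit),
            class = c(subclass, "rate_fit"))
}

# default initial-rate window: first min(n_max, #points) points, further
# shortened to the points still below the conversion cutoff (a linearity
# guard for fast runs); always at least the first two points
default_window <- function(times, values, n_max, max_conversion) {
  n <- length(values)
  idx_max <- min(n_max, n)
  conv <- conversion_like(values)
  keep <- if (is.null(conv)) rep(TRUE, n) else conv <= max_conversion
  leading <- cumsum(!keep) == 0
  last_ok <- if (any(leading)) max(which(leading)) else 1L
  seq_len(max(2L, min(idx_max, last_ok)))
}

# map a monotone observable onto a conversion scale when possible:
# fractions in [0,1] pass through; decaying concentrations become
# fractional consumption; anything else is left alone (NULL)
conversion_like <- function(values) {
  n <- length(values)
  if (all(values >= -1e-9 & values <= 1 + 1e-9)) return(pmin(pmax(values, 0), 1))
  if (values[1L] > 0 && values[n] <= values[1L])
    return((values[1L] - values) / values[1L])
  NULL
}

#' Initial rate by ordinary least squares
#'
#' Fits a straight line through the early portion of a kinetic trace and
#' reports its slope as the initial rate, the standard analysis for a
#' conversion-versus-time series. By default the window is the first
#' `n_max` points (15, a typical acquisition count for a 15-minute run)
#' truncated to the points below a conversion cutoff, protecting
#' linearity for fast reactions.
#'
#' @param times strictly increasing times (minutes).
#' @param values observable at each time (conversion fraction or mM).
#' @param window `NULL` for the default rule, or an integer count of
#'   leading points (must not exceed the series length).
#' @param max_conversion conversion cutoff of the default window rule.
#' @param n_max maximum number of points of the default window rule.
#' @return an object of class `rate_fit` with `slope` (the initial rate,
#'   per minute), `intercept`, `stderr_slope`, `r_squared`, `window`
#'   (indices used).
#' @examples
#' fit_initial_rate(0:2, c(0, 2, 4))$slope   # exactly 2
#' @export
fit_initial_rate <- function(times, values, window = NULL,
                             max_conversion = 0.2, n_max = 15L) {
  check_series(times, values)
  idx <- resolve_window(times, values, window, max_conversion, n_max)
  ols <- ols_fit(times[idx], values[idx])
  new_rate_fit(ols, idx,
               data.frame(time_min = times[idx], value = values[idx]))
}

check_series <- function(times, values) {
  if (!is.numeric(times) || !is.numeric(values) ||
      length(times) != length(values))
    stop("'times' and 'values' must be numeric vectors of equal length")
  if (length(times) < 2L) stop("need at least 2 points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(!is.finite(values))) stop("'values' must be finite")
}

resolve_window <- function(times, values, window, max_conversion, n_max) {
  n <- length(values)
  if (is.null(window))
    return(default_window(times, values, n_max, max_conversion))
  if (!is.numeric(window) || length(window) != 1L || window != round(window))
    stop("'window' must be a single integer")
  if (window > n) stop("window (", window, ") larger than the series (", n, ")")
  if (window < 2L) stop("window must cover at least 2 points")
  seq_len(window)
}

#' Pseudo-first-order decay constant from a trace
#'
#' Under pseudo-first-order conditions the limiting reagent decays as
#' A0 * exp(-k_obs t), so an OLS fit of ln\[A\] (or ln(1 - conversion))
#' against time recovers k_obs without the curvature bias a plain linear
#' initial-rate slope picks up over a finite window.
#'
#' @param times strictly increasing times (minutes).
#' @param values concentrations (mM) or conversion fractions.
#' @param input `"concentration"` or `"conversion"`.
#' @param window as in [fit_initial_rate()].
#' @inheritParams fit_initial_rate
#' @return an object of class `c("pfo_fit", "rate_fit")`; `kobs` holds
#'   the decay constant (min^-1) and `stderr_kobs` its standard error.
#' @examples
#' t <- sample_schedule(82, 20)
#' fit_pfo_kobs(t, pfo_closed_form(1.5, 3.5e-5, 100, t))$kobs  # 3.5e-3
#' @export
fit_pfo_kobs <- function(times, values,
                         input = c("concentration", "conversion"),
                         window = NULL, max_conversion = 0.2, n_max = 20L) {
  input <- match.arg(input)
  check_series(times, values)
  idx <- resolve_window(times, values, window, max_conversion, n_max)
  v <- values[idx]
  lv <- if (input == "conversion") {
    if (any(v < 0 | v >= 1))
      stop("conversions must lie in [0, 1) for a decay fit")
    log(1 - v)
  } else {
    if (any(v <= 0))
      stop("concentrations must be > 0 for a log-linear decay fit")
    log(v)
  }
  ols <- ols_fit(times[idx], lv)
  out <- new_rate_fit(ols, idx,
                      data.frame(time_min = times[idx], value = values[idx]),
                      subclass = "pfo_fit")
  out$kobs <- -ols$slope
  out$stderr_kobs <- ols$stderr_slope
  out
}

#' Second-order rate constant from k_obs versus excess concentration
#'
#' Under pseudo-first-order conditions k_obs = k2 * \[excess\]; an OLS
#' regression of the observed decay constants against the excess-reagent
#' concentrations yields k2 as the slope. The intercept is reported (a
#' diagnostic for a background reaction), not forced through zero.
#'
#' @param excess_mM excess-reagent concentrations (mM), at least two
#'   distinct values.
#' @param kobs observed decay constants (min^-1), all >= 0.
#' @return an object of class `c("k2_fit", "rate_fit")`; `slope` is k2
#'   in mM^-1 min^-1.
#' @examples
#' kobs_to_k2(c(100, 150, 200), c(3.5e-3, 5.25e-3, 7e-3))$slope  # 3.5e-5
#' @export
kobs_to_k2 <- function(excess_mM, kobs) {
  if (!is.numeric(excess_mM) || !is.numeric(kobs) ||
      length(excess_mM) != length(kobs))
    stop("'excess_mM' and 'kobs' must be numeric vectors of equal length")
  if (length(unique(excess_mM)) < 2L)
    stop("need at least two distinct excess concentrations")
  if (any(kobs < 0)) stop("all k_obs must be >= 0")
  ols <- ols_fit(excess_mM, kobs)
  new_rate_fit(ols, seq_along(kobs),
               data.frame(excess_mM = excess_mM, kobs = kobs),
               subclass = "k2_fit")
}

#' Reaction order from a log-log plot
#'
#' Slope of log10(initial rate) against log10(initial concentration)
#' across a concentration series — the classical order-in-reagent
#' determination. Non-positive rates are dropped with a warning.
#'
#' @param conc_mM initial concentrations (mM), > 0.
#' @param rates initial rates, one per concentration.
#' @return an object of class `order_fit` with `order` (the slope),
#'   `stderr`, `r_squared` and the `points` used.
#' @examples
#' conc <- c(100, 75, 50, 37.5, 25)
#' loglog_order(conc, 0.01 * conc^0.7)$order   # 0.7
#' @export
loglog_order <- function(conc_mM, rates) {
  if (!is.numeric(conc_mM) || !is.numeric(rates) ||
      length(conc_mM) != length(rates))
    stop("'conc_mM' and 'rates' must be numeric vectors of equal length")
  if (any(conc_mM <= 0)) stop("concentrations must be > 0")
  bad <- !is.finite(rates) | rates <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive rate(s) dropped from the log-log fit")
    conc_mM <- conc_mM[!bad]
    rates <- rates[!bad]
  }
  if (length(unique(conc_mM)) < 2L)
    stop("fewer than 2 usable distinct concentrations")
  ols <- ols_fit(log10(conc_mM), log10(rates))
  structure(list(order = ols$slope, stderr = ols$stderr_slope,
                 intercept = ols$intercept, r_squared = ols$r_squared,
                 points = data.frame(log10_conc = log10(conc_mM),
                                     log10_rate = log10(rates)),
                 fit = ols$fit),
            class = "order_fit")
}

#' Hammett linear free-energy regression
#'
#' Regresses log10(k_X / k_ref) against tabulated sigma substituent
#' constants; the slope rho reports the charge development in the
#' transition state (negative rho: acceleration by electron donors).
#' Log base 10 throughout, the Hammett convention. rho is invariant to a
#' uniform rescaling of all rates.
#'
#' @param rates named numeric vector of rates (or rate constants)
#'   measured at fixed conditions, one per substituent; all > 0, at
#'   least 3 substituents including the reference.
#' @param sigmas a `sigma_table` (see [hansch_sigma()]) or named numeric
#'   vector covering every substituent in `rates`.
#' @param reference label of the reference substituent (default `"H"`).
#' @return an object of class `hammett_fit` with `rho`, `stderr_rho`,
#'   `intercept`, `r_squared` and the `points` (substituent, sigma,
#'   log10 rate ratio).
#' @examples
#' sig <- hansch_sigma()
#' subs <- c("H", "p-OMe", "p-Cl", "m-Cl")
#' rates <- stats::setNames(10^(-0.98 * sig[subs]), subs)
#' hammett_fit(rates, sig)$rho   # -0.98
#' @export
hammett_fit <- function(rates, sigmas, reference = "H") {
  if (!is.numeric(rates) || is.null(names(rates)))
    stop("'rates' must be a named numeric vector")
  if (length(rates) < 3L) stop("need at least 3 substituents")
  if (any(rates <= 0)) stop("all rates must be > 0")
  if (!reference %in% names(rates))
    stop("reference substituent '", reference, "' missing from 'rates'")
  sv <- if (inherits(sigmas, "sigma_table")) unclass(sigmas)
        else as_sigma_table(sigmas)
  missing <- setdiff(names(rates), names(sv))
  if (length(missing))
    stop("no sigma value for substituent(s): ",
         paste(missing, collapse = ", "))
  sigma <- unname(sv[names(rates)])
  log_ratio <- log10(rates / rates[[reference]])
  ols <- ols_fit(sigma, unname(log_ratio))
  structure(list(rho = ols$slope, stderr_rho = ols$stderr_slope,
                 intercept = ols$intercept, r_squared = ols$r_squared,
                 reference = reference,
                 points = data.frame(substituent = names(rates),
                                     sigma = sigma,
                                     log_ratio = unname(log_ratio)),
                 fit = ols$fit),
            class = "hammett_fit")
}
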