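#' Define one reaction step
#'
#' A reaction step carries reactant and product stoichiometries, a rate
#' constant, and optional per-species order overrides. The rate law is
#' mass-action by default, `rate = k * prod([S]^order_S)` over the
#' reactants, with the exponent of each reactant equal to its
#' stoichiometric coefficient unless overridden. Overrides allow the
#' empirical fractional orders (e.g. ~0.7 in an arylamine) often seen
#' when a one-step scheme stands in for a wider reaction network.
#'
#' @param reactants named numeric vector of reactant stoichiometric
#'   coefficients (must be positive).
#' @param products named numeric vector of product stoichiometric
#'   coefficients (must be positive).
#' @param k rate constant, in units of mM^(1-n) min^-1 for total
#'   molecularity n. Must be finite and non-negative.
#' @param orders optional named numeric vector of exponent overrides;
#'   names must be a subset of `names(reactants)`.
#' @return an object of class `reaction`.
#' @examples
#' reaction(c(A = 1, B = 1), c(C = 1), k = 3.5e-5)
#' reaction(c(TsCl = 1, ArNH2 = 1), c(TsNHAr = 1), k = 1e-3,
#'          orders = c(ArNH2 = 0.7))
#' @export
reaction <- function(reactants, products, k, orders = NULL) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k))
    stop("'k' must be a single finite number")
  if (k < 0) stop("rate constant 'k' must be >= 0")
  check_side <- function(side, what) {
    if (length(side) == 0L) return(stats::setNames(numeric(0), character(0)))
    if (!is.numeric(side) || is.null(names(side)) || any(!nzchar(names(side))))
      stop(what, " stoichiometry must be a named numeric vector")
    if (any(!is.finite(side)) || any(side <= 0))
      stop(what, " stoichiometric coefficients must be positive and finite")
    if (anyDuplicated(names(side)))
      stop("duplicated species in ", what, " stoichiometry")
    side
  }
  reactants <- check_side(reactants, "reactant")
  products <- check_side(products, "product")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("a reaction needs at least one reactant or product")
  if (!is.null(orders)) {
    if (!is.numeric(orders) || is.null(names(orders)))
      stop("'orders' must be a named numeric vector")
    if (any(!is.finite(orders)))
      stop("order-override exponents must be finite")
    if (!all(names(orders) %in% names(reactants)))
      stop("order overrides refer to non-reactant species: ",
           paste(setdiff(names(orders), names(reactants)), collapse = ", "))
  }
  structure(list(reactants = reactants, products = products,
                 k = k, orders = orders),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  side <- function(s) {
    if (!length(s)) return("0")
    paste(ifelse(s == 1, names(s), paste0(s, " ", names(s))), collapse = " + ")
  }
  ord <- ""
  if (!is.null(x$orders))
    ord <- paste0("; orders: ",
                  paste(names(x$orders), x$orders, sep = "^", collapse = ", "))
  cat(sprintf("%s -> %s  (k = %g%s)\n",
              side(x$reactants), side(x$products), x$k, ord))
  invisible(x)
}

#' Assemble a reaction network
#'
#' @param ... one or more [reaction()] objects (or a single list of them).
#' @param species optional character vector naming all species. Defaults
#'   to the union of species appearing in the reactions; if given, it must
#'   cover every species used by a reaction (extra inert species are
#'   allowed and stay constant during simulation).
#' @return an object of class `reaction_network`.
#' @examples
#' net <- reaction_network(reaction(c(A = 1, B = 1), c(C = 1), 3.5e-5))
#' net
#' @export
reaction_network <- function(..., species = NULL) {
  rxns <- list(...)
  if (length(rxns) == 1L && is.list(rxns[[1L]]) && !inherits(rxns[[1L]], "reaction"))
    rxns <- rxns[[1L]]
  if (length(rxns) == 0L) stop("a network needs at least one reaction")
  if (!all(vapply(rxns, inherits, logical(1), "reaction")))
    stop("all arguments must be 'reaction' objects")
  used <- unique(unlist(lapply(rxns, function(r)
    c(names(r$reactants), names(r$products)))))
  if (is.null(species)) {
    species <- used
  } else {
    if (!is.character(species) || anyDuplicated(species))
      stop("'species' must be a character vector without duplicates")
    missing <- setdiff(used, species)
    if (length(missing))
      stop("reactions use species absent from the species list: ",
           paste(missing, collapse = ", "))
  }
  structure(list(species = species, reactions = rxns),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reaction(s)\n",
              length(x$species), length(x$reactions)))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) {
    cat("  ")
    print(r)
  }
  invisible(x)
}

#' Concentration trace container
#'
#' Time-stamped concentrations for every species of a simulated or
#' measured experiment. Times are minutes since reaction start, strictly
#' increasing, the first one non-negative; concentrations are mM and
#' non-negative.
#'
#' @param times numeric vector of times (minutes).
#' @param conc numeric matrix (rows = times) with one named column per
#'   species, or a named list of equal-length numeric vectors.
#' @return an object of class `conc_trace` with elements `times` and
#'   `conc` (matrix).
#' @export
conc_trace <- function(times, conc) {
  if (is.list(conc) && !is.matrix(conc)) {
    conc <- do.call(cbind, conc)
  }
  if (!is.matrix(conc)) conc <- matrix(conc, ncol = 1L)
  if (is.null(colnames(conc)) || any(!nzchar(colnames(conc))))
    stop("'conc' must have species names")
  if (!is.numeric(times) || length(times) != nrow(conc))
    stop("'times' length must match the number of concentration rows")
  if (length(times) == 0L) stop("empty trace")
  if (times[1L] < 0) stop("times must start at >= 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  structure(list(times = as.numeric(times), conc = conc),
            class = "conc_trace")
}

#' @export
print.conc_trace <- function(x, ...) {
  cat(sprintf("Concentration trace: %d time points (%.3g to %.3g min), species: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(colnames(x$conc), collapse = ", ")))
  print(utils::head(as.data.frame(x), 4L))
  if (length(x$times) > 4L) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.conc_trace <- function(x, ...) {
  data.frame(time_min = x$times, x$conc, check.names = FALSE)
}

#' @export
plot.conc_trace <- function(x, ..., xlab = "time (min)", ylab = "concentration (mM)") {
  graphics::matplot(x$times, x$conc, type = "l", lty = 1,
                    xlab = xlab, ylab = ylab, ...)
  graphics::legend("right", legend = colnames(x$conc),
                   col = seq_len(ncol(x$conc)), lty = 1, bty = "n")
  invisible(x)
}

#' Integrate a reaction network to a concentration trace
#'
#' Solves the mass-action (optionally fractional-order) rate equations
#' d\[S\]/dt = sum over reactions of (net stoichiometry) * k *
#' prod(\[reactant\]^order) with an adaptive, stiffness-switching
#' integrator (`deSolve::ode`, method `lsoda`). Concentrations are
#' clipped at zero both inside the rate evaluation and in the output.
#'
#' @param network a [reaction_network()].
#' @param initial named numeric vector of initial concentrations (mM);
#'   must define every species in the network.
#' @param times strictly increasing sampling times (minutes), first >= 0.
#'   If the first time is positive, integration still starts at t = 0.
#' @param rtol,atol integrator tolerances.
#' @return a [conc_trace()].
#' @examples
#' net <- reaction_network(reaction(c(A = 1, B = 1), c(C = 1), 3.5e-5))
#' tr <- simulate_network(net, c(A = 1.5, B = 100, C = 0),
#'                        sample_schedule(82, 20))
#' head(as.data.frame(tr))
#' @export
simulate_network <- function(network, initial, times, rtol = 1e-8, atol = 1e-10) {
  if (!inherits(network, "reaction_network"))
    stop("'network' must be a reaction_network")
  sp <- network$species
  if (!is.numeric(initial) || is.null(names(initial)))
    stop("'initial' must be a named numeric vector")
  unknown <- setdiff(names(initial), sp)
  if (length(unknown))
    stop("unknown species in 'initial': ", paste(unknown, collapse = ", "))
  missing <- setdiff(sp, names(initial))
  if (length(missing))
    stop("'initial' must define every species; missing: ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(initial)) || any(initial < 0))
    stop("initial concentrations must be finite and >= 0")
  if (!is.numeric(times) || length(times) < 1L || times[1L] < 0 ||
      (length(times) > 1L && any(diff(times) <= 0)))
    stop("'times' must be strictly increasing and start at >= 0")

  y0 <- as.numeric(initial[sp])
  names(y0) <- sp
  rxn <- lapply(network$reactions, function(r) {
    ord <- r$reactants
    if (!is.null(r$orders)) ord[names(r$orders)] <- r$orders
    list(k = r$k, who = match(names(ord), sp), ord = unname(ord))
  })
  S <- vapply(network$reactions, function(r) {
    net <- numeric(length(sp))
    names(net) <- sp
    net[names(r$reactants)] <- net[names(r$reactants)] - r$reactants
    net[names(r$products)] <- net[names(r$products)] + r$products
    net
  }, numeric(length(sp)))
  S <- matrix(S, nrow = length(sp))

  deriv <- function(t, y, p) {
    y <- pmax(y, 0)
    rates <- vapply(rxn, function(r)
      r$k * prod(y[r$who]^r$ord), numeric(1))
    list(as.vector(S %*% rates))
  }

  prepend <- times[1L] > 0
  t_ode <- if (prepend) c(0, times) else times
  if (length(t_ode) == 1L) {
    conc <- matrix(y0, nrow = 1L, dimnames = list(NULL, sp))
    return(conc_trace(times, conc))
  }
  sol <- deSolve::ode(y = y0, times = t_ode, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  conc <- unname(sol[, -1L, drop = FALSE])
  if (prepend) conc <- conc[-1L, , drop = FALSE]
  conc <- pmax(conc, 0)
  colnames(conc) <- sp
  conc_trace(times, conc)
}

#' Closed-form pseudo-first-order decay
#'
#' Reference solution for a limiting reagent A consumed by a large excess
#' of B with second-order constant `k2`: \[A\](t) = A0 * exp(-k2 * B0 * t).
#' The product k2 * B0 is the observed decay constant k_obs.
#'
#' @param A0 initial concentration of the limiting reagent (mM).
#' @param k2 second-order rate constant (mM^-1 min^-1).
#' @param B0 concentration of the excess reagent (mM), treated as constant.
#' @param t time or vector of times (minutes).
#' @return concentration(s) of A in mM.
#' @examples
#' pfo_closed_form(1.5, 3.5e-5, 100, c(0, 10, 20))
#' @export
pfo_closed_form <- function(A0, k2, B0, t) {
  if (any(c(A0, k2, B0) < 0) || any(t < 0))
    stop("all arguments must be >= 0")
  A0 * exp(-k2 * B0 * t)
}

#' Build an acquisition schedule
#'
#' Converts an instrument sampling interval in seconds into a vector of
#' acquisition times in minutes (the package's internal time unit).
#' Seconds are only accepted at this boundary.
#'
#' @param interval_s sampling interval in seconds (> 0).
#' @param n_points number of acquisitions (>= 1).
#' @param t0_min time of the first acquisition, minutes (default 0); use
#'   this for a dead time between mixing and the first measurement.
#' @return numeric vector of `n_points` times in minutes.
#' @examples
#' sample_schedule(82, 20)    # 20 points, last at ~25.97 min
#' sample_schedule(112, 97)   # ~3 h screen
#' @export
sample_schedule <- function(interval_s, n_points, t0_min = 0) {
  if (!is.numeric(interval_s) || length(interval_s) != 1L || interval_s <= 0)
    stop("'interval_s' must be a positive number")
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 1 ||
      n_points != round(n_points))
    stop("'n_points' must be a positive integer")
  if (!is.numeric(t0_min) || length(t0_min) != 1L || t0_min < 0)
    stop("'t0_min' must be >= 0")
  t0_min + (seq_len(n_points) - 1) * interval_s / 60
}
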