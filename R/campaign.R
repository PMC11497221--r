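#' Fixed acquisition schedule for an experiment plan
#'
#' @param interval_s sampling interval, seconds (> 0).
#' @param n_points number of acquisitions (>= 1).
#' @param t0_min dead time before the first acquisition, minutes.
#' @return a list of class `fixed_schedule`.
#' @export
fixed_schedule <- function(interval_s, n_points, t0_min = 0) {
  sample_schedule(interval_s, n_points, t0_min)  # validates
  structure(list(interval_s = interval_s, n_points = as.integer(n_points),
                 t0_min = t0_min),
            class = "fixed_schedule")
}

#' Machine-readable plan for one monitored experiment
#'
#' The package's lightweight stand-in for an executable procedure
#' document: reagents and concentrations, a sampling schedule (fixed or
#' monitored with a data-driven stop condition) and a noise seed. Field
#' names stay close to the Add / Wait / Monitor vocabulary of executable
#' synthesis protocols without implementing an interpreter for them.
#'
#' @param id unique identifier within a campaign.
#' @param initial named numeric vector of initial concentrations (mM).
#' @param schedule a [fixed_schedule()], or `NULL` for a monitored plan.
#' @param monitor a [monitor_config()], or `NULL` for a fixed plan.
#'   Exactly one of `schedule` / `monitor` must be given.
#' @param seed integer noise seed for this experiment.
#' @param meta named list of free-form annotations (substituent, excess
#'   concentration, varied reagent, ...).
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(id, initial, schedule = NULL, monitor = NULL,
                            seed = 1L, meta = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be non-empty text")
  if (!is.numeric(initial) || is.null(names(initial)) ||
      any(!is.finite(initial)) || any(initial < 0))
    stop("'initial' must be a named numeric vector of concentrations >= 0")
  if (is.null(schedule) == is.null(monitor))
    stop("exactly one of 'schedule' or 'monitor' must be given")
  if (!is.null(schedule) && !inherits(schedule, "fixed_schedule"))
    stop("'schedule' must be a fixed_schedule")
  if (!is.null(monitor) && !inherits(monitor, "monitor_config"))
    stop("'monitor' must be a monitor_config")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  structure(list(id = id, initial = initial, schedule = schedule,
                 monitor = monitor, seed = as.integer(seed), meta = meta),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  mode <- if (is.null(x$monitor)) {
    sprintf("%d points every %g s", x$schedule$n_points,
            x$schedule$interval_s)
  } else {
    sprintf("monitored (W = %d, eps = %g, max %d)", x$monitor$window,
            x$monitor$threshold, x$monitor$max_measurements)
  }
  cat(sprintf("Plan '%s': %s; %s; seed %d\n", x$id,
              paste(names(x$initial), x$initial, sep = " = ",
                    collapse = ", "),
              mode, x$seed))
  invisible(x)
}

#' Build the plans of a Hammett initial-rates campaign
#'
#' One plan per (substituent, concentration) pair, substituent-major (the
#' campaign runs one arylamine at a time). Defaults follow the tosylation
#' design: 15 datapoints over 15 minutes at five initial amine
#' concentrations, with a fixed substrate (tosyl chloride) loading.
#'
#' @param substituents character vector of substituent labels.
#' @param concentrations_mM initial amine concentrations (mM).
#' @param n_points datapoints per experiment.
#' @param interval_s sampling interval, seconds.
#' @param substrate_mM tosyl chloride concentration (mM).
#' @param seed base seed; plan `i` gets `seed + i`.
#' @return list of [experiment_plan()]s of length
#'   `length(substituents) * length(concentrations_mM)`.
#' @examples
#' plans <- hammett_campaign(c("H", "p-OMe"), c(100, 50))
#' length(plans)  # 4
#' @export
hammett_campaign <- function(substituents, concentrations_mM,
                             n_points = 15L, interval_s = 60,
                             substrate_mM = 5, seed = 1L) {
  if (!is.character(substituents) || length(substituents) < 1L)
    stop("'substituents' must be a non-empty character vector")
  if (!is.numeric(concentrations_mM) || length(concentrations_mM) < 1L ||
      any(concentrations_mM <= 0))
    stop("'concentrations_mM' must be positive concentrations")
  if (anyDuplicated(substituents) || anyDuplicated(concentrations_mM))
    stop("duplicate (substituent, concentration) pairs are not allowed")
  plans <- list()
  i <- 0L
  for (sub in substituents) {
    for (conc in concentrations_mM) {
      i <- i + 1L
      plans[[i]] <- experiment_plan(
        id = sprintf("%s_%gmM", sub, conc),
        initial = c(TsCl = substrate_mM, ArNH2 = conc, TsNHAr = 0),
        schedule = fixed_schedule(interval_s, n_points),
        seed = seed + i,
        meta = list(substituent = sub, amine_mM = conc, order_in_run = i))
    }
  }
  plans
}

#' Build the plans of a pseudo-first-order excess series
#'
#' One plan per excess-reagent level at a fixed limiting-reagent
#' concentration. Defaults follow the cycloaddition design: 1.5 mM
#' limiting reagent against 100/150/200 mM excess reagent, 20 datapoints
#' every 82 seconds.
#'
#' @param A0_mM limiting-reagent concentration (mM).
#' @param excess_mM vector of excess-reagent concentrations (mM).
#' @param n_points datapoints per experiment.
#' @param interval_s sampling interval, seconds.
#' @param seed base seed; plan `i` gets `seed + i`.
#' @return list of [experiment_plan()]s, one per excess level.
#' @export
pseudo_first_order_series <- function(A0_mM = 1.5,
                                      excess_mM = c(100, 150, 200),
                                      n_points = 20L, interval_s = 82,
                                      seed = 1L) {
  if (!is.numeric(excess_mM) || length(excess_mM) < 1L)
    stop("'excess_mM' must be a non-empty numeric vector")
  if (any(excess_mM <= 0)) stop("excess concentrations must be > 0")
  if (anyDuplicated(excess_mM)) stop("duplicate excess concentrations")
  if (!is.numeric(A0_mM) || length(A0_mM) != 1L || A0_mM <= 0)
    stop("'A0_mM' must be a positive concentration")
  lapply(seq_along(excess_mM), function(i) {
    experiment_plan(
      id = sprintf("excess_%gmM", excess_mM[i]),
      initial = c(A = A0_mM, B = excess_mM[i], C = 0),
      schedule = fixed_schedule(interval_s, n_points),
      seed = seed + i,
      meta = list(excess_mM = excess_mM[i]))
  })
}

#' Build the plans of a visual-kinetics excess screen
#'
#' A standard experiment plus one experiment per reagent in which that
#' reagent alone is dosed at `excess_factor` times its standard
#' equivalents — the different-excess design behind a VTNA order scan.
#' Defaults mirror a ~3 h run sampled every 112 seconds.
#'
#' @param standard named numeric vector of reagent equivalents.
#' @param excess_factor multiplier applied to one reagent per extra
#'   experiment (> 1).
#' @param duration_min run length, minutes.
#' @param interval_s sampling interval, seconds.
#' @param base_mM concentration of one equivalent (mM).
#' @param seed base seed.
#' @return list of `1 + length(standard)` [experiment_plan()]s; the
#'   varied reagent of each excess plan is in `meta$varied`.
#' @export
excess_screen <- function(standard, excess_factor = 1.2,
                          duration_min = 180, interval_s = 112,
                          base_mM = 1, seed = 1L) {
  if (!is.numeric(standard) || is.null(names(standard)) ||
      length(standard) < 1L || any(standard <= 0))
    stop("'standard' must be a named vector of positive equivalents")
  if (!is.numeric(excess_factor) || length(excess_factor) != 1L ||
      excess_factor <= 1)
    stop("'excess_factor' must be > 1")
  n_points <- floor(duration_min * 60 / interval_s) + 1L
  sched <- fixed_schedule(interval_s, n_points)
  std_init <- standard * base_mM
  plans <- list(experiment_plan("standard", std_init, sched,
                                seed = seed + 1L,
                                meta = list(varied = NULL)))
  for (i in seq_along(standard)) {
    sp <- names(standard)[i]
    init <- std_init
    init[sp] <- init[sp] * excess_factor
    plans[[i + 1L]] <- experiment_plan(
      id = paste0("excess_", sp), initial = init, schedule = sched,
      seed = seed + 1L + i, meta = list(varied = sp))
  }
  plans
}

#' Chemistry context for a campaign
#'
#' Bundles everything [run_campaign()] needs to execute a plan: how to
#' build the reaction network and full initial-concentration vector for
#' a plan, the spectral signature and grid used to render observables,
#' the processing recipe, and the noise level. Use the shipped presets
#' ([iedda_chemistry()], [tosylation_chemistry()],
#' [complexation_chemistry()]) or build your own.
#'
#' @param network_fn function(plan) returning a [reaction_network()].
#' @param initial_fn function(plan) returning the full named initial
#'   vector (default: the plan's own `initial`).
#' @param signature a [spectral_signature()] (required when rendering).
#' @param grid x-grid for rendering.
#' @param recipe a [trace_recipe()] (required when rendering).
#' @param noise_sigma relative noise level of the rendered spectra.
#' @param render whether plans are executed through rendered spectra
#'   (`TRUE`) or analysed on the noiseless simulated traces (`FALSE`).
#' @param observed,reference,sigma_table analysis metadata used by the
#'   VTNA and Hammett branches.
#' @return an object of class `campaign_chemistry`.
#' @export
campaign_chemistry <- function(network_fn, initial_fn = NULL,
                               signature = NULL, grid = NULL,
                               recipe = NULL, noise_sigma = 0,
                               render = TRUE, observed = NULL,
                               reference = "H",
                               sigma_table = hansch_sigma()) {
  if (!is.function(network_fn)) stop("'network_fn' must be a function")
  if (is.null(initial_fn)) initial_fn <- function(plan) plan$initial
  if (render && (is.null(signature) || is.null(grid) || is.null(recipe)))
    stop("rendering needs 'signature', 'grid' and 'recipe'")
  structure(list(network_fn = network_fn, initial_fn = initial_fn,
                 signature = signature, grid = grid, recipe = recipe,
                 noise_sigma = noise_sigma, render = render,
                 observed = observed, reference = reference,
                 sigma_table = sigma_table),
            class = "campaign_chemistry")
}

# 5% (or rate_noise) multiplicative perturbation of a rate constant,
# drawn deterministically from the plan seed on a private RNG stream
perturb_k <- function(k, rate_noise, seed) {
  if (rate_noise <= 0) return(k)
  f <- with_private_seed(seed + 500000L,
                         1 + rate_noise * stats::rnorm(1))
  k * max(f, 1e-6)
}

#' Cycloaddition chemistry preset (UV-Vis, pseudo-first-order)
#'
#' A bimolecular A + B -> C network monitored by the visible band of the
#' limiting chromophore A (e.g. a tetrazine dienophile partner): band at
#' 540 nm, 40 nm half-width, linear response, so the absorbance trace
#' calibrates directly to \[A\] in mM.
#'
#' @param k2 second-order rate constant (mM^-1 min^-1).
#' @param noise_sigma relative spectral noise.
#' @param rate_noise multiplicative sd applied to `k2` per experiment
#'   (drawn from the plan seed).
#' @param response band absorbance per mM (AU).
#' @return a [campaign_chemistry()].
#' @export
iedda_chemistry <- function(k2 = 3.5e-5, noise_sigma = 0.01,
                            rate_noise = 0, response = 0.5) {
  sig <- spectral_signature(list(A = peak_table(540, 40, response)),
                            "uvvis")
  campaign_chemistry(
    network_fn = function(plan) {
      k <- perturb_k(k2, rate_noise, plan$seed)
      reaction_network(reaction(c(A = 1, B = 1), c(C = 1), k))
    },
    signature = sig,
    grid = seq(300, 800, by = 1),
    recipe = trace_recipe("absorbance", wavelength = 540,
                          calibration = response, species = "A"),
    noise_sigma = noise_sigma,
    observed = "A")
}

#' Tosylation chemistry preset (NMR, Hammett campaign)
#'
#' Pyridine-catalysed sulfonamide formation reduced to one empirical
#' step, TsCl + ArNH2 -> TsNHAr, with rate
#' `k_X * [TsCl] * [ArNH2]^amine_order` and substituent-dependent rate
#' constants `k_X = k_ref * 10^(rho * sigma_X)`. The rendered benchtop
#' NMR spectrum carries the two diagnostic tosyl methyl singlets
#' (substrate 2.46 ppm, product 2.36 ppm — placeholder shifts); the
#' default `k_ref` puts k_obs at 100 mM amine near 0.025 min^-1, i.e. a
#' reaction approaching completion in about two hours.
#'
#' @param k_ref rate constant of the reference substituent
#'   (mM^-amine_order min^-1).
#' @param rho Hammett reaction constant generating the substituent rate
#'   ratios.
#' @param amine_order empirical order in the arylamine.
#' @param sigma_table substituent constants (see [hansch_sigma()]).
#' @param reference reference substituent label.
#' @param noise_sigma relative spectral noise.
#' @param rate_noise multiplicative sd applied to each experiment's rate
#'   constant (drawn from the plan seed).
#' @return a [campaign_chemistry()].
#' @export
tosylation_chemistry <- function(k_ref = 1e-3, rho = -0.98,
                                 amine_order = 0.7,
                                 sigma_table = hansch_sigma(),
                                 reference = "H", noise_sigma = 0.01,
                                 rate_noise = 0) {
  sig <- spectral_signature(list(
    TsCl = peak_table(2.46, 0.005, 3),
    TsNHAr = peak_table(2.36, 0.005, 3)), "nmr")
  sub_region <- region(2.41, 2.56, "TsCl CH3")
  prod_region <- region(2.26, 2.41, "TsNHAr CH3")
  sv <- if (inherits(sigma_table, "sigma_table")) unclass(sigma_table)
        else sigma_table
  campaign_chemistry(
    network_fn = function(plan) {
      sub <- plan$meta$substituent
      if (is.null(sub)) sub <- reference
      if (!sub %in% names(sv))
        stop("no sigma value for substituent '", sub, "'")
      k <- k_ref * 10^(rho * sv[[sub]])
      k <- perturb_k(k, rate_noise, plan$seed)
      reaction_network(reaction(c(TsCl = 1, ArNH2 = 1), c(TsNHAr = 1), k,
                                orders = c(ArNH2 = amine_order)))
    },
    signature = sig,
    grid = seq(2.1, 2.7, by = 0.00125),
    recipe = trace_recipe("conversion", product_region = prod_region,
                          total_regions = list(prod_region, sub_region),
                          baseline = "none"),
    noise_sigma = noise_sigma,
    observed = "TsNHAr", reference = reference,
    sigma_table = as_sigma_table(sv))
}

#' Metal-complexation chemistry preset (visual kinetics / VTNA)
#'
#' Iron(II) plus two in-situ imine ligand components collapsed to one
#' effective step Fe + AQ + FP -> Complex with mass-action (first-order
#' in each reagent) kinetics by default; per-species order overrides let
#' the screen emulate other true orders. Analysed on noiseless traces by
#' default, as a visual kinetic screen.
#'
#' @param k effective rate constant (mM^-2 min^-1 at default orders).
#' @param orders optional named exponent overrides.
#' @param render whether to render UV-Vis spectra (default `FALSE`:
#'   traces are analysed directly).
#' @param noise_sigma relative spectral noise when rendering.
#' @return a [campaign_chemistry()].
#' @export
complexation_chemistry <- function(k = 0.005, orders = NULL,
                                   render = FALSE, noise_sigma = 0) {
  sig <- spectral_signature(list(Complex = peak_table(560, 50, 0.8)),
                            "uvvis")
  campaign_chemistry(
    network_fn = function(plan)
      reaction_network(reaction(c(Fe = 1, AQ = 1, FP = 1),
                                c(Complex = 1), k, orders = orders)),
    initial_fn = function(plan) c(plan$initial, Complex = 0),
    signature = sig,
    grid = seq(300, 820, by = 1),
    recipe = trace_recipe("absorbance", wavelength = 560,
                          calibration = 0.8, species = "Complex"),
    noise_sigma = noise_sigma, render = render,
    observed = "Complex")
}

# execute one fixed-schedule plan: simulate, optionally render + process
run_plan <- function(plan, chem) {
  if (is.null(plan$schedule))
    stop("plan '", plan$id, "' is monitored; use analysis = 'monitor'")
  times <- sample_schedule(plan$schedule$interval_s,
                           plan$schedule$n_points,
                           plan$schedule$t0_min)
  net <- chem$network_fn(plan)
  init <- chem$initial_fn(plan)
  trace <- simulate_network(net, init, times)
  observable <- NULL
  if (isTRUE(chem$render)) {
    nm <- noise_model(chem$noise_sigma, seed = plan$seed)
    spectra <- lapply(seq_along(times), function(i)
      render_spectrum(trace, i, chem$signature, chem$grid, nm))
    observable <- trace_from_spectra(spectra, chem$recipe)
  }
  list(plan = plan, trace = trace, observable = observable)
}

observable_or_trace <- function(run, chem) {
  if (!is.null(run$observable)) run$observable
  else {
    sp <- chem$observed
    data.frame(time_min = run$trace$times,
               value = run$trace$conc[, sp])
  }
}

#' Execute a campaign end-to-end
#'
#' Runs every plan (simulate, render, integrate, fit) and then the
#' campaign-level inference:
#' \describe{
#'   \item{`initial_rates_k2`}{per plan, the limiting reagent's decay
#'     constant via [fit_pfo_kobs()], then [kobs_to_k2()] against the
#'     excess concentrations from `meta$excess_mM`.}
#'   \item{`hammett`}{per plan, the initial rate of the conversion trace
#'     via [fit_initial_rate()]; per substituent, a [loglog_order()] over
#'     its concentration series; across substituents, a [hammett_fit()]
#'     of the rates at the highest common concentration (when at least 3
#'     substituents are present).}
#'   \item{`vtna`}{per varied reagent in the plans' `meta$varied`, a
#'     [vtna_order_scan()] of that excess experiment against the
#'     standard experiment.}
#'   \item{`monitor`}{a single monitored plan: spectra are generated on
#'     the monitor's schedule, [run_monitor()] applies the plateau stop,
#'     and the run is frozen into a [freeze_protocol()] static plan.}
#' }
#'
#' @param plans list of [experiment_plan()]s with unique ids.
#' @param analysis one of `"initial_rates_k2"`, `"hammett"`, `"vtna"`,
#'   `"monitor"`.
#' @param chemistry a [campaign_chemistry()].
#' @param alpha_grid candidate orders for the VTNA branch.
#' @return an object of class `campaign_result` with `experiments` (per
#'   plan: trace, observable, fit), `inference` (the campaign-level
#'   result) and `provenance` (plan ids, seeds, config hash).
#' @export
run_campaign <- function(plans, analysis = c("initial_rates_k2",
                                             "hammett", "vtna",
                                             "monitor"),
                         chemistry, alpha_grid = seq(-1, 3, by = 0.05)) {
  analysis <- match.arg(analysis)
  if (!inherits(chemistry, "campaign_chemistry"))
    stop("'chemistry' must be a campaign_chemistry")
  if (!is.list(plans) || length(plans) < 1L ||
      !all(vapply(plans, inherits, logical(1), "experiment_plan")))
    stop("'plans' must be a list of experiment_plan objects")
  ids <- vapply(plans, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate plan ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))

  if (analysis == "monitor") {
    if (length(plans) != 1L || is.null(plans[[1L]]$monitor))
      stop("monitor analysis needs exactly one monitored plan")
    return(run_monitored_campaign(plans[[1L]], chemistry))
  }
  if (any(vapply(plans, function(p) is.null(p$schedule), logical(1))))
    stop("analysis '", analysis, "' needs fixed-schedule plans")

  runs <- lapply(plans, run_plan, chem = chemistry)
  inference <- switch(
    analysis,
    initial_rates_k2 = infer_k2(runs, chemistry),
    hammett = infer_hammett(runs, chemistry),
    vtna = infer_vtna(runs, chemistry, alpha_grid))

  campaign_result(analysis, runs, inference, plans)
}

campaign_result <- function(analysis, runs, inference, plans) {
  seeds <- vapply(plans, `[[`, integer(1), "seed")
  ids <- vapply(plans, `[[`, character(1), "id")
  cfg <- list(analysis = analysis, ids = ids, seeds = seeds)
  tf <- tempfile()
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(list(analysis = analysis, experiments = runs,
                 inference = inference,
                 provenance = list(plan_ids = ids, seeds = seeds,
                                   config_hash = hash)),
            class = "campaign_result")
}

infer_k2 <- function(runs, chem) {
  per <- lapply(runs, function(r) {
    obs <- observable_or_trace(r, chem)
    if (inherits(obs, "conc_trace")) {
      fit_pfo_kobs(obs$times, obs$conc[, chem$observed])
    } else {
      fit_pfo_kobs(obs$time_min, obs$value)
    }
  })
  excess <- vapply(runs, function(r) r$plan$meta$excess_mM, numeric(1))
  kobs <- vapply(per, `[[`, numeric(1), "kobs")
  list(per_experiment = per,
       k2_fit = kobs_to_k2(excess, kobs))
}

infer_hammett <- function(runs, chem) {
  rates <- vapply(runs, function(r) {
    obs <- r$observable
    if (!inherits(obs, "conversion_series"))
      stop("hammett analysis needs conversion observables (render = TRUE)")
    fit_initial_rate(obs$time_min, obs$conversion)$slope
  }, numeric(1))
  subs <- vapply(runs, function(r) r$plan$meta$substituent, character(1))
  conc <- vapply(runs, function(r) r$plan$meta$amine_mM, numeric(1))

  order_fits <- lapply(split(seq_along(runs), subs)[unique(subs)],
                       function(i) loglog_order(conc[i], rates[i]))

  hammett <- NULL
  top <- max(conc)
  at_top <- conc == top
  if (length(unique(subs[at_top])) >= 3L &&
      chem$reference %in% subs[at_top]) {
    r_top <- stats::setNames(rates[at_top], subs[at_top])
    hammett <- hammett_fit(r_top, chem$sigma_table, chem$reference)
  }
  list(rates = data.frame(substituent = subs, amine_mM = conc,
                          initial_rate = rates),
       orders = order_fits, hammett = hammett)
}

infer_vtna <- function(runs, chem, alpha_grid) {
  varied <- lapply(runs, function(r) r$plan$meta$varied)
  std <- which(vapply(varied, is.null, logical(1)))
  if (length(std) != 1L)
    stop("vtna analysis needs exactly one standard (non-excess) plan")
  scans <- list()
  for (i in setdiff(seq_along(runs), std)) {
    sp <- varied[[i]]
    scans[[sp]] <- vtna_order_scan(
      list(runs[[std]]$trace, runs[[i]]$trace),
      observed = chem$observed, varied = sp, grid = alpha_grid)
  }
  scans
}

run_monitored_campaign <- function(plan, chem) {
  cfg <- plan$monitor
  times <- sample_schedule(cfg$interval_min * 60, cfg$max_measurements,
                           cfg$t0_min)
  net <- chem$network_fn(plan)
  init <- chem$initial_fn(plan)
  trace <- simulate_network(net, init, times)
  nm <- noise_model(chem$noise_sigma, seed = plan$seed)
  spectra <- lapply(seq_along(times), function(i)
    render_spectrum(trace, i, chem$signature, chem$grid, nm))
  record <- run_monitor(spectrum_stream(spectra), chem$recipe, cfg)
  protocol <- if (record$stop_reason == "plateau")
    freeze_protocol(record, plan) else NULL
  campaign_result("monitor",
                  list(list(plan = plan, trace = trace,
                            observable = record$conversions)),
                  list(record = record, protocol = protocol),
                  list(plan))
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("Campaign result (%s): %d experiment(s)\n", x$analysis,
              length(x$experiments)))
  inf <- x$inference
  if (x$analysis == "initial_rates_k2") {
    cat(sprintf("  k2 = %.4g +/- %.2g mM^-1 min^-1\n",
                inf$k2_fit$slope, inf$k2_fit$stderr_slope))
  } else if (x$analysis == "hammett") {
    if (!is.null(inf$hammett))
      cat(sprintf("  rho = %.3f +/- %.3f (r2 = %.3f)\n",
                  inf$hammett$rho, inf$hammett$stderr_rho,
                  inf$hammett$r_squared))
    for (s in names(inf$orders))
      cat(sprintf("  order[%s] = %.3f +/- %.3f\n", s,
                  inf$orders[[s]]$order, inf$orders[[s]]$stderr))
  } else if (x$analysis == "vtna") {
    for (s in names(inf))
      cat(sprintf("  best alpha[%s] = %.2f\n", s, inf[[s]]$best_alpha))
  } else {
    print(inf$record)
  }
  invisible(x)
}

#' Freeze a monitored run into a static protocol
#'
#' Converts a plateau-terminated [monitor_record()] and its plan into a
#' fixed-duration protocol: the data-driven stop condition is replaced
#' by the realized measurement count and duration, so the procedure can
#' be replayed on a platform without analytics.
#'
#' @param record a `monitor_record` with `stop_reason == "plateau"`.
#' @param plan the monitored [experiment_plan()] that produced it.
#' @return an object of class `static_protocol`.
#' @export
freeze_protocol <- function(record, plan) {
  if (!inherits(record, "monitor_record"))
    stop("'record' must be a monitor_record")
  if (!inherits(plan, "experiment_plan") || is.null(plan$monitor))
    stop("'plan' must be a monitored experiment_plan")
  if (record$stop_reason != "plateau")
    stop("cannot verify endpoint: the record did not reach a plateau")
  cfg <- plan$monitor
  n <- record$stopped_at
  structure(list(id = paste0(plan$id, "_static"),
                 source_plan = plan$id,
                 initial = plan$initial,
                 interval_min = cfg$interval_min,
                 t0_min = cfg$t0_min,
                 n_measurements = n,
                 duration_min = cfg$t0_min + (n - 1) * cfg$interval_min,
                 final_conversion = utils::tail(record$conversions$conversion,
                                                1L),
                 threshold = cfg$threshold,
                 seed = plan$seed),
            class = "static_protocol")
}

#' @export
print.static_protocol <- function(x, ...) {
  cat(sprintf(paste0("Static protocol '%s': %d measurements every %g min",
                     " (%.1f min total), final conversion %.3f\n"),
              x$id, x$n_measurements, x$interval_min, x$duration_min,
              x$final_conversion))
  invisible(x)
}

#' Replay a static protocol without monitoring
#'
#' Re-executes the frozen fixed-duration plan through the same
#' simulate-render-integrate pipeline (with a fresh noise stream) and
#' reports the final conversion, verifying that the static protocol
#' reproduces the monitored endpoint.
#'
#' @param protocol a [freeze_protocol()] result.
#' @param chemistry the [campaign_chemistry()] of the original run.
#' @param seed noise seed of the replay (default: the protocol's seed
#'   offset by one, i.e. a different noise realization).
#' @return list with the replayed `series` (conversion data frame) and
#'   `final_conversion`.
#' @export
replay_protocol <- function(protocol, chemistry, seed = NULL) {
  if (!inherits(protocol, "static_protocol"))
    stop("'protocol' must be a static_protocol")
  if (is.null(seed)) seed <- protocol$seed + 1L
  plan <- experiment_plan(
    id = protocol$id, initial = protocol$initial,
    schedule = fixed_schedule(protocol$interval_min * 60,
                              protocol$n_measurements, protocol$t0_min),
    seed = seed)
  run <- run_plan(plan, chemistry)
  series <- run$observable
  final <- if (inherits(series, "conversion_series"))
    utils::tail(series$conversion, 1L)
  else utils::tail(series$value, 1L)
  list(series = series, final_conversion = final)
}
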