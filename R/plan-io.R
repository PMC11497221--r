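# plan / record / campaign serialization: JSON documents, stable field
# order, numbers at full precision so identical inputs give identical bytes

plan_to_list <- function(plan) {
  out <- list(id = plan$id, initial = as.list(plan$initial),
              seed = plan$seed, meta = plan$meta)
  if (!is.null(plan$schedule)) {
    out$schedule <- unclass(plan$schedule)
  } else {
    out$monitor <- unclass(plan$monitor)
  }
  out
}

#' Write / read experiment plans as JSON
#'
#' @param plans list of [experiment_plan()]s.
#' @param path JSON file path.
#' @return `write_plans_json` returns `path` invisibly;
#'   `read_plans_json` returns a list of plans.
#' @export
write_plans_json <- function(plans, path) {
  if (!is.list(plans) ||
      !all(vapply(plans, inherits, logical(1), "experiment_plan")))
    stop("'plans' must be a list of experiment_plan objects")
  jsonlite::write_json(lapply(plans, plan_to_list), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_plans_json
#' @export
read_plans_json <- function(path) {
  docs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(docs, function(d) {
    sched <- if (!is.null(d$schedule))
      fixed_schedule(d$schedule$interval_s, d$schedule$n_points,
                     d$schedule$t0_min)
    mon <- if (!is.null(d$monitor))
      monitor_config(d$monitor$window, d$monitor$threshold,
                     d$monitor$max_measurements, d$monitor$interval_min,
                     d$monitor$t0_min, d$monitor$mode)
    experiment_plan(d$id, unlist(d$initial), schedule = sched,
                    monitor = mon, seed = d$seed,
                    meta = lapply(d$meta, function(m) m))
  })
}

#' Serialize a campaign result to canonical JSON
#'
#' A deterministic JSON record of a [run_campaign()] result: per-plan
#' fits, the campaign-level inference and provenance (plan ids, seeds,
#' config hash). Identical plans and seeds produce identical JSON text,
#' so a campaign is reproducible byte-for-byte.
#'
#' @param result a `campaign_result`.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON text (invisibly when `path` is given).
#' @export
campaign_json <- function(result, path = NULL) {
  if (!inherits(result, "campaign_result"))
    stop("'result' must be a campaign_result")
  inf <- result$inference
  infdoc <- switch(
    result$analysis,
    initial_rates_k2 = list(
      kobs = lapply(result$experiments, function(r) list(
        excess_mM = r$plan$meta$excess_mM)),
      k2 = inf$k2_fit$slope, k2_stderr = inf$k2_fit$stderr_slope,
      intercept = inf$k2_fit$intercept),
    hammett = list(
      rates = inf$rates,
      orders = lapply(inf$orders, function(o)
        list(order = o$order, stderr = o$stderr)),
      rho = if (!is.null(inf$hammett)) inf$hammett$rho,
      rho_stderr = if (!is.null(inf$hammett)) inf$hammett$stderr_rho),
    vtna = lapply(inf, function(v)
      list(best_alpha = v$best_alpha, min_score = min(v$scores))),
    monitor = list(
      stopped_at = inf$record$stopped_at,
      stop_reason = inf$record$stop_reason,
      final_conversion = utils::tail(inf$record$conversions$conversion, 1L),
      static_duration_min = if (!is.null(inf$protocol))
        inf$protocol$duration_min))
  doc <- list(analysis = result$analysis,
              inference = infdoc,
              provenance = result$provenance)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                          dataframe = "columns", null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
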