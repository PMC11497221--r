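test_that("campaign plan arithmetic matches the study designs", {
  subs <- c("p-OMe", "p-Me", "m-Me", "H", "p-F", "p-Cl", "p-Br", "m-Cl")
  plans <- hammett_campaign(subs, c(100, 75, 50, 37.5, 25), n_points = 15)
  expect_length(plans, 40)
  expect_equal(sum(vapply(plans, function(p) p$schedule$n_points,
                          integer(1))), 600)
  # substituent-major ordering: one arylamine at a time
  first8 <- vapply(plans[1:5], function(p) p$meta$substituent, character(1))
  expect_true(all(first8 == "p-OMe"))
  expect_length(hammett_campaign("H", 100), 1)
  expect_error(hammett_campaign(c("H", "H"), 100), "duplicate")
  expect_error(hammett_campaign("H", c(50, 50)), "duplicate")

  pfo <- pseudo_first_order_series(1.5, c(100, 150, 200), 20, 82)
  expect_length(pfo, 3)
  expect_true(all(vapply(pfo, function(p) p$schedule$n_points,
                         integer(1)) == 20))
  expect_equal(vapply(pfo, function(p) p$initial[["B"]], numeric(1)),
               c(100, 150, 200))
  expect_error(pseudo_first_order_series(1.5, numeric(0)), "non-empty")
  single <- pseudo_first_order_series(1.5, 100, 1, 60)
  expect_equal(single[[1]]$schedule$n_points, 1L)

  scr <- excess_screen(c(Fe = 1, AQ = 2, FP = 2), 1.2)
  expect_length(scr, 4)
  expect_error(excess_screen(c(Fe = 1), 1.0), "> 1")
  expect_length(excess_screen(c(Fe = 1), 1.2), 2)
  # the excess plan doses only its own reagent at 1.2x
  expect_equal(scr[[2]]$initial[["Fe"]], 1.2)
  expect_equal(scr[[2]]$initial[["AQ"]], 2)
})

test_that("experiment plans validate their mode and contents", {
  expect_error(experiment_plan("a", c(A = 1)), "exactly one")
  expect_error(experiment_plan("a", c(A = 1),
                               schedule = fixed_schedule(60, 5),
                               monitor = monitor_config(2, 0.1, 5, 1)),
               "exactly one")
  expect_error(experiment_plan("a", c(A = -1),
                               schedule = fixed_schedule(60, 5)), ">= 0")
  expect_error(experiment_plan("", c(A = 1),
                               schedule = fixed_schedule(60, 5)),
               "non-empty")
})

test_that("run_campaign rejects mismatched plan/analysis pairings", {
  plans <- pseudo_first_order_series(seed = 2)
  chem <- iedda_chemistry()
  expect_error(run_campaign(plans, "monitor", chem), "exactly one")
  expect_error(run_campaign(c(plans, plans), "initial_rates_k2", chem),
               "duplicate")
  mon <- experiment_plan("m", c(A = 1, B = 100, C = 0),
                         monitor = monitor_config(3, 0.01, 10, 1))
  expect_error(run_campaign(list(mon), "initial_rates_k2", chem),
               "fixed-schedule")
})

test_that("a noiseless Hammett campaign recovers its generating parameters", {
  subs <- c("p-OMe", "m-Me", "H", "p-Cl", "m-Cl")
  plans <- hammett_campaign(subs, c(100, 50, 25), seed = 8)
  chem <- tosylation_chemistry(noise_sigma = 0, rate_noise = 0)
  res <- run_campaign(plans, "hammett", chem)
  expect_s3_class(res$inference$hammett, "hammett_fit")
  expect_lt(abs(res$inference$hammett$rho + 0.98), 0.05)
  orders <- vapply(res$inference$orders, `[[`, numeric(1), "order")
  expect_true(all(abs(orders - 0.7) < 0.1))
  # a single-substituent campaign still yields the order fit, no Hammett
  one <- run_campaign(hammett_campaign("H", c(100, 50, 25), seed = 2),
                      "hammett", chem)
  expect_null(one$inference$hammett)
  expect_lt(abs(one$inference$orders$H$order - 0.7), 0.1)
})

test_that("the cycloaddition series recovers k2 end-to-end", {
  plans <- pseudo_first_order_series(seed = 77)
  res <- run_campaign(plans, "initial_rates_k2",
                      iedda_chemistry(noise_sigma = 0))
  expect_equal(res$inference$k2_fit$slope, 3.5e-5, tolerance = 1e-3)
})

test_that("campaign results serialize deterministically", {
  plans <- pseudo_first_order_series(seed = 5)
  chem <- iedda_chemistry(noise_sigma = 0.01)
  j1 <- campaign_json(run_campaign(plans, "initial_rates_k2", chem))
  j2 <- campaign_json(run_campaign(plans, "initial_rates_k2", chem))
  expect_identical(as.character(j1), as.character(j2))
  # a different seed changes the result but stays valid JSON
  j3 <- campaign_json(run_campaign(pseudo_first_order_series(seed = 6),
                                   "initial_rates_k2", chem))
  expect_false(identical(as.character(j1), as.character(j3)))
  parsed <- jsonlite::fromJSON(as.character(j1))
  expect_equal(parsed$analysis, "initial_rates_k2")
  expect_true(is.numeric(parsed$inference$k2))
})

test_that("monitored campaigns freeze into replayable static protocols", {
  chem <- tosylation_chemistry(noise_sigma = 0.002)
  plan <- experiment_plan("tosylation", c(TsCl = 5, ArNH2 = 100, TsNHAr = 0),
                          monitor = monitor_config(5, 0.01, 40, 7.5),
                          seed = 21)
  res <- run_campaign(list(plan), "monitor", chem)
  rec <- res$inference$record
  expect_equal(rec$stop_reason, "plateau")
  proto <- res$inference$protocol
  expect_s3_class(proto, "static_protocol")
  expect_equal(proto$n_measurements, rec$stopped_at)
  expect_equal(proto$duration_min, (rec$stopped_at - 1) * 7.5)
  replay <- replay_protocol(proto, chem)
  expect_lt(abs(replay$final_conversion - proto$final_conversion), 0.01)
})

test_that("freezing requires a plateau-terminated record", {
  ramp <- lapply(1:10, function(i) {
    x <- seq(0, 1, 0.01)
    spectrum(x, c(rep(i * 0.03, 51), rep(1, 50)), "uvvis", i)
  })
  prod_r <- region(0, 0.5, "p")
  sub_r <- region(0.5, 1, "s")
  cfg <- monitor_config(4, 1e-9, 10, 1)
  rec <- run_monitor(ramp, trace_recipe("conversion",
                                        product_region = prod_r,
                                        total_regions = list(prod_r, sub_r),
                                        baseline = "none"), cfg)
  expect_equal(rec$stop_reason, "max_reached")
  plan <- experiment_plan("x", c(TsCl = 5, ArNH2 = 100, TsNHAr = 0),
                          monitor = cfg)
  expect_error(freeze_protocol(rec, plan), "cannot verify")
})

test_that("frozen protocols replay to the monitored endpoint across kinetics", {
  set.seed(91)
  for (rep in 1:8) {
    kobs <- stats::runif(1, 0.015, 0.08)
    chem <- tosylation_chemistry(k_ref = kobs / 100^0.7,
                                 noise_sigma = 0.002)
    plan <- experiment_plan(paste0("run", rep),
                            c(TsCl = 5, ArNH2 = 100, TsNHAr = 0),
                            monitor = monitor_config(5, 0.01, 60, 7.5),
                            seed = 300 + rep)
    res <- run_campaign(list(plan), "monitor", chem)
    proto <- res$inference$protocol
    expect_false(is.null(proto))
    replay <- replay_protocol(proto, chem)
    expect_lt(abs(replay$final_conversion - proto$final_conversion), 0.01)
  }
})
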