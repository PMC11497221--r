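test_that("the windowed plateau test matches its definition", {
  expect_true(plateau_reached(rep(0.9, 5), 5, 0.01))
  expect_false(plateau_reached(rep(0.9, 4), 5, 0.01))
  ramp <- seq(0, 2, by = 0.1)
  for (m in 2:length(ramp))
    expect_false(plateau_reached(ramp[1:m], min(m, 5), 0.01))
  # spread exactly at the threshold counts as a plateau
  expect_true(plateau_reached(c(0.5, 0.625), 2, 0.125))
  expect_error(plateau_reached(1:5, 1, 0.1), ">= 2")
  expect_error(plateau_reached(1:5, 2, 0), "> 0")
})

test_that("plateau is monotone in the threshold", {
  set.seed(33)
  for (rep in 1:50) {
    v <- cumsum(stats::rnorm(10, 0.02, 0.05))
    eps <- stats::runif(1, 0.01, 0.2)
    if (plateau_reached(v, 4, eps)) {
      expect_true(plateau_reached(v, 4, eps * 2))
      expect_true(plateau_reached(v, 4, eps + 1))
    }
  }
})

test_that("first plateau index equals the exhaustive-scan oracle", {
  set.seed(44)
  for (rep in 1:1000) {
    n <- sample(5:60, 1)
    W <- sample(2:5, 1)
    eps <- stats::runif(1, 0.005, 0.1)
    # mixture of ramps, logistics and noisy plateaus
    kind <- sample(3, 1)
    v <- switch(kind,
                cumsum(stats::runif(n, 0, 0.05)),
                1 / (1 + exp(-(seq_len(n) - n / 2) * 0.3)) +
                  stats::rnorm(n, 0, 0.002),
                pmin(seq_len(n) * 0.07, 0.8) + stats::rnorm(n, 0, 0.003))
    oracle <- plateau_oracle(v, W, eps)
    first <- NA_integer_
    for (m in seq_len(n)) {
      if (plateau_reached(v[1:m], W, eps)) { first <- m; break }
    }
    expect_identical(first, oracle)
  }
})

test_that("a flat stream stops after exactly W measurements", {
  times <- sample_schedule(60, 10)
  tr <- simulate_network(conversion_network(0),
                         c(Substrate = 5, Product = 2.5), times)
  sig <- roundtrip_signature()
  spectra <- lapply(seq_along(times), function(i)
    render_spectrum(tr, i, sig, roundtrip_grid()))
  cfg <- monitor_config(5, 0.01, 10, 1)
  rec <- run_monitor(spectra, roundtrip_recipe(), cfg)
  expect_equal(rec$stopped_at, 5)
  expect_equal(rec$stop_reason, "plateau")
})

test_that("a never-plateauing ramp runs to max_measurements", {
  # product-region signal keeps growing against a fixed substrate signal
  spectra <- lapply(1:30, function(i) {
    x <- seq(0, 1, 0.01)
    spectrum(x, c(rep(i * 0.03, 51), rep(1, 50)), "uvvis", i)
  })
  prod_r <- region(0, 0.5, "p")
  sub_r <- region(0.5, 1, "s")
  rec <- run_monitor(spectra,
                     trace_recipe("conversion", product_region = prod_r,
                                  total_regions = list(prod_r, sub_r),
                                  baseline = "none"),
                     monitor_config(5, 1e-9, 30, 1))
  expect_equal(rec$stopped_at, 30)
  expect_equal(rec$stop_reason, "max_reached")
})

test_that("stream exhaustion before a full window warns and reports max_reached", {
  times <- sample_schedule(60, 3)
  tr <- simulate_network(conversion_network(0.01),
                         c(Substrate = 5, Product = 0), times)
  spectra <- lapply(1:3, function(i)
    render_spectrum(tr, i, roundtrip_signature(), roundtrip_grid()))
  expect_warning(
    rec <- run_monitor(spectra, roundtrip_recipe(),
                       monitor_config(5, 0.01, 20, 1)),
    "exhausted")
  expect_equal(rec$stopped_at, 3)
  expect_equal(rec$stop_reason, "max_reached")
})

test_that("a monitored first-order run stops at the noiseless-oracle index", {
  # k_obs = 1.5 / h = 0.025 / min, sampled every 7.5 min
  kobs <- 0.025
  interval <- 7.5
  n_max <- 40
  times <- sample_schedule(interval * 60, n_max)
  tr <- simulate_network(conversion_network(kobs),
                         c(Substrate = 5, Product = 0), times)
  sig <- roundtrip_signature()
  cfg <- monitor_config(5, 0.01, n_max, interval)

  # oracle on the noiseless measured conversion series
  noiseless <- lapply(seq_along(times), function(i)
    render_spectrum(tr, i, sig, roundtrip_grid()))
  clean_conv <- trace_from_spectra(noiseless, roundtrip_recipe())$conversion
  oracle <- plateau_oracle(clean_conv, cfg$window, cfg$threshold)

  spectra <- lapply(seq_along(times), function(i)
    render_spectrum(tr, i, sig, roundtrip_grid(),
                    noise_model(0.002, seed = 9)))
  rec <- run_monitor(spectra, roundtrip_recipe(), cfg)
  expect_equal(rec$stop_reason, "plateau")
  expect_lte(abs(rec$stopped_at - oracle), 1)
  # stops close to the asymptote
  final_true <- tr$conc[rec$stopped_at, "Product"] / 5
  expect_gte(final_true, 0.95)
})

test_that("monitoring is deterministic for identical stream and config", {
  times <- sample_schedule(300, 20)
  tr <- simulate_network(conversion_network(0.05),
                         c(Substrate = 5, Product = 0), times)
  mk <- function() lapply(seq_along(times), function(i)
    render_spectrum(tr, i, roundtrip_signature(), roundtrip_grid(),
                    noise_model(0.005, seed = 3)))
  cfg <- monitor_config(4, 0.02, 20, 5)
  r1 <- run_monitor(mk(), roundtrip_recipe(), cfg)
  r2 <- run_monitor(mk(), roundtrip_recipe(), cfg)
  expect_identical(r1, r2)
})

test_that("the raw-spectrum L-infinity mode detects spectral stasis", {
  flat <- lapply(1:8, function(i)
    spectrum(seq(0, 1, 0.1), rep(0.5, 11), "uvvis", i))
  cfg <- monitor_config(4, 0.01, 8, 1, mode = "spectrum_linf")
  rec <- run_monitor(flat, NULL, cfg)
  expect_equal(rec$stop_reason, "plateau")
  expect_equal(rec$stopped_at, 4)
})
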