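test_that("baseline correction removes constants and linear ramps exactly", {
  x <- seq(2.0, 3.0, 0.01)
  reg <- region(2.2, 2.8)
  flat <- spectrum(rev(x), rep(4, length(x)), "nmr")
  expect_equal(baseline_correct(flat, reg)$y,
               rep(0, sum(x >= 2.2 & x <= 2.8)))
  ramp <- spectrum(rev(x), rev(3 * x - 1), "nmr")
  expect_equal(max(abs(baseline_correct(ramp, reg)$y)), 0)
})

test_that("a Lorentzian on a ramp is recovered after baseline correction", {
  x <- seq(-1, 1, 5e-4)
  g <- 0.01
  lor <- 0.5 * (g / pi) / (x^2 + g^2)
  ramp <- 2 + 3 * x
  s <- spectrum(x, lor + ramp, "uvvis", 0)
  reg <- region(-0.5, 0.5)
  seg <- baseline_correct(s, reg)
  pure <- 0.5 * (g / pi) / (seg$x^2 + g^2)
  # ramp is removed exactly up to the Lorentzian's own endpoint values,
  # which are ~g/(pi*0.25) ~ 1e-2; interior agreement is much tighter
  interior <- abs(seg$x) < 0.3
  expect_lt(max(abs(seg$y[interior] - pure[interior])), 2e-2)
  # with a flat baseline instead of a ramp the same subtraction applies,
  # so the two corrected segments agree to near machine precision
  s2 <- spectrum(x, lor + 7, "uvvis", 0)
  expect_lt(max(abs(baseline_correct(s2, reg)$y - seg$y)), 1e-6)
})

test_that("region integration matches analytic areas", {
  # unit-height rectangle of width w
  w <- 0.4
  x <- seq(0, w, length.out = 21)
  s <- spectrum(x, rep(1, 21), "uvvis")
  expect_equal(integrate_region(s, region(0, w), "none")$value, w)

  # Lorentzian over center +/- 20 gamma captures >= 0.96 of pi*gamma*h
  g <- 0.02
  h <- 5
  x <- seq(-1, 1, 1e-4)
  y <- h * g^2 / (x^2 + g^2)
  s <- spectrum(x, y, "uvvis")
  a <- integrate_region(s, region(-20 * g, 20 * g), "none")$value
  expect_gt(a, 0.96 * pi * g * h)
  expect_lt(a, pi * g * h)

  # orientation independence: descending-ppm storage, same positive area
  sn <- spectrum(rev(x + 3), rev(y), "nmr")
  an <- integrate_region(sn, region(3 - 20 * g, 3 + 20 * g), "none")$value
  expect_equal(an, a)
})

test_that("integration is additive over region splits", {
  set.seed(4)
  x <- seq(0, 1, 0.002)
  s <- spectrum(x, stats::runif(length(x)), "uvvis")
  mids <- x[c(53, 251, 394)]   # split points that are sample points
  for (m in mids) {
    a1 <- integrate_region(s, region(0, m), "none")$value
    a2 <- integrate_region(s, region(m, 1), "none")$value
    a <- integrate_region(s, region(0, 1), "none")$value
    expect_lt(abs(a1 + a2 - a), 1e-9)
  }
})

test_that("integration rejects degenerate regions", {
  x <- seq(0, 1, 0.1)
  s <- spectrum(x, x, "uvvis")
  expect_error(integrate_region(s, region(0.31, 0.39), "none"),
               "fewer than")
  expect_error(integrate_region(s, region(0.5, 1.5), "none"),
               "outside")
  expect_error(region(1, 1), "lo < hi")
})

test_that("conversion from integrals is a clipped ratio", {
  expect_equal(conversion_from_integrals(1, c(1, 1)), 0.5)
  expect_equal(conversion_from_integrals(0, c(0, 2)), 0)
  expect_equal(conversion_from_integrals(-0.3, c(-0.1, 2)), 0)
  expect_equal(conversion_from_integrals(5, c(2, 1)), 1)  # clipped
  expect_error(conversion_from_integrals(0, c(0, 0)), "zero")
  # invariant to uniform rescaling of all areas
  for (f in c(0.2, 3, 1e4))
    expect_equal(conversion_from_integrals(1.3 * f, c(1.3, 2.1) * f),
                 conversion_from_integrals(1.3, c(1.3, 2.1)))
})

test_that("absorbance lookup interpolates linearly", {
  s <- spectrum(c(400, 410, 420), c(0.1, 0.3, 0.2), "uvvis")
  expect_equal(absorbance_at(s, 410), 0.3)
  expect_equal(absorbance_at(s, 405), 0.2)   # midpoint mean
  expect_error(absorbance_at(s, 399), "outside")
})

test_that("render -> integrate -> conversion round-trips the simulated trace", {
  times <- sample_schedule(60, 15)
  net <- conversion_network(kobs = 0.1)
  tr <- simulate_network(net, c(Substrate = 5, Product = 0), times)
  true_conv <- tr$conc[, "Product"] / 5
  sig <- roundtrip_signature()
  grid <- roundtrip_grid()
  nm <- noise_model(0.01, seed = 1)
  spectra <- lapply(seq_along(times), function(i)
    render_spectrum(tr, i, sig, grid, nm))
  series <- trace_from_spectra(spectra, roundtrip_recipe())
  expect_s3_class(series, "conversion_series")
  expect_equal(nrow(series), 15)
  expect_lt(max(abs(series$conversion - true_conv)), 0.02)
  # monotone non-decreasing within noise
  expect_gt(min(diff(series$conversion)), -0.02)

  # a single 30%-conversion spectrum recovers 0.30 +/- 0.01
  i30 <- which.min(abs(true_conv - 0.3))
  s30 <- render_spectrum(tr, i30, sig, grid, nm)
  r <- roundtrip_recipe()
  totals <- vapply(r$total_regions, function(rg)
    integrate_region(s30, rg, "none")$value, numeric(1))
  conv30 <- conversion_from_integrals(
    integrate_region(s30, r$product_region, "none")$value, totals)
  expect_lt(abs(conv30 - true_conv[i30]), 0.01)
})

test_that("trace_from_spectra enforces its contracts", {
  r <- roundtrip_recipe()
  empty <- trace_from_spectra(list(), r)
  expect_equal(nrow(empty), 0)
  tr <- conc_trace(c(0, 1, 2), cbind(Substrate = c(5, 4, 3),
                                     Product = c(0, 1, 2)))
  sig <- roundtrip_signature()
  sp <- lapply(1:3, function(i)
    render_spectrum(tr, i, sig, roundtrip_grid()))
  expect_error(trace_from_spectra(sp[c(2, 1, 3)], r), "increasing")
  mixed <- sp
  mixed[[2]] <- spectrum(c(400, 500), c(0, 0), "uvvis", 1)
  expect_error(trace_from_spectra(mixed, r), "mixed")
  # calibrated absorbance mode returns a concentration trace
  utr <- conc_trace(c(0, 1), cbind(A = c(1.5, 1.2)))
  usig <- spectral_signature(list(A = peak_table(540, 40, 0.5)), "uvvis")
  us <- lapply(1:2, function(i)
    render_spectrum(utr, i, usig, seq(300, 800, 1)))
  ur <- trace_recipe("absorbance", wavelength = 540, calibration = 0.5,
                     species = "A")
  ct <- trace_from_spectra(us, ur)
  expect_s3_class(ct, "conc_trace")
  expect_equal(ct$conc[, "A"], c(1.5, 1.2), tolerance = 1e-6)
})
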