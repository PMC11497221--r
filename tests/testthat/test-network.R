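test_that("constructors validate reactions, networks and traces", {
  expect_error(reaction(c(A = 1), c(B = 1), -1), "k")
  expect_error(reaction(c(1), c(B = 1), 1), "named")
  expect_error(reaction(c(A = 0), c(B = 1), 1), "positive")
  expect_error(reaction(c(A = 1), c(B = 1), 1, orders = c(X = 0.5)),
               "non-reactant")
  expect_error(reaction(c(A = 1), c(B = 1), 1, orders = c(A = Inf)),
               "finite")
  expect_error(reaction_network(), "at least one")
  expect_error(reaction_network(reaction(c(A = 1), c(B = 1), 1),
                                species = "A"),
               "absent")
  expect_error(conc_trace(c(0, 0), cbind(A = c(1, 1))), "increasing")
  expect_error(conc_trace(c(0, 1), cbind(A = c(1, -1))), ">= 0")
})

test_that("simulation rejects bad initial conditions and times", {
  net <- pfo_network()
  expect_error(simulate_network(net, c(A = 1, B = 1, X = 1, C = 0), 0:2),
               "unknown species")
  expect_error(simulate_network(net, c(A = 1, B = 1), 0:2), "missing")
  expect_error(simulate_network(net, c(A = -1, B = 1, C = 0), 0:2),
               ">= 0")
  expect_error(simulate_network(net, c(A = 1, B = 1, C = 0), c(2, 1)),
               "increasing")
})

test_that("zero rate constant leaves all traces constant", {
  net <- pfo_network(k = 0)
  tr <- simulate_network(net, c(A = 2, B = 5, C = 0.5), seq(0, 60, 5))
  for (sp in c("A", "B", "C"))
    expect_equal(unname(tr$conc[, sp]),
                 rep(unname(tr$conc[1, sp]), length(tr$times)))
})

test_that("first-order interconversion conserves mass to 1e-9", {
  net <- reaction_network(reaction(c(A = 1), c(B = 1), 0.05))
  tr <- simulate_network(net, c(A = 3, B = 0), seq(0, 120, 4))
  expect_lt(max(abs(tr$conc[, "A"] + tr$conc[, "B"] - 3)), 1e-9)
})

test_that("bimolecular ODE matches the exact second-order closed form", {
  times <- sample_schedule(82, 20)
  for (B0 in c(100, 150, 200)) {
    tr <- simulate_network(pfo_network(), c(A = 1.5, B = B0, C = 0), times)
    exact <- second_order_exact(1.5, B0, 3.5e-5, times)
    expect_lt(max(abs(tr$conc[, "A"] - exact)), 1e-6)
  }
})

test_that("pseudo-first-order closed form approximates the ODE at high excess", {
  times <- seq(0, 30, length.out = 40)
  for (B0 in c(75, 100, 200, 500)) {  # excess ratio >= 50
    tr <- simulate_network(pfo_network(), c(A = 1.5, B = B0, C = 0), times)
    approx_A <- pfo_closed_form(1.5, 3.5e-5, B0, times)
    expect_lt(max(abs(tr$conc[, "A"] - approx_A)), 0.01 * 1.5)
  }
})

test_that("fractional-order rate laws follow their closed form", {
  for (n in c(0.46, 0.7, 0.94)) {
    net <- reaction_network(reaction(c(A = 1), c(B = 1), 0.02,
                                     orders = c(A = n)))
    times <- seq(0, 20, 0.5)
    tr <- simulate_network(net, c(A = 2, B = 0), times)
    expect_lt(max(abs(tr$conc[, "A"] - fractional_exact(2, 0.02, n, times))),
              1e-6)
  }
})

test_that("stoichiometry-weighted totals are conserved in random networks", {
  set.seed(71)
  for (rep in 1:10) {
    k1 <- stats::runif(1, 1e-3, 0.1)
    k2 <- stats::runif(1, 1e-3, 0.1)
    # A + B -> C, C -> D: conserved total A + C + D and B + C + D
    net <- reaction_network(
      reaction(c(A = 1, B = 1), c(C = 1), k1),
      reaction(c(C = 1), c(D = 1), k2))
    init <- c(A = stats::runif(1, 0.5, 3), B = stats::runif(1, 0.5, 3),
              C = 0, D = 0)
    tr <- simulate_network(net, init, seq(0, 200, 10))
    totA <- tr$conc[, "A"] + tr$conc[, "C"] + tr$conc[, "D"]
    totB <- tr$conc[, "B"] + tr$conc[, "C"] + tr$conc[, "D"]
    expect_lt(max(abs(totA - init[["A"]])), 1e-7)
    expect_lt(max(abs(totB - init[["B"]])), 1e-7)
  }
})

test_that("closed-form decay honours its boundary cases", {
  expect_identical(pfo_closed_form(1.5, 0.2, 50, 0), 1.5)
  expect_equal(pfo_closed_form(2, 0, 100, c(0, 5, 50)), rep(2, 3))
  v <- pfo_closed_form(1.5, 3.5e-5, 100, seq(0, 100, 1))
  expect_true(all(diff(v) <= 0))
  # k_obs = k2 * B0 = 3.5e-3 /min at the 100 mM excess level
  expect_equal(pfo_closed_form(1.5, 3.5e-5, 100, 10) / 1.5,
               exp(-3.5e-3 * 10))
  expect_error(pfo_closed_form(-1, 1, 1, 0), ">= 0")
})

test_that("schedules are arithmetic sequences in minutes", {
  s <- sample_schedule(82, 20)
  expect_length(s, 20)
  expect_equal(s[1], 0)
  expect_equal(s[20], 19 * 82 / 60)
  expect_equal(unique(round(diff(sample_schedule(112, 8)), 12)), 112 / 60)
  expect_equal(sample_schedule(60, 1, t0_min = 5), 5)
  expect_error(sample_schedule(0, 5), "positive")
  expect_error(sample_schedule(60, 0), "integer")
})
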