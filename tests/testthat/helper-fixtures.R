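# shared fixtures built in code

# bimolecular A + B -> C
pfo_network <- function(k = 3.5e-5) {
  reaction_network(reaction(c(A = 1, B = 1), c(C = 1), k))
}

# exact two-species second-order closed form for A + B -> C, B0 != A0
second_order_exact <- function(A0, B0, k, t) {
  A0 * (B0 - A0) / (B0 * exp((B0 - A0) * k * t) - A0)
}

# exact closed form for A -> products with fractional order n != 1:
# A(t) = (A0^(1-n) - (1-n) k t)^(1/(1-n)) while positive
fractional_exact <- function(A0, k, n, t) {
  base <- A0^(1 - n) - (1 - n) * k * t
  ifelse(base > 0, base^(1 / (1 - n)), 0)
}

# a random strictly-positive concentration trace for property tests
random_trace <- function(n = 12L, species = "A") {
  times <- cumsum(stats::runif(n, 0.2, 2))
  conc <- matrix(stats::runif(n, 0.05, 3), ncol = 1L,
                 dimnames = list(NULL, species))
  conc_trace(times, conc)
}

# well-separated two-singlet NMR configuration used by round-trip tests:
# wide peak separation and a fine grid keep cross-talk and integration
# noise small relative to the conversion scale
roundtrip_signature <- function() {
  spectral_signature(list(
    Substrate = peak_table(2.6, 0.01, 3),
    Product = peak_table(2.0, 0.01, 3)), "nmr")
}

roundtrip_grid <- function() seq(1.55, 3.05, by = 2e-4)

roundtrip_recipe <- function() {
  prod_r <- region(1.7, 2.3, "product CH3")
  sub_r <- region(2.3, 2.9, "substrate CH3")
  trace_recipe("conversion", product_region = prod_r,
               total_regions = list(prod_r, sub_r), baseline = "none")
}

# first-order conversion trace Substrate -> Product
conversion_network <- function(kobs) {
  reaction_network(reaction(c(Substrate = 1), c(Product = 1), kobs))
}

# brute-force plateau oracle: first measurement count m >= W such that
# max - min of values[(m-W+1)..m] <= eps; NA if never
plateau_oracle <- function(values, W, eps) {
  for (m in seq_along(values)) {
    if (m < W) next
    win <- values[(m - W + 1):m]
    if (max(win) - min(win) <= eps) return(m)
  }
  NA_integer_
}
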