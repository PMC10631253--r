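# Boltzmann statistics, coverage selection, the energy check and TST
# percentages.

test_that("equal barriers give equal populations", {
  b <- boltzmann_weights(c(x = 2, y = 2), 298.15)
  expect_equal(b$members$weight, c(0.5, 0.5))
})

test_that("a 1 kcal/mol gap at 298.15 K gives the 84.4/15.6 split", {
  # closed form: w2 = exp(-1/RT) / (1 + exp(-1/RT)), RT = 0.59248 kcal/mol
  b <- boltzmann_weights(c(lo = 0, hi = 1), 298.15)
  expect_equal(b$members$weight, c(0.844, 0.156), tolerance = 5e-4)
})

test_that("weights are invariant under a common energy shift", {
  e <- stats::runif(5, 0, 4)
  b1 <- boltzmann_weights(e, 310)
  b2 <- boltzmann_weights(e + 123.4, 310)
  expect_equal(b1$members$weight, b2$members$weight)
})

test_that("empty or non-finite energy lists are rejected", {
  expect_error(boltzmann_weights(numeric(0)), "empty",
               class = "dynaselect_validation_error")
  expect_error(boltzmann_weights(c(0, NaN)), "non-finite",
               class = "dynaselect_validation_error")
  expect_error(boltzmann_weights(c(0, 1), temperature = -1), "temperature",
               class = "dynaselect_validation_error")
})

test_that("coverage selection keeps the smallest prefix and renormalizes", {
  # energies reconstructed so the weights are exactly [0.90 0.06 0.03 0.01]
  w <- c(a = 0.90, b = 0.06, c = 0.03, d = 0.01)
  RT <- 1.98720425e-3 * 298.15
  e <- -RT * log(w / w[1])
  b <- boltzmann_weights(e, 298.15)
  expect_equal(b$members$weight, unname(w))
  kept <- select_top_coverage(b, 0.99)
  expect_identical(kept$members$label, c("a", "b", "c"))
  expect_equal(kept$members$weight, c(0.9091, 0.0606, 0.0303),
               tolerance = 1e-4)
  expect_equal(sum(kept$members$weight), 1)
})

test_that("coverage selection identity cases", {
  b <- boltzmann_weights(c(only = 0))
  expect_equal(select_top_coverage(b, 0.99)$members, b$members)
  b4 <- boltzmann_weights(stats::runif(4, 0, 2))
  expect_equal(select_top_coverage(b4, 1.0)$members$weight,
               b4$members$weight)
})

test_that("ties at the coverage boundary are all retained", {
  b <- boltzmann_weights(c(a = 0, b = 3, c = 3, d = 3))
  kept <- select_top_coverage(b, 0.99)
  expect_length(kept$members$label, 4L)
})

test_that("weight gaps shrink monotonically with temperature", {
  temps <- seq(200, 1000, by = 50)
  gaps <- vapply(temps, function(Tk) {
    w <- boltzmann_weights(c(0, 1.3), Tk)$members$weight
    abs(diff(w))
  }, 0)
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("the energy check branches on strict TS2-below-TS1", {
  ts1 <- toy_sp("TS1", "TS1", 10)
  lo <- list(toy_sp("TS2_a", "TS2", 2.5), toy_sp("TS2_b", "TS2", 1.2))
  expect_identical(energy_check(ts1, lo)$method, "VRAI")

  hi <- list(toy_sp("TS2_a", "TS2", 2.5), toy_sp("TS2_c", "TS2", 12))
  dec <- energy_check(ts1, hi)
  expect_identical(dec$method, "TST_fallback")
  expect_match(dec$reason, "TS2_c")

  expect_identical(energy_check(ts1, list())$method, "VRAI")
  # equality is conservative: falls back to TST
  eq <- list(toy_sp("TS2_eq", "TS2", 10))
  expect_identical(energy_check(ts1, eq)$method, "TST_fallback")
})

test_that("TST percentages: symmetric branch splits 50/50", {
  dist <- tst_product_percentages(net_one_ts1(-5, -5))
  expect_equal(unname(dist$percentages[c("A", "B")]), c(50, 50))
})

test_that("TST percentages: two branches follow the Boltzmann ratio", {
  dist <- tst_product_percentages(net_two_branches(e1 = 0, e2 = 1))
  expect_equal(unname(dist$percentages["A"]), 84.4, tolerance = 0.05)
  expect_equal(unname(dist$percentages["B"]), 15.6, tolerance = 0.05)
})

test_that("TST percentages are invariant under relabeling and energy shift", {
  net <- net_two_branches(e1 = 0.3, e2 = 1.1)
  d1 <- tst_product_percentages(net)
  shifted <- net_two_branches(e1 = 0.3 + 77, e2 = 1.1 + 77)
  d2 <- tst_product_percentages(shifted)
  expect_equal(d1$percentages, d2$percentages)
})

test_that("a TS1 without outgoing channels is rejected", {
  pts <- list(toy_sp("TS1", "TS1", 0), toy_sp("TS1_dead", "TS1", 1),
              toy_sp("P", "product", -20))
  expect_error(reaction_network(pts, list(c("TS1", "P"))),
               "TS1_dead", class = "dynaselect_validation_error")
})
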