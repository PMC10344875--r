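test_that("epitope occupancy follows the Langmuir isotherm", {
  expect_equal(epitope_occupancy(1e-9, 1e-9), 0.5)
  expect_equal(epitope_occupancy(0, 1e-9), 0)
  expect_equal(epitope_occupancy(9e-9, 1e-9), 0.9)
  ab <- 10^seq(-15, -6, by = 0.5)
  th <- epitope_occupancy(ab, 1e-9)
  expect_true(all(diff(th) > 0))
  expect_true(all(th >= 0 & th < 1))
  expect_error(epitope_occupancy(-1e-9, 1e-9), "ab_free_total")
  expect_error(epitope_occupancy(1e-9, 0), "kd")
})

test_that("pairing probability matches exhaustive enumeration over label states", {
  thetas <- c(0, 0.25, 0.5, 0.9, 1)
  probe_cases <- list(probe_set(1, 1, 0),      # p5 = p3 = 0.5
                      probe_set(1, 2, 1),      # asymmetric pools
                      probe_set(2, 2, 1),      # p5 = p3 = 0.4, depletant 0.2
                      probe_set(1, 1, 8))      # heavy depletion
  for (n in 2:5) {
    for (pr in probe_cases) {
      s <- pr$c5 + pr$c3 + pr$c_dep
      for (th in thetas) {
        expect_equal(pair_probability(th, n, pr),
                     pair_prob_enum(th, n, pr$c5 / s, pr$c3 / s),
                     tolerance = 1e-12,
                     label = sprintf("n=%d theta=%.2f c=(%g,%g,%g)",
                                     n, th, pr$c5, pr$c3, pr$c_dep))
      }
    }
  }
})

test_that("pairing probability hits its known corner values", {
  # full occupancy, two epitopes, symmetric pools: only the two mixed label
  # assignments of four equally likely ones succeed
  expect_equal(pair_probability(1, 2, probe_set(1e-12, 1e-12)), 0.5)
  # overwhelming depletant: essentially every binding event is unlabelled
  expect_lt(pair_probability(1, 4, probe_set(1e-12, 1e-12, 1e-3)), 1e-8)
  expect_equal(pair_probability(0, 3, probe_set(1, 1)), 0)
  expect_error(pair_probability(1.2, 3, probe_set(1, 1)), "theta")
  expect_error(pair_probability(0.5, 1, probe_set(1, 1)), "epitope_count")
})

test_that("depletant strictly attenuates the pairing probability", {
  for (th in c(0.2, 0.6, 1)) {
    base <- pair_probability(th, 4, probe_set(1e-12, 1e-12, 0))
    dep <- pair_probability(th, 4, probe_set(1e-12, 1e-12, 2e-12))
    expect_lt(dep, base)
  }
  # zero output stays zero
  expect_equal(pair_probability(0, 4, probe_set(1, 1, 5)), 0)
})

test_that("reporter output matches the hand-evaluated closed form", {
  # c5 = c3 = kd, no depletant, 2 epitopes, no dilution or losses:
  # theta = 2/3, p5 = p3 = 1/2, pair prob = 1 - 8/9 + 1/9 = 2/9
  a <- analyte("X", 2, 1e-9, 1, c(1e-13, 1e-10))
  ctx <- assay_context(ligation_efficiency = 1, mass_balance = FALSE,
                       sample_volume = 50e-6)
  x <- c(0, 1e-13, 9e-13, 5e-12)
  expect_equal(reporter_output(x, a, probe_set(1e-9, 1e-9), ctx), x * 2 / 9,
               tolerance = 1e-12)
  # cross-check the same configuration against the enumeration oracle
  th <- 2 / 3
  expect_equal(reporter_output(1e-12, a, probe_set(1e-9, 1e-9), ctx),
               1e-12 * pair_prob_enum(th, 2, 0.5, 0.5), tolerance = 1e-12)
})

test_that("reporter output is monotone in probe loading and linear at the low end", {
  a <- toy_analyte()
  ctx <- toy_ctx()
  x <- 10^seq(-13, -10, by = 0.5)
  lo <- reporter_output(x, a, probe_set(5e-12, 5e-12), ctx)
  hi <- reporter_output(x, a, probe_set(1e-11, 1e-11), ctx)
  expect_true(all(hi > lo))
  # homogeneity of degree 1 well below kd and bead capacity, mass balance off
  ctx_off <- assay_context(mass_balance = FALSE)
  ratios <- reporter_output(x, a, probe_set(5e-12, 5e-12), ctx_off) / x
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-9)
})

test_that("free-dAb mass balance converges and never increases with target load", {
  kd <- 1e-9; n <- 6; total <- 2e-12
  captured <- 10^seq(-13, -8, by = 0.25)
  free <- plaeq:::solve_free_dab(total, kd, n, captured)
  # fixed-point residual
  resid <- free - pmax(total - n * epitope_occupancy(free, kd) * captured, 0)
  expect_lt(max(abs(resid)) / total, 1e-8)
  expect_true(all(diff(free) <= 1e-20))
})

test_that("response curves respect monotonicity under loading and depletion", {
  a <- toy_analyte()
  ctx <- toy_ctx()
  grid <- 10^seq(-13, -10, by = 0.25)
  base <- response_curve(a, probe_set(1e-11, 1e-11), ctx, grid)
  halved <- response_curve(a, probe_set(5e-12, 5e-12), ctx, grid)
  depleted <- response_curve(a, probe_set(1e-11, 1e-11, 5e-11), ctx, grid)
  expect_true(all(halved$reporter_concs <= base$reporter_concs))
  nz <- base$reporter_concs > 0
  expect_true(all(depleted$reporter_concs[nz] < base$reporter_concs[nz]))
  z <- response_curve(a, probe_set(1e-11, 1e-11), ctx, 0)
  expect_equal(z$reporter_concs, 0)
  expect_error(response_curve(a, probe_set(1e-11, 1e-11), ctx, c(2e-12, 1e-12)),
               "increasing")
})

test_that("hook point is detected only when the curve turns over", {
  a <- toy_analyte(range = c(1e-12, 1e-8))
  ctx_lin <- assay_context(mass_balance = FALSE)
  grid <- 10^seq(-12, -7, by = 0.25)
  flat <- response_curve(a, probe_set(1e-11, 1e-11), ctx_lin, grid)
  expect_null(hook_point(flat))
  expect_null(hook_point(response_curve(a, probe_set(1e-11, 1e-11), ctx_lin, 1e-10)))
  # saturating capture + self-consistent dAb depletion: interior maximum,
  # bead capacity at 1% of the grid maximum
  ctx_hook <- assay_context(mass_balance = TRUE, bead_capacity = 0.01 * max(grid),
                            sample_volume = 50e-6)
  hooked <- response_curve(a, probe_set(1e-12, 1e-12), ctx_hook, grid)
  hp <- hook_point(hooked)
  expect_false(is.null(hp))
  expect_true(hp > min(grid) && hp < max(grid))
  expect_lt(hooked$reporter_concs[length(grid)], max(hooked$reporter_concs))
})

test_that("concentration unit parsing and rendering round-trip", {
  expect_equal(parse_conc("10 pM"), 1e-11)
  expect_equal(parse_conc(c("100 aM", "1fM", "2.5 nM", "1 uM")),
               c(1e-16, 1e-15, 2.5e-9, 1e-6))
  expect_equal(parse_conc(3e-9), 3e-9)
  expect_error(parse_conc("10 pg/mL"), "cannot parse")
  expect_equal(format_conc(5e-11), "50 pM")
  expect_equal(parse_conc(format_conc(7.7e-14)), 7.7e-14, tolerance = 1e-6)
})
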