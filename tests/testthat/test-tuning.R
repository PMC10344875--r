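test_that("log-middle is the geometric mean of the testing range", {
  expect_equal(log_middle(c("5 pM", "500 pM")), 5e-11)
  expect_equal(log_middle(c(3e-12, 3e-12)), 3e-12)
  expect_equal(log_middle(c("1 nM", "70 nM")), sqrt(70) * 1e-9)
  expect_error(log_middle(c(0, 1e-9)), "positive")
})

test_that("probe-loading tuning reproduces the target through the forward model", {
  a <- toy_analyte(kd = 1e-9, n = 6, range = c(5e-12, 5e-10))
  ctx <- toy_ctx()
  goal <- tuning_goal(1e-15)
  r <- tune_probe_loading(a, ctx, goal)
  expect_true(r$converged)
  expect_equal(r$evaluation_point, 5e-11)
  expect_equal(r$achieved_output, 1e-15, tolerance = 1e-3)
  # round trip: re-evaluating the forward model at the tuned probes
  expect_equal(reporter_output(5e-11, a, r$probes, ctx), r$achieved_output)
  expect_equal(r$probes$c5, r$probes$c3)  # symmetric pools
})

test_that("tuned loading is monotone in the target output", {
  a <- toy_analyte()
  ctx <- toy_ctx()
  r1 <- tune_probe_loading(a, ctx, tuning_goal(1e-16))
  r2 <- tune_probe_loading(a, ctx, tuning_goal(1e-15))
  expect_true(r1$converged && r2$converged)
  expect_lt(r1$probes$c5, r2$probes$c5)
})

test_that("a target met at the bracket midpoint returns immediately", {
  a <- toy_analyte()
  ctx <- toy_ctx()
  bracket <- c(1e-17, 1e-6)
  mid <- sqrt(prod(bracket))  # first bisection point in log space
  out_mid <- reporter_output(5e-11, a, probe_set(mid, mid), ctx)
  r <- tune_probe_loading(a, ctx, tuning_goal(out_mid), bracket = bracket)
  expect_equal(r$probes$c5, mid, tolerance = 1e-12)
  expect_equal(r$iterations, 1L)
})

test_that("unattainable targets are diagnosed, never clamped", {
  a <- toy_analyte()
  ctx <- toy_ctx()
  r <- tune_probe_loading(a, ctx, tuning_goal(1e-6))  # far above any plateau
  expect_false(r$converged)
  expect_match(r$note, "unattainable")
  expect_lt(r$achieved_output, 1e-6)
})

test_that("depletion fold-drop follows the binomial attenuation", {
  # near-saturating occupancy, two epitopes: doubling the pool with
  # unlabelled antibody halves p5 and p3, quartering the pair probability
  a <- analyte("sat", 2, 1e-15, 1, c(1e-12, 1e-10))
  ctx <- assay_context(mass_balance = FALSE, ligation_efficiency = 1)
  pr <- probe_set(1e-9, 1e-9)
  expect_equal(depletion_fold_drop(a, pr, 0, ctx, at = 1e-11), 1)
  expect_equal(depletion_fold_drop(a, pr, 2e-9, ctx, at = 1e-11), 4, tolerance = 1e-4)
  # monotone nondecreasing in depletant
  folds <- vapply(c(0, 1e-9, 2e-9, 5e-9, 2e-8), function(cd)
    depletion_fold_drop(a, pr, cd, ctx, at = 1e-11), numeric(1))
  expect_true(all(diff(folds) >= 0))
  # zero baseline output is an explicit error
  expect_error(depletion_fold_drop(a, pr, 1e-9, ctx, at = 0), "baseline")
})

test_that("joint depletion tuning meets the target and records the compensation", {
  panel <- synthetic_panel()
  a <- panel$analytes$CRPlike
  ctx <- panel$context
  goal <- tuning_goal(1e-15)
  c_dep <- depletant_for_pool_buffering(a, ctx)
  r <- tune_with_depletion(a, ctx, goal, c_dep = c_dep)
  expect_true(r$converged)
  expect_equal(r$achieved_output, 1e-15, tolerance = 1e-3)
  expect_gt(r$pre_depletion_output, r$achieved_output)
  # compensation identity: depleted / undepleted output equals 1 / fold-drop
  fold <- depletion_fold_drop(a, probe_set(r$probes$c5, r$probes$c3), c_dep,
                              ctx, at = r$evaluation_point)
  expect_equal(r$achieved_output / r$pre_depletion_output, 1 / fold,
               tolerance = 0.01)
  expect_equal(r$fold_drop, fold, tolerance = 0.01)
})

test_that("vanishing depletant degenerates to plain probe-loading tuning", {
  a <- toy_analyte()
  ctx <- toy_ctx()
  r0 <- tune_probe_loading(a, ctx, tuning_goal(1e-15))
  rd <- tune_with_depletion(a, ctx, tuning_goal(1e-15), c_dep = 1e-30)
  expect_equal(rd$probes$c5, r0$probes$c5, tolerance = 1e-3)
  expect_error(tune_with_depletion(a, ctx, tuning_goal(1e-15), c_dep = 0), "c_dep")
})

test_that("panel tuning equalizes outputs at every log-middle", {
  panel <- synthetic_panel()
  tuned <- tune_panel(panel$analytes, panel$context)
  expect_true(all(vapply(tuned$results, `[[`, logical(1), "converged")))
  outs <- vapply(tuned$results, `[[`, numeric(1), "achieved_output")
  expect_true(all(abs(outs / 1e-15 - 1) <= 2e-3))
  # tuning must not touch the testing ranges
  for (nm in names(panel$analytes))
    expect_identical(panel$analytes[[nm]]$testing_range,
                     synthetic_panel()$analytes[[nm]]$testing_range)
  # single-analyte panel: spread equals that analyte's own output span
  single <- tune_panel(panel$analytes["GDF15like"], panel$context)
  s <- single$report$standards$output
  expect_equal(single$report$spread_log10, log10(max(s) / min(s)))
})

test_that("the depletion policy triggers only for flat high-abundance analytes", {
  panel <- synthetic_panel()
  tuned <- tune_panel(panel$analytes, panel$context)
  cdeps <- vapply(tuned$results, function(r) r$probes$c_dep, numeric(1))
  expect_true(cdeps[["CRPlike"]] > 0)
  expect_true(all(cdeps[c("IL6like", "IL1RAlike", "GDF15like")] == 0))
})
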