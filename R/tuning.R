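#' Log-middle (geometric mean) of a concentration range
#'
#' The tuning evaluation point: each analyte is tuned so that its reporter
#' output hits the common target at the geometric mean of its testing range.
#'
#' @param range Length-2 numeric or unit-string vector (low, high), both > 0.
#' @return Geometric mean, molar.
#' @examples
#' log_middle(c("5 pM", "500 pM"))  # 50 pM
#' @export
log_middle <- function(range) {
  range <- parse_conc(range)
  if (length(range) != 2L || any(range <= 0)) stop("range must be two positive concentrations")
  if (range[1] > range[2]) stop("range must be (low, high) with low <= high")
  sqrt(range[1] * range[2])
}

#' Pre-depletion tuning target that compensates a depletion fold-drop
#'
#' When epitope depletion will attenuate the output `fold`-fold, probe
#' loading is first tuned (without depletant) to `fold` times the final
#' target so that the depleted output lands on target.
#'
#' @param target Final reporter-output target (molar).
#' @param fold Expected depletion fold-drop, >= 1.
#' @return Pre-depletion output target (molar).
#' @examples
#' depletion_compensation_target(1e-15, 10)  # 10 fM
#' @export
depletion_compensation_target <- function(target, fold) {
  target <- parse_conc(target)
  if (target <= 0) stop("target must be > 0")
  if (fold < 1) stop("fold must be >= 1")
  fold * target
}

eval_point <- function(analyte, goal) {
  goal$evaluation_point %||% log_middle(analyte$testing_range)
}

new_tuning_result <- function(analyte, probes, achieved, target, eval_at,
                              converged, iterations, pre_depletion_output = NA_real_,
                              fold_drop = NA_real_, note = NULL) {
  structure(list(analyte_name = analyte$name, probes = probes,
                 achieved_output = achieved, target = target,
                 evaluation_point = eval_at,
                 pre_depletion_output = pre_depletion_output,
                 fold_drop = fold_drop,
                 converged = converged, iterations = iterations, note = note),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result>", x$analyte_name,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  dAb:", format_conc(x$probes$c5), "each, depletant:",
      format_conc(x$probes$c_dep), "\n")
  cat("  output at", format_conc(x$evaluation_point), ":",
      format_conc(x$achieved_output), "(target", format_conc(x$target), ")\n")
  if (is.finite(x$pre_depletion_output))
    cat("  pre-depletion output:", format_conc(x$pre_depletion_output),
        sprintf("(fold drop %.2f)", x$fold_drop), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# bisection in log10(dAb) for symmetric pools c5 = c3 = x, c_dep fixed.
# reporter output is monotone increasing in x, so plain bisection brackets.
bisect_dab <- function(analyte, ctx, target, at, c_dep = 0,
                       bracket = c(1e-17, 1e-6), rel_tol = 1e-3,
                       max_iter = 200L) {
  out_at <- function(x) reporter_output(at, analyte, probe_set(x, x, c_dep), ctx)
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  f_lo <- out_at(10^lo); f_hi <- out_at(10^hi)
  if (f_lo > target || f_hi < target) {
    side <- if (f_hi < target) "above bracket plateau" else "below bracket floor"
    best <- if (f_hi < target) 10^hi else 10^lo
    return(list(dab = best, achieved = if (f_hi < target) f_hi else f_lo,
                converged = FALSE, iterations = 0L,
                note = paste0("target ", format_conc(target), " unattainable (",
                              side, ") for dAb in [",
                              format_conc(bracket[1]), ", ",
                              format_conc(bracket[2]), "]")))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f_mid <- out_at(10^mid)
    if (abs(f_mid / target - 1) <= rel_tol || it >= max_iter)
      return(list(dab = 10^mid, achieved = f_mid,
                  converged = abs(f_mid / target - 1) <= rel_tol,
                  iterations = it, note = NULL))
    if (f_mid < target) lo <- mid else hi <- mid
  }
}

#' Tune probe loading so the output hits the goal at the evaluation point
#'
#' Solves the inverse problem for one analyte: find the symmetric dAb
#' concentration (`c5 = c3`, with `c_dep` held fixed) at which the forward
#' model's reporter output at the evaluation point equals the goal target.
#' Bisection in log10(dAb); unconditionally convergent because output is
#' monotone in loading.
#'
#' @param analyte An [analyte()].
#' @param ctx An [assay_context()].
#' @param goal A [tuning_goal()].
#' @param c_dep Depletant held fixed during the solve (default 0).
#' @param bracket Search bracket for the dAb concentration (molar), default
#'   10 aM to 1 uM.
#' @param rel_tol Relative tolerance on the achieved output (default 1e-3).
#' @return A `tuning_result`; `converged = FALSE` with a diagnostic note when
#'   the target is unattainable within the bracket (never a silent clamp).
#' @export
tune_probe_loading <- function(analyte, ctx = assay_context(), goal = tuning_goal(),
                               c_dep = 0, bracket = c(1e-17, 1e-6),
                               rel_tol = 1e-3) {
  at <- eval_point(analyte, goal)
  sol <- bisect_dab(analyte, ctx, goal$target_reporter_output, at,
                    c_dep = parse_conc(c_dep), bracket = parse_conc(bracket),
                    rel_tol = rel_tol)
  new_tuning_result(analyte, probe_set(sol$dab, sol$dab, c_dep), sol$achieved,
                    goal$target_reporter_output, at, sol$converged,
                    sol$iterations, note = sol$note)
}

#' Fold-drop in reporter output caused by a depletant concentration
#'
#' @param analyte An [analyte()].
#' @param probes_without_dep A [probe_set()] with `c_dep = 0` (any `c_dep`
#'   present is ignored for the baseline).
#' @param c_dep Depletant concentration to assess.
#' @param ctx An [assay_context()].
#' @param at Target concentration at which to evaluate (molar).
#' @return Ratio output(no depletant) / output(depletant), >= 1 in the
#'   depletion regime.
#' @export
depletion_fold_drop <- function(analyte, probes_without_dep, c_dep,
                                ctx = assay_context(), at) {
  at <- parse_conc(at); c_dep <- parse_conc(c_dep)
  base <- probe_set(probes_without_dep$c5, probes_without_dep$c3, 0)
  out0 <- reporter_output(at, analyte, base, ctx)
  if (out0 <= 0) stop("undefined fold-drop: baseline output is zero at ", format_conc(at))
  outd <- reporter_output(at, analyte,
                          probe_set(base$c5, base$c3, c_dep), ctx)
  out0 / outd
}

#' Tune probe loading and epitope depletion jointly
#'
#' Two-stage procedure for analytes whose probe-only response is too flat:
#' (1) from a provisional probe-only solution, estimate the fold-drop `F`
#' that the requested depletant causes at the evaluation point; (2) retune
#' the depletant-free output to `F` times the target (the compensation
#' step), then re-solve the loading jointly with the depletant included
#' until the depleted output matches the target.
#'
#' @inheritParams tune_probe_loading
#' @param c_dep Depletant concentration, > 0.
#' @return A `tuning_result` with `pre_depletion_output` and `fold_drop`
#'   recorded.
#' @export
tune_with_depletion <- function(analyte, ctx = assay_context(), goal = tuning_goal(),
                                c_dep, bracket = c(1e-17, 1e-6), rel_tol = 1e-3) {
  c_dep <- parse_conc(c_dep)
  if (c_dep <= 0) stop("c_dep must be > 0 (use tune_probe_loading otherwise)")
  at <- eval_point(analyte, goal)
  target <- goal$target_reporter_output

  # stage 1: provisional loading and fold-drop estimate
  prov <- tune_probe_loading(analyte, ctx, goal, c_dep = 0,
                             bracket = bracket, rel_tol = rel_tol)
  if (!prov$converged) return(prov)
  fold <- depletion_fold_drop(analyte, prov$probes, c_dep, ctx, at)
  pre_target <- depletion_compensation_target(target, max(fold, 1))

  # stage 2: compensate, then joint re-solve with the depletant in place
  comp <- bisect_dab(analyte, ctx, pre_target, at, c_dep = 0,
                     bracket = parse_conc(bracket), rel_tol = rel_tol)
  joint <- bisect_dab(analyte, ctx, target, at, c_dep = c_dep,
                      bracket = parse_conc(bracket), rel_tol = rel_tol)
  probes <- probe_set(joint$dab, joint$dab, c_dep)
  pre_out <- reporter_output(at, analyte, probe_set(joint$dab, joint$dab, 0), ctx)
  new_tuning_result(analyte, probes, joint$achieved, target, at,
                    joint$converged,
                    prov$iterations + comp$iterations + joint$iterations,
                    pre_depletion_output = pre_out,
                    fold_drop = pre_out / joint$achieved,
                    note = joint$note)
}

# decadic slope d log10(output) / d log10(conc) by central difference;
# -Inf when output vanishes on either side.
decadic_slope <- function(analyte, probes, ctx, at, eps = 0.05) {
  y <- reporter_output(at * 10^c(-eps, eps), analyte, probes, ctx)
  if (any(y <= 0)) return(-Inf)
  (log10(y[2]) - log10(y[1])) / (2 * eps)
}

#' Default depletion policy: buffer the antibody pool against target binding
#'
#' Assigns a depletant concentration equal to the maximum bound-epitope
#' concentration over the testing range (`epitope_count` times the captured
#' target at the range high end). At that scale the shared antibody pool is
#' no longer depleted appreciably by target binding, which restores a
#' log-linear response across the range.
#'
#' @param analyte An [analyte()].
#' @param ctx An [assay_context()].
#' @return Depletant concentration (molar).
#' @export
depletant_for_pool_buffering <- function(analyte, ctx = assay_context()) {
  captured_high <- min(analyte$testing_range[2] * sample_dilution(ctx) *
                         analyte$capture_efficiency, ctx$bead_capacity)
  analyte$epitope_count * captured_high
}

#' Six-point serial-dilution standards spanning a testing range
#'
#' @param analyte An [analyte()].
#' @param n_points Number of standards (default 6).
#' @param dilution_factor Serial dilution factor (default 3).
#' @return Decreasing molar concentrations starting at the range high.
#' @export
panel_standards <- function(analyte, n_points = 6, dilution_factor = 3) {
  analyte$testing_range[2] / dilution_factor^(seq_len(n_points) - 1)
}

#' Tune a multiplexed panel to a common reporter output
#'
#' Tunes every analyte to the goal target at its own log-middle. Analytes
#' whose probe-only tuned response is flat or hooked at a testing-range
#' endpoint (decadic slope below `slope_threshold`) are retuned with
#' epitope depletion, using `depletion_policy` to size the depletant.
#'
#' @param panel List of [analyte()] objects.
#' @param ctx An [assay_context()].
#' @param goal A [tuning_goal()].
#' @param depletion_policy Function `(analyte, ctx) -> c_dep` (molar);
#'   default [depletant_for_pool_buffering()].
#' @param slope_threshold Minimum acceptable decadic slope at the range
#'   endpoints (default 0.2).
#' @return An object of class `panel_tuning`: per-analyte `results` plus an
#'   equalization `report` with the simulated outputs over each analyte's
#'   six-point 3x standards, the panel-wide log10 output spread and
#'   per-analyte endpoint slopes.
#' @export
tune_panel <- function(panel, ctx = assay_context(), goal = tuning_goal(),
                       depletion_policy = depletant_for_pool_buffering,
                       slope_threshold = 0.2) {
  if (length(panel) < 1L) stop("panel must contain at least one analyte")
  results <- lapply(panel, function(a) {
    r <- tune_probe_loading(a, ctx, goal)
    if (!r$converged) return(r)
    slopes <- vapply(a$testing_range, function(at)
      decadic_slope(a, r$probes, ctx, at), numeric(1))
    if (any(slopes < slope_threshold)) {
      rd <- tune_with_depletion(a, ctx, goal, c_dep = depletion_policy(a, ctx))
      if (rd$converged) r <- rd
    }
    r
  })
  names(results) <- vapply(panel, `[[`, character(1), "name")
  probes <- lapply(results, `[[`, "probes")
  report <- panel_output_report(panel, probes, ctx, goal,
                                slope_threshold = slope_threshold)
  report$unattainable <- names(results)[!vapply(results, `[[`, logical(1), "converged")]
  structure(list(results = results, report = report, goal = goal),
            class = "panel_tuning")
}

#' Simulated-output report for a panel at given probe loadings
#'
#' Evaluates the forward model over each analyte's six-point 3x standards
#' and summarizes the panel-wide output spread and endpoint resolvability.
#' Useful both for tuned panels and for untuned baselines.
#'
#' @param panel List of [analyte()] objects.
#' @param probes_list Named list of [probe_set()], one per analyte.
#' @param ctx An [assay_context()].
#' @param goal Optional [tuning_goal()] used only for the output window.
#' @param slope_threshold Decadic slope threshold for resolvability.
#' @return List with `standards` (data frame analyte/conc/output),
#'   `spread_log10` (log10 max/min over all positive outputs),
#'   `resolvability` (per-analyte endpoint slopes) and `output_window`.
#' @export
panel_output_report <- function(panel, probes_list, ctx = assay_context(),
                                goal = tuning_goal(), slope_threshold = 0.2) {
  stds <- do.call(rbind, lapply(panel, function(a) {
    concs <- panel_standards(a)
    data.frame(analyte = a$name, conc = concs,
               output = reporter_output(concs, a, probes_list[[a$name]], ctx))
  }))
  rownames(stds) <- NULL
  pos <- stds$output[stds$output > 0]
  spread <- if (length(pos)) log10(max(pos) / min(pos)) else NA_real_
  resolv <- do.call(rbind, lapply(panel, function(a) {
    sl <- vapply(a$testing_range, function(at)
      decadic_slope(a, probes_list[[a$name]], ctx, at), numeric(1))
    data.frame(analyte = a$name, slope_low = sl[1], slope_high = sl[2],
               resolvable = all(sl >= slope_threshold))
  }))
  rownames(resolv) <- NULL
  list(standards = stds, spread_log10 = spread, resolvability = resolv,
       output_window = goal$output_window)
}

#' @export
print.panel_tuning <- function(x, ...) {
  cat("<panel_tuning>", length(x$results), "analytes, target",
      format_conc(x$goal$target_reporter_output), "at each log-middle\n")
  for (r in x$results) {
    cat(sprintf("  %-10s dAb %-10s dep %-8s -> %s %s\n", r$analyte_name,
                format_conc(r$probes$c5), format_conc(r$probes$c_dep),
                format_conc(r$achieved_output),
                if (r$converged) "" else "[unattainable]"))
  }
  cat(sprintf("  standards output spread: %.2f orders of magnitude\n",
              x$report$spread_log10))
  if (length(x$report$unattainable))
    cat("  unattainable:", paste(x$report$unattainable, collapse = ", "), "\n")
  invisible(x)
}
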