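#' Evaluate the four-parameter logistic calibration curve
#'
#' `numi(x) = (A - D) / (1 + (x / C)^B) + D`, where `A` is the response with
#' no analyte, `B` the Hill coefficient, `C` the inflection point (the
#' apparent Kd) and `D` the response at infinite analyte.
#'
#' @param x Analyte concentration(s), >= 0.
#' @param A,B,C,D Curve parameters; alternatively pass a fitted [fit_4pl()]
#'   object (or named vector) as `params`.
#' @param params Optional `fourpl` object or named vector `c(A, B, C, D)`.
#' @return Predicted response values.
#' @examples
#' four_pl(3e-12, A = 0.1, B = 1, C = 1e-12, D = 10)  # 7.525
#' @export
four_pl <- function(x, A, B, C, D, params = NULL) {
  if (!is.null(params)) {
    p <- if (inherits(params, "fourpl")) stats::coef(params) else params
    A <- p[["A"]]; B <- p[["B"]]; C <- p[["C"]]; D <- p[["D"]]
  }
  if (any(x < 0)) stop("x must be >= 0")
  (A - D) / (1 + (x / C)^B) + D
}

#' Fit a four-parameter logistic calibration curve to standards
#'
#' Nonlinear least squares on the log residuals,
#' `sum (log(numi) - log(numi_hat))^2`, so that standards spanning several
#' orders of magnitude contribute comparably. Fitting is done in a bounded
#' parametrization (`A`, `C`, `D` on a log10 scale; `B` in \[0.1, 10\]; `C`
#' within 1000x of the standards' concentration range) with
#' Levenberg-Marquardt (\pkg{minpack.lm}). The starting point is taken from
#' the data: `A` and `D` from the observed extremes (oriented by the data's
#' monotone direction), `C` at the geometric mean of the concentration
#' range, `B = 1`. Replicates enter the loss individually.
#'
#' @param x Model formula `numi ~ conc` (with `data`), or a numeric vector
#'   of concentrations.
#' @param numi Observed normalized UMI counts (when `x` is numeric); all
#'   must be > 0 for the log loss.
#' @param data Data frame for the formula interface.
#' @return An object of class `fourpl` with `coefficients` (A, B, C, D),
#'   log-scale `residuals`, `fitted` values, the data, the residual norm and
#'   a convergence flag. Standard methods: `print`, `summary`, `coef`,
#'   `predict` (forward or inverse), `fitted`, `residuals`, `plot`.
#' @examples
#' conc <- 5e-10 / 3^(0:5)
#' df <- data.frame(conc = conc, numi = four_pl(conc, 0.05, 1.2, 5e-11, 8))
#' fit <- fit_4pl(numi ~ conc, data = df)
#' coef(fit)
#' @export
fit_4pl <- function(x, numi = NULL, data = NULL) {
  cl <- match.call()
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    y <- mf[[1]]; xc <- mf[[2]]
  } else {
    xc <- x; y <- numi
  }
  keep <- is.finite(xc) & is.finite(y)
  xc <- xc[keep]; y <- y[keep]
  if (length(unique(xc[xc > 0])) < 4L)
    stop("need at least 4 distinct positive concentrations for a 4-parameter fit")
  if (any(xc <= 0)) stop("concentrations must be > 0 (log-scale standards)")
  if (any(y <= 0)) stop("all nUMI values must be > 0 for the log-residual loss")

  increasing <- stats::cor(log(xc), log(y), method = "spearman") >= 0
  A0 <- if (increasing) min(y) else max(y)
  D0 <- if (increasing) max(y) else min(y)
  C0 <- sqrt(min(xc) * max(xc))
  start <- list(la = log10(A0), b = 1, lc = log10(C0), ld = log10(D0))
  lower <- c(la = log10(A0) - 6, b = 0.1, lc = log10(min(xc)) - 3, ld = log10(D0) - 6)
  upper <- c(la = log10(A0) + 6, b = 10, lc = log10(max(xc)) + 3, ld = log10(D0) + 6)

  ly <- log(y)
  resid_fn <- function(p) {
    pred <- (10^p[1] - 10^p[4]) / (1 + (xc / 10^p[3])^p[2]) + 10^p[4]
    ly - log(pred)
  }
  # deterministic multi-start ladder (the declared start first, then small
  # nudges); the lowest-residual converged solution wins
  s0 <- unlist(start)
  starts <- list(s0,
                 s0 + c(0, 0.2, 0.5, 0),
                 s0 + c(-0.5, -0.2, -0.5, 0.5))
  best <- NULL; last_msg <- NULL
  for (st in starts) {
    sol <- tryCatch(
      minpack.lm::nls.lm(pmin(pmax(st, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) { last_msg <<- conditionMessage(e); NULL })
    if (is.null(sol)) next
    if (!(sol$info %in% 1:4)) { last_msg <- sol$message; next }
    if (is.null(best) || sum(sol$fvec^2) < sum(best$fvec^2)) best <- sol
  }
  if (is.null(best))
    stop("4PL fit did not converge (start A=", signif(A0, 3), " B=1 C=",
         signif(C0, 3), " D=", signif(D0, 3), "; n=", length(y), "): ", last_msg)
  p <- unname(best$par)
  coefs <- c(A = 10^p[1], B = p[2], C = 10^p[3], D = 10^p[4])
  fitted_numi <- four_pl(xc, params = coefs)
  res <- ly - log(fitted_numi)
  structure(list(coefficients = coefs, data = data.frame(conc = xc, numi = y),
                 fitted = fitted_numi, residuals = res,
                 resid_norm = sqrt(sum(res^2)), increasing = increasing,
                 converged = best$info %in% 1:4, call = cl),
            class = "fourpl")
}

#' @export
print.fourpl <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic calibration\n")
  cat("  A =", signif(x$coefficients[["A"]], digits),
      " B =", signif(x$coefficients[["B"]], digits),
      " C =", format_conc(x$coefficients[["C"]], digits),
      " D =", signif(x$coefficients[["D"]], digits), "\n")
  cat(sprintf("  n = %d, log-residual norm = %.4g\n",
              nrow(x$data), x$resid_norm))
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
fitted.fourpl <- function(object, ...) object$fitted

#' @export
residuals.fourpl <- function(object, ...) object$residuals

#' @export
summary.fourpl <- function(object, ...) {
  print(object)
  cat("  direction:", if (object$increasing) "increasing" else "decreasing",
      " quantifiable nUMI window: (",
      signif(min(object$coefficients[c("A", "D")]), 4), ",",
      signif(max(object$coefficients[c("A", "D")]), 4), ")\n")
  cat("  concentration range of standards:",
      format_conc(min(object$data$conc)), "-", format_conc(max(object$data$conc)), "\n")
  invisible(object)
}

#' @param object A `fourpl` fit.
#' @param newdata Optional data frame with a `conc` column (forward) or
#'   `numi` column (inverse); defaults to the training data.
#' @param type `"response"` predicts nUMI from concentration; `"inverse"`
#'   inverts nUMI to concentration via [invert_4pl()].
#' @rdname fit_4pl
#' @export
predict.fourpl <- function(object, newdata = NULL, type = c("response", "inverse"), ...) {
  type <- match.arg(type)
  if (type == "response") {
    xc <- if (is.null(newdata)) object$data$conc else
      (if (is.data.frame(newdata)) newdata$conc else newdata)
    four_pl(xc, params = object)
  } else {
    y <- if (is.data.frame(newdata)) newdata$numi else newdata
    invert_4pl(y, object)
  }
}

#' @export
plot.fourpl <- function(x, ...) {
  d <- x$data
  plot(d$conc, d$numi, log = "xy", pch = 19,
       xlab = "analyte concentration (M)", ylab = "nUMI", ...)
  grid_x <- 10^seq(log10(min(d$conc)) - 0.5, log10(max(d$conc)) + 0.5, length.out = 200)
  graphics::lines(grid_x, four_pl(grid_x, params = x), col = 2)
  graphics::abline(h = x$coefficients[c("A", "D")], lty = 3, col = "grey")
  invisible(x)
}

#' Invert a four-parameter logistic curve
#'
#' Exact algebraic inverse `x = C * ((A - D) / (numi - D) - 1)^(1/B)` for
#' responses strictly inside the curve's open window. Responses at or
#' beyond the zero-analyte asymptote `A` are flagged `below_lloq`; at or
#' beyond the saturation asymptote `D`, `above_uloq`. Flagged values are
#' never extrapolated to a number.
#'
#' @param numi Observed response value(s).
#' @param params A `fourpl` fit or named vector `c(A, B, C, D)`.
#' @return Data frame with columns `numi`, `conc` (NA when flagged) and
#'   `flag` (`ok`, `below_lloq`, `above_uloq`).
#' @export
invert_4pl <- function(numi, params) {
  p <- if (inherits(params, "fourpl")) stats::coef(params) else params
  A <- p[["A"]]; B <- p[["B"]]; C <- p[["C"]]; D <- p[["D"]]
  if (C <= 0 || A == D || B == 0) stop("invalid 4PL parameters")
  below <- if (A < D) numi <= A else numi >= A
  above <- if (A < D) numi >= D else numi <= D
  ok <- !below & !above
  conc <- rep(NA_real_, length(numi))
  conc[ok] <- C * ((A - D) / (numi[ok] - D) - 1)^(1 / B)
  data.frame(numi = numi, conc = conc,
             flag = ifelse(ok, "ok", ifelse(below, "below_lloq", "above_uloq")))
}

#' Quantify samples against per-analyte calibration curves
#'
#' Inverts each replicate's nUMI through its analyte's fitted 4PL curve and
#' summarizes per analyte: mean and standard deviation over in-range
#' replicates (SD 0 for a single replicate, by convention) plus the
#' replicate flags. Analytes whose replicates are all out of range are
#' reported with the range flag and no numeric mean.
#'
#' @param samples Data frame with columns `analyte`, `numi` and optionally
#'   `replicate`.
#' @param curves Named list of `fourpl` fits, one per analyte in `samples`.
#' @return An object of class `quantification`: `replicates` (per-replicate
#'   concentrations and flags) and `summary` (per-analyte mean_conc,
#'   sd_conc, n_ok, flag).
#' @export
quantify <- function(samples, curves) {
  stopifnot(is.data.frame(samples), all(c("analyte", "numi") %in% names(samples)))
  missing_curves <- setdiff(unique(samples$analyte), names(curves))
  if (length(missing_curves))
    stop("no calibration curve for analyte(s): ", paste(missing_curves, collapse = ", "))
  reps <- do.call(rbind, lapply(split(samples, samples$analyte), function(s) {
    inv <- invert_4pl(s$numi, curves[[s$analyte[1]]])
    data.frame(analyte = s$analyte, numi = s$numi,
               conc = inv$conc, flag = inv$flag)
  }))
  rownames(reps) <- NULL
  summ <- do.call(rbind, lapply(split(reps, reps$analyte), function(r) {
    ok <- r$flag == "ok"
    data.frame(analyte = r$analyte[1],
               n = nrow(r), n_ok = sum(ok),
               mean_conc = if (any(ok)) mean(r$conc[ok]) else NA_real_,
               sd_conc = if (sum(ok) > 1) stats::sd(r$conc[ok])
                         else if (sum(ok) == 1) 0 else NA_real_,
               flag = if (any(ok)) "ok"
                      else names(sort(table(r$flag), decreasing = TRUE))[1])
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ), class = "quantification")
}

#' @export
print.quantification <- function(x, ...) {
  cat("<quantification>\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %s", s$analyte[i],
                if (is.na(s$mean_conc[i])) paste0("[", s$flag[i], "]")
                else paste0(format_conc(s$mean_conc[i]), " +/- ",
                            format_conc(s$sd_conc[i]))))
    cat(sprintf("  (%d/%d replicates in range)\n", s$n_ok[i], s$n[i]))
  }
  invisible(x)
}
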