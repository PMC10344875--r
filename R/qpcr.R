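#' Min-max normalize a qPCR amplification trace
#'
#' Rescales the per-cycle intensities to \[0, 1\]:
#' `(I - min(I)) / (max(I) - min(I))`. Affine-invariant by construction.
#'
#' @param trace Numeric vector of per-cycle intensities (>= 2 cycles).
#' @return Normalized intensities in \[0, 1\].
#' @export
normalize_trace <- function(trace) {
  if (length(trace) < 2L) stop("trace needs at least 2 cycles")
  lo <- min(trace); hi <- max(trace)
  if (hi <= lo) stop("cannot normalize a constant trace")
  (trace - lo) / (hi - lo)
}

#' Extract the quantification cycle (Ct) from a trace
#'
#' The Ct is the first cycle whose normalized intensity reaches the
#' threshold (default 0.25 of maximum). The default integer mode returns
#' that cycle index; the interpolated mode returns the linear crossing
#' between the previous cycle and it, which gives smoother calibration fits.
#'
#' @param trace Numeric per-cycle intensities.
#' @param threshold Normalized threshold (default 0.25).
#' @param interpolate If `TRUE`, return the fractional crossing cycle.
#' @return Ct value (cycle, 1-based), or `NA` when the threshold is never
#'   reached (no amplification — a result, not an error).
#' @export
extract_ct <- function(trace, threshold = 0.25, interpolate = FALSE) {
  norm <- normalize_trace(trace)
  i <- which(norm >= threshold)[1]
  if (is.na(i)) return(NA_real_)
  if (!interpolate || i == 1L) return(as.numeric(i))
  # linear crossing between cycles i-1 and i
  (i - 1) + (threshold - norm[i - 1]) / (norm[i] - norm[i - 1])
}

#' Fit a DNA calibration line to a qPCR dilution series
#'
#' Ordinary least squares of Ct on log10 template concentration:
#' `Ct = m * log10([DNA]) + b`. Zero-concentration blanks cannot enter a log
#' fit and are excluded (they serve as no-amplification checks only), as
#' are samples without a Ct.
#'
#' @param dna_concs Template concentrations (molar or unit strings).
#' @param cts Ct values (NA = no amplification).
#' @return An object of class `qpcr_calibration` with slope `m` (cycles per
#'   decade, negative), intercept `b` (cycles) and `r_squared`.
#' @export
fit_calibration <- function(dna_concs, cts) {
  dna_concs <- parse_conc(dna_concs)
  keep <- dna_concs > 0 & !is.na(cts)
  if (sum(keep) < 2L) stop("need at least 2 positive-concentration points with Ct values")
  fit <- stats::lm(cts[keep] ~ log10(dna_concs[keep]))
  m <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || !is.finite(b)) stop("calibration fit failed (degenerate data)")
  # R^2 computed directly (summary.lm warns on noiseless synthetic fits)
  y <- cts[keep]
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(m = m, b = b, r_squared = r2, n = sum(keep), fit = fit),
            class = "qpcr_calibration")
}

#' @export
print.qpcr_calibration <- function(x, ...) {
  cat(sprintf("<qpcr_calibration> Ct = %.4f * log10([DNA]) + %.4f  (R^2 = %.4f, n = %d)\n",
              x$m, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.qpcr_calibration <- function(object, ...) c(m = object$m, b = object$b)

#' Convert a Ct value back to a template concentration
#'
#' Exact algebraic inverse of the calibration line:
#' `[DNA] = 10^((Ct - b) / m)`.
#'
#' @param ct Ct value(s).
#' @param line A `qpcr_calibration`.
#' @return Template concentration(s), in the units of the fitted series.
#' @export
ct_to_concentration <- function(ct, line) {
  if (!is.finite(line$m) || line$m == 0) stop("invalid calibration line (m must be nonzero)")
  10^((ct - line$b) / line$m)
}

#' Choose per-sample amplification cycle numbers from qPCR Cts
#'
#' Library-preparation rule: if the samples' Cts lie within a 3-cycle band,
#' every sample is amplified to `1 + average Ct`; otherwise each sample gets
#' `1 + its own Ct`. Cycles are rounded half away from zero to integers.
#'
#' @param cts Named or unnamed numeric Ct values; `NA` entries (no
#'   amplification) are excluded with a warning.
#' @return Integer cycle counts, same order/names as the usable inputs.
#' @export
choose_amplification_cycles <- function(cts) {
  usable <- !is.na(cts)
  if (!any(usable)) stop("no samples with a Ct value")
  if (any(!usable))
    warning(sum(!usable), " no-amplification sample(s) excluded from cycle selection")
  ct <- cts[usable]
  cycles <- if (max(ct) - min(ct) < 3) {
    rep(round_half_up(1 + mean(ct)), length(ct))
  } else {
    round_half_up(1 + ct)
  }
  cycles <- as.integer(cycles)
  names(cycles) <- names(ct)
  cycles
}
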