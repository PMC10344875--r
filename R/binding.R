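#' Langmuir epitope occupancy
#'
#' Fraction of epitopes occupied by detection antibody at equilibrium, under
#' the independent-site Langmuir isotherm with one effective dissociation
#' constant for the polyclonal pool.
#'
#' @param ab_free_total Total free antibody concentration (molar), all pools
#'   combined (5', 3' and depletant compete identically for epitopes).
#' @param kd Effective dissociation constant (molar), > 0.
#' @return Occupancy theta = ab / (ab + kd) in \[0, 1).
#' @examples
#' epitope_occupancy(1e-9, 1e-9)   # 0.5 at Kd
#' epitope_occupancy(9e-9, 1e-9)   # 0.9
#' @export
epitope_occupancy <- function(ab_free_total, kd) {
  if (any(ab_free_total < 0)) stop("ab_free_total must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  ab_free_total / (ab_free_total + kd)
}

#' Probability that a bound target yields a ligatable 5'/3' pair
#'
#' Each of the `epitope_count` epitopes is independently occupied with
#' probability `theta`; a bound antibody is a 5'-dAb, 3'-dAb or unlabelled
#' depletant with probabilities proportional to the pool concentrations.
#' A reporter can form only when at least one 5'- and at least one 3'-dAb
#' are bound to the same molecule, which by inclusion-exclusion over the
#' binomial occupancy gives
#' `1 - (1 - theta*p5)^n - (1 - theta*p3)^n + (1 - theta*(p5+p3))^n`.
#'
#' Adding depletant lowers `p5` and `p3`, attenuating the pairing
#' probability (epitope depletion).
#'
#' @param theta Occupancy fraction(s) in \[0, 1\].
#' @param epitope_count Integer >= 2.
#' @param probes A [probe_set()].
#' @return Pairing probability in \[0, 1\], same length as `theta`.
#' @examples
#' pair_probability(1, 2, probe_set(1e-12, 1e-12))  # 0.5
#' @export
pair_probability <- function(theta, epitope_count, probes) {
  if (any(theta < 0 | theta > 1)) stop("theta must be in [0, 1]")
  n <- as.integer(epitope_count)
  if (n < 2L) stop("epitope_count must be >= 2")
  s <- probes$c5 + probes$c3 + probes$c_dep
  p5 <- probes$c5 / s
  p3 <- probes$c3 / s
  p <- 1 - (1 - theta * p5)^n - (1 - theta * p3)^n + (1 - theta * (p5 + p3))^n
  # clip floating dust; anything beyond dust is a real inconsistency
  if (any(p < -1e-12 | p > 1 + 1e-12))
    stop("internal inconsistency: pairing probability outside [0, 1]")
  pmin(pmax(p, 0), 1)
}

# fixed-point solve for total free dAb under mass balance:
#   free = max(total - epitope_count * theta(free) * captured, 0)
# Damped iteration, vectorized over `captured`. The update map's slope is
# bounded by L = epitope_count * captured / kd, so the per-element damping
# min(0.5, 1 / (1 + L)) keeps the damped map a contraction for any load.
solve_free_dab <- function(total, kd, epitope_count, captured,
                           tol = 1e-10, max_iter = 10000L) {
  damping <- pmin(0.5, 1 / (1 + epitope_count * captured / kd))
  free <- rep(total, length.out = length(captured))
  for (i in seq_len(max_iter)) {
    g <- pmax(total - epitope_count * epitope_occupancy(free, kd) * captured, 0)
    new <- (1 - damping) * free + damping * g
    if (max(abs(new - free) / pmax(new, .Machine$double.xmin)) < tol) {
      return(new)
    }
    free <- new
  }
  stop(sprintf(paste0("free-dAb fixed point did not converge in %d iterations ",
                      "(total = %s, kd = %s, max captured = %s)"),
               max_iter, format_conc(total), format_conc(kd),
               format_conc(max(captured))))
}

#' Reporter-DNA output for a target concentration (forward model)
#'
#' The sample is diluted into the reaction, a fraction is captured on beads
#' (capped at the bead capacity), free dAb is (optionally) solved
#' self-consistently against depletion by bound target, and the captured
#' target converts to ligated reporter with the binomial pairing probability
#' times the ligation efficiency.
#'
#' @param target_conc Target concentration(s) in the sample (molar), >= 0.
#' @param analyte An [analyte()].
#' @param probes A [probe_set()].
#' @param ctx An [assay_context()].
#' @return Reporter-DNA concentration(s) in the reaction (molar).
#' @examples
#' a <- analyte("X", 2, 1e-9, 1, c(1e-12, 1e-10))
#' ctx <- assay_context(ligation_efficiency = 1, mass_balance = FALSE,
#'                      sample_volume = 50e-6)  # no dilution
#' reporter_output(9e-13, a, probe_set(1e-9, 1e-9), ctx)  # 2/9 of input
#' @export
reporter_output <- function(target_conc, analyte, probes, ctx = assay_context()) {
  if (any(target_conc < 0)) stop("target_conc must be >= 0")
  captured <- pmin(target_conc * sample_dilution(ctx) * analyte$capture_efficiency,
                   ctx$bead_capacity)
  total_ab <- probes$c5 + probes$c3 + probes$c_dep
  free_ab <- if (ctx$mass_balance) {
    solve_free_dab(total_ab, analyte$kd_dab, analyte$epitope_count, captured)
  } else {
    rep(total_ab, length(captured))
  }
  theta <- epitope_occupancy(free_ab, analyte$kd_dab)
  captured * pair_probability(theta, analyte$epitope_count, probes) *
    ctx$ligation_efficiency
}

#' Simulate a response curve over a concentration grid
#'
#' @inheritParams reporter_output
#' @param grid Strictly increasing non-negative target concentrations.
#' @return An object of class `response_curve` with `target_concs`,
#'   `reporter_concs`, `analyte_name` and `probes`.
#' @export
response_curve <- function(analyte, probes, ctx = assay_context(), grid) {
  grid <- parse_conc(grid)
  if (any(grid < 0)) stop("grid must be non-negative")
  if (length(grid) > 1 && any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  out <- reporter_output(grid, analyte, probes, ctx)
  structure(list(target_concs = grid, reporter_concs = out,
                 analyte_name = analyte$name, probes = probes),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("<response_curve>", x$analyte_name, "over",
      format_conc(min(x$target_concs)), "-", format_conc(max(x$target_concs)),
      sprintf("(%d points)\n", length(x$target_concs)))
  nz <- x$reporter_concs[x$reporter_concs > 0]
  if (length(nz))
    cat("  reporter output:", format_conc(min(nz)), "-", format_conc(max(nz)), "\n")
  hp <- hook_point(x)
  if (!is.null(hp)) cat("  hook at", format_conc(hp), "\n")
  invisible(x)
}

#' @export
plot.response_curve <- function(x, ..., add = FALSE, col = 1) {
  keep <- x$target_concs > 0 & x$reporter_concs > 0
  if (add) {
    graphics::lines(x$target_concs[keep], x$reporter_concs[keep], col = col, ...)
  } else {
    plot(x$target_concs[keep], x$reporter_concs[keep], log = "xy", type = "l",
         col = col, xlab = "target concentration (M)",
         ylab = "reporter DNA (M)", main = x$analyte_name, ...)
  }
  invisible(x)
}

#' Locate the hook point of a response curve, if any
#'
#' The hook effect is the signal decrease at very high target loads caused
#' by reagent saturation. Returns the grid concentration of maximum reporter
#' output if the curve decreases after its maximum, else `NULL`.
#'
#' @param curve A [response_curve()].
#' @return Molar concentration of the output maximum, or `NULL` when the
#'   curve never decreases after its maximum within the grid.
#' @export
hook_point <- function(curve) {
  y <- curve$reporter_concs
  if (length(y) < 2L) return(NULL)
  i <- which.max(y)
  if (i < length(y) && any(y[(i + 1):length(y)] < y[i])) curve$target_concs[i]
  else NULL
}
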