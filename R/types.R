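#' Describe an analyte and its assay-relevant parameters
#'
#' An analyte is a protein target measured by solid-phase proximity ligation:
#' it is captured on antibody-coated beads and detected by a polyclonal pool
#' of DNA-labelled detection antibodies (dAbs) that can address several
#' distinct epitopes per molecule.
#'
#' @param name Identifier.
#' @param epitope_count Integer >= 2; distinct dAb-addressable epitopes per
#'   target molecule.
#' @param kd_dab Dissociation constant (molar) of the polyclonal dAb pool,
#'   one effective value. Accepts unit strings (see [parse_conc()]).
#' @param capture_efficiency Fraction in (0, 1]; fraction of the in-reaction
#'   target captured on beads.
#' @param testing_range Length-2 concentration range (low, high) over which
#'   the assay is tuned and standards are laid out.
#' @param physiological_range Optional annotation range; not used by any
#'   computation.
#' @return An object of class `analyte`.
#' @examples
#' analyte("GDF15", 6, "1 nM", 0.9, c("5 pM", "500 pM"))
#' @export
analyte <- function(name, epitope_count, kd_dab, capture_efficiency,
                    testing_range, physiological_range = NULL) {
  epitope_count <- as.integer(epitope_count)
  kd_dab <- parse_conc(kd_dab)
  testing_range <- parse_conc(testing_range)
  if (!is.null(physiological_range)) physiological_range <- parse_conc(physiological_range)
  stopifnot(is.character(name), length(name) == 1L)
  if (epitope_count < 2L) stop("epitope_count must be >= 2 (two dAbs must be able to bind)")
  if (!is.finite(kd_dab) || kd_dab <= 0) stop("kd_dab must be > 0")
  if (capture_efficiency <= 0 || capture_efficiency > 1)
    stop("capture_efficiency must be in (0, 1]")
  if (length(testing_range) != 2L || testing_range[1] >= testing_range[2])
    stop("testing_range must be (low, high) with low < high")
  if (!is.null(physiological_range) &&
      (length(physiological_range) != 2L || physiological_range[1] >= physiological_range[2]))
    stop("physiological_range must be (low, high) with low < high")
  structure(list(name = name, epitope_count = epitope_count, kd_dab = kd_dab,
                 capture_efficiency = capture_efficiency,
                 testing_range = testing_range,
                 physiological_range = physiological_range),
            class = "analyte")
}

#' @export
print.analyte <- function(x, ...) {
  cat("<analyte>", x$name, "\n")
  cat("  epitopes:", x$epitope_count,
      " Kd(dAb):", format_conc(x$kd_dab),
      " capture eff:", x$capture_efficiency, "\n")
  cat("  testing range:", format_conc(x$testing_range[1]), "-",
      format_conc(x$testing_range[2]), "\n")
  invisible(x)
}

#' Detection-antibody probe loading for one analyte
#'
#' The tunable knobs of the assay: concentrations of the 5'-labelled and
#' 3'-labelled dAb pools and of the unlabelled depletant antibody drawn from
#' the same polyclonal pool.
#'
#' @param c5,c3 5'- and 3'-dAb concentrations (molar or unit strings), > 0.
#' @param c_dep Depletant concentration, >= 0 (default 0).
#' @return An object of class `probe_set`.
#' @examples
#' probe_set("10 pM", "10 pM")
#' probe_set("3.93 pM", "3.93 pM", c_dep = "5 nM")
#' @export
probe_set <- function(c5, c3, c_dep = 0) {
  c5 <- parse_conc(c5); c3 <- parse_conc(c3); c_dep <- parse_conc(c_dep)
  if (c5 <= 0 || c3 <= 0) stop("c5 and c3 must be > 0")
  if (c_dep < 0) stop("c_dep must be >= 0")
  structure(list(c5 = c5, c3 = c3, c_dep = c_dep), class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("<probe_set> c5:", format_conc(x$c5), " c3:", format_conc(x$c3),
      " depletant:", format_conc(x$c_dep), "\n")
  invisible(x)
}

#' Shared assay context for the forward signal model
#'
#' @param reaction_volume Reaction volume in liters (default 50 uL).
#' @param sample_volume Sample volume in liters (default 5 uL); the target is
#'   diluted by `sample_volume / reaction_volume` on entering the reaction.
#' @param ligation_efficiency Fraction in (0, 1] of correctly paired binding
#'   events converted to a ligated reporter.
#' @param bead_capacity Maximum capturable target concentration in the
#'   reaction (molar); models capture-antibody saturation. `Inf` disables.
#' @param mass_balance Logical; if `TRUE`, free dAb concentrations are solved
#'   self-consistently (bound target sequesters dAb), which produces the
#'   hook effect at high target loads.
#' @return An object of class `assay_context`.
#' @export
assay_context <- function(reaction_volume = 50e-6, sample_volume = 5e-6,
                          ligation_efficiency = 0.8, bead_capacity = Inf,
                          mass_balance = TRUE) {
  bead_capacity <- parse_conc(bead_capacity)
  if (sample_volume <= 0 || reaction_volume <= 0 || sample_volume > reaction_volume)
    stop("need 0 < sample_volume <= reaction_volume")
  if (ligation_efficiency <= 0 || ligation_efficiency > 1)
    stop("ligation_efficiency must be in (0, 1]")
  if (!(bead_capacity > 0)) stop("bead_capacity must be > 0")
  structure(list(reaction_volume = reaction_volume, sample_volume = sample_volume,
                 ligation_efficiency = ligation_efficiency,
                 bead_capacity = bead_capacity,
                 mass_balance = isTRUE(mass_balance)),
            class = "assay_context")
}

sample_dilution <- function(ctx) ctx$sample_volume / ctx$reaction_volume

#' Tuning goal: the common reporter output every analyte is equalized to
#'
#' @param target_reporter_output Target reporter-DNA concentration at the
#'   evaluation point (default 1 fM, the working point at which UMI counting
#'   is most precise).
#' @param evaluation_point Concentration at which the target must be met;
#'   `NULL` (default) means the log-middle of each analyte's testing range.
#' @param output_window Acceptable panel-wide output band (low, high),
#'   default three orders of magnitude centred on the target.
#' @return An object of class `tuning_goal`.
#' @export
tuning_goal <- function(target_reporter_output = 1e-15, evaluation_point = NULL,
                        output_window = NULL) {
  target_reporter_output <- parse_conc(target_reporter_output)
  if (!is.null(evaluation_point)) evaluation_point <- parse_conc(evaluation_point)
  if (is.null(output_window))
    output_window <- target_reporter_output * c(10^-1.5, 10^1.5)
  output_window <- parse_conc(output_window)
  if (target_reporter_output <= 0) stop("target_reporter_output must be > 0")
  if (output_window[1] >= output_window[2]) stop("output_window must be (low, high)")
  structure(list(target_reporter_output = target_reporter_output,
                 evaluation_point = evaluation_point,
                 output_window = output_window),
            class = "tuning_goal")
}

#' Read a panel configuration from YAML
#'
#' The YAML holds an optional `context` block (fields of [assay_context()]),
#' an `analytes` list (fields of [analyte()]) and optional per-analyte
#' `probes` blocks (fields of [probe_set()]). Concentrations may use unit
#' suffixes.
#'
#' @param path YAML file path.
#' @return List with `analytes` (list of `analyte`), `probes` (named list of
#'   `probe_set` or NULL) and `context` (`assay_context`).
#' @export
read_panel_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  ctx <- do.call(assay_context, lapply(cfg$context %||% list(), unlist))
  analytes <- lapply(cfg$analytes, function(a) {
    analyte(a$name, a$epitope_count, a$kd_dab, a$capture_efficiency,
            unlist(a$testing_range),
            if (!is.null(a$physiological_range)) unlist(a$physiological_range))
  })
  names(analytes) <- vapply(analytes, `[[`, character(1), "name")
  probes <- lapply(cfg$analytes, function(a) {
    if (is.null(a$probes)) NULL
    else probe_set(a$probes$c5, a$probes$c3, a$probes$c_dep %||% 0)
  })
  names(probes) <- names(analytes)
  list(analytes = analytes, probes = probes, context = ctx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
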