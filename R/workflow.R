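#' Count reporters across a set of per-sample FASTQ files
#'
#' Runs [count_reporters()] on each file and stacks the normalized counts
#' into one long table.
#'
#' @param files Named character vector of FASTQ paths (names = sample ids).
#' @param refs A `reporter_reference_set`.
#' @param min_score Assignment threshold (default 31).
#' @return Data frame with columns `sample`, `reporter`, `numi`.
#' @export
panel_numi_table <- function(files, refs, min_score = 31L) {
  if (is.null(names(files))) names(files) <- sub("\\.f(ast)?q(\\.gz)?$", "", basename(files))
  out <- do.call(rbind, lapply(names(files), function(s) {
    res <- count_reporters(files[[s]], refs, min_score = min_score)
    cbind(sample = s, res$numi)
  }))
  rownames(out) <- NULL
  out
}

#' Fit per-analyte calibration curves from a simulated or measured experiment
#'
#' Joins a long nUMI table with the standards design and fits one 4PL curve
#' per analyte on all replicate points.
#'
#' @param numi_table Output of [panel_numi_table()].
#' @param standards Data frame with columns `sample`, `analyte`, `conc`
#'   (the analyte concentration in each standard sample).
#' @param reporter_map Named character vector analyte -> reporter.
#' @return Named list of [fit_4pl()] objects, one per analyte.
#' @export
calibrate_panel <- function(numi_table, standards, reporter_map) {
  rev_map <- stats::setNames(names(reporter_map), reporter_map)
  numi_table$analyte <- rev_map[numi_table$reporter]
  merged <- merge(numi_table, standards, by = c("sample", "analyte"))
  lapply(split(merged, merged$analyte), function(d)
    fit_4pl(numi ~ conc, data = d))
}
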