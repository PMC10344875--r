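# Full simulate -> count -> fit -> quantify recovery experiment on the
# four-analyte synthetic panel. Shared by the end-to-end tests.
run_recovery_experiment <- function(seed, reads_per_sample = 200000,
                                    truths = c(IL6like = 8e-15, IL1RAlike = 1e-12,
                                               GDF15like = 5e-11, CRPlike = 1e-8),
                                    n_replicates = 3, dir = tempfile("e2e")) {
  panel <- synthetic_panel()
  tuned <- tune_panel(panel$analytes, panel$context)
  probes <- lapply(tuned$results, `[[`, "probes")
  cfg <- sim_config(seed = seed, reads_per_sample = reads_per_sample)
  unknowns <- stats::setNames(rep(list(truths), n_replicates),
                              sprintf("unk_rep%d", seq_len(n_replicates)))
  sim <- simulate_panel_experiment(panel$analytes, probes, panel$context, cfg,
                                   dir = dir, n_replicates = n_replicates,
                                   unknowns = unknowns)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  numi <- panel_numi_table(sim$files, sim$refs)
  curves <- calibrate_panel(numi,
                            sim$standards[!is.na(sim$standards$standard), ],
                            sim$reporter_map)
  rev_map <- stats::setNames(names(sim$reporter_map), sim$reporter_map)
  unk <- numi[grepl("^unk_", numi$sample), ]
  unk$analyte <- rev_map[unk$reporter]
  quant <- quantify(unk[, c("analyte", "numi")], curves)
  rel_err <- abs(quant$summary$mean_conc - truths[quant$summary$analyte]) /
    truths[quant$summary$analyte]
  list(tuned = tuned, curves = curves, quant = quant,
       truths = truths, rel_err = rel_err)
}
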