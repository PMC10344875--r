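# plaeq — signal equalization and quantification for proximity ligation assays

Multiplexed immunoassays resolve concentrations over only 3–4 orders of
magnitude, while the proteins worth measuring in one serum sample span far
more — femtomolar cytokines alongside mid-nanomolar acute-phase proteins.
The usual fix, splitting the sample and diluting each panel differently,
brings the analyte- and sample-dependent artefact of non-linear dilution.

`plaeq` implements the alternative for solid-phase proximity ligation assays
(spPLA): *equalize the signal chemistry per analyte* so that every target's
reporter-DNA output lands in one quantifiable window, and a single undiluted
microliter-scale sample can be read in one sequencing run. It is aimed at
assay developers who want to design, simulate and analyse such panels.

## What's inside

* **Forward signal model** — Langmuir occupancy of the detection-antibody
  (dAb) pool, `θ = T/(T + K_d)`, combined with the binomial probability that
  a captured molecule carries at least one 5′- and one 3′-labelled antibody,
  `P = 1 − (1−θp₅)ⁿ − (1−θp₃)ⁿ + (1−θ(p₅+p₃))ⁿ`, plus bead capture
  saturation and optional self-consistent antibody mass balance (the hook
  effect). `reporter_output()`, `response_curve()`, `hook_point()`.
* **Tuning engine** — bisection on the forward model chooses the probe
  loading (and, for flat high-abundance analytes, an epitope-depletant dose
  with two-stage compensation) so each analyte outputs a common target
  (default 1 fM) at the log-middle of its testing range.
  `tune_panel()`, `tune_probe_loading()`, `tune_with_depletion()`.
* **Sequencing readout** — FASTQ → normalized UMI counts: 52-nt/Phred≥20
  filtering, duplicate collapse, exact positional similarity assignment
  (score > 31, ties discarded), per-reporter unique-UMI counting, division
  by the spiked control oligo. `count_reporters()`.
* **qPCR branch** — min–max trace normalization, first-crossing Ct at 0.25,
  `Ct = m·log₁₀[DNA] + b` calibration and its inverse, amplification-cycle
  selection. `extract_ct()`, `fit_calibration()`.
* **4PL calibration** — `nUMI = (A−D)/(1+(x/C)^B) + D` fitted by bounded
  Levenberg–Marquardt on log residuals, returned as a classed model object
  with `print`/`summary`/`coef`/`predict`/`plot`/`residuals` methods, and a
  guarded algebraic inverse that flags out-of-range responses instead of
  extrapolating. `fit_4pl()`, `invert_4pl()`, `quantify()`.
* **Synthetic data** — seeded generators for reporter references, FASTQ
  libraries with UMI collisions and per-base errors, qPCR traces and full
  panel experiments, so everything above is testable end to end with no
  instrument data. `simulate_panel_experiment()`.

## Worked example

Tune the built-in four-analyte panel (testing ranges 2–200 fM, 0.5–50 pM,
5–500 pM, 1–70 nM) to a common 1 fM reporter output:

```r
library(plaeq)
panel <- synthetic_panel()
tuned <- tune_panel(panel$analytes, panel$context)
tuned
#> <panel_tuning> 4 analytes, target 1 fM at each log-middle
#>   IL6like    dAb 563 pM     dep 0 M      -> 1 fM
#>   IL1RAlike  dAb 10 pM      dep 0 M      -> 1 fM
#>   GDF15like  dAb 3.16 pM    dep 0 M      -> 999 aM
#>   CRPlike    dAb 9.17 pM    dep 37.8 nM  -> 1 fM
#>   standards output spread: 2.46 orders of magnitude
```

Each line is the solved detection-antibody concentration (per pool) and
depletant dose; the femtomolar analyte needs heavy probe loading, the
nanomolar analyte needs epitope depletion with its loading re-compensated.
After tuning, the outputs across all six-point 3× standards of all four
analytes sit within 2.46 orders of magnitude — one quantifiable window —
versus 6.14 orders untuned at a uniform 250 pM.

Simulate a sequencing run of that panel and quantify spiked unknowns:

```r
probes <- lapply(tuned$results, `[[`, "probes")
truths <- c(IL6like = 8e-15, IL1RAlike = 1e-12, GDF15like = 5e-11, CRPlike = 1e-8)
cfg <- sim_config(seed = 11, reads_per_sample = 200000)
sim <- simulate_panel_experiment(panel$analytes, probes, panel$context, cfg,
                                 n_replicates = 3,
                                 unknowns = list(u1 = truths, u2 = truths, u3 = truths))
numi <- panel_numi_table(sim$files, sim$refs)
curves <- calibrate_panel(numi, sim$standards[!is.na(sim$standards$standard), ],
                          sim$reporter_map)
unk <- numi[grepl("^u", numi$sample), ]
unk$analyte <- setNames(names(sim$reporter_map), sim$reporter_map)[unk$reporter]
quantify(unk[, c("analyte", "numi")], curves)
#> <quantification>
#>   CRPlike    9.38 nM +/- 482 pM   (3/3 replicates in range)
#>   GDF15like  49.5 pM +/- 2.88 pM  (3/3 replicates in range)
#>   IL1RAlike  977 fM +/- 86.4 fM   (3/3 replicates in range)
#>   IL6like    8.08 fM +/- 550 aM   (3/3 replicates in range)
```

Concentrations spanning 8 fM to 10 nM — more than six orders of magnitude —
come back within a few percent of truth from a single simulated 200k-read
library per sample.

A thin command-line front end wraps the same functions
(`inst/cli/plaeq.R`; subcommands `simulate`, `tune`, `count`, `calibrate`,
`quantify`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "plaeq.R", package = "plaeq"))')" \
  tune --panel inst/extdata/panel_fourplex.yaml --out tuned.yaml
```

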