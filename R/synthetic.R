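AVOGADRO <- 6.02214076e23

# run code under a fixed seed, restoring the caller's RNG state afterwards
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic sequencing-library generator
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @param umi_length UMI length in bases (default 10, i.e. ~1.05M UMI space,
#'   giving low collision rates at the ~30k molecules of the 1 fM working
#'   point in a 50 uL reaction).
#' @param per_base_error Per-base substitution error rate (default 0.001).
#' @param reads_per_sample Sequencing depth per sample.
#' @param reaction_volume Reaction volume (liters) used to convert reporter
#'   concentrations to molecule counts.
#' @param phred_mean,phred_sd Per-base Phred score profile.
#' @param truncate_rate Fraction of reads emitted one base short, to
#'   exercise the length filter.
#' @param lowq_rate Fraction of reads given one very low-quality base, to
#'   exercise the quality filter.
#' @param control_conc Spiked control-oligo concentration (default 100 aM).
#' @param assay_cv Per-replicate lognormal coefficient of variation applied
#'   to reporter concentrations (pipetting/ligation variability).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, umi_length = 10L, per_base_error = 0.001,
                       reads_per_sample = 200000L, reaction_volume = 50e-6,
                       phred_mean = 35, phred_sd = 3,
                       truncate_rate = 0.01, lowq_rate = 0.01,
                       control_conc = 1e-16, assay_cv = 0.05) {
  if (per_base_error < 0 || per_base_error >= 0.25)
    stop("per_base_error must be in [0, 0.25)")
  stopifnot(umi_length >= 1, reads_per_sample >= 1, reaction_volume > 0)
  structure(list(seed = as.integer(seed), umi_length = as.integer(umi_length),
                 umi_space = 4^umi_length, per_base_error = per_base_error,
                 reads_per_sample = as.integer(reads_per_sample),
                 reaction_volume = reaction_volume,
                 phred_mean = phred_mean, phred_sd = phred_sd,
                 truncate_rate = truncate_rate, lowq_rate = lowq_rate,
                 control_conc = parse_conc(control_conc), assay_cv = assay_cv),
            class = "sim_config")
}

#' Molecule count for a reporter concentration in the reaction
#' @param conc Molar concentration.
#' @param volume Reaction volume in liters.
#' @return Integer molecule count, `round(conc * volume * N_A)`.
#' @export
molecules_at <- function(conc, volume = 50e-6) round(conc * volume * AVOGADRO)

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# n random UMI strings of length L (column-wise big-string split)
random_umis <- function(n, L) {
  if (n == 0) return(character())
  big <- paste(random_bases(n * L), collapse = "")
  substring(big, (seq_len(n) - 1) * L + 1, seq_len(n) * L)
}

#' Generate a synthetic reporter reference set
#'
#' Emits `n_targets + 1` reporter templates of length 52 (the last one is
#' the control oligo), with the UMI block at a common central position and
#' random barcode bases elsewhere. Construction guarantees that the pairwise
#' non-UMI similarity between any two templates is at most 31, so the
#' assignment threshold separates them; generation is deterministic per
#' seed. These are synthetic stand-ins for a real reporter panel.
#'
#' @param n_targets Number of target reporters (>= 1).
#' @param umi_length UMI length (default 10).
#' @param seed Integer seed.
#' @param max_pairwise Maximum allowed pairwise non-UMI similarity
#'   (default 31).
#' @return A `reporter_reference_set`.
#' @export
generate_references <- function(n_targets, umi_length = 10L, seed = 1L,
                                max_pairwise = 31L) {
  stopifnot(n_targets >= 1)
  if (umi_length >= REPORTER_LENGTH - max_pairwise)
    stop("infeasible: too few barcode positions to separate references")
  umi_start <- 22L
  if (umi_start + umi_length - 1L > REPORTER_LENGTH)
    umi_start <- REPORTER_LENGTH - umi_length + 1L
  umi_block <- strrep("N", umi_length)
  n <- n_targets + 1L
  local_seed(seed, {
    for (attempt in 1:100) {
      templates <- vapply(seq_len(n), function(i) {
        bases <- random_bases(REPORTER_LENGTH)
        bases[umi_start:(umi_start + umi_length - 1L)] <- ""
        paste0(substr(paste(bases, collapse = ""), 1, umi_start - 1L), umi_block,
               paste(bases[(umi_start + umi_length):REPORTER_LENGTH], collapse = ""))
      }, character(1))
      mats <- matrix(unlist(strsplit(templates, "")), nrow = REPORTER_LENGTH)
      keep <- mats[, 1] != "N"
      sims <- utils::combn(n, 2, function(ij)
        sum(mats[keep, ij[1]] == mats[keep, ij[2]]))
      if (all(sims <= max_pairwise)) {
        refs <- lapply(seq_len(n), function(i) {
          reporter_reference(
            name = if (i == n) "CTRL" else sprintf("T%02d", i),
            template = templates[i], is_control = i == n)
        })
        return(reference_set(refs))
      }
    }
    stop("could not generate ", n, " separable references at length ",
         REPORTER_LENGTH, " after 100 attempts")
  })
}

# generate one sample's reads and write a FASTQ file.
# molecule_umis: named list reporter -> character vector of that sample's
# molecule UMIs. Returns the path.
write_sample_fastq <- function(sample_id, molecule_umis, refs, cfg, path) {
  counts <- vapply(molecule_umis, length, integer(1))
  stopifnot(sum(counts) > 0)
  depth <- cfg$reads_per_sample
  # depth allocated multinomially over molecules = over reporters by share
  per_rep <- as.integer(stats::rmultinom(1, depth, prob = counts))
  names(per_rep) <- names(molecule_umis)
  seqs <- character(0); origins <- character(0)
  for (rep_name in names(molecule_umis)) {
    d <- per_rep[[rep_name]]
    if (d == 0) next
    r <- refs[[rep_name]]
    umis <- molecule_umis[[rep_name]][sample.int(counts[[rep_name]], d, replace = TRUE)]
    u0 <- r$umi_positions[1]; u1 <- r$umi_positions[length(r$umi_positions)]
    seqs <- c(seqs, paste0(substr(r$template, 1, u0 - 1), umis,
                           substr(r$template, u1 + 1, REPORTER_LENGTH)))
    origins <- c(origins, rep(rep_name, d))
  }
  n <- length(seqs)
  # substitution errors
  if (cfg$per_base_error > 0) {
    n_err <- stats::rbinom(n, REPORTER_LENGTH, cfg$per_base_error)
    for (i in which(n_err > 0)) {
      pos <- sample.int(REPORTER_LENGTH, n_err[i])
      s <- strsplit(seqs[i], "")[[1]]
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      seqs[i] <- paste(s, collapse = "")
    }
  }
  # per-base qualities
  q <- round(stats::rnorm(n * REPORTER_LENGTH, cfg$phred_mean, cfg$phred_sd))
  q <- pmin(pmax(q, 2L), 41L)
  qmat <- matrix(as.integer(q), nrow = REPORTER_LENGTH)
  if (cfg$lowq_rate > 0) {
    bad <- which(stats::runif(n) < cfg$lowq_rate)
    if (length(bad))
      qmat[cbind(sample.int(REPORTER_LENGTH, length(bad), replace = TRUE), bad)] <- 2L
  }
  qbig <- rawToChar(as.raw(as.vector(qmat) + 33L))
  quals <- substring(qbig, (seq_len(n) - 1) * REPORTER_LENGTH + 1,
                     seq_len(n) * REPORTER_LENGTH)
  if (cfg$truncate_rate > 0) {
    short <- stats::runif(n) < cfg$truncate_rate
    seqs[short] <- substr(seqs[short], 1, REPORTER_LENGTH - 1L)
    quals[short] <- substr(quals[short], 1, REPORTER_LENGTH - 1L)
  }
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(reads) <- sprintf("%s:seed%d:%d:%s", sample_id, cfg$seed, seq_len(n), origins)
  # Biostrings warns when dropping (empty) metadata columns on write
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(reads, path))
  path
}

#' Simulate a sequencing library from a reporter truth table
#'
#' For each sample, each reporter's concentration is converted to a molecule
#' count, molecules receive UMIs drawn uniformly from the UMI space (natural
#' collisions included), sequencing depth is allocated multinomially over
#' molecules, and reads acquire per-base substitution errors, Phred strings
#' and the configured rates of truncated / low-quality reads. Deterministic
#' per seed.
#'
#' @param truth Data frame with columns `sample`, `reporter`, `conc`
#'   (reporter-DNA molar concentration in the reaction).
#' @param refs A `reporter_reference_set` covering every reporter in `truth`.
#' @param cfg A [sim_config()].
#' @param dir Output directory for the per-sample FASTQ files.
#' @return `truth` augmented with `molecules`, `true_unique_umis` and, per
#'   sample, the written FASTQ `file`.
#' @export
simulate_reads <- function(truth, refs, cfg = sim_config(), dir = tempfile("fastq")) {
  stopifnot(all(c("sample", "reporter", "conc") %in% names(truth)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth$molecules <- molecules_at(truth$conc, cfg$reaction_volume)
  truth$true_unique_umis <- NA_integer_
  truth$file <- NA_character_
  samples <- unique(truth$sample)
  local_seed(cfg$seed, {
    for (s in samples) {
      rows <- which(truth$sample == s)
      mols <- lapply(rows, function(i) random_umis(truth$molecules[i], cfg$umi_length))
      names(mols) <- truth$reporter[rows]
      truth$true_unique_umis[rows] <-
        vapply(mols, function(u) length(unique(u)), integer(1))
      path <- file.path(dir, paste0(s, ".fastq"))
      keep <- vapply(mols, length, integer(1)) > 0
      write_sample_fastq(s, mols[keep], refs, cfg, path)
      truth$file[rows] <- path
    }
  })
  truth
}

#' Simulate a logistic qPCR amplification trace
#'
#' Signal follows a logistic curve in cycle number whose crossing cycle
#' shifts by `-log10(dilution) / log10(efficiency)` under template dilution
#' (3.32 cycles per decade at perfect efficiency), plus additive Gaussian
#' noise. Deterministic per seed.
#'
#' @param template_conc Template concentration (> 0, molar or unit string).
#' @param efficiency Per-cycle amplification factor in (1, 2\].
#' @param midpoint_scale Concentration scale at which the unamplified
#'   template would already sit at the curve midpoint (sets the intercept).
#' @param noise_sd Additive Gaussian noise SD on the normalized signal.
#' @param seed Integer seed.
#' @param n_cycles Number of cycles (default 39).
#' @return Numeric vector of per-cycle intensities.
#' @export
simulate_qpcr <- function(template_conc, efficiency = 2, midpoint_scale = 1e-9,
                          noise_sd = 0, seed = 1L, n_cycles = 39L) {
  template_conc <- parse_conc(template_conc)
  if (template_conc <= 0) stop("template_conc must be > 0")
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  c_half <- log10(parse_conc(midpoint_scale) / template_conc) / log10(efficiency)
  cycles <- seq_len(n_cycles)
  local_seed(seed, {
    1 / (1 + exp(-log(efficiency) * (cycles - c_half))) +
      stats::rnorm(n_cycles, 0, noise_sd)
  })
}

#' Simulate a full multiplexed panel experiment as sequencing data
#'
#' Renders the forward model as data: for every standard (six-point 3x
#' serial dilutions of an all-analyte mix, in replicate) and every unknown
#' sample, per-analyte reporter concentrations come from
#' [reporter_output()] at the tuned probe loadings, jittered by the
#' configured per-replicate assay CV; the control oligo is spiked at a fixed
#' concentration in every sample. Reads are then simulated and written as
#' per-sample FASTQ files.
#'
#' @param panel List of [analyte()] objects.
#' @param probes_list Named list of [probe_set()] per analyte (e.g. from
#'   [tune_panel()] results).
#' @param ctx An [assay_context()].
#' @param cfg A [sim_config()].
#' @param dir Output directory for FASTQ files.
#' @param reporter_map Named character vector analyte -> reporter name;
#'   defaults to pairing panel order with the non-control reporters of
#'   `refs`.
#' @param refs A `reporter_reference_set`; default generates one.
#' @param n_replicates Replicates per standard (default 3).
#' @param unknowns Optional named list: sample name -> named molar
#'   concentration vector (one entry per analyte).
#' @return List with `refs`, `standards` (sample/analyte/conc),
#'   `truth` (the augmented truth table from [simulate_reads()]) and
#'   `files` (named FASTQ paths).
#' @export
simulate_panel_experiment <- function(panel, probes_list, ctx = assay_context(),
                                      cfg = sim_config(), dir = tempfile("panel"),
                                      reporter_map = NULL, refs = NULL,
                                      n_replicates = 3L, unknowns = NULL) {
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  if (is.null(refs))
    refs <- generate_references(length(panel), cfg$umi_length, seed = cfg$seed)
  if (is.null(reporter_map)) {
    targets <- names(refs)[!vapply(refs, `[[`, logical(1), "is_control")]
    reporter_map <- stats::setNames(targets[seq_along(panel)], names(panel))
  }
  ctrl_name <- names(refs)[vapply(refs, `[[`, logical(1), "is_control")][1]

  std_concs <- lapply(panel, panel_standards)
  n_std <- length(std_concs[[1]])
  standards <- do.call(rbind, lapply(seq_len(n_std), function(s) {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(sample = sprintf("std%d_rep%d", s, r), standard = s, replicate = r,
                 analyte = names(panel),
                 conc = vapply(std_concs, `[`, numeric(1), s))
    }))
  }))
  unk <- if (!is.null(unknowns)) {
    do.call(rbind, lapply(names(unknowns), function(nm) {
      data.frame(sample = nm, standard = NA_integer_, replicate = NA_integer_,
                 analyte = names(panel),
                 conc = unname(unknowns[[nm]][names(panel)]))
    }))
  }
  design <- rbind(standards, unk)

  truth <- local_seed(cfg$seed + 1L, {
    out <- do.call(rbind, lapply(split(design, design$sample), function(d) {
      rep_conc <- vapply(seq_len(nrow(d)), function(i) {
        a <- panel[[d$analyte[i]]]
        reporter_output(d$conc[i], a, probes_list[[a$name]], ctx)
      }, numeric(1))
      rep_conc <- rep_conc * exp(stats::rnorm(nrow(d), 0, cfg$assay_cv))
      rbind(data.frame(sample = d$sample, reporter = reporter_map[d$analyte],
                       analyte = d$analyte, conc = rep_conc),
            data.frame(sample = d$sample[1], reporter = ctrl_name,
                       analyte = NA_character_,
                       conc = cfg$control_conc * exp(stats::rnorm(1, 0, cfg$assay_cv))))
    }))
    rownames(out) <- NULL
    out
  })
  truth <- simulate_reads(truth, refs, cfg, dir)
  files <- vapply(split(truth$file, truth$sample), `[`, character(1), 1)
  list(refs = refs, standards = design, truth = truth, files = files,
       reporter_map = reporter_map)
}
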