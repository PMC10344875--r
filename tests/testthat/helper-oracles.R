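# Independent oracles and small fixture builders shared across test files.

# Brute-force pairing probability: enumerate every epitope state
# (unbound / bound-5' / bound-3' / bound-unlabelled) over all epitopes and
# sum the probability of states with at least one 5' and one 3' label.
# Deliberately independent of the closed form used by the package.
pair_prob_enum <- function(theta, n, p5, p3) {
  pd <- 1 - p5 - p3
  state_p <- c(unbound = 1 - theta, b5 = theta * p5,
               b3 = theta * p3, bd = theta * pd)
  states <- expand.grid(rep(list(names(state_p)), n), stringsAsFactors = FALSE)
  total <- 0
  for (i in seq_len(nrow(states))) {
    s <- unlist(states[i, ])
    if (any(s == "b5") && any(s == "b3"))
      total <- total + prod(state_p[s])
  }
  total
}

# QualityScaledDNAStringSet from plain strings; qual is a single Phred score
# recycled per base, or a list of per-base integer vectors.
make_reads <- function(seqs, qual = 30L) {
  quals <- if (is.list(qual)) {
    vapply(qual, function(q) rawToChar(as.raw(q + 33L)), character(1))
  } else {
    vapply(nchar(seqs), function(n) strrep(rawToChar(as.raw(qual + 33L)), n),
           character(1))
  }
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
}

# mutate k of the given positions of a template string (deterministic base
# rotation A->C->G->T->A, so the new base never equals the old)
rotate_bases <- function(template, positions) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  s <- strsplit(template, "")[[1]]
  s[positions] <- rot[s[positions]]
  paste(s, collapse = "")
}

# a small, fast analyte/context pair used wherever the specific panel
# does not matter
toy_analyte <- function(name = "toy", n = 6, kd = 1e-9,
                        range = c(5e-12, 5e-10)) {
  analyte(name, epitope_count = n, kd_dab = kd, capture_efficiency = 0.9,
          testing_range = range)
}

toy_ctx <- function(...) {
  assay_context(ligation_efficiency = 0.8, bead_capacity = 10e-9,
                mass_balance = TRUE, ...)
}
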