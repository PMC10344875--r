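REPORTER_LENGTH <- 52L

#' Define a reporter reference sequence
#'
#' A reporter is the 52-nt ligation product carrying a protein-specific
#' barcode; `N` symbols in the template mark the UMI positions (random bases
#' identifying individual molecules). Exactly one strand orientation is
#' assumed (single-end amplicon).
#'
#' @param name Reporter identifier.
#' @param template 52-character string over `A`, `C`, `G`, `T`, `N`.
#' @param is_control Logical; `TRUE` for the spiked-in control oligo used
#'   for normalization.
#' @return An object of class `reporter_reference`.
#' @export
reporter_reference <- function(name, template, is_control = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(template), length(template) == 1L)
  if (nchar(template) != REPORTER_LENGTH)
    stop("template must be exactly ", REPORTER_LENGTH, " nt (got ", nchar(template), ")")
  if (grepl("[^ACGTN]", template)) stop("template may only contain A, C, G, T, N")
  structure(list(name = name, template = template,
                 umi_positions = which(strsplit(template, "")[[1]] == "N"),
                 is_control = isTRUE(is_control)),
            class = "reporter_reference")
}

#' Bundle reporter references into a validated reference set
#'
#' @param ... `reporter_reference` objects (or a single list of them).
#' @return An object of class `reporter_reference_set`.
#' @export
reference_set <- function(...) {
  refs <- list(...)
  if (length(refs) == 1L && !inherits(refs[[1]], "reporter_reference")) refs <- refs[[1]]
  if (!length(refs)) stop("empty reference set")
  stopifnot(all(vapply(refs, inherits, logical(1), "reporter_reference")))
  names(refs) <- vapply(refs, `[[`, character(1), "name")
  if (anyDuplicated(names(refs))) stop("duplicate reporter names")
  if (!any(vapply(refs, `[[`, logical(1), "is_control")))
    stop("reference set must contain at least one control reporter")
  umi_len <- vapply(refs, function(r) length(r$umi_positions), integer(1))
  if (length(unique(umi_len)) != 1L)
    stop("UMI mask length must be identical across references")
  structure(refs, class = "reporter_reference_set")
}

#' @export
print.reporter_reference_set <- function(x, ...) {
  cat("<reporter_reference_set>", length(x), "reporters, UMI length",
      length(x[[1]]$umi_positions), "\n")
  for (r in x) cat(sprintf("  %-12s %s%s\n", r$name, r$template,
                           if (r$is_control) "  [control]" else ""))
  invisible(x)
}

#' Read reporter references from YAML or CSV
#'
#' YAML: a list of mappings with `name`, `template`, `is_control`. CSV: the
#' same three columns.
#'
#' @param path File path (`.yaml`/`.yml` or `.csv`).
#' @return A `reporter_reference_set`.
#' @export
read_reporter_refs <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    rows <- yaml::read_yaml(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  reference_set(lapply(rows, function(r)
    reporter_reference(r$name, r$template, isTRUE(r$is_control) ||
                         identical(r$is_control, "TRUE"))))
}

#' Write reporter references to CSV
#' @param refs A `reporter_reference_set`.
#' @param path Output CSV path.
#' @export
write_reporter_refs <- function(refs, path) {
  utils::write.csv(data.frame(
    name = vapply(refs, `[[`, character(1), "name"),
    template = vapply(refs, `[[`, character(1), "template"),
    is_control = vapply(refs, `[[`, logical(1), "is_control")
  ), path, row.names = FALSE)
  invisible(path)
}

#' Read a single-end FASTQ file with qualities
#'
#' @param path FASTQ path (optionally gzipped).
#' @param quality_scoring Phred encoding; `"phred"` is Phred+33 (modern
#'   Illumina), `"illumina"`/`"solexa"` are the legacy +64 encodings.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_reporter_fastq <- function(path, quality_scoring = "phred") {
  # Biostrings warns about dropping (empty) FASTQ metadata columns; benign
  suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = quality_scoring))
}

#' Filter reads by length and per-base quality
#'
#' Keeps exactly the reads of the expected length whose minimum per-base
#' Phred score is at or above the cutoff. Length is checked first, so a
#' short low-quality read is tallied as a length discard.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param min_phred Minimum per-base Phred score (default 20).
#' @param read_length Required read length (default 52).
#' @return List with `kept` (filtered reads, input order preserved) and
#'   `tally` (named counts: input, length_discarded, quality_discarded, kept).
#' @export
quality_filter <- function(reads, min_phred = 20L, read_length = REPORTER_LENGTH) {
  n <- length(reads)
  ok_len <- Biostrings::width(reads) == read_length
  min_q <- rep(NA_integer_, n)
  if (any(ok_len)) {
    q <- methods::as(Biostrings::quality(reads[ok_len]), "IntegerList")
    min_q[ok_len] <- min(q)
  }
  ok_qual <- ok_len & !is.na(min_q) & min_q >= min_phred
  # subsetting warns about dropping (empty) metadata columns; benign
  list(kept = suppressWarnings(reads[ok_qual]),
       tally = c(input = n,
                 length_discarded = sum(!ok_len),
                 quality_discarded = sum(ok_len & !ok_qual),
                 kept = sum(ok_qual)))
}

#' Collapse duplicate reads into unique sequences with multiplicities
#'
#' Exact-sequence deduplication so that each UMI-bearing molecule is
#' represented once regardless of amplification depth. Output order is
#' deterministic: descending multiplicity, then lexicographic sequence.
#'
#' @param reads Character vector of sequences, or anything coercible with
#'   `as.character()` (e.g. a `DNAStringSet`).
#' @return Data frame with columns `sequence` and `count`.
#' @export
collapse_duplicates <- function(reads) {
  seqs <- as.character(reads)
  if (!length(seqs)) return(data.frame(sequence = character(), count = integer()))
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact positional similarity score against a reporter reference
#'
#' Counts the positions at which the read base equals the reference base,
#' over the non-UMI positions only (UMI positions are random and contribute
#' nothing). No gaps, no shifts — deliberately not an alignment, because the
#' reporters share near-identical subsequences shifted by a few bases and a
#' gapped aligner would blur them together.
#'
#' @param read_sequence 52-character read.
#' @param reference A [reporter_reference()].
#' @return Integer score in `[0, 52 - umi_length]`.
#' @export
similarity_score <- function(read_sequence, reference) {
  if (nchar(read_sequence) != REPORTER_LENGTH)
    stop("read must be ", REPORTER_LENGTH, " nt")
  rc <- strsplit(read_sequence, "")[[1]]
  tc <- strsplit(reference$template, "")[[1]]
  keep <- tc != "N"
  sum(rc[keep] == tc[keep])
}

# vectorized scorer: 52 x n character matrix against each reference
score_matrix <- function(seq_mat, refs) {
  vapply(refs, function(r) {
    tc <- strsplit(r$template, "")[[1]]
    keep <- tc != "N"
    as.integer(colSums(seq_mat[keep, , drop = FALSE] == tc[keep]))
  }, integer(ncol(seq_mat)))
}

#' Assign collapsed reads to reporters by best similarity score
#'
#' Each read goes to the reporter with the highest exact similarity score,
#' provided that score is strictly greater than `min_score`; reads whose
#' best score ties between two or more reporters are discarded as ambiguous
#' (the references are similar by construction, so ties risk cross-talk).
#'
#' @param collapsed Data frame from [collapse_duplicates()] (or a character
#'   vector of unique sequences).
#' @param refs A `reporter_reference_set`.
#' @param min_score Score threshold; assignment requires score > `min_score`
#'   (default 31).
#' @return `collapsed` with added columns `reporter` (NA when unassigned)
#'   and `reason` (`assigned`, `low_score` or `tie`).
#' @export
assign_reads <- function(collapsed, refs, min_score = 31L) {
  if (!inherits(refs, "reporter_reference_set")) refs <- reference_set(refs)
  if (is.character(collapsed))
    collapsed <- data.frame(sequence = collapsed, count = 1L)
  n <- nrow(collapsed)
  collapsed$reporter <- NA_character_
  collapsed$reason <- character(n)
  if (!n) return(collapsed)
  if (any(nchar(collapsed$sequence) != REPORTER_LENGTH))
    stop("all sequences must be ", REPORTER_LENGTH, " nt (quality_filter first)")
  seq_mat <- matrix(unlist(strsplit(collapsed$sequence, ""), use.names = FALSE),
                    nrow = REPORTER_LENGTH)
  scores <- score_matrix(seq_mat, refs)
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)  # single read
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(n), best)]
  n_best <- rowSums(scores == best_score)
  low <- best_score <= min_score
  tie <- !low & n_best > 1L
  ok <- !low & !tie
  collapsed$reporter[ok] <- names(refs)[best[ok]]
  collapsed$reason <- ifelse(ok, "assigned", ifelse(low, "low_score", "tie"))
  collapsed
}

#' Count unique UMIs per reporter
#'
#' For each reporter, extracts the bases at that reporter's UMI positions
#' from its assigned (already collapsed) reads and counts distinct UMI
#' strings; reads differing only outside the UMI collapse onto one UMI.
#'
#' @param assigned Data frame from [assign_reads()].
#' @param refs A `reporter_reference_set`.
#' @return An object of class `umi_count_table`: data frame with columns
#'   `reporter`, `is_control`, `assigned_reads` (sum of read multiplicities)
#'   and `unique_umis`, with a `totals` attribute tallying input/assigned/
#'   low-score/tie read multiplicities.
#' @export
count_umis <- function(assigned, refs) {
  if (!inherits(refs, "reporter_reference_set")) refs <- reference_set(refs)
  rows <- lapply(refs, function(r) {
    sel <- !is.na(assigned$reporter) & assigned$reporter == r$name
    if (any(sel)) {
      seq_mat <- matrix(unlist(strsplit(assigned$sequence[sel], ""), use.names = FALSE),
                        nrow = REPORTER_LENGTH)
      umis <- apply(seq_mat[r$umi_positions, , drop = FALSE], 2, paste, collapse = "")
      data.frame(reporter = r$name, is_control = r$is_control,
                 assigned_reads = sum(assigned$count[sel]),
                 unique_umis = length(unique(umis)))
    } else {
      data.frame(reporter = r$name, is_control = r$is_control,
                 assigned_reads = 0L, unique_umis = 0L)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  totals <- c(input = sum(assigned$count),
              assigned = sum(assigned$count[assigned$reason == "assigned"]),
              low_score = sum(assigned$count[assigned$reason == "low_score"]),
              tie = sum(assigned$count[assigned$reason == "tie"]))
  structure(out, totals = totals, class = c("umi_count_table", "data.frame"))
}

#' Normalize UMI counts to the control reporter (nUMI)
#'
#' nUMI for each target is its unique-UMI count divided by the control
#' reporter's unique-UMI count in the same sample, cancelling sample-level
#' factors such as library pooling depth.
#'
#' @param table A `umi_count_table`.
#' @return Data frame with columns `reporter` and `numi` for the non-control
#'   reporters.
#' @export
normalize_counts <- function(table) {
  ctrl <- sum(table$unique_umis[table$is_control])
  if (ctrl <= 0)
    stop("normalization failure: control reporter has zero unique UMIs")
  tgt <- table[!table$is_control, , drop = FALSE]
  data.frame(reporter = tgt$reporter, numi = tgt$unique_umis / ctrl)
}

#' Expected number of distinct UMIs among n molecules
#'
#' Classic birthday-collision expectation for uniform UMI draws: with `u`
#' possible UMIs and `n` molecules, `u * (1 - (1 - 1/u)^n)` distinct UMIs
#' are expected. Used by the simulator and as a saturation diagnostic.
#'
#' @param n_molecules Number of molecules, >= 0.
#' @param umi_space Number of possible UMI sequences (4^umi_length), >= 1.
#' @return Expected distinct UMI count, `<= min(n_molecules, umi_space)`.
#' @examples
#' expected_unique_umis(1000, 1000)  # ~632.3
#' @export
expected_unique_umis <- function(n_molecules, umi_space) {
  stopifnot(all(n_molecules >= 0), all(umi_space >= 1))
  umi_space * (1 - (1 - 1 / umi_space)^n_molecules)
}

#' Run the full FASTQ-to-nUMI readout pipeline for one sample
#'
#' Quality filter, duplicate collapse, exact-similarity assignment, UMI
#' counting and control normalization in one call.
#'
#' @param fastq Path to a single-sample FASTQ file, or a
#'   `QualityScaledDNAStringSet` already in memory.
#' @param refs A `reporter_reference_set`.
#' @param min_score Assignment threshold (score must be > this; default 31).
#' @param min_phred Per-base quality cutoff (default 20).
#' @return List with `counts` (a `umi_count_table`), `numi` (normalized
#'   counts) and `tally` (read bookkeeping across both stages).
#' @export
count_reporters <- function(fastq, refs, min_score = 31L, min_phred = 20L) {
  reads <- if (is.character(fastq)) read_reporter_fastq(fastq) else fastq
  flt <- quality_filter(reads, min_phred = min_phred)
  collapsed <- collapse_duplicates(flt$kept)
  assigned <- assign_reads(collapsed, refs, min_score = min_score)
  counts <- count_umis(assigned, refs)
  numi <- tryCatch(normalize_counts(counts), error = function(e) NULL)
  list(counts = counts, numi = numi,
       tally = c(flt$tally, attr(counts, "totals")[c("assigned", "low_score", "tie")]))
}
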