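refs2 <- generate_references(2, umi_length = 10, seed = 42)
tmpl1 <- refs2[[1]]$template
umi_pos <- refs2[[1]]$umi_positions
non_umi <- setdiff(seq_len(52), umi_pos)
fill_umi <- function(template, umi = strrep("A", 10)) {
  paste0(substr(template, 1, min(umi_pos) - 1), umi,
         substr(template, max(umi_pos) + 1, 52))
}

test_that("quality filter keeps exactly full-length, high-quality reads", {
  q19 <- rep(30L, 52); q19[17] <- 19L
  reads <- make_reads(c(strrep("A", 52), strrep("C", 51), strrep("G", 52)),
                      qual = list(rep(30L, 52), rep(40L, 51), q19))
  f <- quality_filter(reads)
  expect_equal(as.character(f$kept), strrep("A", 52))
  expect_equal(f$tally[["length_discarded"]], 1)
  expect_equal(f$tally[["quality_discarded"]], 1)
  # conservation: input = kept + discards
  expect_equal(f$tally[["input"]],
               f$tally[["kept"]] + f$tally[["length_discarded"]] +
                 f$tally[["quality_discarded"]])
  # boundary: Phred 20 everywhere passes
  f20 <- quality_filter(make_reads(strrep("T", 52), qual = 20L))
  expect_equal(f20$tally[["kept"]], 1)
})

test_that("duplicate collapse is exact, ordered and idempotent", {
  s1 <- strrep("A", 52); s2 <- strrep("C", 52); s3 <- strrep("G", 52)
  cd <- collapse_duplicates(c(s1, s2, s1, s1, s2, s3))
  expect_equal(cd$sequence, c(s1, s2, s3))  # count desc, then lexicographic
  expect_equal(cd$count, c(3L, 2L, 1L))
  distinct <- collapse_duplicates(c(s3, s1, s2))
  expect_equal(distinct$count, rep(1L, 3))
  expect_equal(distinct$sequence, sort(c(s1, s2, s3)))
  # idempotence on the unique sequences
  expect_equal(collapse_duplicates(cd$sequence)$sequence, sort(cd$sequence))
  # multiset recovery from a deep resample of known templates
  set.seed(7)
  templates <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 52, replace = TRUE), collapse = ""),
    character(1))
  draws <- sample(templates, 5000, replace = TRUE)
  cd2 <- collapse_duplicates(draws)
  expect_equal(sort(cd2$count), sort(as.integer(table(draws))))
})

test_that("similarity score counts exact matches outside the UMI only", {
  read_exact <- fill_umi(tmpl1)
  expect_equal(similarity_score(read_exact, refs2[[1]]), 42)
  expect_equal(similarity_score(strrep("N", 52), refs2[[1]]), 0)
  # mutate 7 of the 42 informative positions -> score 35
  read35 <- fill_umi(rotate_bases(tmpl1, non_umi[c(1, 5, 9, 13, 20, 30, 40)]))
  expect_equal(similarity_score(read35, refs2[[1]]), 35)
  # UMI content is invisible to the score
  expect_equal(similarity_score(fill_umi(tmpl1, strrep("T", 10)), refs2[[1]]), 42)
  expect_error(similarity_score(strrep("A", 51), refs2[[1]]), "52")
})

test_that("assignment applies the strict >31 threshold and discards ties", {
  r1 <- refs2[[1]]
  expect_equal(assign_reads(fill_umi(tmpl1), refs2)$reporter, r1$name)
  # exactly 31 matches: below the strict threshold
  read31 <- fill_umi(rotate_bases(tmpl1, non_umi[1:11]))
  a31 <- assign_reads(read31, refs2)
  expect_equal(similarity_score(read31, r1), 31)
  expect_true(is.na(a31$reporter) && a31$reason == "low_score")
  # 32 matches: assigned
  read32 <- fill_umi(rotate_bases(tmpl1, non_umi[1:10]))
  expect_equal(assign_reads(read32, refs2)$reporter, r1$name)
  # two references tying above threshold are ambiguous
  flip <- non_umi[1:10]
  twin <- reporter_reference("TWIN", rotate_bases(tmpl1, flip))
  refs3 <- reference_set(c(unclass(refs2), list(twin)))
  tie_read <- fill_umi(rotate_bases(tmpl1, flip[1:5]))
  at <- assign_reads(tie_read, refs3)
  expect_equal(similarity_score(tie_read, r1), 37)
  expect_equal(similarity_score(tie_read, twin), 37)
  expect_true(is.na(at$reporter) && at$reason == "tie")
  expect_error(assign_reads(fill_umi(tmpl1), list()), "empty")
})

test_that("UMI counting collapses by UMI within reporter and conserves reads", {
  reads <- c(fill_umi(tmpl1, strrep("A", 10)),
             fill_umi(tmpl1, strrep("C", 10)),           # new UMI -> 2 distinct
             rotate_bases(fill_umi(tmpl1, strrep("A", 10)), non_umi[3]))
  assigned <- assign_reads(collapse_duplicates(reads), refs2)
  tab <- count_umis(assigned, refs2)
  expect_equal(tab$unique_umis[tab$reporter == refs2[[1]]$name], 2L)
  tot <- attr(tab, "totals")
  expect_equal(tot[["input"]],
               tot[["assigned"]] + tot[["low_score"]] + tot[["tie"]])
  expect_true(all(tab$unique_umis <= pmax(tab$assigned_reads, 1)))
})

test_that("the UMI count table is invariant under read permutation", {
  set.seed(33)
  umis <- replicate(50, paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                              collapse = ""))
  reads <- c(vapply(umis, function(u) fill_umi(tmpl1, u), character(1)),
             vapply(umis[1:20], function(u) fill_umi(refs2[[2]]$template, u),
                    character(1)))
  t1 <- count_umis(assign_reads(collapse_duplicates(reads), refs2), refs2)
  t2 <- count_umis(assign_reads(collapse_duplicates(rev(sample(reads))), refs2), refs2)
  expect_equal(t1, t2)
})

test_that("normalization divides by the control reporter's unique UMIs", {
  tab <- structure(
    data.frame(reporter = c("T01", "T02", "CTRL"),
               is_control = c(FALSE, FALSE, TRUE),
               assigned_reads = c(400L, 10L, 150L),
               unique_umis = c(250L, 0L, 100L)),
    class = c("umi_count_table", "data.frame"))
  nm <- normalize_counts(tab)
  expect_equal(nm$numi[nm$reporter == "T01"], 2.5)
  expect_equal(nm$numi[nm$reporter == "T02"], 0)
  tab$unique_umis[3] <- 0L
  expect_error(normalize_counts(tab), "control")
})

test_that("expected unique UMIs follows the collision closed form", {
  expect_equal(expected_unique_umis(0, 1000), 0)
  expect_equal(expected_unique_umis(5, 1), 1)
  expect_equal(expected_unique_umis(1000, 1000), 632.3046, tolerance = 1e-6)
  n <- c(10, 100, 1000, 1e5)
  e <- expected_unique_umis(n, 4^10)
  expect_true(all(e <= pmin(n, 4^10)))
  expect_true(all(diff(e) > 0))
})

test_that("a zero-error channel recovers the generator's UMI truth exactly", {
  cfg <- sim_config(seed = 5, per_base_error = 0, truncate_rate = 0,
                    lowq_rate = 0, reads_per_sample = 20000)
  conc <- c(150, 300, 70) / (cfg$reaction_volume * 6.02214076e23)
  truth <- data.frame(sample = "s1",
                      reporter = c("T01", "T02", "CTRL"), conc = conc)
  truth <- simulate_reads(truth, refs2, cfg, dir = withr::local_tempdir())
  res <- count_reporters(truth$file[1], refs2)
  expect_equal(res$counts$unique_umis[match(truth$reporter, res$counts$reporter)],
               truth$true_unique_umis)
  expect_equal(res$numi$numi[res$numi$reporter == "T01"],
               truth$true_unique_umis[1] / truth$true_unique_umis[3])
})

test_that("under 0.1% per-base error nearly all reads assign to their true reporter", {
  cfg <- sim_config(seed = 9, per_base_error = 0.001, truncate_rate = 0,
                    lowq_rate = 0, reads_per_sample = 20000)
  conc <- c(500, 500, 200) / (cfg$reaction_volume * 6.02214076e23)
  truth <- data.frame(sample = "s1",
                      reporter = c("T01", "T02", "CTRL"), conc = conc)
  truth <- simulate_reads(truth, refs2, cfg, dir = withr::local_tempdir())
  reads <- read_reporter_fastq(truth$file[1])
  kept <- quality_filter(reads)$kept
  origin <- vapply(strsplit(names(kept), ":"), `[`, character(1), 4)
  assigned <- assign_reads(data.frame(sequence = as.character(kept),
                                      count = 1L), refs2)
  correct <- sum(!is.na(assigned$reporter) & assigned$reporter == origin)
  expect_gte(correct / length(kept), 0.99)
})

test_that("reference sets validate structure and round-trip through CSV", {
  expect_error(reference_set(refs2[[1]]), "control")
  path <- withr::local_tempfile(fileext = ".csv")
  write_reporter_refs(refs2, path)
  back <- read_reporter_refs(path)
  expect_equal(vapply(back, `[[`, character(1), "template"),
               vapply(refs2, `[[`, character(1), "template"))
  expect_error(reporter_reference("bad", strrep("A", 51)), "52")
  expect_error(reporter_reference("bad", paste0(strrep("A", 51), "X")), "only contain")
})
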