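small_spec <- function(...) {
  cohort_spec(n_classes = 2, samples_per_class = c(6L, 6L), n_regions = 12,
              signal_regions = integer(0), seed = 3, ...)
}

test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(n_classes = 3, samples_per_class = c(5, 5)),
               "samples_per_class")
  expect_error(cohort_spec(n_classes = 2, samples_per_class = c(5, 5),
                           n_regions = 4, signal_regions = 1:6))
  expect_error(cohort_spec(n_classes = 2, samples_per_class = c(5, 5),
                           dropout_rate = 1.5))
})

test_that("same spec and seed give byte-identical cohorts", {
  a <- generate_cohort(small_spec())
  b <- generate_cohort(small_spec())
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$reference$sequence, b$reference$sequence)
})

test_that("zero rates produce perfect tandem repeats", {
  co <- generate_cohort(small_spec(base_mutation_rate = 0,
                                   pattern_noise_rate = 0, dropout_rate = 0))
  gt <- co$ground_truth
  expect_true(all(gt$present))
  expect_true(all(gt$witness_m == 0))
  perfect <- mapply(function(s, pat, d) identical(s, strrep(pat, d)),
                    gt$region_sequence, gt$pattern, gt$true_d)
  expect_true(all(perfect))
})

test_that("ground-truth histories are replayable and coordinates slice the contig", {
  co <- generate_cohort(small_spec())
  gt <- co$ground_truth[co$ground_truth$present, ]
  sliced <- substring(co$sequences[gt$sample_id], gt$start + 1, gt$end)
  expect_identical(unname(sliced), gt$region_sequence)
})

test_that("dropout marks regions absent at roughly the requested rate", {
  co <- generate_cohort(cohort_spec(n_classes = 2, samples_per_class = c(25L, 25L),
                                    n_regions = 20, signal_regions = integer(0),
                                    dropout_rate = 0.3, seed = 8))
  frac <- mean(!co$ground_truth$present)
  expect_gt(frac, 0.24)
  expect_lt(frac, 0.36)
  gt <- co$ground_truth
  expect_true(all(is.na(gt$start[!gt$present])))
})

test_that("with zero shifts no region separates the classes", {
  co <- generate_cohort(cohort_spec(n_classes = 2, samples_per_class = c(30L, 30L),
                                    n_regions = 25, signal_regions = integer(0),
                                    m_shift = 0, d_shift = 0, seed = 12))
  gt <- co$ground_truth[co$ground_truth$present, ]
  pvals <- vapply(split(gt, gt$region_id), function(r) {
    a <- r$witness_m[r$class == "class01"]
    b <- r$witness_m[r$class == "class02"]
    stats::poisson.test(c(sum(a), sum(b)), c(length(a), length(b)))$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.01 / length(pvals)))  # Bonferroni at alpha = 0.01
})

test_that("planted shifts raise the witness mutation rate only where planted", {
  co <- generate_cohort(cohort_spec(n_classes = 2, samples_per_class = c(40L, 40L),
                                    n_regions = 20, signal_regions = 1:4,
                                    effect_class = 1, m_shift = 3, seed = 13))
  gt <- co$ground_truth[co$ground_truth$present, ]
  gt$signal <- gt$region_id %in% sprintf("r%04d", 1:4)
  mw <- tapply(gt$witness_m, list(gt$class, gt$signal), mean)
  expect_gt(mw["class01", "TRUE"], mw["class02", "TRUE"] + 1.5)
  expect_lt(abs(mw["class01", "FALSE"] - mw["class02", "FALSE"]), 0.5)
})

test_that("cohorts round-trip through the on-disk layout", {
  co <- generate_cohort(small_spec())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "cohort.fasta", "reference.fasta", "labels.tsv",
    "ground_truth.tsv", "cohort_spec.yaml")))))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "cohort.fasta"))
  expect_identical(as.character(seqs), co$sequences)
})
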