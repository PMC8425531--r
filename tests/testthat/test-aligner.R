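test_that("normalized edit distance matches the worked values and the oracle", {
  expect_equal(normalized_edit_distance("CG", "CGTA"), 2 / 3)
  expect_equal(normalized_edit_distance("CG", "CG"), 0)
  expect_equal(normalized_edit_distance("A", "CCC"), 3 / 2)
  expect_error(normalized_edit_distance("", "A"), "non-empty")
  set.seed(31)
  for (i in 1:30) {
    a <- random_pattern(sample(1:8, 1))
    b <- random_pattern(sample(1:8, 1))
    expect_equal(normalized_edit_distance(a, b),
                 oracle_lev(a, b) / ((nchar(a) + nchar(b)) / 2))
    expect_equal(normalized_edit_distance(a, b), normalized_edit_distance(b, a))
    expect_equal(normalized_edit_distance(a, b) == 0, a == b)
  }
})

test_that("the worked profile alignment prefers the gap at the longer pattern", {
  q <- profile_tbl(c("A", "CG"), m = c(0, 1), d = c(7, 4))
  r <- profile_tbl(c("A", "CGTA", "CG"), m = c(0, 0, 1), d = c(8, 3, 3),
                   sample_id = "ref")
  al <- align_profiles(q, r)
  expect_equal(attr(al, "cost"), 0.4)
  expect_equal(attr(al, "n_gaps"), 1L)
  expect_equal(al$matched, c(TRUE, FALSE, TRUE))
  expect_equal(al$m, c(0L, NA, 1L))
  expect_equal(al$d, c(7L, NA, 4L))
})

test_that("self-alignment has zero cost and no gaps", {
  q <- profile_tbl(c("A", "AG", "ACGT", "CCT"), m = 0:3, d = c(4, 5, 6, 7))
  al <- align_profiles(q, q)
  expect_equal(attr(al, "cost"), 0)
  expect_equal(attr(al, "n_gaps"), 0L)
  expect_true(all(al$matched))
})

test_that("the DP cost equals the brute-force minimum on random profiles", {
  set.seed(37)
  for (i in 1:100) {
    nq <- sample(0:8, 1)
    nr <- sample(1:8, 1)
    qpat <- replicate(nq, random_pattern(sample(1:5, 1)))
    rpat <- replicate(nr, random_pattern(sample(1:5, 1)))
    q <- profile_tbl(as.character(qpat), m = rep(0, nq), d = rep(2, nq))
    r <- profile_tbl(as.character(rpat), m = rep(0, nr), d = rep(2, nr),
                     sample_id = "ref")
    expect_equal(alignment_cost(q, r),
                 oracle_align_cost(as.character(qpat), as.character(rpat)),
                 tolerance = 1e-9)
  }
})

test_that("near-equal patterns pair whenever pairing is feasible", {
  # normalized distance below the 0.4 gap cost means pairing beats gapping
  q <- profile_tbl(c("ACGTA"), m = 1, d = 3)
  r <- profile_tbl(c("ACGTT"), m = 0, d = 3, sample_id = "ref")
  al <- align_profiles(q, r)
  expect_lt(normalized_edit_distance("ACGTA", "ACGTT"), 0.4)
  expect_true(al$matched)
})

test_that("the feature matrix interleaves m and d in reference order", {
  q <- profile_tbl(c("A", "CG"), m = c(0, 1), d = c(7, 4))
  r <- profile_tbl(c("A", "CGTA", "CG"), m = c(0, 0, 1), d = c(8, 3, 3),
                   sample_id = "ref")
  mat <- build_matrix(q, r)
  expect_equal(unname(as.numeric(mat[1, -1])), c(0, 7, 0, 0, 1, 4))
  expect_equal(ncol(mat), 1 + 2 * 3)
  expect_equal(attr(mat, "reference_regions"),
               paste0("s:", r$start, "-", r$end))
})

test_that("samples identical to the reference reproduce its index vector", {
  r <- profile_tbl(c("AT", "CCG", "A"), m = c(1, 0, 2), d = c(3, 4, 9),
                   sample_id = "ref")
  q <- r
  q$sample_id <- "q1"
  mat <- build_matrix(q, r)
  expect_equal(unname(as.numeric(mat[1, -1])), c(1, 3, 0, 4, 2, 9))
})

test_that("adding a sample never changes existing rows", {
  r <- profile_tbl(c("AT", "CCG", "AACC"), m = c(1, 0, 2), d = c(3, 4, 9),
                   sample_id = "ref")
  q1 <- profile_tbl(c("AT", "AACC"), m = c(0, 1), d = c(3, 8), sample_id = "q1")
  q2 <- profile_tbl(c("CCG"), m = 2, d = 5, sample_id = "q2")
  m1 <- build_matrix(q1, r)
  m12 <- build_matrix(dplyr::bind_rows(q1, q2), r)
  expect_equal(as.data.frame(m12[m12$sample_id == "q1", ]), as.data.frame(m1))
})

test_that("dropout shows up as near-nominal gap filling in the matrix", {
  co <- generate_cohort(cohort_spec(n_classes = 2, samples_per_class = c(15L, 15L),
                                    n_regions = 20, signal_regions = integer(0),
                                    base_mutation_rate = 0, pattern_noise_rate = 0,
                                    dropout_rate = 0.2, seed = 41))
  profs <- dplyr::bind_rows(lapply(names(co$sequences), function(sid) {
    mutation_profile(detect_repeats(co$sequences[[sid]], seq_id = sid), sid)
  }))
  ref <- mutation_profile(detect_repeats(co$reference$sequence, seq_id = "ref"),
                          "reference")
  mat <- build_matrix(profs, ref, labels = co$labels)
  dcols <- as.matrix(as.data.frame(mat)[grep("^d_", names(mat))])
  gap_frac <- mean(dcols == 0)
  # binomial 99% interval around the 0.2 dropout rate
  ci <- qbinom(c(0.005, 0.995), length(dcols), 0.2) / length(dcols)
  expect_gte(gap_frac, ci[1] - 0.02)
  expect_lte(gap_frac, ci[2] + 0.02)
})

test_that("matrices round-trip through TSV", {
  r <- profile_tbl(c("AT", "CCG"), m = c(1, 0), d = c(3, 4), sample_id = "ref")
  q <- profile_tbl(c("AT", "CCG"), m = c(0, 2), d = c(3, 5), sample_id = "q1")
  mat <- build_matrix(q, r, labels = tibble::tibble(sample_id = "q1", class = "x"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(mat, path)
  back <- read_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(mat))
  expect_equal(attr(back, "reference_regions"), attr(mat, "reference_regions"))
})
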