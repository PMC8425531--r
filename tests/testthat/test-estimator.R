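test_that("block partition reproduces the worked examples", {
  pb <- partition_blocks("ACGTACGTACATAGAT", "ACGT")
  expect_equal(pb$blocks, c("ACGT", "ACGT", "ACAT", "AGAT"))
  expect_equal(pb$d, 4)
  expect_equal(partition_blocks("GTGAGTGAGTGA", "GTGA")$blocks, rep("GTGA", 3))
  expect_equal(partition_blocks("ACGT", "ACGT")$d, 1)
  expect_error(partition_blocks("AC", "ACGT"), "at least as long")
})

test_that("exact and estimated index agree on the worked mutation history", {
  expect_equal(estimate_index_exact("ACGTACGTACATAGAT", 4), list(m = 2, d = 4))
  expect_equal(estimate_index(list(region_sequence = "ACGTACGTACATAGAT",
                                   pattern = "ACGT")),
               list(m = 2, d = 4))
})

test_that("perfect repeats have mutation index zero for every rotation phase", {
  set.seed(7)
  for (i in 1:20) {
    p <- sample(1:6, 1)
    pat <- random_pattern(p)
    d <- sample(2:8, 1)
    seq <- strrep(pat, d)
    rot <- string_rotations(pat)[sample(seq_len(max(p - 1, 1)), 1)]
    idx <- estimate_index(list(region_sequence = seq, pattern = rot))
    expect_equal(idx$m, 0)
  }
})

test_that("the exact search is guarded to small instances", {
  expect_error(estimate_index_exact(strrep("ACGT", 7), 4), "guard")
  expect_error(estimate_index_exact("ACGTACGT", 5), "guard")
})

test_that("exact m is bounded by the distance to the best perfect repeat", {
  # enumeration bound: any 4-fold repeat of a 2-mer is a feasible history
  set.seed(11)
  two_mers <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")), 1,
                    paste, collapse = "")
  for (i in 1:40) {
    s <- random_pattern(8)
    bound <- min(vapply(two_mers, function(w) oracle_lev(s, strrep(w, 4)),
                        numeric(1)))
    expect_lte(estimate_index_exact(s, 2)$m, bound)
  }
})

test_that("the estimator never undercuts the exact minimum and mostly matches it", {
  set.seed(19)
  n_eq <- 0L
  n <- 0L
  while (n < 120) {
    p <- sample(2:4, 1)
    pat <- random_pattern(p)
    h <- simulate_history(pat, sample(1:4, 1),
                          sample(0:3, 1, prob = c(.35, .3, .2, .15)))
    s <- h$final_sequence
    if (nchar(s) > 24 || nchar(s) < p) next
    n <- n + 1L
    g <- estimate_index(list(region_sequence = s, pattern = pat))$m
    e <- estimate_index_exact(s, p)$m
    expect_gte(g, e)
    n_eq <- n_eq + (g == e)
  }
  expect_gte(n_eq / n, 0.9)
})

test_that("one interior substitution raises estimated m by at most one", {
  set.seed(23)
  for (i in 1:20) {
    pat <- random_pattern(sample(2:6, 1))
    d <- sample(3:6, 1)
    seq <- strrep(pat, d)
    pos <- sample(seq_len(nchar(seq) - 2), 1) + 1
    old <- substr(seq, pos, pos)
    mutated <- seq
    substr(mutated, pos, pos) <- sample(setdiff(c("A","C","G","T"), old), 1)
    idx <- estimate_index(list(region_sequence = mutated, pattern = pat))
    expect_lte(idx$m, 1)
  }
})

test_that("estimated m respects the witness bound on simulated regions", {
  co <- generate_cohort(cohort_spec(n_classes = 2, samples_per_class = c(10L, 10L),
                                    n_regions = 25, signal_regions = 1:3,
                                    effect_class = 1, m_shift = 2, seed = 29))
  gt <- co$ground_truth[co$ground_truth$present, ]
  viol <- 0L
  tested <- 0L
  for (sid in unique(gt$sample_id)) {
    cat <- detect_repeats(co$sequences[[sid]], seq_id = sid)
    g <- gt[gt$sample_id == sid, ]
    hit <- match(paste(g$start, g$end), paste(cat$start, cat$end))
    ok <- !is.na(hit)
    ok[ok] <- nchar(cat$pattern[hit[ok]]) == nchar(g$pattern[ok])
    for (k in which(ok)) {
      m <- estimate_index(cat[hit[k], ])$m
      tested <- tested + 1L
      viol <- viol + (m > g$witness_m[k])
    }
  }
  expect_gt(tested, 100)
  expect_equal(viol, 0L)
})

test_that("mutation profiles are coordinate-sorted and serialise losslessly", {
  seq <- paste0("CTGGTTGC", strrep("GTGA", 5), "CGTGCTGCAT",
                strrep("TTAGC", 4), "CGATGCTG")
  prof <- mutation_profile(detect_repeats(seq, seq_id = "s1"), sample_id = "x")
  expect_equal(prof$sample_id, rep("x", nrow(prof)))
  expect_true(!is.unsorted(prof$start))
  expect_true(all(prof$m == 0))
  expect_equal(prof$d, c(5L, 4L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  expect_equal(as.data.frame(read_profile(path)), as.data.frame(prof))
})
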