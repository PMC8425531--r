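test_that("the worked detection example yields the GTGA repeat with 3 copies", {
  out <- detect_repeats("ATGACGTGAGTGAGTGAGT")
  expect_equal(nrow(out), 1)
  expect_equal(out$pattern, canonical_rotation("GTGA"))
  expect_equal(out$copy_count, 3)
  expect_equal(out$region_sequence, "GTGAGTGAGTGA")
  expect_equal(c(out$start, out$end), c(5L, 17L))
})

test_that("repeat-free sequence yields an empty catalog", {
  expect_equal(nrow(detect_repeats("ACGTACGATCGGATCCTAG")), 0)
  expect_equal(nrow(detect_repeats("")), 0)
})

test_that("a homopolymer run embedded in distinct flanks is found exactly", {
  out <- detect_repeats(paste0("CTGGTTGC", strrep("A", 7), "CGTGCTGC"))
  expect_equal(nrow(out), 1)
  expect_equal(out$pattern, "A")
  expect_equal(out$copy_count, 7)
})

test_that("detected regions are disjoint, sorted, and within limits", {
  set.seed(5)
  for (i in 1:10) {
    seq <- paste0(random_pattern(40), strrep(random_pattern(3), 6),
                  random_pattern(35), strrep(random_pattern(5), 4),
                  random_pattern(40))
    out <- detect_repeats(seq)
    if (nrow(out) < 2) next
    expect_true(all(diff(out$start) > 0))
    expect_true(all(utils::head(out$end, -1) <= utils::tail(out$start, -1)))
    expect_true(all(nchar(out$pattern) <= 10))
    expect_true(all(out$copy_count <= 100))
    expect_true(all(out$end - out$start < 1000))
  }
})

test_that("candidate windows containing N are skipped", {
  out <- detect_repeats(paste0("CTGGTTGC", "GTGAGTNAGTGAGTGA", "CGTGCTGC"))
  expect_true(all(!grepl("N", out$region_sequence)))
})

test_that("detection recovers planted perfect repeats with exact boundaries", {
  co <- generate_cohort(cohort_spec(
    n_classes = 2, samples_per_class = c(8L, 8L), n_regions = 30,
    base_mutation_rate = 0, pattern_noise_rate = 0, dropout_rate = 0,
    signal_regions = integer(0), pattern_length_range = c(2, 10), seed = 11))
  gt <- co$ground_truth
  gt <- gt[gt$present & gt$true_d >= 3 & nchar(gt$pattern) * gt$true_d >= 7, ]
  hits <- 0L
  for (sid in names(co$sequences)) {
    cat <- detect_repeats(co$sequences[[sid]], seq_id = sid)
    g <- gt[gt$sample_id == sid, ]
    hits <- hits + sum(paste(g$start, g$end) %in% paste(cat$start, cat$end))
  }
  expect_gte(hits / nrow(gt), 0.95)
})

test_that("TRF tables are parsed, converted and filtered", {
  lines <- c(
    "Sequence: chr_test extra",
    "",
    "Parameters: 2 7 7 80 10 50 500",
    paste("5 16 4 3.0 4 100 0 24 25 25 25 25 2.0 GTGA GTGAGTGAGTGA"),
    paste("30 53 12 2.0 12 95 0 30 25 25 25 25 2.0 ACGTACGTACGT",
          "ACGTACGTACGTACGTACGTACGT"))
  path <- withr::local_tempfile(lines = lines, fileext = ".dat")
  expect_message(out <- read_trf_table(path), "dropped")
  expect_equal(nrow(out), 1)                 # period-12 record filtered out
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(out$seq_id, "chr_test")
  expect_equal(c(out$start, out$end), c(4L, 16L))  # 1-based inclusive -> 0-based half-open
  expect_equal(out$pattern, canonical_rotation("GTGA"))
})

test_that("malformed TRF lines fail with the line number", {
  path <- withr::local_tempfile(lines = c("Sequence: x", "1 2 three"),
                                fileext = ".dat")
  expect_error(read_trf_table(path), "line 2")
})

test_that("catalogs round-trip losslessly through TSV", {
  cat <- detect_repeats(paste0("CTGGTTGC", strrep("GTGA", 5), "CGTGCTGCAT",
                               strrep("TTAGC", 4), "CGATGCTG"), seq_id = "c1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(cat))
  # empty catalog: header-only file
  write_catalog(cat[0, ], path)
  expect_equal(length(readLines(path)), 1)
})
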