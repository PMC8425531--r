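test_that("pure duplication reproduces the copy-number example", {
  h <- simulate_history("GTGA", n_duplications = 2, n_mutations = 0, seed = 1)
  expect_equal(h$final_sequence, "GTGAGTGAGTGA")
  expect_length(h$final_blocks, 3)
})

test_that("a history with no events is the identity", {
  h <- simulate_history("A", 0, 0, seed = 1)
  expect_equal(h$final_sequence, "A")
  expect_equal(nrow(h$events), 0)
})

test_that("replay closure holds across event mixes and seeds", {
  set.seed(42)
  for (i in 1:60) {
    p <- sample(1:8, 1)
    h <- simulate_history(random_pattern(p),
                          n_duplications = sample(0:6, 1),
                          n_mutations = sample(0:4, 1))
    expect_identical(replay_history(h), h$final_sequence)
    expect_identical(oracle_replay(h), h$final_sequence)
  }
})

test_that("event bookkeeping matches the declared counts", {
  h <- simulate_history("ACGT", 3, 2, seed = 9)
  expect_equal(sum(h$events$kind == "duplication"), 3)
  expect_equal(sum(h$events$kind != "duplication"), 2)
  expect_length(h$final_blocks, 4)  # block count = duplications + 1
  expect_identical(paste(h$final_blocks, collapse = ""), h$final_sequence)
})

test_that("invalid patterns are rejected", {
  expect_error(simulate_history("", 1, 0), "pattern")
  expect_error(simulate_history("ACGX", 1, 0), "pattern")
})
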