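#' Partition a repeat region into pattern-length blocks
#'
#' Dynamic-programming partition of a region into consecutive blocks, each
#' scored by its Levenshtein distance to a rotation of the pattern; the
#' partition minimising total distance (ties: block lengths closest to the
#' pattern length, then lexicographically smallest rotation) defines the
#' block structure and the copy number d.  All rotations of the pattern are
#' tried so that the phase of the detected consensus cannot inflate the
#' distance.  Equivalent to cutting the optimal wraparound alignment of the
#' region against cyclic repetitions of the pattern at period boundaries.
#'
#' @param region_sequence Nucleotide string of the region.
#' @param pattern Repeat pattern (length >= 1, at most the region length).
#' @return A list with `blocks` (character vector, concatenating to the
#'   region), `rotation` (the pattern rotation used), `block_distances`, and
#'   `d` (the block count).
#' @examples
#' partition_blocks("ACGTACGTACATAGAT", "ACGT")
#' @export
partition_blocks <- function(region_sequence, pattern) {
  check_region_pattern(region_sequence, pattern)
  res <- cpp_partition_blocks(region_sequence, pattern)
  list(blocks = res$blocks, rotation = res$rotation,
       block_distances = levenshtein(res$blocks, res$rotation),
       d = length(res$blocks))
}

check_region_pattern <- function(region_sequence, pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) < 1) {
    stop("`pattern` must be a non-empty string", call. = FALSE)
  }
  if (!is.character(region_sequence) || length(region_sequence) != 1 ||
      nchar(region_sequence) < nchar(pattern)) {
    stop("region must be at least as long as the pattern", call. = FALSE)
  }
  invisible(TRUE)
}

#' Estimate the mutation index (m, d) of a repeat region
#'
#' The mutation index summarises a region's inferred single-block
#' duplication history: `d` is the copy number (block count of the optimal
#' partition) and `m` the error number, the total count of substitutions,
#' insertions and deletions in the most parsimonious history found.
#'
#' `estimate_index()` is the polynomial-time estimator used throughout the
#' pipeline: it partitions the region into blocks ([partition_blocks()]) and
#' then contracts the block list in reverse-history order -- repeatedly
#' merging the adjacent pair at minimal edit distance (ties: the pair
#' farther from the pattern, then leftmost), charging that distance to m and
#' deleting the pair member farther from the pattern rotation (ties: the
#' right one) -- finally adding the surviving block's distance to its
#' nearest pattern rotation.  The result is an upper bound on the exact
#' minimum, with equality on the vast majority of realistic regions (see
#' the package vignette for the measured equality rate).
#'
#' `estimate_index_exact()` computes the true minimum by exhaustive search
#' over all histories in the event model (any length-p root; duplication of
#' any block to its adjacent right; unit point mutations anywhere, which
#' propagate through later duplications of the mutated block).  The search
#' is exponential in m and guarded to regions of length at most 24 with
#' pattern length at most 4.
#'
#' @param region A single-row repeat catalog tibble (or a list) with fields
#'   `region_sequence` and `pattern`.
#' @param region_sequence,pattern_length Region string and pattern length
#'   for the exact search.
#' @return A list with elements `m` and `d`.
#' @examples
#' estimate_index_exact("ACGTACGTACATAGAT", 4)
#' @export
estimate_index <- function(region) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1)
    region <- as.list(region)
  }
  check_region_pattern(region$region_sequence, region$pattern)
  res <- cpp_greedy_index(region$region_sequence, region$pattern)
  list(m = res$m, d = res$d)
}

#' @rdname estimate_index
#' @export
estimate_index_exact <- function(region_sequence, pattern_length) {
  stopifnot(is.character(region_sequence), length(region_sequence) == 1,
            pattern_length >= 1)
  n <- nchar(region_sequence)
  if (n > 24 || pattern_length > 4) {
    stop("exact search is guarded to regions of length <= 24 and pattern ",
         "length <= 4; use estimate_index() for larger regions", call. = FALSE)
  }
  if (n < pattern_length) stop("region shorter than pattern", call. = FALSE)
  # the greedy estimate is a feasible history, hence an upper bound that
  # also caps the iterative deepening of the exact search
  pat <- substr(region_sequence, 1, pattern_length)
  greedy <- cpp_greedy_index(region_sequence, pat)
  m <- cpp_exact_min_mutations(region_sequence, as.integer(pattern_length),
                               greedy$m)
  list(m = m, d = greedy$d)
}

#' Compute a sample's mutation profile
#'
#' Applies [estimate_index()] to every region of a repeat catalog, yielding
#' the sample's mutation profile: the coordinate-ordered list of
#' (pattern, m, d) over its repeat regions.  Stored per sample, the profile
#' is the feature vector (twice the region count wide once aligned) used by
#' the classification stage.
#'
#' @param catalog A repeat catalog tibble ([detect_repeats()] output).
#' @param sample_id Sample identifier recorded in the profile.
#' @return A tibble with columns `sample_id`, `seq_id`, `start`, `end`,
#'   `pattern`, `m`, `d`, sorted by (`seq_id`, `start`).
#' @export
mutation_profile <- function(catalog, sample_id = "sample") {
  if (nrow(catalog) == 0) {
    return(tibble::tibble(sample_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          pattern = character(), m = integer(), d = integer()))
  }
  idx <- purrr::map2(catalog$region_sequence, catalog$pattern, function(s, p) {
    cpp_greedy_index(s, p)
  })
  tibble::tibble(
    sample_id = sample_id,
    seq_id = catalog$seq_id,
    start = catalog$start,
    end = catalog$end,
    pattern = catalog$pattern,
    m = vapply(idx, function(x) as.integer(x$m), integer(1)),
    d = vapply(idx, function(x) as.integer(x$d), integer(1))
  ) |> dplyr::arrange(.data$seq_id, .data$start)
}

#' Write / read mutation profiles as TSV
#'
#' @param profile A mutation profile tibble (one or several samples).
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()` the
#'   profile tibble.
#' @export
write_profile <- function(profile, path) {
  cols <- c("sample_id", "seq_id", "start", "end", "pattern", "m", "d")
  stopifnot(all(cols %in% names(profile)))
  readr::write_tsv(profile[cols], path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), seq_id = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    pattern = readr::col_character(), m = readr::col_integer(),
    d = readr::col_integer()))
}
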