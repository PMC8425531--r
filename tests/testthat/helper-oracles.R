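# Independent oracles used across the suite.  These deliberately avoid the
# package's own C++ routines so that agreement is informative.

# plain recursive-DP Levenshtein distance
oracle_lev <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(A) + 1, length(B) + 1)
  d[, 1] <- 0:length(A)
  d[1, ] <- 0:length(B)
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      d[i + 1, j + 1] <- min(d[i, j] + (A[i] != B[j]),
                             d[i, j + 1] + 1L, d[i + 1, j] + 1L)
    }
  }
  d[length(A) + 1, length(B) + 1]
}

# exhaustive minimum over all monotone alignments of two profile entry
# lists (recursive enumeration; feasible for <= 8 entries per side)
oracle_align_cost <- function(qpat, rpat, gap = 0.4) {
  ned <- function(a, b) oracle_lev(a, b) / ((nchar(a) + nchar(b)) / 2)
  rec <- function(i, j) {
    if (i > length(qpat)) return((length(rpat) - j + 1) * gap)
    if (j > length(rpat)) return((length(qpat) - i + 1) * gap)
    min(rec(i + 1, j + 1) + ned(qpat[i], rpat[j]),
        rec(i + 1, j) + gap,
        rec(i, j + 1) + gap)
  }
  rec(1, 1)
}

# independent replay of a simulated history (list-of-characters state)
oracle_replay <- function(history) {
  chars <- strsplit(history$root_pattern, "")[[1]]
  blocks <- list(chars)
  ev <- history$events
  for (k in seq_len(nrow(ev))) {
    kind <- ev$kind[k]
    if (kind == "duplication") {
      i <- ev$block_index[k]
      blocks <- append(blocks, blocks[i], after = i)
    } else {
      lens <- lengths(blocks)
      pos <- ev$position[k]
      if (kind == "insertion" && pos > sum(lens)) {
        # appending position: the new base goes after the last character
        b <- length(blocks)
        blocks[[b]] <- c(blocks[[b]], ev$detail[k])
        next
      }
      b <- which(pos <= cumsum(lens))[1]
      off <- pos - c(0, cumsum(lens))[b]
      if (kind == "substitution") {
        blocks[[b]][off] <- ev$detail[k]
      } else if (kind == "deletion") {
        blocks[[b]] <- blocks[[b]][-off]
      } else {
        blocks[[b]] <- append(blocks[[b]], ev$detail[k], after = off - 1)
      }
    }
  }
  paste(unlist(blocks), collapse = "")
}

random_pattern <- function(p) {
  paste(sample(c("A", "C", "G", "T"), p, replace = TRUE), collapse = "")
}

# tiny profile tibble builder
profile_tbl <- function(patterns, m, d, sample_id = "q", seq_id = "s") {
  k <- length(patterns)
  tibble::tibble(sample_id = sample_id, seq_id = seq_id,
                 start = seq(0L, by = 100L, length.out = k),
                 end = seq(0L, by = 100L, length.out = k) + nchar(patterns),
                 pattern = patterns, m = as.integer(m), d = as.integer(d))
}

# small feature matrix with an optional planted mean shift
toy_matrix <- function(n_per_class, classes, n_feat, shift_cols = integer(0),
                       shift_class = classes[1], shift = 0, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(classes, each = n_per_class)
    X <- matrix(rpois(length(lab) * n_feat, 2), length(lab), n_feat,
                dimnames = list(NULL, paste0("f", seq_len(n_feat))))
    X[lab == shift_class, shift_cols] <- X[lab == shift_class, shift_cols] + shift
    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%03d", seq_along(lab)), class = lab),
      tibble::as_tibble(X))
    class(out) <- c("repeatsig_matrix", class(out))
    out
  })
}
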