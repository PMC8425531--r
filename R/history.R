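#' Simulate a single-block duplication history
#'
#' Generates a tandem repeat region through an explicit event process: the
#' root pattern is duplicated block-by-block (each duplication copies one
#' existing block and inserts the copy immediately to its right) and point
#' mutations (substitutions, insertions, deletions) strike uniformly chosen
#' positions.  Duplications and mutations are interleaved uniformly at
#' random, so a mutated block may itself be duplicated later, propagating
#' the change into several copies -- exactly the mechanism that makes
#' parsimonious history reconstruction informative.
#'
#' A deletion that would empty a length-1 block is redirected to an eligible
#' position; when no position is eligible (all blocks of length 1) the event
#' is drawn as a substitution instead, so the witness mutation count always
#' equals `n_mutations`.
#'
#' @param pattern Root pattern (ACGT string, length >= 1).
#' @param n_duplications Number of duplication events (>= 0).
#' @param n_mutations Number of point mutation events (>= 0).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as [generate_cohort()] does).
#' @return An object of class `repeatsig_history`: a list with
#'   `root_pattern`, `events` (a tibble with columns `kind`, `block_index`,
#'   `position`, `detail`), `final_sequence`, and `final_blocks`.
#' @examples
#' h <- simulate_history("GTGA", n_duplications = 2, n_mutations = 0, seed = 1)
#' h$final_sequence
#' @export
simulate_history <- function(pattern, n_duplications, n_mutations, seed = NULL) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) < 1 ||
      grepl("[^ACGT]", pattern)) {
    stop("`pattern` must be a non-empty ACGT string", call. = FALSE)
  }
  stopifnot(n_duplications >= 0, n_mutations >= 0)
  if (!is.null(seed)) withr::local_seed(seed)

  blocks <- list(split_chars(pattern))
  kinds <- sample(c(rep("duplication", n_duplications), rep("mutation", n_mutations)))
  events <- vector("list", length(kinds))

  for (e in seq_along(kinds)) {
    if (kinds[e] == "duplication") {
      i <- sample.int(length(blocks), 1)
      blocks <- append(blocks, blocks[i], after = i)
      events[[e]] <- list(kind = "duplication", block_index = i,
                          position = NA_integer_, detail = NA_character_)
    } else {
      events[[e]] <- apply_random_mutation(blocks)
      blocks <- events[[e]]$blocks
      events[[e]]$blocks <- NULL
    }
  }

  final_blocks <- vapply(blocks, paste, character(1), collapse = "")
  structure(list(
    root_pattern = pattern,
    events = dplyr::bind_rows(lapply(events, tibble::as_tibble)),
    final_sequence = paste(final_blocks, collapse = ""),
    final_blocks = final_blocks
  ), class = "repeatsig_history")
}

# Draw one point mutation on the block list; returns the event record plus
# the updated blocks.  Positions are 1-based over the concatenated sequence.
apply_random_mutation <- function(blocks) {
  lens <- lengths(blocks)
  total <- sum(lens)
  kind <- sample(c("substitution", "insertion", "deletion"), 1)
  if (kind == "deletion" && all(lens == 1)) kind <- "substitution"
  if (kind == "insertion") {
    pos <- sample.int(total + 1, 1)
    base <- sample(DNA_BASES, 1)
    # the new base becomes the pos-th character; position total+1 appends
    at <- locate_insertion(lens, pos)
    blocks[[at$block]] <- append(blocks[[at$block]], base, after = at$offset)
    return(list(kind = "insertion", block_index = at$block, position = pos,
                detail = base, blocks = blocks))
  }
  if (kind == "deletion") {
    eligible <- which(rep(lens >= 2, lens))
    pos <- eligible[sample.int(length(eligible), 1)]
    at <- locate_position(lens, pos)
    blocks[[at$block]] <- blocks[[at$block]][-at$offset]
    return(list(kind = "deletion", block_index = at$block, position = pos,
                detail = NA_character_, blocks = blocks))
  }
  pos <- sample.int(total, 1)
  at <- locate_position(lens, pos)
  old <- blocks[[at$block]][at$offset]
  base <- sample(setdiff(DNA_BASES, old), 1)
  blocks[[at$block]][at$offset] <- base
  list(kind = "substitution", block_index = at$block, position = pos,
       detail = base, blocks = blocks)
}

locate_position <- function(lens, pos) {
  cum <- cumsum(lens)
  b <- which(pos <= cum)[1]
  list(block = b, offset = pos - c(0, cum)[b])
}

locate_insertion <- function(lens, pos) {
  total <- sum(lens)
  if (pos > total) return(list(block = length(lens), offset = lens[length(lens)]))
  at <- locate_position(lens, pos)
  list(block = at$block, offset = at$offset - 1)
}

#' Replay a duplication history from its root
#'
#' Re-executes the recorded events from `root_pattern` and returns the
#' resulting sequence.  For any history produced by [simulate_history()]
#' the replay reproduces `final_sequence` exactly; this is the package's
#' internal consistency check for generated ground truth.
#'
#' @param history A `repeatsig_history` object.
#' @return The replayed sequence (character scalar).
#' @export
replay_history <- function(history) {
  stopifnot(inherits(history, "repeatsig_history"))
  blocks <- list(split_chars(history$root_pattern))
  ev <- history$events
  for (e in seq_len(nrow(ev))) {
    kind <- ev$kind[e]
    if (kind == "duplication") {
      i <- ev$block_index[e]
      blocks <- append(blocks, blocks[i], after = i)
    } else if (kind == "substitution") {
      at <- locate_position(lengths(blocks), ev$position[e])
      blocks[[at$block]][at$offset] <- ev$detail[e]
    } else if (kind == "insertion") {
      at <- locate_insertion(lengths(blocks), ev$position[e])
      blocks[[at$block]] <- append(blocks[[at$block]], ev$detail[e], after = at$offset)
    } else if (kind == "deletion") {
      at <- locate_position(lengths(blocks), ev$position[e])
      blocks[[at$block]] <- blocks[[at$block]][-at$offset]
    } else {
      stop("unknown event kind: ", kind, call. = FALSE)
    }
  }
  paste(vapply(blocks, paste, character(1), collapse = ""), collapse = "")
}

#' @export
print.repeatsig_history <- function(x, ...) {
  cat("<duplication history>\n")
  cat("  root pattern : ", x$root_pattern, "\n", sep = "")
  cat("  events       : ", nrow(x$events), " (",
      sum(x$events$kind == "duplication"), " duplications, ",
      sum(x$events$kind != "duplication"), " mutations)\n", sep = "")
  cat("  final        : ", x$final_sequence, "\n", sep = "")
  invisible(x)
}
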