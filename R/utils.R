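DNA_BASES <- c("A", "C", "G", "T")

#' Levenshtein distance between nucleotide strings
#'
#' Unit-cost edit distance (substitutions, insertions, deletions).
#' Vectorised with recycling over the longer argument.
#'
#' @param a,b Character vectors of sequences.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("CG", "CGTA")
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) > 0, length(b) > 0)
  cpp_levenshtein(a, b)
}

string_rotations <- function(pattern) {
  p <- nchar(pattern)
  if (p == 1) return(pattern)
  unique(vapply(seq_len(p), function(r) {
    paste0(substr(pattern, r, p), substr(pattern, 1, r - 1))
  }, character(1)))
}

#' Canonical rotation of a tandem repeat pattern
#'
#' A tandem pattern is defined only up to rotation (GTGA and TGAG describe
#' the same repeat).  The canonical form is the lexicographically smallest
#' rotation; it is used for all pattern comparisons in the package.
#'
#' @param pattern Character vector of patterns.
#' @return Character vector of canonical rotations.
#' @examples
#' canonical_rotation("GTGA")
#' @export
canonical_rotation <- function(pattern) {
  vapply(pattern, function(p) min(string_rotations(p)), character(1),
         USE.NAMES = FALSE)
}

# Shortest word w such that pattern == w^k; equals pattern when primitive.
primitive_root <- function(pattern) {
  p <- nchar(pattern)
  for (l in seq_len(p - 1)) {
    if (p %% l != 0) next
    w <- substr(pattern, 1, l)
    if (strrep(w, p / l) == pattern) return(w)
  }
  pattern
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# One random unit edit applied to a pattern (used for pattern-variant noise).
random_pattern_variant <- function(pattern) {
  ch <- split_chars(pattern)
  L <- length(ch)
  kind <- sample(c("substitution", "insertion", if (L > 1) "deletion"), 1)
  if (kind == "substitution") {
    i <- sample.int(L, 1)
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  } else if (kind == "insertion") {
    i <- sample.int(L + 1, 1)
    ch <- append(ch, sample(DNA_BASES, 1), after = i - 1)
  } else {
    ch <- ch[-sample.int(L, 1)]
  }
  paste(ch, collapse = "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
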