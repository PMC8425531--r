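#' Detector parameters
#'
#' Size limits and scoring weights for [detect_repeats()].  The size limits
#' (pattern length at most 10, copy number at most 100, hence regions under
#' 1000 nucleotides) bound the search to short tandem repeats /
#' microsatellites.  The scoring weights drive the X-drop extension of
#' seeded candidates: extension accrues `match_weight` per position agreeing
#' with the candidate period and loses `mismatch_weight` per disagreement,
#' and stops once the running score falls `xdrop` below its maximum.
#'
#' @param max_pattern_length Maximum consensus pattern length (default 10).
#' @param max_copy_number Maximum copy number (default 100).
#' @param min_copy_number Minimum copy number for reporting (default 2).
#' @param min_region_length Minimum region length for reporting (default 7).
#'   Plays the role of a detector's minimum alignment score: it suppresses
#'   the very short perfect periodicities (a chance `AA`, `ACA`, ...) that
#'   arise everywhere in random sequence.
#' @param max_region_length Regions must be shorter than this (default 1000).
#' @param match_weight,mismatch_weight,xdrop Extension scoring weights.
#' @return A list of class `repeatsig_detector_params`.
#' @export
detector_params <- function(max_pattern_length = 10L, max_copy_number = 100L,
                            min_copy_number = 2, min_region_length = 7L,
                            max_region_length = 1000L,
                            match_weight = 1, mismatch_weight = 2, xdrop = 4) {
  stopifnot(max_pattern_length >= 1, max_copy_number >= 2,
            min_copy_number >= 2, min_region_length >= 2,
            max_region_length > 2 * max_pattern_length,
            match_weight > 0, mismatch_weight > 0, xdrop > 0)
  structure(list(max_pattern_length = as.integer(max_pattern_length),
                 max_copy_number = as.integer(max_copy_number),
                 min_copy_number = min_copy_number,
                 min_region_length = as.integer(min_region_length),
                 max_region_length = as.integer(max_region_length),
                 match_weight = match_weight,
                 mismatch_weight = mismatch_weight,
                 xdrop = xdrop),
            class = "repeatsig_detector_params")
}

empty_catalog <- function() {
  tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                 pattern = character(), period = integer(),
                 copy_count = numeric(), score = numeric(),
                 region_sequence = character())
}

#' Detect tandem repeat regions in a nucleotide sequence
#'
#' Self-contained short-tandem-repeat detector.  For every candidate period
#' p = 1..`max_pattern_length` it marks the positions agreeing with the
#' sequence p characters earlier, seeds candidates at runs of at least p
#' consecutive agreements (two exact adjacent copies), extends each seed in
#' both directions under X-drop scoring, trims the candidate to a whole
#' number of copies at the offset maximising periodic agreement, and takes
#' the column-wise majority over the pattern-length blocks as the consensus
#' pattern.  Non-primitive consensus patterns are reduced to their shortest
#' period.  Candidates split by an indel's phase shift are re-joined, and
#' overlaps are resolved by the periodicity alignment score (then length,
#' smaller period, leftmost); emitted regions are disjoint, sorted by
#' start, and respect the size limits in `params`.
#'
#' Coordinates are 0-based half-open.  Patterns are reported in canonical
#' rotation (lexicographically smallest).  Candidate windows containing `N`
#' are skipped.
#'
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param seq_id Identifier recorded in the catalog (default "seq").
#' @param params A [detector_params()] object.
#' @return A tibble with columns `seq_id`, `start`, `end`, `pattern`,
#'   `period`, `copy_count`, `score`, `region_sequence`.
#' @examples
#' detect_repeats("ATGACGTGAGTGAGTGAGT")
#' @export
detect_repeats <- function(sequence, seq_id = "seq", params = detector_params()) {
  stopifnot(inherits(params, "repeatsig_detector_params"))
  if (!is.character(sequence) || length(sequence) != 1) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("`sequence` must be over the alphabet {A,C,G,T,N}", call. = FALSE)
  }
  n <- nchar(sequence)
  if (n == 0) return(empty_catalog())
  x <- split_chars(sequence)

  cands <- lapply(seq_len(min(params$max_pattern_length, n %/% 2)),
                  function(p) period_candidates(x, p, params))
  cand <- do.call(rbind, c(list(data.frame(start = integer(), end = integer(),
                                           pattern = character(),
                                           period = integer(),
                                           copy_count = numeric(),
                                           score = numeric())),
                           cands))
  if (nrow(cand) == 0) return(empty_catalog())
  cand <- cand[!duplicated(cand), ]

  # overlap resolution: best-scoring candidate first (the periodicity
  # alignment score, so a long well-fitting period beats a degenerate
  # one), then longer, smaller period, leftmost
  cand <- cand[order(-cand$score, -(cand$end - cand$start), cand$period,
                     cand$start), ]
  keep <- rep(TRUE, nrow(cand))
  taken <- integer(0)
  for (i in seq_len(nrow(cand))) {
    span <- seq.int(cand$start[i] + 1L, cand$end[i])
    if (any(span %in% taken)) keep[i] <- FALSE else taken <- c(taken, span)
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$start), ]
  cand$pattern <- canonical_rotation(cand$pattern)

  # A point mutation interrupts the fixed-phase periodicity: an indel
  # shifts the phase (the consensus of the continuation is a rotation,
  # i.e. the same canonical pattern) and a substitution cluster or a
  # propagated variant yields a one-edit pattern.  Both split one mutated
  # region into adjacent candidates separated by a tiny gap: re-join them,
  # keeping the pattern of the higher-scoring side.
  if (nrow(cand) > 1) {
    keep <- rep(TRUE, nrow(cand))
    cur <- 1L
    for (i in 2L:nrow(cand)) {
      gap <- cand$start[i] - cand$end[cur]
      near <- cand$pattern[i] == cand$pattern[cur] ||
        levenshtein(cand$pattern[i], cand$pattern[cur]) <= 1L
      if (near && gap <= max(cand$period[cur], cand$period[i]) + 4L &&
          (cand$end[i] - cand$start[cur]) < params$max_region_length) {
        if (cand$score[i] > cand$score[cur]) {
          cand$pattern[cur] <- cand$pattern[i]
          cand$period[cur] <- cand$period[i]
        }
        cand$end[cur] <- cand$end[i]
        cand$copy_count[cur] <- (cand$end[cur] - cand$start[cur]) / cand$period[cur]
        cand$score[cur] <- cand$score[cur] + cand$score[i] -
          params$mismatch_weight * max(gap, 0)
        keep[i] <- FALSE
      } else {
        cur <- i
      }
    }
    cand <- cand[keep, ]
    cand <- cand[cand$copy_count <= params$max_copy_number, ]
  }

  tibble::tibble(
    seq_id = seq_id,
    start = cand$start,
    end = cand$end,
    pattern = cand$pattern,
    period = cand$period,
    copy_count = cand$copy_count,
    score = cand$score,
    region_sequence = substring(sequence, cand$start + 1L, cand$end)
  )
}

# Candidates for one period: seed at runs of >= p matches, X-drop extend,
# trim to whole copies, build majority consensus, apply filters.
period_candidates <- function(x, p, params) {
  n <- length(x)
  idx <- (p + 1):n
  match <- x[idx] == x[idx - p] & x[idx] != "N" & x[idx - p] != "N"
  r <- rle(match)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seeds <- which(r$values & r$lengths >= p)
  o_start <- integer(0); o_end <- integer(0); o_pat <- character(0)
  o_per <- integer(0); o_cp <- numeric(0); o_sc <- numeric(0)
  seen <- character(0)
  for (s in seeds) {
    a <- starts[s]; b <- ends[s]
    # X-drop extension over the match indicator
    b <- xdrop_extend(match, b, +1L, params)
    a <- xdrop_extend(match, a, -1L, params)
    # match index i covers sequence positions i..i+p (1-based), so the
    # candidate sequence interval is [a, b + p] inclusive
    cs <- a; ce <- b + p
    len <- ce - cs + 1L
    if (len < max(2L * p, params$min_region_length)) next
    # trim to a whole number of copies at the best offset
    k <- len %/% p
    r0 <- len - k * p
    if (r0 > 0) {
      best_off <- 0L; best_sc <- -1L
      for (off in 0:r0) {
        w0 <- cs + off; w1 <- w0 + k * p - 1L
        sc <- sum(match[seq.int(w0, w1 - p)])  # match[i] covers positions i..i+p
        if (sc > best_sc) { best_sc <- sc; best_off <- off }
      }
      cs <- cs + best_off; ce <- cs + k * p - 1L
      if (ce - cs + 1L < max(2L * p, params$min_region_length)) next
    }
    key <- paste(cs, ce)
    if (key %in% seen) next
    seen <- c(seen, key)
    seg <- x[cs:ce]
    if (any(seg == "N")) next
    cons <- majority_consensus(seg, p)
    root <- primitive_root(cons)
    period <- nchar(root)
    copies <- (ce - cs + 1L) / period
    if (period > params$max_pattern_length) next
    if (copies < params$min_copy_number || copies > params$max_copy_number) next
    if (ce - cs + 1L >= params$max_region_length) next
    # periodicity alignment score; non-positive candidates are noise
    nmatch <- sum(match[seq.int(cs, ce - p)])
    score <- nmatch * params$match_weight -
      (ce - cs + 1L - p - nmatch) * params$mismatch_weight
    if (score <= 0) next
    o_start <- c(o_start, cs - 1L); o_end <- c(o_end, ce)
    o_pat <- c(o_pat, root); o_per <- c(o_per, as.integer(period))
    o_cp <- c(o_cp, copies); o_sc <- c(o_sc, score)
  }
  data.frame(start = o_start, end = o_end, pattern = o_pat,
             period = o_per, copy_count = o_cp, score = o_sc)
}

xdrop_extend <- function(match, pos, dir, params) {
  score <- 0; best <- 0; best_pos <- pos
  i <- pos + dir
  while (i >= 1 && i <= length(match)) {
    score <- score + if (match[i]) params$match_weight else -params$mismatch_weight
    if (score > best) { best <- score; best_pos <- i }
    if (score < best - params$xdrop) break
    i <- i + dir
  }
  best_pos
}

majority_consensus <- function(seg, p) {
  code <- match(seg, DNA_BASES)
  pos <- rep_len(seq_len(p), length(seg))
  # per pattern position, the most frequent base; ties alphabetical
  # (which.max over counts in A,C,G,T order)
  paste(vapply(seq_len(p), function(i) {
    DNA_BASES[which.max(tabulate(code[pos == i], nbins = 4L))]
  }, character(1)), collapse = "")
}

#' Read a Tandem Repeat Finder data table
#'
#' Parses the whitespace-separated data-line dialect of TRF `.dat` output
#' (fields: start, end, period size, copy number, consensus size, percent
#' matches, percent indels, score, A/C/G/T composition, entropy, consensus
#' pattern, region sequence; `Sequence:` header lines set the sequence id).
#' Coordinates are converted from 1-based inclusive to 0-based half-open.
#' Records violating the catalog limits (pattern length > 10, copies > 100,
#' region length >= 1000) are dropped; the number dropped is reported in a
#' message and attached as attribute `n_dropped`.
#'
#' @param path Path to a TRF `.dat` file.
#' @param params A [detector_params()] object supplying the limits.
#' @return A repeat catalog tibble as from [detect_repeats()].
#' @export
read_trf_table <- function(path, params = detector_params()) {
  lines <- readLines(path, warn = FALSE)
  seq_id <- "seq"
  recs <- list()
  dropped <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "Parameters:")) next
    if (startsWith(line, "Sequence:")) {
      seq_id <- trimws(sub("^Sequence:", "", line))
      seq_id <- strsplit(seq_id, "\\s+")[[1]][1]
      next
    }
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) < 15 || anyNA(suppressWarnings(as.numeric(f[1:13])))) {
      stop("malformed TRF record at line ", ln, call. = FALSE)
    }
    start <- as.integer(f[1]) - 1L
    end <- as.integer(f[2])
    period <- as.integer(f[3])
    copies <- as.numeric(f[4])
    pattern <- f[14]
    regseq <- f[15]
    if (period > params$max_pattern_length || copies > params$max_copy_number ||
        (end - start) >= params$max_region_length) {
      dropped <- dropped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- tibble::tibble(
      seq_id = seq_id, start = start, end = end,
      pattern = canonical_rotation(pattern), period = period,
      copy_count = copies, score = as.numeric(f[8]),
      region_sequence = regseq)
  }
  out <- if (length(recs)) dplyr::bind_rows(recs) else empty_catalog()
  if (dropped > 0) message(dropped, " TRF record(s) outside catalog limits dropped")
  attr(out, "n_dropped") <- dropped
  out
}

#' Write / read a repeat catalog as TSV
#'
#' Plain tab-separated serialisation of a repeat catalog with a header and
#' stable column order; `read_catalog(write_catalog(x))` is lossless.
#'
#' @param regions A repeat catalog tibble.
#' @param path Output (input) file path.
#' @return `write_catalog()` returns `path` invisibly; `read_catalog()`
#'   returns the catalog tibble.
#' @export
write_catalog <- function(regions, path) {
  cols <- c("seq_id", "start", "end", "pattern", "period", "copy_count",
            "score", "region_sequence")
  stopifnot(all(cols %in% names(regions)))
  readr::write_tsv(regions[cols], path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    seq_id = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), pattern = readr::col_character(),
    period = readr::col_integer(), copy_count = readr::col_double(),
    score = readr::col_double(), region_sequence = readr::col_character()))
}
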