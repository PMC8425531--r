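#' Alignment parameters
#'
#' Costs for the profile-alignment dynamic program.  `gap_cost` is the
#' fixed cost of pairing a pattern with a missing pattern ('-'); 0.4 by
#' construction, so two patterns at normalized edit distance below 0.4 are
#' effectively treated as equal while more distant ones are better left
#' unpaired.  `match_threshold` records that convention.
#'
#' @param gap_cost Cost of an unpaired entry (default 0.4).
#' @param match_threshold Normalized distance below which patterns count as
#'   equal (default 0.4).
#' @return A list of class `repeatsig_align_params`.
#' @export
align_params <- function(gap_cost = 0.4, match_threshold = 0.4) {
  stopifnot(gap_cost > 0, gap_cost <= 1, match_threshold > 0, match_threshold <= 1)
  structure(list(gap_cost = gap_cost, match_threshold = match_threshold),
            class = "repeatsig_align_params")
}

#' Normalized edit distance between two patterns
#'
#' Levenshtein distance divided by the average length of the two patterns:
#' `lev(a, b) / ((|a| + |b|) / 2)`.  Symmetric, zero iff the patterns are
#' equal, and at most 2.  Missing patterns are not handled here -- they are
#' charged `gap_cost` by the alignment.
#'
#' @param a,b Pattern strings (vectorised, recycled).
#' @return Numeric vector of distances in `[0, 2]`.
#' @examples
#' normalized_edit_distance("CG", "CGTA")  # 2/3
#' @export
normalized_edit_distance <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("patterns must be non-empty; missing patterns are handled by the ",
         "alignment gap cost", call. = FALSE)
  }
  cpp_levenshtein(a, b) / ((nchar(a) + nchar(b)) / 2)
}

#' Align a mutation profile against a reference profile
#'
#' Global monotone alignment of the query's repeat regions against the
#' reference's, minimising the total cost: the sum of normalized edit
#' distances between paired patterns plus `gap_cost` for every unpaired
#' entry on either side.  Ties are broken in favour of fewer gaps, then by
#' a deterministic traceback that places gaps leftmost.  Entries are
#' matched within the same sequence when the two profiles share sequence
#' ids; two single-contig profiles are aligned directly.
#'
#' The result keeps the reference's region order: one row per reference
#' entry carrying the aligned query pattern and its (m, d), or a gap.
#' Query-only entries (regions missing from the reference) are dropped.
#' The optimal total cost and gap count are attached as attributes `cost`
#' and `n_gaps` (the cost includes gaps charged to dropped query entries).
#'
#' @param query,reference Mutation profile tibbles ([mutation_profile()]).
#' @param params An [align_params()] object.
#' @return A tibble with columns `region_id`, `ref_pattern`, `pattern`,
#'   `m`, `d`, `matched`, plus attributes `cost` and `n_gaps`.
#' @export
align_profiles <- function(query, reference, params = align_params()) {
  stopifnot(inherits(params, "repeatsig_align_params"))
  if (nrow(reference) == 0) stop("reference profile is empty", call. = FALSE)
  ref_ids <- unique(reference$seq_id)
  qry_ids <- unique(query$seq_id)
  if (!setequal(ref_ids, qry_ids)) {
    if (length(ref_ids) == 1 && length(qry_ids) <= 1) {
      # single-contig profiles align regardless of contig naming
      query$seq_id <- ref_ids
    } else {
      stop("profiles cover different sequence ids; cannot align", call. = FALSE)
    }
  }
  out <- vector("list", length(ref_ids))
  cost <- 0
  gaps <- 0L
  for (k in seq_along(ref_ids)) {
    r <- reference[reference$seq_id == ref_ids[k], ]
    r <- r[order(r$start), ]
    q <- query[query$seq_id == ref_ids[k], ]
    q <- q[order(q$start), ]
    al <- align_entry_lists(q, r, params)
    out[[k]] <- al$rows
    cost <- cost + al$cost
    gaps <- gaps + al$n_gaps
  }
  res <- dplyr::bind_rows(out)
  attr(res, "cost") <- cost
  attr(res, "n_gaps") <- gaps
  res
}

# Needleman-Wunsch over profile entries with (cost, gap-count) lexicographic
# objective; traceback prefers pairing, then a reference gap, then a query
# gap, which places gaps leftmost in the forward direction.
align_entry_lists <- function(q, r, params) {
  nq <- nrow(q)
  nr <- nrow(r)
  g <- params$gap_cost
  ned <- if (nq > 0) outer(seq_len(nq), seq_len(nr), function(i, j) {
    normalized_edit_distance(q$pattern[i], r$pattern[j])
  }) else matrix(0, 0, nr)

  C <- matrix(0, nq + 1, nr + 1)     # cost
  G <- matrix(0L, nq + 1, nr + 1)    # gap count
  C[1, ] <- g * (0:nr); G[1, ] <- 0:nr
  C[, 1] <- g * (0:nq); G[, 1] <- 0:nq
  for (i in seq_len(nq)) {
    for (j in seq_len(nr)) {
      cand_c <- c(C[i, j] + ned[i, j], C[i, j + 1] + g, C[i + 1, j] + g)
      cand_g <- c(G[i, j], G[i, j + 1] + 1L, G[i + 1, j] + 1L)
      best <- order(cand_c, cand_g)[1]
      C[i + 1, j + 1] <- cand_c[best]
      G[i + 1, j + 1] <- cand_g[best]
    }
  }
  # traceback
  pair <- rep(NA_integer_, nr)  # query row paired to each reference row
  i <- nq; j <- nr
  eps <- 1e-9
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(C[i + 1, j + 1] - (C[i, j] + ned[i, j])) < eps &&
        G[i + 1, j + 1] == G[i, j]) {
      pair[j] <- i; i <- i - 1; j <- j - 1
    } else if (j > 0 && abs(C[i + 1, j + 1] - (C[i + 1, j] + g)) < eps &&
               G[i + 1, j + 1] == G[i + 1, j] + 1L) {
      j <- j - 1
    } else {
      i <- i - 1
    }
  }
  rows <- tibble::tibble(
    region_id = paste0(r$seq_id, ":", r$start, "-", r$end),
    ref_pattern = r$pattern,
    pattern = ifelse(is.na(pair), NA_character_, q$pattern[pair]),
    m = ifelse(is.na(pair), NA_integer_, q$m[pair]),
    d = ifelse(is.na(pair), NA_integer_, q$d[pair]),
    matched = !is.na(pair))
  list(rows = rows, cost = C[nq + 1, nr + 1], n_gaps = G[nq + 1, nr + 1])
}

#' Optimal alignment cost between two profiles
#'
#' Convenience wrapper returning only the total cost of the optimal
#' alignment computed by [align_profiles()].
#'
#' @inheritParams align_profiles
#' @return The optimal total alignment cost (numeric scalar).
#' @export
alignment_cost <- function(query, reference, params = align_params()) {
  attr(align_profiles(query, reference, params), "cost")
}

#' Build the aligned feature matrix for a set of samples
#'
#' Aligns every sample's mutation profile against the reference profile and
#' assembles the fixed-width feature table: per reference region k two
#' columns, `m_<region k>` and `d_<region k>`, interleaved in reference
#' order; unmatched reference regions contribute the fill value (0, 0).
#' Column names derive from the reference region ids, so the feature layout
#' is identical for every sample and stable when samples are added.
#'
#' @param profiles A mutation profile tibble covering one or more samples
#'   (distinguished by `sample_id`).
#' @param reference The reference mutation profile.
#' @param params An [align_params()] object.
#' @param labels Optional label tibble (`sample_id`, `class`) merged into
#'   the result.
#' @return A tibble of class `repeatsig_matrix`: `sample_id`, optional
#'   `class`, then `2 * R` numeric feature columns.  The reference region
#'   ids are attached as attribute `reference_regions`.
#' @export
build_matrix <- function(profiles, reference, params = align_params(),
                         labels = NULL) {
  if (nrow(reference) == 0) stop("reference profile is empty", call. = FALSE)
  ids <- unique(profiles$sample_id)
  if (length(ids) == 0) stop("no profiles supplied", call. = FALSE)
  ref_sorted <- reference[order(reference$seq_id, reference$start), ]
  region_ids <- paste0(ref_sorted$seq_id, ":", ref_sorted$start, "-", ref_sorted$end)
  rows <- lapply(ids, function(sid) {
    al <- align_profiles(profiles[profiles$sample_id == sid, ], reference, params)
    al <- al[match(region_ids, al$region_id), ]
    v <- as.numeric(rbind(ifelse(al$matched, al$m, 0),
                          ifelse(al$matched, al$d, 0)))
    setNames(v, paste0(rep(c("m_", "d_"), length(region_ids)),
                       rep(region_ids, each = 2)))
  })
  mat <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = ids), mat)
  if (!is.null(labels)) {
    out <- dplyr::left_join(out, labels[c("sample_id", "class")], by = "sample_id")
    out <- dplyr::relocate(out, "class", .after = "sample_id")
  }
  attr(out, "reference_regions") <- region_ids
  class(out) <- c("repeatsig_matrix", class(out))
  out
}

#' Write / read an aligned feature matrix as TSV
#'
#' @param matrix A `repeatsig_matrix` tibble.
#' @param path File path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` the
#'   matrix tibble (reconstructing the `reference_regions` attribute from
#'   the column names).
#' @export
write_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_guess()))
  feat <- grep("^m_", names(out), value = TRUE)
  attr(out, "reference_regions") <- sub("^m_", "", feat)
  class(out) <- c("repeatsig_matrix", class(out))
  out
}
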