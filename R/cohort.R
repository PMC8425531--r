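#' Specification of a synthetic cohort
#'
#' Generative parameters for [generate_cohort()].  The defaults emulate the
#' structure of the blood-derived whole-exome cohort the package's analysis
#' is designed for: eleven sample classes with a few hundred samples each,
#' one "signature" class whose point-mutation load is shifted in a small
#' planted subset of repeat regions, per-region duplication and mutation
#' event counts drawn from Poisson laws, occasional region dropout, and
#' occasional one-edit pattern variants.  Tests and examples override the
#' sizes downwards; the generative law is unchanged.
#'
#' Per sample and region, the duplication count is `1 + rpois(lambda_d - 1)`
#' (so every present region has at least two copies) and the mutation count
#' `rpois(lambda_m)`, where the lambdas are the base rates plus the class
#' shift in signal regions for the effect class.
#'
#' @param n_classes Number of classes.
#' @param samples_per_class Integer vector of class sizes (length
#'   `n_classes`); names, when present, become the class labels.
#' @param n_regions Number of repeat regions R.
#' @param pattern_length_range Inclusive range of pattern lengths.
#' @param base_duplication_count Expected duplications per region (>= 1).
#' @param base_mutation_rate Expected point mutations per region.
#' @param signal_regions Region ordinals carrying the class effect.
#' @param effect_class Ordinal of the signature class.
#' @param m_shift,d_shift Additive shifts of the expected mutation /
#'   duplication counts in signal regions for the effect class.
#' @param dropout_rate Probability that a region is absent from a sample.
#' @param pattern_noise_rate Probability that a sample's region pattern
#'   carries a one-edit variant.
#' @param spacer_length_range Length range of the non-repetitive spacers
#'   separating regions (minimum 30 nt).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return A list of class `repeatsig_cohort_spec`.
#' @export
cohort_spec <- function(n_classes = 11L,
                        samples_per_class = c(344L, 153L, 396L, 393L, 440L, 513L,
                                              411L, 432L, 316L, 190L, 255L),
                        n_regions = 100L,
                        pattern_length_range = c(1L, 10L),
                        base_duplication_count = 5,
                        base_mutation_rate = 1,
                        signal_regions = 1:10,
                        effect_class = 1L,
                        m_shift = 3,
                        d_shift = 0,
                        dropout_rate = 0.1,
                        pattern_noise_rate = 0.05,
                        spacer_length_range = c(30L, 50L),
                        seed = 1L) {
  if (length(samples_per_class) != n_classes) {
    stop("`samples_per_class` must have `n_classes` entries", call. = FALSE)
  }
  stopifnot(n_regions >= 1,
            length(pattern_length_range) == 2,
            pattern_length_range[1] >= 1,
            pattern_length_range[2] >= pattern_length_range[1],
            base_duplication_count >= 1, base_mutation_rate >= 0,
            m_shift >= 0, d_shift >= 0,
            dropout_rate >= 0, dropout_rate <= 1,
            pattern_noise_rate >= 0, pattern_noise_rate <= 1,
            spacer_length_range[1] >= 30,
            effect_class >= 1, effect_class <= n_classes)
  if (length(signal_regions) > 0) {
    stopifnot(all(signal_regions >= 1), all(signal_regions <= n_regions))
  }
  classes <- names(samples_per_class) %||% sprintf("class%02d", seq_len(n_classes))
  structure(list(
    n_classes = as.integer(n_classes),
    samples_per_class = as.integer(samples_per_class),
    classes = classes,
    n_regions = as.integer(n_regions),
    pattern_length_range = as.integer(pattern_length_range),
    base_duplication_count = base_duplication_count,
    base_mutation_rate = base_mutation_rate,
    signal_regions = as.integer(signal_regions),
    effect_class = as.integer(effect_class),
    m_shift = m_shift, d_shift = d_shift,
    dropout_rate = dropout_rate,
    pattern_noise_rate = pattern_noise_rate,
    spacer_length_range = as.integer(spacer_length_range),
    seed = as.integer(seed)
  ), class = "repeatsig_cohort_spec")
}

#' Generate a synthetic cohort with ground-truth histories
#'
#' Builds one contig per sample by concatenating its present repeat regions,
#' each produced by [simulate_history()] under the class's event rates,
#' separated by random non-repetitive spacers (rejection-sampled until the
#' detector finds no repeat in them, so region boundaries are unambiguous).
#' Alongside the sequences it returns the complete ground truth -- the
#' witness mutation count, true block count, generating pattern and
#' coordinates of every present region -- and a zero-mutation ancestor
#' sequence that serves as the cohort's reference genome for profile
#' alignment.  Deterministic under a fixed spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `repeatsig_cohort` with elements
#'   `sequences` (named character vector, one contig per sample),
#'   `labels` (tibble: `sample_id`, `class`),
#'   `ground_truth` (tibble: `sample_id`, `class`, `region_id`, `present`,
#'   `pattern`, `root_pattern`, `witness_m`, `true_d`, `start`, `end`),
#'   `reference` (list with `sequence` and a `regions` tibble), and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_classes = 2, samples_per_class = c(3, 3), n_regions = 5, seed = 7))
#' cohort$labels
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "repeatsig_cohort_spec"))
  withr::local_seed(spec$seed)
  params <- detector_params()

  regions <- tibble::tibble(
    region_id = sprintf("r%04d", seq_len(spec$n_regions)),
    pattern = replicate(spec$n_regions, random_primitive_pattern(spec$pattern_length_range)),
    signal = seq_len(spec$n_regions) %in% spec$signal_regions
  )

  labels <- tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(sum(spec$samples_per_class))),
    class = rep(spec$classes, spec$samples_per_class)
  )

  pool <- spacer_pool(spec, params, n_pool = max(64L, 2L * spec$n_regions))

  # reference (ancestor): every region as a perfect repeat at the expected
  # copy number, with its own repeat-free spacers
  d_ref <- max(2L, as.integer(round(1 + spec$base_duplication_count)))
  ref <- assemble_sample(regions$pattern, rep(d_ref - 1L, spec$n_regions),
                         rep(0L, spec$n_regions), rep(TRUE, spec$n_regions),
                         spec, params, pool)
  reference <- list(
    sequence = ref$sequence,
    regions = tibble::tibble(region_id = regions$region_id,
                             pattern = regions$pattern,
                             copies = d_ref,
                             start = ref$start, end = ref$end))

  gt <- vector("list", nrow(labels))
  seqs <- character(nrow(labels))
  for (i in seq_len(nrow(labels))) {
    is_effect <- labels$class[i] == spec$classes[spec$effect_class]
    lam_m <- spec$base_mutation_rate + ifelse(regions$signal & is_effect, spec$m_shift, 0)
    lam_d <- spec$base_duplication_count + ifelse(regions$signal & is_effect, spec$d_shift, 0)
    n_dup <- 1L + rpois(spec$n_regions, pmax(lam_d - 1, 0))
    n_mut <- rpois(spec$n_regions, lam_m)
    present <- stats::runif(spec$n_regions) >= spec$dropout_rate
    pat <- regions$pattern
    noisy <- stats::runif(spec$n_regions) < spec$pattern_noise_rate
    pat[noisy] <- vapply(pat[noisy], random_pattern_variant, character(1))
    asm <- assemble_sample(pat, n_dup, n_mut, present, spec, params, pool)
    seqs[i] <- asm$sequence
    gt[[i]] <- tibble::tibble(
      sample_id = labels$sample_id[i], class = labels$class[i],
      region_id = regions$region_id, present = present,
      pattern = pat, root_pattern = regions$pattern,
      witness_m = ifelse(present, n_mut, NA_integer_),
      true_d = ifelse(present, n_dup + 1L, NA_integer_),
      start = asm$start, end = asm$end,
      region_sequence = asm$region_sequence)
  }
  names(seqs) <- labels$sample_id

  structure(list(sequences = seqs, labels = labels,
                 ground_truth = dplyr::bind_rows(gt),
                 reference = reference, spec = spec),
            class = "repeatsig_cohort")
}

# Simulate the present regions and join them with repeat-free spacers drawn
# from the cohort's verified pool.  Returns the contig plus 0-based
# half-open region coordinates (NA when the region is absent).
assemble_sample <- function(patterns, n_dup, n_mut, present, spec, params,
                            spacer_pool) {
  R <- length(patterns)
  region_seq <- rep(NA_character_, R)
  for (r in which(present)) {
    h <- simulate_history(patterns[r], n_dup[r], n_mut[r])
    region_seq[r] <- h$final_sequence
  }
  parts <- character(0)
  start <- rep(NA_integer_, R)
  end <- rep(NA_integer_, R)
  at <- 0L
  prev_seq <- NULL
  prev_p <- NULL
  for (r in seq_len(R)) {
    nxt <- if (present[r]) region_seq[r] else NULL
    nxt_p <- if (present[r]) nchar(patterns[r]) else NULL
    sp <- pick_spacer(spacer_pool, prev_seq, prev_p, nxt, nxt_p)
    parts <- c(parts, sp)
    at <- at + nchar(sp)
    if (present[r]) {
      parts <- c(parts, region_seq[r])
      start[r] <- at
      at <- at + nchar(region_seq[r])
      end[r] <- at
      prev_seq <- region_seq[r]
      prev_p <- nchar(patterns[r])
    } else {
      prev_seq <- NULL
    }
  }
  parts <- c(parts, pick_spacer(spacer_pool, prev_seq, prev_p, NULL, NULL))
  list(sequence = paste(parts, collapse = ""), start = start, end = end,
       region_sequence = region_seq)
}

# Draw a pool spacer whose junction with the flanking regions breaks their
# periodicity for at least 4 positions on each side, so a planted region
# cannot be extended past its true boundary by a chance junction match.
pick_spacer <- function(pool, prev_seq, prev_p, next_seq, next_p) {
  for (try in seq_len(200)) {
    sp <- pool[sample.int(length(pool), 1)]
    ok <- (is.null(prev_seq) || junction_breaks_right(prev_seq, prev_p, sp)) &&
          (is.null(next_seq) || junction_breaks_left(sp, next_seq, next_p))
    if (ok) return(sp)
  }
  sp  # extremely unlikely; a soft boundary costs recall, not correctness
}

# spacer t followed by region r with period p: the last 4 positions of t
# must each disagree with the character p later in the joined string
junction_breaks_left <- function(t, r, p) {
  u <- split_chars(paste0(t, r))
  lt <- nchar(t)
  for (i in 1:4) {
    a <- lt - i + 1L
    if (a < 1 || a + p > length(u)) break
    if (u[a] == u[a + p]) return(FALSE)
  }
  TRUE
}

# region r with period p followed by spacer t: the first 4 positions of t
# must each disagree with the character p earlier in the joined string
junction_breaks_right <- function(r, p, t) {
  u <- split_chars(paste0(r, t))
  lr <- nchar(r)
  for (j in 1:4) {
    b <- lr + j
    if (b > length(u) || b - p < 1) break
    if (u[b] == u[b - p]) return(FALSE)
  }
  TRUE
}

# Pool of spacers rejection-sampled until the detector finds no repeat in
# them, so planted region boundaries stay unambiguous.
spacer_pool <- function(spec, params, n_pool) {
  lens <- seq.int(spec$spacer_length_range[1], spec$spacer_length_range[2])
  vapply(seq_len(n_pool), function(i) {
    for (try in 1:1000) {
      sp <- random_dna(lens[sample.int(length(lens), 1)])
      if (nrow(detect_repeats(sp, params = params)) == 0) return(sp)
    }
    stop("could not sample a repeat-free spacer", call. = FALSE)
  }, character(1))
}

random_primitive_pattern <- function(range) {
  lens <- seq.int(range[1], range[2])
  repeat {
    p <- random_dna(lens[sample.int(length(lens), 1)])
    if (primitive_root(p) == p) return(p)
  }
}

#' Write a cohort to disk
#'
#' Writes the per-sample FASTA (one record per sample), the reference FASTA,
#' the label table and the ground-truth table into a directory, and the
#' cohort spec as YAML.
#'
#' @param cohort A `repeatsig_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "repeatsig_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$sequences),
                              file.path(dir, "cohort.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(reference = cohort$reference$sequence)),
    file.path(dir, "reference.fasta"))
  readr::write_tsv(cohort$labels, file.path(dir, "labels.tsv"))
  readr::write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  spec <- cohort$spec
  yaml::write_yaml(unclass(spec), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' @export
print.repeatsig_cohort <- function(x, ...) {
  cat("<synthetic cohort> ", length(x$sequences), " samples, ",
      x$spec$n_regions, " regions, ", x$spec$n_classes, " classes\n", sep = "")
  invisible(x)
}
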