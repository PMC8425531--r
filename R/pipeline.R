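#' Pipeline configuration
#'
#' Assembles the stage parameters of the end-to-end run: simulate (or load)
#' a cohort, detect repeat regions, estimate mutation indices, align
#' profiles against the reference, and train the classifiers.  Stages are
#' executed in that fixed order; completed stages are skipped on re-run
#' when their inputs are unchanged (checksum-based), so a run is resumable.
#'
#' When `fasta` and `labels_file` are given the simulate stage is skipped
#' and sequences are read from disk (`reference_fasta` supplies the
#' reference contig).
#'
#' @param output_dir Directory receiving all stage outputs and the manifest.
#' @param cohort A [cohort_spec()] (used unless `fasta` is supplied).
#' @param fasta,labels_file,reference_fasta Optional paths to an existing
#'   multi-record sample FASTA, a two-column label TSV and a reference
#'   FASTA.
#' @param detector A [detector_params()].
#' @param align A [align_params()].
#' @param classifier A [classifier_config()].
#' @param mode Classifier mode: "pairwise", "multiclass" or "both".
#' @param seed Global seed; stage seeds derive from it.
#' @return A list of class `repeatsig_pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            cohort = cohort_spec(),
                            fasta = NULL, labels_file = NULL,
                            reference_fasta = NULL,
                            detector = detector_params(),
                            align = align_params(),
                            classifier = classifier_config(),
                            mode = c("pairwise", "multiclass", "both"),
                            seed = 1L) {
  mode <- match.arg(mode)
  structure(list(output_dir = output_dir, cohort = cohort, fasta = fasta,
                 labels_file = labels_file, reference_fasta = reference_fasta,
                 detector = detector, align = align, classifier = classifier,
                 mode = mode, seed = as.integer(seed)),
            class = "repeatsig_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> detect -> index -> align -> classify, writing each
#' stage's outputs under `config$output_dir` together with a JSON manifest
#' recording parameters, seeds and file checksums.  A stage whose recorded
#' input checksums still match is skipped on re-run.  Any stage failure
#' halts the run with the failing stage named; completed outputs are kept.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "repeatsig_pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(stages = list())
  manifest$parameters <- serializable_config(config)

  stages <- c("simulate", "detect", "index", "align", "classify")
  skipped <- logical(0)
  for (stage in stages) {
    res <- tryCatch(
      run_stage(stage, config, manifest),
      error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    manifest <- res$manifest
    skipped[stage] <- res$skipped
    write_manifest(manifest, manifest_path)
  }
  attr(manifest, "skipped_stages") <- skipped
  invisible(manifest)
}

params_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

serializable_config <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

stage_io <- function(stage, config) {
  out <- config$output_dir
  f <- function(...) file.path(out, ...)
  switch(stage,
    simulate = list(
      inputs = character(0),
      outputs = c(f("cohort.fasta"), f("reference.fasta"), f("labels.tsv"),
                  f("ground_truth.tsv"), f("cohort_spec.yaml"))),
    detect = list(
      inputs = c(f("cohort.fasta"), f("reference.fasta")),
      outputs = c(f("catalog.tsv"), f("reference_catalog.tsv"))),
    index = list(
      inputs = c(f("catalog.tsv"), f("reference_catalog.tsv")),
      outputs = c(f("profiles.tsv"), f("reference_profile.tsv"))),
    align = list(
      inputs = c(f("profiles.tsv"), f("reference_profile.tsv"), f("labels.tsv")),
      outputs = f("matrix.tsv")),
    classify = list(
      inputs = f("matrix.tsv"),
      outputs = c(f("metrics.tsv"), f("artifacts.rds"))))
}

run_stage <- function(stage, config, manifest) {
  io <- stage_io(stage, config)
  if (stage == "simulate" && !is.null(config$fasta)) {
    # external inputs: copy into the run directory so later stages are uniform
    for (p in c(config$fasta, config$labels_file, config$reference_fasta)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input file not found: ", p %||% "(missing path)")
      }
    }
    file.copy(config$fasta, file.path(config$output_dir, "cohort.fasta"),
              overwrite = TRUE)
    file.copy(config$reference_fasta,
              file.path(config$output_dir, "reference.fasta"), overwrite = TRUE)
    file.copy(config$labels_file, file.path(config$output_dir, "labels.tsv"),
              overwrite = TRUE)
    manifest$stages[[stage]] <- list(external = TRUE,
                                     checksums = checksums(io$outputs))
    return(list(manifest = manifest, skipped = FALSE))
  }
  missing_in <- io$inputs[!file.exists(io$inputs)]
  if (length(missing_in) > 0) {
    stop("missing input(s): ", paste(basename(missing_in), collapse = ", "))
  }
  prev <- manifest$stages[[stage]]
  in_sums <- checksums(io$inputs)
  if (!is.null(prev) && all(file.exists(io$outputs)) &&
      identical(params_json(prev$input_checksums), params_json(in_sums)) &&
      identical(params_json(prev$parameters),
                params_json(stage_parameters(stage, config)))) {
    return(list(manifest = manifest, skipped = TRUE))
  }
  do_stage(stage, config)
  manifest$stages[[stage]] <- list(
    parameters = stage_parameters(stage, config),
    input_checksums = in_sums,
    checksums = checksums(io$outputs))
  list(manifest = manifest, skipped = FALSE)
}

stage_parameters <- function(stage, config) {
  switch(stage,
    simulate = unclass(config$cohort),
    detect = unclass(config$detector),
    index = list(),
    align = unclass(config$align),
    classify = c(unclass(config$classifier), list(mode = config$mode)))
}

checksums <- function(paths) {
  as.list(tools::md5sum(paths[file.exists(paths)]))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

do_stage <- function(stage, config) {
  out <- config$output_dir
  f <- function(...) file.path(out, ...)
  if (stage == "simulate") {
    write_cohort(generate_cohort(config$cohort), out)
  } else if (stage == "detect") {
    seqs <- read_fasta(f("cohort.fasta"))
    cat <- dplyr::bind_rows(lapply(names(seqs), function(sid) {
      dplyr::mutate(detect_repeats(seqs[[sid]], seq_id = sid,
                                   params = config$detector),
                    sample_id = sid, .before = 1)
    }))
    readr::write_tsv(cat, f("catalog.tsv"))
    ref <- read_fasta(f("reference.fasta"))
    write_catalog(detect_repeats(ref[[1]], seq_id = "reference",
                                 params = config$detector),
                  f("reference_catalog.tsv"))
  } else if (stage == "index") {
    cat <- readr::read_tsv(f("catalog.tsv"), col_types = readr::cols())
    prof <- cat |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_map(~ mutation_profile(.x, sample_id = .y$sample_id)) |>
      dplyr::bind_rows()
    write_profile(prof, f("profiles.tsv"))
    write_profile(mutation_profile(read_catalog(f("reference_catalog.tsv")),
                                   sample_id = "reference"),
                  f("reference_profile.tsv"))
  } else if (stage == "align") {
    prof <- read_profile(f("profiles.tsv"))
    ref <- read_profile(f("reference_profile.tsv"))
    labels <- readr::read_tsv(f("labels.tsv"), col_types = readr::cols())
    mat <- build_matrix(prof, ref, params = config$align, labels = labels)
    write_matrix(mat, f("matrix.tsv"))
  } else if (stage == "classify") {
    mat <- read_matrix(f("matrix.tsv"))
    cfg <- config$classifier
    cfg$seed <- config$seed
    artifacts <- list(reference_profile = read_profile(f("reference_profile.tsv")),
                      align = config$align, mode = config$mode)
    mets <- list()
    if (config$mode %in% c("pairwise", "both")) {
      pw <- train_pairwise(mat, config = cfg)
      artifacts$pairwise <- pw
      mets$pairwise <- report_metrics(pw)$summary
    }
    if (config$mode %in% c("multiclass", "both")) {
      mc <- train_multiclass(mat, config = cfg)
      artifacts$multiclass <- mc
      mets$multiclass <- dplyr::mutate(mc$fold_accuracy, class_a = NA_character_,
                                       class_b = NA_character_)
    }
    readr::write_tsv(dplyr::bind_rows(mets, .id = "report"), f("metrics.tsv"))
    saveRDS(artifacts, f("artifacts.rds"))
  }
  invisible(NULL)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Score a sample against trained pipeline artifacts
#'
#' Applies a completed run's multiclass model to one sample's mutation
#' profile: the profile is aligned against the stored reference, turned
#' into the model's feature vector, and scored.  A sample that was part of
#' the training cohort is scored by the model of its own held-out fold (so
#' the returned probabilities equal the stored out-of-fold values); unseen
#' samples receive the average of the fold models' probabilities.
#'
#' @param profile A mutation profile tibble for one sample.
#' @param artifacts The artifact list written by the classify stage
#'   (`artifacts.rds`), or its path.
#' @return A tibble `class`, `probability` (summing to 1).
#' @export
score_sample <- function(profile, artifacts) {
  if (is.character(artifacts)) artifacts <- readRDS(artifacts)
  mc <- artifacts$multiclass
  if (is.null(mc)) stop("artifacts contain no multiclass model", call. = FALSE)
  mat <- build_matrix(profile, artifacts$reference_profile,
                      params = artifacts$align)
  feat <- mc$features$feature[mc$features$selected]
  if (!all(feat %in% names(mat))) {
    stop("incompatibility error: profile was aligned against a different ",
         "reference region set", call. = FALSE)
  }
  xs <- feature_matrix(mat)[, feat, drop = FALSE]
  sid <- profile$sample_id[1]
  fold <- mc$folds$fold[match(sid, mc$folds$sample_id)]
  dm <- xgboost::xgb.DMatrix(xs)
  k <- length(mc$classes)
  if (!is.na(fold)) {
    p <- softprob_matrix(stats::predict(mc$models[[fold]], dm), k)
  } else {
    p <- Reduce(`+`, lapply(mc$models, function(m) {
      softprob_matrix(stats::predict(m, dm), k)
    })) / length(mc$models)
  }
  tibble::tibble(class = mc$classes, probability = as.numeric(p))
}
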