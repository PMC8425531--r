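#' Summarise pairwise classifier reports
#'
#' Aggregates a [train_pairwise()] result into the quantities usually
#' reported for one-vs-one classification: per pair the mean and standard
#' deviation over folds of AUC, accuracy, sensitivity and specificity; the
#' pooled ROC points; and square all-pairs "seriation" matrices (one per
#' metric) with the classes on both axes and an empty diagonal.
#'
#' @param reports A `repeatsig_pairwise` object.
#' @return A list with `summary` (tibble, one row per pair), `roc` (tibble
#'   of validation ROC points) and `seriation` (named list of K x K
#'   matrices for auc, accuracy, sensitivity, specificity).
#' @export
report_metrics <- function(reports) {
  stopifnot(inherits(reports, "repeatsig_pairwise"))
  if (nrow(reports$metrics) == 0) stop("no trained pairs to report", call. = FALSE)
  summary <- reports$metrics |>
    dplyr::group_by(.data$class_a, .data$class_b) |>
    dplyr::summarise(dplyr::across(
      c("auc", "accuracy", "sensitivity", "specificity"),
      list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE))),
      .groups = "drop")
  classes <- reports$classes
  seriation <- lapply(c(auc = "auc_mean", accuracy = "accuracy_mean",
                        sensitivity = "sensitivity_mean",
                        specificity = "specificity_mean"), function(col) {
    m <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(classes, classes))
    for (i in seq_len(nrow(summary))) {
      a <- summary$class_a[i]; b <- summary$class_b[i]
      m[a, b] <- m[b, a] <- summary[[col]][i]
    }
    m
  })
  list(summary = summary, roc = reports$roc, seriation = seriation)
}

#' Tidy per-region mutation index distributions
#'
#' Long-format export of the per-region (m, d) distributions by class --
#' the data behind per-region violin plots contrasting a signature class
#' against the others.  Accepts either an aligned feature matrix or a
#' ground-truth table from [generate_cohort()].
#'
#' @param x A `repeatsig_matrix` (or cohort ground-truth tibble with
#'   `witness_m` / `true_d`).
#' @return A tibble `sample_id`, `class`, `region_id`, `statistic`
#'   ("m" or "d"), `value`.
#' @export
region_distributions <- function(x) {
  if (all(c("witness_m", "true_d") %in% names(x))) {
    out <- x |>
      dplyr::filter(.data$present) |>
      dplyr::select("sample_id", "class", "region_id",
                    m = "witness_m", d = "true_d")
  } else {
    stopifnot(inherits(x, "repeatsig_matrix"), "class" %in% names(x))
    out <- x |>
      tidyr::pivot_longer(cols = -c("sample_id", "class"),
                          names_to = c("statistic", "region_id"),
                          names_pattern = "^([md])_(.*)$") |>
      tidyr::pivot_wider(names_from = "statistic", values_from = "value")
  }
  tidyr::pivot_longer(out, cols = c("m", "d"), names_to = "statistic",
                      values_to = "value")
}

#' @export
print.repeatsig_pairwise <- function(x, ...) {
  k <- length(x$classes)
  cat("<pairwise classifiers> ", k, " classes, ", k * (k - 1) / 2,
      " pairs, ", x$config$n_folds, "-fold CV\n", sep = "")
  invisible(x)
}

#' @export
print.repeatsig_multiclass <- function(x, ...) {
  cat("<multiclass classifier> ", length(x$classes), " classes, ",
      x$config$n_folds, "-fold CV, mean accuracy ",
      sprintf("%.3f", mean(x$fold_accuracy$accuracy)), "\n", sep = "")
  invisible(x)
}

#' Broom-style accessors for fitted classifier objects
#'
#' `tidy()` returns per-fold metrics (pairwise) or per-fold accuracy
#' (multiclass); `glance()` a one-row overall summary.
#'
#' @param x A `repeatsig_pairwise` or `repeatsig_multiclass` object.
#' @param ... Unused.
#' @return A tibble.
#' @name repeatsig-broom
NULL

#' @rdname repeatsig-broom
#' @method tidy repeatsig_pairwise
#' @export
tidy.repeatsig_pairwise <- function(x, ...) x$metrics

#' @rdname repeatsig-broom
#' @method glance repeatsig_pairwise
#' @export
glance.repeatsig_pairwise <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_pairs = nrow(dplyr::distinct(x$metrics, .data$class_a, .data$class_b)),
    n_folds = x$config$n_folds,
    mean_auc = mean(x$metrics$auc, na.rm = TRUE),
    mean_accuracy = mean(x$metrics$accuracy, na.rm = TRUE))
}

#' @rdname repeatsig-broom
#' @method tidy repeatsig_multiclass
#' @export
tidy.repeatsig_multiclass <- function(x, ...) x$fold_accuracy

#' @rdname repeatsig-broom
#' @method glance repeatsig_multiclass
#' @export
glance.repeatsig_multiclass <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_folds = x$config$n_folds,
    mean_accuracy = mean(x$fold_accuracy$accuracy))
}

#' Plot methods for classifier results
#'
#' `autoplot()` on a pairwise object draws the validation ROC curves per
#' class pair; on a multiclass object, the out-of-fold class probability
#' profiles; on the output of [region_distributions()], per-region violin
#' plots of m or d by class.
#'
#' @param object A fitted classifier object or a `region_distributions()`
#'   tibble.
#' @param statistic For region distributions: "m" or "d".
#' @param regions Optional subset of region ids to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name repeatsig-autoplot
NULL

#' @rdname repeatsig-autoplot
#' @method autoplot repeatsig_pairwise
#' @export
autoplot.repeatsig_pairwise <- function(object, ...) {
  roc <- dplyr::mutate(object$roc,
                       pair = paste(.data$class_a, "vs", .data$class_b),
                       fold = factor(.data$fold))
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "fold") +
    ggplot2::theme_minimal()
}

#' @rdname repeatsig-autoplot
#' @method autoplot repeatsig_multiclass
#' @export
autoplot.repeatsig_multiclass <- function(object, ...) {
  long <- tidyr::pivot_longer(object$probabilities,
                              cols = dplyr::starts_with("p_"),
                              names_to = "predicted", values_to = "probability",
                              names_prefix = "p_")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$predicted,
                                     fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~class, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "sample (grouped by true class)", y = "predicted class",
                  fill = "out-of-fold\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname repeatsig-autoplot
#' @export
plot_region_distributions <- function(object, statistic = c("m", "d"),
                                      regions = NULL, ...) {
  stat <- match.arg(statistic)
  df <- dplyr::filter(object, .data$statistic == stat)
  if (!is.null(regions)) df <- dplyr::filter(df, .data$region_id %in% regions)
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$value, fill = .data$class)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~region_id, scales = "free_y") +
    ggplot2::labs(y = stat, x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
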