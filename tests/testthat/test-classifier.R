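test_that("a single strongly shifted column ranks first", {
  m <- toy_matrix(20, c("a", "b"), n_feat = 15, shift_cols = 7, shift = 8,
                  seed = 2)
  sel <- select_features(m, config = classifier_config(seed = 2))
  expect_equal(sel$feature[1], "f7")
  expect_true(sel$selected[1])
})

test_that("selection caps at the configured number of features", {
  m <- toy_matrix(12, c("a", "b", "c"), n_feat = 50, shift_cols = 1:5,
                  shift = 4, seed = 3)
  sel <- select_features(m, config = classifier_config(n_top_features = 30, seed = 3))
  expect_equal(sum(sel$selected), 30)
  expect_equal(sel$rank, seq_len(50))
})

test_that("classes smaller than the fold count raise a stratification error", {
  m <- toy_matrix(3, c("a", "b"), n_feat = 5, seed = 4)
  expect_error(select_features(m, config = classifier_config(n_folds = 4)),
               "stratification")
})

test_that("the pair count law holds and separable classes reach AUC 1", {
  m <- toy_matrix(12, c("a", "b", "c", "d"), n_feat = 20, shift_cols = 1:3,
                  shift = 30, shift_class = "a", seed = 5)
  pw <- train_pairwise(m, config = classifier_config(seed = 5))
  expect_equal(nrow(dplyr::distinct(pw$metrics, class_a, class_b)), choose(4, 2))
  auc_a <- pw$metrics$auc[pw$metrics$class_a == "a"]
  expect_true(all(auc_a == 1))
  expect_true(all(pw$metrics$auc >= 0 & pw$metrics$auc <= 1, na.rm = TRUE))
})

test_that("the rank-statistic AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  score <- runif(60)
  truth <- rbinom(60, 1, 0.4)
  got <- repeatsig:::auc_rank(score, truth)
  ref <- as.numeric(pROC::auc(suppressMessages(
    pROC::roc(truth, score, direction = "<", quiet = TRUE))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  m <- toy_matrix(10, c("a", "b", "c"), n_feat = 12, shift_cols = 1,
                  shift = 3, seed = 7)
  cfg <- classifier_config(seed = 11, nrounds = 30)
  p1 <- train_pairwise(m, config = cfg)
  p2 <- train_pairwise(m, config = cfg)
  expect_identical(p1$metrics, p2$metrics)
  m1 <- train_multiclass(m, config = cfg)
  m2 <- train_multiclass(m, config = cfg)
  expect_identical(m1$probabilities, m2$probabilities)
  expect_identical(m1$confusion, m2$confusion)
})

test_that("multiclass probabilities are proper and out-of-fold hygiene holds", {
  m <- toy_matrix(12, c("a", "b", "c"), n_feat = 15, shift_cols = 1:2,
                  shift = 6, seed = 8)
  cfg <- classifier_config(seed = 8, nrounds = 40)
  mc <- train_multiclass(m, config = cfg)
  probs <- as.matrix(mc$probabilities[grep("^p_", names(mc$probabilities))])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  # the shifted class dominates its own confusion row
  expect_equal(names(which.max(mc$confusion["a", ])), "a")
  # fold bookkeeping: each sample's prediction fold equals its assigned fold
  expect_identical(mc$probabilities$fold, mc$folds$fold)
  expect_equal(sort(unique(mc$folds$fold)), 1:4)
  # every class appears in every validation fold (stratification)
  tab <- table(mc$probabilities$class, mc$probabilities$fold)
  expect_true(all(tab > 0))
})

test_that("pairwise validation predictions come only from held-out folds", {
  m <- toy_matrix(8, c("a", "b"), n_feat = 10, shift_cols = 1, shift = 5,
                  seed = 9)
  pw <- train_pairwise(m, config = classifier_config(seed = 9, nrounds = 20))
  pred <- pw$predictions
  # each sample is predicted exactly once, by its own fold
  expect_equal(sort(table(pred$sample_id)), sort(table(m$sample_id)))
  expect_equal(nrow(pred), nrow(m))
})

test_that("metric summaries reproduce hand-computed moments and seriation shape", {
  m <- toy_matrix(10, c("a", "b", "c"), n_feat = 10, shift_cols = 1, shift = 4,
                  seed = 10)
  pw <- train_pairwise(m, config = classifier_config(seed = 10, nrounds = 20))
  # splice in known fold AUCs for one pair and check the moments
  pw$metrics$auc[pw$metrics$class_a == "a" & pw$metrics$class_b == "b"] <-
    c(0.8, 0.9, 1.0, 0.9)
  rep <- report_metrics(pw)
  row <- rep$summary[rep$summary$class_a == "a" & rep$summary$class_b == "b", ]
  expect_equal(row$auc_mean, 0.9)
  expect_equal(row$auc_sd, sd(c(0.8, 0.9, 1.0, 0.9)))
  ser <- rep$seriation$auc
  expect_equal(dim(ser), c(3, 3))
  expect_true(all(is.na(diag(ser))))
  expect_equal(ser["a", "b"], ser["b", "a"])
  # an empty report errors
  pw0 <- pw
  pw0$metrics <- pw0$metrics[0, ]
  expect_error(report_metrics(pw0), "no trained pairs")
})

test_that("label permutation drops the selected-feature overlap to chance", {
  m <- toy_matrix(16, c("a", "b"), n_feat = 60, shift_cols = 1:5, shift = 6,
                  seed = 12)
  cfg <- classifier_config(seed = 12, n_top_features = 10, nrounds = 30)
  sel <- select_features(m, config = cfg)
  top <- sel$feature[sel$selected]
  expect_true(all(paste0("f", 1:5) %in% top))
  perm <- m
  withr::with_seed(99, perm$class <- sample(perm$class))
  sel_p <- select_features(perm, config = cfg)
  top_p <- sel_p$feature[sel_p$selected]
  overlap <- length(intersect(top, top_p))
  # under the hypergeometric null (10 of 60 vs 10 of 60) an overlap this
  # large would be extreme; anything <= 5 is consistent with chance
  expect_lte(overlap, 5)
})

test_that("tidy, glance and autoplot cover the fitted objects", {
  m <- toy_matrix(8, c("a", "b", "c"), n_feat = 8, shift_cols = 1, shift = 5,
                  seed = 13)
  cfg <- classifier_config(seed = 13, nrounds = 15)
  pw <- train_pairwise(m, config = cfg)
  mc <- train_multiclass(m, config = cfg)
  expect_s3_class(tidy(pw), "tbl_df")
  expect_equal(nrow(glance(pw)), 1)
  expect_equal(glance(pw)$n_pairs, 3)
  expect_s3_class(tidy(mc), "tbl_df")
  expect_s3_class(autoplot(pw), "ggplot")
  expect_s3_class(autoplot(mc), "ggplot")
})

test_that("region distributions pivot ground truth into plotting form", {
  co <- generate_cohort(cohort_spec(n_classes = 2, samples_per_class = c(5L, 5L),
                                    n_regions = 6, signal_regions = integer(0),
                                    seed = 14))
  rd <- region_distributions(co$ground_truth)
  expect_setequal(unique(rd$statistic), c("m", "d"))
  expect_true(all(c("sample_id", "class", "region_id", "value") %in% names(rd)))
  expect_s3_class(plot_region_distributions(rd, "m"), "ggplot")
})
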