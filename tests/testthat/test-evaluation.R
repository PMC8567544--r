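test_that("fold plans partition the positives with balanced sizes", {
  O <- tiny_assoc(6, 10, density = 0.4)
  n_pos <- sum(O)
  plan <- make_folds(O, k = 5, seed = 3)
  sizes <- vapply(plan$folds, nrow, 1L)
  expect_equal(sum(sizes), n_pos)
  expect_lte(max(sizes) - min(sizes), 1)
  all_cells <- do.call(rbind, plan$folds)
  expect_equal(nrow(unique(as.data.frame(all_cells))), n_pos)
  expect_true(all(O[all_cells] == 1))

  expect_identical(make_folds(O, 5, 3)$folds, plan$folds)
  expect_false(identical(make_folds(O, 5, 4)$folds, plan$folds))
  expect_error(make_folds(O, k = 1), "at least 2")
  expect_error(make_folds(O, k = n_pos + 1), "exceeds")

  # 20 positives into 10 folds -> exactly 2 each
  O2 <- matrix(0, 5, 8); O2[sample(40, 20)] <- 1
  expect_true(all(vapply(make_folds(O2, 10, 1)$folds, nrow, 1L) == 2))
})

test_that("auroc matches exhaustive pair counting with ties at half", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(5, 4, 3), c(1, 1, 0)), 1)
  expect_equal(auroc(rep(1, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(5:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # many ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auroc(scores, labels), pair_count_auroc(scores, labels))
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "single class")
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, 0.3)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("confusion metrics match hand counts", {
  # 3 TP, 1 FP above threshold; 1 FN, 5 TN below
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.25, 0.2, 0.15, 0.1)
  labels <- c(1,   1,   1,   0,   1,   0,   0,    0,   0,    0)
  cm <- confusion_metrics(scores, labels, threshold = 0.5)
  expect_equal(cm[c("tp", "fp", "fn", "tn")], list(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$recall, 0.75)
  expect_equal(cm$f_measure, 0.75)
  expect_equal(cm$acc, 0.8)

  expect_equal(confusion_metrics(scores, labels, min(scores))$recall, 1)
  cm_hi <- confusion_metrics(scores, labels, max(scores) + 1)
  expect_equal(cm_hi$tp + cm_hi$fp, 0)
  expect_equal(cm_hi$f_measure, 0)
})

test_that("ranking metrics are invariant to strictly monotone score transforms", {
  set.seed(19)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.3)
  for (tf in list(function(x) 3 * x + 2, function(x) exp(x), function(x) atan(x))) {
    expect_equal(auroc(tf(scores), labels), auroc(scores, labels))
    expect_equal(auprc(tf(scores), labels), auprc(scores, labels))
  }
})

test_that("auprc equals the step integral on small cases", {
  # perfect ranking: precision 1 everywhere
  expect_equal(auprc(c(3, 2, 1), c(1, 1, 0)), 1)
  # ranking [1,0,1,0]: steps at recall 1/2 (prec 1) and 1 (prec 2/3)
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 0, 1, 0)), 0.5 * 1 + 0.5 * (2 / 3))
  # all scores tied: single step, precision = prevalence
  expect_equal(auprc(rep(1, 4), c(1, 0, 1, 0)), 0.5)
})

test_that("cross-validation masks test labels and reports sane metrics", {
  gen <- small_bundle()
  cfg <- fast_config()
  cv <- cross_validate(gen$bundle, config = cfg, k = 4, seed = 2)
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$folds), 4)
  expect_true(all(cv$folds$auroc >= 0 & cv$folds$auroc <= 1))
  expect_true(all(cv$folds$auprc >= 0 & cv$folds$auprc <= 1))
  expect_true(all(cv$folds$acc >= 0 & cv$folds$acc <= 1))
  expect_true(all(cv$folds$f_measure >= 0 & cv$folds$f_measure <= 1))
  # an informative bundle must beat chance decisively even with a light config
  expect_gt(mean(cv$folds$auroc), 0.6)
  # leakage guard: every fold's training matrix has its test positives zeroed
  for (fold in cv$plan$folds) {
    expect_true(all(mask_fold(gen$bundle$associations, fold)[fold] == 0))
  }
})

test_that("negative subsampling changes the negative pool, not the protocol", {
  gen <- small_bundle()
  cv <- cross_validate(gen$bundle, config = fast_config(), k = 3, seed = 5,
                       neg_sample = 200)
  expect_true(all(cv$folds$n_test_neg == 200))
})

test_that("per-disease ranking holds out the whole disease and orders by score", {
  gen <- small_bundle()
  target <- rownames(gen$bundle$associations)[3]
  rl <- rank_drugs_for_disease(gen$bundle, target, top_k = 10,
                               config = fast_config())
  expect_equal(nrow(rl), 10)
  expect_true(all(diff(rl$score) <= 0))
  expect_false(any(duplicated(rl$drug_id)))
  expect_identical(attr(rl, "disease_id"), target)

  all_ranked <- rank_drugs_for_disease(gen$bundle, target,
                                       top_k = ncol(gen$bundle$associations) + 5,
                                       config = fast_config())
  expect_equal(nrow(all_ranked), ncol(gen$bundle$associations))
  expect_error(rank_drugs_for_disease(gen$bundle, "nope", config = fast_config()),
               "unknown disease")
})

test_that("grid search shares the fold plan and sorts by mean AUROC", {
  gen <- small_bundle()
  cfg <- fast_config()
  plan <- make_folds(gen$bundle$associations, k = 3, seed = 9)
  grid <- data.frame(rank_disease = c(2, 4), rank_drug = c(2, 4))
  res <- grid_search(gen$bundle, grid, config = cfg, plan = plan)
  expect_equal(nrow(res), 2)
  expect_true(all(diff(res$mean_auroc) <= 0))
  # a single-point grid reproduces a plain cv run exactly
  cfg1 <- cfg; cfg1$rank_disease <- 2; cfg1$rank_drug <- 2
  cv <- cross_validate(gen$bundle, plan = plan, config = cfg1)
  one <- grid_search(gen$bundle, grid[1, , drop = FALSE], config = cfg, plan = plan)
  expect_equal(one$mean_auroc, unname(cv$mean["auroc"]))
})

test_that("roc_points starts at the origin and ends at (1,1)", {
  set.seed(2)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  rp <- roc_points(scores, labels)
  expect_equal(unlist(rp[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rp[nrow(rp), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
})
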