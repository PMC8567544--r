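#' Partition the known associations into cross-validation folds
#'
#' The positive cells of the association matrix are shuffled with a seeded
#' RNG and dealt round-robin into `k` folds, so folds are disjoint, exhaust
#' the positive set, and differ in size by at most one.
#'
#' @param O binary association matrix.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: list with `k`, `seed`, and
#'   `folds`, a list of two-column integer matrices of held-out `(i, j)`
#'   cells.
#' @export
make_folds <- function(O, k = 10, seed = 1) {
  stopifnot(is_binary_matrix(O))
  pos <- which(O == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (k < 2) stop_validation("k must be at least 2")
  if (k > n_pos) stop_validation(sprintf("k = %d exceeds the %d positives", k, n_pos))
  perm <- with_seed(seed, sample.int(n_pos))
  shuffled <- pos[perm, , drop = FALSE]
  assign_fold <- rep_len(seq_len(k), n_pos)
  folds <- lapply(seq_len(k), function(f) {
    m <- shuffled[assign_fold == f, , drop = FALSE]
    colnames(m) <- c("i", "j")
    m
  })
  structure(list(k = as.integer(k), seed = as.integer(seed), folds = folds),
            class = "fold_plan")
}

#' Zero out one fold's held-out positives
#'
#' @param O binary association matrix.
#' @param fold two-column `(i, j)` matrix of cells to mask.
#' @return The training copy of `O` with those cells set to 0.
#' @export
mask_fold <- function(O, fold) {
  O_train <- O
  O_train[fold] <- 0
  O_train
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, ties counted 1/2. Computed from
#' midranks, so it matches exhaustive pair counting exactly.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_two_classes(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integral of precision over recall, descending the score axis with
#' tied scores grouped at one threshold (so the curve is invariant to any
#' strictly monotone transform of the scores).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_two_classes(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- which(!duplicated(grp, fromLast = TRUE))   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  n1 <- sum(labels == 1)
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Scores at or above the threshold are predicted positive. Accuracy is
#' `(TP + TN) / n`; F-measure is the harmonic mean of precision and recall,
#' defined as 0 when `precision + recall = 0`.
#'
#' @inheritParams auroc
#' @param threshold decision threshold.
#' @return Named list: `tp`, `fp`, `fn`, `tn`, `acc`, `precision`, `recall`,
#'   `f_measure`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  check_two_classes(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       acc = (tp + tn) / length(labels),
       precision = precision, recall = recall, f_measure = f)
}

check_two_classes <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (all(labels == 1) || all(labels == 0)) {
    stop_validation("metric undefined: labels contain a single class")
  }
  invisible(TRUE)
}

#' Threshold maximizing F-measure
#'
#' Scans every distinct score as a candidate threshold and returns the one
#' with the highest F-measure (largest threshold wins ties).
#'
#' @inheritParams auroc
#' @return The selected threshold.
#' @export
best_f_threshold <- function(scores, labels) {
  check_two_classes(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)   # last index within each tie group
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  n1 <- sum(labels == 1)
  prec <- tp / (tp + fp)
  rec <- tp / n1
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  s[keep][which.max(f)]
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold the held-out positives are zeroed in a training copy of the
#' association matrix, both GIP similarity networks are recomputed from that
#' masked matrix (so no test label reaches the similarity features), the
#' model is trained with [fit_joint()], and the fold's test cells -- its
#' held-out positives against every pair that is 0 in the FULL association
#' matrix -- are scored. The accuracy/F threshold is selected to maximize
#' F-measure on the fold's training cells only, then applied to the test
#' cells.
#'
#' @param bundle a `dd_bundle`.
#' @param plan a [make_folds()] plan (built from `bundle$associations` when
#'   `NULL`).
#' @param config a [train_config()].
#' @param k,seed fold count and seed used when `plan` is `NULL`.
#' @param neg_sample optional number of test negatives to subsample per fold
#'   (seeded by the fold); `NULL` scores all unknown pairs.
#' @return An object of class `cv_report`: per-fold metric data frame, mean
#'   and pooled metrics, and the fold plan.
#' @export
cross_validate <- function(bundle, plan = NULL, config = train_config(),
                           k = 10, seed = 1, neg_sample = NULL) {
  O <- bundle$associations
  if (is.null(plan)) plan <- make_folds(O, k = k, seed = seed)
  neg_idx <- which(O == 0)
  per_fold <- vector("list", plan$k)
  pooled_scores <- list()
  pooled_labels <- list()
  for (f in seq_len(plan$k)) {
    fold <- plan$folds[[f]]
    O_train <- mask_fold(O, fold)
    if (any(O_train[fold] != 0)) {
      stop_validation("internal leakage: held-out positive still 1 in training matrix")
    }
    train_bundle <- bundle
    train_bundle$associations <- O_train
    fit <- fit_joint(train_bundle, config)
    S <- fit$scores
    test_pos <- S[fold]
    neg_use <- neg_idx
    if (!is.null(neg_sample) && neg_sample < length(neg_idx)) {
      neg_use <- with_seed(stage_seed(plan$seed, 100 + f),
                           sample(neg_idx, neg_sample))
    }
    test_scores <- c(test_pos, S[neg_use])
    test_labels <- c(rep(1, length(test_pos)), rep(0, length(neg_use)))
    # threshold from training cells only (everything but this fold's test positives)
    lin_fold <- (fold[, "j"] - 1L) * nrow(O) + fold[, "i"]
    train_cells <- setdiff(seq_along(O), lin_fold)
    thr <- best_f_threshold(S[train_cells], O_train[train_cells])
    cm <- confusion_metrics(test_scores, test_labels, thr)
    per_fold[[f]] <- data.frame(
      fold = f,
      auroc = auroc(test_scores, test_labels),
      auprc = auprc(test_scores, test_labels),
      acc = cm$acc, f_measure = cm$f_measure, threshold = thr,
      n_test_pos = length(test_pos), n_test_neg = length(neg_use)
    )
    pooled_scores[[f]] <- test_scores
    pooled_labels[[f]] <- test_labels
  }
  folds_df <- do.call(rbind, per_fold)
  ps <- unlist(pooled_scores); pl <- unlist(pooled_labels)
  structure(list(
    folds = folds_df,
    mean = colMeans(folds_df[, c("auroc", "auprc", "acc", "f_measure")]),
    pooled = c(auroc = auroc(ps, pl), auprc = auprc(ps, pl)),
    plan = plan, config = unclass(config)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold cross-validation (seed %d)\n",
              x$plan$k, x$plan$seed))
  cat(sprintf("  mean : AUROC %.3f  AUPRC %.3f  ACC %.3f  F %.3f\n",
              x$mean["auroc"], x$mean["auprc"], x$mean["acc"], x$mean["f_measure"]))
  cat(sprintf("  pooled: AUROC %.3f  AUPRC %.3f\n",
              x$pooled["auroc"], x$pooled["auprc"]))
  invisible(x)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs at every distinct threshold, for curve dumps and plots.
#'
#' @inheritParams auroc
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  check_two_classes(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  data.frame(fpr = c(0, fp / sum(labels == 0)), tpr = c(0, tp / sum(labels == 1)))
}

#' Rank candidate drugs for one disease (case-study protocol)
#'
#' Every association of the target disease is deleted from the training
#' matrix, the model is retrained from scratch on the rest of the network,
#' and all drugs are scored for the target disease. The top `top_k` drugs by
#' score are returned, with ties broken by drug id for determinism.
#'
#' @param bundle a `dd_bundle`.
#' @param disease_id disease identifier (must be a rowname of the
#'   associations).
#' @param top_k number of candidates to return.
#' @param config a [train_config()].
#' @return Data frame with columns `rank`, `drug_id`, `score`; attribute
#'   `disease_id`.
#' @export
rank_drugs_for_disease <- function(bundle, disease_id, top_k = 10,
                                   config = train_config()) {
  O <- bundle$associations
  if (!disease_id %in% rownames(O)) {
    stop_validation(sprintf("unknown disease id: %s", disease_id))
  }
  train_bundle <- bundle
  train_bundle$associations[disease_id, ] <- 0
  fit <- fit_joint(train_bundle, config)
  s <- fit$scores[disease_id, ]
  ord <- order(-s, colnames(O))
  top <- utils::head(ord, top_k)
  out <- data.frame(rank = seq_along(top), drug_id = colnames(O)[top],
                    score = unname(s[top]))
  attr(out, "disease_id") <- disease_id
  out
}

#' Grid search over fusion ranks
#'
#' Runs [cross_validate()] once per grid point with a shared fold plan and
#' returns the results sorted by mean AUROC, best first. This is the
#' rank-selection protocol for real datasets.
#'
#' @param bundle a `dd_bundle`.
#' @param grid data frame with columns `rank_disease`, `rank_drug`.
#' @param config base [train_config()]; its ranks are overridden per point.
#' @param plan shared [make_folds()] plan (built when `NULL`).
#' @param k,seed used when `plan` is `NULL`.
#' @param neg_sample passed to [cross_validate()].
#' @return Data frame `rank_disease`, `rank_drug`, `mean_auroc`,
#'   `mean_auprc`, sorted by `mean_auroc` descending.
#' @export
grid_search <- function(bundle, grid, config = train_config(), plan = NULL,
                        k = 10, seed = 1, neg_sample = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("rank_disease", "rank_drug") %in% names(grid)))
  if (is.null(plan)) plan <- make_folds(bundle$associations, k = k, seed = seed)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$rank_disease <- grid$rank_disease[g]
    cfg$rank_drug <- grid$rank_drug[g]
    cv <- cross_validate(bundle, plan = plan, config = cfg,
                         neg_sample = neg_sample)
    data.frame(rank_disease = cfg$rank_disease, rank_drug = cfg$rank_drug,
               mean_auroc = unname(cv$mean["auroc"]),
               mean_auprc = unname(cv$mean["auprc"]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_auroc), , drop = FALSE]
}
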