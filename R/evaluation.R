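# Performance protocol: stratified 70/30 holdout, rank-based ROC/AUC on the
# holdout and on the full dataset, stratified 10-fold cross-validation
# classification error, confusion matrix at the 0.5 posterior threshold.

#' Stratified train/test split
#'
#' Per class, the training count is the class size times `frac` rounded to
#' the nearest integer (half rounds up); remaining rows form the test set.
#' Disjoint and exhaustive; deterministic under `seed`.
#'
#' @param table a feature table with a `group` column.
#' @param frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with tibbles `train` and `test`.
#' @export
stratified_split <- function(table, frac = 0.7, seed = 1L) {
  classes <- unique(table$group)
  if (length(classes) < 2) stop_fx("both classes must be present")
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in classes) {
    ix <- which(table$group == cl)
    if (length(ix) < 2) stop_fx("class '%s' has fewer than 2 members", cl)
    n_tr <- floor(length(ix) * frac + 0.5)
    if (n_tr >= length(ix))
      stop_fx("training fraction %g leaves class '%s' with an empty test set", frac, cl)
    if (n_tr < 1) stop_fx("training fraction %g gives class '%s' an empty training set", frac, cl)
    train_idx <- c(train_idx, sample(ix, n_tr))
  }
  list(train = table[sort(train_idx), , drop = FALSE],
       test  = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half — identical to trapezoidal
#' integration of the empirical ROC curve.
#'
#' @param scores numeric classifier scores (posterior of the positive class).
#' @param labels labels; `positive` marks the positive class.
#' @param positive positive-class label (default `"FXS"`).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "FXS") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_fx("both classes must be present in labels")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' Step curve from (0,0) to (1,1): at each distinct score threshold
#' (descending), the false- and true-positive rates of classifying
#' scores >= threshold as positive.
#'
#' @inheritParams roc_auc
#' @return tibble with columns `fpr`, `tpr`, both non-decreasing.
#' @export
roc_points <- function(scores, labels, positive = "FXS") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_fx("both classes must be present in labels")
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  s <- scores[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # final element of each tied block
  tibble::tibble(fpr = c(0, fp[last] / n0, 1), tpr = c(0, tp[last] / n1, 1)) |>
    dplyr::distinct()
}

#' Trapezoidal AUC of an ROC curve
#' @param roc a [roc_points()] tibble.
#' @return AUC in [0, 1].
#' @export
roc_trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Stratified k-fold cross-validation classification error
#'
#' Rows are assigned to folds per class (shuffled, then dealt cyclically);
#' each fold is predicted by a model fit on the remaining folds; the error
#' is total misclassifications over n. If a class has fewer members than
#' `k`, the fold count is reduced to that size with a warning (or an error
#' in `strict` mode).
#'
#' @param table feature table.
#' @param features feature column names.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param positive positive-class label.
#' @param strict error instead of reducing folds.
#' @return classification error rate in [0, 1].
#' @export
kfold_cv_error <- function(table, features, k = 10, seed = 1L,
                           positive = "FXS", strict = FALSE) {
  classes <- unique(table$group)
  min_class <- min(table(table$group))
  if (min_class < k) {
    if (strict) stop_fx("class with %d members cannot fill %d folds", min_class, k)
    warning(sprintf("reducing folds from %d to %d (smallest class size)", k, min_class),
            call. = FALSE)
    k <- min_class
  }
  set.seed(seed)
  fold <- integer(nrow(table))
  for (cl in classes) {
    ix <- sample(which(table$group == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  wrong <- 0L
  for (f in seq_len(k)) {
    model <- nbc_fit(table[fold != f, , drop = FALSE], features, positive = positive)
    pred <- nbc_predict(model, table[fold == f, , drop = FALSE])
    wrong <- wrong + sum(pred != table$group[fold == f])
  }
  wrong / nrow(table)
}

#' Evaluate one variable set under the full study protocol
#'
#' Fits on a stratified 70% training split; reports holdout AUC from the
#' withheld 30%, AUC and the 0.5-threshold confusion matrix from the same
#' model applied back to the entire dataset (in-sample by construction, as
#' the protocol defines), and a 10-fold cross-validation error from an
#' independent stratified pass. All randomness is derived from `seed`.
#'
#' @param table feature table.
#' @param features feature column names.
#' @param seed integer seed.
#' @param name variable-set name recorded in the report.
#' @param positive positive-class label.
#' @param frac training fraction.
#' @param k cross-validation folds.
#' @return object of class `eval_report`: list with `summary` (one-row
#'   tibble: name, n, auc_holdout, auc_full, cv_error, tp/fp/tn/fn, seed)
#'   and `roc` (full-dataset ROC points).
#' @export
evaluate_variable_set <- function(table, features, seed = 1L, name = NA_character_,
                                  positive = "FXS", frac = 0.7, k = 10) {
  sp <- stratified_split(table, frac, seed = derive_seed(seed, "split"))
  model <- nbc_fit(sp$train, features, positive = positive)

  sc_test <- nbc_posterior(model, sp$test)
  auc_holdout <- roc_auc(sc_test, sp$test$group, positive)

  sc_full <- nbc_posterior(model, table)
  auc_full <- roc_auc(sc_full, table$group, positive)
  pred <- ifelse(sc_full > 0.5, positive, setdiff(model$classes, positive))
  is_pos <- table$group == positive
  tp <- sum(pred == positive & is_pos);  fp <- sum(pred == positive & !is_pos)
  fn <- sum(pred != positive & is_pos); tn <- sum(pred != positive & !is_pos)

  cv <- kfold_cv_error(table, features, k = k,
                       seed = derive_seed(seed, "cv"), positive = positive)

  structure(list(
    summary = tibble::tibble(
      variable_set = name, n = nrow(table), n_features = length(features),
      auc_holdout = auc_holdout, auc_full = auc_full, cv_error = cv,
      tp = tp, fp = fp, tn = tn, fn = fn, seed = seed),
    roc = roc_points(sc_full, table$group, positive),
    model = model
  ), class = "eval_report")
}

#' Report column headings of the study tables
#'
#' @return named character vector mapping internal column names to the
#'   exact published-style headings used in exported CSV reports.
#' @export
report_column_names <- function() {
  c(variable_set = "Variable",
    auc_holdout = "AUC – 30% holdout test set",
    auc_full = "AUC – entire dataset",
    cv_error = "Cross Validation Classification Error")
}
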