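#' Classifier specification
#'
#' The age-discrimination battery compares four models: linear discriminant
#' analysis, a linear SVM with default cost, and linear / radial-kernel SVMs
#' with grid-search-tuned hyperparameters.
#'
#' @param kind One of `"lda"`, `"linear_svm_untuned"`, `"linear_svm_tuned"`,
#'   `"rbf_svm_tuned"`.
#' @param cost SVM cost; `"default"` (= 1) for untuned kinds.
#' @param gamma RBF kernel width; `"default"` for non-RBF kinds.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "linear_svm_untuned",
                                     "linear_svm_tuned", "rbf_svm_tuned"),
                            cost = "default", gamma = "default") {
  kind <- match.arg(kind)
  structure(list(kind = kind, cost = cost, gamma = gamma),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> ", x$kind,
      if (!identical(x$cost, "default")) paste0(" cost=", signif(x$cost, 4)),
      if (!identical(x$gamma, "default")) paste0(" gamma=", signif(x$gamma, 4)),
      "\n", sep = "")
  invisible(x)
}

spec_is_tuned <- function(spec) spec$kind %in% c("linear_svm_tuned", "rbf_svm_tuned")

#' Stratified cross-validation folds
#'
#' Assigns each observation to one of `folds` folds, keeping class
#' proportions as equal as possible; the within-class shuffle is driven by
#' `seed` only, so identical seeds give identical folds.
#'
#' @param labels Class labels (coerced to factor).
#' @param folds Number of folds (default 4).
#' @param seed Integer seed.
#' @return An integer vector of fold ids in `1:folds`.
#' @export
make_folds <- function(labels, folds = 4, seed = 0) {
  labels <- factor(labels)
  fold_id <- integer(length(labels))
  # one shared permutation of all observations: fold assignment then depends
  # only on the class membership *sets*, not on the class names, so
  # relabeling the classes leaves the folds unchanged
  ord <- withr::with_seed(seed, sample(length(labels)))
  for (cl in levels(labels)) {
    idx <- ord[labels[ord] == cl]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

positive_class <- function(labels) {
  lv <- if (is.factor(labels)) levels(labels) else levels(factor(labels))
  if ("infant" %in% lv) "infant" else lv[length(lv)]
}

#' Rank-based AUC (Mann-Whitney formulation, ties half-credit)
#'
#' @param scores Continuous decision scores, higher = more positive-class.
#' @param labels Class labels; the positive class is `"infant"` when
#'   present, otherwise the last factor level.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  pos <- labels == positive_class(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Standardize columns using training-set statistics; zero-variance columns
# pass through unscaled (they carry no information either way).
standardizer <- function(train_X) {
  mu <- colMeans(train_X)
  sdv <- apply(train_X, 2, sd)
  sdv[sdv < .Machine$double.eps] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
}

# Fit one classifier on (train_X, train_y) and return held-out class
# predictions and continuous scores (higher = positive class) for test_X.
fit_predict <- function(train_X, train_y, test_X, spec, standardize = TRUE) {
  if (!is.factor(train_y)) train_y <- factor(train_y)
  posc <- positive_class(train_y)
  if (standardize && spec$kind != "lda") {
    zs <- standardizer(train_X)
    train_X <- zs(train_X); test_X <- zs(test_X)
  }
  if (spec$kind == "lda") {
    fit <- tryCatch(MASS::lda(train_X, grouping = train_y),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warn("Degenerate LDA fit (constant features); predicting majority class.")
      maj <- names(which.max(table(train_y)))
      return(list(pred = factor(rep(maj, nrow(test_X)), levels = levels(train_y)),
                  score = rep(0, nrow(test_X))))
    }
    pr <- predict(fit, test_X)
    return(list(pred = pr$class, score = pr$posterior[, posc]))
  }
  cost <- if (identical(spec$cost, "default")) 1 else spec$cost
  kernel <- if (spec$kind == "rbf_svm_tuned") "radial" else "linear"
  args <- list(x = train_X, y = train_y, kernel = kernel, cost = cost,
               scale = FALSE)
  if (kernel == "radial") {
    args$gamma <- if (identical(spec$gamma, "default")) 1 / ncol(train_X) else spec$gamma
  }
  fit <- do.call(e1071::svm, args)
  pr <- predict(fit, test_X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pair <- strsplit(colnames(dv)[1], "/")[[1]]
  score <- if (pair[1] == posc) dv[, 1] else -dv[, 1]
  list(pred = pr, score = unname(score))
}

#' Cross-validated evaluation of a classifier
#'
#' Stratified k-fold cross-validation: accuracy is the pooled fraction of
#' correct held-out predictions (equal to the mean of per-fold accuracies
#' when fold sizes are equal), and AUC is computed from the held-out
#' continuous decision scores (signed margin for SVMs, positive-class
#' posterior for LDA) pooled over folds with the rank formulation. Training
#' (resubstitution) accuracy/AUC are also reported, clearly separated,
#' because tuned models can trivially approach training accuracy 1.
#'
#' Features are standardized per column using training-fold statistics
#' before SVM fitting (LDA is scale-equivariant and is left alone); disable
#' with `standardize = FALSE`.
#'
#' @param features Numeric matrix (or data frame) of predictors, `n x m`.
#' @param labels Binary class labels (`adult`/`infant` in the intended use).
#' @param spec A [classifier_spec()]; must be concrete (tuned kinds carry
#'   numeric hyperparameters) unless `nested = TRUE`.
#' @param folds Number of CV folds (default 4).
#' @param seed Integer seed controlling fold assignment (default 0).
#' @param standardize Standardize features inside each training fold.
#' @param nested For tuned kinds, re-run the hyperparameter grid search
#'   inside each training fold (nested CV) instead of using `spec`'s values.
#' @param grid_exp Exponent grid for nested tuning.
#' @param train_metrics Also compute resubstitution (training) accuracy/AUC
#'   (default `TRUE`; skipped inside permutation loops for speed).
#' @return An object of class `eval_result`: list with `spec`,
#'   `features_used` (column names of the predictor matrix), `accuracy`,
#'   `auc`, `accuracy_train`, `auc_train`, `per_fold` tibble, `seed`,
#'   `folds`.
#' @export
evaluate_classifier <- function(features, labels, spec, folds = 4, seed = 0,
                                standardize = TRUE, nested = FALSE,
                                grid_exp = -10:10, train_metrics = TRUE) {
  X <- as.matrix(features)
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(y) != 2) abort("evaluate_classifier() needs exactly 2 classes.")
  if (!nested && spec_is_tuned(spec) && identical(spec$cost, "default")) {
    abort("Tuned classifier_spec has no concrete hyperparameters; tune first or use nested = TRUE.")
  }
  fold_id <- make_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  score <- numeric(length(y))
  fold_acc <- rep(NA_real_, folds)
  fold_auc <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    if (!any(te)) next  # possible when a class has fewer members than folds
    fspec <- spec
    if (nested && spec_is_tuned(spec)) {
      fspec <- tune_hyperparameters(X[!te, , drop = FALSE], y[!te], spec$kind,
                                    folds = folds, seed = seed + f,
                                    grid_exp = grid_exp,
                                    standardize = standardize)
    }
    fp <- fit_predict(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                      fspec, standardize)
    pred[te] <- fp$pred
    score[te] <- fp$score
    fold_acc[f] <- mean(fp$pred == y[te])
    fold_auc[f] <- auc_rank(fp$score, y[te])
  }
  fp_tr <- if (train_metrics) fit_predict(X, y, X, spec, standardize)
  used <- which(!is.na(fold_acc))
  structure(
    list(spec = spec,
         features_used = colnames(X) %||% paste0("V", seq_len(ncol(X))),
         accuracy = mean(pred == y),
         auc = auc_rank(score, y),
         accuracy_train = if (train_metrics) mean(fp_tr$pred == y) else NA_real_,
         auc_train = if (train_metrics) auc_rank(fp_tr$score, y) else NA_real_,
         per_fold = tibble::new_tibble(list(fold = used,
                                            accuracy = fold_acc[used],
                                            auc = fold_auc[used]),
                                       nrow = length(used)),
         seed = seed, folds = folds),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> ", x$spec$kind, ": CV accuracy ",
      sprintf("%.3f", x$accuracy), ", CV AUC ", sprintf("%.3f", x$auc),
      " (train ", sprintf("%.3f", x$accuracy_train), "/",
      sprintf("%.3f", x$auc_train), ")\n", sep = "")
  invisible(x)
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustive search over `cost = 2^i` (and, for the RBF kernel,
#' `gamma = 2^j`) for integer exponents `grid_exp` (default `-10:10`, 21
#' values per hyperparameter, 441 pairs for RBF), selecting the combination
#' maximizing mean stratified `folds`-fold cross-validated accuracy. Ties
#' are broken toward smaller cost, then smaller gamma.
#'
#' @inheritParams evaluate_classifier
#' @param kind `"linear_svm_tuned"` or `"rbf_svm_tuned"`.
#' @return A concrete [classifier_spec()] with attributes `cv_accuracy`
#'   (the winning mean CV accuracy) and `grid` (the full search table).
#' @export
tune_hyperparameters <- function(features, labels,
                                 kind = c("linear_svm_tuned", "rbf_svm_tuned"),
                                 folds = 4, seed = 0, grid_exp = -10:10,
                                 standardize = TRUE) {
  kind <- match.arg(kind)
  X <- as.matrix(features)
  y <- factor(labels)
  if (min(table(y)) < folds) {
    abort(paste0("Need >= ", folds, " specimens per class for ", folds,
                 "-fold stratified tuning."))
  }
  fold_id <- make_folds(y, folds, seed)
  costs <- 2^grid_exp
  gammas <- if (kind == "rbf_svm_tuned") 2^grid_exp else NA_real_
  grid <- expand.grid(gamma = gammas, cost = costs)  # cost varies slowest
  grid <- grid[order(grid$cost, grid$gamma), ]
  acc <- numeric(nrow(grid))
  splits <- lapply(seq_len(folds), function(f) fold_id == f)
  for (g in seq_len(nrow(grid))) {
    spec_g <- classifier_spec(kind, cost = grid$cost[g],
                              gamma = if (is.na(grid$gamma[g])) "default" else grid$gamma[g])
    correct <- 0L
    for (te in splits) {
      if (!any(te)) next
      fp <- fit_predict(X[!te, , drop = FALSE], y[!te],
                        X[te, , drop = FALSE], spec_g, standardize)
      correct <- correct + sum(fp$pred == y[te])
    }
    acc[g] <- correct / length(y)
  }
  best <- which.max(acc)  # first max = smallest cost, then smallest gamma
  out <- classifier_spec(kind, cost = grid$cost[best],
                         gamma = if (is.na(grid$gamma[best])) "default" else grid$gamma[best])
  attr(out, "cv_accuracy") <- acc[best]
  attr(out, "grid") <- tibble(cost = grid$cost, gamma = grid$gamma,
                              cv_accuracy = acc)
  out
}

#' Select the best classifier from a set of evaluations
#'
#' Maximizes cross-validated accuracy; ties are broken by AUC, then by model
#' simplicity (LDA before linear SVMs before the RBF SVM).
#'
#' @param results A list of [evaluate_classifier()] results.
#' @return The winning `classifier_spec`.
#' @export
select_best <- function(results) {
  if (length(results) == 0) abort("select_best(): empty result list.")
  simplicity <- c(lda = 1, linear_svm_untuned = 2, linear_svm_tuned = 3,
                  rbf_svm_tuned = 4)
  ord <- order(-vapply(results, `[[`, 0, "accuracy"),
               -vapply(results, `[[`, 0, "auc"),
               simplicity[vapply(results, function(r) r$spec$kind, "")])
  results[[ord[1]]]$spec
}

#' Run the four-model age-classification battery
#'
#' Fits and cross-validates the four models of the battery on the same
#' stratified folds: LDA, untuned linear SVM (cost 1), tuned linear SVM, and
#' tuned RBF SVM. Tuning is non-nested by default (the grid search and the
#' reported evaluation share the fold structure); `nested = TRUE` re-tunes
#' inside each training fold instead.
#'
#' @inheritParams evaluate_classifier
#' @return A tibble with one row per model (`model`, `cost`, `gamma`,
#'   `accuracy`, `auc`, `accuracy_train`, `auc_train`, `seed`) and
#'   attributes `results` (the four `eval_result`s) and `best`
#'   (the [select_best()] winner).
#' @export
classifier_battery <- function(features, labels, folds = 4, seed = 0,
                               grid_exp = -10:10, standardize = TRUE,
                               nested = FALSE) {
  kinds <- c("lda", "linear_svm_untuned", "linear_svm_tuned", "rbf_svm_tuned")
  results <- purrr::map(kinds, function(kind) {
    spec <- if (kind %in% c("linear_svm_tuned", "rbf_svm_tuned") && !nested) {
      tune_hyperparameters(features, labels, kind, folds = folds, seed = seed,
                           grid_exp = grid_exp, standardize = standardize)
    } else {
      classifier_spec(kind)
    }
    evaluate_classifier(features, labels, spec, folds = folds, seed = seed,
                        standardize = standardize, nested = nested,
                        grid_exp = grid_exp)
  })
  out <- purrr::map_dfr(results, function(r) {
    tibble(model = r$spec$kind,
           cost = if (identical(r$spec$cost, "default")) NA_real_ else r$spec$cost,
           gamma = if (identical(r$spec$gamma, "default")) NA_real_ else r$spec$gamma,
           accuracy = r$accuracy, auc = r$auc,
           accuracy_train = r$accuracy_train, auc_train = r$auc_train,
           seed = seed)
  })
  attr(out, "results") <- results
  attr(out, "best") <- select_best(results)
  out
}
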