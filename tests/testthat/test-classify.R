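test_that("folds are stratified and seed-deterministic", {
  y <- factor(rep(c("adult", "infant"), each = 20))
  f1 <- make_folds(y, 4, seed = 3)
  f2 <- make_folds(y, 4, seed = 3)
  f3 <- make_folds(y, 4, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  tab <- table(f1, y)
  expect_true(all(tab == 5))
})

test_that("well-separated clusters give accuracy and AUC of 1 for every kind", {
  toy <- separable_toy(n_per_class = 16, gap = 10)
  for (kind in c("lda", "linear_svm_untuned")) {
    ev <- evaluate_classifier(toy$X, toy$y, classifier_spec(kind), seed = 1)
    expect_equal(ev$accuracy, 1)
    expect_equal(ev$auc, 1)
  }
  for (kind in c("linear_svm_tuned", "rbf_svm_tuned")) {
    spec <- tune_hyperparameters(toy$X, toy$y, kind, seed = 1,
                                 grid_exp = -4:4)
    ev <- evaluate_classifier(toy$X, toy$y, spec, seed = 1)
    expect_equal(ev$accuracy, 1)
    expect_equal(ev$auc, 1)
  }
})

test_that("pooled accuracy equals the mean of per-fold accuracies", {
  toy <- separable_toy(n_per_class = 16, gap = 2)
  ev <- evaluate_classifier(toy$X, toy$y, classifier_spec("lda"), seed = 2)
  expect_equal(ev$accuracy, mean(ev$per_fold$accuracy), tolerance = 1e-12)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
})

test_that("evaluation is bitwise-deterministic under a fixed seed", {
  toy <- separable_toy(n_per_class = 12, gap = 1.5, seed = 5)
  e1 <- evaluate_classifier(toy$X, toy$y, classifier_spec("lda"), seed = 9)
  e2 <- evaluate_classifier(toy$X, toy$y, classifier_spec("lda"), seed = 9)
  expect_identical(e1$accuracy, e2$accuracy)
  expect_identical(e1$auc, e2$auc)
  expect_identical(e1$per_fold, e2$per_fold)
})

test_that("the tuning grid has 21 cost values and ties break to the smallest", {
  toy <- separable_toy(n_per_class = 8, gap = 20, seed = 6)
  spec <- tune_hyperparameters(toy$X, toy$y, "linear_svm_tuned", seed = 1)
  grid <- attr(spec, "grid")
  expect_equal(nrow(grid), 21)
  expect_setequal(grid$cost, 2^(-10:10))
  # wide margin: every cost separates perfectly, tie-break returns 2^-10
  expect_equal(attr(spec, "cv_accuracy"), 1)
  expect_equal(spec$cost, 2^-10)

  spec_rbf <- tune_hyperparameters(toy$X, toy$y, "rbf_svm_tuned", seed = 1,
                                   grid_exp = -2:2)
  expect_equal(nrow(attr(spec_rbf, "grid")), 25)
})

test_that("tuning matches an independent nested-loop re-search", {
  withr::with_seed(7, {
    X <- rbind(matrix(rnorm(40), ncol = 2),
               matrix(rnorm(40, mean = 1.2), ncol = 2))
  })
  y <- factor(rep(c("adult", "infant"), each = 20))
  spec <- tune_hyperparameters(X, y, "rbf_svm_tuned", seed = 4,
                               grid_exp = -2:2)
  fold_id <- make_folds(y, 4, seed = 4)
  best <- c(acc = -1, cost = NA, gamma = NA)
  for (ce in -2:2) for (ge in -2:2) {
    correct <- 0
    for (f in 1:4) {
      te <- fold_id == f
      mu <- colMeans(X[!te, , drop = FALSE])
      sdv <- apply(X[!te, , drop = FALSE], 2, sd)
      tr_z <- sweep(sweep(X[!te, , drop = FALSE], 2, mu), 2, sdv, "/")
      te_z <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
      m <- e1071::svm(tr_z, y[!te], kernel = "radial", cost = 2^ce,
                      gamma = 2^ge, scale = FALSE)
      correct <- correct + sum(predict(m, te_z) == y[te])
    }
    acc <- correct / length(y)
    if (acc > best["acc"]) best <- c(acc = acc, cost = 2^ce, gamma = 2^ge)
  }
  expect_equal(attr(spec, "cv_accuracy"), unname(best["acc"]))
  expect_equal(spec$cost, unname(best["cost"]))
  expect_equal(spec$gamma, unname(best["gamma"]))
})

test_that("the rank AUC matches pROC and is invariant to swap-with-negation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    sc <- rnorm(30)
    y <- factor(sample(rep(c("adult", "infant"), 15)))
  })
  got <- auc_rank(sc, y)
  oracle <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = sc,
                                           levels = c("adult", "infant"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(got, oracle, tolerance = 1e-12)
  # relabel classes and negate scores: AUC unchanged
  y_swap <- factor(ifelse(y == "adult", "infant", "adult"))
  expect_equal(auc_rank(-sc, y_swap), got, tolerance = 1e-12)
  # ties get half credit
  expect_equal(auc_rank(rep(1, 30), y), 0.5)
})

test_that("duplicated feature columns leave LDA predictions unchanged", {
  withr::with_seed(9, {
    X <- rbind(matrix(rnorm(60), ncol = 3),
               matrix(rnorm(60, mean = 1), ncol = 3))
  })
  y <- factor(rep(c("adult", "infant"), each = 20))
  e1 <- evaluate_classifier(X, y, classifier_spec("lda"), seed = 2)
  e2 <- evaluate_classifier(cbind(X, X + matrix(rnorm(120, sd = 1e-6), 40, 3)),
                            y, classifier_spec("lda"), seed = 2)
  expect_equal(e1$accuracy, e2$accuracy, tolerance = 0.051)
})

test_that("select_best maximizes accuracy, then AUC, then simplicity", {
  mk <- function(kind, acc, auc) {
    structure(list(spec = classifier_spec(kind), accuracy = acc, auc = auc),
              class = "eval_result")
  }
  expect_equal(select_best(list(mk("lda", 0.7, 0.8)))$kind, "lda")
  expect_equal(select_best(list(mk("lda", 0.9, 0.80),
                                mk("rbf_svm_tuned", 0.9, 0.95)))$kind,
               "rbf_svm_tuned")
  expect_equal(select_best(list(mk("rbf_svm_tuned", 0.9, 0.9),
                                mk("lda", 0.9, 0.9)))$kind, "lda")
  # the printed quadruple from the study: rbf wins on accuracy then AUC
  quad <- list(mk("lda", 0.80, 0.91),
               mk("linear_svm_untuned", 0.78, 0.95),
               mk("linear_svm_tuned", 0.94, 0.98),
               mk("rbf_svm_tuned", 0.95, 0.98))
  expect_equal(select_best(quad)$kind, "rbf_svm_tuned")
})

test_that("constant features degrade gracefully with a warning", {
  X <- matrix(1, 24, 2)
  y <- factor(rep(c("adult", "infant"), each = 12))
  expect_warning(ev <- evaluate_classifier(X, y, classifier_spec("lda"),
                                           seed = 1), "Degenerate")
  expect_true(is.finite(ev$accuracy))
})

test_that("the battery returns four rows and records hyperparameters", {
  toy <- separable_toy(n_per_class = 10, gap = 3, seed = 10)
  bat <- classifier_battery(toy$X, toy$y, seed = 1, grid_exp = -3:3)
  expect_equal(nrow(bat), 4)
  expect_setequal(bat$model, c("lda", "linear_svm_untuned",
                               "linear_svm_tuned", "rbf_svm_tuned"))
  expect_false(anyNA(bat$cost[bat$model == "linear_svm_tuned"]))
  expect_false(anyNA(bat$gamma[bat$model == "rbf_svm_tuned"]))
  expect_s3_class(attr(bat, "best"), "classifier_spec")
})
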