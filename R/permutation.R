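#' Permutation test of classifier performance
#'
#' Compares the cross-validated performance of a classifier against the
#' empirical null obtained by refitting after randomly permuting the class
#' labels `B` times. The p-value uses the add-one estimator
#' `p = (1 + #[null >= observed]) / (B + 1)`, which can never be exactly
#' zero; its minimum attainable value is `1 / (B + 1)`.
#'
#' When `retune = TRUE` and `spec` is a tuned kind, the hyperparameter grid
#' search is re-run inside every permutation, so that the null distribution
#' reflects the full modelling pipeline. The default is `retune = FALSE`
#' (hyperparameters frozen at their observed-data values): re-tuning an RBF
#' grid inside each of 1000 permutations costs three orders of magnitude
#' more CPU and, in practice, moves permutation accuracies near chance by
#' far less than the resolution of the test; the conservative option remains
#' available.
#'
#' @inheritParams evaluate_classifier
#' @param B Number of permutations (default 1000).
#' @param statistic `"accuracy"` (default) or `"auc"`.
#' @param retune Re-run grid-search tuning inside each permutation.
#' @param grid_exp Exponent grid used when `retune = TRUE`.
#' @return An object of class `permutation_result`: list with
#'   `observed_stat`, `null_stats` (length `B`), `p_value`, `B`, `seed`,
#'   `statistic`, and the observed `eval` result.
#' @export
permutation_test <- function(features, labels, spec, B = 1000, seed = 0,
                             folds = 4, statistic = c("accuracy", "auc"),
                             standardize = TRUE, retune = FALSE,
                             grid_exp = -10:10) {
  statistic <- match.arg(statistic)
  if (B < 1) abort("B must be >= 1.")
  X <- as.matrix(features)
  y <- factor(labels)
  obs_eval <- evaluate_classifier(X, y, spec, folds = folds, seed = seed,
                                  standardize = standardize)
  observed <- obs_eval[[statistic]]
  perms <- withr::with_seed(seed + 1L, {
    replicate(B, sample(length(y)), simplify = FALSE)
  })
  null_stats <- vapply(seq_len(B), function(b) {
    yb <- y[perms[[b]]]
    spec_b <- spec
    if (retune && spec_is_tuned(spec)) {
      spec_b <- tune_hyperparameters(X, yb, spec$kind, folds = folds,
                                     seed = seed, grid_exp = grid_exp,
                                     standardize = standardize)
    }
    evaluate_classifier(X, yb, spec_b, folds = folds, seed = seed,
                        standardize = standardize,
                        train_metrics = FALSE)[[statistic]]
  }, numeric(1))
  structure(
    list(observed_stat = observed, null_stats = null_stats,
         p_value = (1 + sum(null_stats >= observed)) / (B + 1),
         B = B, seed = seed, statistic = statistic, eval = obs_eval),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed ", x$statistic, " = ",
      sprintf("%.3f", x$observed_stat), ", p = ",
      format.pval(x$p_value, digits = 3), " (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Direction of the age effect on a score axis
#'
#' @param scores Numeric vector of per-specimen scores on one axis.
#' @param labels Age classes (`"adult"` / `"infant"`).
#' @return `"A_lt_I"` if the adult mean is below the infant mean,
#'   `"I_lt_A"` if above, `"none"` on an exact tie.
#' @export
direction_of_effect <- function(scores, labels) {
  labels <- factor(labels)
  stopifnot(all(c("adult", "infant") %in% levels(labels)))
  d <- mean(scores[labels == "infant"]) - mean(scores[labels == "adult"])
  if (d > 0) "A_lt_I" else if (d < 0) "I_lt_A" else "none"
}

significance_band <- function(p) {
  dplyr::case_when(
    p < 0.005 ~ "p<.005", p < 0.01 ~ "p<.01", p < 0.05 ~ "p<.05",
    p < 0.10 ~ "p<.10", TRUE ~ "ns"
  )
}

#' Per-component, per-species age-classification table
#'
#' For the pooled dataset and for each species separately, re-fits the
#' chosen classifier on each principal component alone and tabulates
#' cross-validated accuracy, AUC, permutation p-value, effect direction
#' (adult vs infant mean score) and significance band — the long-format
#' analogue of a significant-PCs-and-directions table. Species rows use only
#' that species' specimens but the scores from the joint decomposition of
#' all specimens.
#'
#' Raw permutation p-values are reported (each cell is its own planned
#' test); a Benjamini-Hochberg column `p_bh` over the whole grid is added
#' for transparency. Tuned classifier kinds are re-tuned within each
#' (group, PC) cell before testing (`retune_per_cell`). Cells whose group
#' has fewer than 2 specimens per class are flagged `insufficient_n` and
#' carry `NA` metrics instead of being dropped.
#'
#' @param model A `relative_warp_model` with scores, or a score matrix.
#' @param metadata Metadata tibble with `specimen_id`, `species`,
#'   `age_class` (defaults to the model's).
#' @param pcs Integer vector of components to test (default `1:11`).
#' @param spec [classifier_spec()] used in every cell (default the tuned RBF
#'   SVM, re-tuned per cell).
#' @param B Permutations per cell (default 1000).
#' @param seed Integer seed; each cell derives its own stream from it.
#' @param per_species Also produce one block per species (default `TRUE`).
#' @param retune_per_cell Re-tune tuned kinds on each cell's data.
#' @param statistic,folds,standardize,grid_exp Passed to the classifier
#'   machinery.
#' @return A tibble (`age_class_table`) with columns `group`, `pc`,
#'   `n`, `accuracy`, `auc`, `p_value`, `p_bh`, `direction`, `band`,
#'   `insufficient_n`.
#' @export
per_pc_analysis <- function(model, metadata = NULL, pcs = 1:11,
                            spec = classifier_spec("rbf_svm_tuned"),
                            B = 1000, seed = 0, per_species = TRUE,
                            retune_per_cell = TRUE,
                            statistic = "accuracy", folds = 4,
                            standardize = TRUE, grid_exp = -10:10) {
  if (inherits(model, "relative_warp_model")) {
    scores <- model$scores
    metadata <- metadata %||% model$metadata
  } else {
    scores <- as.matrix(model)
  }
  if (is.null(metadata)) abort("per_pc_analysis() needs specimen metadata.")
  ids <- rownames(scores) %||% metadata$specimen_id
  md <- metadata[match(ids, metadata$specimen_id), ]
  pcs <- pcs[pcs <= ncol(scores)]
  groups <- c("pooled", if (per_species) sort(unique(md$species)))

  rows <- purrr::map_dfr(groups, function(grp) {
    sel <- if (grp == "pooled") rep(TRUE, nrow(md)) else md$species == grp
    y <- factor(md$age_class[sel], levels = c("adult", "infant"))
    purrr::map_dfr(seq_along(pcs), function(j) {
      pc <- pcs[j]
      xs <- scores[sel, pc, drop = FALSE]
      if (min(table(y)) < 2) {
        return(tibble(group = grp, pc = pc, n = sum(sel),
                      accuracy = NA_real_, auc = NA_real_, p_value = NA_real_,
                      direction = NA_character_, band = NA_character_,
                      insufficient_n = TRUE))
      }
      cell_seed <- seed + 1000L * match(grp, groups) + pc
      cell_spec <- spec
      if (retune_per_cell && spec_is_tuned(spec)) {
        cell_spec <- tune_hyperparameters(xs, y, spec$kind, folds = folds,
                                          seed = cell_seed,
                                          grid_exp = grid_exp,
                                          standardize = standardize)
      }
      pt <- permutation_test(xs, y, cell_spec, B = B, seed = cell_seed,
                             folds = folds, statistic = statistic,
                             standardize = standardize)
      tibble(group = grp, pc = pc, n = sum(sel),
             accuracy = pt$eval$accuracy, auc = pt$eval$auc,
             p_value = pt$p_value,
             direction = direction_of_effect(scores[sel, pc], y),
             band = significance_band(pt$p_value),
             insufficient_n = FALSE)
    })
  })
  rows$p_bh <- stats::p.adjust(rows$p_value, method = "BH")
  rows <- rows %>%
    select("group", "pc", "n", "accuracy", "auc", "p_value", "p_bh",
           "direction", "band", "insufficient_n")
  class(rows) <- c("age_class_table", class(rows))
  rows
}
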