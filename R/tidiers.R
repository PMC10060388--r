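#' Tidy a Procrustes fit
#'
#' One row per specimen: original centroid size and root-summed-squared
#' Procrustes residual distance to the consensus, joined to metadata when
#' available.
#'
#' @param x A `procrustes_fit`.
#' @param ... Unused.
#' @method tidy procrustes_fit
#' @export
tidy.procrustes_fit <- function(x, ...) {
  out <- tibble(specimen_id = dimnames(x$aligned)[[3]],
                centroid_size = unname(x$centroid_sizes),
                procrustes_distance = unname(procrustes_distances(x)))
  if (!is.null(x$metadata)) out <- left_join(out, x$metadata, by = "specimen_id")
  out
}

#' @rdname tidy.procrustes_fit
#' @method glance procrustes_fit
#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble(n_specimens = dim(x$aligned)[3], k_landmarks = dim(x$aligned)[1],
         n_iterations = x$n_iterations, converged = x$converged,
         total_procrustes_ss = utils::tail(x$trace, 1),
         sliding_mode = x$sliding_mode)
}

#' Tidy a relative-warp model
#'
#' `tidy()` returns the per-component variance table; `augment()` returns
#' per-specimen PC scores joined to metadata; `glance()` a one-row model
#' summary.
#'
#' @param x A `relative_warp_model`.
#' @param ... Unused.
#' @method tidy relative_warp_model
#' @export
tidy.relative_warp_model <- function(x, ...) variance_table(x)

#' @rdname tidy.relative_warp_model
#' @method augment relative_warp_model
#' @export
augment.relative_warp_model <- function(x, ...) score_table(x)

#' @rdname tidy.relative_warp_model
#' @method glance relative_warp_model
#' @export
glance.relative_warp_model <- function(x, ...) {
  vt <- variance_table(x)
  j <- min(11, nrow(vt))
  tibble(n_specimens = nrow(x$scores), n_nontrivial_pcs = x$n_nontrivial,
         alpha = x$alpha,
         cumvar_11 = vt$cumulative_fraction[j])
}

#' Tidy a classifier evaluation
#'
#' `tidy()` gives per-fold accuracy/AUC; `glance()` the pooled
#' cross-validated and training metrics.
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @method tidy eval_result
#' @export
tidy.eval_result <- function(x, ...) x$per_fold

#' @rdname tidy.eval_result
#' @method glance eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble(model = x$spec$kind,
         cost = if (identical(x$spec$cost, "default")) NA_real_ else x$spec$cost,
         gamma = if (identical(x$spec$gamma, "default")) NA_real_ else x$spec$gamma,
         accuracy = x$accuracy, auc = x$auc,
         accuracy_train = x$accuracy_train, auc_train = x$auc_train,
         folds = x$folds, seed = x$seed)
}

#' Tidy a permutation test
#'
#' `tidy()` returns the null statistics; `glance()` the observed statistic
#' and p-value.
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_len(x$B), null_stat = x$null_stats)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed_stat,
         p_value = x$p_value, B = x$B, seed = x$seed)
}

#' Tidy a reliability report
#'
#' `tidy()` returns per-landmark, per-axis ICCs; `glance()` the summary
#' means and ranges.
#'
#' @param x A `reliability_report`.
#' @param ... Unused.
#' @method tidy reliability_report
#' @export
tidy.reliability_report <- function(x, ...) x$per_landmark

#' @rdname tidy.reliability_report
#' @method glance reliability_report
#' @export
glance.reliability_report <- function(x, ...) {
  tibble(icc_form = x$icc_form, n_specimens = x$n_specimens,
         mean_x = x$mean_x, min_x = x$range_x[1], max_x = x$range_x[2],
         mean_y = x$mean_y, min_y = x$range_y[1], max_y = x$range_y[2])
}
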