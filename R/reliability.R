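#' Intra-annotator landmark reliability (ICC)
#'
#' Quantifies digitization reproducibility when the same annotator places
#' the landmarks twice on the same specimens: for every landmark and axis,
#' an intraclass correlation coefficient is computed across the two sessions
#' over specimens. The default form is two-way random, single measures,
#' absolute agreement — ICC(A,1) — the defensible choice for coordinate
#' reproducibility since a constant session offset should count against
#' agreement; a consistency form ICC(C,1) is available.
#'
#' Landmarks with zero between-specimen variance have an undefined ICC and
#' are reported as `NA` with a warning.
#'
#' @param session_a,session_b Landmark tibbles covering the same specimens
#'   (matched by `specimen_id`; at least 3) with the same landmark count.
#' @param form `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @return An object of class `reliability_report`: list with `per_landmark`
#'   (tibble `landmark`, `axis`, `icc`), `mean_x`, `mean_y`, `range_x`,
#'   `range_y`, `n_specimens`, `icc_form`.
#' @export
icc_report <- function(session_a, session_b,
                       form = c("agreement", "consistency")) {
  form <- match.arg(form)
  A <- landmark_array(session_a)
  B <- landmark_array(session_b)
  ids_a <- dimnames(A)[[3]]; ids_b <- dimnames(B)[[3]]
  if (!setequal(ids_a, ids_b)) {
    abort(paste0("Sessions cover different specimens; only in A: ",
                 paste(setdiff(ids_a, ids_b), collapse = ", "),
                 "; only in B: ", paste(setdiff(ids_b, ids_a), collapse = ", ")))
  }
  if (dim(A)[1] != dim(B)[1]) abort("Sessions have different landmark counts.")
  n <- length(ids_a)
  if (n < 3) abort("icc_report() needs at least 3 matched specimens.")
  B <- B[, , ids_a, drop = FALSE]
  k <- dim(A)[1]

  cells <- purrr::map_dfr(seq_len(k), function(lm) {
    purrr::map_dfr(1:2, function(ax) {
      tibble(landmark = lm, axis = c("x", "y")[ax],
             icc = icc_two_way(cbind(A[lm, ax, ], B[lm, ax, ]), form))
    })
  })
  if (anyNA(cells$icc)) {
    warn(paste0("ICC undefined (zero between-specimen variance) for ",
                sum(is.na(cells$icc)), " landmark-axis cell(s); reported as NA."))
  }
  xs <- cells$icc[cells$axis == "x"]; ys <- cells$icc[cells$axis == "y"]
  structure(
    list(per_landmark = cells,
         mean_x = mean(xs, na.rm = TRUE), mean_y = mean(ys, na.rm = TRUE),
         range_x = range(xs, na.rm = TRUE), range_y = range(ys, na.rm = TRUE),
         n_specimens = n,
         icc_form = if (form == "agreement") "ICC(A,1)" else "ICC(C,1)"),
    class = "reliability_report"
  )
}

# Two-way single-measure ICC over an n x k matrix (rows = specimens,
# columns = sessions), from the two-way ANOVA mean squares.
icc_two_way <- function(Y, form) {
  n <- nrow(Y); k <- ncol(Y)
  rm_ <- rowMeans(Y); cm_ <- colMeans(Y); g <- mean(Y)
  MSR <- k * sum((rm_ - g)^2) / (n - 1)
  MSC <- n * sum((cm_ - g)^2) / (k - 1)
  MSE <- sum((Y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g)^2) /
    ((n - 1) * (k - 1))
  denom <- if (form == "agreement") {
    MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  } else {
    MSR + (k - 1) * MSE
  }
  if (abs(denom) < .Machine$double.eps) return(NA_real_)
  (MSR - MSE) / denom
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report> ", x$icc_form, " over ", x$n_specimens,
      " re-digitized specimens\n", sep = "")
  cat(sprintf("  x-coordinates: mean %.3f (%.3f-%.3f)\n",
              x$mean_x, x$range_x[1], x$range_x[2]))
  cat(sprintf("  y-coordinates: mean %.3f (%.3f-%.3f)\n",
              x$mean_y, x$range_y[1], x$range_y[2]))
  invisible(x)
}
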