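#' Optimal rotation between two centered configurations
#'
#' Returns the 2 x 2 proper rotation (determinant +1; reflections are never
#' allowed, since faces have a left/right identity) minimizing the summed
#' squared distances between `source %*% R` and `target`, via the SVD of the
#' cross-covariance matrix.
#'
#' @param source,target Centered `k x 2` matrices with the same `k`.
#' @return A 2 x 2 rotation matrix `R` such that `source %*% R` best matches
#'   `target`.
#' @export
optimal_rotation <- function(source, target) {
  stopifnot(nrow(source) == nrow(target))
  M <- crossprod(source, target)
  if (sum(M^2) < .Machine$double.eps^2) {
    abort("Zero cross-covariance: cannot align degenerate configurations.")
  }
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Superimposes all configurations by iterated translation, scaling and
#' rotation: each specimen is centered and scaled to unit centroid size,
#' rotated to the current consensus, and the consensus is recomputed as the
#' mean of the aligned specimens re-normalized to unit centroid size (which
#' is the least-squares consensus among unit-size shapes). Iteration stops
#' when the root-sum-square change in the consensus falls below `tol` or
#' after `max_iter` iterations; non-convergence sets `converged = FALSE` with
#' a warning rather than an error. A final rotation pass against the
#' converged consensus makes the rotation optimality conditions hold exactly.
#'
#' @param dataset A `landmark_dataset`, a landmark tibble, or a `k x 2 x n`
#'   array.
#' @param tol Convergence tolerance on the consensus change (default 1e-8).
#' @param max_iter Maximum GPA iterations (default 100).
#' @return An object of class `procrustes_fit`: list with `aligned`
#'   (`k x 2 x n`), `consensus` (`k x 2`, centroid at origin, unit centroid
#'   size), `centroid_sizes` (original scale), `n_iterations`, `converged`,
#'   `trace` (summed squared residuals per iteration, non-increasing),
#'   `sliding_mode` (`"none"`), and the dataset's `metadata`/`sliders` when
#'   available.
#' @seealso [slide_semilandmarks()], [tangent_project()]
#' @export
gpa <- function(dataset, tol = 1e-8, max_iter = 100) {
  parts <- dataset_parts(dataset)
  arr <- parts$arr
  n <- dim(arr)[3]
  if (n < 2) abort("GPA needs at least 2 configurations.")

  sizes <- numeric(n)
  aligned <- arr
  for (i in seq_len(n)) {
    m <- center_config(arr[, , i])
    cs <- sqrt(sum(m^2))
    if (cs <= .Machine$double.eps * nrow(m)) {
      abort(paste0("Degenerate specimen (zero centroid size): '",
                   dimnames(arr)[[3]][i], "'."))
    }
    sizes[i] <- cs
    aligned[, , i] <- m / cs
  }
  names(sizes) <- dimnames(arr)[[3]]

  consensus <- aligned[, , 1]
  consensus <- consensus / sqrt(sum(consensus^2))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
    }
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    trace <- c(trace, sum(sweep(aligned, c(1, 2), consensus)^2))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(paste0("GPA did not converge in ", max_iter, " iterations."))
  }
  for (i in seq_len(n)) { # exact optimality w.r.t. the final consensus
    aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
  }
  structure(
    list(aligned = aligned, consensus = consensus, centroid_sizes = sizes,
         n_iterations = iter, converged = converged, trace = trace,
         sliding_mode = "none", metadata = parts$metadata,
         sliders = parts$sliders),
    class = "procrustes_fit"
  )
}

dataset_parts <- function(dataset) {
  if (inherits(dataset, "landmark_dataset")) {
    list(arr = landmark_array(dataset$landmarks), metadata = dataset$metadata,
         sliders = dataset$sliders)
  } else if (is.data.frame(dataset)) {
    list(arr = landmark_array(dataset), metadata = NULL, sliders = NULL)
  } else if (is.array(dataset) && length(dim(dataset)) == 3) {
    list(arr = dataset, metadata = NULL, sliders = NULL)
  } else {
    abort("Expected a landmark_dataset, a landmark tibble, or a k x 2 x n array.")
  }
}

#' Project aligned shapes into the tangent space at the consensus
#'
#' Orthogonal projection of each aligned, flattened configuration onto the
#' hyperplane tangent to the unit sphere of shapes at the consensus:
#' `row = v - (v . c) c`, with `c` the flattened consensus (unit norm). Rows
#' are therefore consensus-centered (the consensus maps to the zero row) and
#' the projection is idempotent. Flattening order is `(x1, y1, x2, y2, ...)`.
#'
#' @param fit A `procrustes_fit`.
#' @return An `n x 2k` numeric matrix with specimen ids as row names.
#' @export
tangent_project <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  cvec <- flatten_config(fit$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  n <- dim(fit$aligned)[3]
  rows <- matrix(NA_real_, n, length(cvec),
                 dimnames = list(dimnames(fit$aligned)[[3]], NULL))
  for (i in seq_len(n)) {
    v <- flatten_config(fit$aligned[, , i])
    rows[i, ] <- v - sum(v * cvec) * cvec
  }
  rows
}

#' Procrustes residual distances to the consensus
#'
#' @param fit A `procrustes_fit`.
#' @return A named numeric vector of root-summed-squared distances of each
#'   aligned specimen to the consensus.
#' @export
procrustes_distances <- function(fit) {
  apply(sweep(fit$aligned, c(1, 2), fit$consensus), 3, function(m) sqrt(sum(m^2)))
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> ", dim(x$aligned)[3], " specimens x ",
      dim(x$aligned)[1], " landmarks\n", sep = "")
  cat("  iterations: ", x$n_iterations,
      if (x$converged) " (converged)" else " (NOT converged)",
      "; sliding: ", x$sliding_mode, "\n", sep = "")
  cat("  total Procrustes SS: ", format(utils::tail(x$trace, 1), digits = 6), "\n", sep = "")
  invisible(x)
}
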