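#' Relative warp (shape principal component) decomposition
#'
#' Decomposes tangent-space shape coordinates into relative warps. With the
#' default `alpha = 0` (uniform weighting of all spatial scales) this is an
#' ordinary principal component analysis of the shape coordinates —
#' implemented as an eigendecomposition of their covariance matrix. With
#' `alpha != 0` the non-affine part of each shape is first expressed in the
#' partial-warp basis of the bending-energy model `be` and its components
#' scaled by `lambda^(-alpha/2)` (positive `alpha` emphasizes large-scale,
#' small-bending-energy variation; the affine component keeps weight 1)
#' before the PCA.
#'
#' Eigen-pairs with eigenvalue below `1e-12` times the largest are reported
#' as trivial and dropped from scores/eigenvectors; `n_nontrivial` records
#' how many remain. For `n` generic specimens of `k` 2-D landmarks after
#' Procrustes alignment and tangent projection this is `min(n - 1, 2k - 4)`.
#'
#' Each eigenvector's sign is fixed so that, when `metadata` with an
#' `age_class` column is available, the infant mean score minus the adult
#' mean score is non-negative on the fitted data; otherwise so that the
#' largest-magnitude loading is positive. This makes "adult < infant" effect
#' directions reproducible across runs and platforms.
#'
#' @param x A `procrustes_fit` (tangent coordinates are computed via
#'   [tangent_project()]) or an `n x 2k` matrix of tangent rows.
#' @param alpha Relative-warp weighting exponent (default 0 = plain PCA).
#' @param be A [bending_energy()] model; required when `alpha != 0`.
#' @param metadata Optional metadata tibble (defaults to the fit's) used
#'   only for the sign convention.
#' @return An object of class `relative_warp_model`: list with `consensus`,
#'   `eigenvectors` (`2k x m`, columns unit norm, flattening order
#'   `(x1, y1, ...)`), `eigenvalues`, `scores` (`n x m`, named columns
#'   `PC1..PCm`), `variance_fraction`, `n_nontrivial`, `alpha`, `center`.
#' @export
relative_warps <- function(x, alpha = 0, be = NULL, metadata = NULL) {
  if (inherits(x, "procrustes_fit")) {
    rows <- tangent_project(x)
    consensus <- x$consensus
    metadata <- metadata %||% x$metadata
  } else {
    rows <- as.matrix(x)
    consensus <- NULL
  }
  n <- nrow(rows)
  if (n < 2) abort("relative_warps() needs at least 2 specimens.")
  if (alpha != 0 && is.null(be)) {
    abort("alpha != 0 requires a bending-energy model `be`.")
  }

  Wmat <- NULL
  if (alpha != 0) {
    eig <- eigen(be$energy_matrix, symmetric = TRUE)
    pos <- eig$values > 1e-10 * max(eig$values)
    V <- eig$vectors[, pos, drop = FALSE]         # non-affine basis, k x (k-3)
    lam <- eig$values[pos]
    k <- nrow(be$energy_matrix)
    # weight operator on interleaved 2k vectors: scale partial-warp
    # components by lam^(-alpha/2), keep the complement (affine) unweighted
    Wk <- diag(k) + V %*% diag(lam^(-alpha / 2) - 1) %*% t(V)
    Wmat <- matrix(0, 2 * k, 2 * k)
    idx_x <- seq(1, 2 * k, by = 2); idx_y <- idx_x + 1
    Wmat[idx_x, idx_x] <- Wk; Wmat[idx_y, idx_y] <- Wk
    rows <- rows %*% Wmat   # Wmat symmetric
  }

  ctr <- colMeans(rows)
  centered <- sweep(rows, 2, ctr)
  eg <- eigen(cov(centered), symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  nontrivial <- which(vals >= 1e-12 * max(vals))
  m <- length(nontrivial)
  vecs <- eg$vectors[, nontrivial, drop = FALSE]
  vals <- vals[nontrivial]
  scores <- centered %*% vecs

  # sign convention
  age <- if (!is.null(metadata) && "age_class" %in% names(metadata) &&
             !is.null(rownames(rows))) {
    metadata$age_class[match(rownames(rows), metadata$specimen_id)]
  } else NULL
  for (j in seq_len(m)) {
    flip <- if (!is.null(age) && !anyNA(age) && all(c("adult", "infant") %in% age)) {
      d <- mean(scores[age == "infant", j]) - mean(scores[age == "adult", j])
      if (d != 0) d < 0 else vecs[which.max(abs(vecs[, j])), j] < 0
    } else {
      vecs[which.max(abs(vecs[, j])), j] < 0
    }
    if (flip) { vecs[, j] <- -vecs[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(scores) <- paste0("PC", seq_len(m))
  colnames(vecs) <- paste0("PC", seq_len(m))

  structure(
    list(consensus = consensus, eigenvectors = vecs, eigenvalues = vals,
         scores = scores, variance_fraction = vals / sum(vals),
         n_nontrivial = m, alpha = alpha, center = ctr,
         weight_matrix = Wmat, metadata = metadata),
    class = "relative_warp_model"
  )
}

#' Per-component variance table
#'
#' @param model A `relative_warp_model`.
#' @return A tibble with `pc`, `eigenvalue`, `variance_fraction`,
#'   `cumulative_fraction` (non-decreasing, ending at 1).
#' @export
variance_table <- function(model) {
  stopifnot(inherits(model, "relative_warp_model"))
  tibble(
    pc = seq_len(model$n_nontrivial),
    eigenvalue = model$eigenvalues,
    variance_fraction = model$variance_fraction,
    cumulative_fraction = cumsum(model$variance_fraction)
  )
}

#' PC scores joined to specimen metadata
#'
#' @param model A `relative_warp_model` fitted from a `procrustes_fit` that
#'   carried metadata (or pass `metadata`).
#' @param metadata Optional metadata tibble.
#' @return A tibble with `specimen_id`, metadata columns, and `PC1..PCm`.
#' @export
score_table <- function(model, metadata = NULL) {
  stopifnot(inherits(model, "relative_warp_model"))
  metadata <- metadata %||% model$metadata
  sc <- as_tibble(model$scores)
  sc$specimen_id <- rownames(model$scores) %||% as.character(seq_len(nrow(sc)))
  out <- sc %>% select("specimen_id", dplyr::everything())
  if (!is.null(metadata)) out <- left_join(metadata, out, by = "specimen_id")
  out
}

#' Reconstruct the landmark configuration at a given PC score
#'
#' Returns `consensus + score * eigenvector[pc]`, unflattened to `k x 2` —
#' with `score = c * sqrt(eigenvalue)` this draws the shape `c` standard
#' deviations along a component, e.g. the +/-1.5 SD extremes used to
#' visualize what a component means anatomically.
#'
#' @param model A `relative_warp_model` fitted from a `procrustes_fit`.
#' @param pc Component index (1-based).
#' @param score Score (in the same units as `model$scores`).
#' @return A `k x 2` matrix.
#' @export
shape_at_score <- function(model, pc, score) {
  stopifnot(inherits(model, "relative_warp_model"))
  if (pc < 1 || pc > model$n_nontrivial) {
    abort(paste0("pc must be in 1..", model$n_nontrivial, "."))
  }
  if (is.null(model$consensus)) {
    abort("Model has no consensus shape (fitted from a bare matrix).")
  }
  v <- model$eigenvectors[, pc]
  if (!is.null(model$weight_matrix)) { # undo alpha-weighting for display
    v <- solve(model$weight_matrix, v)
  }
  base <- flatten_config(model$consensus) + score * v
  unflatten_config(base)
}

#' Mean shape of a subset of aligned specimens
#'
#' Arithmetic mean of the aligned configurations selected by filtering the
#' fit's metadata (e.g. `species == "bonobo", age_class == "infant"`),
#' re-normalized to unit centroid size. With no filter this returns the
#' consensus (GPA fixed point) up to numerical tolerance.
#'
#' @param fit A `procrustes_fit` carrying metadata.
#' @param ... Filtering expressions evaluated on the metadata
#'   (as in [dplyr::filter()]). Omit to average all specimens.
#' @return A `k x 2` matrix (centroid at origin, unit centroid size).
#' @export
mean_shape <- function(fit, ...) {
  stopifnot(inherits(fit, "procrustes_fit"))
  ids <- dimnames(fit$aligned)[[3]]
  quos <- rlang::enquos(...)
  if (length(quos) > 0) {
    if (is.null(fit$metadata)) abort("Fit carries no metadata to filter on.")
    keep <- fit$metadata %>% filter(!!!quos) %>% pull(.data$specimen_id)
  } else {
    keep <- ids
  }
  sel <- which(ids %in% keep)
  if (length(sel) == 0) {
    abort(paste0("Empty subset: ", paste(vapply(quos, rlang::quo_text, ""),
                                         collapse = ", ")))
  }
  m <- apply(fit$aligned[, , sel, drop = FALSE], c(1, 2), mean)
  m <- center_config(m)
  m / sqrt(sum(m^2))
}

#' @export
print.relative_warp_model <- function(x, ...) {
  cat("<relative_warp_model> ", nrow(x$scores), " specimens, ",
      x$n_nontrivial, " non-trivial PCs (alpha = ", x$alpha, ")\n", sep = "")
  vt <- variance_table(x)
  cat("  PC1..PC", min(11, nrow(vt)), " cumulative variance: ",
      sprintf("%.1f%%", 100 * vt$cumulative_fraction[min(11, nrow(vt))]),
      "\n", sep = "")
  invisible(x)
}
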