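#' Slide semilandmarks along their outlines
#'
#' Semilandmarks mark positions along curves whose exact placement along the
#' curve is arbitrary; sliding removes that arbitrary tangential variation.
#' Each semilandmark may move only along its tangent direction — the unit
#' chord from its `before` to its `after` landmark in the current specimen —
#' with the displacement chosen to minimize either
#'
#' * `"procrustes_distance"` (default): the Procrustes distance to the
#'   consensus, which is the closed-form orthogonal projection of each
#'   semilandmark's residual onto its tangent, independently per
#'   semilandmark; or
#' * `"bending_energy"` (the tpsRelw convention): the thin-plate-spline
#'   bending energy of the specimen's displacement field relative to the
#'   consensus, solved jointly over all semilandmarks.
#'
#' The bending-energy solve is a linearization that treats the outline as
#' straight along the chord. Smooth tangential flows along an outline carry
#' little bending energy, so the unconstrained minimizer can slide points
#' far beyond the chord's validity, and iterating the slide + GPA cycle
#' then inflates, rather than reduces, the total Procrustes sum of squares.
#' Each bending-energy slide is therefore limited to `cap_frac` times the
#' specimen's chord length — a trust region for the linearization. The
#' Procrustes-distance criterion needs no cap (its displacement is bounded
#' by the residual), which is why it is the default.
#'
#' After each sliding pass the generalized Procrustes fit is re-run, and the
#' slide + GPA cycle repeats `outer_iter` times or until the consensus stops
#' changing. Non-semilandmark points never move during sliding. A singular
#' bending-energy system for a specimen falls back to the
#' Procrustes-distance criterion for that specimen with a warning.
#'
#' @param fit A converged [gpa()] fit.
#' @param sliders Slider tibble (`before`, `slider`, `after`, 1-based);
#'   defaults to the sliders stored in the fit.
#' @param mode `"procrustes_distance"` or `"bending_energy"`.
#' @param outer_iter Maximum slide + GPA cycles (default 5).
#' @param cap_frac Trust-region cap on bending-energy slides, as a fraction
#'   of each semilandmark's chord length (default 0.25).
#' @param tol Consensus-change tolerance for stopping early (default 1e-8).
#' @return A `procrustes_fit` with `sliding_mode` set and an `outer_trace`
#'   of consensus changes per cycle.
#' @export
slide_semilandmarks <- function(fit, sliders = NULL,
                                mode = c("procrustes_distance", "bending_energy"),
                                outer_iter = 5, tol = 1e-8, cap_frac = 0.25) {
  stopifnot(inherits(fit, "procrustes_fit"))
  mode <- match.arg(mode)
  sliders <- sliders %||% fit$sliders
  if (is.null(sliders)) abort("No slider table supplied or stored in the fit.")
  k <- dim(fit$aligned)[1]
  validate_sliders(sliders, k)

  aligned <- fit$aligned
  consensus <- fit$consensus
  sizes <- fit$centroid_sizes
  outer_trace <- numeric(0)
  fell_back <- FALSE
  n <- dim(aligned)[3]

  for (cycle in seq_len(outer_iter)) {
    be <- if (mode == "bending_energy") bending_energy(consensus) else NULL
    for (i in seq_len(n)) {
      res <- slide_one(aligned[, , i], consensus, sliders, mode, be, cap_frac)
      aligned[, , i] <- res$config
      fell_back <- fell_back || res$fell_back
    }
    refit <- gpa(array(aligned, dim = dim(aligned), dimnames = dimnames(aligned)))
    aligned <- refit$aligned
    delta <- sqrt(sum((refit$consensus - consensus)^2))
    consensus <- refit$consensus
    outer_trace <- c(outer_trace, delta)
    if (delta < tol) break
  }
  if (fell_back) {
    warn("Singular bending-energy system for >=1 specimen; used Procrustes-distance sliding there.")
  }
  structure(
    list(aligned = aligned, consensus = consensus, centroid_sizes = sizes,
         n_iterations = fit$n_iterations, converged = fit$converged,
         trace = fit$trace, outer_trace = outer_trace, sliding_mode = mode,
         metadata = fit$metadata, sliders = sliders),
    class = "procrustes_fit"
  )
}

# Slide the semilandmarks of one aligned specimen toward the consensus.
slide_one <- function(X, consensus, sliders, mode, be = NULL, cap_frac = 0.25) {
  m <- nrow(sliders)
  tangents <- matrix(0, m, 2)
  chord_len <- numeric(m)
  for (j in seq_len(m)) {
    chord <- X[sliders$after[j], ] - X[sliders$before[j], ]
    len <- sqrt(sum(chord^2))
    chord_len[j] <- len
    if (len > .Machine$double.eps^0.5) tangents[j, ] <- chord / len
  }
  fell_back <- FALSE
  if (mode == "procrustes_distance") {
    for (j in seq_len(m)) {
      s <- sliders$slider[j]
      d <- sum((consensus[s, ] - X[s, ]) * tangents[j, ])
      X[s, ] <- X[s, ] + d * tangents[j, ]
    }
  } else {
    k <- nrow(X)
    Bk <- be$energy_matrix
    # residual displacement field, k x 2, and its bending-energy gradient
    H0 <- X - consensus
    # A[j,l] = t_j' (B2)_{s_j s_l} t_l with B2 = Bk acting per axis
    S <- sliders$slider
    Bss <- Bk[S, S, drop = FALSE]
    A <- Bss * (tangents %*% t(tangents))
    b <- -rowSums((Bk[S, , drop = FALSE] %*% H0) * tangents)
    w <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) {
      fell_back <- TRUE
      for (j in seq_len(m)) {
        s <- S[j]
        d <- sum((consensus[s, ] - X[s, ]) * tangents[j, ])
        X[s, ] <- X[s, ] + d * tangents[j, ]
      }
    } else {
      w <- pmin(pmax(w, -cap_frac * chord_len), cap_frac * chord_len)
      X[S, ] <- X[S, ] + tangents * w
    }
  }
  list(config = X, fell_back = fell_back)
}
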