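# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by different routes than the
# package implementation (brute force, grid scan, quadrature, textbook
# formulas) so agreement is evidence, not tautology.

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# random k x 2 x n array of noisy copies of a base shape
random_shapes <- function(k, n, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(k * 2), k, 2)
    arr <- array(NA_real_, c(k, 2, n),
                 dimnames = list(NULL, NULL, paste0("s", seq_len(n))))
    for (i in seq_len(n)) arr[, , i] <- base + matrix(rnorm(2 * k, sd = sd), k, 2)
    arr
  })
}

apply_similarity <- function(m, theta = 0, scale = 1, shift = c(0, 0)) {
  scale * (m %*% rot2(theta)) + matrix(shift, nrow(m), 2, byrow = TRUE)
}

# Brute-force optimal rotation by scanning angles at `step` degrees.
scan_rotation <- function(source, target, step = 0.001) {
  angles <- seq(-180, 180, by = step) * pi / 180
  rss <- vapply(angles, function(a) sum((source %*% rot2(a) - target)^2),
                numeric(1))
  angles[which.min(rss)]
}

# Alternating-minimization GPA oracle with a different update order than the
# package (sequential specimen rotations, consensus updated after each
# specimen, plain mean without renormalization until the end).
gpa_oracle <- function(arr, iters = 2000) {
  n <- dim(arr)[3]
  for (i in seq_len(n)) {
    m <- scale(arr[, , i], scale = FALSE)
    arr[, , i] <- m / sqrt(sum(m^2))
  }
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      cons <- apply(arr[, , -i, drop = FALSE], c(1, 2), mean)
      sv <- svd(crossprod(arr[, , i], cons))
      d <- sign(det(sv$u %*% t(sv$v))); if (d == 0) d <- 1
      arr[, , i] <- arr[, , i] %*% (sv$u %*% diag(c(1, d)) %*% t(sv$v))
    }
  }
  cons <- apply(arr, c(1, 2), mean)
  cons <- scale(cons, scale = FALSE)
  cons <- cons / sqrt(sum(cons^2))
  list(aligned = arr, consensus = cons,
       ss = sum(sweep(arr, c(1, 2), cons)^2))
}

# Numerically integrated thin-plate bending energy of the spline
# interpolating x-displacements h over reference ref, via midpoint
# quadrature of (f_xx^2 + 2 f_xy^2 + f_yy^2) / (16 pi).
quadrature_bending_energy <- function(ref, h, lo = -19.5, hi = 20.5, nn = 800) {
  d2m <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2m > 0, d2m * log(d2m), 0)
  L <- rbind(cbind(K, cbind(1, ref)),
             cbind(t(cbind(1, ref)), matrix(0, 3, 3)))
  w <- solve(L, c(h, 0, 0, 0))[seq_len(nrow(ref))]
  hx <- (hi - lo) / nn
  xs <- seq(lo + hx / 2, hi - hx / 2, length.out = nn)
  total <- 0
  for (px in xs) {
    fxx <- 0; fxy <- 0; fyy <- 0
    for (i in seq_len(nrow(ref))) {
      dx <- px - ref[i, 1]; dy <- xs - ref[i, 2]
      r2 <- dx^2 + dy^2
      lg <- log(r2)
      fxx <- fxx + w[i] * (2 * (lg + 1) + 4 * dx^2 / r2)
      fyy <- fyy + w[i] * (2 * (lg + 1) + 4 * dy^2 / r2)
      fxy <- fxy + w[i] * (4 * dx * dy / r2)
    }
    total <- total + sum(fxx^2 + 2 * fxy^2 + fyy^2)
  }
  total * hx^2 / (16 * pi)
}

# Two well-separated Gaussian clusters for classifier sanity checks.
separable_toy <- function(n_per_class = 20, gap = 10, p = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p) + gap, ncol = p))
  })
  list(X = X, y = factor(rep(c("adult", "infant"), each = n_per_class)))
}

# small synthetic landmark dataset for fast end-to-end tests
small_dataset <- function(n_per_cell = 4, seed = 1, ...) {
  simulate_dataset(synthetic_truth(seed = seed, ...),
                   n_per_cell = n_per_cell, seed = seed)
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
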