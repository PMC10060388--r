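test_that("centroid size matches hand values, homogeneity and brute force", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(2), tolerance = 1e-12)

  withr::with_seed(5, {
    cfg <- matrix(rnorm(97 * 2), 97, 2)
  })
  ctr <- colMeans(cfg)
  brute <- sqrt(sum((cfg[, 1] - ctr[1])^2 + (cfg[, 2] - ctr[2])^2))
  expect_equal(centroid_size(cfg), brute, tolerance = 1e-12)

  expect_error(centroid_size(matrix(1, 4, 2)), "Degenerate")
})

test_that("optimal rotation recovers exact rotations and matches a grid scan", {
  withr::with_seed(11, {
    src <- scale(matrix(rnorm(20), 10, 2), scale = FALSE)
  })
  expect_equal(optimal_rotation(src, src), diag(2), tolerance = 1e-9)

  R90 <- rot2(pi / 2)
  Rhat <- optimal_rotation(src, src %*% R90)
  expect_equal(Rhat, R90, tolerance = 1e-9)
  expect_equal(det(Rhat), 1, tolerance = 1e-12)

  # noisy pair: minimized residual matches a fine brute-force angle scan
  withr::with_seed(12, {
    tgt <- scale(src %*% rot2(0.7) + matrix(rnorm(20, sd = 0.1), 10, 2),
                 scale = FALSE)
  })
  Ropt <- optimal_rotation(src, tgt)
  ang_opt <- atan2(Ropt[2, 1], Ropt[1, 1])
  ang_scan <- scan_rotation(src, tgt, step = 0.001)
  expect_equal(ang_opt, ang_scan, tolerance = 0.001 * pi / 180 + 1e-9)

  expect_error(optimal_rotation(matrix(0, 5, 2), src[1:5, ]),
               "cross-covariance")
})

test_that("reflections are never used even when they fit better", {
  withr::with_seed(13, {
    src <- scale(matrix(rnorm(16), 8, 2), scale = FALSE)
  })
  tgt <- cbind(-src[, 1], src[, 2])  # pure reflection
  R <- optimal_rotation(src, tgt)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("GPA aligns similarity-transformed copies of one shape exactly", {
  withr::with_seed(21, {
    base <- matrix(rnorm(24), 12, 2)
    arr <- array(NA_real_, c(12, 2, 6),
                 dimnames = list(NULL, NULL, paste0("s", 1:6)))
    for (i in 1:6) {
      arr[, , i] <- apply_similarity(base, theta = runif(1, -pi, pi),
                                     scale = runif(1, 0.5, 2),
                                     shift = rnorm(2, sd = 5))
    }
  })
  fit <- gpa(arr)
  expect_true(fit$converged)
  expect_lt(max(procrustes_distances(fit)), 1e-7)
  # consensus equals the shape up to similarity: align and compare
  b <- scale(base, scale = FALSE); b <- b / sqrt(sum(b^2))
  R <- optimal_rotation(b, fit$consensus)
  expect_lt(sqrt(sum((b %*% R - fit$consensus)^2)), 1e-7)
  # consensus gauge: centroid at origin, unit centroid size
  expect_lt(max(abs(colMeans(fit$consensus))), 1e-9)
  expect_equal(sqrt(sum(fit$consensus^2)), 1, tolerance = 1e-9)
})

test_that("two-specimen Procrustes distance is symmetric in input order", {
  arr <- random_shapes(9, 2, sd = 0.3, seed = 31)
  d12 <- procrustes_distances(gpa(arr))
  d21 <- procrustes_distances(gpa(arr[, , 2:1]))
  expect_equal(unname(sum(d12^2)), unname(sum(d21^2)), tolerance = 1e-12)
})

test_that("GPA matches an independent alternating-minimization oracle", {
  arr <- random_shapes(6, 5, sd = 0.25, seed = 41)
  fit <- gpa(arr, tol = 1e-12, max_iter = 500)
  orac <- gpa_oracle(arr, iters = 500)
  ss_fit <- sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2)
  expect_equal(ss_fit, orac$ss, tolerance = 1e-6)
})

test_that("GPA is invariant to similarity transforms of any input", {
  arr <- random_shapes(10, 8, sd = 0.15, seed = 51)
  fit0 <- gpa(arr)
  arr2 <- arr
  withr::with_seed(52, {
    for (i in c(2, 5)) {
      arr2[, , i] <- apply_similarity(arr[, , i], theta = runif(1, -pi, pi),
                                      scale = runif(1, 0.2, 5),
                                      shift = rnorm(2, sd = 10))
    }
  })
  fit2 <- gpa(arr2)
  R <- optimal_rotation(fit2$consensus, fit0$consensus)
  expect_lt(sqrt(sum((fit2$consensus %*% R - fit0$consensus)^2)), 1e-6)
})

test_that("the GPA objective trace is monotone non-increasing", {
  arr <- random_shapes(15, 12, sd = 0.4, seed = 61)
  fit <- gpa(arr)
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("permuting specimen order changes nothing but row order", {
  arr <- random_shapes(8, 6, sd = 0.2, seed = 71)
  fit <- gpa(arr)
  perm <- c(3, 1, 6, 2, 5, 4)
  fitp <- gpa(arr[, , perm])
  R <- optimal_rotation(fitp$consensus, fit$consensus)
  expect_lt(sqrt(sum((fitp$consensus %*% R - fit$consensus)^2)), 1e-8)
  expect_equal(unname(fitp$centroid_sizes), unname(fit$centroid_sizes[perm]),
               tolerance = 1e-12)
})

test_that("degenerate specimens are rejected by name", {
  arr <- random_shapes(5, 3, sd = 0.2, seed = 81)
  arr[, , 2] <- 1
  expect_error(gpa(arr), "s2")
})

test_that("tangent projection is consensus-centered, idempotent, first-order", {
  arr <- random_shapes(12, 10, sd = 0.05, seed = 91)
  fit <- gpa(arr)
  rows <- tangent_project(fit)
  cvec <- as.vector(t(fit$consensus))
  cvec <- cvec / sqrt(sum(cvec^2))
  # consensus maps to the zero row
  fitc <- fit
  fitc$aligned <- array(fit$consensus, c(12, 2, 2),
                        dimnames = list(NULL, NULL, c("a", "b")))
  expect_lt(max(abs(tangent_project(fitc))), 1e-12)
  # rows orthogonal to the consensus direction (idempotency of I - cc')
  expect_lt(max(abs(rows %*% cvec)), 1e-12)
  reproj <- rows - (rows %*% cvec) %*% t(cvec)
  expect_equal(reproj, rows, tolerance = 1e-12)
  # near-consensus shapes: projection differs from raw residual at O(d^2)
  d <- sqrt(rowSums((rows - t(apply(fit$aligned, 3, function(m) {
    as.vector(t(m)) - as.vector(t(fit$consensus))
  })))^2))
  dist <- procrustes_distances(fit)
  expect_true(all(d <= 1.5 * dist^2 + 1e-12))
})
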