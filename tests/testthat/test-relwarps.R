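test_that("relative warps with alpha = 0 match a singular-value oracle", {
  arr <- random_shapes(9, 14, sd = 0.08, seed = 101)
  fit <- gpa(arr)
  rw <- relative_warps(fit)
  rows <- tangent_project(fit)
  centered <- sweep(rows, 2, colMeans(rows))
  sv <- svd(centered)
  eig_oracle <- sv$d^2 / (nrow(rows) - 1)
  m <- rw$n_nontrivial
  expect_equal(rw$eigenvalues, eig_oracle[seq_len(m)], tolerance = 1e-9)
  # orthonormal eigenvectors
  G <- crossprod(rw$eigenvectors)
  expect_lt(max(abs(G - diag(m))), 1e-8)
  # score columns: zero mean, variance = eigenvalue
  expect_lt(max(abs(colMeans(rw$scores))), 1e-9)
  expect_equal(unname(apply(rw$scores, 2, var)), rw$eigenvalues,
               tolerance = 1e-9)
  # variance fractions non-increasing, sum 1
  expect_true(all(diff(rw$variance_fraction) <= 1e-12))
  expect_equal(sum(rw$variance_fraction), 1, tolerance = 1e-9)
})

test_that("non-trivial PC count is min(n-1, 2k-4) in both regimes", {
  # n - 1 < 2k - 4
  fit1 <- gpa(random_shapes(12, 8, sd = 0.1, seed = 111))
  expect_equal(relative_warps(fit1)$n_nontrivial, 7)
  # n - 1 > 2k - 4
  fit2 <- gpa(random_shapes(6, 20, sd = 0.1, seed = 112))
  expect_equal(relative_warps(fit2)$n_nontrivial, 8)
})

test_that("rows on one line give a single PC carrying all variance", {
  withr::with_seed(113, v <- rnorm(10))
  v <- v / sqrt(sum(v^2))
  rows <- outer(seq(-2, 2, length.out = 9), v)
  rw <- relative_warps(rows)
  expect_equal(rw$n_nontrivial, 1)
  expect_equal(rw$variance_fraction, 1, tolerance = 1e-9)
})

test_that("scores and eigenvectors reconstruct the centered rows", {
  arr <- random_shapes(7, 12, sd = 0.1, seed = 121)
  fit <- gpa(arr)
  rw <- relative_warps(fit)
  rows <- tangent_project(fit)
  centered <- sweep(rows, 2, colMeans(rows))
  recon <- rw$scores %*% t(rw$eigenvectors)
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("variance_table is a valid cumulative decomposition", {
  rw <- relative_warps(gpa(random_shapes(8, 10, sd = 0.1, seed = 131)))
  vt <- variance_table(rw)
  expect_true(all(diff(vt$cumulative_fraction) >= -1e-12))
  expect_equal(utils::tail(vt$cumulative_fraction, 1), 1, tolerance = 1e-9)
  expect_equal(vt$variance_fraction, vt$eigenvalue / sum(vt$eigenvalue),
               tolerance = 1e-12)
})

test_that("shape_at_score is linear in score and round-trips projection", {
  ds <- small_dataset(n_per_cell = 2, seed = 141)
  fit <- gpa(ds)
  rw <- relative_warps(fit)
  expect_equal(shape_at_score(rw, 1, 0), unname(fit$consensus),
               tolerance = 1e-12, ignore_attr = TRUE)
  s <- 1.5 * sqrt(rw$eigenvalues[2])
  hi <- shape_at_score(rw, 2, +s)
  lo <- shape_at_score(rw, 2, -s)
  expect_equal((hi + lo) / 2, unname(fit$consensus), tolerance = 1e-12,
               ignore_attr = TRUE)
  # projecting the returned shape back onto the PC recovers the score
  back <- sum((as.vector(t(hi)) - as.vector(t(fit$consensus))) *
                rw$eigenvectors[, 2])
  expect_equal(back, s, tolerance = 1e-9)
  expect_error(shape_at_score(rw, rw$n_nontrivial + 1, 0), "pc must be")
})

test_that("mean_shape averages subsets and reduces to known fixed points", {
  ds <- small_dataset(n_per_cell = 2, seed = 151)
  fit <- gpa(ds)
  # the all-specimen mean is the consensus
  expect_equal(mean_shape(fit), unname(fit$consensus), tolerance = 1e-6,
               ignore_attr = TRUE)
  # a single-specimen subset returns that aligned specimen
  id1 <- ds$metadata$specimen_id[1]
  m1 <- mean_shape(fit, .data$specimen_id == id1)
  a1 <- fit$aligned[, , id1]
  expect_equal(m1, unname(a1 / sqrt(sum(a1^2))), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the mean of a +d / -d perturbed pair is the unperturbed shape
  C <- fit$consensus
  withr::with_seed(152, d <- matrix(rnorm(length(C), sd = 0.01),
                                    nrow(C), 2))
  d <- d - matrix(colMeans(d), nrow(C), 2, byrow = TRUE)
  pair <- array(c(C + d, C - d), c(nrow(C), 2, 2),
                dimnames = list(NULL, NULL, c("p", "m")))
  pf <- list(aligned = pair, consensus = C, metadata = NULL)
  class(pf) <- "procrustes_fit"
  got <- mean_shape(pf)
  expect_equal(got, unname(C / sqrt(sum(C^2))), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(mean_shape(fit, .data$species == "dodo"), "Empty subset")
})

test_that("the PC sign convention puts infants above adults on each PC", {
  ds <- small_dataset(n_per_cell = 4, seed = 161)
  rw <- relative_warps(slide_semilandmarks(gpa(ds)))
  st <- score_table(rw)
  for (pc in paste0("PC", 1:5)) {
    d <- mean(st[[pc]][st$age_class == "infant"]) -
      mean(st[[pc]][st$age_class == "adult"])
    expect_gte(d, 0)
  }
})

test_that("rigid motion of the whole dataset leaves scores unchanged up to sign", {
  arr <- random_shapes(8, 10, sd = 0.1, seed = 171)
  rw0 <- relative_warps(gpa(arr))
  arr2 <- arr
  for (i in seq_len(dim(arr)[3])) {
    arr2[, , i] <- apply_similarity(arr[, , i], theta = 1.1, scale = 2,
                                    shift = c(4, -7))
  }
  rw2 <- relative_warps(gpa(arr2))
  m <- min(rw0$n_nontrivial, rw2$n_nontrivial)
  for (j in seq_len(m)) {
    expect_equal(abs(rw2$scores[, j]), abs(rw0$scores[, j]), tolerance = 1e-6)
  }
})

test_that("alpha != 0 requires a bending-energy model and reweights scales", {
  fit <- gpa(random_shapes(10, 8, sd = 0.05, seed = 181))
  expect_error(relative_warps(fit, alpha = 1), "requires a bending-energy")
  be <- bending_energy(fit$consensus)
  rw <- relative_warps(fit, alpha = 1, be = be)
  expect_s3_class(rw, "relative_warp_model")
  expect_equal(rw$alpha, 1)
  expect_equal(rw$n_nontrivial, relative_warps(fit)$n_nontrivial)
})
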