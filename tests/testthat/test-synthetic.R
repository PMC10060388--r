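test_that("the template has 97 landmarks, 76 adjacent-neighbour sliders", {
  tm <- face_template()
  expect_equal(nrow(tm$points), 97)
  expect_equal(nrow(tm$sliders), 76)
  expect_equal(sum(!tm$fixed), 76)
  expect_true(all(sort(unique(tm$group)) ==
                    sort(c("brow", "eye_left", "eye_right", "pupil_left",
                           "pupil_right", "nose_left", "nose_right",
                           "subnasale", "mouth", "chin"))))
  # unit centroid size, centered
  expect_equal(sqrt(sum(tm$points^2)), 1, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(tm$points))), 1e-12)
  # every slider triplet references adjacent points of one outline group
  for (j in seq_len(nrow(tm$sliders))) {
    tri <- unlist(tm$sliders[j, ])
    expect_equal(length(unique(tm$group[tri])), 1)
    idx <- which(tm$group == tm$group[tri[1]])
    pos <- match(tri, idx)
    m <- length(idx)
    gap <- function(a, b) min((a - b) %% m, (b - a) %% m)
    expect_equal(gap(pos[1], pos[2]), 1)
    expect_equal(gap(pos[2], pos[3]), 1)
  }
  validate_sliders(tm$sliders, 97)
})

test_that("reflection about the midline permutes left/right groups exactly", {
  tm <- face_template()
  mirrored <- cbind(-tm$points[, 1], tm$points[, 2])
  expect_lt(max(abs(mirrored - tm$points[tm$mirror, ])), 1e-12)
  expect_true(all(tm$mirror[tm$mirror] == seq_len(97)))  # involution
  swap <- function(g) {
    ifelse(grepl("_left$", g), sub("_left$", "_right", g),
           sub("_right$", "_left", g))
  }
  expect_equal(tm$group[tm$mirror], swap(tm$group))
})

test_that("age axes are unit, similarity-orthogonal and tangent-free", {
  tm <- face_template()
  axes <- make_age_axes(tm)
  sim <- facewarp:::similarity_basis(tm$points)
  tang <- facewarp:::tangential_basis(tm)
  for (j in 1:3) {
    expect_equal(sum(axes[, j]^2), 1, tolerance = 1e-12)
    expect_lt(max(abs(crossprod(sim, axes[, j]))), 1e-8)
    expect_lt(max(abs(crossprod(tang, axes[, j]))), 1e-8)
  }
})

test_that("the eye axis grows eye area; vertical compression squashes the face", {
  tm <- face_template()
  axes <- make_age_axes(tm)
  shoelace <- function(p) {
    n <- nrow(p)
    abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
  }
  eye_area <- function(pts) {
    sum(vapply(c("eye_left", "eye_right"), function(g) {
      shoelace(pts[tm$group == g, , drop = FALSE])
    }, numeric(1)))
  }
  eps <- 1e-3
  # displaced configs via unflatten, keeping the interleaved order
  disp <- function(axis, e) tm$points + e * facewarp:::unflatten_config(axis)
  expect_gt(eye_area(disp(axes[, "eye_size_low"], eps)), eye_area(tm$points))
  expect_lt(eye_area(disp(axes[, "eye_size_low"], -eps)), eye_area(tm$points))
  ratio <- function(pts) diff(range(pts[, 2])) / diff(range(pts[, 1]))
  expect_lt(ratio(disp(axes[, "vertical_compress"], eps)), ratio(tm$points))
  expect_gt(ratio(disp(axes[, "vertical_compress"], -eps)), ratio(tm$points))
})

test_that("noise-free, nuisance-free simulation reproduces template + offsets", {
  tr <- synthetic_truth(noise_sigma = 0, rotation_max = 0,
                        scale_range = c(1, 1), translation_max = 0,
                        age_magnitudes = c(eye_size_low = 0,
                                           vertical_compress = 0,
                                           top_heavy = 0),
                        species_offset_magnitude = 0, seed = 3)
  ds <- simulate_dataset(tr, n_per_cell = 2, seed = 3)
  arr <- landmark_array(ds$landmarks)
  for (i in seq_len(dim(arr)[3])) {
    expect_lt(max(abs(arr[, , i] - tr$template$points)), 1e-12)
  }
  fit <- gpa(ds)
  expect_lt(max(procrustes_distances(fit)), 1e-8)
})

test_that("simulated datasets validate, are balanced, and are reproducible", {
  tr <- synthetic_truth(seed = 5)
  ds <- simulate_dataset(tr, n_per_cell = 3, seed = 5)
  expect_equal(ds$n, 30)
  expect_equal(ds$k, 97)
  cc <- validate_dataset(ds)$cell_counts
  expect_true(all(cc$n_specimens == 3))
  ds2 <- simulate_dataset(tr, n_per_cell = 3, seed = 5)
  expect_identical(ds$landmarks, ds2$landmarks)
  ds3 <- simulate_dataset(tr, n_per_cell = 3, seed = 6)
  expect_false(identical(ds$landmarks, ds3$landmarks))
  # half of each cell male (n_per_cell = 8 gives the study's 4/4 split)
  ds8 <- simulate_dataset(tr, n_per_cell = 8, seed = 5)
  sexes <- dplyr::count(ds8$metadata, .data$species, .data$age_class, .data$sex)
  expect_true(all(sexes$n == 4))
})

test_that("species offsets are pure shape with the requested magnitude", {
  tr <- synthetic_truth(seed = 7)
  sim <- facewarp:::similarity_basis(tr$template$points)
  for (sp in tr$species) {
    v <- tr$species_offsets[, sp]
    expect_equal(sqrt(sum(v^2)), 0.02, tolerance = 1e-12)
    expect_lt(max(abs(crossprod(sim, v))), 1e-10)
  }
})

test_that("doubling noise lowers per-PC classification accuracy", {
  accs <- vapply(c(0.01, 0.02), function(sig) {
    mean(vapply(1:6, function(s) {
      tr <- synthetic_truth(noise_sigma = sig, seed = s)
      ds <- simulate_dataset(tr, n_per_cell = 8, seed = s)
      rw <- relative_warps(slide_semilandmarks(gpa(ds)))
      st <- score_table(rw)
      ev <- evaluate_classifier(as.matrix(st[, "PC1"]),
                                factor(st$age_class),
                                classifier_spec("lda"), seed = s)
      ev$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_lt(accs[2], accs[1])
})
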