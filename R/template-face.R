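#' Schematic 97-landmark great-ape face template
#'
#' A bilaterally symmetric, schematic frontal face carrying the same
#' landmark economy as the study scheme: 97 landmarks partitioned into named
#' groups (brow arc, left/right eye outlines, pupils, left/right nose edges,
#' subnasale, mouth outline, chin arc), of which 76 outline points are
#' semilandmarks with a matching slider table whose triplets always
#' reference adjacent points along the same outline. The per-group layout
#' is a documented constant of the generator:
#'
#' | group      | points | fixed | semilandmarks |
#' |------------|-------:|------:|--------------:|
#' | brow       | 17     | 3     | 14            |
#' | eye_left   | 12     | 2     | 10            |
#' | eye_right  | 12     | 2     | 10            |
#' | pupils     | 2      | 2     | 0             |
#' | nose_left  | 7      | 2     | 5             |
#' | nose_right | 7      | 2     | 5             |
#' | subnasale  | 1      | 1     | 0             |
#' | mouth      | 16     | 4     | 12            |
#' | chin       | 23     | 3     | 20            |
#'
#' The template is centered on its centroid and scaled to unit centroid
#' size, with y increasing upward; reflection about the midline maps the
#' left-side groups exactly onto the right-side ones (the `mirror`
#' permutation records the pairing).
#'
#' @return An object of class `face_template`: list with `points` (97 x 2),
#'   `group` (character, per landmark), `fixed` (logical, per landmark),
#'   `sliders` (76-row tibble), `mirror` (integer permutation such that
#'   point `i` reflected about x = 0 coincides with point `mirror[i]`).
#' @export
face_template <- function() {
  pts <- list(); grp <- list(); fixed <- list()
  add <- function(xy, group, fix) {
    pts[[length(pts) + 1]] <<- xy
    grp[[length(grp) + 1]] <<- rep(group, nrow(xy))
    fixed[[length(fixed) + 1]] <<- fix
  }

  # brow arc: 17 points, ends and glabella (center) fixed
  bx <- seq(-0.45, 0.45, length.out = 17)
  add(cbind(bx, 0.40 + 0.10 * (1 - (bx / 0.45)^2)), "brow",
      seq_len(17) %in% c(1, 9, 17))

  # eye outlines: 12-point ellipses; corners (temporal/nasal) fixed.
  # The left eye uses the mirrored parameterization so that point j of the
  # left outline is the reflection of point j of the right outline.
  th12 <- (seq_len(12) - 1) * 30 * pi / 180
  eye <- function(side) cbind(side * (0.22 + 0.13 * cos(th12)),
                              0.18 + 0.075 * sin(th12))
  add(eye(-1), "eye_left",  seq_len(12) %in% c(1, 7))
  add(eye(+1), "eye_right", seq_len(12) %in% c(1, 7))

  add(cbind(-0.22, 0.18), "pupil_left",  TRUE)
  add(cbind(+0.22, 0.18), "pupil_right", TRUE)

  # nose edges: open 7-point curves, endpoints fixed
  tn <- (seq_len(7) - 1) / 6
  nose <- function(side) cbind(side * (0.06 + 0.05 * tn + 0.02 * sin(pi * tn)),
                               0.12 - 0.19 * tn)
  add(nose(-1), "nose_left",  seq_len(7) %in% c(1, 7))
  add(nose(+1), "nose_right", seq_len(7) %in% c(1, 7))

  add(cbind(0, -0.10), "subnasale", TRUE)

  # mouth outline: 16-point ellipse; corners and lip midpoints fixed
  th16 <- (seq_len(16) - 1) * 22.5 * pi / 180
  add(cbind(0.185 * cos(th16), -0.27 + 0.075 * sin(th16)), "mouth",
      seq_len(16) %in% c(1, 5, 9, 13))

  # chin arc: 23 points from right to left through the menton; ends and
  # menton fixed
  phi <- (seq_len(23) - 1) * pi / 22
  add(cbind(0.33 * cos(phi), -0.36 - 0.19 * sin(phi)), "chin",
      seq_len(23) %in% c(1, 12, 23))

  points <- do.call(rbind, pts)
  group <- unlist(grp)
  fixed <- unlist(fixed)
  stopifnot(nrow(points) == 97, sum(!fixed) == 76)

  # sliders: adjacent neighbours along each outline (closed outlines wrap)
  closed <- c(eye_left = TRUE, eye_right = TRUE, mouth = TRUE,
              brow = FALSE, nose_left = FALSE, nose_right = FALSE,
              chin = FALSE)
  sliders <- purrr::map_dfr(names(closed), function(g) {
    idx <- which(group == g)
    m <- length(idx)
    within <- which(!fixed[idx])
    purrr::map_dfr(within, function(j) {
      if (closed[[g]]) {
        tibble(before = idx[(j - 2) %% m + 1], slider = idx[j],
               after = idx[j %% m + 1])
      } else {
        tibble(before = idx[j - 1], slider = idx[j], after = idx[j + 1])
      }
    })
  }) %>% arrange(.data$slider)
  stopifnot(nrow(sliders) == 76)

  # center, scale to unit centroid size (x-symmetry is preserved)
  points <- center_config(points)
  points <- points / sqrt(sum(points^2))
  colnames(points) <- c("x", "y")

  mirrored <- cbind(-points[, 1], points[, 2])
  mirror <- vapply(seq_len(97), function(i) {
    d <- rowSums(sweep(points, 2, mirrored[i, ])^2)
    which.min(d)
  }, integer(1))

  structure(list(points = points, group = group, fixed = fixed,
                 sliders = sliders, mirror = mirror),
            class = "face_template")
}

#' @export
print.face_template <- function(x, ...) {
  cat("<face_template> 97 landmarks, ", nrow(x$sliders),
      " semilandmarks, groups: ",
      paste(unique(x$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Age-effect axes on the face template
#'
#' Three named unit vectors in shape space (flattened `(x1, y1, ...)` order)
#' implementing the canonical infantile facial shape changes:
#'
#' * `eye_size_low` — eye outlines and pupils scaled up about their own
#'   centers and translated down the face (bigger eyes located lower);
#' * `vertical_compress` — vertical shrink with horizontal widening about
#'   the face centroid (rounder, vertically shorter face);
#' * `top_heavy` — upper face widened, lower face narrowed (inverted
#'   triangular outline).
#'
#' Each raw displacement field is projected to be exactly orthogonal to (a)
#' the similarity-transform subspace at the template (x/y translation,
#' rotation, uniform scaling), so that adding a multiple of an axis changes
#' shape rather than position, orientation or size, and (b) the tangential
#' directions of all semilandmarks, so that the planted effect is genuine
#' outline shape change: moving a semilandmark along its own outline is, by
#' the logic of the sliding step, not an identifiable shape difference, and
#' an effect planted there would be (correctly) removed again during
#' superimposition. The projected field is then normalized to unit length.
#'
#' @param template A [face_template()].
#' @return A `194 x 3` matrix with columns `eye_size_low`,
#'   `vertical_compress`, `top_heavy`.
#' @export
make_age_axes <- function(template) {
  stopifnot(inherits(template, "face_template"))
  P <- template$points
  k <- nrow(P)
  g <- template$group

  axes <- matrix(0, 2 * k, 3,
                 dimnames = list(NULL, c("eye_size_low", "vertical_compress",
                                         "top_heavy")))
  d <- matrix(0, k, 2)
  for (side in c("left", "right")) {
    eye_idx <- which(g %in% paste0(c("eye_", "pupil_"), side))
    outline <- P[g == paste0("eye_", side), , drop = FALSE]
    ctr <- colMeans(outline)
    r_eye <- mean(sqrt(rowSums(sweep(outline, 2, ctr)^2)))
    d[eye_idx, ] <- sweep(P[eye_idx, , drop = FALSE], 2, ctr) +
      matrix(c(0, -0.8 * r_eye), length(eye_idx), 2, byrow = TRUE)
  }
  axes[, 1] <- flatten_config(d)
  axes[, 2] <- flatten_config(cbind(0.5 * P[, 1], -P[, 2]))
  axes[, 3] <- flatten_config(cbind(2 * P[, 1] * P[, 2], 0))

  drop <- cbind(similarity_basis(P), tangential_basis(template))
  drop <- qr.Q(qr(drop))
  for (j in 1:3) {
    v <- axes[, j]
    v <- v - drop %*% crossprod(drop, v)
    axes[, j] <- v / sqrt(sum(v^2))
  }
  axes
}

# Orthonormal basis of the semilandmark-tangential subspace: for each
# slider, the unit chord between its flanking landmarks, placed at the
# slider's coordinates. Columns are mutually orthogonal because each
# involves a distinct landmark.
tangential_basis <- function(template) {
  P <- template$points
  k <- nrow(P)
  sl <- template$sliders
  B <- matrix(0, 2 * k, nrow(sl))
  for (j in seq_len(nrow(sl))) {
    chord <- P[sl$after[j], ] - P[sl$before[j], ]
    chord <- chord / sqrt(sum(chord^2))
    B[2 * sl$slider[j] - 1, j] <- chord[1]
    B[2 * sl$slider[j], j] <- chord[2]
  }
  B
}

# Orthonormal basis (columns) of the similarity-transform subspace at a
# centered configuration: x/y translation, uniform scaling, rotation.
similarity_basis <- function(P) {
  k <- nrow(P)
  tx <- flatten_config(cbind(rep(1, k), 0))
  ty <- flatten_config(cbind(0, rep(1, k)))
  sc <- flatten_config(P)
  rot <- flatten_config(cbind(-P[, 2], P[, 1]))
  B <- cbind(tx, ty, sc, rot)
  qr.Q(qr(B))
}
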