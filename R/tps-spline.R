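#' Thin-plate-spline bending energy of a reference configuration
#'
#' Builds the standard 2-D thin-plate-spline system with kernel
#' `U(r) = r^2 log r^2` and affine block `[1, x, y]`, and extracts the
#' bending-energy matrix: the upper-left `k x k` block of the inverted
#' bordered system. For a landmark displacement field `h` (one coordinate
#' axis at a time), `t(h) %*% energy_matrix %*% h` is proportional to the
#' integrated bending `int(f_xx^2 + 2 f_xy^2 + f_yy^2)` of the
#' interpolating spline (the constant is `1/(16*pi)` for this kernel
#' normalization), is zero for any affine displacement, and is
#' non-negative.
#'
#' @param reference A `k x 2` matrix (or single-specimen landmark tibble)
#'   with at least 3 non-collinear points.
#' @return An object of class `bending_energy_model`: list with `reference`
#'   and the symmetric positive-semidefinite `energy_matrix`.
#' @export
bending_energy <- function(reference) {
  ref <- as_config_matrix(reference)
  k <- nrow(ref)
  if (k < 3) abort("bending_energy() needs at least 3 points.")
  L <- tps_system(ref)
  Linv <- tryCatch(solve(L), error = function(e) {
    abort("Singular thin-plate-spline system (collinear or coincident reference points).")
  })
  Bk <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  Bk <- (Bk + t(Bk)) / 2
  structure(list(reference = ref, energy_matrix = Bk),
            class = "bending_energy_model")
}

# TPS radial kernel U(r) = r^2 log(r^2); U(0) = 0.
tps_kernel <- function(r2) ifelse(r2 <= 0, 0, r2 * log(r2))

# Bordered TPS system [[K, P], [t(P), 0]] for a k x 2 reference.
tps_system <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- tps_kernel(d2)
  P <- cbind(1, ref)
  rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
}

#' Thin-plate-spline interpolant between two configurations
#'
#' Solves the TPS system mapping `reference` exactly onto `target` and
#' returns a function evaluating the warp at arbitrary points. The map is
#' exactly affine when `target` is an affine transform of `reference`.
#'
#' @param reference,target `k x 2` matrices (or single-specimen tibbles)
#'   with the same `k`.
#' @return A function taking an `m x 2` matrix of points and returning their
#'   `m x 2` images; it carries the spline coefficients as attributes
#'   `weights` (`k x 2`) and `affine` (`3 x 2`).
#' @export
tps_warp <- function(reference, target) {
  ref <- as_config_matrix(reference)
  tar <- as_config_matrix(target)
  stopifnot(nrow(ref) == nrow(tar))
  k <- nrow(ref)
  L <- tps_system(ref)
  rhs <- rbind(tar, matrix(0, 3, 2))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    abort("Singular thin-plate-spline system (collinear or coincident reference points).")
  })
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + 1:3, , drop = FALSE]
  f <- function(pts) {
    pts <- as_config_matrix(pts)
    d2 <- outer(rowSums(pts^2), rowSums(ref^2), "+") - 2 * pts %*% t(ref)
    d2[d2 < 0] <- 0
    cbind(1, pts) %*% A + tps_kernel(d2) %*% W
  }
  attr(f, "weights") <- W
  attr(f, "affine") <- A
  f
}

#' Thin-plate-spline deformation grid
#'
#' Evaluates the TPS interpolant mapping `reference` to `target` on a
#' `density x density` grid spanning the reference bounding box (with an
#' optional margin), the standard visualization of shape change as a warped
#' Cartesian grid. The warp is exact at the landmarks.
#'
#' @param reference,target `k x 2` matrices or single-specimen tibbles.
#' @param density Grid points per side (default 24).
#' @param margin Fractional bounding-box expansion (default 0.05).
#' @return A tibble with columns `gx`, `gy` (reference grid), `wx`, `wy`
#'   (warped positions), `row`, `col` (grid indices, for drawing grid
#'   lines).
#' @export
deformation_grid <- function(reference, target, density = 24, margin = 0.05) {
  ref <- as_config_matrix(reference)
  warp <- tps_warp(ref, target)
  rng_x <- range(ref[, 1]); rng_y <- range(ref[, 2])
  pad_x <- margin * diff(rng_x); pad_y <- margin * diff(rng_y)
  gx <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = density)
  gy <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = density)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  warped <- warp(grid)
  tibble(gx = grid[, 1], gy = grid[, 2],
         wx = warped[, 1], wy = warped[, 2],
         col = rep(seq_len(density), times = density),
         row = rep(seq_len(density), each = density))
}
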