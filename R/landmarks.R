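#' Convert a landmark tibble to a k x 2 x n array
#'
#' The package stores landmark data in long tibbles (one row per landmark per
#' specimen, columns `specimen_id`, `landmark`, `x`, `y`). Numerical routines
#' work on dense arrays; these two helpers convert between the forms without
#' ever reordering landmarks, since landmark order is the homology order.
#'
#' @param landmarks A landmark tibble with columns `specimen_id`, `landmark`,
#'   `x`, `y`. Landmark indices must be `1:k` for every specimen.
#' @return A numeric array of dimension `c(k, 2, n)`; the third dimension is
#'   named by specimen id in first-appearance order.
#' @export
landmark_array <- function(landmarks) {
  stopifnot(all(c("specimen_id", "landmark", "x", "y") %in% names(landmarks)))
  ids <- unique(landmarks$specimen_id)
  ks <- landmarks %>% count(.data$specimen_id, name = "k")
  if (length(unique(ks$k)) > 1) {
    abort("All specimens must share the same number of landmarks.")
  }
  k <- ks$k[1]
  out <- array(NA_real_, dim = c(k, 2, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    sub <- landmarks[landmarks$specimen_id == ids[i], ]
    if (!identical(as.integer(sub$landmark), seq_len(k))) {
      sub <- sub[order(sub$landmark), ]
      if (!identical(as.integer(sub$landmark), seq_len(k))) {
        abort(paste0("Specimen '", ids[i], "' does not have landmarks 1..", k, "."))
      }
    }
    out[, 1, i] <- sub$x
    out[, 2, i] <- sub$y
  }
  if (any(!is.finite(out))) abort("Non-finite landmark coordinates.")
  out
}

#' Convert a k x 2 x n array (or a single k x 2 matrix) to a landmark tibble
#'
#' @param arr Array `c(k, 2, n)` with specimen ids as third dimnames, or a
#'   single `k x 2` matrix.
#' @param specimen_id Ids to use; defaults to the array dimnames (or `"shape"`
#'   for a bare matrix).
#' @return A landmark tibble.
#' @rdname landmark_array
#' @export
landmark_tibble <- function(arr, specimen_id = NULL) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(nrow(arr), 2, 1))
  n <- dim(arr)[3]
  k <- dim(arr)[1]
  if (is.null(specimen_id)) {
    specimen_id <- dimnames(arr)[[3]]
    if (is.null(specimen_id)) specimen_id <- if (n == 1) "shape" else paste0("spec_", seq_len(n))
  }
  purrr::map_dfr(seq_len(n), function(i) {
    tibble(specimen_id = specimen_id[i], landmark = seq_len(k),
           x = arr[, 1, i], y = arr[, 2, i])
  })
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid -- the standard size measure removed by Procrustes scaling.
#' Scaling a configuration by `c` scales its centroid size by `c`.
#'
#' @param config A `k x 2` numeric matrix, or a landmark tibble holding a
#'   single specimen.
#' @return A positive scalar.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # sqrt(2)
#' @export
centroid_size <- function(config) {
  m <- as_config_matrix(config)
  if (nrow(m) < 2) abort("centroid_size() needs at least 2 points.")
  cs <- sqrt(sum(scale(m, scale = FALSE)^2))
  if (cs <= .Machine$double.eps * nrow(m)) {
    abort("Degenerate configuration: all points coincide.")
  }
  cs
}

# Accept a k x 2 matrix or a single-specimen landmark tibble.
as_config_matrix <- function(config) {
  if (is.matrix(config)) {
    stopifnot(ncol(config) == 2)
    return(unname(config))
  }
  if (is.data.frame(config)) {
    if (length(unique(config$specimen_id %||% "one")) > 1) {
      abort("Expected a single-specimen configuration.")
    }
    ord <- order(config$landmark %||% seq_len(nrow(config)))
    return(cbind(config$x, config$y)[ord, , drop = FALSE])
  }
  abort("Cannot interpret `config` as a landmark configuration.")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten k x 2 -> length 2k, interleaved (x1, y1, x2, y2, ...). This order
# is fixed package-wide; eigenvectors and effect axes use it.
flatten_config <- function(m) as.vector(t(m))

unflatten_config <- function(v) {
  matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

center_config <- function(m) sweep(m, 2, colMeans(m), "-")
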