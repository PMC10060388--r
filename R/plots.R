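#' Plot aligned landmarks and consensus
#'
#' Scatter of all aligned specimens (grey) with the consensus configuration
#' on top, the standard visual check of a Procrustes fit.
#'
#' @param object A `procrustes_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot procrustes_fit
#' @export
autoplot.procrustes_fit <- function(object, ...) {
  pts <- landmark_tibble(object$aligned)
  cons <- landmark_tibble(object$consensus, specimen_id = "consensus")
  ggplot(pts, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.15, size = 0.6, colour = "grey40") +
    geom_point(data = cons, colour = "firebrick", size = 1.2) +
    coord_fixed() +
    labs(title = "Procrustes-aligned landmarks",
         subtitle = paste0("consensus in red; sliding: ", object$sliding_mode),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Scree plot of a relative-warp model
#'
#' Per-component variance fractions with the cumulative curve.
#'
#' @param object A `relative_warp_model`.
#' @param n_pcs Number of leading components to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot relative_warp_model
#' @export
autoplot.relative_warp_model <- function(object, n_pcs = 20, ...) {
  vt <- head(variance_table(object), n_pcs)
  ggplot(vt, aes(x = .data$pc)) +
    geom_col(aes(y = .data$variance_fraction), fill = "steelblue") +
    geom_line(aes(y = .data$cumulative_fraction), colour = "firebrick") +
    geom_point(aes(y = .data$cumulative_fraction), colour = "firebrick") +
    scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    labs(x = "Principal component", y = "Variance fraction",
         title = "Relative-warp variance spectrum") +
    theme_minimal()
}

#' Plot a landmark configuration
#'
#' @param config A `k x 2` matrix or single-specimen landmark tibble.
#' @param colour Point colour.
#' @return A ggplot.
#' @export
plot_shape <- function(config, colour = "black") {
  m <- as_config_matrix(config)
  df <- tibble(x = m[, 1], y = m[, 2])
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point(colour = colour, size = 1) +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_void()
}

#' Plot the shape extremes of one principal component
#'
#' Overlays the configurations at `-sd_extreme` and `+sd_extreme` standard
#' deviations along a component — the conventional rendering of what a
#' shape PC means anatomically.
#'
#' @param model A `relative_warp_model` fitted from a `procrustes_fit`.
#' @param pc Component index.
#' @param sd_extreme Score multiple in SDs (default 1.5).
#' @return A ggplot.
#' @export
plot_pc_extremes <- function(model, pc, sd_extreme = 1.5) {
  s <- sd_extreme * sqrt(model$eigenvalues[pc])
  lo <- landmark_tibble(shape_at_score(model, pc, -s), "low")
  hi <- landmark_tibble(shape_at_score(model, pc, +s), "high")
  df <- bind_rows(lo, hi) %>%
    mutate(extreme = factor(.data$specimen_id, levels = c("low", "high"),
                            labels = paste0(c("-", "+"), sd_extreme, " SD")))
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$extreme)) +
    geom_point(size = 1) +
    coord_fixed() +
    scale_colour_manual(values = c("steelblue", "firebrick")) +
    labs(title = paste0("PC", pc, " shape extremes"), x = NULL, y = NULL,
         colour = NULL) +
    theme_void()
}

#' Plot a thin-plate-spline deformation grid
#'
#' @param grid A [deformation_grid()] tibble.
#' @param landmarks Optional `k x 2` target configuration to overlay.
#' @return A ggplot.
#' @export
plot_deformation_grid <- function(grid, landmarks = NULL) {
  p <- ggplot(grid, aes(x = .data$wx, y = .data$wy)) +
    geom_path(aes(group = .data$row), linewidth = 0.2, colour = "grey50") +
    geom_path(aes(group = .data$col), linewidth = 0.2, colour = "grey50") +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_void()
  if (!is.null(landmarks)) {
    m <- as_config_matrix(landmarks)
    p <- p + geom_point(data = tibble(wx = m[, 1], wy = m[, 2]),
                        colour = "firebrick", size = 1)
  }
  p
}

#' Significance-band tile plot of an age-classification table
#'
#' The graphical analogue of a significant-PCs-and-directions table: one
#' tile per (group, PC), shaded by significance band and labelled with the
#' effect direction.
#'
#' @param object An `age_class_table` from [per_pc_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot age_class_table
#' @export
autoplot.age_class_table <- function(object, ...) {
  df <- object %>%
    mutate(band = factor(.data$band,
                         levels = c("p<.005", "p<.01", "p<.05", "p<.10", "ns")),
           dir_label = dplyr::case_when(
             .data$direction == "A_lt_I" ~ "A<I",
             .data$direction == "I_lt_A" ~ "I<A",
             TRUE ~ ""),
           group = factor(.data$group, levels = rev(unique(.data$group))))
  ggplot(df, aes(x = factor(.data$pc), y = .data$group, fill = .data$band)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = ifelse(.data$band == "ns", "", .data$dir_label)),
              size = 2.8) +
    scale_fill_manual(values = c("p<.005" = "#99000d", "p<.01" = "#cb181d",
                                 "p<.05" = "#fb6a4a", "p<.10" = "#fcae91",
                                 "ns" = "grey92"), drop = FALSE) +
    labs(x = "Principal component", y = NULL, fill = "Permutation p",
         title = "Age discriminability per principal component") +
    theme_minimal()
}
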