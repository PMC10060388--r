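#' Ground truth for the synthetic face-landmark generator
#'
#' Defines a complete generative model for landmark datasets with the same
#' design as the study (five species, adult/infant classes): a common
#' [face_template()], one species-level mean-shape offset per species (drawn
#' once from a seeded isotropic Gaussian in shape space and scaled to
#' `species_offset_magnitude` — species realism is not needed to exercise
#' the inference machinery), the three planted infant-effect axes of
#' [make_age_axes()] with per-axis magnitudes, isotropic digitization noise,
#' and nuisance similarity transforms. Offsets and axes are orthogonal to
#' the similarity subspace at the template, so all planted structure is pure
#' shape. All magnitudes are in units of the template's (unit) centroid
#' size.
#'
#' @param species Species names (default the five study species).
#' @param species_offset_magnitude Shape-space norm of each species' mean
#'   offset (default 0.02).
#' @param age_magnitudes Named per-axis infant-effect magnitudes; infants
#'   are displaced by `sum(magnitude * axis)` (default
#'   `c(eye_size_low = 0.05, vertical_compress = 0.03, top_heavy = 0.025)`).
#' @param noise_sigma SD of the isotropic Gaussian digitization noise per
#'   landmark coordinate (default 0.01).
#' @param rotation_max Nuisance rotation, uniform in `+/- rotation_max`
#'   degrees (default 15).
#' @param scale_range Nuisance scale factor range (default `c(0.8, 1.2)`).
#' @param translation_max Nuisance translation, uniform per axis in
#'   `+/- translation_max` (default 0.5).
#' @param seed Integer seed for the species-offset draw and the default
#'   simulation stream.
#' @return An object of class `synthetic_truth`; notable elements:
#'   `template`, `age_axes` (`2k x 3`), `age_magnitudes`, `species_offsets`
#'   (`2k x 5`), `combined_age_axis` (unit vector along the total planted
#'   adult-to-infant displacement), `combined_age_magnitude`.
#' @export
synthetic_truth <- function(species = c("human", "chimpanzee", "bonobo",
                                        "gorilla", "orangutan"),
                            species_offset_magnitude = 0.02,
                            age_magnitudes = c(eye_size_low = 0.05,
                                               vertical_compress = 0.03,
                                               top_heavy = 0.025),
                            noise_sigma = 0.01,
                            rotation_max = 15,
                            scale_range = c(0.8, 1.2),
                            translation_max = 0.5,
                            seed = 1) {
  stopifnot(noise_sigma >= 0, all(age_magnitudes >= 0),
            species_offset_magnitude >= 0)
  template <- face_template()
  axes <- make_age_axes(template)
  stopifnot(setequal(names(age_magnitudes), colnames(axes)))
  age_magnitudes <- age_magnitudes[colnames(axes)]
  k <- nrow(template$points)
  sim <- similarity_basis(template$points)
  offsets <- withr::with_seed(seed, {
    o <- matrix(rnorm(2 * k * length(species)), 2 * k, length(species))
    apply(o, 2, function(v) {
      v <- v - sim %*% crossprod(sim, v)
      v / sqrt(sum(v^2)) * species_offset_magnitude
    })
  })
  colnames(offsets) <- species
  combined <- axes %*% age_magnitudes
  cmag <- sqrt(sum(combined^2))
  structure(
    list(template = template, age_axes = axes,
         age_magnitudes = age_magnitudes,
         species = species, species_offsets = offsets,
         combined_age_axis = if (cmag > 0) as.vector(combined) / cmag else as.vector(combined),
         combined_age_magnitude = cmag,
         noise_sigma = noise_sigma, rotation_max = rotation_max,
         scale_range = scale_range, translation_max = translation_max,
         seed = seed),
    class = "synthetic_truth"
  )
}

#' Simulate a landmark dataset from a synthetic truth
#'
#' For each species x age-class cell, generates `n_per_cell` specimens as
#' `template + species offset + (infant ? planted age displacement : 0) +
#' N(0, noise_sigma^2)` per coordinate, then applies a random similarity
#' transform (rotation, scaling, translation) drawn from the truth's
#' nuisance ranges — the variation the Procrustes fit must remove. Sexes are
#' assigned half male, half female per cell. The result is bit-reproducible
#' under a fixed `seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param n_per_cell Specimens per species x age cell (default 8, the study
#'   design).
#' @param seed Integer seed (defaults to `truth$seed`).
#' @return A validated `landmark_dataset` (with the truth attached as
#'   attribute `"truth"`).
#' @export
simulate_dataset <- function(truth, n_per_cell = 8, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), n_per_cell >= 1)
  tmpl <- truth$template$points
  k <- nrow(tmpl)
  infant_shift <- unflatten_config(truth$combined_age_axis *
                                     truth$combined_age_magnitude)
  lm_list <- list(); md_list <- list()
  withr::with_seed(seed, {
    for (sp in truth$species) {
      off <- unflatten_config(truth$species_offsets[, sp])
      for (age in c("adult", "infant")) {
        for (r in seq_len(n_per_cell)) {
          cfg <- tmpl + off
          if (age == "infant") cfg <- cfg + infant_shift
          cfg <- cfg + matrix(rnorm(2 * k, sd = truth$noise_sigma), k, 2)
          theta <- runif(1, -truth$rotation_max, truth$rotation_max) * pi / 180
          R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
          s <- runif(1, truth$scale_range[1], truth$scale_range[2])
          tr <- runif(2, -truth$translation_max, truth$translation_max)
          cfg <- s * (cfg %*% R) + matrix(tr, k, 2, byrow = TRUE)
          id <- sprintf("%s_%s_%02d", sp, age, r)
          lm_list[[id]] <- tibble(specimen_id = id, landmark = seq_len(k),
                                  x = cfg[, 1], y = cfg[, 2])
          md_list[[id]] <- tibble(specimen_id = id, species = sp,
                                  age_class = age,
                                  sex = if (r <= n_per_cell / 2) "male" else "female")
        }
      }
    }
  })
  ds <- landmark_dataset(bind_rows(lm_list), bind_rows(md_list),
                         truth$template$sliders)
  attr(ds, "truth") <- truth
  ds
}
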