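#' Assemble a landmark dataset
#'
#' Bundles landmark configurations, specimen metadata and (optionally) a
#' slider table into a single validated object consumed by the downstream
#' stages ([gpa()], [relative_warps()], [per_pc_analysis()]).
#'
#' @param landmarks Landmark tibble (see [read_tps()]).
#' @param metadata Metadata tibble (see [read_specimen_metadata()]).
#' @param sliders Optional slider tibble (see [read_sliders()]).
#' @return An object of class `landmark_dataset`: a list with elements
#'   `landmarks`, `metadata`, `sliders`, `k`, `n`.
#' @export
landmark_dataset <- function(landmarks, metadata, sliders = NULL) {
  ds <- structure(
    list(landmarks = as_tibble(landmarks), metadata = as_tibble(metadata),
         sliders = if (is.null(sliders)) NULL else as_tibble(sliders),
         k = length(unique(landmarks$landmark)),
         n = length(unique(landmarks$specimen_id))),
    class = "landmark_dataset"
  )
  validate_dataset(ds)
}

#' Validate a landmark dataset
#'
#' Checks every structural invariant at once and reports all violations, not
#' just the first: uniform landmark count, finite coordinates, a one-to-one
#' specimen correspondence between landmarks and metadata, slider indices in
#' range, and unique, non-degenerate slider triplets. On success the dataset
#' is returned with a `cell_counts` element (specimens per species x
#' age_class).
#'
#' @param dataset A `landmark_dataset`.
#' @return The validated dataset (invisibly augmented with `cell_counts`).
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  probs <- character()
  lm <- dataset$landmarks
  md <- dataset$metadata

  ks <- lm %>% count(.data$specimen_id, name = "k")
  if (length(unique(ks$k)) > 1) {
    probs <- c(probs, paste0("inconsistent landmark counts: ",
                             paste(sort(unique(ks$k)), collapse = ", ")))
  }
  if (any(!is.finite(lm$x)) || any(!is.finite(lm$y))) {
    probs <- c(probs, "non-finite coordinates present")
  }
  lm_ids <- unique(lm$specimen_id)
  md_ids <- md$specimen_id
  if (anyDuplicated(md_ids)) {
    probs <- c(probs, paste0("duplicated metadata specimen_id: ",
                             paste(unique(md_ids[duplicated(md_ids)]), collapse = ", ")))
  }
  miss_md <- setdiff(lm_ids, md_ids)
  if (length(miss_md)) {
    probs <- c(probs, paste0("specimens without metadata: ",
                             paste(miss_md, collapse = ", ")))
  }
  miss_lm <- setdiff(md_ids, lm_ids)
  if (length(miss_lm)) {
    probs <- c(probs, paste0("metadata rows without landmarks: ",
                             paste(miss_lm, collapse = ", ")))
  }
  if (!is.null(dataset$sliders)) {
    sl <- dataset$sliders
    idx <- c(sl$before, sl$slider, sl$after)
    if (any(idx < 1) || any(idx > dataset$k)) {
      probs <- c(probs, paste0("slider indices outside 1..k (k = ", dataset$k, ")"))
    }
    if (anyDuplicated(sl$slider)) probs <- c(probs, "duplicate slider indices")
    bad <- with(sl, before == slider | slider == after | before == after)
    if (any(bad)) probs <- c(probs, "degenerate slider triplet(s)")
  }
  if (length(probs)) {
    abort(paste0("Invalid landmark dataset:\n- ", paste(probs, collapse = "\n- ")))
  }
  dataset$cell_counts <- md %>%
    count(.data$species, .data$age_class, name = "n_specimens")
  invisible(dataset)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("<landmark_dataset> ", x$n, " specimens x ", x$k, " landmarks",
      if (!is.null(x$sliders)) paste0(" (", nrow(x$sliders), " semilandmarks)"),
      "\n", sep = "")
  if (!is.null(x$cell_counts)) print(x$cell_counts, n = Inf)
  invisible(x)
}
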