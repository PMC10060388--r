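#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis in one validated list.
#' The defaults reproduce the study's stated analysis settings: scores of
#' PCs 1-11 for model selection, fourfold cross-validation, a 2^-10..2^10
#' hyperparameter grid, and 1000 permutations.
#'
#' @param tps,sliders,metadata Input file paths (TPS landmarks, slider
#'   table, metadata CSV); alternatively pass a ready `dataset`.
#' @param dataset A `landmark_dataset` (overrides the paths).
#' @param flip_y Negate y at TPS ingestion (see [read_tps()]).
#' @param sliding_mode `"procrustes_distance"` (default), `"bending_energy"`
#'   or `"none"`.
#' @param alpha Relative-warp weighting exponent (default 0 = PCA).
#' @param n_pcs Number of leading PCs fed to the classifier battery and the
#'   per-PC analysis (default 11).
#' @param folds Cross-validation folds (default 4).
#' @param grid_exp Hyperparameter exponent grid (default `-10:10`).
#' @param B Permutations per cell (default 1000).
#' @param statistic Permutation statistic, `"accuracy"` or `"auc"`.
#' @param standardize Standardize features inside training folds.
#' @param per_species Per-species blocks in the per-PC table.
#' @param retune_per_cell Re-tune tuned classifiers per (group, PC) cell.
#' @param sd_extreme Score multiple (in SDs) for the exported PC-extreme
#'   shapes (default 1.5).
#' @param seed Global seed; stages derive their streams as `seed + 10`
#'   (classifier battery) and `seed + 20` (per-PC analysis), so stages can
#'   be re-run in isolation.
#' @param out_dir Output directory (created if missing); `NULL` to skip all
#'   file output.
#' @param quiet Suppress stage messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tps = NULL, sliders = NULL, metadata = NULL,
                            dataset = NULL, flip_y = FALSE,
                            sliding_mode = c("procrustes_distance",
                                             "bending_energy", "none"),
                            alpha = 0, n_pcs = 11, folds = 4,
                            grid_exp = -10:10, B = 1000,
                            statistic = "accuracy", standardize = TRUE,
                            per_species = TRUE, retune_per_cell = TRUE,
                            sd_extreme = 1.5, seed = 0, out_dir = NULL,
                            quiet = FALSE) {
  sliding_mode <- match.arg(sliding_mode)
  if (is.null(dataset) && is.null(tps)) {
    abort("pipeline_config(): supply either `dataset` or `tps` (+ `metadata`).")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes read/validate, generalized Procrustes superimposition with
#' semilandmark sliding, relative-warp decomposition, the four-model
#' classifier battery on the leading PCs, and the per-PC / per-species
#' permutation analysis with the selected model. When `out_dir` is set, a
#' reproducible bundle of plain-text outputs is written: aligned
#' coordinates, consensus, centroid sizes, variance table, PC scores, the
#' model-comparison table, the long-format age-classification table, mean
#' shapes per species x age class (TPS), PC-extreme shapes at
#' `+/- sd_extreme` SD (TPS), and a `manifest.txt` of every setting and
#' seed. Identical inputs and config give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `dataset`, `fit`, `model`,
#'   `variance`, `scores`, `battery`, `best_spec`, `age_table`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  say <- function(...) if (!cfg$quiet) inform(paste0("[facewarp] ", ...))
  stage <- "ingest"
  res <- tryCatch({
    ds <- cfg$dataset
    if (is.null(ds)) {
      say("reading ", cfg$tps)
      lm <- read_tps(cfg$tps, flip_y = cfg$flip_y)
      md <- read_specimen_metadata(cfg$metadata)
      sl <- if (!is.null(cfg$sliders)) {
        read_sliders(cfg$sliders, k = length(unique(lm$landmark)))
      }
      ds <- landmark_dataset(lm, md, sl)
    }
    ds <- validate_dataset(ds)
    say("dataset: ", ds$n, " specimens x ", ds$k, " landmarks")

    stage <- "gpa"
    fit <- gpa(ds)
    if (cfg$sliding_mode != "none" && !is.null(ds$sliders)) {
      say("sliding semilandmarks (", cfg$sliding_mode, ")")
      fit <- slide_semilandmarks(fit, mode = cfg$sliding_mode)
    }

    stage <- "relative_warps"
    model <- relative_warps(fit, alpha = cfg$alpha,
                            be = if (cfg$alpha != 0) bending_energy(fit$consensus))
    vt <- variance_table(model)
    n_pcs <- min(cfg$n_pcs, model$n_nontrivial)
    say(model$n_nontrivial, " non-trivial PCs; PC1-", n_pcs,
        " cumulative variance ",
        sprintf("%.1f%%", 100 * vt$cumulative_fraction[n_pcs]))

    stage <- "classifier_battery"
    st <- score_table(model)
    y <- factor(st$age_class, levels = c("adult", "infant"))
    X <- as.matrix(st[, paste0("PC", seq_len(n_pcs))])
    rownames(X) <- st$specimen_id
    battery <- classifier_battery(X, y, folds = cfg$folds,
                                  seed = cfg$seed + 10L,
                                  grid_exp = cfg$grid_exp,
                                  standardize = cfg$standardize)
    best <- attr(battery, "best")
    say("best model: ", best$kind)

    stage <- "per_pc_analysis"
    age_table <- per_pc_analysis(model, pcs = seq_len(n_pcs),
                                 spec = classifier_spec(best$kind,
                                                        cost = best$cost,
                                                        gamma = best$gamma),
                                 B = cfg$B, seed = cfg$seed + 20L,
                                 per_species = cfg$per_species,
                                 retune_per_cell = cfg$retune_per_cell,
                                 statistic = cfg$statistic,
                                 folds = cfg$folds, grid_exp = cfg$grid_exp,
                                 standardize = cfg$standardize)

    list(dataset = ds, fit = fit, model = model, variance = vt,
         scores = st, battery = battery, best_spec = best,
         age_table = age_table)
  }, error = function(e) {
    abort(paste0("Pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })

  res$manifest <- pipeline_manifest(cfg, res)
  if (!is.null(cfg$out_dir)) {
    say("writing outputs to ", cfg$out_dir)
    write_pipeline_outputs(res, cfg)
  }
  invisible(res)
}

pipeline_manifest <- function(cfg, res) {
  c(facewarp_version = as.character(utils::packageVersion("facewarp")),
    n_specimens = res$dataset$n, k_landmarks = res$dataset$k,
    sliding_mode = cfg$sliding_mode, alpha = cfg$alpha,
    n_pcs = cfg$n_pcs, folds = cfg$folds,
    grid_exp = paste(range(cfg$grid_exp), collapse = ".."),
    B = cfg$B, statistic = cfg$statistic,
    standardize = cfg$standardize, seed = cfg$seed,
    battery_seed = cfg$seed + 10L, per_pc_seed = cfg$seed + 20L,
    best_model = res$best_spec$kind,
    n_nontrivial_pcs = res$model$n_nontrivial)
}

write_pipeline_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  readr::write_csv(landmark_tibble(res$fit$aligned), p("aligned.csv"))
  readr::write_csv(landmark_tibble(res$fit$consensus,
                                   specimen_id = "consensus"),
                   p("consensus.csv"))
  readr::write_csv(tibble(specimen_id = names(res$fit$centroid_sizes),
                          centroid_size = res$fit$centroid_sizes),
                   p("centroid_sizes.csv"))
  readr::write_csv(res$variance, p("variance_table.csv"))
  readr::write_csv(res$scores, p("pc_scores.csv"))
  readr::write_csv(res$battery, p("model_comparison.csv"))
  readr::write_csv(res$age_table, p("age_class_table.csv"))

  md <- res$dataset$metadata
  means <- purrr::map_dfr(unique(md$species), function(sp) {
    purrr::map_dfr(c("adult", "infant"), function(ag) {
      m <- mean_shape(res$fit, .data$species == sp, .data$age_class == ag)
      landmark_tibble(m, specimen_id = paste0(sp, "_", ag, "_mean"))
    })
  })
  write_tps(bind_rows(
    means, landmark_tibble(mean_shape(res$fit), specimen_id = "grand_mean")
  ), p("mean_shapes.tps"))

  n_pcs <- min(cfg$n_pcs, res$model$n_nontrivial)
  extremes <- purrr::map_dfr(seq_len(n_pcs), function(pc) {
    s <- cfg$sd_extreme * sqrt(res$model$eigenvalues[pc])
    bind_rows(
      landmark_tibble(shape_at_score(res$model, pc, +s),
                      specimen_id = sprintf("PC%d_plus_%.1fSD", pc, cfg$sd_extreme)),
      landmark_tibble(shape_at_score(res$model, pc, -s),
                      specimen_id = sprintf("PC%d_minus_%.1fSD", pc, cfg$sd_extreme))
    )
  })
  write_tps(extremes, p("pc_extreme_shapes.tps"))

  writeLines(paste0(names(res$manifest), "=", unlist(res$manifest)),
             p("manifest.txt"))
}
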