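#' Read a tpsDig landmark file
#'
#' Parses the plain-text TPS dialect written by tpsDig: records start with an
#' `LM=<n>` line, followed by `n` whitespace-separated `x y` coordinate lines,
#' optionally followed by `IMAGE=`, `ID=` and `SCALE=` lines. Records without
#' an `ID=` line get their 1-based record index as `specimen_id`.
#'
#' TPS files store y increasing upward (origin bottom left). `flip_y = TRUE`
#' negates y at ingestion for data digitized in screen convention; mixing the
#' two conventions silently reflects shapes, so the reader never guesses.
#' `SCALE=` values are stored in a `scale` column as provenance but are not
#' applied: size is removed by the Procrustes fit, so applying scale has no
#' effect on shape. Unknown record keywords (e.g. `CURVES=`, `POINTS=`) are
#' rejected rather than skipped, to fail loudly on dialect drift.
#'
#' @param path Path to a TPS file.
#' @param flip_y Negate all y coordinates on read (default `FALSE`).
#' @return A landmark tibble with columns `specimen_id`, `landmark`, `x`,
#'   `y`, `image`, `scale`; all records must share one landmark count.
#' @seealso [write_tps()], [read_sliders()]
#' @export
read_tps <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  rec_idx <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      abort(paste0("Line ", i, ": expected 'LM=<n>' record header, got '", line, "'."))
    }
    rec_idx <- rec_idx + 1L
    n_lm <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line, ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 1) {
      abort(paste0("Record ", rec_idx, " (line ", i, "): malformed LM count."))
    }
    i <- i + 1L
    coords <- matrix(NA_real_, n_lm, 2)
    for (j in seq_len(n_lm)) {
      if (i > length(lines) || grepl("^[A-Za-z]+\\s*=", trimws(lines[i]))) {
        abort(paste0("Record ", rec_idx, ": LM=", n_lm,
                     " but only ", j - 1L, " coordinate lines found."))
      }
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || any(is.na(vals))) {
        abort(paste0("Line ", i, ": non-numeric or malformed coordinate pair '",
                     trimws(lines[i]), "'."))
      }
      coords[j, ] <- vals
      i <- i + 1L
    }
    image <- NA_character_; id <- NA_character_; scale <- NA_real_
    while (i <= length(lines) && grepl("^[A-Za-z]+\\s*=", trimws(lines[i]))) {
      kvline <- trimws(lines[i])
      if (grepl("^LM\\s*=", kvline, ignore.case = TRUE)) break
      key <- toupper(sub("\\s*=.*$", "", kvline))
      val <- sub("^[A-Za-z]+\\s*=\\s*", "", kvline)
      if (key == "IMAGE") image <- val
      else if (key == "ID") id <- val
      else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale) || scale <= 0) {
          abort(paste0("Line ", i, ": SCALE= must be a positive number."))
        }
      } else {
        abort(paste0("Line ", i, ": unsupported TPS keyword '", key,
                     "='. Only LM=, IMAGE=, ID=, SCALE= are accepted."))
      }
      i <- i + 1L
    }
    if (is.na(id)) id <- as.character(rec_idx)
    recs[[rec_idx]] <- tibble(
      specimen_id = id, landmark = seq_len(n_lm),
      x = coords[, 1], y = if (flip_y) -coords[, 2] else coords[, 2],
      image = image, scale = scale
    )
  }
  if (rec_idx == 0L) abort("No TPS records found.")
  out <- bind_rows(recs)
  ks <- out %>% count(.data$specimen_id, name = "k") %>% pull(.data$k)
  if (length(unique(ks)) > 1) {
    abort(paste0("Inconsistent landmark counts across records: ",
                 paste(sort(unique(ks)), collapse = ", "), "."))
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Emits `LM=` / coordinate / `ID=` records (plus `IMAGE=` and `SCALE=` when
#' present) readable by [read_tps()]. Coordinates are written with 6 decimal
#' places.
#'
#' @param landmarks A landmark tibble (uniform landmark count per specimen).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  if (nrow(landmarks) == 0) abort("write_tps(): empty landmark set.")
  ks <- landmarks %>% count(.data$specimen_id, name = "k") %>% pull(.data$k)
  if (length(unique(ks)) > 1) {
    abort("write_tps(): specimens have differing landmark counts.")
  }
  ids <- unique(landmarks$specimen_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    sub <- landmarks[landmarks$specimen_id == id, ]
    sub <- sub[order(sub$landmark), ]
    writeLines(paste0("LM=", nrow(sub)), con)
    writeLines(sprintf("%.6f %.6f", sub$x, sub$y), con)
    img <- if ("image" %in% names(sub)) sub$image[1] else NA_character_
    if (!is.na(img)) writeLines(paste0("IMAGE=", img), con)
    writeLines(paste0("ID=", id), con)
    scl <- if ("scale" %in% names(sub)) sub$scale[1] else NA_real_
    if (!is.na(scl)) writeLines(sprintf("SCALE=%.6f", scl), con)
  }
  invisible(path)
}

#' Read a semilandmark slider file
#'
#' Each slider is a `(before, slider, after)` landmark-index triplet: the
#' middle landmark is allowed to slide along the chord between its two
#' flanking landmarks during superimposition. Two on-disk dialects are
#' accepted: plain text with three integer columns (`#` comments allowed),
#' and the tpsUtil sliders dialect whose first line is an NTS-style header
#' (`1 <n>L 3 0`).
#'
#' In-file indices may be 0- or 1-based. With `indexing = "auto"` and a known
#' `k`, indices are taken as 1-based if any index equals `k` and none equals
#' 0, otherwise 0-based; without `k`, the presence of a 0 decides. The
#' detected convention is reported with a message. Returned triplets are
#' always 1-based (R convention).
#'
#' @param path Path to the slider file.
#' @param k Number of landmarks in the configurations the sliders refer to
#'   (used for index validation and base detection); optional.
#' @param indexing `"auto"` (default), `"one"`, or `"zero"` — base of the
#'   indices in the file.
#' @return A tibble with integer columns `before`, `slider`, `after`
#'   (1-based).
#' @export
read_sliders <- function(path, k = NULL, indexing = c("auto", "one", "zero")) {
  indexing <- match.arg(indexing)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) abort("Slider file contains no triplets.")
  n_declared <- NA_integer_
  if (grepl("^1\\s+\\d+L?\\s+3\\s+0", lines[1])) { # NTS-style tpsUtil header
    n_declared <- as.integer(sub("^1\\s+(\\d+)L?.*$", "\\1", lines[1]))
    lines <- lines[-1]
  }
  mat <- t(vapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[i], "[[:space:],]+")[[1]]))
    if (length(vals) != 3 || any(is.na(vals)) || any(vals != round(vals))) {
      abort(paste0("Slider line '", lines[i], "': expected three integers."))
    }
    as.integer(vals)
  }, integer(3)))
  if (!is.na(n_declared) && n_declared != nrow(mat)) {
    abort(paste0("Slider header declares ", n_declared, " rows but file has ",
                 nrow(mat), "."))
  }
  base1 <- switch(indexing,
    one  = TRUE,
    zero = FALSE,
    auto = if (!is.null(k)) any(mat == k) && !any(mat == 0) else !any(mat == 0)
  )
  if (indexing == "auto") {
    inform(paste0("read_sliders: indices detected as ",
                  if (base1) "1" else "0", "-based."))
  }
  if (!base1) mat <- mat + 1L
  sliders <- tibble(before = mat[, 1], slider = mat[, 2], after = mat[, 3])
  validate_sliders(sliders, k)
  sliders
}

validate_sliders <- function(sliders, k = NULL) {
  probs <- character()
  if (anyDuplicated(sliders$slider)) {
    probs <- c(probs, "duplicate slider indices")
  }
  bad <- with(sliders, before == slider | slider == after | before == after)
  if (any(bad)) {
    probs <- c(probs, paste0("degenerate triplet(s) at row(s) ",
                             paste(which(bad), collapse = ", ")))
  }
  if (any(unlist(sliders) < 1)) probs <- c(probs, "indices below 1")
  if (!is.null(k) && any(unlist(sliders) > k)) {
    probs <- c(probs, paste0("indices above k = ", k))
  }
  if (length(probs)) {
    abort(paste0("Invalid slider table: ", paste(probs, collapse = "; "), "."))
  }
  invisible(sliders)
}

#' Read a specimen metadata table
#'
#' CSV with header `specimen_id,species,age_class,sex`; values are
#' case-insensitive. `age_class` must be adult/infant; `sex` must be
#' male/female/unknown (missing values become `"unknown"`).
#'
#' @param path CSV file path.
#' @return A tibble with those four columns, values lower-cased.
#' @export
read_specimen_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE)
  names(md) <- tolower(names(md))
  need <- c("specimen_id", "species", "age_class", "sex")
  if (!all(need %in% names(md))) {
    abort(paste0("Metadata must have columns ", paste(need, collapse = ", "), "."))
  }
  md <- md %>%
    mutate(specimen_id = as.character(.data$specimen_id),
           species = tolower(as.character(.data$species)),
           age_class = tolower(as.character(.data$age_class)),
           sex = tolower(ifelse(is.na(.data$sex), "unknown", as.character(.data$sex)))) %>%
    select(dplyr::all_of(need))
  bad_age <- setdiff(unique(md$age_class), c("adult", "infant"))
  if (length(bad_age)) {
    abort(paste0("Unknown age_class value(s): ", paste(bad_age, collapse = ", "), "."))
  }
  bad_sex <- setdiff(unique(md$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) {
    abort(paste0("Unknown sex value(s): ", paste(bad_sex, collapse = ", "), "."))
  }
  md
}
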