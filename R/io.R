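# Canonical annotation data model and file formats.
#
# Point annotations live in a tibble with columns
#   image_id, rater_id, study_phase ("P1"/"P2"), x, y, cls
# where coordinates are 0-based pixel centers in the H&E frame and cls is one
# of MF (phase 1), HE_AND_PHH3 / HE_ONLY / PHH3_ONLY (phase 2). On disk the
# canonical format is JSON lines with sorted keys (byte-stable round trips);
# a flat CSV export with the same columns is provided as well.

ANNOTATION_COLS <- c("image_id", "rater_id", "study_phase", "x", "y", "cls")

#' Validate an annotation tibble
#'
#' Checks the schema and the phase/class invariants: phase-1 annotations must
#' carry class `MF` and phase-2 annotations one of `HE_AND_PHH3`, `HE_ONLY`,
#' `PHH3_ONLY`; coordinates must be finite and non-negative.
#'
#' @param annotations Tibble to validate.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_annotations <- function(annotations) {
  missing <- setdiff(ANNOTATION_COLS, names(annotations))
  if (length(missing)) {
    abort(sprintf("annotation table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad_phase <- which(!annotations$study_phase %in% c("P1", "P2"))
  if (length(bad_phase)) {
    abort(sprintf("row %d: invalid study_phase '%s'",
                  bad_phase[1], annotations$study_phase[bad_phase[1]]))
  }
  bad_cls <- which(!annotations$cls %in% ANNOTATION_CLASSES)
  if (length(bad_cls)) {
    abort(sprintf("row %d: invalid cls '%s'", bad_cls[1],
                  annotations$cls[bad_cls[1]]))
  }
  p1_bad <- which(annotations$study_phase == "P1" & annotations$cls != "MF")
  if (length(p1_bad)) {
    abort(sprintf("row %d: field cls: P1 annotations must have cls = MF (got '%s')",
                  p1_bad[1], annotations$cls[p1_bad[1]]))
  }
  p2_bad <- which(annotations$study_phase == "P2" & annotations$cls == "MF")
  if (length(p2_bad)) {
    abort(sprintf("row %d: field cls: P2 annotations must use the three assisted classes",
                  p2_bad[1]))
  }
  bad_xy <- which(!is.finite(annotations$x) | !is.finite(annotations$y) |
                    annotations$x < 0 | annotations$y < 0)
  if (length(bad_xy)) {
    abort(sprintf("row %d: field x/y: coordinates must be finite and >= 0", bad_xy[1]))
  }
  annotations
}

#' Write point annotations as JSON lines
#'
#' One JSON object per line, keys sorted, so identical tables always produce
#' byte-identical files.
#'
#' @param annotations Annotation tibble (validated on the way out).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  lines <- purrr::map_chr(seq_len(nrow(annotations)), function(i) {
    jsonlite::toJSON(list(
      cls = annotations$cls[i],
      image_id = annotations$image_id[i],
      rater_id = annotations$rater_id[i],
      study_phase = annotations$study_phase[i],
      x = annotations$x[i],
      y = annotations$y[i]
    ), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read point annotations from JSON lines or CSV
#'
#' The format is inferred from the file extension (`.csv` versus anything
#' else, treated as JSON lines). An empty file yields an empty, well-typed
#' annotation tibble. Malformed rows raise an error naming the line and
#' field.
#'
#' @param path Input file.
#' @return Annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  empty <- tibble::tibble(image_id = character(), rater_id = character(),
                          study_phase = character(), x = numeric(),
                          y = numeric(), cls = character())
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) return(empty)
    out <- tibble::as_tibble(df)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty)
    rows <- purrr::map(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) abort(sprintf(
                        "line %d: malformed JSON (%s)", i, conditionMessage(e))))
      for (f in ANNOTATION_COLS) {
        if (is.null(rec[[f]])) abort(sprintf("line %d: missing field '%s'", i, f))
      }
      tibble::tibble(image_id = as.character(rec$image_id),
                     rater_id = as.character(rec$rater_id),
                     study_phase = as.character(rec$study_phase),
                     x = as.numeric(rec$x), y = as.numeric(rec$y),
                     cls = as.character(rec$cls))
    })
    out <- dplyr::bind_rows(rows)
  }
  validate_annotations(out[ANNOTATION_COLS])
}

#' Export annotations as CSV
#'
#' Flat table with header `image_id,rater_id,study_phase,x,y,cls`.
#'
#' @inheritParams write_annotations
#' @export
write_annotations_csv <- function(annotations, path) {
  validate_annotations(annotations)
  utils::write.csv(annotations[ANNOTATION_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a study dataset to a directory
#'
#' Emits the dataset manifest (`manifest.json`, sorted keys), the ground
#' truth (`ground_truth.csv`) and the annotations of both phases
#' (`annotations.jsonl`). Byte-identical for identical studies.
#'
#' @param study A `study_dataset`.
#' @param dir Output directory.
#' @param images If `TRUE`, also render and write every image pair as PNGs.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, images = FALSE) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    ground_truth = "ground_truth.csv",
    image_ids = study$image_ids,
    image_size_px = study$config$image_size_px,
    mpp = study$config$mpp,
    n_images = study$config$n_images,
    n_raters = study$config$n_raters
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(study$cells, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_annotations(study$annotations, file.path(dir, "annotations.jsonl"))
  if (images) {
    for (id in study$image_ids) {
      write_image_pair(render_study_image(study, id), file.path(dir, "images"))
    }
  }
  invisible(dir)
}

#' Monte-Carlo train/validation/test splits by image
#'
#' Draws `n_splits` independent random partitions of the image ids into
#' train/validation/test subsets. Fractions apply to image counts with
#' rounding toward the training set (validation and test sizes are floored).
#' Splitting is by image, never by patch, so no tissue leaks across subsets.
#' All models in an experiment must reuse one and the same splits object.
#'
#' @param image_ids Character vector of image ids.
#' @param n_splits Number of Monte-Carlo repetitions.
#' @param fractions Length-3 numeric vector (train, val, test) summing to 1.
#' @param seed Random seed.
#' @return Tibble with columns `split`, `image_id`, `subset`.
#' @export
monte_carlo_splits <- function(image_ids, n_splits = 5,
                               fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(image_ids) < 3) abort("need at least 3 images to split")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three numbers summing to 1")
  }
  n <- length(image_ids)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1) {
    abort("fractions leave an empty subset at this image count")
  }
  with_seed(derive_seed(seed, "splits"), {
    purrr::map(seq_len(n_splits), function(s) {
      perm <- sample(image_ids)
      tibble::tibble(
        split = s,
        image_id = perm,
        subset = rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
      )
    }) |> dplyr::bind_rows()
  })
}

#' Image ids of one subset of one split
#'
#' @param splits Tibble from [monte_carlo_splits()].
#' @param split Split index.
#' @param subset `"train"`, `"val"` or `"test"`.
#' @return Character vector of image ids.
#' @export
split_ids <- function(splits, split, subset) {
  splits$image_id[splits$split == split & splits$subset == subset]
}
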