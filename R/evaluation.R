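# Whole-image evaluation: overlapping-tile inference with global
# non-maximum suppression, distance-matched average precision, and the
# train-label x eval-label experiment grid.

#' Tile origins covering an extent
#'
#' Origins advance by `tile - overlap`; the final origin is clamped so the
#' border is covered. For width 1024, tile 512 and overlap 50 the x-origins
#' are 0, 462, 512.
#'
#' @param size Image extent in pixels.
#' @param tile Tile side.
#' @param overlap Overlap between consecutive tiles.
#' @return Sorted unique integer origins.
#' @export
tile_origins <- function(size, tile, overlap = 50) {
  if (tile >= size) return(0L)
  if (overlap >= tile) abort("overlap must be smaller than the tile")
  step <- tile - overlap
  org <- seq(0L, size - tile, by = step)
  sort(unique(c(org, size - tile)))
}

#' Tiled whole-image inference
#'
#' Divides the image into overlapping tiles, runs the detector on each tile
#' (both stains for dual models), transfers detections back to global
#' coordinates, and removes duplicates from overlap zones with one global
#' IoU-based non-maximum suppression. Images no larger than the tile get a
#' single full pass.
#'
#' @param detector Any detector with a [detect_patch()] method.
#' @param image_pair An `image_pair` (or list with `he` and optionally
#'   `phh3` arrays).
#' @param tile Tile side in pixels.
#' @param overlap Tile overlap in pixels.
#' @param nms_iou IoU threshold of the global suppression.
#' @param edge_margin Detections closer than this to a tile edge that is not
#'   an image edge are discarded before pooling (tile-border effects are
#'   covered by the neighboring tile). 0 keeps everything.
#' @return Detection tibble in global image coordinates.
#' @export
tiled_inference <- function(detector, image_pair, tile = 512, overlap = 50,
                            nms_iou = 0.3, edge_margin = 0) {
  he <- image_pair$he
  phh3 <- image_pair$phh3
  h <- dim(he)[1]
  w <- dim(he)[2]
  oxs <- tile_origins(w, tile, overlap)
  oys <- tile_origins(h, tile, overlap)
  out <- list()
  for (oy in oys) {
    for (ox in oxs) {
      ts_h <- min(tile, h)
      ts_w <- min(tile, w)
      he_t <- as_double_img(he[(oy + 1):(oy + ts_h), (ox + 1):(ox + ts_w), , drop = FALSE])
      ph_t <- if (!is.null(phh3))
        as_double_img(phh3[(oy + 1):(oy + ts_h), (ox + 1):(ox + ts_w), , drop = FALSE])
      det <- detect_patch(detector, he_t, ph_t)
      if (nrow(det) && edge_margin > 0) {
        keep <- rep(TRUE, nrow(det))
        if (ox > 0) keep <- keep & det$x >= edge_margin
        if (ox + ts_w < w) keep <- keep & det$x <= ts_w - 1 - edge_margin
        if (oy > 0) keep <- keep & det$y >= edge_margin
        if (oy + ts_h < h) keep <- keep & det$y <= ts_h - 1 - edge_margin
        det <- det[keep, ]
      }
      if (nrow(det)) {
        det$x <- det$x + ox
        det$y <- det$y + oy
        det$x0 <- det$x0 + ox
        det$x1 <- det$x1 + ox
        det$y0 <- det$y0 + oy
        det$y1 <- det$y1 + oy
        out[[length(out) + 1L]] <- det
      }
    }
  }
  det <- dplyr::bind_rows(out)
  if (!nrow(det)) {
    return(tibble::tibble(x = numeric(), y = numeric(), x0 = numeric(),
                          y0 = numeric(), x1 = numeric(), y1 = numeric(),
                          score = numeric()))
  }
  nms_detections(det, nms_iou)
}

#' Distance-matched average precision
#'
#' Detections are ranked by descending score; each is greedily matched to
#' the nearest still-unmatched ground-truth point within the radius.
#' Precision/recall are accumulated over the ranked list and the AP is the
#' area under the all-point interpolated precision-recall curve. Empty
#' ground truth makes the AP undefined (`NA` with an explanatory note); a
#' detector with no detections scores 0.
#'
#' @param detections Detection tibble (`x`, `y`, `score`, optionally
#'   `image_id`).
#' @param gt_points Ground-truth tibble (`x`, `y`, optionally `image_id`).
#' @param radius_um Matching radius in microns.
#' @param mpp Microns per pixel.
#' @return An `eval_result` list: `ap`, `curve` (tibble `recall`,
#'   `precision`), `tp`, `fp`, `fn`, `radius_um`.
#' @export
average_precision <- function(detections, gt_points, radius_um = 7.5,
                              mpp = 0.25) {
  check_mpp(mpp)
  radius_px <- um_to_px(radius_um, mpp)
  if (nrow(gt_points) == 0) {
    return(structure(list(ap = NA_real_, curve = NULL, tp = 0L, fp = 0L,
                          fn = 0L, radius_um = radius_um,
                          note = "AP undefined: empty ground truth"),
                     class = "eval_result"))
  }
  if (!"image_id" %in% names(detections)) detections$image_id <- "image"
  if (!"image_id" %in% names(gt_points)) gt_points$image_id <- "image"
  n_gt <- nrow(gt_points)
  if (nrow(detections) == 0) {
    return(structure(list(ap = 0, curve = tibble::tibble(recall = 0, precision = 0),
                          tp = 0L, fp = 0L, fn = n_gt, radius_um = radius_um),
                     class = "eval_result"))
  }
  ord <- order(-detections$score, seq_len(nrow(detections)))
  matched <- rep(FALSE, n_gt)
  is_tp <- logical(nrow(detections))
  for (k in ord) {
    cand <- which(!matched & gt_points$image_id == detections$image_id[k])
    if (!length(cand)) next
    d <- sqrt((gt_points$x[cand] - detections$x[k])^2 +
                (gt_points$y[cand] - detections$y[k])^2)
    j <- which.min(d)
    if (d[j] <= radius_px) {
      matched[cand[j]] <- TRUE
      is_tp[k] <- TRUE
    }
  }
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # all-point interpolation: precision envelope from the right
  prec_env <- rev(cummax(rev(precision)))
  rec_step <- diff(c(0, recall))
  ap <- sum(rec_step * prec_env)
  structure(list(ap = ap,
                 curve = tibble::tibble(recall = recall, precision = prec_env),
                 tp = sum(is_tp), fp = sum(!is_tp), fn = n_gt - sum(is_tp),
                 radius_um = radius_um),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  if (is.na(x$ap)) {
    cat(sprintf("<eval_result> AP undefined (%s)\n", x$note))
  } else {
    cat(sprintf("<eval_result> AP = %.3f (TP %d, FP %d, FN %d; radius %.1f um)\n",
                x$ap, x$tp, x$fp, x$fn, x$radius_um))
  }
  invisible(x)
}

#' Evaluate a detector on whole images under one label set
#'
#' Runs tiled inference over the listed images and scores the pooled
#' detections against the label set.
#'
#' @param detector Detector object.
#' @param study A `study_dataset`.
#' @param labels Label tibble.
#' @param image_ids Images to evaluate.
#' @param tile,overlap Tiling parameters.
#' @param radius_um Matching radius.
#' @param cache Optional image cache (see internals) reused across calls.
#' @return An `eval_result`.
#' @export
evaluate_detector <- function(detector, study, labels, image_ids,
                              tile = 512, overlap = 50, radius_um = 7.5,
                              cache = NULL) {
  if (is.null(cache)) cache <- new_image_cache()
  dets <- purrr::map(image_ids, function(id) {
    pair <- cache_get(cache, study, id)
    d <- tiled_inference(detector, pair, tile, overlap)
    d$image_id <- id
    d
  }) |> dplyr::bind_rows()
  gt <- labels[labels$image_id %in% image_ids, ]
  average_precision(dets, gt, radius_um, study$config$mpp)
}

#' Run the train-label by eval-label experiment grid
#'
#' For every model configuration and training label set, trains one detector
#' per Monte-Carlo split and evaluates it on that split's test images under
#' every evaluation label set (the same splits for every model). The result
#' grid is the machine-readable twin of the cross-validated mean +/- sd AP
#' table.
#'
#' @param study A `study_dataset`.
#' @param label_sets Named list of label tibbles (training and evaluation
#'   sets are named out of this list).
#' @param splits Splits tibble from [monte_carlo_splits()].
#' @param models Named list of [detector_config()]s.
#' @param train_on Character vector of label-set names to train on.
#' @param eval_on Character vector of label-set names to evaluate on.
#' @param seed Base seed.
#' @param tile,overlap Tiling parameters for test-image inference.
#' @param cache Optional image cache shared across repeated grid runs (see
#'   [new_image_cache()]); rendering each image once dominates the cost of
#'   repeated experiments.
#' @param verbose Print progress.
#' @return A `result_grid` tibble: `model`, `train_labels`, `eval_labels`,
#'   `split`, `ap`.
#' @export
run_experiment_grid <- function(study, label_sets, splits,
                                models = list(
                                  single = detector_config("single"),
                                  dual = detector_config("dual")),
                                train_on = c("he_only_labels", "phh3_assisted_labels"),
                                eval_on = names(label_sets),
                                seed = 1L, tile = 512, overlap = 50,
                                cache = NULL, verbose = FALSE) {
  miss <- setdiff(union(train_on, eval_on), names(label_sets))
  if (length(miss)) {
    abort(sprintf("label set(s) missing: %s", paste(miss, collapse = ", ")))
  }
  if (is.null(cache)) cache <- new_image_cache()
  split_ids_all <- sort(unique(splits$split))
  rows <- list()
  for (mname in names(models)) {
    for (tr in train_on) {
      for (s in split_ids_all) {
        det <- train_detector(
          study, label_sets[[tr]],
          train_ids = split_ids(splits, s, "train"),
          val_ids = split_ids(splits, s, "val"),
          config = models[[mname]],
          seed = derive_seed(seed, c("grid", mname, tr, s)),
          cache = cache)
        # detections do not depend on the evaluation label set: run tiled
        # inference once per test image and score against every label set
        test_ids <- split_ids(splits, s, "test")
        dets <- purrr::map(test_ids, function(id) {
          pair <- cache_get(cache, study, id)
          d <- tiled_inference(det, pair, tile, overlap)
          d$image_id <- id
          d
        }) |> dplyr::bind_rows()
        for (ev in eval_on) {
          gt <- label_sets[[ev]][label_sets[[ev]]$image_id %in% test_ids, ]
          res <- average_precision(dets, gt, radius_um = 7.5,
                                   mpp = study$config$mpp)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            model = mname, train_labels = tr, eval_labels = ev,
            split = s, ap = res$ap)
          if (verbose) {
            message(sprintf("%s / train %s / split %d / eval %s: AP %.3f",
                            mname, tr, s, ev, res$ap))
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("result_grid", class(out))
  out
}

#' Matched-filter baseline detector
#'
#' A classical detector that correlates the stain-darkness map with a
#' disc-shaped kernel at the nucleus scale and reports local maxima above a
#' threshold. It is exactly translation-equivariant, which makes it the
#' reference model for tile-border consistency checks; it is also a useful
#' cheap stand-in wherever a deterministic detector is needed. In dual mode
#' the PHH3 brown-signal map is added to the response so marker-only cells
#' are detected too.
#'
#' @param mode `"single"` or `"dual"`.
#' @param kernel_radius_px Radius of the matched disc.
#' @param threshold Response threshold in \[0, 1\].
#' @param box_size_px Side of the reported boxes.
#' @return A `template_detector` object with a [detect_patch()] method.
#' @export
template_detector <- function(mode = c("single", "dual"), kernel_radius_px = 8,
                              threshold = 0.35, box_size_px = 50) {
  mode <- match.arg(mode)
  structure(list(mode = mode, r = kernel_radius_px, threshold = threshold,
                 box = box_size_px),
            class = c("template_detector"))
}

#' @export
detect_patch.template_detector <- function(detector, he, phh3 = NULL, ...) {
  resp <- chromatin_response(he)
  if (detector$mode == "dual" && !is.null(phh3)) {
    resp <- pmax(resp, dab_response(phh3))
  }
  r <- detector$r
  disc <- outer(-r:r, -r:r, function(i, j) as.numeric(i^2 + j^2 <= r^2))
  sm <- cpp_filter2d(resp, disc / sum(disc))
  det <- local_maxima(sm, detector$threshold, min_dist = r)
  if (!nrow(det)) {
    return(tibble::tibble(x = numeric(), y = numeric(), x0 = numeric(),
                          y0 = numeric(), x1 = numeric(), y1 = numeric(),
                          score = numeric()))
  }
  h <- detector$box / 2
  tibble::tibble(x = det$x, y = det$y,
                 x0 = det$x - h, y0 = det$y - h,
                 x1 = det$x + h, y1 = det$y + h,
                 score = det$score)
}

# Dark condensed-chromatin response of an H&E patch in [0, 1].
chromatin_response <- function(he) {
  darkness <- 1 - (he[, , 1] + he[, , 2] + he[, , 3]) / 3
  pmin(pmax((darkness - 0.45) / 0.35, 0), 1)
}

# Brown immunolabel response of a PHH3 patch.
dab_response <- function(phh3) {
  brown <- phh3[, , 1] - phh3[, , 3]
  pmin(pmax((brown - 0.1) / 0.3, 0), 1)
}

local_maxima <- function(m, threshold, min_dist = 6) {
  idx <- which(m >= threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(tibble::tibble(x = numeric(), y = numeric(), score = numeric()))
  vals <- m[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  keep <- matrix(numeric(0), 0, 2)
  score <- numeric(0)
  for (k in ord) {
    p <- idx[k, ]
    if (nrow(keep)) {
      d2 <- (keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2
      if (min(d2) < min_dist^2) next
    }
    keep <- rbind(keep, p)
    score <- c(score, vals[k])
  }
  # array rows are y+1, cols are x+1 (0-based pixel coordinates)
  tibble::tibble(x = keep[, 2] - 1, y = keep[, 1] - 1, score = score)
}

#' F1-maximizing operating threshold of a ranked detection list
#'
#' Greedily matches ranked detections to ground truth (as in the average
#' precision computation) and returns the score at which the running F1 is
#' maximal; used to calibrate a model's operating point on validation
#' images.
#'
#' @param detections Detection tibble with `score` (and `image_id`).
#' @param gt_points Ground-truth points.
#' @param radius_um,mpp Matching radius.
#' @return Scalar threshold (0 if there are no detections).
#' @export
best_f1_threshold <- function(detections, gt_points, radius_um = 7.5,
                              mpp = 0.25) {
  if (!nrow(detections) || !nrow(gt_points)) return(0)
  radius_px <- um_to_px(radius_um, mpp)
  if (!"image_id" %in% names(detections)) detections$image_id <- "image"
  if (!"image_id" %in% names(gt_points)) gt_points$image_id <- "image"
  ord <- order(-detections$score, seq_len(nrow(detections)))
  matched <- rep(FALSE, nrow(gt_points))
  is_tp <- logical(length(ord))
  for (idx in seq_along(ord)) {
    k <- ord[idx]
    cand <- which(!matched & gt_points$image_id == detections$image_id[k])
    if (!length(cand)) next
    d <- sqrt((gt_points$x[cand] - detections$x[k])^2 +
                (gt_points$y[cand] - detections$y[k])^2)
    j <- which.min(d)
    if (d[j] <= radius_px) {
      matched[cand[j]] <- TRUE
      is_tp[idx] <- TRUE
    }
  }
  tp <- cumsum(is_tp)
  f1 <- 2 * tp / (nrow(gt_points) + seq_along(tp))
  detections$score[ord][which.max(f1)]
}
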