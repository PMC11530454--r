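# Distance-based consensus clustering of multi-rater point annotations.
#
# The clustering rule: annotations are processed in a deterministic order
# (rater_id, then x, then y); each annotation joins the nearest existing
# cluster whose *current* centroid lies within the radius and which does not
# yet contain an annotation from the same rater (support counts count
# experts, so a rater can back a cell at most once); otherwise it founds a
# new cluster. Centroids are running means, recomputed after every
# admission. Ties on distance break toward the lowest cluster index.

#' Cluster point annotations of one image
#'
#' @param annotations Annotation tibble, all rows from a single image.
#' @param radius_um Admission radius in microns (7.5 is one nucleus
#'   diameter).
#' @param mpp Microns per pixel.
#' @return The input tibble with an added `.cluster` integer column, plus a
#'   `"clusters"` attribute: tibble of `cluster`, `x`, `y` (centroid),
#'   `support` (number of distinct supporting raters).
#' @export
cluster_annotations <- function(annotations, radius_um = 7.5, mpp = 0.25) {
  check_mpp(mpp)
  if (length(unique(annotations$image_id)) > 1) {
    abort("cluster_annotations() operates on one image at a time")
  }
  radius_px <- um_to_px(radius_um, mpp)
  ord <- order(annotations$rater_id, annotations$x, annotations$y)
  n <- nrow(annotations)
  raters <- unique(annotations$rater_id)
  r_idx <- match(annotations$rater_id, raters)
  assign <- integer(n)
  # preallocated growing cluster state; has_rater[r, k] marks membership
  cap <- max(16L, n)
  cx <- numeric(cap)
  cy <- numeric(cap)
  csize <- integer(cap)
  has_rater <- matrix(FALSE, length(raters), cap)
  nc <- 0L
  for (k in seq_len(n)) {
    i <- ord[k]
    x <- annotations$x[i]
    y <- annotations$y[i]
    r <- r_idx[i]
    best <- 0L
    if (nc > 0L) {
      sel <- seq_len(nc)
      d2 <- (cx[sel] - x)^2 + (cy[sel] - y)^2
      eligible <- which(d2 <= radius_px^2 & !has_rater[r, sel])
      if (length(eligible)) best <- eligible[which.min(d2[eligible])]
    }
    if (best == 0L) {
      nc <- nc + 1L
      cx[nc] <- x
      cy[nc] <- y
      csize[nc] <- 1L
      has_rater[r, nc] <- TRUE
      assign[i] <- nc
    } else {
      m <- csize[best]
      cx[best] <- (cx[best] * m + x) / (m + 1)
      cy[best] <- (cy[best] * m + y) / (m + 1)
      csize[best] <- m + 1L
      has_rater[r, best] <- TRUE
      assign[i] <- best
    }
  }
  out <- annotations
  out$.cluster <- assign
  attr(out, "clusters") <- tibble::tibble(
    cluster = seq_len(nc), x = cx[seq_len(nc)], y = cy[seq_len(nc)],
    support = as.integer(colSums(has_rater[, seq_len(nc), drop = FALSE]))
  )
  attr(out, "radius_um") <- radius_um
  attr(out, "mpp") <- mpp
  out
}

#' Threshold clusters into a consensus set
#'
#' Retains every cluster centroid supported by at least `min_support`
#' distinct raters.
#'
#' @param clustered Result of [cluster_annotations()].
#' @param min_support Minimum number of supporting raters (>= 1).
#' @return Consensus tibble: `image_id`, `x`, `y`, `support`.
#' @export
build_consensus <- function(clustered, min_support = 6) {
  if (min_support < 1) abort("`min_support` must be >= 1")
  cl <- attr(clustered, "clusters")
  if (is.null(cl)) abort("`clustered` must come from cluster_annotations()")
  keep <- cl[cl$support >= min_support, ]
  tibble::tibble(
    image_id = rep(if (nrow(clustered)) clustered$image_id[1] else "image", nrow(keep)),
    x = keep$x, y = keep$y, support = keep$support
  )
}

#' Leave-one-out consensus for scoring a single rater
#'
#' Builds the consensus from all raters except the one being scored. The
#' support threshold defaults to at least half of the remaining experts,
#' rounded up: `ceil(support_fraction * (n_raters - 1))`, i.e. 6 for a
#' 13-expert panel.
#'
#' @param annotations Annotation tibble of one image (or one image-phase).
#' @param excluded_rater Rater id to hold out.
#' @param radius_um,mpp See [cluster_annotations()].
#' @param support_fraction Fraction of the remaining raters that must agree.
#' @return Consensus tibble as in [build_consensus()].
#' @export
leave_one_out_consensus <- function(annotations, excluded_rater,
                                    radius_um = 7.5, mpp = 0.25,
                                    support_fraction = 0.5) {
  raters <- unique(annotations$rater_id)
  if (!excluded_rater %in% raters) {
    abort(sprintf("rater '%s' not present in the annotations", excluded_rater))
  }
  if (length(raters) < 2) abort("need at least 2 raters for a leave-one-out consensus")
  min_support <- ceiling(support_fraction * (length(raters) - 1))
  rest <- annotations[annotations$rater_id != excluded_rater, ]
  if (!nrow(rest)) {
    return(tibble::tibble(image_id = character(), x = numeric(),
                          y = numeric(), support = integer()))
  }
  build_consensus(cluster_annotations(rest, radius_um, mpp), min_support)
}

#' Derive the study's H&E-only and PHH3-assisted label sets
#'
#' The H&E-only label set is the full-panel consensus over phase-1
#' annotations. The PHH3-assisted label set pools the phase-2 annotation
#' classes `HE_AND_PHH3` and `HE_ONLY` *before* clustering (cells the
#' experts called identifiable in H&E at least) and takes the full-panel
#' consensus; `PHH3_ONLY` annotations never contribute support.
#'
#' @param study A `study_dataset`, or a plain annotation tibble covering both
#'   phases (then `mpp` must be given).
#' @param radius_um Clustering radius in microns.
#' @param min_support Full-panel support threshold; defaults to half the
#'   panel minus one rater, rounded up (6 for 13 raters).
#' @param mpp Microns per pixel; taken from the study config when omitted.
#' @return Named list of two label tibbles (`he_only_labels`,
#'   `phh3_assisted_labels`), each `image_id`, `x`, `y`, `support`.
#' @export
derive_label_sets <- function(study, radius_um = 7.5, min_support = NULL,
                              mpp = NULL) {
  if (inherits(study, "study_dataset")) {
    ann <- study$annotations
    mpp <- mpp %||% study$config$mpp
    n_raters <- study$config$n_raters
  } else {
    ann <- study
    if (is.null(mpp)) abort("`mpp` is required when passing a plain annotation table")
    n_raters <- length(unique(ann$rater_id))
  }
  if (is.null(min_support)) min_support <- ceiling(0.5 * (n_raters - 1))

  consensus_of <- function(sub) {
    if (!nrow(sub)) {
      return(tibble::tibble(image_id = character(), x = numeric(),
                            y = numeric(), support = integer()))
    }
    sub |>
      dplyr::group_by(.data$image_id) |>
      dplyr::group_split() |>
      purrr::map(~ build_consensus(cluster_annotations(.x, radius_um, mpp),
                                   min_support)) |>
      dplyr::bind_rows()
  }
  list(
    he_only_labels = consensus_of(ann[ann$study_phase == "P1", ]),
    phh3_assisted_labels = consensus_of(
      ann[ann$study_phase == "P2" & ann$cls %in% c("HE_AND_PHH3", "HE_ONLY"), ])
  )
}

#' Points of one label set that are new relative to another
#'
#' A point is "newly found" if no point of the reference set lies within the
#' matching radius in the same image.
#'
#' @param labels,reference Label tibbles (`image_id`, `x`, `y`).
#' @param radius_um,mpp Matching radius.
#' @return The subset of `labels` that is new.
#' @export
newly_found_points <- function(labels, reference, radius_um = 7.5, mpp = 0.25) {
  radius_px <- um_to_px(radius_um, mpp)
  keep <- purrr::map_lgl(seq_len(nrow(labels)), function(i) {
    ref <- reference[reference$image_id == labels$image_id[i], ]
    if (!nrow(ref)) return(TRUE)
    min(sqrt((ref$x - labels$x[i])^2 + (ref$y - labels$y[i])^2)) > radius_px
  })
  labels[keep, ]
}

#' Clean a PHH3-assisted label set with post-hoc morphology verdicts
#'
#' Removes every newly-found point whose expert panel majority verdict is
#' "not recognizable" in H&E. Points that are already present in the
#' H&E-only label set are never removed. Each newly-found point must carry a
#' panel decision; a missing decision is an error.
#'
#' @param phh3_labels PHH3-assisted label tibble.
#' @param posthoc_decisions Tibble with `image_id`, `x`, `y` and a
#'   list-column `verdicts` of at least three per-expert verdicts, as
#'   produced by [simulate_posthoc_verdicts()].
#' @param he_only_labels H&E-only label tibble (protected points).
#' @param radius_um,mpp Matching radius used to associate decisions and
#'   protected points with label points.
#' @return The cleaned label tibble.
#' @export
clean_label_set <- function(phh3_labels, posthoc_decisions, he_only_labels,
                            radius_um = 7.5, mpp = 0.25) {
  radius_px <- um_to_px(radius_um, mpp)
  new_pts <- newly_found_points(phh3_labels, he_only_labels, radius_um, mpp)
  drop <- rep(FALSE, nrow(phh3_labels))
  for (i in seq_len(nrow(phh3_labels))) {
    # protected: present in the H&E-only set
    is_new <- nrow(new_pts) > 0 && any(
      new_pts$image_id == phh3_labels$image_id[i] &
        abs(new_pts$x - phh3_labels$x[i]) < 1e-9 &
        abs(new_pts$y - phh3_labels$y[i]) < 1e-9)
    if (!is_new) next
    dec <- posthoc_decisions[posthoc_decisions$image_id == phh3_labels$image_id[i], ]
    if (nrow(dec)) {
      d <- sqrt((dec$x - phh3_labels$x[i])^2 + (dec$y - phh3_labels$y[i])^2)
      dec <- dec[d <= radius_px, ]
      if (nrow(dec) > 1) dec <- dec[which.min(d[d <= radius_px]), ]
    }
    if (!nrow(dec)) {
      abort(sprintf("missing post-hoc decision for newly-found point (%s, %.1f, %.1f)",
                    phh3_labels$image_id[i], phh3_labels$x[i], phh3_labels$y[i]))
    }
    v <- dec$verdicts[[1]]
    if (length(v) < 3) abort("each post-hoc decision needs at least three verdicts")
    drop[i] <- sum(v == "not_recognizable") >= ceiling(length(v) / 2)
  }
  phh3_labels[!drop, ]
}
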