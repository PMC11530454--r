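# Inter-rater agreement statistics: object-level matching against
# leave-one-out consensus, intraclass correlation of mitotic counts, Fleiss'
# kappa for categorical verdicts, and the paired significance protocol.

#' Greedy one-to-one matching of two point sets
#'
#' Candidate pairs are all (prediction, reference) pairs within the matching
#' radius; pairs are accepted in ascending distance order (ties broken by
#' prediction index, then reference index), each point matched at most once.
#'
#' @param predictions,references Tibbles with `x`, `y` (pixels), from one
#'   image.
#' @param radius_um Matching radius in microns.
#' @param mpp Microns per pixel.
#' @return A `point_matching` list: `pairs` (tibble `prediction`,
#'   `reference`, `dist_px`), `unmatched_predictions`, `unmatched_references`
#'   (integer indices).
#' @export
match_points <- function(predictions, references, radius_um = 7.5, mpp = 0.25) {
  check_mpp(mpp)
  radius_px <- um_to_px(radius_um, mpp)
  np <- nrow(predictions)
  nr <- nrow(references)
  pairs <- tibble::tibble(prediction = integer(), reference = integer(),
                          dist_px = numeric())
  if (np && nr) {
    d <- outer(predictions$x, references$x, "-")^2 +
      outer(predictions$y, references$y, "-")^2
    d <- sqrt(d)
    cand <- which(d <= radius_px, arr.ind = TRUE)
    if (nrow(cand)) {
      dist <- d[cand]
      ord <- order(dist, cand[, 1], cand[, 2])
      used_p <- logical(np)
      used_r <- logical(nr)
      keep_p <- integer(0)
      keep_r <- integer(0)
      keep_d <- numeric(0)
      for (k in ord) {
        p <- unname(cand[k, 1])
        r <- unname(cand[k, 2])
        if (!used_p[p] && !used_r[r]) {
          used_p[p] <- TRUE
          used_r[r] <- TRUE
          keep_p <- c(keep_p, p)
          keep_r <- c(keep_r, r)
          keep_d <- c(keep_d, dist[k])
        }
      }
      pairs <- tibble::tibble(prediction = keep_p, reference = keep_r,
                              dist_px = keep_d)
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_predictions = setdiff(seq_len(np), pairs$prediction),
    unmatched_references = setdiff(seq_len(nr), pairs$reference)
  ), class = "point_matching")
}

#' Instance-level precision, recall and F1 of a point set against a reference
#'
#' Matched pairs are true positives; unmatched predictions false positives;
#' unmatched references false negatives. The 0/0 convention is 0 for all
#' three metrics. Tables spanning several images are matched per image and
#' pooled.
#'
#' @param predictions,references Point tibbles with `x`, `y` and optionally
#'   `image_id`.
#' @param radius_um,mpp Matching radius.
#' @return Tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
instance_prf <- function(predictions, references, radius_um = 7.5, mpp = 0.25) {
  if (!"image_id" %in% names(predictions)) predictions$image_id <- "image"
  if (!"image_id" %in% names(references)) references$image_id <- "image"
  imgs <- union(unique(predictions$image_id), unique(references$image_id))
  tp <- fp <- fn <- 0L
  for (im in imgs) {
    m <- match_points(predictions[predictions$image_id == im, ],
                      references[references$image_id == im, ],
                      radius_um, mpp)
    tp <- tp + nrow(m$pairs)
    fp <- fp + length(m$unmatched_predictions)
    fn <- fn + length(m$unmatched_references)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1)
}

#' Per-rater leave-one-out agreement for both study phases
#'
#' For every rater and phase, compares the rater's annotations (phase 2:
#' only the classes deemed identifiable in H&E, `HE_AND_PHH3` and `HE_ONLY`)
#' against the consensus of the remaining raters of that phase, pooled over
#' all images.
#'
#' @param study A `study_dataset` or an annotation tibble.
#' @param radius_um,mpp Matching/clustering radius.
#' @param support_fraction Leave-one-out support fraction (0.5 gives 6 of 12
#'   for a 13-rater panel).
#' @return An `agreement_report` tibble: `rater_id`, `study_phase`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
rater_agreement <- function(study, radius_um = 7.5, mpp = NULL,
                            support_fraction = 0.5) {
  ann <- if (inherits(study, "study_dataset")) study$annotations else study
  if (is.null(mpp)) {
    if (!inherits(study, "study_dataset")) abort("`mpp` is required")
    mpp <- study$config$mpp
  }
  raters <- sort(unique(ann$rater_id))
  min_support <- ceiling(support_fraction * (length(raters) - 1))
  rows <- purrr::map(c("P1", "P2"), function(ph) {
    sub <- ann[ann$study_phase == ph, ]
    if (ph == "P2") sub <- sub[sub$cls %in% c("HE_AND_PHH3", "HE_ONLY"), ]
    purrr::map(raters, function(r) {
      loo <- sub[sub$rater_id != r, ] |>
        dplyr::group_by(.data$image_id) |>
        dplyr::group_split() |>
        purrr::map(~ build_consensus(cluster_annotations(.x, radius_um, mpp),
                                     min_support)) |>
        dplyr::bind_rows()
      own <- sub[sub$rater_id == r, ]
      dplyr::bind_cols(
        tibble::tibble(rater_id = r, study_phase = ph),
        instance_prf(own, loo, radius_um, mpp)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("agreement_report", class(rows))
  attr(rows, "radius_um") <- radius_um
  rows
}

#' Mitotic count matrix (images by raters)
#'
#' Counts each rater's annotations per image for one study phase; phase 2
#' counts only the H&E-identifiable classes. Rows are images (targets),
#' columns raters.
#'
#' @param study A `study_dataset` or annotation tibble.
#' @param study_phase `"P1"` or `"P2"`.
#' @return Integer matrix, images x raters.
#' @export
mitotic_count_matrix <- function(study, study_phase) {
  ann <- if (inherits(study, "study_dataset")) study$annotations else study
  imgs <- if (inherits(study, "study_dataset")) study$image_ids else
    sort(unique(ann$image_id))
  sub <- ann[ann$study_phase == study_phase, ]
  if (study_phase == "P2") sub <- sub[sub$cls %in% c("HE_AND_PHH3", "HE_ONLY"), ]
  raters <- sort(unique(ann$rater_id))
  counts <- matrix(0L, length(imgs), length(raters),
                   dimnames = list(imgs, raters))
  tab <- table(factor(sub$image_id, levels = imgs),
               factor(sub$rater_id, levels = raters))
  counts[] <- as.integer(tab)
  counts
}

#' Intraclass correlation for a fixed rater panel (consistency, ICC(3,·))
#'
#' Two-way mixed-effects, consistency definition, from the ANOVA mean
#' squares of the targets-by-raters table: the single-rater reliability is
#' `ICC(3,1) = (MS_T - MS_E) / (MS_T + (k-1) MS_E)` and the average-of-k
#' reliability `ICC(3,k) = (MS_T - MS_E) / MS_T`, which equals the
#' Spearman-Brown adjustment of ICC(3,1) to k raters.
#'
#' @param counts Numeric matrix, n targets x k raters (n, k >= 2).
#' @return An `icc_fit` list: `icc_k`, `icc_1`, `ms_targets`, `ms_error`,
#'   `n`, `k`.
#' @export
icc_avg_fixed_raters <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("ICC needs at least 2 targets and 2 raters")
  }
  if (!all(is.finite(counts))) abort("ICC input must be finite")
  n <- nrow(counts)
  k <- ncol(counts)
  grand <- mean(counts)
  row_m <- rowMeans(counts)
  col_m <- colMeans(counts)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((counts - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_t <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_t <= 0) {
    abort("ICC undefined: no between-target variance in the count matrix")
  }
  icc_k <- (ms_t - ms_e) / ms_t
  icc_1 <- (ms_t - ms_e) / (ms_t + (k - 1) * ms_e)
  structure(list(icc_k = icc_k, icc_1 = icc_1, ms_targets = ms_t,
                 ms_error = ms_e, n = n, k = k), class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(3,%d) = %.4f  [single-rater ICC(3,1) = %.4f; n = %d targets]\n",
              x$k, x$icc_k, x$icc_1, x$n))
  invisible(x)
}

#' Fleiss' kappa for multiple raters and categorical verdicts
#'
#' Standard chance-corrected agreement for a fixed number of raters per
#' subject: `kappa = (Pbar - Pe) / (1 - Pe)`.
#'
#' @param ratings Count matrix, subjects x categories; every row must sum to
#'   the same number of raters (>= 2).
#' @return Kappa (scalar).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  rs <- rowSums(ratings)
  if (length(unique(rs)) != 1) {
    abort("Fleiss' kappa requires the same number of raters for every subject")
  }
  m <- rs[1]
  if (m < 2) abort("Fleiss' kappa needs at least 2 raters per subject")
  n <- nrow(ratings)
  p_j <- colSums(ratings) / (n * m)
  p_i <- (rowSums(ratings^2) - m) / (m * (m - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (1 - p_e <= .Machine$double.eps) {
    abort("Fleiss' kappa undefined: a single category was ever used (Pe = 1)")
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Convert per-subject categorical verdicts to a Fleiss count matrix
#'
#' @param verdicts List of character vectors (one per subject), all of the
#'   same length.
#' @return Count matrix, subjects x categories.
#' @export
verdicts_to_counts <- function(verdicts) {
  cats <- sort(unique(unlist(verdicts)))
  t(vapply(verdicts, function(v) {
    as.integer(table(factor(v, levels = cats)))
  }, integer(length(cats))))
}

#' Paired significance test between two metric vectors
#'
#' Paired t-test on the phase differences with k - 1 degrees of freedom,
#' normality of the differences checked by a Shapiro-Wilk test, and the
#' significance level Bonferroni-corrected by the number of metrics tested.
#' Identical vectors (zero-variance differences) yield an explicit undefined
#' result rather than a statistic.
#'
#' @param values_p1,values_p2 Numeric vectors of equal length k (one value
#'   per rater).
#' @param n_tests Number of metrics tested in the family (Bonferroni
#'   divisor).
#' @param alpha Family-wise significance level.
#' @return A `paired_metric_test` list: `t`, `df`, `p_value`, `shapiro_p`,
#'   `alpha_adjusted`, `significant`, `mean_diff`, `note`.
#' @export
paired_metric_test <- function(values_p1, values_p2, n_tests = 1, alpha = 0.05) {
  if (length(values_p1) != length(values_p2)) {
    abort("paired test needs vectors of equal length")
  }
  k <- length(values_p1)
  if (k < 3) abort("need at least 3 pairs")
  d <- values_p2 - values_p1
  alpha_adj <- alpha / n_tests
  if (sd(d) < .Machine$double.eps) {
    out <- list(t = NA_real_, df = k - 1L, p_value = NA_real_,
                shapiro_p = NA_real_, alpha_adjusted = alpha_adj,
                significant = FALSE, mean_diff = mean(d),
                note = "differences have zero variance; t undefined")
    return(structure(out, class = "paired_metric_test"))
  }
  tt <- t.test(values_p1, values_p2, paired = TRUE)
  sw <- shapiro.test(d)
  structure(list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, shapiro_p = sw$p.value,
    alpha_adjusted = alpha_adj,
    significant = tt$p.value < alpha_adj,
    mean_diff = mean(d), note = NA_character_
  ), class = "paired_metric_test")
}

#' @export
print.paired_metric_test <- function(x, ...) {
  if (is.na(x$t)) {
    cat(sprintf("paired t-test: undefined (%s)\n", x$note))
  } else {
    cat(sprintf("paired t-test: t(%d) = %.3f, p = %.3g (Shapiro-Wilk p = %.3g, alpha* = %.3g)%s\n",
                x$df, x$t, x$p_value, x$shapiro_p, x$alpha_adjusted,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}
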