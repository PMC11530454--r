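# Visualization and tidier methods.

#' @exportS3Method ggplot2::autoplot
autoplot.image_pair <- function(object, stain = c("he", "phh3"), ...) {
  stain <- match.arg(stain)
  img <- object[[stain]]
  d <- dim(img)
  df <- tidyr::expand_grid(y = seq_len(d[1]) - 1, x = seq_len(d[2]) - 1)
  df$fill <- grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s)", object$image_id, toupper(stain)),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
autoplot.agreement_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$study_phase, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6,
                         ggplot2::aes(color = .data$rater_id)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "study phase", y = "value",
                  title = "Per-rater agreement with the leave-one-out consensus") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.result_grid <- function(object, ...) {
  summ <- glance(object)
  ggplot2::ggplot(summ, ggplot2::aes(.data$eval_labels, .data$mean_ap,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ap - .data$sd_ap,
                                        ymax = .data$mean_ap + .data$sd_ap),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2) +
    ggplot2::facet_wrap(~train_labels) +
    ggplot2::labs(x = "evaluation label set", y = "average precision",
                  title = "Cross-validated AP by training and evaluation label set") +
    ggplot2::theme_minimal()
}

#' Plot a projected embedding set with TP/FN coloring and density regions
#'
#' One panel per mitotic phase group; the same projected coordinates appear
#' in every panel, only membership and coloring differ. The 75% regions of
#' the detected and missed populations are outlined.
#'
#' @param embedding_set Projected `embedding_set`.
#' @param flags Logical per-cell detection flags (TRUE = detected).
#' @param cells Cell tibble aligned with `flags`.
#' @return A ggplot object.
#' @export
plot_latent_map <- function(embedding_set, flags, cells) {
  meta <- embedding_set$meta
  proj <- embedding_set$projection
  detected <- flags[match(meta$cell_id, cells$cell_id)]
  df <- tibble::tibble(umap1 = proj[, 1], umap2 = proj[, 2],
                       phase_group = meta$phase_group,
                       status = ifelse(detected, "TP", "FN"))
  df <- df[!is.na(df$phase_group), ]
  regs <- list()
  for (grp in levels(df$phase_group)) {
    for (st in c("TP", "FN")) {
      sel <- df$phase_group == grp & df$status == st
      if (sum(sel) < 3) next
      reg <- quartile_region(cbind(df$umap1[sel], df$umap2[sel]))
      if (nrow(reg$polygons) > 1) {
        regs[[length(regs) + 1L]] <- dplyr::mutate(reg$polygons,
                                                   phase_group = grp, status = st)
      }
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2,
                                        color = .data$status)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::facet_wrap(~phase_group) +
    ggplot2::scale_color_manual(values = c(TP = "#e08214", FN = "#2166ac")) +
    ggplot2::labs(title = "Latent space of the mapping network",
                  color = NULL) +
    ggplot2::theme_minimal()
  if (length(regs)) {
    rdf <- dplyr::bind_rows(regs)
    p <- p + ggplot2::geom_path(
      data = rdf, ggplot2::aes(.data$x, .data$y, group = .data$piece,
                               color = .data$status), linewidth = 0.7)
  }
  p
}

# --- broom-style methods ---------------------------------------------------

#' @exportS3Method generics::tidy
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(term = c("icc_avg_k", "icc_single"),
                 estimate = c(x$icc_k, x$icc_1),
                 ms_targets = x$ms_targets, ms_error = x$ms_error,
                 n_targets = x$n, k_raters = x$k)
}

#' @exportS3Method generics::glance
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc_k = x$icc_k, icc_1 = x$icc_1, n_targets = x$n,
                 k_raters = x$k)
}

#' @exportS3Method generics::tidy
tidy.paired_metric_test <- function(x, ...) {
  tibble::tibble(statistic = x$t, df = x$df, p_value = x$p_value,
                 shapiro_p = x$shapiro_p, alpha_adjusted = x$alpha_adjusted,
                 significant = x$significant, mean_diff = x$mean_diff)
}

#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$study_phase),
    dplyr::across(c("precision", "recall", "f1"),
                  list(mean = mean, sd = stats::sd)),
    .groups = "drop")
}

#' @exportS3Method generics::glance
glance.result_grid <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$model, .data$train_labels,
                    .data$eval_labels),
    mean_ap = mean(.data$ap), sd_ap = stats::sd(.data$ap), n = dplyr::n(),
    .groups = "drop")
}

#' @exportS3Method generics::tidy
tidy.eval_result <- function(x, ...) {
  tibble::tibble(ap = x$ap, tp = x$tp, fp = x$fp, fn = x$fn,
                 radius_um = x$radius_um)
}
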