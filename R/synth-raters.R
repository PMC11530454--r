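#' Simulate one rater annotating one image
#'
#' Applies a rater profile to the ground-truth cells of an image pair. In
#' phase `"P1"` (H&E only) every H&E-visible mitotic figure is annotated with
#' the rater's phase-wise sensitivity and lookalikes with the false-positive
#' rate; all annotations carry class `MF`. In phase `"P2"` (PHH3-assisted)
#' H&E-visible figures are annotated with the maximum of H&E and PHH3
#' sensitivity and classed `HE_AND_PHH3` (or `HE_ONLY` if the PHH3 signal is
#' absent, as for some telophases); mismatch cells are found via the marker
#' with probability `phh3_sensitivity` and classed `PHH3_ONLY`, except that
#' with probability `hindsight_bias` the rater upgrades them to
#' `HE_AND_PHH3` (the hindsight-bias mechanism); lookalikes are annotated at
#' a suppressed false-positive rate (they carry no marker signal) and
#' classed `HE_ONLY`. Every annotation position is the cell position in H&E
#' coordinates plus isotropic Gaussian jitter.
#'
#' The morphology decision is a soft threshold on the cell's latent
#' distinctness: a rater with marginal sensitivity `s` accepts a figure of
#' distinctness `d` with probability
#' `clamp((d - (1 - s) + tau/2) / tau, 0, 1)` where `tau` is the profile's
#' `cutoff_softness`. Over the uniform distinctness distribution the
#' marginal detection probability is exactly `s`, while raters largely agree
#' on which individual figures they accept — the shared-cutoff behaviour
#' that makes consensus membership track how distinct a figure really is.
#' Marker-driven decisions (the PHH3 screening path) do not depend on
#' distinctness.
#'
#' @param image_pair An `image_pair` (only its `cells`, `mpp` and image size
#'   are used), or a plain list with those fields.
#' @param profile One-row [rater_profiles()] tibble.
#' @param study_phase `"P1"` or `"P2"`.
#' @param seed Seed for this rater/image/phase stream.
#' @return Annotation tibble: `image_id`, `rater_id`, `study_phase`, `x`,
#'   `y`, `cls`.
#' @export
simulate_rater <- function(image_pair, profile, study_phase, seed = 1L) {
  if (!study_phase %in% c("P1", "P2")) {
    abort("`study_phase` must be \"P1\" or \"P2\".")
  }
  stopifnot(nrow(profile) == 1)
  cells <- image_pair$cells
  mpp <- image_pair$mpp
  size <- if (!is.null(image_pair$he)) dim(image_pair$he)[1] else
    attr(cells, "image_size_px") %||% Inf
  sens <- profile$sensitivity_by_phase[[1]]
  jitter_px <- um_to_px(profile$jitter_sd_um, mpp)
  tau <- if ("cutoff_softness" %in% names(profile)) profile$cutoff_softness else 0.5
  fp_non <- if ("fp_rate_nonmitotic" %in% names(profile)) profile$fp_rate_nonmitotic else 0
  d <- if ("he_distinctness" %in% names(cells)) cells$he_distinctness else
    rep(1, nrow(cells))
  # soft cutoff on distinctness with exact marginal s over d ~ U(0, 1)
  morph_p <- function(s, dd) {
    out <- pmin(pmax((dd - (1 - s) + tau / 2) / tau, 0), 1)
    out[s >= 1] <- 1
    out[s <= 0] <- 0
    out
  }

  with_seed(seed, {
    u <- runif(nrow(cells))
    ann_idx <- integer(0)
    cls <- character(0)
    if (study_phase == "P1") {
      p_take <- numeric(nrow(cells))
      vis <- cells$is_mf & cells$he_visible
      p_take[vis] <- morph_p(sens[cells$phase[vis]], d[vis])
      look <- cells$phase == "lookalike"
      p_take[look] <- morph_p(rep(profile$fp_rate_lookalike, sum(look)), d[look])
      p_take[cells$phase == "nonmitotic"] <- fp_non
      ann_idx <- which(u < p_take)
      cls <- rep("MF", length(ann_idx))
    } else {
      p_take <- numeric(nrow(cells))
      mf_vis <- cells$is_mf & cells$he_visible
      mismatch <- cells$phh3_positive & !cells$he_visible
      both <- mf_vis & cells$phh3_positive
      p_take[both] <- pmax(morph_p(sens[cells$phase[both]], d[both]),
                           profile$phh3_sensitivity)
      he_only <- mf_vis & !cells$phh3_positive
      p_take[he_only] <- morph_p(sens[cells$phase[he_only]], d[he_only])
      p_take[mismatch] <- profile$phh3_sensitivity
      look <- cells$phase == "lookalike"
      p_take[look] <- morph_p(
        rep(profile$fp_rate_lookalike * profile$phh3_fp_suppression, sum(look)),
        d[look])
      p_take[cells$phase == "nonmitotic"] <- fp_non * profile$phh3_fp_suppression
      ann_idx <- which(u < p_take)
      cls <- character(length(ann_idx))
      for (j in seq_along(ann_idx)) {
        i <- ann_idx[j]
        if (mismatch[i]) {
          cls[j] <- if (runif(1) < profile$hindsight_bias) "HE_AND_PHH3" else "PHH3_ONLY"
        } else if (cells$phase[i] %in% c("lookalike", "nonmitotic")) {
          cls[j] <- "HE_ONLY"
        } else if (cells$phh3_positive[i]) {
          cls[j] <- "HE_AND_PHH3"
        } else {
          cls[j] <- "HE_ONLY"
        }
      }
    }
    n <- length(ann_idx)
    x <- cells$x[ann_idx] + rnorm(n, 0, jitter_px)
    y <- cells$y[ann_idx] + rnorm(n, 0, jitter_px)
    if (is.finite(size)) {
      x <- pmin(pmax(x, 0), size - 1)
      y <- pmin(pmax(y, 0), size - 1)
    }
    tibble::tibble(
      image_id = rep(if (nrow(cells)) cells$image_id[1] else "image", n),
      rater_id = rep(profile$rater_id, n),
      study_phase = rep(study_phase, n),
      x = x, y = y, cls = cls
    )
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Simulate the full two-phase multi-expert annotation study
#'
#' Generates the cell populations for all images and simulates every rater
#' annotating every image in both study phases. The washout period between
#' phases is modeled as independent random substreams per (image, phase,
#' rater): a rater retains no memory of phase one.
#'
#' @param config A [study_config()].
#' @param profiles A [rater_profiles()] tibble with `config$n_raters` rows.
#' @return A `study_dataset`: list with `config`, `profiles`, `cells` (ground
#'   truth for all images), `annotations` (all raters, both phases) and
#'   `image_ids`.
#' @export
generate_study <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(profiles)) {
    profiles <- rater_profiles(config$n_raters, seed = config$rng_seed)
  }
  if (nrow(profiles) != config$n_raters) {
    abort(sprintf("profile count (%d) must equal config$n_raters (%d)",
                  nrow(profiles), config$n_raters))
  }
  image_ids <- sprintf("img_%03d", seq_len(config$n_images))
  cells <- purrr::map(image_ids, function(id) {
    cc <- generate_cell_population(config, id)
    attr(cc, "image_size_px") <- config$image_size_px
    cc
  })
  names(cells) <- image_ids
  all_cells <- dplyr::bind_rows(cells)

  ann <- purrr::map(image_ids, function(id) {
    fake_pair <- list(cells = cells[[id]], mpp = config$mpp)
    purrr::map(c("P1", "P2"), function(ph) {
      purrr::map(seq_len(nrow(profiles)), function(r) {
        simulate_rater(
          fake_pair, profiles[r, ], ph,
          seed = derive_seed(config$rng_seed, c("ann", id, ph, profiles$rater_id[r]))
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(list(config = config, profiles = profiles, cells = all_cells,
                 annotations = ann, image_ids = image_ids),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d images, %d raters, %d cells, %d annotations\n",
              length(x$image_ids), nrow(x$profiles), nrow(x$cells),
              nrow(x$annotations)))
  invisible(x)
}

#' Render one image of a study dataset on demand
#'
#' Images are rendered lazily from the stored ground truth so that large
#' studies never hold all rasters in memory at once. Rendering is
#' deterministic: the same `image_id` always yields the same pixels.
#'
#' @param study A `study_dataset`.
#' @param image_id One of `study$image_ids`.
#' @return An `image_pair`.
#' @export
render_study_image <- function(study, image_id) {
  stopifnot(inherits(study, "study_dataset"))
  cells <- dplyr::filter(study$cells, .data$image_id == !!image_id)
  render_image_pair(cells, study$config, image_id = image_id)
}

#' Simulate the post-hoc morphology re-assessment panel
#'
#' Emulates the blinded three-expert re-evaluation of consensus points that
#' were newly found under PHH3 assistance: each expert judges from H&E
#' morphology alone whether the cell is recognizable as a mitotic figure.
#' Each point is attributed to its nearest ground-truth cell; the true
#' verdict is "recognizable" iff that cell is H&E-visible, and each expert
#' reports the truth independently with probability `accuracy` (1 gives the
#' truthful oracle).
#'
#' @param study A `study_dataset`.
#' @param points Tibble of newly-found consensus points (`image_id`, `x`, `y`).
#' @param n_experts Panel size.
#' @param accuracy Per-expert probability of reporting the true morphology
#'   class.
#' @param seed Random seed.
#' @return `points` with a list-column `verdicts` of per-expert verdicts
#'   (`"recognizable"` / `"not_recognizable"`).
#' @export
simulate_posthoc_verdicts <- function(study, points, n_experts = 3,
                                      accuracy = 0.75, seed = 1L) {
  stopifnot(inherits(study, "study_dataset"))
  if (!nrow(points)) {
    points$verdicts <- list()
    return(points)
  }
  truth <- purrr::map_chr(seq_len(nrow(points)), function(i) {
    cc <- dplyr::filter(study$cells, .data$image_id == points$image_id[i])
    d2 <- (cc$x - points$x[i])^2 + (cc$y - points$y[i])^2
    if (cc$he_visible[which.min(d2)]) "recognizable" else "not_recognizable"
  })
  with_seed(derive_seed(seed, "posthoc"), {
    points$verdicts <- purrr::map(truth, function(tv) {
      flip <- runif(n_experts) >= accuracy
      other <- setdiff(c("recognizable", "not_recognizable"), tv)
      ifelse(flip, other, tv)
    })
  })
  points
}
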