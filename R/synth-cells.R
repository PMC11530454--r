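#' Generate the ground-truth cell population of one image
#'
#' Places mitotic figures, ordinary nuclei, and mitotic-figure lookalikes
#' uniformly at random with a minimum pairwise separation of one nucleus
#' diameter, then assigns each cell its mitotic phase, H&E-morphology
#' visibility and PHH3 signal according to the configured phase mixture and
#' mismatch fraction. Mismatch cells (PHH3-positive but not H&E-visible) can
#' only arise among pro-/prometaphase figures; telophase figures may lack the
#' PHH3 signal; lookalikes and non-mitotic nuclei are always PHH3-negative.
#'
#' @param config A [study_config()].
#' @param image_id Image identifier (also salts the random stream, so each
#'   image has an independent, reproducible population).
#' @return Tibble with columns `cell_id`, `image_id`, `x`, `y` (pixels,
#'   0-based, x rightwards, y downwards), `phase`, `is_mf`, `he_visible`,
#'   `he_distinctness` (latent morphological distinctness in \[0, 1\] for
#'   H&E-visible figures and lookalikes: it scales the rendered chromatin
#'   contrast and is the quantity rater cutoffs act on), `phh3_positive`,
#'   `phh3_intensity`.
#' @export
generate_cell_population <- function(config, image_id) {
  stopifnot(inherits(config, "study_config"))
  with_seed(derive_seed(config$rng_seed, c("cells", image_id)), {
    n_mit <- rpois(1, config$mitotic_per_image)
    n_non <- rpois(1, config$nonmitotic_per_image)
    n_look <- rpois(1, config$lookalike_per_image)
    n <- n_mit + n_non + n_look

    pos <- place_points_min_sep(
      n = n,
      size = config$image_size_px,
      min_sep_px = um_to_px(config$min_separation_um, config$mpp),
      margin_px = um_to_px(config$min_separation_um, config$mpp) / 2
    )

    phase <- c(
      sample(MITOTIC_PHASES, n_mit, replace = TRUE, prob = config$phase_mix),
      rep("nonmitotic", n_non),
      rep("lookalike", n_look)
    )
    is_mf <- phase %in% MITOTIC_PHASES

    phh3_positive <- is_mf
    telo <- which(phase == "telophase")
    if (length(telo)) {
      phh3_positive[telo] <- runif(length(telo)) < config$telophase_phh3_rate
    }

    he_visible <- phase != "nonmitotic"
    pp <- which(phase %in% c("prophase", "prometaphase") & phh3_positive)
    if (length(pp)) {
      he_visible[pp] <- runif(length(pp)) >= config$mismatch_fraction
    }

    phh3_intensity <- ifelse(phh3_positive, runif(n, 0.6, 1), 0)

    # latent morphological distinctness: how clearly the figure (or mimic)
    # stands out in H&E; 0 for objects with no mitotic morphology
    he_distinctness <- numeric(n)
    vis <- he_visible & phase != "nonmitotic"
    he_distinctness[vis] <- runif(sum(vis))

    tibble::tibble(
      cell_id = sprintf("%s_c%03d", image_id, seq_len(n)),
      image_id = image_id,
      x = pos[, 1],
      y = pos[, 2],
      phase = phase,
      is_mf = is_mf,
      he_visible = he_visible,
      he_distinctness = he_distinctness,
      phh3_positive = phh3_positive,
      phh3_intensity = phh3_intensity
    )
  })
}

# Dart-throwing placement with a minimum pairwise separation. Errors with the
# name of the violated constraint when the image cannot host the population.
place_points_min_sep <- function(n, size, min_sep_px, margin_px = 0) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  lo <- margin_px
  hi <- size - 1 - margin_px
  if (hi <= lo) abort("image too small for the configured cell margin")
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 400L * n
  min_sep2 <- min_sep_px^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(paste0(
        "placement failed: could not place %d cells at minimum separation ",
        "%.1f px in a %d px image (placed %d)"), n, min_sep_px, size, placed))
    }
    px <- runif(1, lo, hi)
    py <- runif(1, lo, hi)
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2
      if (min(d2) < min_sep2) next
    }
    placed <- placed + 1L
    xs[placed] <- px
    ys[placed] <- py
  }
  cbind(xs, ys)
}
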