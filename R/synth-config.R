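#' Configuration of a synthetic dual-stain annotation study
#'
#' Bundles every tunable of the synthetic data generator: image geometry,
#' cellularity, the mitotic-phase mixture, the information-mismatch rate, and
#' the rater-panel size. The defaults encode the study conditions of the
#' multi-expert experiment the package emulates: 13 raters, 20 regions of
#' interest, a 48/37/15 split of pro-/prometaphase, metaphase and
#' ana-/telophase among mitotic figures, and a mismatch fraction of 0.56
#' (the share of pro-/prometaphase cells that carry a PHH3 signal but no
#' recognizable H&E morphology, 172 of 308 at study scale).
#'
#' @param n_images Number of regions of interest to simulate.
#' @param image_size_px Side length of the square images, in pixels.
#' @param mpp Microns per pixel (0.25 corresponds to a typical 40x scan).
#' @param mitotic_per_image Expected number of true mitotic figures per image
#'   (Poisson distributed).
#' @param nonmitotic_per_image Expected number of ordinary (non-mitotic)
#'   nuclei per image.
#' @param lookalike_per_image Expected number of mitotic-figure lookalikes
#'   (H&E-visible mimics without PHH3 signal) per image.
#' @param phase_mix Named probability vector over the five mitotic phases;
#'   must sum to 1.
#' @param mismatch_fraction Fraction of pro-/prometaphase cells that are
#'   PHH3-positive but not H&E-visible (the mismatch mechanism).
#' @param telophase_phh3_rate Probability that a telophase figure carries a
#'   PHH3 signal (the marker is less sensitive to late phases).
#' @param min_separation_um Minimum pairwise distance between cell centers,
#'   in microns. Matches the nucleus-diameter clustering radius so distinct
#'   cells can never be merged by consensus clustering.
#' @param max_deformation_um Upper bound on the residual registration
#'   displacement between the two stains, in microns.
#' @param n_raters Size of the simulated expert panel.
#' @param rng_seed Base seed; every random stream of the generator is derived
#'   deterministically from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_images = 20,
                         image_size_px = 512,
                         mpp = 0.25,
                         mitotic_per_image = 32,
                         nonmitotic_per_image = 80,
                         lookalike_per_image = 12,
                         phase_mix = c(prophase = 0.24, prometaphase = 0.24,
                                       metaphase = 0.37, anaphase = 0.06,
                                       telophase = 0.09),
                         mismatch_fraction = 0.56,
                         telophase_phh3_rate = 0.7,
                         min_separation_um = 7.5,
                         max_deformation_um = 1.0,
                         n_raters = 13,
                         rng_seed = 1L) {
  check_mpp(mpp)
  stopifnot_scalar_number(mismatch_fraction, "mismatch_fraction", 0, 1)
  stopifnot_scalar_number(telophase_phh3_rate, "telophase_phh3_rate", 0, 1)
  stopifnot_scalar_number(min_separation_um, "min_separation_um", 0)
  stopifnot_scalar_number(max_deformation_um, "max_deformation_um", 0)
  if (!setequal(names(phase_mix), MITOTIC_PHASES)) {
    abort("`phase_mix` must be named with exactly the five mitotic phases.")
  }
  phase_mix <- phase_mix[MITOTIC_PHASES]
  if (any(phase_mix < 0) || abs(sum(phase_mix) - 1) > 1e-8) {
    abort("`phase_mix` must be non-negative and sum to 1.")
  }
  structure(list(
    n_images = as.integer(n_images),
    image_size_px = as.integer(image_size_px),
    mpp = mpp,
    mitotic_per_image = mitotic_per_image,
    nonmitotic_per_image = nonmitotic_per_image,
    lookalike_per_image = lookalike_per_image,
    phase_mix = phase_mix,
    mismatch_fraction = mismatch_fraction,
    telophase_phh3_rate = telophase_phh3_rate,
    min_separation_um = min_separation_um,
    max_deformation_um = max_deformation_um,
    n_raters = as.integer(n_raters),
    rng_seed = as.integer(rng_seed)
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  %d images of %d px (%.2f um/px), %d raters\n",
              x$n_images, x$image_size_px, x$mpp, x$n_raters))
  cat(sprintf("  ~%.0f mitotic / %.0f nonmitotic / %.0f lookalike cells per image\n",
              x$mitotic_per_image, x$nonmitotic_per_image, x$lookalike_per_image))
  cat(sprintf("  mismatch fraction %.2f, telophase PHH3 rate %.2f, seed %d\n",
              x$mismatch_fraction, x$telophase_phh3_rate, x$rng_seed))
  invisible(x)
}

#' Simulated expert panel profiles
#'
#' Draws per-rater annotation behaviour parameters around field-realistic
#' centres: moderate and phase-dependent H&E sensitivity (lowest for
#' prophase, highest for telophase), near-perfect screening sensitivity when
#' the PHH3 overlay is available, a non-trivial lookalike false-positive
#' rate, sub-nucleus localization jitter, and a hindsight-bias probability of
#' calling a morphology-free PHH3-positive cell H&E-identifiable once the
#' marker has been seen. Rater-to-rater spread in these internal cutoffs is
#' what produces the dispersion of per-rater precision/recall.
#'
#' @param n_raters Number of raters.
#' @param seed Seed for the per-rater parameter draws.
#' @param base_sensitivity Named vector of phase-wise H&E detection
#'   probabilities around which raters vary.
#' @param phh3_sensitivity Detection probability for PHH3-positive cells when
#'   the overlay is available.
#' @param fp_rate_lookalike Probability of annotating a lookalike in the
#'   H&E-only phase (a shared-object confusion: convincing mimics fool many
#'   raters and can reach consensus).
#' @param fp_rate_nonmitotic Probability of annotating an ordinary nucleus
#'   (idiosyncratic per rater and cell: such marks are personal errors and
#'   essentially never reach consensus).
#' @param phh3_fp_suppression Multiplier on the lookalike false-positive rate
#'   when the PHH3 overlay is available (lookalikes carry no signal).
#' @param jitter_sd_um Standard deviation of isotropic localization noise,
#'   in microns.
#' @param hindsight_bias Probability that a mismatch cell, once seen in
#'   PHH3, is labeled as identifiable in both stains.
#' @param cutoff_softness Width of the soft morphology cutoff on the latent
#'   distinctness scale (small values make a rater nearly deterministic
#'   given a cell's distinctness; 1 approaches independent per-cell noise).
#' @param spread Half-width of the uniform per-rater perturbation applied to
#'   the sensitivity and false-positive parameters.
#' @return A tibble with one row per rater (`rater_profiles` class), with a
#'   list-column `sensitivity_by_phase`.
#' @export
rater_profiles <- function(n_raters = 13,
                           seed = 1L,
                           base_sensitivity = c(prophase = 0.25,
                                                prometaphase = 0.35,
                                                metaphase = 0.52,
                                                anaphase = 0.48,
                                                telophase = 0.58),
                           phh3_sensitivity = 0.95,
                           fp_rate_lookalike = 0.25,
                           fp_rate_nonmitotic = 0.12,
                           phh3_fp_suppression = 0.3,
                           jitter_sd_um = 1.0,
                           hindsight_bias = 0.65,
                           cutoff_softness = 0.5,
                           spread = 0.25) {
  if (!setequal(names(base_sensitivity), MITOTIC_PHASES)) {
    abort("`base_sensitivity` must be named with the five mitotic phases.")
  }
  base_sensitivity <- base_sensitivity[MITOTIC_PHASES]
  with_seed(derive_seed(seed, "rater_profiles"), {
    profs <- purrr::map(seq_len(n_raters), function(r) {
      shift <- runif(1, -spread, spread)
      sens <- pmin(pmax(base_sensitivity + shift +
                          runif(5, -spread / 2, spread / 2), 0), 1)
      tibble::tibble(
        rater_id = sprintf("rater_%02d", r),
        sensitivity_by_phase = list(sens),
        phh3_sensitivity = min(max(phh3_sensitivity + runif(1, -0.04, 0.04), 0), 1),
        fp_rate_lookalike = min(max(fp_rate_lookalike + runif(1, -spread, spread), 0), 1),
        fp_rate_nonmitotic = min(max(fp_rate_nonmitotic + runif(1, -0.06, 0.06), 0), 1),
        phh3_fp_suppression = phh3_fp_suppression,
        jitter_sd_um = max(jitter_sd_um + runif(1, -0.3, 0.3), 0),
        hindsight_bias = min(max(hindsight_bias + runif(1, -0.15, 0.15), 0), 1),
        cutoff_softness = cutoff_softness
      )
    })
    out <- dplyr::bind_rows(profs)
    class(out) <- c("rater_profiles", class(out))
    out
  })
}

#' A single fully specified rater profile
#'
#' Convenience constructor for deterministic rater behaviour in tests and
#' examples (for instance a perfect rater: all sensitivities 1, no false
#' positives, no jitter).
#'
#' @param rater_id Identifier.
#' @param sensitivity Either a single probability applied to all five phases
#'   or a named vector over the phases.
#' @param phh3_sensitivity,fp_rate_lookalike,fp_rate_nonmitotic,phh3_fp_suppression,jitter_sd_um,hindsight_bias,cutoff_softness
#'   See [rater_profiles()].
#' @return One-row `rater_profiles` tibble.
#' @export
rater_profile <- function(rater_id = "rater_01",
                          sensitivity = 1,
                          phh3_sensitivity = 1,
                          fp_rate_lookalike = 0,
                          fp_rate_nonmitotic = 0,
                          phh3_fp_suppression = 1,
                          jitter_sd_um = 0,
                          hindsight_bias = 0,
                          cutoff_softness = 0.5) {
  if (length(sensitivity) == 1) {
    sensitivity <- stats::setNames(rep(sensitivity, 5), MITOTIC_PHASES)
  }
  if (!setequal(names(sensitivity), MITOTIC_PHASES)) {
    abort("`sensitivity` must be a scalar or named over the five mitotic phases.")
  }
  if (any(sensitivity < 0 | sensitivity > 1)) abort("sensitivities must be in [0, 1].")
  out <- tibble::tibble(
    rater_id = rater_id,
    sensitivity_by_phase = list(sensitivity[MITOTIC_PHASES]),
    phh3_sensitivity = phh3_sensitivity,
    fp_rate_lookalike = fp_rate_lookalike,
    fp_rate_nonmitotic = fp_rate_nonmitotic,
    phh3_fp_suppression = phh3_fp_suppression,
    jitter_sd_um = jitter_sd_um,
    hindsight_bias = hindsight_bias,
    cutoff_softness = cutoff_softness
  )
  class(out) <- c("rater_profiles", class(out))
  out
}
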