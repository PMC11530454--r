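# Shared constants and small helpers.

MITOTIC_PHASES <- c("prophase", "prometaphase", "metaphase", "anaphase", "telophase")
ALL_PHASES <- c(MITOTIC_PHASES, "lookalike", "nonmitotic")
ANNOTATION_CLASSES <- c("MF", "HE_AND_PHH3", "HE_ONLY", "PHH3_ONLY")
PHASE_GROUPS <- c("pro/prometaphase", "metaphase", "ana/telophase")

#' Group mitotic phases as reported in phase-resolved analyses
#'
#' Collapses the five mitotic phases into the three groups used throughout the
#' latent-space analysis: pro/prometaphase, metaphase, and ana/telophase.
#'
#' @param phase Character vector of phase names.
#' @return Factor with levels `"pro/prometaphase"`, `"metaphase"`,
#'   `"ana/telophase"` (`NA` for non-mitotic phases).
#' @export
phase_group <- function(phase) {
  out <- rep(NA_character_, length(phase))
  out[phase %in% c("prophase", "prometaphase")] <- "pro/prometaphase"
  out[phase == "metaphase"] <- "metaphase"
  out[phase %in% c("anaphase", "telophase")] <- "ana/telophase"
  factor(out, levels = PHASE_GROUPS)
}

# Deterministic 32-bit sub-seed derived from a base seed and a string key.
# Keeps every random stream in the package attributable to (seed, purpose).
derive_seed <- function(seed, key) {
  codes <- utf8ToInt(paste0(key, collapse = "/"))
  h <- as.double(seed %% 2147483647L)
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].", name, min, max))
  }
  invisible(x)
}

check_mpp <- function(mpp) {
  if (!is.numeric(mpp) || length(mpp) != 1 || !is.finite(mpp) || mpp <= 0) {
    abort("`mpp` (microns per pixel) must be a single positive number.")
  }
  invisible(mpp)
}

um_to_px <- function(um, mpp) um / mpp
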