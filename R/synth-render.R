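# Stylized rendering of co-registered H&E / PHH3 image pairs.
#
# The rendering is deliberately schematic (disc nuclei plus condensed
# chromatin glyphs), not photorealistic: the mechanism under study is
# informational. The binding contract is that a mismatch cell (PHH3-positive,
# not H&E-visible) is rendered in the H&E raster by exactly the same routine
# as a non-mitotic nucleus, so no detector can tell them apart from H&E
# pixels alone.

HE_BG <- c(0.92, 0.80, 0.86)
HE_NUCLEUS <- c(0.46, 0.36, 0.62)
HE_CHROMATIN <- c(0.20, 0.12, 0.35)
HE_LOOKALIKE <- c(0.28, 0.18, 0.42)
PHH3_BG <- c(0.93, 0.90, 0.87)
PHH3_NUCLEUS <- c(0.72, 0.70, 0.82)
PHH3_DAB <- c(0.42, 0.24, 0.08)

#' Render a co-registered H&E / PHH3 image pair
#'
#' Produces the two RGB rasters for a cell population. The H&E raster shows
#' an eosin-like background with hematoxylin-like nuclei for every cell and a
#' distinct condensed-chromatin glyph only where `he_visible` is set; the
#' PHH3 raster shows a faint counterstain plus brown diaminobenzidine blobs
#' of the configured intensity wherever `phh3_positive` is set, displaced by
#' a smooth residual-registration deformation field bounded by
#' `max_deformation_um`.
#'
#' @param cells Cell tibble from [generate_cell_population()].
#' @param config The [study_config()] used to generate the cells.
#' @param image_id Image identifier; defaults to the one stored in `cells`.
#' @param deformation Optional deformation parameters (as produced by
#'   `make_deformation()`); by default derived deterministically from the
#'   config seed and image id. Use `max_deformation_um = 0` in the config to
#'   disable deformation.
#' @return An `image_pair` object: list with `he` and `phh3` arrays
#'   (`size x size x 3`, values in \[0, 1\]), `mpp`, `cells`, `image_id`,
#'   and the `deformation` parameters.
#' @export
render_image_pair <- function(cells, config, image_id = NULL, deformation = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(image_id)) {
    image_id <- if (nrow(cells)) cells$image_id[[1]] else "image"
  }
  size <- config$image_size_px
  if (nrow(cells) && (any(cells$x < 0 | cells$x > size - 1) ||
                      any(cells$y < 0 | cells$y > size - 1))) {
    abort("cells must lie within the image bounds")
  }
  if (is.null(deformation)) {
    deformation <- make_deformation(
      max_px = um_to_px(config$max_deformation_um, config$mpp),
      size = size,
      seed = derive_seed(config$rng_seed, c("deform", image_id))
    )
  }
  r_nuc <- um_to_px(config$min_separation_um, config$mpp) / 2

  he <- flat_image(size, HE_BG,
                   seed = derive_seed(config$rng_seed, c("he_bg", image_id)))
  phh3 <- flat_image(size, PHH3_BG,
                     seed = derive_seed(config$rng_seed, c("phh3_bg", image_id)))

  he_spec <- list()
  ph_spec <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    ang <- glyph_angle(config$rng_seed, cell$cell_id)
    he_spec[[i]] <- he_cell_spec(cell, r_nuc, ang)
    d <- apply_deformation(deformation, cell$x, cell$y)
    ph <- ellipse_spec(d[1], d[2], r_nuc * 0.9, r_nuc * 0.9, 0, PHH3_NUCLEUS, 0.5)
    if (cell$phh3_positive) {
      ph <- rbind(ph, ellipse_spec(d[1], d[2], r_nuc * 0.85, r_nuc * 0.85, 0,
                                   PHH3_DAB, cell$phh3_intensity))
    }
    ph_spec[[i]] <- ph
  }
  draw_spec(he, do.call(rbind, he_spec))
  draw_spec(phh3, do.call(rbind, ph_spec))

  structure(list(he = he, phh3 = phh3, mpp = config$mpp, cells = cells,
                 image_id = image_id, deformation = deformation),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair '%s'> %dx%d px, %.2f um/px, %d cells (%d MF, %d mismatch)\n",
              x$image_id, dim(x$he)[1], dim(x$he)[2], x$mpp, nrow(x$cells),
              sum(x$cells$is_mf), sum(x$cells$phh3_positive & !x$cells$he_visible)))
  invisible(x)
}

# Deterministic per-cell glyph orientation.
glyph_angle <- function(seed, cell_id) {
  (derive_seed(seed, c("angle", cell_id)) %% 360L) * pi / 180
}

# One ellipse as a spec row: cx, cy, a, b, angle, R, G, B, alpha.
ellipse_spec <- function(cx, cy, a, b, angle, rgb, alpha) {
  matrix(c(cx, cy, a, b, angle, rgb[1], rgb[2], rgb[3], alpha), nrow = 1)
}

# Composite a batch of soft-edged ellipses into the image (in place; the
# buffer is created by the caller and uniquely owned).
draw_spec <- function(img, spec) {
  if (is.null(spec) || nrow(spec) == 0) return(invisible(img))
  cpp_draw_ellipses(img, spec[, 1], spec[, 2], spec[, 3], spec[, 4],
                    spec[, 5], spec[, 6:8, drop = FALSE], spec[, 9])
  invisible(img)
}

# Ellipse specs of one cell's H&E rendering. Mismatch cells take exactly the
# non-mitotic path: identical pixels, no morphological trace. For visible
# figures the chromatin color is interpolated toward the plain nucleus hue
# as the latent distinctness falls: faint figures are genuinely faint.
he_cell_spec <- function(cell, r_nuc, ang) {
  x <- cell$x
  y <- cell$y
  if (!cell$he_visible || cell$phase == "nonmitotic") {
    return(ellipse_spec(x, y, r_nuc * 0.85, r_nuc * 0.85, 0, HE_NUCLEUS, 0.95))
  }
  d <- if ("he_distinctness" %in% names(cell)) cell$he_distinctness else 1
  # contrast tracks distinctness with a small floor: borderline figures are
  # rendered borderline (faint but not strictly invisible), while mismatch
  # cells (no morphology at all) take the plain-nucleus path above
  contrast <- 0.15 + 0.85 * d
  chromatin <- HE_NUCLEUS + (HE_CHROMATIN - HE_NUCLEUS) * contrast
  mimic <- HE_NUCLEUS + (HE_LOOKALIKE - HE_NUCLEUS) * contrast
  switch(cell$phase,
    lookalike = rbind(
      ellipse_spec(x, y, r_nuc * 0.85, r_nuc * 0.85, 0, HE_NUCLEUS, 0.9),
      ellipse_spec(x, y, r_nuc * 0.8, r_nuc * 0.6, ang, mimic, 0.95)),
    prophase = ,
    prometaphase = {
      spec <- rbind(
        ellipse_spec(x, y, r_nuc * 0.9, r_nuc * 0.9, 0, HE_NUCLEUS, 0.9),
        ellipse_spec(x, y, r_nuc * 0.55, r_nuc * 0.55, 0, chromatin, 1))
      for (k in 0:3) {
        a <- ang + k * pi / 2
        spec <- rbind(spec, ellipse_spec(x + cos(a) * r_nuc * 0.55,
                                         y + sin(a) * r_nuc * 0.55,
                                         r_nuc * 0.22, r_nuc * 0.22, 0,
                                         chromatin, 1))
      }
      spec
    },
    metaphase = rbind(
      ellipse_spec(x, y, r_nuc * 0.9, r_nuc * 0.9, 0, HE_NUCLEUS, 0.85),
      ellipse_spec(x, y, r_nuc * 1.05, r_nuc * 0.38, ang, chromatin, 1)),
    anaphase = {
      off <- r_nuc * 0.45
      rbind(
        ellipse_spec(x, y, r_nuc * 0.95, r_nuc * 0.95, 0, HE_NUCLEUS, 0.8),
        ellipse_spec(x + cos(ang) * off, y + sin(ang) * off, r_nuc * 0.75,
                     r_nuc * 0.3, ang + pi / 2, chromatin, 1),
        ellipse_spec(x - cos(ang) * off, y - sin(ang) * off, r_nuc * 0.75,
                     r_nuc * 0.3, ang + pi / 2, chromatin, 1))
    },
    telophase = {
      off <- r_nuc * 0.6
      rbind(
        ellipse_spec(x + cos(ang) * off, y + sin(ang) * off, r_nuc * 0.5,
                     r_nuc * 0.5, 0, chromatin, 1),
        ellipse_spec(x - cos(ang) * off, y - sin(ang) * off, r_nuc * 0.5,
                     r_nuc * 0.5, 0, chromatin, 1))
    },
    abort(sprintf("unknown phase '%s'", cell$phase))
  )
}


# Background with low-amplitude smooth texture so images are not constant.
flat_image <- function(size, rgb, seed) {
  img <- array(rep(rgb, each = size * size), dim = c(size, size, 3))
  with_seed(seed, {
    fx <- runif(2, 1, 3)
    ph <- runif(2, 0, 2 * pi)
    g <- outer(seq_len(size), seq_len(size), function(i, j) {
      0.015 * (sin(2 * pi * fx[1] * i / size + ph[1]) +
               cos(2 * pi * fx[2] * j / size + ph[2]))
    })
    for (c in 1:3) img[, , c] <- pmin(pmax(img[, , c] + g, 0), 1)
  })
  img
}

# Soft-edged disc / ellipse compositing on a copy (single-shape helpers,
# 0-based pixel-center coordinates).
draw_disc <- function(img, cx, cy, r, rgb, alpha = 1) {
  draw_ellipse(img, cx, cy, r, r, 0, rgb, alpha)
}

draw_ellipse <- function(img, cx, cy, a, b, angle, rgb, alpha = 1) {
  out <- img + 0
  draw_spec(out, ellipse_spec(cx, cy, a, b, angle, rgb, alpha))
  out
}

# Smooth sinusoidal displacement field with ||d|| <= max_px everywhere.
make_deformation <- function(max_px, size, seed) {
  with_seed(seed, {
    list(
      max_px = max_px,
      size = size,
      fx = runif(2, 0.5, 2),
      fy = runif(2, 0.5, 2),
      phase = runif(4, 0, 2 * pi),
      # split the budget so the euclidean norm never exceeds max_px
      amp = max_px / sqrt(2)
    )
  })
}

# Displaced position of a point under the residual registration deformation.
apply_deformation <- function(def, x, y) {
  if (def$max_px == 0) return(c(x, y))
  s <- def$size
  dx <- def$amp * sin(2 * pi * def$fx[1] * x / s + def$phase[1]) *
    cos(2 * pi * def$fy[1] * y / s + def$phase[2])
  dy <- def$amp * sin(2 * pi * def$fx[2] * y / s + def$phase[3]) *
    cos(2 * pi * def$fy[2] * x / s + def$phase[4])
  c(x + dx, y + dy)
}

#' Write an image pair to disk as PNG files
#'
#' @param pair An `image_pair`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_image_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(pair$image_id, c("_he.png", "_phh3.png")))
  png::writePNG(pair$he, paths[1])
  png::writePNG(pair$phh3, paths[2])
  invisible(paths)
}
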