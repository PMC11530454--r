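# Synthetic study generator: cell populations, rendering, rater simulation.

test_that("cell populations respect phase rules, mismatch fraction and geometry", {
  cfg0 <- study_config(n_images = 1, mismatch_fraction = 0, rng_seed = 1)
  cells0 <- generate_cell_population(cfg0, "img_001")
  expect_true(all(cells0$he_visible[cells0$phh3_positive]))

  # lookalikes/nonmitotic never PHH3-positive; lookalikes always H&E-visible
  expect_true(all(!cells0$phh3_positive[cells0$phase %in% c("lookalike", "nonmitotic")]))
  expect_true(all(cells0$he_visible[cells0$phase == "lookalike"]))

  # mismatch cells only among pro/prometaphase
  cfg <- study_config(n_images = 1, rng_seed = 7)
  cells <- generate_cell_population(cfg, "img_001")
  mm <- cells$phh3_positive & !cells$he_visible
  expect_true(all(cells$phase[mm] %in% c("prophase", "prometaphase")))

  # mismatch conservation: PHH3-only-identifiable = positives - visible positives
  expect_identical(sum(mm),
                   sum(cells$phh3_positive) - sum(cells$phh3_positive & cells$he_visible))

  # minimum pairwise separation of one nucleus diameter
  d <- as.matrix(dist(cbind(cells$x, cells$y)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_separation_um / cfg$mpp - 1e-9)

  # determinism
  expect_identical(cells, generate_cell_population(cfg, "img_001"))
})

test_that("mismatch fraction is hit at binomial tolerance over many cells", {
  cfg <- study_config(n_images = 30, image_size_px = 400,
                      mitotic_per_image = 25, nonmitotic_per_image = 5,
                      lookalike_per_image = 0, mismatch_fraction = 0.56,
                      rng_seed = 11)
  cells <- dplyr::bind_rows(purrr::map(sprintf("img_%03d", 1:30),
                                       ~ generate_cell_population(cfg, .x)))
  pp <- cells[cells$phase %in% c("prophase", "prometaphase") & cells$phh3_positive, ]
  expect_gt(nrow(pp), 300)
  phat <- mean(!pp$he_visible)
  se <- sqrt(0.56 * 0.44 / nrow(pp))
  expect_lt(abs(phat - 0.56), 3 * se)
})

test_that("placement errors name the separation constraint", {
  cfg <- study_config(n_images = 1, image_size_px = 64,
                      mitotic_per_image = 300, rng_seed = 1)
  expect_error(generate_cell_population(cfg, "img_001"), "separation")
})

test_that("mismatch cells are rendered pixel-identically to nonmitotic nuclei", {
  cfg <- study_config(n_images = 1, rng_seed = 3)
  cells <- generate_cell_population(cfg, "img_001")
  mm <- cells[cells$phh3_positive & !cells$he_visible, ][1, ]
  twin <- mm
  twin$phase <- "nonmitotic"
  twin$phh3_positive <- FALSE
  twin$phh3_intensity <- 0
  p_mm <- render_image_pair(mm, cfg, image_id = "img_001")
  p_tw <- render_image_pair(twin, cfg, image_id = "img_001")
  expect_identical(p_mm$he, p_tw$he)
})

test_that("PHH3 blob centroids sit at the cell position without deformation and within the bound with it", {
  centroid_of_dab <- function(pair) {
    brown <- pair$phh3[, , 1] - pair$phh3[, , 3]
    w <- pmax(brown - 0.15, 0)
    idx <- which(w > 0, arr.ind = TRUE)
    c(x = sum((idx[, 2] - 1) * w[idx]) / sum(w[idx]),
      y = sum((idx[, 1] - 1) * w[idx]) / sum(w[idx]))
  }
  cfg0 <- study_config(n_images = 1, max_deformation_um = 0, rng_seed = 5)
  cell <- tibble::tibble(cell_id = "c1", image_id = "img_001", x = 201.0,
                         y = 149.0, phase = "metaphase", is_mf = TRUE,
                         he_visible = TRUE, phh3_positive = TRUE,
                         phh3_intensity = 1)
  p0 <- render_image_pair(cell, cfg0, image_id = "img_001")
  cen <- centroid_of_dab(p0)
  expect_lt(abs(cen["x"] - cell$x), 0.5)
  expect_lt(abs(cen["y"] - cell$y), 0.5)

  cfg1 <- study_config(n_images = 1, max_deformation_um = 1.5, rng_seed = 5)
  p1 <- render_image_pair(cell, cfg1, image_id = "img_001")
  cen1 <- centroid_of_dab(p1)
  max_px <- 1.5 / cfg1$mpp
  expect_lte(sqrt((cen1["x"] - cell$x)^2 + (cen1["y"] - cell$y)^2), max_px + 0.5)
})

test_that("a perfect rater annotates exactly the H&E-visible mitotic figures in phase 1", {
  study <- tiny_study()
  cells <- study$cells[study$cells$image_id == "img_001", ]
  pair <- list(cells = cells, mpp = study$config$mpp)
  ann <- simulate_rater(pair, rater_profile(), "P1", seed = 9)
  expect_equal(nrow(ann), sum(cells$is_mf & cells$he_visible))
  expect_true(all(ann$cls == "MF"))
  # zero jitter: positions coincide with cell positions
  expect_true(all(round(ann$x, 6) %in% round(cells$x, 6)))
})

test_that("hindsight bias controls the class of mismatch-cell annotations in phase 2", {
  study <- tiny_study()
  cells <- study$cells[study$cells$image_id == "img_002", ]
  pair <- list(cells = cells, mpp = study$config$mpp)
  n_mm <- sum(cells$phh3_positive & !cells$he_visible)
  expect_gt(n_mm, 0)

  p_no_bias <- rater_profile(hindsight_bias = 0)
  ann0 <- simulate_rater(pair, p_no_bias, "P2", seed = 2)
  mm_xy <- cells[cells$phh3_positive & !cells$he_visible, c("x", "y")]
  is_mm_ann <- paste(round(ann0$x, 6), round(ann0$y, 6)) %in%
    paste(round(mm_xy$x, 6), round(mm_xy$y, 6))
  expect_true(all(ann0$cls[is_mm_ann] == "PHH3_ONLY"))

  p_bias <- rater_profile(hindsight_bias = 1)
  ann1 <- simulate_rater(pair, p_bias, "P2", seed = 2)
  is_mm_ann1 <- paste(round(ann1$x, 6), round(ann1$y, 6)) %in%
    paste(round(mm_xy$x, 6), round(mm_xy$y, 6))
  expect_equal(sum(is_mm_ann1), n_mm)
  expect_true(all(ann1$cls[is_mm_ann1] == "HE_AND_PHH3"))

  expect_error(simulate_rater(pair, p_bias, "P3", seed = 1), "study_phase")
})

test_that("study simulation has the full rater-by-phase-by-image structure and is reproducible", {
  cfg <- study_config(n_images = 3, image_size_px = 256, mitotic_per_image = 10,
                      nonmitotic_per_image = 10, lookalike_per_image = 3,
                      rng_seed = 21)
  profs <- dplyr::bind_rows(purrr::map(1:13, function(r) {
    rater_profile(rater_id = sprintf("rater_%02d", r), sensitivity = 1,
                  phh3_sensitivity = 1, jitter_sd_um = 1)
  }))
  study <- generate_study(cfg, profs)
  counts <- dplyr::count(study$annotations, image_id, study_phase, rater_id)
  # every rater annotates every image in both phases (13 x 3 x 2 lists)
  expect_equal(nrow(counts), 13 * 3 * 2)

  study2 <- generate_study(cfg, profs)
  expect_identical(study$annotations, study2$annotations)

  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  write_study(study, d1)
  write_study(study2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  expect_error(generate_study(cfg, rater_profiles(5, seed = 1)), "n_raters")

})
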