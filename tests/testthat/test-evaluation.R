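# Tiled inference, non-maximum suppression, average precision, result grid.

test_that("tile origins advance by tile minus overlap and clamp at the border", {
  expect_equal(tile_origins(1024, 512, 50), c(0L, 462L, 512L))
  expect_equal(tile_origins(512, 512, 50), 0L)
  expect_equal(tile_origins(400, 512, 50), 0L)
  # full coverage: every pixel inside some tile
  for (size in c(700, 1024, 1500)) {
    org <- tile_origins(size, 512, 50)
    covered <- rep(FALSE, size)
    for (o in org) covered[(o + 1):(o + 512)] <- TRUE
    expect_true(all(covered))
  }
  expect_error(tile_origins(1024, 100, 100), "overlap")
})

test_that("non-maximum suppression keeps the highest-scoring of overlapping boxes", {
  det <- tibble::tibble(
    x = c(100, 102, 300), y = c(100, 101, 300),
    x0 = c(75, 77, 275), y0 = c(75, 76, 275),
    x1 = c(125, 127, 325), y1 = c(125, 126, 325),
    score = c(0.9, 0.8, 0.7))
  kept <- nms_detections(det, 0.3)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$score, c(0.9, 0.7))
  # center-distance alternative
  kept2 <- nms_detections(det, method = "center", dist_px = 10)
  expect_equal(nrow(kept2), 2)
})

test_that("average precision follows the oracle on ranked lists and edge conventions", {
  gt <- tibble::tibble(x = c(10, 60, 110, 160, 210), y = rep(10, 5))
  perfect <- tibble::tibble(x = gt$x, y = gt$y, score = 1)
  expect_equal(average_precision(perfect, gt, 7.5, 0.25)$ap, 1)

  none <- tibble::tibble(x = numeric(), y = numeric(), score = numeric())
  expect_equal(average_precision(none, gt, 7.5, 0.25)$ap, 0)

  undef <- average_precision(perfect, gt[0, ], 7.5, 0.25)
  expect_true(is.na(undef$ap))

  # three true detections at high rank, two false at the bottom
  dets <- tibble::tibble(x = c(10, 60, 110, 500, 600),
                         y = c(10, 10, 10, 10, 10),
                         score = c(0.9, 0.8, 0.7, 0.6, 0.5))
  got <- average_precision(dets, gt, 7.5, 0.25)
  want <- brute_force_ap(dets, gt, 30)
  expect_equal(got$ap, want, tolerance = 1e-12)

  # randomized ranked lists against the enumeration oracle
  set.seed(21)
  for (i in 1:25) {
    g <- tibble::tibble(x = runif(8, 0, 400), y = runif(8, 0, 400))
    d <- tibble::tibble(x = runif(12, 0, 400), y = runif(12, 0, 400),
                        score = runif(12))
    expect_equal(average_precision(d, g, 7.5, 0.25)$ap,
                 brute_force_ap(d, g, 30), tolerance = 1e-12)
  }
})

test_that("appending a lowest-score false positive never raises the AP", {
  set.seed(3)
  gt <- tibble::tibble(x = runif(6, 0, 300), y = runif(6, 0, 300))
  d <- tibble::tibble(x = c(gt$x[1:4] + 1, 250), y = c(gt$y[1:4], 290),
                      score = c(0.9, 0.85, 0.8, 0.75, 0.5))
  base <- average_precision(d, gt, 7.5, 0.25)$ap
  worse <- dplyr::bind_rows(d, tibble::tibble(x = 1, y = 1, score = 0.01))
  expect_lte(average_precision(worse, gt, 7.5, 0.25)$ap, base)
  # removing a false positive never lowers it
  no_fp <- d[-5, ]
  expect_gte(average_precision(no_fp, gt, 7.5, 0.25)$ap, base)
})

test_that("tiled inference of an isolated object yields exactly one detection", {
  cfg <- study_config(n_images = 1, image_size_px = 700, rng_seed = 1)
  cell <- tibble::tibble(cell_id = "c", image_id = "img_001", x = 200, y = 350,
                         phase = "metaphase", is_mf = TRUE, he_visible = TRUE,
                         phh3_positive = TRUE, phh3_intensity = 1)
  pair <- render_image_pair(cell, cfg, image_id = "img_001")
  det <- tiled_inference(template_detector("single"), pair, tile = 512,
                         overlap = 50, edge_margin = 10)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 200), 3)
  expect_lt(abs(det$y - 350), 3)
})

test_that("the experiment grid covers every model, label-set and split combination once", {
  study <- tiny_study()
  ls <- derive_label_sets(study)
  splits <- monte_carlo_splits(study$image_ids, n_splits = 1,
                               fractions = c(0.5, 0.25, 0.25), seed = 2)
  models <- list(single = desk_detector_config("single", max_epochs = 1,
                                               steps_per_epoch = 2),
                 dual = desk_detector_config("dual", max_epochs = 1,
                                             steps_per_epoch = 2))
  grid <- run_experiment_grid(study, ls, splits, models = models, seed = 3)
  expect_s3_class(grid, "result_grid")
  expect_equal(nrow(grid), 2 * 2 * 2 * 1)  # model x train x eval x split
  expect_equal(nrow(dplyr::distinct(grid[c("model", "train_labels",
                                           "eval_labels", "split")])),
               nrow(grid))
  g <- glance(grid)
  expect_true(all(c("mean_ap", "sd_ap") %in% names(g)))
  expect_error(run_experiment_grid(study, ls, splits, models = models,
                                   train_on = "nope"), "missing")
})
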