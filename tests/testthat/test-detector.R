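# Detection models: backbones, fusion, patch sampling, augmentation,
# target encoding and the training protocol.

test_that("backbone feature maps have the contracted shapes and are deterministic", {
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  cfg <- detector_config("single", "tiny")
  model <- fcos_model(cfg)
  lv <- backbone_forward(img, model = model)
  expect_equal(purrr::map(lv, dim),
               list(c(32L, 32L, 12L), c(16L, 16L, 24L), c(8L, 8L, 48L)))
  # strictly halving spatial sizes
  sizes <- purrr::map_dbl(lv, ~ dim(.x)[1])
  expect_equal(sizes, c(32, 16, 8))
  expect_identical(lv, backbone_forward(img, model = model))
  expect_error(backbone_forward(array(0, c(100, 100, 3)), model = model),
               "divisible")
})

test_that("the residual resnet18 layout yields blocks 2-4 at strides 8/16/32 with 128/256/512 channels", {
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  cfg <- detector_config("single", "resnet18")
  lv <- backbone_forward(img, cfg)
  expect_equal(purrr::map(lv, dim),
               list(c(32L, 32L, 128L), c(16L, 16L, 256L), c(8L, 8L, 512L)))
})

test_that("mid-fusion halves concatenated channels, rectifies, and is order-sensitive", {
  set.seed(3)
  he <- purrr::map(c(12, 24, 48), ~ array(rnorm(32 * 32 * .x), c(32, 32, .x)))
  ph <- purrr::map(c(12, 24, 48), ~ array(rnorm(32 * 32 * .x), c(32, 32, .x)))
  fused <- fuse_features(he, ph, seed = 5)
  expect_equal(purrr::map(fused, dim), purrr::map(he, dim))
  expect_true(all(purrr::map_lgl(fused, ~ all(.x >= 0))))
  # deterministic
  expect_identical(fused, fuse_features(he, ph, seed = 5))
  # order matters through channel positions
  swapped <- fuse_features(ph, he, seed = 5)
  expect_false(isTRUE(all.equal(fused[[1]], swapped[[1]])))
  expect_error(fuse_features(he, ph[1:2]), "level counts")
})

test_that("a constant PHH3 image contributes no spatial information to the fused features", {
  cfg <- detector_config("dual", "tiny")
  model <- fcos_model(cfg)
  he <- array(runif(128 * 128 * 3), c(128, 128, 3))
  const_ph <- array(0.5, c(128, 128, 3))
  bb <- stainshift:::backbone_fw(model$backbone_phh3, model$arch, const_ph)
  # interior margins exceed the receptive-field radius in feature cells;
  # the coarsest 8x8 map has no padding-free interior and is skipped
  margins <- c(5, 6)
  for (l in 1:2) {
    lv <- bb$levels[[l]]
    d <- dim(lv)
    m <- margins[l]
    interior <- lv[(m + 1):(d[1] - m), (m + 1):(d[2] - m), , drop = FALSE]
    spatial_sd <- apply(interior, 3, sd)
    expect_lt(max(spatial_sd), 1e-8)
  }
})

test_that("parameter accounting reproduces the size ordering of the architectures", {
  n_single18 <- model_parameter_count(detector_config("single", "resnet18"))
  n_dual18 <- model_parameter_count(detector_config("dual", "resnet18"))
  n_single101 <- model_parameter_count(detector_config("single", "resnet101"))
  expect_lt(n_single18, n_dual18)
  expect_lt(n_dual18, n_single101)
  # full-size models land in the tens of millions, like their namesakes
  expect_gt(n_single18, 1e7)
  expect_lt(n_single101, 1e8)
  # the instantiated tiny model's registry agrees with the analytic count
  cfg <- detector_config("dual", "tiny")
  m <- fcos_model(cfg)
  expect_equal(stainshift:::registry_param_count(m$registry),
               model_parameter_count(cfg))
})

test_that("point-to-box conversion is centered, clipped, and invertible away from borders", {
  b <- points_to_boxes(tibble::tibble(x = 100, y = 100), 50)
  expect_equal(c(b$x0, b$y0, b$x1, b$y1), c(75, 75, 125, 125))
  corner <- points_to_boxes(tibble::tibble(x = 0, y = 0), 50, image_size = 512)
  expect_true(corner$x1 > corner$x0 && corner$y1 > corner$y0)
  expect_equal(corner$x0, 0)
  # round trip via box centers
  pts <- tibble::tibble(x = c(60, 200), y = c(80, 300))
  bb <- points_to_boxes(pts, 50, image_size = 512)
  expect_equal((bb$x0 + bb$x1) / 2, pts$x)
  expect_equal((bb$y0 + bb$y1) / 2, pts$y)
})

test_that("patch sampling honors the positive fraction and never uses label-free images for positives", {
  labels <- tibble::tibble(image_id = rep("img_001", 5),
                           x = runif(5, 100, 400), y = runif(5, 100, 400))
  specs <- sample_training_patches(labels, c("img_001", "img_002"), 512, 128,
                                   n = 1000, mf_patch_fraction = 0.5, seed = 3)
  expect_identical(specs,
                   sample_training_patches(labels, c("img_001", "img_002"),
                                           512, 128, 1000, 0.5, seed = 3))
  # positives really contain a label center strictly inside
  pos <- specs[specs$positive, ]
  expect_gte(nrow(pos), 500)
  expect_true(all(pos$image_id == "img_001"))
  ok <- purrr::map_lgl(seq_len(nrow(pos)), function(i) {
    any(labels$x > pos$x0[i] & labels$x < pos$x0[i] + 127 &
          labels$y > pos$y0[i] & labels$y < pos$y0[i] + 127)
  })
  expect_true(all(ok))
  frac <- mean(purrr::map_lgl(seq_len(nrow(specs)), function(i) {
    any(labels$x > specs$x0[i] & labels$x < specs$x0[i] + 127 &
          labels$y > specs$y0[i] & labels$y < specs$y0[i] + 127)
  }))
  expect_gte(frac, 0.5 - 3 * sqrt(0.25 / 1000))
})

test_that("augmentation is identity at zero probabilities and keeps points glued to pixels", {
  patch <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pts <- tibble::tibble(x = c(10, 40), y = c(20, 55))
  off <- list(p_jitter = 0, p_blur = 0, p_drop = 0, drop_rate = 0, p_rotate = 0)
  out <- augment_patch(list(he = patch), pts, off, seed = 1)
  expect_identical(out$patches$he, patch)
  expect_identical(out$points, pts)

  # mark a pixel, rotate, and check the point lands on the marked pixel
  marked <- array(0, c(64, 64, 3))
  marked[21, 11, ] <- 1  # pixel (x = 10, y = 20)
  rot_only <- list(p_jitter = 0, p_blur = 0, p_drop = 0, drop_rate = 0, p_rotate = 1)
  for (seed in 1:5) {
    out2 <- augment_patch(list(he = marked), tibble::tibble(x = 10, y = 20),
                          rot_only, seed = seed)
    hit <- which(out2$patches$he[, , 1] == 1, arr.ind = TRUE)
    expect_equal(unname(hit[1, ]), c(out2$points$y + 1, out2$points$x + 1))
  }

  # pixel drop zeroes about the configured fraction
  drop_only <- list(p_jitter = 0, p_blur = 0, p_drop = 1, drop_rate = 0.1,
                    p_rotate = 0)
  big <- array(1, c(64, 64, 3))
  out3 <- augment_patch(list(he = big), pts, drop_only, seed = 7)
  frac <- mean(out3$patches$he[, , 1] == 0)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / (64 * 64)))

  # dual mode: identical rotation for both stains
  out4 <- augment_patch(list(he = marked, phh3 = marked), pts, rot_only, seed = 2)
  expect_identical(which(out4$patches$he == 1), which(out4$patches$phh3 == 1))
})

test_that("centerness is 1 at the box center and target encoding decodes back to the box", {
  expect_equal(centerness(25, 25, 25, 25), 1)
  expect_equal(centerness(10, 20, 30, 20), sqrt(10 / 30))

  cfg <- detector_config("single", "tiny", patch_size = 128)
  grids <- purrr::map(seq_along(cfg$strides), function(l) {
    stainshift:::level_locations(c(128, 128) / cfg$strides[l], cfg$strides[l])
  })
  boxes <- tibble::tibble(x = 64, y = 64, x0 = 39, y0 = 39, x1 = 89, y1 = 89)
  tg <- stainshift:::assign_fcos_targets(boxes, grids, cfg$strides, cfg$level_ranges)
  # at least one positive location; encoded distances decode to the box
  found <- FALSE
  for (l in seq_along(tg)) {
    pos <- which(tg[[l]]$cls == 1, arr.ind = TRUE)
    if (!nrow(pos)) next
    found <- TRUE
    g <- grids[[l]]
    for (r in seq_len(nrow(pos))) {
      i <- pos[r, 1]; j <- pos[r, 2]
      x <- g$x[i, j]; y <- g$y[i, j]
      expect_equal(x - tg[[l]]$reg[i, j, 1], 39, tolerance = 1e-9)
      expect_equal(y - tg[[l]]$reg[i, j, 2], 39, tolerance = 1e-9)
      expect_equal(x + tg[[l]]$reg[i, j, 3], 89, tolerance = 1e-9)
      expect_equal(y + tg[[l]]$reg[i, j, 4], 89, tolerance = 1e-9)
    }
  }
  expect_true(found)
})

test_that("training learns, selects the best validation checkpoint, and respects the patience rule", {
  study <- tiny_study()
  ls <- derive_label_sets(study)
  cfg <- desk_detector_config("single", max_epochs = 5, steps_per_epoch = 12,
                              restart_floor = 0)  # isolate the patience rule
  det <- train_detector(study, ls$he_only_labels,
                        train_ids = study$image_ids[1:3],
                        val_ids = study$image_ids[4],
                        config = cfg, seed = 4)
  h <- det$history
  expect_lte(nrow(h), 5)
  # training loss decreases over the run
  expect_lt(tail(h$loss, 1), h$loss[1])
  # returned checkpoint is the validation-AP maximum over the candidate
  # window (epochs past the burn-in)
  eligible <- h$val_ap
  eligible[seq_len(min(cfg$min_epochs - 1, length(eligible)))] <- -Inf
  expect_equal(det$best_val_ap, max(eligible, na.rm = TRUE))
  expect_equal(det$best_epoch, which.max(eligible))
  # if stopped early, exactly patience evaluations passed without improvement
  if (nrow(h) < cfg$max_epochs) {
    expect_equal(nrow(h) - det$best_epoch, cfg$patience)
  }
  # prediction interface
  pair <- render_study_image(study, study$image_ids[1])
  d <- detect_patch(det, pair$he[1:128, 1:128, , drop = FALSE])
  expect_true(all(c("x", "y", "score") %in% names(d)))

  expect_error(train_detector(study, ls$he_only_labels[0, ],
                              study$image_ids[1:3], study$image_ids[4],
                              cfg), "no labels")
})
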