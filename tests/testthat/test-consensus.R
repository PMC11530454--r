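# Distance clustering, support thresholds, label-set derivation and cleaning.

ann_at <- function(xy, raters, image_id = "img_001", phase = "P1",
                   cls = "MF") {
  tibble::tibble(image_id = image_id, rater_id = raters, study_phase = phase,
                 x = xy[, 1], y = xy[, 2], cls = cls)
}

test_that("coincident annotations form one cluster; the nucleus-diameter radius separates cells", {
  raters <- sprintf("rater_%02d", 1:13)
  same <- ann_at(cbind(rep(50, 13), rep(60, 13)), raters)
  cl <- cluster_annotations(same, radius_um = 7.5, mpp = 0.25)
  expect_equal(nrow(attr(cl, "clusters")), 1)
  expect_equal(attr(cl, "clusters")$support, 13L)

  # 7.6 um apart (different raters) -> two clusters
  two <- ann_at(rbind(c(100, 100), c(100 + 7.6 / 0.25, 100)),
                c("rater_01", "rater_02"))
  cl2 <- cluster_annotations(two, radius_um = 7.5, mpp = 0.25)
  expect_equal(nrow(attr(cl2, "clusters")), 2)

  # 7.4 um apart -> one cluster
  near <- ann_at(rbind(c(100, 100), c(100 + 7.4 / 0.25, 100)),
                 c("rater_01", "rater_02"))
  cl3 <- cluster_annotations(near, radius_um = 7.5, mpp = 0.25)
  expect_equal(nrow(attr(cl3, "clusters")), 1)

  # same rater twice never supports one cluster twice
  dup <- ann_at(rbind(c(100, 100), c(101, 100)), c("rater_01", "rater_01"))
  cl4 <- cluster_annotations(dup, radius_um = 7.5, mpp = 0.25)
  expect_equal(nrow(attr(cl4, "clusters")), 2)

  expect_error(cluster_annotations(same, mpp = 0), "mpp")
})

test_that("clustering matches the brute-force executor of the ordered rule", {
  set.seed(77)
  for (trial in 1:40) {
    n <- sample(3:25, 1)
    ann <- tibble::tibble(
      image_id = "img_001",
      rater_id = sprintf("rater_%02d", sample(1:6, n, replace = TRUE)),
      study_phase = "P1",
      x = runif(n, 0, 120), y = runif(n, 0, 120), cls = "MF")
    got <- cluster_annotations(ann, radius_um = 7.5, mpp = 0.25)
    want <- brute_force_clustering(ann, 7.5, 0.25)
    # same membership partition
    got_sets <- unname(split(seq_len(n), got$.cluster))
    want_sets <- lapply(want, sort)
    expect_setequal(lapply(got_sets, sort), want_sets)
  }
})

test_that("support thresholds retain and drop clusters as configured", {
  raters <- sprintf("rater_%02d", 1:13)
  xy6 <- cbind(rep(50, 6), rep(50, 6))
  xy5 <- cbind(rep(200, 5), rep(200, 5))
  ann <- dplyr::bind_rows(ann_at(xy6, raters[1:6]), ann_at(xy5, raters[7:11]))
  cl <- cluster_annotations(ann, 7.5, 0.25)
  kept <- build_consensus(cl, min_support = 6)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$support, 6L)
  expect_equal(nrow(build_consensus(cl, min_support = 1)), 2)

  # monotonicity in the threshold
  counts <- vapply(1:13, function(m) nrow(build_consensus(cl, m)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("leave-one-out consensus uses half of the remaining panel and excludes the held-out rater", {
  study <- tiny_study()
  ann <- study$annotations
  img1 <- ann[ann$image_id == "img_001" & ann$study_phase == "P1", ]
  loo <- leave_one_out_consensus(img1, "rater_01", 7.5, study$config$mpp)
  # 13 raters -> ceil(0.5 * 12) = 6
  full <- cluster_annotations(img1[img1$rater_id != "rater_01", ], 7.5,
                              study$config$mpp)
  expect_equal(nrow(loo), sum(attr(full, "clusters")$support >= 6))

  # excluded rater's annotations never move a centroid
  jittered <- img1
  jittered$x[jittered$rater_id == "rater_01"] <-
    jittered$x[jittered$rater_id == "rater_01"] + 3
  loo2 <- leave_one_out_consensus(jittered, "rater_01", 7.5, study$config$mpp)
  expect_equal(loo$x, loo2$x)

  three <- ann_at(rbind(c(1, 1), c(50, 50), c(90, 90)),
                  c("rater_01", "rater_02", "rater_03"))
  loo3 <- leave_one_out_consensus(three, "rater_03", 7.5, 0.25)
  # ceil(0.5 * 2) = 1: every remaining cluster retained
  expect_equal(nrow(loo3), 2)

  expect_error(leave_one_out_consensus(three, "rater_09", 7.5, 0.25), "not present")
})

test_that("cluster membership is invariant to rescaling pixels and mpp together", {
  set.seed(8)
  ann <- tibble::tibble(
    image_id = "img_001",
    rater_id = sprintf("rater_%02d", sample(1:5, 15, replace = TRUE)),
    study_phase = "P1", x = runif(15, 0, 200), y = runif(15, 0, 200),
    cls = "MF")
  a <- cluster_annotations(ann, 7.5, mpp = 0.25)
  ann2 <- dplyr::mutate(ann, x = x / 2, y = y / 2)
  b <- cluster_annotations(ann2, 7.5, mpp = 0.5)
  expect_identical(a$.cluster, b$.cluster)
})

test_that("label sets pool the H&E-identifiable phase-2 classes and ignore PHH3-only marks", {
  study <- tiny_study()
  ls <- derive_label_sets(study)
  expect_named(ls, c("he_only_labels", "phh3_assisted_labels"))

  # removing PHH3_ONLY annotations changes nothing
  ann_wo <- study$annotations[study$annotations$cls != "PHH3_ONLY", ]
  ls2 <- derive_label_sets(ann_wo, mpp = study$config$mpp)
  expect_equal(ls$phh3_assisted_labels, ls2$phh3_assisted_labels)

  # a study whose phase 2 is a copy of phase 1 yields identical label sets
  ann_p1 <- study$annotations[study$annotations$study_phase == "P1", ]
  fake_p2 <- dplyr::mutate(ann_p1, study_phase = "P2", cls = "HE_AND_PHH3")
  both <- dplyr::bind_rows(ann_p1, fake_p2)
  ls3 <- derive_label_sets(both, mpp = study$config$mpp)
  expect_equal(ls3$he_only_labels[c("image_id", "x", "y")],
               ls3$phh3_assisted_labels[c("image_id", "x", "y")])
})

test_that("perfect raters with full hindsight produce phh3-assisted = he-only + mismatch cells", {
  cfg <- study_config(n_images = 2, image_size_px = 320, mitotic_per_image = 16,
                      nonmitotic_per_image = 10, lookalike_per_image = 0,
                      n_raters = 13, rng_seed = 31)
  profs <- dplyr::bind_rows(purrr::map(1:13, function(r) {
    rater_profile(rater_id = sprintf("rater_%02d", r), sensitivity = 1,
                  phh3_sensitivity = 1, hindsight_bias = 1)
  }))
  study <- generate_study(cfg, profs)
  ls <- derive_label_sets(study)
  n_mm <- sum(study$cells$phh3_positive & !study$cells$he_visible)
  n_he_vis <- sum(study$cells$is_mf & study$cells$he_visible)
  expect_equal(nrow(ls$he_only_labels), n_he_vis)
  expect_equal(nrow(ls$phh3_assisted_labels), n_he_vis + n_mm)
})

test_that("post-hoc cleaning removes majority-not-recognizable newly-found points only", {
  study <- tiny_study()
  ls <- derive_label_sets(study)
  new_pts <- newly_found_points(ls$phh3_assisted_labels, ls$he_only_labels,
                                7.5, study$config$mpp)
  expect_gt(nrow(new_pts), 0)

  # all recognizable -> unchanged
  dec_all_ok <- new_pts
  dec_all_ok$verdicts <- replicate(nrow(new_pts),
                                   rep("recognizable", 3), simplify = FALSE)
  cleaned <- clean_label_set(ls$phh3_assisted_labels, dec_all_ok,
                             ls$he_only_labels, 7.5, study$config$mpp)
  expect_equal(nrow(cleaned), nrow(ls$phh3_assisted_labels))

  # 2-of-3 not-recognizable majority removes the point
  dec_mixed <- new_pts
  dec_mixed$verdicts <- replicate(nrow(new_pts),
                                  c("not_recognizable", "not_recognizable",
                                    "recognizable"), simplify = FALSE)
  cleaned2 <- clean_label_set(ls$phh3_assisted_labels, dec_mixed,
                              ls$he_only_labels, 7.5, study$config$mpp)
  expect_equal(nrow(cleaned2), nrow(ls$phh3_assisted_labels) - nrow(new_pts))

  # missing decision is an error
  expect_error(clean_label_set(ls$phh3_assisted_labels, dec_mixed[-1, ],
                               ls$he_only_labels, 7.5, study$config$mpp),
               "missing post-hoc")

  # truthful verdict oracle: cleaned equals the H&E-visible subset
  dec_oracle <- simulate_posthoc_verdicts(study, new_pts, accuracy = 1, seed = 3)
  cleaned3 <- clean_label_set(ls$phh3_assisted_labels, dec_oracle,
                              ls$he_only_labels, 7.5, study$config$mpp)
  visible_subset <- purrr::map_lgl(seq_len(nrow(ls$phh3_assisted_labels)), function(i) {
    cc <- study$cells[study$cells$image_id == ls$phh3_assisted_labels$image_id[i], ]
    d2 <- (cc$x - ls$phh3_assisted_labels$x[i])^2 +
      (cc$y - ls$phh3_assisted_labels$y[i])^2
    is_new <- min(sqrt((ls$he_only_labels$x[ls$he_only_labels$image_id ==
                          ls$phh3_assisted_labels$image_id[i]] -
                          ls$phh3_assisted_labels$x[i])^2 +
                       (ls$he_only_labels$y[ls$he_only_labels$image_id ==
                          ls$phh3_assisted_labels$image_id[i]] -
                          ls$phh3_assisted_labels$y[i])^2),
                  Inf) > 7.5 / study$config$mpp
    !is_new || cc$he_visible[which.min(d2)]
  })
  expect_equal(nrow(cleaned3), sum(visible_subset))
})
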