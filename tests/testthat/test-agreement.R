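# Matching, precision/recall/F1, ICC, Fleiss' kappa, paired testing.

pts <- function(m) tibble::tibble(x = m[, 1], y = m[, 2])

test_that("greedy matching is one-to-one, radius-limited and deterministic", {
  a <- pts(rbind(c(10, 10), c(50, 50), c(90, 90)))
  m <- match_points(a, a, 7.5, 0.25)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$unmatched_predictions, 0)
  expect_length(m$unmatched_references, 0)

  # 8 um away at 0.25 mpp = 32 px > 30 px radius: no match
  far <- pts(rbind(c(10 + 8 / 0.25, 10)))
  m2 <- match_points(far, pts(rbind(c(10, 10))), 7.5, 0.25)
  expect_equal(nrow(m2$pairs), 0)

  # each point matched at most once even with several candidates
  preds <- pts(rbind(c(0, 0), c(4, 0)))
  refs <- pts(rbind(c(2, 0)))
  m3 <- match_points(preds, refs, 7.5, 0.25)
  expect_equal(nrow(m3$pairs), 1)
  expect_equal(m3$pairs$prediction, 1)  # closer pair wins; tie-break by index
  expect_error(match_points(preds, refs, 7.5, -1), "mpp")
})

test_that("precision/recall/F1 follow the stated 0/0 conventions", {
  refs <- pts(rbind(c(10, 10), c(60, 60), c(110, 110), c(160, 160)))
  half <- refs[1:2, ]
  r <- instance_prf(half, refs, 7.5, 0.25)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 * 1 * 0.5 / 1.5)

  none <- instance_prf(pts(matrix(numeric(0), 0, 2)), refs, 7.5, 0.25)
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))

  both_empty <- instance_prf(pts(matrix(numeric(0), 0, 2)),
                             pts(matrix(numeric(0), 0, 2)), 7.5, 0.25)
  expect_equal(both_empty$f1, 0)
})

test_that("a simulated rater's recall against ground truth recovers its sensitivity", {
  # one fixed sensitivity, many cells, no jitter and no false positives
  cfg <- study_config(n_images = 6, image_size_px = 448, mitotic_per_image = 30,
                      nonmitotic_per_image = 5, lookalike_per_image = 0,
                      mismatch_fraction = 0, rng_seed = 19)
  prof <- rater_profile(sensitivity = 0.8)
  cells <- dplyr::bind_rows(purrr::map(sprintf("img_%03d", 1:6), function(id) {
    generate_cell_population(cfg, id)
  }))
  n_mf <- sum(cells$is_mf & cells$he_visible)
  expect_gte(n_mf, 100)
  ann <- dplyr::bind_rows(purrr::map(unique(cells$image_id), function(id) {
    simulate_rater(list(cells = cells[cells$image_id == id, ], mpp = cfg$mpp),
                   prof, "P1", seed = 100 + match(id, unique(cells$image_id)))
  }))
  gt <- cells[cells$is_mf & cells$he_visible, c("image_id", "x", "y")]
  r <- instance_prf(ann, gt, 7.5, cfg$mpp)
  se <- sqrt(0.8 * 0.2 / n_mf)
  expect_lt(abs(r$recall - 0.8), 3 * se)
  expect_equal(r$precision, 1)
})

test_that("ICC(3,k) matches the ANOVA oracle and satisfies the Spearman-Brown identity", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  fit <- icc_avg_fixed_raters(m)
  want <- aov_icc3(m)
  expect_equal(fit$icc_k, want$icc_k, tolerance = 1e-12)
  expect_equal(fit$icc_1, want$icc_1, tolerance = 1e-12)

  # identical columns -> perfect reliability
  same <- cbind(1:7, 1:7, 1:7)
  expect_equal(icc_avg_fixed_raters(same)$icc_k, 1)

  # Spearman-Brown identity on random matrices
  set.seed(123)
  for (i in 1:25) {
    mm <- matrix(rpois(8 * 4, 10) + rnorm(32, 0, 0.5), 8, 4)
    f <- icc_avg_fixed_raters(mm)
    k <- f$k
    sb <- k * f$icc_1 / (1 + (k - 1) * f$icc_1)
    expect_equal(f$icc_k, sb, tolerance = 1e-10)
  }

  expect_error(icc_avg_fixed_raters(matrix(5, 4, 3)), "between-target")
  expect_error(icc_avg_fixed_raters(m[1, , drop = FALSE]), "at least 2")
})

test_that("Fleiss' kappa is 1 under perfect agreement and invariant to category relabeling", {
  perfect <- cbind(c(3, 0, 3, 0), c(0, 3, 0, 3))
  expect_equal(fleiss_kappa(perfect), 1)

  set.seed(5)
  r <- t(stats::rmultinom(30, 4, c(0.3, 0.5, 0.2)))
  expect_equal(fleiss_kappa(r), fleiss_kappa(r[, c(2, 3, 1)]))

  expect_error(fleiss_kappa(rbind(c(2, 1), c(3, 1))), "same number of raters")
  expect_error(fleiss_kappa(cbind(c(3, 3), c(0, 0))), "single category")

  v <- list(c("a", "a", "b"), c("b", "b", "b"))
  counts <- verdicts_to_counts(v)
  expect_equal(dim(counts), c(2, 2))
  expect_equal(unname(rowSums(counts)), c(3, 3))
})

test_that("the paired protocol reports t, Shapiro-Wilk normality and Bonferroni-adjusted significance", {
  x <- c(0.5, 0.55, 0.48, 0.61, 0.52, 0.58, 0.49, 0.54, 0.51, 0.56, 0.5, 0.53, 0.52)
  same <- paired_metric_test(x, x, n_tests = 3)
  expect_true(is.na(same$t))
  expect_false(same$significant)

  set.seed(9)
  y <- x + 1 + rnorm(13, 0, 0.1)
  r <- paired_metric_test(x, y, n_tests = 3)
  expect_equal(r$df, 12)  # thirteen raters give t(12)
  expect_true(r$significant)
  expect_equal(r$alpha_adjusted, 0.05 / 3)
  td <- tidy(r)
  expect_true(all(c("statistic", "shapiro_p", "alpha_adjusted") %in% names(td)))

  # agreement with the stock implementations it wraps
  expect_equal(r$t, unname(t.test(x, y, paired = TRUE)$statistic))
  expect_equal(r$shapiro_p, shapiro.test(y - x)$p.value)
})

test_that("the full agreement report carries per-rater rows for both phases", {
  study <- tiny_study()
  ag <- rater_agreement(study)
  expect_s3_class(ag, "agreement_report")
  expect_equal(nrow(ag), 13 * 2)
  expect_true(all(ag$f1 >= 0 & ag$f1 <= 1))
  g <- glance(ag)
  expect_equal(nrow(g), 2)
  cm <- mitotic_count_matrix(study, "P1")
  expect_equal(dim(cm), c(4, 13))
  expect_true(all(cm >= 0))
})
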