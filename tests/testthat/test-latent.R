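# Latent-space analysis: mapping network, TTA embedding, projection,
# majority-vote flags and highest-density regions.

fake_embedder <- list(embed = function(patch) {
  c(mean(patch), stats::sd(patch), mean(patch[, , 1]))
})

test_that("TTA allocation is round-robin, exact in total, and unaugmented for the first copy", {
  n <- 308
  cells <- tibble::tibble(cell_id = sprintf("c%03d", 1:n),
                          phase = rep(MITOTIC_PHASES_FOR_TESTS <- c(
                            "prophase", "metaphase", "telophase"), length.out = n))
  patches <- purrr::map(1:n, ~ array(runif(16 * 16 * 3), c(16, 16, 3)))
  es <- embed_with_tta(cells, patches, fake_embedder, n_total = 2000, seed = 2)
  expect_equal(nrow(es$meta), 2000)
  per_cell <- table(es$meta$cell_id)
  expect_true(all(per_cell %in% c(6, 7)))
  expect_equal(sum(per_cell), 2000)

  # identity at n_total = n: embeddings equal the direct ones
  es1 <- embed_with_tta(cells, patches, fake_embedder, n_total = n, seed = 2)
  direct <- t(vapply(patches, fake_embedder$embed, numeric(3)))
  expect_equal(unname(es1$embeddings), unname(direct))

  # determinism
  es2 <- embed_with_tta(cells, patches, fake_embedder, n_total = 2000, seed = 2)
  expect_identical(es$embeddings, es2$embeddings)

  expect_error(embed_with_tta(cells[0, ], list(), fake_embedder), "no cells")
  expect_error(embed_with_tta(cells, patches, fake_embedder, n_total = 10),
               "at least")
})

test_that("the mapping network separates distinct patch classes and embeds deterministically", {
  set.seed(6)
  n <- 60
  make_patch <- function(dark) {
    base <- array(runif(32 * 32 * 3, 0.7, 0.9), c(32, 32, 3))
    if (dark) base[12:20, 12:20, ] <- base[12:20, 12:20, ] * 0.2
    base
  }
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  patches <- purrr::map(labels, make_patch)
  net <- train_mapping_network(patches, labels, max_epochs = 4, seed = 3)
  expect_equal(length(net$embed(patches[[1]])), net$feature_width)
  expect_identical(net$embed(patches[[1]]), net$embed(patches[[1]]))

  # linear probe on held-out patches
  test_labels <- rep(c(TRUE, FALSE), 20)
  test_patches <- purrr::map(test_labels, make_patch)
  emb <- t(vapply(test_patches, net$embed, numeric(net$feature_width)))
  probe <- suppressWarnings(
    stats::glm.fit(cbind(1, emb), as.numeric(test_labels),
                   family = stats::binomial()))
  acc <- mean((probe$fitted.values > 0.5) == test_labels)
  expect_gt(acc, 0.95)
})

test_that("the 2-D projection is deterministic and preserves clear cluster structure", {
  set.seed(4)
  x <- rbind(matrix(rnorm(150 * 5, 0), ncol = 5),
             matrix(rnorm(150 * 5, 8), ncol = 5))
  p1 <- umap_project(x, seed = 7)
  expect_equal(dim(p1), c(300, 2))
  p2 <- umap_project(x, seed = 7)
  expect_identical(p1, p2)

  cl <- rep(1:2, each = 150)
  sil <- cluster::silhouette(cl, dist(p1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("majority-vote detection flags match a direct recount", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"),
                          image_id = "img_001",
                          x = c(10, 100, 200), y = c(10, 100, 200))
  hit <- function(x, y) tibble::tibble(image_id = "img_001", x = x, y = y)
  dets <- list(hit(c(10, 100), c(10, 100)),   # finds a, b
               hit(10, 10),                    # finds a
               hit(c(10, 200), c(10, 200)),   # finds a, c
               hit(numeric(0), numeric(0)),   # finds none
               hit(100, 100))                  # finds b
  flags <- tpfn_flags(cells, dets, 7.5, 0.25)
  # a: 3/5 -> TP; b: 2/5 -> FN; c: 1/5 -> FN
  expect_equal(flags, c(TRUE, FALSE, FALSE))

  # recount oracle
  recount <- vapply(seq_len(3), function(i) {
    votes <- vapply(dets, function(d) {
      any(sqrt((d$x - cells$x[i])^2 + (d$y - cells$y[i])^2) <= 30)
    }, logical(1))
    sum(votes) > 2.5
  }, logical(1))
  expect_equal(flags, recount)
})

test_that("the three-quartile region holds 75% mass and degrades gracefully", {
  set.seed(11)
  pts <- cbind(rnorm(2000), rnorm(2000))
  reg <- quartile_region(pts)
  held_out <- cbind(rnorm(4000), rnorm(4000))
  mass <- mean(region_contains(reg, held_out))
  expect_gte(mass, 0.72)
  expect_lte(mass, 0.78)

  # centroid of the enclosed points is near the distribution center
  expect_lt(sqrt(sum(reg$centroid^2)), 0.25)

  # a subsample's region stays inside a dilation of the full region:
  # every subsample boundary vertex is inside the full region or within a
  # modest tolerance of its boundary
  sub <- pts[sample(2000, 500), ]
  reg_sub <- quartile_region(sub)
  verts <- as.matrix(reg_sub$polygons[, c("x", "y")])
  inside <- region_contains(reg, verts)
  boundary <- as.matrix(reg$polygons[, c("x", "y")])
  near <- vapply(seq_len(nrow(verts)), function(i) {
    min(sqrt((boundary[, 1] - verts[i, 1])^2 +
               (boundary[, 2] - verts[i, 2])^2)) < 0.5
  }, logical(1))
  expect_true(all(inside | near))

  # degenerate input: all points identical
  same <- matrix(1, 10, 2)
  reg0 <- quartile_region(same)
  expect_true(reg0$degenerate)
  expect_equal(unname(reg0$centroid), c(1, 1))
})
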