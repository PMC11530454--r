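# Latent-space decision-boundary analysis: a mitosis-classification mapping
# network provides embeddings of cell patches; test-time augmentation
# densifies the embedded population; UMAP projects to 2-D; each cell is
# colored by whether the majority of cross-validation detectors found it;
# and the region holding three quartiles of each distribution is drawn from
# a 2-D kernel density estimate.

#' Extract a square patch centered on a cell
#'
#' @param img `(H, W, 3)` array.
#' @param x,y Cell center (0-based pixel coordinates).
#' @param size Patch side; areas outside the image are padded with the edge
#'   value.
#' @return `(size, size, 3)` array.
#' @export
extract_cell_patch <- function(img, x, y, size = 64) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  half <- size %/% 2
  rows <- pmin(pmax(round(y) + 1 + (-half):(half - 1) + 1, 1), h)
  cols <- pmin(pmax(round(x) + 1 + (-half):(half - 1) + 1, 1), w)
  img[rows, cols, , drop = FALSE]
}

#' Train the mapping network for latent-space analysis
#'
#' A compact convolutional classifier (mitotic figure versus not) trained
#' with the same augmentation pipeline as the detectors; on convergence
#' (validation loss, early stopping) the classification layer is discarded
#' and the global-average-pooled feature stem serves as the embedder.
#'
#' @param patches List of `(S, S, 3)` arrays.
#' @param labels Logical/0-1 vector (mitotic figure or not).
#' @param max_epochs,patience,lr,batch_size Training schedule.
#' @param val_fraction Fraction held out for the validation loss.
#' @param seed Seed.
#' @param verbose Print per-epoch losses.
#' @return A `mapping_network` with `$embed(patch)` returning a feature
#'   vector of length `$feature_width`.
#' @export
train_mapping_network <- function(patches, labels, max_epochs = 10,
                                  patience = 3, lr = 1e-3, batch_size = 8,
                                  val_fraction = 0.2, seed = 1L,
                                  verbose = FALSE) {
  stopifnot(length(patches) == length(labels))
  labels <- as.numeric(labels)
  arch <- backbone_arch("tiny")
  registry <- new_registry()
  with_seed(derive_seed(seed, "mapnet"), {
    stages <- build_backbone(arch, registry)
    fw_width <- arch$level_channels[3]
    fc <- make_conv(fw_width, 1, 1, 1, pad = 0, registry = registry)  # 1x1 head on pooled features
  })
  n <- length(patches)
  with_seed(derive_seed(seed, "mapsplit"), {
    val_idx <- sample(n, max(1, round(val_fraction * n)))
  })
  train_idx <- setdiff(seq_len(n), val_idx)

  forward_logit <- function(patch, keep_cache = FALSE) {
    bb <- backbone_fw(stages, arch, patch, keep = keep_cache)
    feat <- bb$levels[[3]]
    d <- dim(feat)
    pooled <- array(colMeans(matrix(feat, d[1] * d[2], d[3])), c(1, 1, d[3]))
    fcout <- conv_fw(fc, pooled)
    list(logit = fcout$y[1, 1, 1],
         cache = if (keep_cache) list(bb = bb, fcc = fcout$cache, d = d))
  }
  backward_logit <- function(cache, dlogit) {
    dpool <- conv_bw(fc, cache$fcc, array(dlogit, c(1, 1, 1)))
    d <- cache$d
    dfeat <- array(rep(as.vector(dpool) / (d[1] * d[2]), each = d[1] * d[2]), d)
    backbone_bw(stages, arch, cache$bb, list(NULL, NULL, dfeat))
  }

  val_loss <- function() {
    mean(purrr::map_dbl(val_idx, function(i) {
      z <- forward_logit(patches[[i]])$logit
      p <- min(max(sigmoid(z), 1e-7), 1 - 1e-7)
      -(labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
    }))
  }

  best <- Inf
  best_snap <- NULL
  stale <- 0L
  history <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    ord <- with_seed(derive_seed(seed, c("maporder", epoch)),
                     sample(train_idx))
    for (start in seq(1, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1, length(ord))]
      for (i in batch) {
        aug <- augment_patch(list(he = patches[[i]]),
                             tibble::tibble(x = numeric(), y = numeric()),
                             seed = derive_seed(seed, c("mapaug", epoch, i)))
        fwd <- forward_logit(aug$patches$he, keep_cache = TRUE)
        p <- min(max(sigmoid(fwd$logit), 1e-7), 1 - 1e-7)
        backward_logit(fwd$cache, (p - labels[i]) / length(batch))
      }
      adamw_step(registry, lr = lr)
    }
    vl <- val_loss()
    history <- c(history, vl)
    if (verbose) message(sprintf("mapping epoch %d: val loss %.4f", epoch, vl))
    if (vl < best) {
      best <- vl
      best_snap <- registry_snapshot(registry)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  if (!is.null(best_snap)) registry_restore(registry, best_snap)

  embed <- function(patch) {
    bb <- backbone_fw(stages, arch, patch, keep = FALSE)
    feat <- bb$levels[[3]]
    d <- dim(feat)
    colMeans(matrix(feat, d[1] * d[2], d[3]))
  }
  structure(list(embed = embed, feature_width = fw_width,
                 history = history, registry = registry),
            class = "mapping_network")
}

#' Embed cells with test-time augmentation
#'
#' Allocates `n_total` embedded representations round-robin across the cells
#' (with 308 cells and 2000 representations every cell gets 6 or 7): the
#' first representation of each cell is the unaugmented patch, the rest are
#' drawn from the training augmentation pipeline. Each representation keeps
#' its source cell's phase group and id.
#'
#' @param cells Tibble with `cell_id`, `phase` and patch-providing columns
#'   (see `patches`).
#' @param patches List of `(S, S, 3)` arrays aligned with `cells` rows.
#' @param embedder A `mapping_network`.
#' @param n_total Total number of representations (>= number of cells).
#' @param seed Seed for the augmentation draws.
#' @return An `embedding_set`: list with `meta` (tibble `cell_id`, `rep`,
#'   `phase`, `phase_group`) and `embeddings` (matrix, rows aligned with
#'   `meta`).
#' @export
embed_with_tta <- function(cells, patches, embedder, n_total = 2000, seed = 1L) {
  n <- nrow(cells)
  if (n == 0) abort("no cells to embed")
  if (n_total < n) abort("`n_total` must be at least the number of cells")
  base <- n_total %/% n
  extra <- n_total %% n
  reps <- rep(base, n) + (seq_len(n) <= extra)
  meta <- list()
  embs <- list()
  k <- 0L
  for (i in seq_len(n)) {
    for (r in seq_len(reps[i])) {
      k <- k + 1L
      patch <- if (r == 1) patches[[i]] else {
        augment_patch(list(he = patches[[i]]),
                      tibble::tibble(x = numeric(), y = numeric()),
                      seed = derive_seed(seed, c("tta", i, r)))$patches$he
      }
      embs[[k]] <- embedder$embed(patch)
      meta[[k]] <- tibble::tibble(cell_id = cells$cell_id[i], rep = r,
                                  phase = cells$phase[i])
    }
  }
  meta <- dplyr::bind_rows(meta)
  meta$phase_group <- phase_group(meta$phase)
  structure(list(meta = meta, embeddings = do.call(rbind, embs)),
            class = "embedding_set")
}

#' Project embeddings to two dimensions with UMAP
#'
#' Deterministic given the seed (single-threaded layout optimization). The
#' same projected coordinates are reused across all per-phase plots; only
#' the coloring changes.
#'
#' @param embeddings Numeric matrix (rows are representations) or an
#'   `embedding_set`.
#' @param seed Seed.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @return For a matrix: an n x 2 matrix. For an `embedding_set`: the set
#'   with a `projection` matrix added.
#' @export
umap_project <- function(embeddings, seed = 1L, n_neighbors = 15,
                         min_dist = 0.1) {
  m <- if (inherits(embeddings, "embedding_set")) embeddings$embeddings else embeddings
  proj <- with_seed(derive_seed(seed, "umap"), {
    uwot::umap(m, n_neighbors = min(n_neighbors, nrow(m) - 1),
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
               fast_sgd = FALSE)
  })
  colnames(proj) <- c("umap1", "umap2")
  if (inherits(embeddings, "embedding_set")) {
    embeddings$projection <- proj
    embeddings
  } else {
    proj
  }
}

#' Majority-vote detection flags across cross-validation models
#'
#' A cell is a true positive if more than half of the cross-validation
#' models produced a detection within the matching radius of it; otherwise
#' it is a false negative.
#'
#' @param cells Tibble with `cell_id`, `image_id`, `x`, `y`.
#' @param detections_by_model List (one element per model) of detection
#'   tibbles with `image_id`, `x`, `y`.
#' @param radius_um,mpp Matching radius.
#' @return Logical vector aligned with `cells` rows (TRUE = detected by the
#'   majority).
#' @export
tpfn_flags <- function(cells, detections_by_model, radius_um = 7.5, mpp = 0.25) {
  radius_px <- um_to_px(radius_um, mpp)
  votes <- purrr::map(detections_by_model, function(dets) {
    purrr::map_lgl(seq_len(nrow(cells)), function(i) {
      d <- dets[dets$image_id == cells$image_id[i], ]
      if (!nrow(d)) return(FALSE)
      min(sqrt((d$x - cells$x[i])^2 + (d$y - cells$y[i])^2)) <= radius_px
    })
  })
  Reduce(`+`, votes) > length(detections_by_model) / 2
}

#' Region containing three quartiles of a 2-D point distribution
#'
#' Highest-density region of a Gaussian kernel density estimate holding 75%
#' of the probability mass, returned as contour polygon(s). Degenerate
#' inputs (fewer than 3 distinct points) collapse to a point region.
#'
#' @param points Two-column matrix or tibble of 2-D coordinates.
#' @param mass Probability mass to enclose.
#' @param grid_n KDE grid resolution.
#' @return A `density_region`: list with `polygons` (tibble `piece`, `x`,
#'   `y`), `level`, `mass`, and `centroid` (mean of the enclosed points).
#' @export
quartile_region <- function(points, mass = 0.75, grid_n = 120) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  ok <- stats::complete.cases(pts)
  pts <- pts[ok, , drop = FALSE]
  distinct <- unique(round(pts, 10))
  if (nrow(distinct) < 3 || any(apply(pts, 2, stats::sd) < 1e-12)) {
    cen <- colMeans(pts)
    return(structure(list(
      polygons = tibble::tibble(piece = 1L, x = cen[1], y = cen[2]),
      level = Inf, mass = mass, centroid = cen, degenerate = TRUE),
      class = "density_region"))
  }
  pad_x <- diff(range(pts[, 1])) * 0.25 + 1e-9
  pad_y <- diff(range(pts[, 2])) * 0.25 + 1e-9
  kde <- MASS::kde2d(pts[, 1], pts[, 2], n = grid_n,
                     lims = c(range(pts[, 1]) + c(-pad_x, pad_x),
                              range(pts[, 2]) + c(-pad_y, pad_y)))
  cell_area <- diff(kde$x[1:2]) * diff(kde$y[1:2])
  dens <- sort(as.vector(kde$z), decreasing = TRUE)
  cum_mass <- cumsum(dens * cell_area)
  total <- sum(dens * cell_area)
  level <- dens[which(cum_mass >= mass * total)[1]]
  cl <- grDevices::contourLines(kde$x, kde$y, kde$z, levels = level)
  polygons <- purrr::imap(cl, function(p, i) {
    tibble::tibble(piece = i, x = p$x, y = p$y)
  }) |> dplyr::bind_rows()
  inside <- region_contains(polygons, pts)
  structure(list(polygons = polygons, level = level, mass = mass,
                 centroid = colMeans(pts[inside, , drop = FALSE]),
                 degenerate = FALSE),
            class = "density_region")
}

#' Test whether points fall inside a density region
#'
#' Even-odd ray-casting point-in-polygon over all contour pieces.
#'
#' @param region A `density_region` or its `polygons` tibble.
#' @param points Two-column matrix of coordinates.
#' @return Logical vector.
#' @export
region_contains <- function(region, points) {
  polys <- if (inherits(region, "density_region")) region$polygons else region
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (!nrow(polys)) return(rep(FALSE, nrow(pts)))
  inside <- rep(FALSE, nrow(pts))
  for (pc in unique(polys$piece)) {
    poly <- polys[polys$piece == pc, ]
    nv <- nrow(poly)
    if (nv < 3) next
    px <- poly$x
    py <- poly$y
    jj <- c(nv, seq_len(nv - 1))
    for (i in seq_len(nrow(pts))) {
      x <- pts[i, 1]
      y <- pts[i, 2]
      crossings <- (py > y) != (py[jj] > y)
      if (!any(crossings)) next
      xs <- px[crossings] + (y - py[crossings]) /
        (py[jj][crossings] - py[crossings]) *
        (px[jj][crossings] - px[crossings])
      if (sum(xs > x) %% 2 == 1) inside[i] <- !inside[i]
    }
  }
  inside
}

#' Latent-space decision-boundary shift analysis
#'
#' End-to-end reproduction of the boundary-shift experiment on a synthetic
#' study: embeds the PHH3-assisted consensus cells with test-time
#' augmentation, projects them with UMAP once, flags each cell as detected
#' or missed by the majority of the cross-validation detectors trained under
#' each labeling condition, and measures, per mitotic phase group, how far
#' the centroid of the false-negative 75% region moves between the two
#' trainings.
#'
#' @param embedding_set An `embedding_set` with `projection` (see
#'   [umap_project()]).
#' @param flags_by_condition Named list (condition -> logical vector aligned
#'   with the *cells*, TRUE = detected) as from [tpfn_flags()].
#' @param cells Tibble aligned with the flag vectors (`cell_id`, `phase`).
#' @return Tibble with per phase-group FN-region centroids per condition and
#'   the centroid shift between conditions.
#' @export
latent_boundary_shift <- function(embedding_set, flags_by_condition, cells) {
  stopifnot(!is.null(embedding_set$projection))
  conds <- names(flags_by_condition)
  stopifnot(length(conds) == 2)
  meta <- embedding_set$meta
  rows <- list()
  for (grp in PHASE_GROUPS) {
    cen <- list()
    for (cond in conds) {
      flags <- flags_by_condition[[cond]]
      fn_cells <- cells$cell_id[!flags]
      sel <- meta$cell_id %in% fn_cells & !is.na(meta$phase_group) &
        meta$phase_group == grp
      if (sum(sel) < 3) {
        cen[[cond]] <- c(NA_real_, NA_real_)
        next
      }
      reg <- quartile_region(embedding_set$projection[sel, , drop = FALSE])
      cen[[cond]] <- reg$centroid
    }
    shift <- sqrt(sum((cen[[1]] - cen[[2]])^2))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      phase_group = grp,
      cx_1 = cen[[1]][1], cy_1 = cen[[1]][2],
      cx_2 = cen[[2]][1], cy_2 = cen[[2]][2],
      shift = shift)
  }
  out <- dplyr::bind_rows(rows)
  names(out)[2:5] <- c(paste0(c("cx_", "cy_"), conds[1]),
                       paste0(c("cx_", "cy_"), conds[2]))
  out
}

#' Attribute label-set points to ground-truth cells
#'
#' Matches each consensus point to the nearest ground-truth cell of its image
#' within the radius, keeping mitotic cells only (the cells whose phase is
#' defined).
#'
#' @param study A `study_dataset`.
#' @param points Label tibble (`image_id`, `x`, `y`).
#' @param radius_um,mpp Matching radius.
#' @return Cell tibble (subset of `study$cells`, deduplicated).
#' @export
cells_for_points <- function(study, points, radius_um = 7.5, mpp = NULL) {
  mpp <- mpp %||% study$config$mpp
  radius_px <- um_to_px(radius_um, mpp)
  ids <- purrr::map_chr(seq_len(nrow(points)), function(i) {
    cc <- study$cells[study$cells$image_id == points$image_id[i], ]
    d <- sqrt((cc$x - points$x[i])^2 + (cc$y - points$y[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= radius_px) cc$cell_id[j] else NA_character_
  })
  cells <- study$cells[match(unique(stats::na.omit(ids)), study$cells$cell_id), ]
  cells[cells$is_mf, ]
}

#' End-to-end latent decision-boundary analysis on a synthetic study
#'
#' Trains single-stain detectors under both labeling conditions (H&E-only
#' and PHH3-assisted consensus) across `n_cv` Monte-Carlo splits, flags every
#' analyzed cell as detected-by-majority or missed per condition, embeds the
#' cells with a mitosis-classification mapping network plus test-time
#' augmentation, projects once with UMAP, and measures the per-phase-group
#' centroid shift of the missed-cell 75% density regions between the two
#' conditions.
#'
#' @param study A `study_dataset`.
#' @param label_sets List with `he_only_labels` and `phh3_assisted_labels`.
#' @param n_cv Number of Monte-Carlo splits (= cross-validation detectors
#'   per condition).
#' @param detector_config Configuration for the single-stain detectors.
#' @param n_total Total TTA representations (raised internally to at least
#'   one per analyzed cell).
#' @param patch_size Cell patch side for the mapping network.
#' @param flag_score_threshold Operating score threshold used when deciding
#'   whether a model detected a cell. `NULL` (default) calibrates it per
#'   model as the F1-maximizing threshold on the model's validation images
#'   against its training label set.
#' @param mapping_network Optional pre-trained [train_mapping_network()]
#'   result to reuse (the analysis design uses a single mapping network;
#'   repeated runs can share it).
#' @param seed Seed for everything downstream.
#' @param cache Optional shared image cache.
#' @return List: `shifts` (tibble per phase group), `embedding_set`,
#'   `flags_by_condition`, `cells`.
#' @export
run_latent_analysis <- function(study, label_sets, n_cv = 2,
                                detector_config = desk_detector_config("single"),
                                n_total = 2000, patch_size = 48,
                                flag_score_threshold = NULL, seed = 1L,
                                mapping_network = NULL, cache = NULL) {
  if (is.null(cache)) cache <- new_image_cache()
  mpp <- study$config$mpp
  splits <- monte_carlo_splits(study$image_ids, n_splits = n_cv,
                               seed = derive_seed(seed, "latentsplits"))

  # analyzed cells: PHH3-assisted consensus points attributed to true cells
  cells <- cells_for_points(study, label_sets$phh3_assisted_labels, 7.5, mpp)
  # at least one representation per cell
  n_total <- max(n_total, nrow(cells))

  # detectors and their whole-image detections per labeling condition
  conditions <- c(he = "he_only_labels", phh3 = "phh3_assisted_labels")
  flags <- purrr::map(conditions, function(lsname) {
    dets_by_model <- purrr::map(seq_len(n_cv), function(s) {
      det <- train_detector(study, label_sets[[lsname]],
                            train_ids = split_ids(splits, s, "train"),
                            val_ids = split_ids(splits, s, "val"),
                            config = detector_config,
                            seed = derive_seed(seed, c("latentdet", lsname, s)),
                            cache = cache)
      dets <- purrr::map(study$image_ids, function(id) {
        d <- tiled_inference(det, cache_get(cache, study, id))
        d$image_id <- id
        d
      }) |> dplyr::bind_rows()
      thr <- flag_score_threshold
      if (is.null(thr)) {
        val_ids <- split_ids(splits, s, "val")
        thr <- best_f1_threshold(
          dets[dets$image_id %in% val_ids, ],
          label_sets[[lsname]][label_sets[[lsname]]$image_id %in% val_ids, ],
          7.5, mpp)
      }
      dets[dets$score >= thr, ]
    })
    tpfn_flags(cells, dets_by_model, 7.5, mpp)
  })
  names(flags) <- names(conditions)

  # mapping network trained on study patches (mitotic vs not)
  net <- mapping_network
  if (is.null(net)) {
    train_cells <- study$cells
    lbl <- train_cells$is_mf & train_cells$he_visible
    neg <- which(!train_cells$is_mf)
    pos <- which(lbl)
    sel <- with_seed(derive_seed(seed, "mapsel"), {
      pos <- if (length(pos) > 300) sample(pos, 300) else pos
      c(pos, sample(neg, min(length(neg), length(pos))))
    })
    patches <- purrr::map(sel, function(i) {
      pair <- cache_get(cache, study, train_cells$image_id[i])
      as_double_img(extract_cell_patch(pair$he, train_cells$x[i],
                                       train_cells$y[i], patch_size))
    })
    net <- train_mapping_network(patches, lbl[sel], max_epochs = 6,
                                 seed = derive_seed(seed, "mapnet"))
  }

  cell_patches <- purrr::map(seq_len(nrow(cells)), function(i) {
    pair <- cache_get(cache, study, cells$image_id[i])
    as_double_img(extract_cell_patch(pair$he, cells$x[i], cells$y[i], patch_size))
  })
  es <- embed_with_tta(cells, cell_patches, net, n_total = n_total,
                       seed = derive_seed(seed, "tta"))
  es <- umap_project(es, seed = derive_seed(seed, "umap"))

  shifts <- latent_boundary_shift(es, flags, cells)
  list(shifts = shifts, embedding_set = es, flags_by_condition = flags,
       cells = cells, mapping_network = net)
}
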