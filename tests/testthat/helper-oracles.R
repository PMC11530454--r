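# Independent oracles used across the suite. Each reimplements the rule it
# checks in a deliberately naive way, sharing no code with the package paths
# it validates.

# Brute-force executor of the ordered greedy clustering rule: process
# annotations sorted by (rater_id, x, y); join the nearest cluster whose
# current centroid (arithmetic mean of members) is within the radius and
# that has no member of the same rater, ties toward the lowest cluster
# index; otherwise open a new cluster.
brute_force_clustering <- function(ann, radius_um, mpp) {
  radius_px <- radius_um / mpp
  ord <- order(ann$rater_id, ann$x, ann$y)
  clusters <- list()  # each: list(members = integer row indices)
  for (i in ord) {
    best <- 0
    best_d <- Inf
    for (k in seq_along(clusters)) {
      members <- clusters[[k]]
      if (ann$rater_id[i] %in% ann$rater_id[members]) next
      cxy <- c(mean(ann$x[members]), mean(ann$y[members]))
      d <- sqrt((cxy[1] - ann$x[i])^2 + (cxy[2] - ann$y[i])^2)
      if (d <= radius_px && d < best_d) {
        best <- k
        best_d <- d
      }
    }
    if (best == 0) {
      clusters[[length(clusters) + 1]] <- i
    } else {
      clusters[[best]] <- c(clusters[[best]], i)
    }
  }
  clusters
}

# Maximum-cardinality bipartite matching size between two point sets under a
# radius constraint, via igraph.
max_matching_size <- function(pred, ref, radius_px) {
  np <- nrow(pred)
  nr <- nrow(ref)
  if (np == 0 || nr == 0) return(0L)
  d <- sqrt(outer(pred$x, ref$x, "-")^2 + outer(pred$y, ref$y, "-")^2)
  edges <- which(d <= radius_px, arr.ind = TRUE)
  if (!nrow(edges)) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, nr)),
    edges = as.vector(t(cbind(edges[, 1], np + edges[, 2]))))
  igraph::max_bipartite_match(g)$matching_size
}

# Direct precision-recall enumeration for ranked detections matched by
# nearest-unmatched ground truth within a radius, with all-point
# interpolation; mirrors the definition, not the implementation.
brute_force_ap <- function(det, gt, radius_px) {
  ord <- order(-det$score)
  used <- rep(FALSE, nrow(gt))
  tp <- numeric(0)
  for (k in ord) {
    match_found <- FALSE
    if (any(!used)) {
      idx <- which(!used)
      dd <- sqrt((gt$x[idx] - det$x[k])^2 + (gt$y[idx] - det$y[k])^2)
      if (min(dd) <= radius_px) {
        used[idx[which.min(dd)]] <- TRUE
        match_found <- TRUE
      }
    }
    tp <- c(tp, match_found)
  }
  n_gt <- nrow(gt)
  rec <- cumsum(tp) / n_gt
  prec <- cumsum(tp) / seq_along(tp)
  # interpolated precision at each achieved recall level
  ap <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    p_int <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_int
    prev_r <- rec[i]
  }
  ap
}

# Two-way ANOVA mean squares via stats::aov for the ICC oracle.
aov_icc3 <- function(counts) {
  df <- data.frame(
    y = as.vector(counts),
    target = factor(rep(seq_len(nrow(counts)), ncol(counts))),
    rater = factor(rep(seq_len(ncol(counts)), each = nrow(counts)))
  )
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  ms_t <- tab["target", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  k <- ncol(counts)
  list(icc_k = (ms_t - ms_e) / ms_t,
       icc_1 = (ms_t - ms_e) / (ms_t + (k - 1) * ms_e))
}

# Small study fixture shared across tests.
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config(n_images = 4, image_size_px = 256,
                          mitotic_per_image = 14, nonmitotic_per_image = 18,
                          lookalike_per_image = 5, rng_seed = 42)
      cache <<- generate_study(cfg)
    }
    cache
  }
})
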