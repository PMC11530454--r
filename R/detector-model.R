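# Anchor-free detection models: a single-stain fully convolutional one-stage
# detector and its dual-input variant with per-level mid-fusion of the H&E
# and PHH3 feature branches, F = ReLU(Conv1x1(LayerNorm(Cat(H, P)))) with the
# 1x1 convolution halving the concatenated channels.

#' Detector configuration
#'
#' @param mode `"single"` (H&E only) or `"dual"` (H&E + PHH3 mid-fusion).
#' @param backbone `"tiny"` (compact 3-level backbone for desk-scale work),
#'   `"resnet18"` or `"resnet101"` (standard residual layouts; the feature
#'   pyramid is built from backbone blocks 2-4).
#' @param patch_size Training patch side in pixels (divisible by the total
#'   backbone stride).
#' @param mf_patch_fraction Minimum fraction of training patches containing
#'   at least one labeled mitotic figure.
#' @param box_size_px Side of the square box a point label is converted to.
#' @param score_threshold Minimum detection score kept at inference.
#' @param nms_iou IoU threshold of the global non-maximum suppression.
#' @param lr AdamW learning rate.
#' @param patience Early-stopping patience, in validation evaluations.
#' @param min_epochs Burn-in: epochs before this do not provide checkpoint
#'   candidates and do not count toward patience (validation AP estimates
#'   from a barely-trained model are too noisy to select on).
#' @param max_epochs Upper bound on training epochs.
#' @param warmup_steps Optimizer steps over which the learning rate ramps
#'   linearly from zero (0 disables warmup).
#' @param restart_floor Validation-AP floor under which a finished training
#'   run is considered diverged and restarted once from a reseeded
#'   initialization (the better run by validation AP is kept). 0 disables
#'   restarts.
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param batch_size Patches per optimizer step.
#' @param level_ranges Regression-range breakpoints (pixels) assigning boxes
#'   to pyramid levels.
#' @param fpn_channels,head_convs Feature-pyramid width and head tower depth
#'   (defaults depend on the backbone).
#' @param cls_prior Initial foreground probability encoded in the
#'   classification bias (focal-loss prior initialization).
#' @param pretrained Accepted for interface compatibility; the package ships
#'   no pretrained weights and trains from random initialization.
#' @param seed Seed controlling weight initialization and patch sampling.
#' @return A `detector_config` list.
#' @export
detector_config <- function(mode = c("single", "dual"),
                            backbone = c("tiny", "resnet18", "resnet101"),
                            patch_size = 128,
                            mf_patch_fraction = 0.5,
                            box_size_px = 50,
                            score_threshold = 0.05,
                            nms_iou = 0.3,
                            lr = 1e-4,
                            patience = 5,
                            min_epochs = 4,
                            warmup_steps = 0,
                            restart_floor = 0.35,
                            max_epochs = 8,
                            steps_per_epoch = 30,
                            batch_size = 4,
                            level_ranges = c(0, 24, 48, Inf),
                            fpn_channels = NULL,
                            head_convs = NULL,
                            cls_prior = 0.01,
                            pretrained = FALSE,
                            seed = 1L) {
  mode <- match.arg(mode)
  backbone <- match.arg(backbone)
  if (is.null(fpn_channels)) fpn_channels <- if (backbone == "tiny") 16 else 256
  if (is.null(head_convs)) head_convs <- if (backbone == "tiny") 1 else 4
  strides <- switch(backbone, tiny = c(4L, 8L, 16L),
                    resnet18 = c(8L, 16L, 32L), resnet101 = c(8L, 16L, 32L))
  if (patch_size %% max(strides) != 0) {
    abort(sprintf("patch_size must be divisible by the total stride (%d)",
                  max(strides)))
  }
  structure(list(mode = mode, backbone = backbone, patch_size = patch_size,
                 mf_patch_fraction = mf_patch_fraction,
                 box_size_px = box_size_px, score_threshold = score_threshold,
                 nms_iou = nms_iou, lr = lr, patience = patience,
                 min_epochs = min_epochs,
                 warmup_steps = warmup_steps, restart_floor = restart_floor,
                 max_epochs = max_epochs, steps_per_epoch = steps_per_epoch,
                 batch_size = batch_size, level_ranges = level_ranges,
                 fpn_channels = fpn_channels, head_convs = head_convs,
                 cls_prior = cls_prior,
                 strides = strides, pretrained = pretrained,
                 seed = as.integer(seed)),
            class = "detector_config")
}

# --- architecture descriptors ---------------------------------------------

backbone_arch <- function(name) {
  switch(name,
    tiny = list(
      stages = list(
        list(list(kind = "plain", cin = 3, cout = 6, k = 3, stride = 2)),
        list(list(kind = "plain", cin = 6, cout = 12, k = 3, stride = 2),
             list(kind = "plain", cin = 12, cout = 12, k = 3, stride = 1)),
        list(list(kind = "plain", cin = 12, cout = 24, k = 3, stride = 2),
             list(kind = "plain", cin = 24, cout = 24, k = 3, stride = 1)),
        list(list(kind = "plain", cin = 24, cout = 48, k = 3, stride = 2),
             list(kind = "plain", cin = 48, cout = 48, k = 3, stride = 1))
      ),
      level_stages = c(2, 3, 4), level_channels = c(12, 24, 48)
    ),
    resnet18 = list(
      stages = c(
        list(list(list(kind = "plain", cin = 3, cout = 64, k = 7, stride = 2),
                  list(kind = "maxpool", k = 3, stride = 2))),
        list(resnet_stage("basic", 64, 64, 2, 1),
             resnet_stage("basic", 64, 128, 2, 2),
             resnet_stage("basic", 128, 256, 2, 2),
             resnet_stage("basic", 256, 512, 2, 2))
      ),
      level_stages = c(3, 4, 5), level_channels = c(128, 256, 512)
    ),
    resnet101 = list(
      stages = c(
        list(list(list(kind = "plain", cin = 3, cout = 64, k = 7, stride = 2),
                  list(kind = "maxpool", k = 3, stride = 2))),
        list(resnet_stage("bottleneck", 64, 256, 3, 1),
             resnet_stage("bottleneck", 256, 512, 4, 2),
             resnet_stage("bottleneck", 512, 1024, 23, 2),
             resnet_stage("bottleneck", 1024, 2048, 3, 2))
      ),
      level_stages = c(3, 4, 5), level_channels = c(512, 1024, 2048)
    ),
    abort(sprintf("unknown backbone '%s'", name))
  )
}

resnet_stage <- function(kind, cin, cout, n_blocks, first_stride) {
  purrr::map(seq_len(n_blocks), function(i) {
    list(kind = kind,
         cin = if (i == 1) cin else cout,
         cout = cout,
         stride = if (i == 1) first_stride else 1)
  })
}

# --- block instantiation / forward / backward ------------------------------

build_block <- function(spec, registry) {
  b <- list(kind = spec$kind, spec = spec)
  if (spec$kind == "plain") {
    b$conv <- make_conv(spec$cin, spec$cout, spec$k, spec$stride, registry = registry)
    b$ln <- make_layernorm(spec$cout, registry)
  } else if (spec$kind == "maxpool") {
    b$pool <- make_maxpool(spec$k, spec$stride, pad = 1)
  } else if (spec$kind == "basic") {
    b$conv1 <- make_conv(spec$cin, spec$cout, 3, spec$stride, registry = registry)
    b$ln1 <- make_layernorm(spec$cout, registry)
    b$conv2 <- make_conv(spec$cout, spec$cout, 3, 1, registry = registry)
    b$ln2 <- make_layernorm(spec$cout, registry)
    if (spec$stride != 1 || spec$cin != spec$cout) {
      b$proj <- make_conv(spec$cin, spec$cout, 1, spec$stride, pad = 0, registry = registry)
      b$lnp <- make_layernorm(spec$cout, registry)
    }
  } else if (spec$kind == "bottleneck") {
    mid <- spec$cout %/% 4
    b$conv1 <- make_conv(spec$cin, mid, 1, 1, pad = 0, registry = registry)
    b$ln1 <- make_layernorm(mid, registry)
    b$conv2 <- make_conv(mid, mid, 3, spec$stride, registry = registry)
    b$ln2 <- make_layernorm(mid, registry)
    b$conv3 <- make_conv(mid, spec$cout, 1, 1, pad = 0, registry = registry)
    b$ln3 <- make_layernorm(spec$cout, registry)
    if (spec$stride != 1 || spec$cin != spec$cout) {
      b$proj <- make_conv(spec$cin, spec$cout, 1, spec$stride, pad = 0, registry = registry)
      b$lnp <- make_layernorm(spec$cout, registry)
    }
  }
  b
}

block_fw <- function(b, x, keep = TRUE) {
  if (b$kind == "plain") {
    c1 <- conv_fw(b$conv, x, keep)
    n1 <- lnrelu_fw(b$ln, c1$y)
    return(list(y = n1$y, cache = list(c1 = c1$cache, n1 = n1$cache)))
  }
  if (b$kind == "maxpool") {
    p <- maxpool_fw(b$pool, x)
    return(list(y = p$y, cache = p$cache))
  }
  if (b$kind == "basic") {
    c1 <- conv_fw(b$conv1, x, keep); n1 <- lnrelu_fw(b$ln1, c1$y)
    c2 <- conv_fw(b$conv2, n1$y, keep); n2 <- ln_fw(b$ln2, c2$y)
    if (!is.null(b$proj)) {
      cp <- conv_fw(b$proj, x, keep); np <- ln_fw(b$lnp, cp$y)
      skip <- np$y
      pc <- list(cp = cp$cache, np = np$cache)
    } else {
      skip <- x
      pc <- NULL
    }
    ro <- relu_fw(n2$y + skip)
    return(list(y = ro$y, cache = list(c1 = c1$cache, n1 = n1$cache,
                                       c2 = c2$cache, n2 = n2$cache, p = pc,
                                       mo = ro$cache)))
  }
  if (b$kind == "bottleneck") {
    c1 <- conv_fw(b$conv1, x, keep); n1 <- lnrelu_fw(b$ln1, c1$y)
    c2 <- conv_fw(b$conv2, n1$y, keep); n2 <- lnrelu_fw(b$ln2, c2$y)
    c3 <- conv_fw(b$conv3, n2$y, keep); n3 <- ln_fw(b$ln3, c3$y)
    if (!is.null(b$proj)) {
      cp <- conv_fw(b$proj, x, keep); np <- ln_fw(b$lnp, cp$y)
      skip <- np$y; pc <- list(cp = cp$cache, np = np$cache)
    } else {
      skip <- x; pc <- NULL
    }
    ro <- relu_fw(n3$y + skip)
    return(list(y = ro$y, cache = list(c1 = c1$cache, n1 = n1$cache,
                                       c2 = c2$cache, n2 = n2$cache,
                                       c3 = c3$cache, n3 = n3$cache, p = pc,
                                       mo = ro$cache)))
  }
  abort("unknown block kind")
}

block_bw <- function(b, cache, dy, want_dx = TRUE) {
  if (b$kind == "plain") {
    d <- lnrelu_bw(b$ln, cache$n1, dy)
    return(conv_bw(b$conv, cache$c1, d, want_dx))
  }
  if (b$kind == "maxpool") {
    return(maxpool_bw(b$pool, cache, dy))
  }
  if (b$kind == "basic") {
    dsum <- relu_bw(cache$mo, dy)
    d2 <- ln_bw(b$ln2, cache$n2, dsum)
    d2 <- conv_bw(b$conv2, cache$c2, d2)
    d1 <- lnrelu_bw(b$ln1, cache$n1, d2)
    dx1 <- conv_bw(b$conv1, cache$c1, d1, want_dx)
    if (!is.null(b$proj)) {
      dp <- ln_bw(b$lnp, cache$p$np, dsum)
      dxp <- conv_bw(b$proj, cache$p$cp, dp, want_dx)
    } else {
      dxp <- dsum
    }
    if (!want_dx) return(NULL)
    return(dx1 + dxp)
  }
  if (b$kind == "bottleneck") {
    dsum <- relu_bw(cache$mo, dy)
    d3 <- ln_bw(b$ln3, cache$n3, dsum)
    d3 <- conv_bw(b$conv3, cache$c3, d3)
    d2 <- lnrelu_bw(b$ln2, cache$n2, d3)
    d2 <- conv_bw(b$conv2, cache$c2, d2)
    d1 <- lnrelu_bw(b$ln1, cache$n1, d2)
    dx1 <- conv_bw(b$conv1, cache$c1, d1, want_dx)
    if (!is.null(b$proj)) {
      dp <- ln_bw(b$lnp, cache$p$np, dsum)
      dxp <- conv_bw(b$proj, cache$p$cp, dp, want_dx)
    } else {
      dxp <- dsum
    }
    if (!want_dx) return(NULL)
    return(dx1 + dxp)
  }
  abort("unknown block kind")
}

build_backbone <- function(arch, registry) {
  purrr::map(arch$stages, function(stage) purrr::map(stage, build_block, registry = registry))
}

# A backbone consisting solely of plain conv+LN+ReLU blocks runs as one
# fused C++ chain; residual architectures use the generic block path.
backbone_is_plain_chain <- function(stages) {
  all(purrr::map_lgl(unlist(stages, recursive = FALSE),
                     ~ identical(.x$kind, "plain")))
}

plainseq_params <- function(stages) {
  blocks <- unlist(stages, recursive = FALSE)
  purrr::map(blocks, function(b) {
    list(w = b$conv$w, b = b$conv$b, gamma = b$ln$w, beta = b$ln$b,
         k = b$conv$k, stride = b$conv$stride, pad = b$conv$pad)
  })
}

plainseq_level_after <- function(arch) {
  n_per_stage <- purrr::map_int(arch$stages, length)
  cumsum(n_per_stage)[arch$level_stages]
}

# Forward through all stages; returns the three pyramid-level inputs.
backbone_fw <- function(stages, arch, x, keep = TRUE) {
  if (backbone_is_plain_chain(stages)) {
    out <- cpp_plainseq_fwd(x, plainseq_params(stages),
                            plainseq_level_after(arch), keep)
    return(list(levels = out$levels, caches = out$caches, fast = TRUE))
  }
  caches <- vector("list", length(stages))
  outs <- vector("list", length(stages))
  h <- x
  for (s in seq_along(stages)) {
    sc <- vector("list", length(stages[[s]]))
    for (bi in seq_along(stages[[s]])) {
      r <- block_fw(stages[[s]][[bi]], h, keep)
      h <- r$y
      sc[[bi]] <- r$cache
    }
    caches[[s]] <- sc
    outs[[s]] <- h
  }
  list(levels = outs[arch$level_stages], caches = caches, outs = outs)
}

# Backward with per-stage upstream gradients (dlevels for the level stages).
backbone_bw <- function(stages, arch, cache, dlevels) {
  if (isTRUE(cache$fast)) {
    grads <- cpp_plainseq_bwd(plainseq_params(stages), cache$caches, dlevels,
                              plainseq_level_after(arch))
    blocks <- unlist(stages, recursive = FALSE)
    for (b in seq_along(blocks)) {
      g <- grads[[b]]
      if (is.null(g)) next
      blocks[[b]]$conv$gw <- blocks[[b]]$conv$gw + g$dw
      blocks[[b]]$conv$gb <- blocks[[b]]$conv$gb + as.vector(g$db)
      blocks[[b]]$ln$gw <- blocks[[b]]$ln$gw + as.vector(g$dgamma)
      blocks[[b]]$ln$gb <- blocks[[b]]$ln$gb + as.vector(g$dbeta)
    }
    return(invisible(NULL))
  }
  n_stages <- length(stages)
  dstage <- vector("list", n_stages)
  for (k in seq_along(arch$level_stages)) {
    s <- arch$level_stages[k]
    dstage[[s]] <- dlevels[[k]]
  }
  dnext <- NULL
  for (s in rev(seq_len(n_stages))) {
    d <- dnext
    if (!is.null(dstage[[s]])) d <- if (is.null(d)) dstage[[s]] else d + dstage[[s]]
    if (is.null(d)) next
    for (bi in rev(seq_along(stages[[s]]))) {
      want_dx <- !(s == 1 && bi == 1)
      d <- block_bw(stages[[s]][[bi]], cache$caches[[s]][[bi]], d, want_dx)
    }
    dnext <- d
  }
  invisible(NULL)
}

# --- fusion ----------------------------------------------------------------

build_fusion <- function(level_channels, registry) {
  purrr::map(level_channels, function(C) {
    conv <- make_conv(2 * C, C, 1, 1, pad = 0, registry = registry)
    # residual-style conditioning: start as a pass-through of the PHH3 half
    # plus small random mixing of the H&E half, so the marker pathway (the
    # dual detector's distinctive information source) is active from the
    # first step while the fusion remains order-sensitive and trainable
    conv$w <- conv$w * 0.3
    conv$w[C + seq_len(C), ] <- conv$w[C + seq_len(C), ] + diag(C)
    list(ln = make_layernorm(2 * C, registry), conv = conv)
  })
}

fusion_fw <- function(fus, he, phh3, keep = TRUE) {
  d <- dim(he)
  if (!all(dim(phh3) == d)) abort("fusion branches must have identical shapes")
  cat_ <- array(c(he, phh3), dim = c(d[1], d[2], 2 * d[3]))
  n <- ln_fw(fus$ln, cat_)
  cv <- conv_fw(fus$conv, n$y, keep)
  r <- relu_fw(cv$y)
  list(y = r$y, cache = list(n = n$cache, cv = cv$cache, m = r$cache, c_he = d[3]))
}

fusion_bw <- function(fus, cache, dy) {
  d <- relu_bw(cache$m, dy)
  d <- conv_bw(fus$conv, cache$cv, d)
  d <- ln_bw(fus$ln, cache$n, d)
  C <- cache$c_he
  list(dhe = d[, , seq_len(C), drop = FALSE],
       dphh3 = d[, , C + seq_len(C), drop = FALSE])
}

#' Per-level mid-fusion of two stain feature maps
#'
#' Concatenates the H&E and PHH3 feature maps of each pyramid level along
#' the channel axis, layer-normalizes across channels, halves the channels
#' back with a 1x1 convolution, and rectifies. One independent merging
#' network per level; output shapes equal the single-branch shapes.
#'
#' @param he_maps,phh3_maps Lists of `(H, W, C)` arrays, one per level, with
#'   identical shapes across branches.
#' @param fusion Optional fusion layer list (random weights are created when
#'   omitted).
#' @param seed Seed for weight creation.
#' @return List of fused `(H, W, C)` arrays.
#' @export
fuse_features <- function(he_maps, phh3_maps, fusion = NULL, seed = 1L) {
  if (length(he_maps) != length(phh3_maps)) abort("level counts differ")
  if (is.null(fusion)) {
    fusion <- with_seed(seed,
      build_fusion(purrr::map_int(he_maps, ~ dim(.x)[3]), NULL))
  }
  purrr::map(seq_along(he_maps), function(l) {
    fusion_fw(fusion[[l]], he_maps[[l]], phh3_maps[[l]])$y
  })
}

# --- full detector ---------------------------------------------------------

#' Build a detector model
#'
#' Instantiates the backbone(s), the optional per-level fusion networks, the
#' three-level feature pyramid and the shared detection head (classification,
#' centerness, and four-sided box regression). Weights are drawn from a
#' seeded He initialization; the classification bias starts at the focal-loss
#' prior.
#'
#' @param config A [detector_config()].
#' @return An `fcos_model` environment.
#' @export
fcos_model <- function(config) {
  stopifnot(inherits(config, "detector_config"))
  arch <- backbone_arch(config$backbone)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$arch <- arch
  m$registry <- new_registry()
  with_seed(derive_seed(config$seed, c("init", config$mode, config$backbone)), {
    m$backbone_he <- build_backbone(arch, m$registry)
    if (config$mode == "dual") {
      m$backbone_phh3 <- build_backbone(arch, m$registry)
      m$fusion <- build_fusion(arch$level_channels, m$registry)
    }
    fc <- config$fpn_channels
    m$lat <- purrr::map(arch$level_channels,
                        ~ make_conv(.x, fc, 1, 1, pad = 0, registry = m$registry))
    m$smooth <- purrr::map(1:3, ~ make_conv(fc, fc, 3, 1, registry = m$registry))
    m$tower <- purrr::map(seq_len(config$head_convs),
                          ~ make_conv(fc, fc, 3, 1, registry = m$registry))
    m$cls <- make_conv(fc, 1, 3, 1, registry = m$registry)
    m$cls$b[] <- -log((1 - config$cls_prior) / config$cls_prior)  # focal prior
    m$ctr <- make_conv(fc, 1, 3, 1, registry = m$registry)
    m$reg <- make_conv(fc, 4, 3, 1, registry = m$registry)
  })
  class(m) <- "fcos_model"
  m
}

#' Backbone feature maps of an image
#'
#' Runs one stain branch of a detector (or a standalone backbone built on the
#' fly) and returns the three pyramid-level feature maps from backbone blocks
#' 2-4. Spatial sizes halve per level; channel counts are fixed by the
#' architecture (tiny: 12/24/48; resnet18: 128/256/512 at strides 8/16/32).
#'
#' @param image `(H, W, 3)` array with H and W divisible by the total stride.
#' @param config A [detector_config()] (or an existing `fcos_model` via
#'   `model`).
#' @param model Optional prebuilt model whose H&E branch is used.
#' @return List of three `(H_l, W_l, C_l)` arrays.
#' @export
backbone_forward <- function(image, config = detector_config(), model = NULL) {
  if (is.null(model)) model <- fcos_model(config)
  d <- dim(image)
  stride <- max(model$config$strides)
  if (d[1] %% stride != 0 || d[2] %% stride != 0) {
    abort(sprintf("image size %dx%d must be divisible by the total stride %d",
                  d[1], d[2], stride))
  }
  backbone_fw(model$backbone_he, model$arch, image)$levels
}

# Full forward pass: pyramid heads on every level.
fcos_forward <- function(model, he, phh3 = NULL, keep_cache = FALSE) {
  cfg <- model$config
  keep <- keep_cache
  bb_he <- backbone_fw(model$backbone_he, model$arch, he, keep)
  cache <- list(bb_he = bb_he)
  levels <- bb_he$levels
  if (cfg$mode == "dual") {
    if (is.null(phh3)) abort("dual-mode model needs the PHH3 image")
    bb_ph <- backbone_fw(model$backbone_phh3, model$arch, phh3, keep)
    cache$bb_ph <- bb_ph
    fus <- purrr::map(1:3, function(l) {
      fusion_fw(model$fusion[[l]], bb_he$levels[[l]], bb_ph$levels[[l]], keep)
    })
    cache$fus <- purrr::map(fus, "cache")
    levels <- purrr::map(fus, "y")
  }
  # feature pyramid + shared head, fused in C++
  res <- cpp_fpn_head_fwd(levels,
                          purrr::map(model$lat, conv_param_list),
                          purrr::map(model$smooth, conv_param_list),
                          purrr::map(model$tower, conv_param_list),
                          conv_param_list(model$cls),
                          conv_param_list(model$ctr),
                          conv_param_list(model$reg),
                          keep)
  cache$fpn <- res$cache
  if (keep_cache) list(outs = res$outs, cache = cache) else list(outs = res$outs)
}

conv_param_list <- function(l) {
  list(w = l$w, b = l$b, k = l$k, stride = l$stride, pad = l$pad)
}

# Backward from per-level gradients on (cls, ctr, reg).
fcos_backward <- function(model, cache, douts) {
  g <- cpp_fpn_head_bwd(douts, cache$fpn,
                        purrr::map(model$lat, conv_param_list),
                        purrr::map(model$smooth, conv_param_list),
                        purrr::map(model$tower, conv_param_list),
                        conv_param_list(model$cls),
                        conv_param_list(model$ctr),
                        conv_param_list(model$reg))
  for (l in 1:3) {
    model$lat[[l]]$gw <- model$lat[[l]]$gw + g$lat[[l]]$dw
    model$lat[[l]]$gb <- model$lat[[l]]$gb + as.vector(g$lat[[l]]$db)
    model$smooth[[l]]$gw <- model$smooth[[l]]$gw + g$smooth[[l]]$dw
    model$smooth[[l]]$gb <- model$smooth[[l]]$gb + as.vector(g$smooth[[l]]$db)
  }
  for (t in seq_along(model$tower)) {
    model$tower[[t]]$gw <- model$tower[[t]]$gw + g$tower[[t]]$dw
    model$tower[[t]]$gb <- model$tower[[t]]$gb + as.vector(g$tower[[t]]$db)
  }
  model$cls$gw <- model$cls$gw + g$cls$dw
  model$cls$gb <- model$cls$gb + as.vector(g$cls$db)
  model$ctr$gw <- model$ctr$gw + g$ctr$dw
  model$ctr$gb <- model$ctr$gb + as.vector(g$ctr$db)
  model$reg$gw <- model$reg$gw + g$reg$dw
  model$reg$gb <- model$reg$gb + as.vector(g$reg$db)
  dlevels <- g$dlevels
  if (model$config$mode == "dual") {
    dhe <- vector("list", 3)
    dph <- vector("list", 3)
    for (l in 1:3) {
      d <- fusion_bw(model$fusion[[l]], cache$fus[[l]], dlevels[[l]])
      dhe[[l]] <- d$dhe
      dph[[l]] <- d$dphh3
    }
    backbone_bw(model$backbone_phh3, model$arch, cache$bb_ph, dph)
    backbone_bw(model$backbone_he, model$arch, cache$bb_he, dhe)
  } else {
    backbone_bw(model$backbone_he, model$arch, cache$bb_he, dlevels)
  }
  invisible(NULL)
}

#' Parameter accounting for a detector configuration
#'
#' Counts trainable parameters analytically from the architecture descriptor
#' (no weights are allocated), covering backbone(s), fusion networks, feature
#' pyramid and heads.
#'
#' @param config A [detector_config()].
#' @return Number of trainable parameters.
#' @export
model_parameter_count <- function(config) {
  arch <- backbone_arch(config$backbone)
  conv_n <- function(cin, cout, k) k * k * cin * cout + cout
  ln_n <- function(c) 2 * c
  block_n <- function(sp) {
    if (sp$kind == "plain") return(conv_n(sp$cin, sp$cout, sp$k) + ln_n(sp$cout))
    if (sp$kind == "maxpool") return(0)
    proj <- if (sp$stride != 1 || sp$cin != sp$cout)
      conv_n(sp$cin, sp$cout, 1) + ln_n(sp$cout) else 0
    if (sp$kind == "basic") {
      return(conv_n(sp$cin, sp$cout, 3) + ln_n(sp$cout) +
               conv_n(sp$cout, sp$cout, 3) + ln_n(sp$cout) + proj)
    }
    mid <- sp$cout %/% 4
    conv_n(sp$cin, mid, 1) + ln_n(mid) + conv_n(mid, mid, 3) + ln_n(mid) +
      conv_n(mid, sp$cout, 1) + ln_n(sp$cout) + proj
  }
  bb <- sum(purrr::map_dbl(arch$stages, function(st) sum(purrr::map_dbl(st, block_n))))
  n <- bb
  if (config$mode == "dual") {
    n <- n + bb + sum(purrr::map_dbl(arch$level_channels, function(C) {
      ln_n(2 * C) + conv_n(2 * C, C, 1)
    }))
  }
  fc <- config$fpn_channels
  n <- n + sum(purrr::map_dbl(arch$level_channels, ~ conv_n(.x, fc, 1)))
  n <- n + 3 * conv_n(fc, fc, 3)
  n <- n + config$head_convs * conv_n(fc, fc, 3)
  n <- n + conv_n(fc, 1, 3) + conv_n(fc, 1, 3) + conv_n(fc, 4, 3)
  n
}

#' @export
print.fcos_model <- function(x, ...) {
  cat(sprintf("<fcos_model> %s / %s, %.1f M parameters (instantiated: %s)\n",
              x$config$mode, x$config$backbone,
              model_parameter_count(x$config) / 1e6,
              format(registry_param_count(x$registry), big.mark = ",")))
  invisible(x)
}

#' Desk-scale training configuration
#'
#' The tuned compact-detector schedule used by the package's replication
#' experiments: tiny backbone, 128-px patches, AdamW at 1e-3 with two-patch
#' batches and 40 steps per epoch, early stopping with patience 5. The
#' higher learning rate (relative to the full-scale protocol default of
#' 1e-4) matches the much smaller parameter count and short schedule; see
#' the methods vignette.
#'
#' @param mode `"single"` or `"dual"`.
#' @param ... Overrides forwarded to [detector_config()].
#' @return A `detector_config`.
#' @export
desk_detector_config <- function(mode = c("single", "dual"), ...) {
  mode <- match.arg(mode)
  args <- list(...)
  defaults <- list(mode = mode, backbone = "tiny", patch_size = 128,
                   lr = 1e-3, batch_size = 2, steps_per_epoch = 36,
                   max_epochs = 13, patience = 5)
  do.call(detector_config, utils::modifyList(defaults, args))
}
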