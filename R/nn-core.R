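# Minimal convolutional-network core with hand-derived backpropagation.
#
# Layers are environments holding parameters, accumulated gradients, and
# AdamW moments; forward functions return the output together with an
# explicit cache, and backward functions consume (cache, upstream gradient),
# accumulate parameter gradients in the layer, and return the input
# gradient. Caches being explicit makes layers safely shareable (the
# detection head runs over all pyramid levels with the same weights).
# Tensors are numeric arrays of dim (H, W, C).

new_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env
}

reg_add <- function(registry, layer) {
  if (!is.null(registry)) registry$layers[[length(registry$layers) + 1L]] <- layer
  layer
}

# --- convolution -----------------------------------------------------------

make_conv <- function(cin, cout, k = 3, stride = 1, pad = NULL,
                      registry = NULL, bias = TRUE) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  l <- new.env(parent = emptyenv())
  l$kind <- "conv"
  l$cin <- cin; l$cout <- cout; l$k <- k; l$stride <- stride; l$pad <- pad
  fan_in <- k * k * cin
  l$w <- matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  l$b <- if (bias) numeric(cout) else NULL
  l$gw <- matrix(0, fan_in, cout)
  l$gb <- numeric(cout)
  reg_add(registry, l)
}

conv_fw <- function(l, x, keep = TRUE) {
  out <- cpp_conv_fwd(x, l$w, l$b %||0% numeric(l$cout), l$k, l$stride, l$pad,
                      want_col = keep)
  list(y = out$y, cache = if (keep) list(col = out$col, xdim = dim(x)))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

conv_bw <- function(l, cache, dy, want_dx = TRUE) {
  out <- cpp_conv_bwd(cache$col, l$w, dy, cache$xdim, l$k, l$stride, l$pad,
                      want_dx)
  l$gw <- l$gw + out$dw
  if (!is.null(l$b)) l$gb <- l$gb + out$db
  if (want_dx) out$dx else NULL
}

# --- channelwise layer normalization --------------------------------------
# Normalizes over the channel dimension independently at every spatial
# position (the fusion network's normalization; also used inside the
# backbones in place of batch statistics, which are meaningless at batch
# size one).

make_layernorm <- function(c, registry = NULL) {
  l <- new.env(parent = emptyenv())
  l$kind <- "layernorm"
  l$c <- c
  l$w <- rep(1, c)   # gamma
  l$b <- rep(0, c)   # beta
  l$gw <- numeric(c)
  l$gb <- numeric(c)
  reg_add(registry, l)
}

ln_fw <- function(l, x) {
  out <- cpp_lnrelu_fwd(x, l$w, l$b, FALSE)
  list(y = out$y, cache = list(xn = out$xn, istd = out$istd))
}

ln_bw <- function(l, cache, dy) {
  r <- cpp_lnrelu_bwd(dy, cache$xn, cache$istd, l$w, NULL)
  l$gw <- l$gw + as.vector(r$dgamma)
  l$gb <- l$gb + as.vector(r$dbeta)
  r$dx
}

# Fused LayerNorm + ReLU (single C++ pass each way).
lnrelu_fw <- function(l, x) {
  out <- cpp_lnrelu_fwd(x, l$w, l$b, TRUE)
  list(y = out$y, cache = list(xn = out$xn, istd = out$istd, mask = out$mask))
}

lnrelu_bw <- function(l, cache, dy) {
  r <- cpp_lnrelu_bwd(dy, cache$xn, cache$istd, l$w, cache$mask)
  l$gw <- l$gw + as.vector(r$dgamma)
  l$gb <- l$gb + as.vector(r$dbeta)
  r$dx
}

# --- stateless pieces ------------------------------------------------------

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bw <- function(cache, dy) dy * cache

upsample2_fw <- function(x) {
  d <- dim(x)
  idx_i <- rep(seq_len(d[1]), each = 2)
  idx_j <- rep(seq_len(d[2]), each = 2)
  list(y = x[idx_i, idx_j, , drop = FALSE], cache = d)
}

upsample2_bw <- function(cache, dy) {
  d <- cache
  dd <- dim(dy)
  out <- array(0, d)
  for (c in seq_len(d[3])) {
    m <- dy[, , c]
    # sum 2x2 blocks
    m <- m[seq(1, dd[1], by = 2), ] + m[seq(2, dd[1], by = 2), ]
    out[, , c] <- m[, seq(1, dd[2], by = 2)] + m[, seq(2, dd[2], by = 2)]
  }
  out
}

# Upsample to a target size: exact factor-2 fast path, generic
# nearest-neighbor otherwise (odd-sized feature maps).
upsample_to_fw <- function(x, target_hw) {
  d <- dim(x)
  if (target_hw[1] == 2 * d[1] && target_hw[2] == 2 * d[2]) {
    r <- upsample2_fw(x)
    return(list(y = r$y, cache = list(fast2 = TRUE, d = d)))
  }
  upsample_to_fw_generic(x, target_hw)
}

upsample_to_bw <- function(cache, dy) {
  if (isTRUE(cache$fast2)) return(upsample2_bw(cache$d, dy))
  upsample_to_bw_generic(cache, dy)
}

upsample_to_fw_generic <- function(x, target_hw) {
  d <- dim(x)
  idx_i <- pmin(floor(seq(0, target_hw[1] - 1) * d[1] / target_hw[1]) + 1, d[1])
  idx_j <- pmin(floor(seq(0, target_hw[2] - 1) * d[2] / target_hw[2]) + 1, d[2])
  list(y = x[idx_i, idx_j, , drop = FALSE],
       cache = list(d = d, idx_i = idx_i, idx_j = idx_j))
}

upsample_to_bw_generic <- function(cache, dy) {
  out <- array(0, cache$d)
  dd <- dim(dy)
  # row/column index sums; pyramid maps are small so plain loops suffice
  for (c in seq_len(cache$d[3])) {
    acc <- matrix(0, cache$d[1], cache$d[2])
    dyc <- dy[, , c]
    for (jj in seq_len(dd[2])) {
      tgt <- cache$idx_j[jj]
      sums <- rowsum(dyc[, jj], cache$idx_i)
      acc[as.integer(rownames(sums)), tgt] <- acc[as.integer(rownames(sums)), tgt] + sums[, 1]
    }
    out[, , c] <- acc
  }
  out
}

make_maxpool <- function(k = 3, stride = 2, pad = 1) {
  l <- new.env(parent = emptyenv())
  l$kind <- "maxpool"; l$k <- k; l$stride <- stride; l$pad <- pad
  l
}

maxpool_fw <- function(l, x) {
  out <- cpp_maxpool_fwd(x, l$k, l$stride, l$pad)
  list(y = out$y, cache = list(arg = out$arg, xdim = dim(x)))
}

maxpool_bw <- function(l, cache, dy) {
  cpp_maxpool_bwd(dy, cache$arg, cache$xdim)
}

# --- optimizer -------------------------------------------------------------

#' @noRd
adamw_step <- function(registry, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  for (l in registry$layers) {
    if (is.null(l$t)) l$t <- 0L
    l$t <- l$t + 1L
    bc1 <- 1 - beta1^l$t
    bc2 <- 1 - beta2^l$t
    if (!is.null(l$w)) {
      if (is.null(l$mw)) { l$mw <- l$gw * 0; l$vw <- l$gw * 0 }
      l$mw <- beta1 * l$mw + (1 - beta1) * l$gw
      l$vw <- beta2 * l$vw + (1 - beta2) * l$gw^2
      decay <- if (l$kind == "conv") weight_decay else 0
      l$w <- l$w - lr * ((l$mw / bc1) / (sqrt(l$vw / bc2) + eps) + decay * l$w)
      l$gw <- l$gw * 0
    }
    if (!is.null(l$b)) {
      if (is.null(l$mb)) { l$mb <- l$gb * 0; l$vb <- l$gb * 0 }
      l$mb <- beta1 * l$mb + (1 - beta1) * l$gb
      l$vb <- beta2 * l$vb + (1 - beta2) * l$gb^2
      l$b <- l$b - lr * (l$mb / bc1) / (sqrt(l$vb / bc2) + eps)
      l$gb <- l$gb * 0
    }
  }
  invisible(NULL)
}

registry_param_count <- function(registry) {
  sum(vapply(registry$layers, function(l) {
    length(l$w %||0% numeric(0)) + length(l$b %||0% numeric(0))
  }, numeric(1)))
}

# Snapshot / restore all parameter values (for best-epoch checkpointing).
registry_snapshot <- function(registry) {
  lapply(registry$layers, function(l) list(w = l$w, b = l$b))
}

registry_restore <- function(registry, snapshot) {
  for (i in seq_along(registry$layers)) {
    registry$layers[[i]]$w <- snapshot[[i]]$w
    registry$layers[[i]]$b <- snapshot[[i]]$b
  }
  invisible(NULL)
}
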