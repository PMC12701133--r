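# FRegNet feature extractor: a residual stem whose side branch is modulated
# by a global-average-pooled projection under a Softplus activation, a staged
# convolutional body with residual blocks, and a path-aggregated feature
# pyramid (FPAFPN) that restores resolution with cubic-convolution
# upsampling and re-aggregates it bottom-up.

#' Backbone configuration
#'
#' Collects the architectural hyperparameters of the FRegNet feature
#' extractor. The defaults give a small detector suitable for face-like
#' images of around 96 pixels; all widths and depths are tunable.
#'
#' @param in_channels Number of input image channels (1 = greyscale).
#' @param stem_width Channel width of the residual stem output.
#' @param widths Integer vector of per-stage body widths (one per stage).
#' @param depths Integer vector of residual blocks per stage.
#' @param fpn_channels Shared channel width of all fused pyramid levels.
#' @param second_pass Direction of the second aggregation pass:
#'   `"bottomup"` (finest to coarsest, with stride-2 downsampling
#'   convolutions) or `"topdown"`.
#' @return A list of class `"fregnet_config"`.
#' @export
fregnet_config <- function(in_channels = 1L, stem_width = 32L,
                           widths = c(32L, 64L, 128L), depths = c(1L, 2L, 2L),
                           fpn_channels = 64L,
                           second_pass = c("bottomup", "topdown")) {
  stopifnot(length(widths) == length(depths), length(widths) >= 2L)
  structure(list(in_channels = as.integer(in_channels),
                 stem_width = as.integer(stem_width),
                 widths = as.integer(widths), depths = as.integer(depths),
                 fpn_channels = as.integer(fpn_channels),
                 second_pass = match.arg(second_pass)),
            class = "fregnet_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

conv_init <- function(k, cin, cout) {
  list(w = he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
}

#' Initialize FRegNet parameters
#'
#' Draws He-normal initial weights for every convolution in the stem, body
#' and pyramid. Uses the current RNG state; seed it for reproducibility.
#'
#' @param config A [fregnet_config()].
#' @return Nested list of numeric arrays (the trainable state).
#' @export
fregnet_init <- function(config) {
  cw <- config$stem_width
  stem <- list(conv_c = conv_init(3L, config$in_channels, cw),
               conv_d = conv_init(3L, config$in_channels, cw),
               w_gap = he_init(c(cw, cw), cw),
               b_gap = rep(1, cw))
  stages <- list()
  cin <- cw
  for (s in seq_along(config$widths)) {
    w <- config$widths[s]
    blocks <- lapply(seq_len(config$depths[s]), function(i) {
      list(conv1 = conv_init(3L, w, w), conv2 = conv_init(3L, w, w))
    })
    stages[[s]] <- list(down = conv_init(3L, cin, w), blocks = blocks)
    cin <- w
  }
  fc <- config$fpn_channels
  n <- length(config$widths)
  fpn <- list(lateral = lapply(config$widths, function(w) conv_init(1L, w, fc)),
              out = lapply(seq_len(n), function(i) conv_init(1L, fc, fc)),
              agg = lapply(seq_len(n - 1L), function(i) conv_init(3L, fc, fc)))
  list(stem = stem, stages = stages, fpn = fpn)
}

#' Residual stem forward pass
#'
#' Two-path input block: the main branch applies a 3x3 convolution with a
#' ReLU, the side branch a parallel 3x3 convolution; their sum is modulated
#' channel-wise by a projection of its own global average pooling
#' (squeeze-excite style, so spatial structure is preserved) and passed
#' through a Softplus, making every output strictly positive.
#'
#' @param x Input feature map, `height x width x channels` array (or a
#'   tape node during training).
#' @param params Stem parameter list (`conv_c`, `conv_d`, `w_gap`, `b_gap`),
#'   as produced by [fregnet_init()]`$stem`.
#' @param stride Stride shared by both stem convolutions (the backbone uses
#'   2; 1 preserves spatial size).
#' @return Feature map with `stem_width` channels.
#' @export
rstem_forward <- function(x, params, stride = 1L) {
  g <- ag_relu(ag_conv2d(x, params$conv_c$w, params$conv_c$b, stride = stride))
  u <- ag_add(g, ag_conv2d(x, params$conv_d$w, params$conv_d$b, stride = stride))
  pooled <- ag_gap(u)
  gate <- ag_add(ag_matmul(ag_reshape(pooled, c(1L, length(ag_val(pooled)))),
                           params$w_gap),
                 params$b_gap)
  gate <- ag_reshape(gate, NULL)
  ag_softplus(ag_mul(u, gate))
}

residual_block_forward <- function(x, blk) {
  h <- ag_relu(ag_conv2d(x, blk$conv1$w, blk$conv1$b))
  h <- ag_conv2d(h, blk$conv2$w, blk$conv2$b)
  ag_relu(ag_add(x, h))
}

#' Staged convolutional body
#'
#' Runs the stem output through the configured stages; each stage opens with
#' a stride-2 3x3 convolution and continues with residual blocks. Combined
#' with the stride-4 stem, a three-stage body emits bottom-up levels at
#' strides 8, 16 and 32 of the input.
#'
#' @param stem Stem output feature map.
#' @param params `$stages` component of [fregnet_init()].
#' @return List of bottom-up feature maps `C` (finest first).
#' @export
regnet_body_forward <- function(stem, params) {
  x <- stem
  out <- vector("list", length(params))
  for (s in seq_along(params)) {
    d <- dim(ag_val(x))
    if (d[1L] < 2L || d[2L] < 2L) {
      stop("input too small for the configured downsampling depth")
    }
    x <- ag_relu(ag_conv2d(x, params[[s]]$down$w, params[[s]]$down$b, stride = 2L))
    for (blk in params[[s]]$blocks) x <- residual_block_forward(x, blk)
    out[[s]] <- x
  }
  out
}

#' Cubic-convolution upsampling
#'
#' Enlarges a feature map by an integer factor of 2 or 3 using separable
#' cubic-convolution (Catmull-Rom) interpolation with half-pixel alignment
#' and border replication; channels are processed independently. The
#' interpolation weights form a partition of unity, so constant maps are
#' reproduced exactly, and the operator is linear in its input. Factor 1 is
#' accepted as the identity.
#'
#' @param x Feature map array `height x width x channels`.
#' @param factor Integer upsampling factor, 2 or 3 (1 = identity).
#' @return Feature map of `factor` times the spatial size.
#' @export
bicubic_upsample <- function(x, factor) {
  ag_upsample_bicubic(x, as.integer(factor))
}

#' Path-aggregated feature pyramid forward pass
#'
#' First a top-down pass `P_i = Con(C_i) + H(P_{i+1})` where `H` is cubic
#' upsampling by the spatial ratio of adjacent levels (the coarsest `P` is
#' its lateral convolution alone), then a second aggregation pass producing
#' the fused maps `F`; by default this runs finest to coarsest with stride-2
#' downsampling convolutions (path aggregation), with a top-down variant
#' available via the configuration.
#'
#' @param C List of bottom-up feature maps (finest first).
#' @param params `$fpn` component of [fregnet_init()].
#' @param second_pass `"bottomup"` or `"topdown"`.
#' @return List of fused maps `F`, all at the configured shared width.
#' @export
fpafpn_forward <- function(C, params, second_pass = "bottomup") {
  n <- length(C)
  stopifnot(n >= 2L, length(params$lateral) == n)
  lat <- lapply(seq_len(n), function(i) {
    ag_conv2d(C[[i]], params$lateral[[i]]$w, params$lateral[[i]]$b)
  })
  P <- vector("list", n)
  P[[n]] <- lat[[n]]
  for (i in rev(seq_len(n - 1L))) {
    hi <- dim(ag_val(lat[[i]]))[1L]
    lo <- dim(ag_val(P[[i + 1L]]))[1L]
    if (hi %% lo != 0L) stop("adjacent pyramid levels are not integer-ratio")
    P[[i]] <- ag_add(lat[[i]], ag_upsample_bicubic(P[[i + 1L]], hi %/% lo))
  }
  Fm <- vector("list", n)
  if (identical(second_pass, "bottomup")) {
    Fm[[1L]] <- ag_conv2d(P[[1L]], params$out[[1L]]$w, params$out[[1L]]$b)
    for (i in seq_len(n - 1L) + 1L) {
      down <- ag_conv2d(Fm[[i - 1L]], params$agg[[i - 1L]]$w,
                        params$agg[[i - 1L]]$b, stride = 2L)
      if (!identical(dim(ag_val(down))[1:2], dim(ag_val(P[[i]]))[1:2])) {
        stop("spatial mismatch in second aggregation pass")
      }
      Fm[[i]] <- ag_add(ag_conv2d(P[[i]], params$out[[i]]$w, params$out[[i]]$b),
                        down)
    }
  } else {
    Fm[[n]] <- ag_conv2d(P[[n]], params$out[[n]]$w, params$out[[n]]$b)
    for (i in rev(seq_len(n - 1L))) {
      hi <- dim(ag_val(P[[i]]))[1L]
      lo <- dim(ag_val(Fm[[i + 1L]]))[1L]
      up <- ag_upsample_bicubic(
        ag_conv2d(Fm[[i + 1L]], params$agg[[i]]$w, params$agg[[i]]$b),
        hi %/% lo)
      Fm[[i]] <- ag_add(ag_conv2d(P[[i]], params$out[[i]]$w, params$out[[i]]$b),
                        up)
    }
  }
  Fm
}

# Full backbone: image -> fused pyramid levels (strides 8/16/32 for a
# three-stage configuration).  `params` from fregnet_init(), possibly
# wrapped as tape nodes.
fregnet_forward <- function(image, params, config) {
  s <- rstem_forward(image, params$stem, stride = 2L)
  s <- ag_avgpool2(s)
  C <- regnet_body_forward(s, params$stages)
  fpafpn_forward(C, params$fpn, config$second_pass)
}

#' Count trainable parameters
#'
#' @param params Nested parameter list.
#' @return Total number of scalar parameters.
#' @export
n_parameters <- function(params) {
  sum(vapply(flatten_params(params), length, 1L))
}

## ---- nested parameter-list utilities ---------------------------------------

flatten_params <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nm <- names(x)
    if (is.null(nm)) nm <- as.character(seq_along(x))
    for (i in seq_along(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm[i]) else nm[i]
      out <- c(out, flatten_params(x[[i]], key))
    }
    out
  } else {
    stats::setNames(list(x), prefix)
  }
}

grad_sumsq <- function(g) {
  if (is.list(g)) sum(vapply(g, grad_sumsq, 1)) else sum(g * g)
}

map_params <- function(x, f) {
  if (is.list(x) && !ag_is(x)) lapply(x, map_params, f = f) else f(x)
}

ag_wrap_params <- function(tape, params) {
  map_params(params, function(p) ag_param(tape, p))
}

ag_unwrap_grads <- function(wrapped) {
  map_params(wrapped, function(nd) {
    g <- nd$grad
    if (is.null(g)) array(0, dim = if (is.null(dim(nd$value))) length(nd$value)
                          else dim(nd$value)) else g
  })
}

ag_unwrap_values <- function(wrapped) map_params(wrapped, function(nd) nd$value)

## ---- Adam optimizer on nested parameter lists ------------------------------

adam_state <- function(params) {
  list(m = map_params(params, function(p) p * 0),
       v = map_params(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- lapply(seq_along(p), function(i) walk(p[[i]], g[[i]], m[[i]], v[[i]]))
      list(p = stats::setNames(lapply(res, `[[`, "p"), names(p)),
           m = stats::setNames(lapply(res, `[[`, "m"), names(p)),
           v = stats::setNames(lapply(res, `[[`, "v"), names(p)))
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}
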