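# Spatial primitives: same-padding 2-d convolution via im2col + BLAS matmul,
# 2x2 average pooling, global average pooling, and cubic-convolution
# (Catmull-Rom) upsampling expressed as a pair of dense interpolation
# matrices so that the backward pass is just the transpose.

.op_cache <- new.env(parent = emptyenv())

# Linear indices into the zero-padded array for every (output position,
# kernel offset, channel) pair; column order matches column-major flattening
# of a [kh, kw, cin] kernel block.  Memoized: the same shapes recur at every
# training step.
im2col_index <- function(h, w, cin, kh, kw, stride, pad) {
  key <- paste("i2c", h, w, cin, kh, kw, stride, pad, sep = "_")
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  .op_cache[[key]] <- im2col_index_build(h, w, cin, kh, kw, stride, pad)
}

im2col_index_build <- function(h, w, cin, kh, kw, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  hout <- (hp - kh) %/% stride + 1L
  wout <- (wp - kw) %/% stride + 1L
  oi <- seq.int(1L, by = stride, length.out = hout)
  oj <- seq.int(1L, by = stride, length.out = wout)
  base_row <- rep(oi, times = wout) + (rep(oj, each = hout) - 1L) * hp
  off <- expand.grid(ki = seq_len(kh) - 1L, kj = seq_len(kw) - 1L,
                     c = seq_len(cin) - 1L)
  base_col <- off$ki + off$kj * hp + off$c * hp * wp
  list(lin = outer(base_row, base_col, `+`), hout = hout, wout = wout,
       hp = hp, wp = wp)
}

pad_map <- function(x, pad) {
  d <- dim(x)
  if (pad == 0L) return(x)
  xp <- array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L]))
  xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
  xp
}

conv2d_forward <- function(x, w, b, stride = 1L, pad = (dim(w)[1L] - 1L) %/% 2L) {
  d <- dim(x); dw <- dim(w)
  if (d[3L] != dw[3L]) {
    stop("channel mismatch: input has ", d[3L], " channels, kernel expects ", dw[3L])
  }
  idx <- im2col_index(d[1L], d[2L], d[3L], dw[1L], dw[2L], stride, pad)
  xp <- pad_map(x, pad)
  patch <- matrix(xp[as.vector(idx$lin)], nrow(idx$lin), ncol(idx$lin))
  wm <- matrix(w, dw[1L] * dw[2L] * dw[3L], dw[4L])
  out <- patch %*% wm
  out <- sweep(out, 2L, b, `+`)
  list(out = array(out, c(idx$hout, idx$wout, dw[4L])),
       patch = patch, idx = idx, wm = wm, din = d, dw = dw, pad = pad)
}

conv2d_backward <- function(fw, gout) {
  gm <- matrix(gout, nrow(fw$patch), fw$dw[4L])
  gw <- crossprod(fw$patch, gm)
  dim(gw) <- fw$dw
  gb <- colSums(gm)
  gpatch <- tcrossprod(gm, fw$wm)
  gxp <- numeric(fw$idx$hp * fw$idx$wp * fw$din[3L])
  lin <- fw$idx$lin
  for (q in seq_len(ncol(lin))) {
    gxp[lin[, q]] <- gxp[lin[, q]] + gpatch[, q]
  }
  gxp <- array(gxp, c(fw$idx$hp, fw$idx$wp, fw$din[3L]))
  p <- fw$pad
  gx <- gxp[p + seq_len(fw$din[1L]), p + seq_len(fw$din[2L]), , drop = FALSE]
  list(gx = gx, gw = gw, gb = gb)
}

ag_conv2d <- function(x, w, b, stride = 1L) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b)
  fw <- conv2d_forward(xv, wv, bv, stride)
  ag_make(list(x, w, b), fw$out, function(g) {
    bk <- conv2d_backward(fw, g)
    list(bk$gx, bk$gw, bk$gb)
  })
}

ag_avgpool2 <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  if (d[1L] %% 2L || d[2L] %% 2L) stop("average pooling needs even spatial dims")
  a <- xv[seq(1L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE]
  b <- xv[seq(2L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE]
  cc <- xv[seq(1L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE]
  dd <- xv[seq(2L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE]
  val <- (a + b + cc + dd) / 4
  ag_make(list(x), val, function(g) {
    gx <- array(0, d)
    gq <- g / 4
    gx[seq(1L, d[1L], 2L), seq(1L, d[2L], 2L), ] <- gq
    gx[seq(2L, d[1L], 2L), seq(1L, d[2L], 2L), ] <-
      gx[seq(2L, d[1L], 2L), seq(1L, d[2L], 2L), , drop = FALSE] + gq
    gx[seq(1L, d[1L], 2L), seq(2L, d[2L], 2L), ] <-
      gx[seq(1L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE] + gq
    gx[seq(2L, d[1L], 2L), seq(2L, d[2L], 2L), ] <-
      gx[seq(2L, d[1L], 2L), seq(2L, d[2L], 2L), , drop = FALSE] + gq
    list(gx)
  })
}

ag_gap <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  val <- apply(xv, 3L, mean)
  ag_make(list(x), val, function(g) {
    list(aperm(array(rep(g / (d[1L] * d[2L]), each = d[1L] * d[2L]),
                     c(d[1L], d[2L], d[3L])), c(1L, 2L, 3L)))
  })
}

## ---- cubic-convolution interpolation ---------------------------------------

# Catmull-Rom cubic kernel (a = -0.5), the standard 4-point support.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Dense n_out x n_in interpolation matrix for one axis, half-pixel centers,
# border replication.  Rows sum to 1 (partition of unity), so constants are
# reproduced exactly.
bicubic_matrix <- function(n_in, factor) {
  key <- paste("bcm", n_in, factor, sep = "_")
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  .op_cache[[key]] <- bicubic_matrix_build(n_in, factor)
}

bicubic_matrix_build <- function(n_in, factor) {
  n_out <- n_in * factor
  m <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) / factor + 0.5
    i0 <- floor(src)
    for (k in -1:2) {
      i <- i0 + k
      wgt <- cubic_kernel(src - i)
      ic <- min(max(i, 1L), n_in)
      m[o, ic] <- m[o, ic] + wgt
    }
  }
  m
}

ag_upsample_bicubic <- function(x, factor) {
  if (!factor %in% c(1L, 2L, 3L)) {
    stop("upsampling factor must be 1 (identity), 2 or 3")
  }
  xv <- ag_val(x)
  if (factor == 1L) return(x)
  d <- dim(xv)
  ly <- bicubic_matrix(d[1L], factor)
  lx <- bicubic_matrix(d[2L], factor)
  val <- array(0, c(d[1L] * factor, d[2L] * factor, d[3L]))
  for (c in seq_len(d[3L])) val[, , c] <- ly %*% xv[, , c] %*% t(lx)
  ag_make(list(x), val, function(g) {
    gx <- array(0, d)
    for (c in seq_len(d[3L])) gx[, , c] <- t(ly) %*% g[, , c] %*% lx
    list(gx)
  })
}
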