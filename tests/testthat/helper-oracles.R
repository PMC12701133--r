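# Independent scalar-loop oracles used to verify the vectorized
# implementations.  These are deliberately naive (explicit loops, textbook
# formulas) and share no code with the package internals.

# Plain same-padding convolution by explicit loops.
oracle_conv2d <- function(x, w, b, stride = 1L) {
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  pad <- (kh - 1L) %/% 2L
  h <- dim(x)[1L]; wd <- dim(x)[2L]
  hout <- (h + 2L * pad - kh) %/% stride + 1L
  wout <- (wd + 2L * pad - kw) %/% stride + 1L
  out <- array(0, c(hout, wout, cout))
  for (co in seq_len(cout)) for (oi in seq_len(hout)) for (oj in seq_len(wout)) {
    acc <- b[co]
    for (ki in seq_len(kh)) for (kj in seq_len(kw)) for (ci in seq_len(cin)) {
      ii <- (oi - 1L) * stride + ki - pad
      jj <- (oj - 1L) * stride + kj - pad
      if (ii >= 1L && ii <= h && jj >= 1L && jj <= wd) {
        acc <- acc + x[ii, jj, ci] * w[ki, kj, ci, co]
      }
    }
    out[oi, oj, co] <- acc
  }
  out
}

# Residual stem per the two-branch equations, evaluated step by step with
# loops: G = relu(conv_c x); u = G + conv_d x; gate = W %*% gap(u) + b_gap;
# out = softplus(u * gate[channel]).
oracle_rstem <- function(x, params) {
  g <- oracle_conv2d(x, params$conv_c$w, params$conv_c$b)
  g[g < 0] <- 0
  u <- g + oracle_conv2d(x, params$conv_d$w, params$conv_d$b)
  cc <- dim(u)[3L]
  gap <- numeric(cc)
  for (c in seq_len(cc)) gap[c] <- mean(u[, , c])
  gate <- as.vector(gap %*% params$w_gap) + params$b_gap
  out <- u
  for (c in seq_len(cc)) {
    v <- u[, , c] * gate[c]
    out[, , c] <- log(1 + exp(v))
  }
  out
}

# Textbook cubic-convolution (Keys, a = -0.5) upsampling with half-pixel
# centers and clamped borders, scalar loops.
oracle_cubic_kernel <- function(t) {
  t <- abs(t)
  if (t <= 1) 1.5 * t^3 - 2.5 * t^2 + 1
  else if (t < 2) -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2
  else 0
}

oracle_bicubic <- function(x, factor) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; cc <- dim(x)[3L]
  out <- array(0, c(h * factor, w * factor, cc))
  for (c in seq_len(cc)) for (oy in seq_len(h * factor)) for (ox in seq_len(w * factor)) {
    sy <- (oy - 0.5) / factor + 0.5
    sx <- (ox - 0.5) / factor + 0.5
    acc <- 0
    for (ky in -1:2) for (kx in -1:2) {
      iy <- floor(sy) + ky
      ix <- floor(sx) + kx
      wgt <- oracle_cubic_kernel(sy - iy) * oracle_cubic_kernel(sx - ix)
      iyc <- min(max(iy, 1L), h); ixc <- min(max(ix, 1L), w)
      acc <- acc + wgt * x[iyc, ixc, c]
    }
    out[oy, ox, c] <- acc
  }
  out
}

# LSTM step by scalar loops over hidden units.
oracle_lstm_step <- function(x_t, h_prev, c_prev, p) {
  hsz <- length(h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  f <- i <- o <- cd <- numeric(hsz)
  for (k in seq_len(hsz)) {
    f[k] <- sig(sum(h_prev * p$W_f[, k]) + sum(x_t * p$U_f[, k]) + p$b_f[k])
    i[k] <- sig(sum(h_prev * p$W_i[, k]) + sum(x_t * p$U_i[, k]) + p$b_i[k])
    o[k] <- sig(sum(h_prev * p$W_o[, k]) + sum(x_t * p$U_o[, k]) + p$b_o[k])
    cd[k] <- tanh(sum(h_prev * p$W_c[, k]) + sum(x_t * p$U_c[, k]) + p$b_c[k])
  }
  C <- f * c_prev + i * cd
  list(h = o * tanh(C), C = C)
}

# Exhaustive O(n^2) greedy NMS.
oracle_nms <- function(boxes, scores, thr) {
  n <- length(scores)
  alive <- rep(TRUE, n)
  keep <- integer(0)
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  repeat {
    cand <- which(alive)
    if (!length(cand)) break
    best <- cand[1L]
    for (c in cand) if (scores[c] > scores[best]) best <- c
    keep <- c(keep, best)
    alive[best] <- FALSE
    for (c in which(alive)) {
      if (iou1(boxes[best, ], boxes[c, ]) > thr) alive[c] <- FALSE
    }
  }
  keep
}

# AUC by exhaustive pairwise comparison, ties counted one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AP by explicit point-by-point enumeration of the PR curve (greedy
# confidence-ordered matching, all-point interpolation via direct max).
oracle_ap <- function(det, gt, thr) {
  ord <- order(-det$confidence)
  det <- det[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gt))
  tp <- logical(nrow(det))
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  for (i in seq_len(nrow(det))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gt))) {
      if (used[j] || gt$image_id[j] != det$image_id[i]) next
      v <- iou1(as.numeric(det[i, c("x_min", "y_min", "x_max", "y_max")]),
                as.numeric(gt[j, c("x_min", "y_min", "x_max", "y_max")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { tp[i] <- TRUE; used[bj] <- TRUE }
  }
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / nrow(gt)
  # area under all-point-interpolated curve, evaluated point by point
  ap <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    if (rec[i] > prev_r) {
      ap <- ap + (rec[i] - prev_r) * max(prec[i:length(prec)])
      prev_r <- rec[i]
    }
  }
  ap
}

# Random valid box in a s x s canvas.
random_box <- function(s = 60) {
  x0 <- runif(1, 0, s - 6); y0 <- runif(1, 0, s - 6)
  w <- runif(1, 2, s / 2); h <- runif(1, 2, s / 2)
  c(x0, y0, min(x0 + w, s), min(y0 + h, s))
}

# Finite-difference gradient of a scalar function of a nested param list.
fd_grad <- function(lossfun, params, name, j, eps = 1e-5) {
  fl <- facesurv:::flatten_params(params)
  rebuild <- function(plist, fl2) {
    rec <- function(x, prefix = "") {
      if (is.list(x)) {
        nm <- names(x)
        if (is.null(nm)) nm <- as.character(seq_along(x))
        stats::setNames(lapply(seq_along(x), function(i) {
          rec(x[[i]], if (nzchar(prefix)) paste0(prefix, ".", nm[i]) else nm[i])
        }), names(x))
      } else {
        v <- fl2[[prefix]]
        dim(v) <- dim(x)
        v
      }
    }
    rec(plist)
  }
  f1 <- fl; f1[[name]][j] <- f1[[name]][j] + eps
  f2 <- fl; f2[[name]][j] <- f2[[name]][j] - eps
  (lossfun(rebuild(params, f1)) - lossfun(rebuild(params, f2))) / (2 * eps)
}
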