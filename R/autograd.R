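# Minimal reverse-mode automatic differentiation on base-R arrays.
#
# Every op below is dual-mode: called on plain numeric arrays it just computes
# the value, called on at least one tape node it records the operation so
# ag_backward() can accumulate gradients.  The same code path therefore serves
# inference (plain arrays) and training (nodes), which keeps the two from
# drifting apart.  Values are numeric vectors, matrices or 3-d arrays
# (height x width x channels for feature maps); gradients have the shape of
# the value they correspond to.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_is <- function(x) inherits(x, "ag_node")

ag_val <- function(x) if (ag_is(x)) x$value else x

ag_param <- function(tape, value) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$backfn <- NULL
  node$tape <- tape
  class(node) <- "ag_node"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- node
  node
}

# Record an op whose inputs `args` produced `value`; backfn(g) must return a
# list of gradients aligned with args (NULL entries for plain-array args).
ag_make <- function(args, value, backfn) {
  nodes <- Filter(ag_is, args)
  if (length(nodes) == 0L) return(value)
  node <- ag_param(nodes[[1L]]$tape, value)
  node$parents <- args
  node$backfn <- backfn
  node
}

ag_accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(tape, loss) {
  stopifnot(ag_is(loss), length(loss$value) == 1L)
  loss$grad <- 1
  for (k in rev(seq_len(tape$n))) {
    node <- tape$nodes[[k]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      if (ag_is(p) && !is.null(gs[[i]])) ag_accumulate(p, gs[[i]])
    }
    node$backfn <- NULL   # free closures as we go
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra primitives ------------------------------

ag_matmul <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_make(list(a, b), av %*% bv, function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# Addition with limited broadcasting: equal shapes; matrix + length-ncol
# vector (row bias); 3-d map + length-nchannel vector (channel bias); scalar.
ag_add <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  val <- ag_broadcast_combine(av, bv, `+`)
  ag_make(list(a, b), val, function(g) {
    list(ag_reduce_like(g, av), ag_reduce_like(g, bv))
  })
}

ag_sub <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  val <- ag_broadcast_combine(av, bv, `-`)
  ag_make(list(a, b), val, function(g) {
    list(ag_reduce_like(g, av), -ag_reduce_like(g, bv))
  })
}

# Elementwise product with the same broadcasting rules as ag_add.
ag_mul <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  val <- ag_broadcast_combine(av, bv, `*`)
  ag_make(list(a, b), val, function(g) {
    list(ag_reduce_like(g * ag_expand_like(bv, g), av),
         ag_reduce_like(g * ag_expand_like(av, g), bv))
  })
}

# Apply op to a pair where one side may be a broadcastable vector/scalar.
ag_broadcast_combine <- function(av, bv, op) {
  if (identical(dim(av), dim(bv)) && length(av) == length(bv)) return(op(av, bv))
  if (length(bv) == 1L || length(av) == 1L) return(op(av, bv))
  da <- dim(av); db <- dim(bv)
  if (!is.null(da) && is.null(db)) return(op(av, ag_expand_vec(bv, da)))
  if (is.null(da) && !is.null(db)) return(op(ag_expand_vec(av, db), bv))
  stop("non-conformable shapes in autodiff op")
}

ag_expand_vec <- function(v, d) {
  if (length(d) == 2L && length(v) == d[2L]) {
    return(matrix(v, d[1L], d[2L], byrow = TRUE))
  }
  if (length(d) == 3L && length(v) == d[3L]) {
    return(aperm(array(v, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L)))
  }
  stop("cannot broadcast vector of length ", length(v))
}

ag_expand_like <- function(x, g) {
  if (identical(length(x), length(g))) return(x)
  if (length(x) == 1L) return(x)
  ag_expand_vec(x, dim(g))
}

# Sum g down to the shape of target x (inverse of broadcasting).
ag_reduce_like <- function(g, x) {
  if (identical(length(g), length(x)) ) {
    if (!is.null(dim(x))) dim(g) <- dim(x) else g <- as.vector(g)
    return(g)
  }
  if (length(x) == 1L) return(sum(g))
  dg <- dim(g)
  if (length(dg) == 2L && length(x) == dg[2L]) return(colSums(g))
  if (length(dg) == 3L && length(x) == dg[3L]) return(apply(g, 3L, sum))
  stop("cannot reduce gradient to target shape")
}

ag_sigmoid <- function(a) {
  av <- ag_val(a)
  s <- plogis(av)
  ag_make(list(a), s, function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  av <- ag_val(a)
  v <- tanh(av)
  ag_make(list(a), v, function(g) list(g * (1 - v^2)))
}

ag_relu <- function(a) {
  av <- ag_val(a)
  v <- pmax(av, 0)
  if (!is.null(dim(av))) dim(v) <- dim(av)
  ag_make(list(a), v, function(g) list(g * (av > 0)))
}

# Numerically stable softplus ln(1 + e^x); derivative is the sigmoid.
ag_softplus <- function(a) {
  av <- ag_val(a)
  v <- pmax(av, 0) + log1p(exp(-abs(av)))
  if (!is.null(dim(av))) dim(v) <- dim(av)
  ag_make(list(a), v, function(g) list(g * plogis(av)))
}

ag_pow_const <- function(a, p) {
  av <- ag_val(a)
  ag_make(list(a), av^p, function(g) list(g * p * av^(p - 1)))
}

ag_sum <- function(a) {
  av <- ag_val(a)
  ag_make(list(a), sum(av), function(g) {
    gv <- array(g, dim = if (is.null(dim(av))) length(av) else dim(av))
    if (is.null(dim(av))) gv <- as.vector(gv)
    list(gv)
  })
}

ag_mean <- function(a) {
  av <- ag_val(a)
  n <- length(av)
  ag_make(list(a), mean(av), function(g) {
    gv <- array(g / n, dim = if (is.null(dim(av))) n else dim(av))
    if (is.null(dim(av))) gv <- as.vector(gv)
    list(gv)
  })
}

ag_reshape <- function(a, d) {
  av <- ag_val(a)
  v <- av
  dim(v) <- d
  ag_make(list(a), v, function(g) {
    if (is.null(dim(av))) list(as.vector(g)) else { dim(g) <- dim(av); list(g) }
  })
}

ag_aperm <- function(a, perm) {
  av <- ag_val(a)
  ag_make(list(a), aperm(av, perm), function(g) list(aperm(g, order(perm))))
}

ag_rbind <- function(args) {
  vals <- lapply(args, ag_val)
  rows <- vapply(vals, nrow, 1L)
  ag_make(args, do.call(rbind, vals), function(g) {
    out <- vector("list", length(vals))
    at <- 0L
    for (i in seq_along(vals)) {
      out[[i]] <- g[at + seq_len(rows[i]), , drop = FALSE]
      at <- at + rows[i]
    }
    out
  })
}

ag_cols <- function(a, idx) {
  av <- ag_val(a)
  ag_make(list(a), av[, idx, drop = FALSE], function(g) {
    gx <- matrix(0, nrow(av), ncol(av))
    gx[, idx] <- g
    list(gx)
  })
}

# Row-wise softmax with the standard analytic Jacobian-vector product.
ag_softmax_rows <- function(a) {
  av <- ag_val(a)
  m <- av - apply(av, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  ag_make(list(a), p, function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

## ---- losses -----------------------------------------------------------------

# Sum of elementwise binary cross-entropy on logits, optionally weighted.
ag_bce_logits <- function(logits, targets, weights = 1) {
  lv <- ag_val(logits)
  ce <- (pmax(lv, 0) + log1p(exp(-abs(lv)))) - lv * targets
  ag_make(list(logits), sum(weights * ce), function(g) {
    list(g * weights * (plogis(lv) - targets))
  })
}

# Sum of smooth-L1 (Huber, delta = 1) between pred and constant target.
ag_smooth_l1 <- function(pred, target) {
  pv <- ag_val(pred)
  d <- pv - target
  v <- sum(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
  ag_make(list(pred), v, function(g) {
    gd <- ifelse(abs(d) < 1, d, sign(d))
    if (!is.null(dim(pv))) dim(gd) <- dim(pv)
    list(g * gd)
  })
}

# Batch normalization over the rows of an n x k matrix (training mode,
# biased variance as is conventional).  Returns list(node, mean, var) so the
# caller can maintain running statistics.
ag_batchnorm_train <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_val(x); gv <- ag_val(gamma); bv <- ag_val(beta)
  n <- nrow(xv)
  if (n < 2L) {
    stop("batch normalization in training mode needs batch size >= 2 ",
         "(batch statistics are undefined for a single sample); ",
         "use eval mode for single-sample prediction")
  }
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  val <- sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`)
  node <- ag_make(list(x, gamma, beta), val, function(g) {
    gxhat <- sweep(g, 2L, gv, `*`)
    s1 <- colSums(gxhat)
    s2 <- colSums(gxhat * xhat)
    gx <- sweep(gxhat - matrix(s1 / n, n, length(mu), byrow = TRUE) -
                  sweep(xhat, 2L, s2 / n, `*`),
                2L, inv, `*`)
    list(gx, colSums(g * xhat), colSums(g))
  })
  list(out = node, mean = mu, var = va)
}
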