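# ETED: the tabular survival classifier.  Feature vectors are partitioned
# into ordered pseudo-timesteps, passed through a per-timestep elementwise
# affine dense map, an LSTM, adaptive softmax(tanh) attention over the
# hidden trajectory, a sigmoid gate on the pooled representation, and a
# batch-normalized residual branch, ending in a single sigmoid output unit
# for the probability of death within seven days.

#' ETED configuration
#'
#' @param n_features Length of the input feature vector.
#' @param n_timesteps Number of ordered pseudo-timesteps `T` the features
#'   are partitioned into (zero-padded when `n_features` is not divisible).
#' @param hidden_size LSTM hidden state width.
#' @param learning_rate,epochs,batch_size Adam recipe.
#' @param val_fraction Fraction held out (stratified) for validation; 0
#'   disables the split and reports training metrics instead.
#' @param patience Early-stopping patience on validation AUC (epochs).
#' @param gate_target Where the sigmoid gate multiplies: the pooled
#'   attention output (`"pooled"`, default) or the hidden states
#'   (`"hidden"`).
#' @param threshold Probability cutoff for hard labels.
#' @param seed Integer seed.
#' @return List of class `"eted_config"`.
#' @export
eted_config <- function(n_features = 36L, n_timesteps = 6L, hidden_size = 16L,
                        learning_rate = 1e-3, epochs = 60L, batch_size = 32L,
                        val_fraction = 0.2, patience = 10L,
                        gate_target = c("pooled", "hidden"), threshold = 0.5,
                        seed = 1L) {
  structure(list(n_features = as.integer(n_features),
                 n_timesteps = as.integer(n_timesteps),
                 hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 gate_target = match.arg(gate_target), threshold = threshold,
                 seed = as.integer(seed)),
            class = "eted_config")
}

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

#' Initialize ETED parameters
#'
#' @param config An [eted_config()].
#' @return Nested list of numeric arrays; see [eted_forward()].
#' @export
eted_init <- function(config) {
  tt <- config$n_timesteps
  d <- ceiling(config$n_features / tt)
  h <- config$hidden_size
  lstm <- list()
  for (g in c("f", "i", "c", "o")) {
    lstm[[paste0("W_", g)]] <- glorot(h, h)
    lstm[[paste0("U_", g)]] <- glorot(d, h)
    lstm[[paste0("b_", g)]] <- numeric(h)
  }
  lstm$b_f <- rep(1, h)   # standard forget-gate bias
  list(lstm = lstm,
       dense = list(w = matrix(1, tt, d), alpha = matrix(0, tt, d)),
       attn = list(v = glorot(h, 1L), b = 0),
       gate = list(W = glorot(tt * d, h), b = numeric(h)),
       res = list(W = glorot(tt * d, h), b = numeric(h),
                  gamma = rep(1, h), beta = numeric(h), B = numeric(h)),
       head = list(w = glorot(h, 1L), b = 0))
}

#' One LSTM step
#'
#' Gate activations `f, i, o = sigmoid(W h + U x + b)`, cell update
#' `C = f * C_prev + i * tanh(W_c h + U_c x + b_c)`, hidden output
#' `h = o * tanh(C)`. All gates consume the same per-timestep input.
#'
#' @param x_t Input matrix (`n x d`, rows are samples) or a length-d vector.
#' @param state List with `h` and `C` (matrices `n x hidden`, or vectors).
#' @param params LSTM parameter list (`W_*` hidden-to-gate, `U_*`
#'   input-to-gate, `b_*`), as in [eted_init()]`$lstm`.
#' @return Updated state list with `h` and `C`.
#' @export
lstm_step <- function(x_t, state, params) {
  vec <- is.null(dim(ag_val(x_t)))
  as_row <- function(v) {
    if (ag_is(v)) ag_reshape(v, c(1L, length(ag_val(v)))) else matrix(ag_val(v), 1L)
  }
  if (vec) {
    x_t <- as_row(x_t)
    state <- list(h = as_row(state$h), C = as_row(state$C))
  }
  hprev <- state$h; cprev <- state$C
  gate <- function(W, U, b) {
    ag_add(ag_add(ag_matmul(hprev, W), ag_matmul(x_t, U)), b)
  }
  f <- ag_sigmoid(gate(params$W_f, params$U_f, params$b_f))
  i <- ag_sigmoid(gate(params$W_i, params$U_i, params$b_i))
  o <- ag_sigmoid(gate(params$W_o, params$U_o, params$b_o))
  cand <- ag_tanh(gate(params$W_c, params$U_c, params$b_c))
  C <- ag_add(ag_mul(f, cprev), ag_mul(i, cand))
  h <- ag_mul(o, ag_tanh(C))
  if (vec && !ag_is(h)) list(h = as.vector(h), C = as.vector(C))
  else list(h = h, C = C)
}

# Row extraction as a recorded op.
ag_row <- function(a, i) {
  av <- ag_val(a)
  ag_make(list(a), av[i, ], function(g) {
    gx <- matrix(0, nrow(av), ncol(av))
    gx[i, ] <- g
    list(gx)
  })
}

# Column binding of a list of n x k_i blocks.
ag_cbind <- function(args) {
  vals <- lapply(args, ag_val)
  cols <- vapply(vals, ncol, 1L)
  ag_make(args, do.call(cbind, vals), function(g) {
    out <- vector("list", length(vals))
    at <- 0L
    for (i in seq_along(vals)) {
      out[[i]] <- g[, at + seq_len(cols[i]), drop = FALSE]
      at <- at + cols[i]
    }
    out
  })
}

# Multiply an n x k matrix by a per-sample column (n x 1).
ag_mul_col <- function(a, col) {
  av <- ag_val(a); cv <- ag_val(col)
  val <- av * as.vector(cv)
  ag_make(list(a, col), val, function(g) {
    list(g * as.vector(cv), matrix(rowSums(g * av), ncol = 1L))
  })
}

#' Per-timestep elementwise affine map
#'
#' `z[t] = x[t] * w[t] + alpha[t]`, applied elementwise per timestep.
#'
#' @param x List over timesteps of `n x d` matrices (or length-d vectors).
#' @param w,alpha `T x d` weight and bias matrices.
#' @return List over timesteps of mapped matrices.
#' @export
dense_map <- function(x, w, alpha) {
  wv <- ag_val(w); av <- ag_val(alpha)
  lapply(seq_along(x), function(t) {
    xt <- x[[t]]
    vec <- is.null(dim(ag_val(xt)))
    if (vec) xt <- if (ag_is(xt)) ag_reshape(xt, c(1L, length(ag_val(xt)))) else matrix(ag_val(xt), 1L)
    wt <- if (ag_is(w)) ag_row(w, t) else wv[t, ]
    at <- if (ag_is(alpha)) ag_row(alpha, t) else av[t, ]
    out <- ag_add(ag_mul(xt, wt), at)
    if (vec && !ag_is(out)) as.vector(out) else out
  })
}

#' Adaptive attention weights over timesteps
#'
#' `weights = softmax(tanh(scores))` across timesteps, one weight per
#' timestep per sample; rows sum to one.
#'
#' @param scores `n x T` matrix of per-timestep scores, or a length-T
#'   vector for a single sample.
#' @return Matrix (or vector) of normalized attention weights.
#' @export
attention_weights <- function(scores) {
  sv <- ag_val(scores)
  vec <- is.null(dim(sv))
  if (vec && length(sv) == 0L) stop("attention needs at least one timestep")
  s <- if (vec) {
    if (ag_is(scores)) ag_reshape(scores, c(1L, length(sv))) else matrix(sv, 1L)
  } else scores
  w <- ag_softmax_rows(ag_tanh(s))
  if (vec) {
    if (ag_is(w)) ag_reshape(w, NULL) else as.vector(w)
  } else w
}

#' Attention-weighted pooling
#'
#' `R = sum_t weight[, t] * feature[[t]]` — the weighted sum of per-timestep
#' feature matrices under normalized attention weights.
#'
#' @param weights `n x T` matrix (or length-T vector) of weights.
#' @param features List over timesteps of `n x k` matrices (or vectors).
#' @return Pooled `n x k` matrix (or length-k vector).
#' @export
attention_pool <- function(weights, features) {
  wv <- ag_val(weights)
  vec <- is.null(dim(wv))
  tt <- if (vec) length(wv) else ncol(wv)
  if (tt != length(features)) stop("weights / features length mismatch")
  wmat <- if (vec) {
    if (ag_is(weights)) ag_reshape(weights, c(1L, tt)) else matrix(wv, 1L)
  } else weights
  acc <- NULL
  for (t in seq_len(tt)) {
    ft <- features[[t]]
    if (is.null(dim(ag_val(ft)))) {
      ft <- if (ag_is(ft)) ag_reshape(ft, c(1L, length(ag_val(ft)))) else matrix(ag_val(ft), 1L)
    }
    term <- ag_mul_col(ft, ag_cols(wmat, t))
    acc <- if (is.null(acc)) term else ag_add(acc, term)
  }
  if (vec) {
    if (ag_is(acc)) ag_reshape(acc, NULL) else as.vector(acc)
  } else acc
}

#' Sigmoid gate value
#'
#' `Gate = sigmoid(rowSums(R * f(z)))` — the inner product of the pooled
#' representation with a projection of the dense-mapped input, squashed to
#' `(0, 1)`; one gate value per sample.
#'
#' @param R Pooled representation, `n x h` matrix or length-h vector.
#' @param z_proj Projection `f(z)` of matching shape.
#' @return Gate values in `(0, 1)` (an `n x 1` matrix, or a scalar for
#'   vector input).
#' @export
gate_value <- function(R, z_proj) {
  rv <- ag_val(R)
  vec <- is.null(dim(rv))
  if (vec) {
    R <- if (ag_is(R)) ag_reshape(R, c(1L, length(rv))) else matrix(rv, 1L)
    zp <- ag_val(z_proj)
    z_proj <- if (ag_is(z_proj)) ag_reshape(z_proj, c(1L, length(zp))) else matrix(zp, 1L)
  }
  prod <- ag_mul(R, z_proj)
  ones <- matrix(1, ncol(ag_val(prod)), 1L)
  g <- ag_sigmoid(ag_matmul(prod, ones))
  if (vec) {
    if (ag_is(g)) ag_reshape(g, NULL) else as.vector(g)
  } else g
}

#' Batch-normalized residual branch
#'
#' `F = BatchNorm(ReLU(W z + b)) + B`, the skip branch added to the gated
#' representation. In training mode batch statistics are used (batch size
#' must exceed one); in eval mode the running statistics are applied
#' (momentum 0.1 updates during training).
#'
#' @param z_flat `n x (T d)` flattened dense-mapped input.
#' @param params Residual parameters (`W`, `b`, `gamma`, `beta`, `B`).
#' @param training Logical; batch vs running statistics.
#' @param running List with `mean` and `var` (updated and returned in
#'   training mode).
#' @param momentum Running-statistics momentum.
#' @return List with `out` (`n x h`) and `running`.
#' @export
residual_block <- function(z_flat, params, training = FALSE,
                           running = NULL, momentum = 0.1) {
  a <- ag_relu(ag_add(ag_matmul(z_flat, params$W), params$b))
  h <- length(ag_val(params$beta))
  if (is.null(running)) running <- list(mean = numeric(h), var = rep(1, h))
  if (training) {
    bn <- ag_batchnorm_train(a, params$gamma, params$beta)
    running <- list(mean = (1 - momentum) * running$mean + momentum * bn$mean,
                    var = (1 - momentum) * running$var + momentum * bn$var)
    out <- ag_add(bn$out, params$B)
  } else {
    xhat <- ag_mul(ag_sub(a, running$mean), 1 / sqrt(running$var + 1e-5))
    out <- ag_add(ag_add(ag_mul(xhat, params$gamma), params$beta), params$B)
  }
  list(out = out, running = running)
}

# Partition an n x p feature matrix into T timestep matrices (zero-padded).
split_timesteps <- function(x, n_timesteps) {
  p <- ncol(x)
  d <- ceiling(p / n_timesteps)
  if (d * n_timesteps > p) {
    x <- cbind(x, matrix(0, nrow(x), d * n_timesteps - p))
  }
  lapply(seq_len(n_timesteps), function(t) {
    x[, (t - 1L) * d + seq_len(d), drop = FALSE]
  })
}

#' ETED forward pass
#'
#' Features are reshaped into `T` pseudo-timesteps, passed through the
#' dense map and the LSTM; attention over the hidden trajectory pools the
#' states, the sigmoid gate modulates the pooled representation (or the
#' hidden states, per configuration), the batch-normalized residual branch
#' is added, and a single linear unit with a sigmoid yields the probability
#' of death within seven days.
#'
#' @param x `n x p` matrix of (standardized) features, or a single vector.
#' @param params [eted_init()] parameter list (plain or tape-wrapped).
#' @param config The [eted_config()].
#' @param training Logical, selects batch-norm mode.
#' @param running Batch-norm running statistics.
#' @return List with `p` (probability vector), `logit` (node / matrix),
#'   `attention` (`n x T`), `gate` (length-n), `hidden` (list of hidden
#'   matrices) and `running`.
#' @export
eted_forward <- function(x, params, config, training = FALSE, running = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  n <- nrow(x)
  xs <- split_timesteps(x, config$n_timesteps)
  z <- dense_map(xs, params$dense$w, params$dense$alpha)
  h <- config$hidden_size
  state <- list(h = matrix(0, n, h), C = matrix(0, n, h))
  hidden <- vector("list", length(z))
  for (t in seq_along(z)) {
    state <- lstm_step(z[[t]], state, params$lstm)
    hidden[[t]] <- state$h
  }
  score_cols <- lapply(hidden, function(ht) {
    ag_add(ag_matmul(ht, params$attn$v), params$attn$b)
  })
  scores <- ag_cbind(score_cols)
  attn <- attention_weights(scores)
  z_flat <- ag_cbind(z)
  zp <- ag_add(ag_matmul(z_flat, params$gate$W), params$gate$b)
  if (config$gate_target == "pooled") {
    pooled <- attention_pool(attn, hidden)
    gate <- gate_value(pooled, zp)
    gated <- ag_mul_col(pooled, gate)
  } else {
    pooled0 <- attention_pool(attn, hidden)
    gate <- gate_value(pooled0, zp)
    hidden_g <- lapply(hidden, function(ht) ag_mul_col(ht, gate))
    gated <- attention_pool(attn, hidden_g)
  }
  res <- residual_block(z_flat, params$res, training = training,
                        running = running)
  merged <- ag_add(gated, res$out)
  logit <- ag_add(ag_matmul(merged, params$head$w), params$head$b)
  list(p = as.vector(plogis(ag_val(logit))), logit = logit,
       attention = ag_val(attn), gate = as.vector(ag_val(gate)),
       hidden = hidden, running = res$running)
}

# Stratified train/validation row split.
stratified_split <- function(y, val_fraction) {
  val <- integer(0)
  for (cl in unique(y)) {
    rows <- which(y == cl)
    nv <- round(length(rows) * val_fraction)
    if (nv > 0L) val <- c(val, sample(rows, nv))
  }
  sort(val)
}

#' Train the ETED survival classifier
#'
#' Standardizes features with training-split statistics, then minimizes
#' binary cross-entropy with Adam on mini-batches, recording accuracy,
#' precision, recall, F1 and AUC on the validation split each epoch, with
#' early stopping on validation AUC. Deterministic given `config$seed`.
#'
#' @param x `n x p` numeric feature matrix or data frame.
#' @param y Binary 0/1 labels (1 = died within seven days).
#' @param config An [eted_config()] (its `n_features` is set from `x`).
#' @param verbose Print per-epoch metrics.
#' @return Object of class `"eted"`: trained parameters, standardization
#'   statistics, batch-norm running statistics, metric `history` and the
#'   configuration.
#' @export
train_eted <- function(x, y, config = eted_config(), verbose = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  config$n_features <- ncol(x)
  set.seed(config$seed)
  val_idx <- if (config$val_fraction > 0) stratified_split(y, config$val_fraction) else integer(0)
  if (length(val_idx) && length(unique(y[val_idx])) < 2L) {
    warning("validation split holds a single class (cohort too small); ",
            "reporting training-split metrics instead")
    val_idx <- integer(0)
  }
  tr_idx <- setdiff(seq_len(nrow(x)), val_idx)
  if (length(unique(y[tr_idx])) < 2L) {
    stop("training split contains a single class; cannot fit a classifier")
  }
  # missing values: mean-impute with training-split statistics only
  impute <- colMeans(x[tr_idx, , drop = FALSE], na.rm = TRUE)
  impute[is.nan(impute)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- impute[j]
  center <- colMeans(x[tr_idx, , drop = FALSE])
  scale <- apply(x[tr_idx, , drop = FALSE], 2L, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, `/`)
  xtr <- xs[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  xva <- xs[val_idx, , drop = FALSE]; yva <- y[val_idx]
  params <- eted_init(config)
  opt <- adam_state(params)
  running <- NULL
  best <- list(auc = -Inf, params = params, running = running, epoch = 0L)
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    # step decay late in the schedule sharpens convergence
    lr <- config$learning_rate * if (ep > 2 * config$epochs / 3) 0.3 else 1
    ord <- sample.int(length(ytr))
    nb <- ceiling(length(ord) / config$batch_size)
    splits <- split(ord, rep(seq_len(nb), each = config$batch_size,
                             length.out = length(ord)))
    # fold a lone remainder into the previous batch (batch norm needs >= 2)
    sizes <- lengths(splits)
    if (length(splits) > 1L && sizes[length(splits)] < 2L) {
      splits[[length(splits) - 1L]] <- c(splits[[length(splits) - 1L]],
                                         splits[[length(splits)]])
      splits[[length(splits)]] <- NULL
    }
    ep_loss <- 0
    for (b in splits) {
      tape <- ag_tape()
      wp <- ag_wrap_params(tape, params)
      fwd <- eted_forward(xtr[b, , drop = FALSE], wp, config,
                          training = TRUE, running = running)
      running <- fwd$running
      loss <- ag_mul(ag_bce_logits(fwd$logit, matrix(ytr[b], ncol = 1L)),
                     1 / length(b))
      ag_backward(tape, loss)
      st <- adam_step(params, ag_unwrap_grads(wp), opt, lr = lr)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + ag_val(loss) * length(b)
    }
    evx <- if (length(val_idx)) xva else xtr
    evy <- if (length(val_idx)) yva else ytr
    pv <- eted_forward(evx, params, config, training = FALSE,
                       running = running)$p
    cm <- classification_metrics(evy, pv, config$threshold)
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / length(ytr),
                             accuracy = cm$accuracy, precision = cm$precision,
                             recall = cm$recall, f1 = cm$f1, auc = cm$auc)
    if (verbose) {
      message(sprintf("epoch %d loss %.4f val auc %.3f", ep,
                      hist[[ep]]$loss, cm$auc))
    }
    if (cm$auc > best$auc + 1e-9) {
      best <- list(auc = cm$auc, params = params, running = running,
                   epoch = ep)
    }
    if (length(val_idx) && ep - best$epoch >= config$patience) break
  }
  structure(list(params = best$params, running = best$running,
                 config = config, center = center, scale = scale,
                 impute = impute,
                 feature_names = colnames(x),
                 history = do.call(rbind, hist), best_epoch = best$epoch),
            class = "eted")
}

#' @export
predict.eted <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (!is.null(object$impute)) {
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- object$impute[j]
  }
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  p <- eted_forward(xs, object$params, object$config, training = FALSE,
                    running = object$running)$p
  if (type == "prob") p else as.integer(p >= object$config$threshold)
}

#' @export
print.eted <- function(x, ...) {
  cat("ETED seven-day survival classifier\n")
  cat("  features:", x$config$n_features, " timesteps:",
      x$config$n_timesteps, " hidden:", x$config$hidden_size, "\n")
  cat("  parameters:", n_parameters(x$params), "\n")
  h <- x$history[x$best_epoch, ]
  cat(sprintf("  best epoch %d: accuracy %.3f, AUC %.3f\n",
              x$best_epoch, h$accuracy, h$auc))
  invisible(x)
}

#' @export
summary.eted <- function(object, ...) {
  print(object)
  cat("\nMetric history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
plot.eted <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$auc, type = "b",
                 xlab = "epoch", ylab = "validation AUC",
                 main = "ETED training history", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
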