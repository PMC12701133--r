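# Anchor-based one-stage detection head on the fused pyramid levels, with
# focal-loss / smooth-L1 training.  Boxes use 0-based half-open pixel corner
# coordinates (x_min, y_min, x_max, y_max) throughout.

#' Detector configuration
#'
#' Hyperparameters for the full detector: backbone, head, anchors and the
#' training recipe. Defaults suit 96-pixel face-like images with eye and lip
#' targets of roughly 10-20 pixels.
#'
#' @param image_size Square input size in pixels.
#' @param classes Character vector of target class names.
#' @param backbone A [fregnet_config()].
#' @param head_width Channel width of the shared head tower.
#' @param anchor_scales List (one vector per pyramid level) of anchor side
#'   scales in pixels (scale = sqrt(width x height)).
#' @param anchor_aspects Aspect ratios (height / width) shared by all levels.
#' @param iou_pos,iou_neg IoU assignment thresholds: anchors at or above
#'   `iou_pos` become positives, at or below `iou_neg` negatives, the rest
#'   are ignored. The best anchor for each ground-truth box is force-matched.
#' @param score_thresh Confidence threshold applied before NMS at detection
#'   time (a low value is used for evaluation).
#' @param nms_iou IoU threshold of per-class greedy non-maximum suppression.
#' @param loss Classification loss, `"focal"` (default) or `"bce"`.
#' @param focal_alpha,focal_gamma Focal loss parameters.
#' @param learning_rate,epochs Adam step size and passes over the data.
#' @param box_loss_weight Weight of the smooth-L1 box term.
#' @param seed Integer seed fixing initialization and data order.
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(image_size = 96L,
                            classes = c("eye", "lip"),
                            backbone = fregnet_config(
                              in_channels = 1L, stem_width = 8L,
                              widths = c(16L, 24L, 32L), depths = c(1L, 1L, 1L),
                              fpn_channels = 16L),
                            head_width = 16L,
                            anchor_scales = list(c(10, 14, 19), c(28, 40), c(56, 80)),
                            anchor_aspects = c(0.35, 0.7, 1.0),
                            iou_pos = 0.5, iou_neg = 0.4,
                            score_thresh = 0.05, nms_iou = 0.5,
                            loss = c("focal", "bce"),
                            focal_alpha = 0.5, focal_gamma = 2,
                            learning_rate = 5e-3, epochs = 12L,
                            box_loss_weight = 1, seed = 1L) {
  stopifnot(iou_neg <= iou_pos, length(classes) >= 1L)
  if (any(vapply(anchor_scales, length, 1L) == 0L)) {
    stop("each pyramid level needs at least one anchor scale")
  }
  structure(list(image_size = as.integer(image_size), classes = classes,
                 backbone = backbone, head_width = as.integer(head_width),
                 anchor_scales = anchor_scales, anchor_aspects = anchor_aspects,
                 iou_pos = iou_pos, iou_neg = iou_neg,
                 score_thresh = score_thresh, nms_iou = nms_iou,
                 loss = match.arg(loss),
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 box_loss_weight = box_loss_weight, seed = as.integer(seed)),
            class = "detector_config")
}

head_init <- function(config) {
  fc <- config$backbone$fpn_channels
  hw <- config$head_width
  k <- length(config$classes)
  a <- length(config$anchor_aspects) *
    max(vapply(config$anchor_scales, length, 1L))
  # final-layer convs start near zero (sd 0.01) with a prior-probability
  # class bias, the standard stable initialization for focal-loss heads
  cls <- list(w = array(stats::rnorm(hw * a * k, sd = 0.01),
                        c(1L, 1L, hw, a * k)),
              b = rep(-log((1 - 0.01) / 0.01), a * k))
  box <- list(w = array(stats::rnorm(hw * a * 4L, sd = 0.01),
                        c(1L, 1L, hw, a * 4L)),
              b = numeric(a * 4L))
  list(tower = conv_init(3L, fc, hw), cls = cls, box = box)
}

# Per-level anchor combo table; levels with fewer scales than the maximum
# reuse their last scale so the head channel count stays uniform.
anchor_combos <- function(config, level) {
  amax <- max(vapply(config$anchor_scales, length, 1L))
  sc <- config$anchor_scales[[level]]
  sc <- sc[pmin(seq_len(amax), length(sc))]
  expand.grid(scale = sc, aspect = config$anchor_aspects)
}

#' Generate anchors over pyramid levels
#'
#' Tiles every spatial location of each fused pyramid level with one anchor
#' per scale/aspect combination. Centers sit at cell centers
#' (`(index - 0.5) * stride`); widths and heights follow
#' `w = scale / sqrt(aspect)`, `h = scale * sqrt(aspect)`.
#'
#' @param level_dims List of `c(height, width)` per level.
#' @param strides Integer vector of level strides in pixels.
#' @param config A [detector_config()].
#' @return Data frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `level`; row order is (row fastest, then column, then combo, then
#'   level), matching the head output layout.
#' @export
generate_anchors <- function(level_dims, strides, config) {
  out <- vector("list", length(level_dims))
  for (l in seq_along(level_dims)) {
    h <- level_dims[[l]][1L]; w <- level_dims[[l]][2L]
    st <- strides[l]
    combos <- anchor_combos(config, l)
    cy <- (rep(seq_len(h), times = w) - 0.5) * st
    cx <- (rep(seq_len(w), each = h) - 0.5) * st
    per <- lapply(seq_len(nrow(combos)), function(a) {
      aw <- combos$scale[a] / sqrt(combos$aspect[a])
      ah <- combos$scale[a] * sqrt(combos$aspect[a])
      data.frame(x_min = cx - aw / 2, y_min = cy - ah / 2,
                 x_max = cx + aw / 2, y_max = cy + ah / 2, level = l)
    })
    out[[l]] <- do.call(rbind, per)
  }
  do.call(rbind, out)
}

# Pairwise IoU between two corner-coordinate box matrices (n x 4, m x 4).
corner_matrix <- function(x) {
  cn <- c("x_min", "y_min", "x_max", "y_max")
  if (is.data.frame(x) && all(cn %in% names(x))) {
    as.matrix(x[, cn, drop = FALSE])
  } else {
    as.matrix(x)[, 1:4, drop = FALSE]
  }
}

iou_matrix <- function(a, b) {
  a <- corner_matrix(a); b <- corner_matrix(b)
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, pmin(outer(a[, 3L], rep(1, m)), outer(rep(1, n), b[, 3L])) -
               pmax(outer(a[, 1L], rep(1, m)), outer(rep(1, n), b[, 1L])))
  iy <- pmax(0, pmin(outer(a[, 4L], rep(1, m)), outer(rep(1, n), b[, 4L])) -
               pmax(outer(a[, 2L], rep(1, m)), outer(rep(1, n), b[, 2L])))
  inter <- ix * iy
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  un <- outer(area_a, rep(1, m)) + outer(rep(1, n), area_b) - inter
  ifelse(un > 0, inter / un, 0)
}

#' Assign anchors to ground-truth boxes
#'
#' Standard IoU assignment: anchors with IoU at or above `iou_pos` to some
#' ground-truth box become positives carrying that box's class and
#' regression targets, anchors at or below `iou_neg` become negatives, the
#' rest are ignored. Every ground-truth box is force-matched to its
#' best-overlapping anchor so no target goes unsupervised.
#'
#' @param anchors Anchor data frame from [generate_anchors()].
#' @param gt Ground-truth data frame with corner columns and a `class`
#'   column.
#' @param iou_pos,iou_neg Assignment thresholds (`iou_neg <= iou_pos`).
#' @return List with `label` (1 positive / 0 negative / -1 ignored),
#'   `matched` (ground-truth row index, NA if none), `class` (matched class
#'   name), and `reg` (n x 4 matrix of box regression targets
#'   `(dx, dy, dw, dh)` in anchor-normalized log-space).
#' @export
match_anchors <- function(anchors, gt, iou_pos = 0.5, iou_neg = 0.4) {
  stopifnot(iou_neg <= iou_pos)
  n <- nrow(anchors)
  if (is.null(gt) || nrow(gt) == 0L) {
    return(list(label = rep(0L, n), matched = rep(NA_integer_, n),
                class = rep(NA_character_, n), reg = matrix(0, n, 4L)))
  }
  iou <- iou_matrix(anchors, gt)
  best <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(n), best)]
  label <- rep(-1L, n)
  label[best_iou <= iou_neg] <- 0L
  label[best_iou >= iou_pos] <- 1L
  # force-match: the best anchor for each ground truth becomes positive
  for (j in seq_len(nrow(gt))) {
    i <- which.max(iou[, j])
    if (iou[i, j] > 0) {
      label[i] <- 1L
      best[i] <- j
    }
  }
  matched <- ifelse(label == 1L, best, NA_integer_)
  reg <- matrix(0, n, 4L)
  pos <- which(label == 1L)
  if (length(pos)) {
    a <- corner_matrix(anchors[pos, , drop = FALSE])
    g <- corner_matrix(gt[best[pos], , drop = FALSE])
    aw <- a[, 3L] - a[, 1L]; ah <- a[, 4L] - a[, 2L]
    acx <- (a[, 1L] + a[, 3L]) / 2; acy <- (a[, 2L] + a[, 4L]) / 2
    gw <- g[, 3L] - g[, 1L]; gh <- g[, 4L] - g[, 2L]
    gcx <- (g[, 1L] + g[, 3L]) / 2; gcy <- (g[, 2L] + g[, 4L]) / 2
    reg[pos, ] <- cbind((gcx - acx) / aw, (gcy - acy) / ah,
                        log(gw / aw), log(gh / ah))
  }
  list(label = label, matched = matched,
       class = ifelse(is.na(matched), NA_character_,
                      as.character(gt$class[matched])),
       reg = reg)
}

decode_boxes <- function(anchors, reg) {
  a <- corner_matrix(anchors)
  aw <- a[, 3L] - a[, 1L]; ah <- a[, 4L] - a[, 2L]
  acx <- (a[, 1L] + a[, 3L]) / 2; acy <- (a[, 2L] + a[, 4L]) / 2
  cx <- acx + reg[, 1L] * aw; cy <- acy + reg[, 2L] * ah
  w <- aw * exp(pmin(reg[, 3L], 4)); h <- ah * exp(pmin(reg[, 4L], 4))
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Greedy non-maximum suppression
#'
#' Keeps the highest-confidence box, removes all remaining boxes whose IoU
#' with it exceeds `iou_thresh`, and repeats. Confidence ties are broken by
#' input order, so the result is deterministic.
#'
#' @param boxes Matrix or data frame of corner-coordinate boxes.
#' @param scores Numeric confidence vector.
#' @param iou_thresh Suppression IoU threshold.
#' @return Integer indices of surviving boxes, in decreasing confidence.
#' @export
nms <- function(boxes, scores, iou_thresh = 0.5) {
  if (length(scores) == 0L) return(integer(0))
  ord <- order(-scores)   # stable: ties keep input order
  boxes <- corner_matrix(boxes)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1L]
    iou <- iou_matrix(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])[1L, ]
    ord <- rest[iou <= iou_thresh]
  }
  keep
}

# Forward the backbone + head on one image; returns per-anchor class logits
# (n x K) and box regression outputs (n x 4), plus level dims for anchors.
detector_forward <- function(image, params, config) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  Fm <- fregnet_forward(image, params$backbone, config$backbone)
  k <- length(config$classes)
  a <- nrow(anchor_combos(config, 1L))
  cls_list <- list(); box_list <- list()
  dims <- list()
  for (l in seq_along(Fm)) {
    t <- ag_relu(ag_conv2d(Fm[[l]], params$head$tower$w, params$head$tower$b))
    cl <- ag_conv2d(t, params$head$cls$w, params$head$cls$b)
    bx <- ag_conv2d(t, params$head$box$w, params$head$box$b)
    d <- dim(ag_val(cl))
    dims[[l]] <- d[1:2]
    clm <- ag_reshape(cl, c(d[1L] * d[2L], a * k))
    bxm <- ag_reshape(bx, c(d[1L] * d[2L], a * 4L))
    for (ai in seq_len(a)) {
      cls_list[[length(cls_list) + 1L]] <- ag_cols(clm, (ai - 1L) * k + seq_len(k))
      box_list[[length(box_list) + 1L]] <- ag_cols(bxm, (ai - 1L) * 4L + seq_len(4L))
    }
  }
  list(cls = ag_rbind(cls_list), box = ag_rbind(box_list), level_dims = dims)
}

detector_strides <- function(config) {
  4L * 2L^seq_along(config$backbone$widths)
}

# Focal or plain BCE classification loss plus smooth-L1 box loss for one
# image, normalized by the number of positive anchors.
detector_loss <- function(fwd, assign, targets_cls, config) {
  lab <- assign$label
  used <- lab >= 0L
  npos <- max(1, sum(lab == 1L))
  logits <- fwd$cls
  lv_rows <- which(used)
  lsub <- ag_make(list(logits), ag_val(logits)[lv_rows, , drop = FALSE],
                  function(g) {
                    gx <- matrix(0, nrow(ag_val(logits)), ncol(ag_val(logits)))
                    gx[lv_rows, ] <- g
                    list(gx)
                  })
  tsub <- targets_cls[lv_rows, , drop = FALSE]
  if (config$loss == "focal") {
    p <- ag_sigmoid(lsub)
    ce_pos <- ag_softplus(ag_mul(lsub, -1))       # -log p
    ce_neg <- ag_softplus(lsub)                   # -log (1-p)
    mod_pos <- ag_pow_const(ag_sub(1, p), config$focal_gamma)
    mod_neg <- ag_pow_const(p, config$focal_gamma)
    term_pos <- ag_mul(ag_mul(mod_pos, ce_pos), config$focal_alpha * tsub)
    term_neg <- ag_mul(ag_mul(mod_neg, ce_neg), (1 - config$focal_alpha) * (1 - tsub))
    cls_loss <- ag_mul(ag_sum(ag_add(term_pos, term_neg)), 1 / npos)
  } else {
    cls_loss <- ag_mul(ag_bce_logits(lsub, tsub), 1 / npos)
  }
  pos <- which(lab == 1L)
  if (length(pos)) {
    bsub <- ag_make(list(fwd$box), ag_val(fwd$box)[pos, , drop = FALSE],
                    function(g) {
                      gx <- matrix(0, nrow(ag_val(fwd$box)), 4L)
                      gx[pos, ] <- g
                      list(gx)
                    })
    box_loss <- ag_mul(ag_smooth_l1(bsub, assign$reg[pos, , drop = FALSE]),
                       config$box_loss_weight / npos)
    ag_add(cls_loss, box_loss)
  } else {
    cls_loss
  }
}

#' Train the facial-feature detector
#'
#' Fits the FRegNet backbone and anchor head by per-image Adam steps on a
#' focal (or cross-entropy) classification loss plus a smooth-L1 box
#' regression loss over matched anchors. Fully deterministic given
#' `config$seed`.
#'
#' @param images List of labeled images, each `list(image =, boxes =, id =)`
#'   as produced by [generate_face_images()]; `boxes` has corner columns and
#'   `class`.
#' @param config A [detector_config()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `"fregnet_detector"` with elements `params`,
#'   `config`, `anchors`, and `losses` (mean loss per epoch).
#' @export
train_detector <- function(images, config = detector_config(), verbose = FALSE) {
  stopifnot(length(images) > 0L)
  set.seed(config$seed)
  params <- list(backbone = fregnet_init(config$backbone),
                 head = head_init(config))
  # precompute anchors from one forward pass
  fwd0 <- detector_forward(images[[1L]]$image, params, config)
  anchors <- generate_anchors(fwd0$level_dims, detector_strides(config), config)
  assigns <- lapply(images, function(im) {
    match_anchors(anchors, im$boxes, config$iou_pos, config$iou_neg)
  })
  if (!any(vapply(assigns, function(a) any(a$label == 1L), TRUE))) {
    stop("no anchor matched any ground-truth box; ",
         "rescale `anchor_scales` toward the target box sizes")
  }
  k <- length(config$classes)
  targets <- lapply(assigns, function(a) {
    t <- matrix(0, length(a$label), k)
    pos <- which(a$label == 1L)
    if (length(pos)) {
      t[cbind(pos, match(a$class[pos], config$classes))] <- 1
    }
    t
  })
  opt <- adam_state(params)
  losses <- numeric(config$epochs)
  step <- 0L
  warmup <- min(200L, length(images) * config$epochs %/% 4L)
  for (ep in seq_len(config$epochs)) {
    # step decay: drop the rate for the final third of training
    lr_ep <- config$learning_rate * if (ep > 2 * config$epochs / 3) 0.3 else 1
    ord <- sample.int(length(images))
    tot <- 0
    for (i in ord) {
      step <- step + 1L
      # linear warmup guards the focal loss against early collapse
      lr <- lr_ep * if (step < warmup) (0.1 + 0.9 * step / warmup) else 1
      tape <- ag_tape()
      wp <- ag_wrap_params(tape, params)
      fwd <- detector_forward(images[[i]]$image, wp, config)
      loss <- detector_loss(fwd, assigns[[i]], targets[[i]], config)
      ag_backward(tape, loss)
      grads <- ag_unwrap_grads(wp)
      # global-norm clipping: rare gradient spikes can collapse training
      gn <- sqrt(grad_sumsq(grads))
      if (is.finite(gn) && gn > 50) {
        grads <- map_params(grads, function(g) g * (50 / gn))
      }
      st <- adam_step(params, grads, opt, lr = lr)
      params <- st$params; opt <- st$state
      tot <- tot + ag_val(loss)
    }
    losses[ep] <- tot / length(images)
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, losses[ep]))
  }
  structure(list(params = params, config = config, anchors = anchors,
                 losses = losses),
            class = "fregnet_detector")
}

#' Run the detector on one image
#'
#' Forward pass, per-class sigmoid scores, confidence thresholding, box
#' decoding, clipping to image bounds and per-class greedy NMS.
#'
#' @param image `height x width x channels` array (a plain matrix is treated
#'   as one channel).
#' @param detector A `"fregnet_detector"` (or a list with `params`,
#'   `config`, `anchors` for an untrained head).
#' @param score_thresh,nms_iou Overrides of the configured thresholds.
#' @param image_id Identifier copied into the result rows.
#' @return Data frame of detections (`image_id`, `class`, corner columns,
#'   `confidence`), sorted by decreasing confidence.
#' @export
detect <- function(image, detector, score_thresh = NULL, nms_iou = NULL,
                   image_id = 1L) {
  config <- detector$config
  if (is.null(score_thresh)) score_thresh <- config$score_thresh
  if (is.null(nms_iou)) nms_iou <- config$nms_iou
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  fwd <- detector_forward(image, detector$params, config)
  anchors <- detector$anchors
  scores <- plogis(ag_val(fwd$cls))
  reg <- ag_val(fwd$box)
  boxes <- decode_boxes(anchors, reg)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  boxes[, c(1L, 3L)] <- pmin(pmax(boxes[, c(1L, 3L)], 0), w)
  boxes[, c(2L, 4L)] <- pmin(pmax(boxes[, c(2L, 4L)], 0), h)
  out <- list()
  for (ki in seq_along(config$classes)) {
    sc <- scores[, ki]
    cand <- which(sc >= score_thresh &
                    boxes[, 3L] > boxes[, 1L] & boxes[, 4L] > boxes[, 2L])
    if (!length(cand)) next
    keep <- nms(boxes[cand, , drop = FALSE], sc[cand], nms_iou)
    idx <- cand[keep]
    out[[length(out) + 1L]] <- data.frame(
      image_id = image_id, class = config$classes[ki],
      x_min = boxes[idx, 1L], y_min = boxes[idx, 2L],
      x_max = boxes[idx, 3L], y_max = boxes[idx, 4L],
      confidence = sc[idx])
  }
  if (!length(out)) {
    return(data.frame(image_id = integer(0), class = character(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      confidence = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(-res$confidence), , drop = FALSE]
}

#' @export
print.fregnet_detector <- function(x, ...) {
  cat("FRegNet facial-feature detector\n")
  cat("  classes:", paste(x$config$classes, collapse = ", "), "\n")
  cat("  parameters:", n_parameters(x$params), "\n")
  cat("  anchors:", nrow(x$anchors), "over",
      length(x$config$backbone$widths), "pyramid levels\n")
  cat("  epochs trained:", length(x$losses),
      sprintf("(final loss %.4f)\n", utils::tail(x$losses, 1L)))
  invisible(x)
}

#' @export
predict.fregnet_detector <- function(object, images, ...) {
  if (!is.null(dim(images)) && !is.list(images)) images <- list(list(image = images, id = 1L))
  out <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    detect(im$image, object, image_id = if (!is.null(im$id)) im$id else i)
  })
  do.call(rbind, out)
}

#' @export
plot.fregnet_detector <- function(x, ...) {
  graphics::plot(seq_along(x$losses), x$losses, type = "b",
                 xlab = "epoch", ylab = "mean training loss",
                 main = "Detector training loss", ...)
  invisible(x)
}
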