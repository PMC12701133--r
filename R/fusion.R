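# Fusion stage: summarize a patient's detections into a facial feature
# vector, standardize and concatenate with the clinical indicators (training
# statistics only), and run the unimodal-vs-multimodal experiment.

facial_feature_names <- function() {
  c("eye_count", "lip_count", "eye_confidence", "eye_aspect",
    "inter_eye_dist", "eye_area", "eye_aspect_sd", "miss_eye", "miss_lip")
}

#' Extract a facial feature vector from detections
#'
#' Deterministic geometric and confidence summaries of one patient's
#' detections: eye/lip counts, mean eye confidence, mean eye box aspect
#' ratio (height/width), center distance between the two most confident
#' eyes as a fraction of image width, mean eye box area as a fraction of
#' image area, and (with several frames per patient, grouped by `image_id`)
#' the across-frame standard deviation of the eye aspect — the variability
#' channel, 0 for a single frame. Missing geometry is mean-imputable
#' downstream; the `miss_eye` / `miss_lip` flags record absence.
#'
#' @param detections Data frame from [detect()] for one patient (possibly
#'   several frames); may be empty.
#' @param image_dim `c(height, width)` of the source images in pixels.
#' @return Named numeric vector (`NA` for missing geometric features,
#'   flags set accordingly); names from `eye_count` to `miss_lip`.
#' @export
extract_facial_features <- function(detections, image_dim) {
  h <- image_dim[1L]; w <- image_dim[2L]
  empty <- is.null(detections) || nrow(detections) == 0L
  frames <- if (empty) integer(0) else unique(detections$image_id)
  per <- lapply(frames, function(fr) {
    d <- detections[detections$image_id == fr, , drop = FALSE]
    eyes <- d[d$class == "eye", , drop = FALSE]
    lips <- d[d$class == "lip", , drop = FALSE]
    eyes <- eyes[order(-eyes$confidence), , drop = FALSE]
    top <- utils::head(eyes, 2L)
    asp <- if (nrow(top)) mean((top$y_max - top$y_min) /
                                 (top$x_max - top$x_min)) else NA_real_
    ied <- if (nrow(top) == 2L) {
      cx <- (top$x_min + top$x_max) / 2
      cy <- (top$y_min + top$y_max) / 2
      sqrt(diff(cx)^2 + diff(cy)^2) / w
    } else NA_real_
    area <- if (nrow(top)) mean((top$x_max - top$x_min) *
                                  (top$y_max - top$y_min)) / (h * w) else NA_real_
    c(eye_count = nrow(eyes), lip_count = nrow(lips),
      eye_confidence = if (nrow(eyes)) mean(eyes$confidence) else NA_real_,
      eye_aspect = asp, inter_eye_dist = ied, eye_area = area)
  })
  if (!length(per)) {
    out <- c(eye_count = 0, lip_count = 0, eye_confidence = NA_real_,
             eye_aspect = NA_real_, inter_eye_dist = NA_real_,
             eye_area = NA_real_, eye_aspect_sd = NA_real_,
             miss_eye = 1, miss_lip = 1)
    return(out)
  }
  m <- do.call(rbind, per)
  avg <- colMeans(m, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  aspect_sd <- if (length(frames) > 1L && sum(!is.na(m[, "eye_aspect"])) > 1L) {
    stats::sd(m[, "eye_aspect"], na.rm = TRUE)
  } else if (any(!is.na(m[, "eye_aspect"]))) 0 else NA_real_
  c(avg, eye_aspect_sd = aspect_sd,
    miss_eye = as.numeric(avg[["eye_count"]] == 0 || is.na(avg[["eye_aspect"]])),
    miss_lip = as.numeric(avg[["lip_count"]] == 0))
}

#' Training-split fusion statistics
#'
#' Means and standard deviations of indicators and facial features computed
#' on the training split only; frozen and reapplied to any other split so
#' no test information leaks into standardization or imputation.
#'
#' @param indicators `n x 36` matrix of the training split's indicators.
#' @param facial `n x f` matrix of the training split's facial features
#'   (NAs allowed).
#' @return List with `ind_center`, `ind_scale`, `fac_center`, `fac_scale`.
#' @export
fusion_statistics <- function(indicators, facial) {
  sd1 <- function(m) {
    s <- apply(m, 2L, stats::sd, na.rm = TRUE)
    s[s == 0 | is.na(s)] <- 1
    s
  }
  cmean <- function(m) {
    cm <- colMeans(m, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    cm
  }
  list(ind_center = cmean(indicators), ind_scale = sd1(indicators),
       fac_center = cmean(facial), fac_scale = sd1(facial))
}

#' Fuse clinical indicators with facial features
#'
#' Early concatenation after per-feature standardization with the
#' training-split statistics; missing facial values are imputed to the
#' training means (the missing-flag columns keep the information that they
#' were absent).
#'
#' @param indicators `n x 36` indicator matrix (any split).
#' @param facial `n x f` facial feature matrix aligned by row.
#' @param stats A [fusion_statistics()] list.
#' @return Standardized `n x (36 + f)` multimodal matrix.
#' @export
fuse_modalities <- function(indicators, facial, stats) {
  ind <- sweep(sweep(as.matrix(indicators), 2L, stats$ind_center), 2L,
               stats$ind_scale, `/`)
  fac <- as.matrix(facial)
  for (j in seq_len(ncol(fac))) {
    fac[is.na(fac[, j]), j] <- stats$fac_center[j]
  }
  fac <- sweep(sweep(fac, 2L, stats$fac_center), 2L, stats$fac_scale, `/`)
  cbind(ind, fac)
}

#' Run the unimodal-vs-multimodal survival experiment
#'
#' End to end on synthetic data: generates a cohort and one face image per
#' patient carrying the cohort's facial signal, trains (or reuses) the
#' detector, extracts facial features from its detections, and trains the
#' ETED classifier twice on identical splits and seeds — once on the 36
#' indicators alone, once on the fused multimodal matrix — reporting both
#' metric sets and confusion matrices side by side.
#'
#' @param config List: `cohort_spec` (a [synthetic_cohort_spec()]),
#'   `image_spec_args` (extra arguments for [synthetic_image_spec()]),
#'   `detector` (a trained `"fregnet_detector"` to reuse, else one is
#'   trained via `detector_config`), `detector_config`, `eted_config`,
#'   `train_fraction` (stratified, default 0.8) and `seed`.
#' @return List of class `"fusion_report"` with `unimodal`, `multimodal`
#'   (each: metrics plus confusion), `detection` (detector metrics on the
#'   test images), and `pairing` bookkeeping.
#' @export
run_pipeline <- function(config = list()) {
  # exact [[ ]] access throughout: $ partial matching would make
  # config$detector pick up a detector_config entry
  seed <- config[["seed"]] %||% 1L
  cohort_spec <- config[["cohort_spec"]] %||% synthetic_cohort_spec(seed = seed)
  eted_cfg <- config[["eted_config"]] %||% eted_config(seed = seed)
  train_fraction <- config[["train_fraction"]] %||% 0.8
  cohort <- generate_clinical_cohort(cohort_spec)
  n <- nrow(cohort)
  img_args <- config[["image_spec_args"]] %||% list()
  img_args$n_images <- n
  img_args$eye_aspect_signal <- attr(cohort, "eye_aspect")
  img_args$seed <- cohort_spec$seed + 1L
  images <- generate_face_images(do.call(synthetic_image_spec, img_args))
  linked <- link_facial_signal(images, cohort)
  detector <- config[["detector"]]
  set.seed(seed)
  test_idx <- stratified_split(cohort$label, 1 - train_fraction)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (is.null(detector)) {
    det_cfg <- config[["detector_config"]] %||% detector_config(seed = seed)
    detector <- train_detector(images$images[train_idx], det_cfg)
  }
  dets <- lapply(seq_len(n), function(i) {
    detect(images$images[[i]]$image, detector, image_id = i)
  })
  dim_img <- dim(images$images[[1L]]$image)[1:2]
  facial <- do.call(rbind, lapply(dets, extract_facial_features,
                                  image_dim = dim_img))
  indicators <- as.matrix(cohort[, clinical_indicator_names()])
  fstats <- fusion_statistics(indicators[train_idx, , drop = FALSE],
                              facial[train_idx, , drop = FALSE])
  fused <- fuse_modalities(indicators, facial, fstats)
  colnames(fused) <- c(clinical_indicator_names(), facial_feature_names())
  y <- cohort$label
  arm <- function(x) {
    fit <- train_eted(x[train_idx, , drop = FALSE], y[train_idx], eted_cfg)
    p <- predict(fit, x[test_idx, , drop = FALSE])
    list(fit = fit, metrics = classification_metrics(y[test_idx], p,
                                                     eted_cfg$threshold))
  }
  uni <- arm(indicators)
  multi <- arm(fused)
  det_metrics <- NULL
  gt_test <- do.call(rbind, lapply(images$images[test_idx], function(im) im$boxes))
  det_test <- do.call(rbind, dets[test_idx])
  if (!is.null(gt_test) && nrow(gt_test)) {
    det_metrics <- summarize_detection(det_test, gt_test)
  }
  structure(list(unimodal = uni$metrics, multimodal = multi$metrics,
                 detection = det_metrics,
                 unimodal_fit = uni$fit, multimodal_fit = multi$fit,
                 detector = detector,
                 test_idx = test_idx, pairing = linked$pairing,
                 n_test = length(test_idx), seed = seed),
            class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("Seven-day survival prediction: unimodal vs multimodal\n")
  cat(sprintf("  indicators only : accuracy %.3f  AUC %.3f\n",
              x$unimodal$accuracy, x$unimodal$auc))
  cat(sprintf("  + facial features: accuracy %.3f  AUC %.3f\n",
              x$multimodal$accuracy, x$multimodal$auc))
  if (!is.null(x$detection)) {
    cat(sprintf("  detector on test images: AP@0.5 %.3f\n", x$detection$ap50))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
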