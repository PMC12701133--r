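# Synthetic stand-ins for the two private modalities: face-like greyscale
# images with two ellipse "eyes" and one ellipse "lip" (exact bounding boxes
# known), and a clinical cohort drawn from a stated logistic model with a
# latent facial-signal channel linking the two.

#' Canonical clinical indicator names
#'
#' The 36 physiological indicators used by the cohort generator and expected
#' by the clinical CSV reader (temperature in deg C, pressures in mmHg,
#' scores unitless, laboratory values in their conventional units).
#'
#' @return Character vector of length 36.
#' @export
clinical_indicator_names <- function() {
  c("age", "apache", "temperature", "systolic_pressure", "diastolic_pressure",
    "map", "heart_rate", "respiratory_rate", "po2", "ph", "na", "k", "cr",
    "hct", "wbc", "gcs", "ae_score", "chronic_health_evaluation",
    "hemoglobin", "platelet", "pco2", "lac", "be", "alt", "ast", "bun",
    "bsl", "alb", "bil", "serum_calcium", "amylase", "lipase", "pt", "aptt",
    "fib", "d_dimer")
}

default_indicator_means <- function() {
  c(age = 65, apache = 14, temperature = 36.9, systolic_pressure = 115,
    diastolic_pressure = 66, map = 82, heart_rate = 100,
    respiratory_rate = 21, po2 = 98, ph = 7.43, na = 137, k = 4.5, cr = 178,
    hct = 30, wbc = 12.5, gcs = 9, ae_score = 3.9,
    chronic_health_evaluation = 0.7, hemoglobin = 101, platelet = 198,
    pco2 = 30, lac = 2.2, be = -1.1, alt = 52, ast = 82, bun = 17,
    bsl = 9.1, alb = 31, bil = 29, serum_calcium = 2.07, amylase = 90,
    lipase = 62, pt = 25, aptt = 42, fib = 4.3, d_dimer = 5)
}

default_indicator_sds <- function() {
  c(age = 14, apache = 6, temperature = 0.7, systolic_pressure = 22,
    diastolic_pressure = 13, map = 16, heart_rate = 22,
    respiratory_rate = 5, po2 = 30, ph = 0.07, na = 5, k = 0.9, cr = 110,
    hct = 6, wbc = 6, gcs = 4, ae_score = 1.6,
    chronic_health_evaluation = 0.9, hemoglobin = 21, platelet = 80,
    pco2 = 7, lac = 1.8, be = 4, alt = 60, ast = 110, bun = 10, bsl = 3.6,
    alb = 6, bil = 32, serum_calcium = 0.2, amylase = 70, lipase = 75,
    pt = 10, aptt = 12, fib = 1.4, d_dimer = 4)
}

#' Default generating coefficients of the synthetic cohort
#'
#' Coefficients of the generating logistic model, on standardized
#' indicators, for the label "died within seven days". Signs follow the
#' clinically expected directions: higher mean arterial pressure and
#' chronic health evaluation favour survival, while higher temperature,
#' prolonged coagulation times and elevated fibrinogen accompany death.
#'
#' @return Named length-36 numeric vector.
#' @export
default_beta <- function() {
  b <- stats::setNames(numeric(36L), clinical_indicator_names())
  b["temperature"] <- 0.8
  b["systolic_pressure"] <- -0.9
  b["map"] <- -1.2
  b["respiratory_rate"] <- 0.6
  b["gcs"] <- 1.0
  b["chronic_health_evaluation"] <- -0.8
  b["ast"] <- 0.5
  b["bil"] <- 0.6
  b["pt"] <- 0.9
  b["aptt"] <- 0.7
  b["fib"] <- 0.8
  b
}

#' Synthetic image specification
#'
#' @param n_images Number of images.
#' @param image_size Square image side in pixels.
#' @param target_scale_range Range of eye widths as a fraction of the image
#'   size (lips are 40 percent wider).
#' @param eye_aspect_signal Optional numeric vector in `[0, 1]`, one value
#'   per image, carried by the eye ellipses' height/width aspect ratio; by
#'   default drawn uniformly.
#' @param contrast Additive grey-level offset of a target over the local
#'   background.
#' @param noise_sd Standard deviation of additive pixel noise.
#' @param occlusion_prob Probability that a target is occluded (not
#'   rendered, its annotation dropped and the image flagged).
#' @param seed Integer seed.
#' @return A list of class `"synthetic_image_spec"`.
#' @export
synthetic_image_spec <- function(n_images, image_size = 96L,
                                 target_scale_range = c(0.12, 0.2),
                                 eye_aspect_signal = NULL, contrast = 0.45,
                                 noise_sd = 0.02, occlusion_prob = 0,
                                 seed = 1L) {
  if (max(target_scale_range) > 0.28) {
    stop("target_scale_range too large: targets would not fit the face layout")
  }
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 target_scale_range = target_scale_range,
                 eye_aspect_signal = eye_aspect_signal, contrast = contrast,
                 noise_sd = noise_sd, occlusion_prob = occlusion_prob,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Low-frequency background texture: coarse gaussian grid enlarged with the
# package's own cubic interpolation.
smooth_background <- function(n, base = 0.35, amp = 0.08) {
  coarse <- matrix(stats::rnorm(36), 6L, 6L)
  f <- n %/% 6L
  if (f * 6L != n) {
    ly <- bicubic_matrix(6L, ceiling(n / 6))[seq_len(n), , drop = FALSE]
    bg <- ly %*% coarse %*% t(ly)
  } else {
    ly <- bicubic_matrix(6L, f)
    bg <- ly %*% coarse %*% t(ly)
  }
  pmin(pmax(base + amp * bg, 0.05), 0.7)
}

render_ellipse <- function(img, cx, cy, rx, ry, contrast) {
  n <- nrow(img)
  xs <- (seq_len(n) - 0.5)   # 0-based pixel centers
  mx <- outer(rep(1, n), xs)  # column coordinate (x) per pixel
  my <- outer(xs, rep(1, n))  # row coordinate (y)
  mask <- ((mx - cx) / rx)^2 + ((my - cy) / ry)^2 <= 1
  img[mask] <- img[mask] + contrast
  img
}

#' Generate annotated face-like images
#'
#' Each image holds two ellipse "eyes" and one wider, flatter ellipse "lip"
#' as additive bright targets on a low-frequency textured background with
#' optional pixel noise. Eye aspect ratio (height/width) is
#' `0.5 + 0.45 * signal`, so the per-image `eye_aspect_signal` is carried by
#' target geometry. Ground-truth boxes are the exact ellipse bounding boxes
#' in 0-based half-open pixel corner coordinates. Deterministic given the
#' spec seed.
#'
#' @param spec A [synthetic_image_spec()].
#' @return List with `images` (list of `list(image, boxes, id, flagged)`),
#'   `annotations` (all boxes in one data frame), `ellipses` (generating
#'   parameters per target) and `signal` (the per-image aspect signal).
#' @export
generate_face_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  n <- spec$n_images
  sz <- spec$image_size
  signal <- spec$eye_aspect_signal
  if (is.null(signal)) signal <- stats::runif(n)
  if (n > 0L) stopifnot(length(signal) == n, all(signal >= 0 & signal <= 1))
  images <- vector("list", n)
  ann <- list()
  ell <- list()
  for (i in seq_len(n)) {
    img <- smooth_background(sz)
    asp <- 0.5 + 0.45 * signal[i]
    we <- stats::runif(1L, spec$target_scale_range[1L],
                       spec$target_scale_range[2L]) * sz
    wl <- 1.4 * stats::runif(1L, spec$target_scale_range[1L],
                             spec$target_scale_range[2L]) * sz
    jit <- function(f) f * sz + stats::runif(1L, -0.03, 0.03) * sz
    targets <- data.frame(
      class = c("eye", "eye", "lip"),
      cx = c(jit(0.30), jit(0.70), jit(0.50)),
      cy = c(jit(0.36), jit(0.36), jit(0.72)),
      rx = c(we, we, wl) / 2,
      ry = c(asp * we, asp * we, 0.35 * wl) / 2)
    occluded <- stats::runif(3L) < spec$occlusion_prob
    boxes <- list()
    for (t in seq_len(3L)) {
      if (occluded[t]) next
      img <- render_ellipse(img, targets$cx[t], targets$cy[t],
                            targets$rx[t], targets$ry[t], spec$contrast)
      boxes[[length(boxes) + 1L]] <- data.frame(
        image_id = i, class = targets$class[t],
        x_min = targets$cx[t] - targets$rx[t],
        y_min = targets$cy[t] - targets$ry[t],
        x_max = targets$cx[t] + targets$rx[t],
        y_max = targets$cy[t] + targets$ry[t])
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(sz * sz, sd = spec$noise_sd), sz, sz)
    }
    img <- pmin(pmax(img, 0), 1)
    boxes <- if (length(boxes)) do.call(rbind, boxes) else
      data.frame(image_id = integer(0), class = character(0),
                 x_min = numeric(0), y_min = numeric(0),
                 x_max = numeric(0), y_max = numeric(0))
    images[[i]] <- list(image = img, boxes = boxes, id = i,
                        flagged = any(occluded))
    ann[[i]] <- boxes
    ell[[i]] <- cbind(image_id = i, targets, occluded = occluded)
  }
  list(images = images,
       annotations = if (n > 0L) do.call(rbind, ann) else
         data.frame(image_id = integer(0), class = character(0),
                    x_min = numeric(0), y_min = numeric(0),
                    x_max = numeric(0), y_max = numeric(0)),
       ellipses = if (n > 0L) do.call(rbind, ell) else NULL,
       signal = signal)
}

#' Synthetic cohort specification
#'
#' Defines the generating logistic model for the seven-day survival label:
#' indicators are drawn from independent normal marginals (an optional
#' correlation matrix is supported), standardized by the stated means and
#' SDs, and the label (1 = died within seven days) follows
#' `Bernoulli(plogis(intercept + beta . x_std + gamma * s))` with a latent
#' standard-normal facial signal `s`.
#'
#' @param n_patients Number of patients.
#' @param beta Length-36 coefficient vector on standardized indicators.
#' @param gamma Coefficient of the latent facial signal.
#' @param intercept Intercept of the linear predictor.
#' @param indicator_means,indicator_sds Length-36 marginal parameters.
#' @param indicator_corr Optional 36 x 36 correlation matrix.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_cohort_spec"`.
#' @export
synthetic_cohort_spec <- function(n_patients = 298L, beta = default_beta(),
                                  gamma = 1.2, intercept = -1,
                                  indicator_means = default_indicator_means(),
                                  indicator_sds = default_indicator_sds(),
                                  indicator_corr = NULL, seed = 1L) {
  if (length(beta) != 36L) {
    stop("beta must have length 36 (one coefficient per indicator), got ",
         length(beta))
  }
  stopifnot(length(indicator_means) == 36L, length(indicator_sds) == 36L,
            all(indicator_sds > 0))
  structure(list(n_patients = as.integer(n_patients), beta = beta,
                 gamma = gamma, intercept = intercept,
                 indicator_means = indicator_means,
                 indicator_sds = indicator_sds,
                 indicator_corr = indicator_corr, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic clinical cohort
#'
#' Draws the 36 indicators and the binary seven-day label from the stated
#' logistic model of a [synthetic_cohort_spec()]. The latent facial signal
#' `s` and its `[0, 1]` mapping `pnorm(s)` (the image generator's aspect
#' signal) are attached as attributes `"signal"` and `"eye_aspect"`.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return Data frame with `patient_id`, the 36 indicator columns and
#'   `label` (1 = died within seven days).
#' @export
generate_clinical_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  p <- 36L
  z <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(spec$indicator_corr)) {
    z <- z %*% chol(spec$indicator_corr)
  }
  x <- sweep(sweep(z, 2L, spec$indicator_sds, `*`), 2L,
             spec$indicator_means, `+`)
  colnames(x) <- clinical_indicator_names()
  x_std <- sweep(sweep(x, 2L, spec$indicator_means), 2L,
                 spec$indicator_sds, `/`)
  s <- stats::rnorm(n)
  eta <- spec$intercept + as.vector(x_std %*% spec$beta) + spec$gamma * s
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)), x,
                    label = y, check.names = FALSE)
  attr(out, "signal") <- s
  attr(out, "eye_aspect") <- stats::pnorm(s)
  attr(out, "spec") <- spec
  out
}

#' Pair images with cohort rows through the facial signal
#'
#' Verifies one image per patient and that the images were generated with
#' the cohort's own eye-aspect signal, then records the pairing.
#'
#' @param images Result of [generate_face_images()] whose spec used
#'   `attr(cohort, "eye_aspect")` as the aspect signal.
#' @param cohort Result of [generate_clinical_cohort()].
#' @return List with `images`, `cohort` and `pairing` (data frame of
#'   `patient_id`, `image_id`, `signal`).
#' @export
link_facial_signal <- function(images, cohort) {
  n_img <- length(images$images)
  if (n_img != nrow(cohort)) {
    stop("pairing error: ", n_img, " image sets but ", nrow(cohort),
         " patients")
  }
  list(images = images, cohort = cohort,
       pairing = data.frame(patient_id = cohort$patient_id,
                            image_id = seq_len(n_img),
                            signal = attr(cohort, "signal")))
}
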