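test_that("image generation is bit-identical under a fixed seed", {
  s <- synthetic_image_spec(5, seed = 7)
  a <- generate_face_images(s)
  b <- generate_face_images(s)
  for (i in 1:5) {
    expect_identical(a$images[[i]]$image, b$images[[i]]$image)
    expect_identical(a$images[[i]]$boxes, b$images[[i]]$boxes)
  }
})

test_that("zero images produce empty outputs", {
  d <- generate_face_images(synthetic_image_spec(0, seed = 1))
  expect_length(d$images, 0)
  expect_equal(nrow(d$annotations), 0)
})

test_that("all ground-truth boxes lie inside the image", {
  d <- generate_face_images(synthetic_image_spec(20, seed = 8))
  ann <- d$annotations
  expect_true(all(ann$x_min >= 0 & ann$y_min >= 0))
  expect_true(all(ann$x_max <= 96 & ann$y_max <= 96))
  expect_true(all(ann$x_max > ann$x_min & ann$y_max > ann$y_min))
})

test_that("emitted boxes are exactly the stored ellipses' bounding boxes", {
  d <- generate_face_images(synthetic_image_spec(10, seed = 9))
  e <- d$ellipses[!d$ellipses$occluded, ]
  expect_equal(d$annotations$x_min, e$cx - e$rx)
  expect_equal(d$annotations$x_max, e$cx + e$rx)
  expect_equal(d$annotations$y_min, e$cy - e$ry)
  expect_equal(d$annotations$y_max, e$cy + e$ry)
})

test_that("noise-free targets sit at exactly the configured contrast over background", {
  # oracle: the same spec with contrast 0 consumes the identical RNG stream,
  # so the pixel-wise difference must be contrast * (union of ellipse masks)
  s1 <- synthetic_image_spec(5, noise_sd = 0, occlusion_prob = 0,
                             contrast = 0.2, seed = 10)
  s0 <- synthetic_image_spec(5, noise_sd = 0, occlusion_prob = 0,
                             contrast = 0, seed = 10)
  d1 <- generate_face_images(s1)
  d0 <- generate_face_images(s0)
  for (i in 1:5) {
    diffim <- d1$images[[i]]$image - d0$images[[i]]$image
    e <- d1$ellipses[d1$ellipses$image_id == i, ]
    n <- nrow(diffim)
    xs <- seq_len(n) - 0.5
    mask <- matrix(FALSE, n, n)
    for (t in seq_len(nrow(e))) {
      mask <- mask | outer(xs, xs, function(y, x) {
        ((x - e$cx[t]) / e$rx[t])^2 + ((y - e$cy[t]) / e$ry[t])^2 <= 1
      })
    }
    expect_equal(max(abs(diffim[mask] - 0.2)), 0, tolerance = 1e-12)
    expect_equal(max(abs(diffim[!mask])), 0, tolerance = 1e-12)
  }
})

test_that("eye aspect ratio carries the requested signal exactly", {
  sig <- c(0, 0.5, 1)
  d <- generate_face_images(synthetic_image_spec(3, eye_aspect_signal = sig,
                                                 noise_sd = 0, seed = 11))
  for (i in 1:3) {
    b <- d$images[[i]]$boxes
    eyes <- b[b$class == "eye", ]
    asp <- (eyes$y_max - eyes$y_min) / (eyes$x_max - eyes$x_min)
    expect_equal(asp, rep(0.5 + 0.45 * sig[i], 2), tolerance = 1e-9)
  }
})

test_that("oversized targets are rejected", {
  expect_error(synthetic_image_spec(1, target_scale_range = c(0.3, 0.5)),
               "target_scale_range")
})

test_that("occlusion drops annotations and flags the image", {
  d <- generate_face_images(synthetic_image_spec(40, occlusion_prob = 0.5,
                                                 seed = 12))
  n_boxes <- vapply(d$images, function(im) nrow(im$boxes), 1L)
  flags <- vapply(d$images, function(im) im$flagged, TRUE)
  expect_true(any(n_boxes < 3))
  expect_equal(flags, n_boxes < 3)
})

test_that("cohort has 36 named indicator columns plus one binary label", {
  co <- generate_clinical_cohort(synthetic_cohort_spec(50, seed = 13))
  expect_true(all(clinical_indicator_names() %in% names(co)))
  expect_length(clinical_indicator_names(), 36L)
  expect_true(all(co$label %in% c(0, 1)))
  expect_equal(ncol(co), 1 + 36 + 1)   # patient_id + indicators + label
})

test_that("null model gives prevalence 0.5 within binomial error", {
  spec <- synthetic_cohort_spec(5000, beta = numeric(36), gamma = 0,
                                intercept = 0, seed = 14)
  co <- generate_clinical_cohort(spec)
  expect_lt(abs(mean(co$label) - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("wrong beta length raises a dimension error", {
  expect_error(synthetic_cohort_spec(10, beta = numeric(10)), "length 36")
})

test_that("prevalence matches an independent Monte-Carlo sampler", {
  spec <- synthetic_cohort_spec(5000, seed = 15)
  co <- generate_clinical_cohort(spec)
  # independent oracle: sample the generative model directly
  set.seed(99)
  m <- 200000
  eta <- spec$intercept +
    as.vector(matrix(rnorm(m * 36), m, 36) %*% spec$beta) +
    spec$gamma * rnorm(m)
  p_mc <- mean(plogis(eta))
  se <- sqrt(p_mc * (1 - p_mc) / 5000)
  expect_lt(abs(mean(co$label) - p_mc), 3 * se)
})

test_that("fresh draws are exchangeable with the stated model", {
  # two-sample prevalence tests at the 1% level across 20 seeds: expect at
  # most ~1 rejection (allow 2 as slack for the discrete binomial)
  spec0 <- synthetic_cohort_spec(5000, seed = 1)
  rej <- 0L
  for (s in 1:20) {
    a <- generate_clinical_cohort(synthetic_cohort_spec(5000, seed = 100 + s))
    b <- generate_clinical_cohort(synthetic_cohort_spec(5000, seed = 200 + s))
    p <- stats::prop.test(c(sum(a$label), sum(b$label)),
                          c(5000, 5000))$p.value
    if (p < 0.01) rej <- rej + 1L
  }
  expect_lte(rej, 2L)
})

test_that("facial-signal linkage pairs by construction and breaks under shuffling", {
  spec <- synthetic_cohort_spec(200, seed = 16)
  co <- generate_clinical_cohort(spec)
  d <- generate_face_images(synthetic_image_spec(
    200, eye_aspect_signal = attr(co, "eye_aspect"), noise_sd = 0,
    seed = 17))
  linked <- link_facial_signal(d, co)
  asp <- vapply(d$images, function(im) {
    b <- im$boxes[im$boxes$class == "eye", ]
    mean((b$y_max - b$y_min) / (b$x_max - b$x_min))
  }, 1)
  expect_equal(stats::cor(asp, attr(co, "eye_aspect")), 1, tolerance = 1e-9)
  set.seed(18)
  cors <- replicate(10, stats::cor(sample(asp), attr(co, "signal")))
  expect_lt(stats::median(abs(cors)), 0.2)
  expect_error(link_facial_signal(d, co[1:100, ]), "pairing")
  one <- link_facial_signal(
    list(images = d$images[1]),
    structure(co[1, ], signal = attr(co, "signal")[1]))
  expect_equal(nrow(one$pairing), 1L)
})
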