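test_that("residual stem with all-zero parameters outputs softplus(0) = ln 2", {
  set.seed(1)
  cfg <- fregnet_config(in_channels = 2L, stem_width = 3L,
                        widths = c(4L, 4L), depths = c(1L, 1L),
                        fpn_channels = 4L)
  p <- fregnet_init(cfg)$stem
  p <- facesurv:::map_params(p, function(v) v * 0)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  out <- rstem_forward(x, p)
  expect_equal(max(abs(out - log(2))), 0, tolerance = 1e-12)
})

test_that("residual stem output is strictly positive for random inputs", {
  set.seed(2)
  cfg <- fregnet_config(in_channels = 3L, stem_width = 4L,
                        widths = c(4L, 4L), depths = c(1L, 1L),
                        fpn_channels = 4L)
  for (r in 1:5) {
    p <- fregnet_init(cfg)$stem
    x <- array(rnorm(8 * 8 * 3, sd = 2), c(8, 8, 3))
    expect_gt(min(rstem_forward(x, p)), 0)
  }
})

test_that("residual stem matches the scalar-loop evaluation of its equations", {
  set.seed(3)
  cfg <- fregnet_config(in_channels = 3L, stem_width = 4L,
                        widths = c(4L, 4L), depths = c(1L, 1L),
                        fpn_channels = 4L)
  for (r in 1:10) {
    p <- fregnet_init(cfg)$stem
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    expect_lt(max(abs(rstem_forward(x, p) - oracle_rstem(x, p))), 1e-6)
  }
})

test_that("stem mismatched input channels raise a shape error", {
  set.seed(4)
  cfg <- fregnet_config(in_channels = 3L, stem_width = 4L,
                        widths = c(4L, 4L), depths = c(1L, 1L),
                        fpn_channels = 4L)
  p <- fregnet_init(cfg)$stem
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_error(rstem_forward(x, p), "channel mismatch")
})

test_that("body emits levels at strides 8, 16, 32 for a 96px input", {
  set.seed(5)
  cfg <- fregnet_config(in_channels = 1L, stem_width = 4L,
                        widths = c(4L, 6L, 8L), depths = c(1L, 1L, 1L),
                        fpn_channels = 4L)
  p <- fregnet_init(cfg)
  x <- array(rnorm(96 * 96), c(96, 96, 1))
  s <- facesurv:::ag_avgpool2(rstem_forward(x, p$stem, stride = 2L))
  C <- regnet_body_forward(s, p$stages)
  expect_equal(vapply(C, function(m) dim(m)[1], 1), c(12, 6, 3))
  expect_equal(vapply(C, function(m) dim(m)[3], 1), c(4, 6, 8))
})

test_that("zero-weight body propagates a constant (bias-only) map", {
  set.seed(6)
  cfg <- fregnet_config(in_channels = 1L, stem_width = 4L,
                        widths = c(4L, 4L), depths = c(1L, 2L),
                        fpn_channels = 4L)
  p <- facesurv:::map_params(fregnet_init(cfg)$stages, function(v) v * 0)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  C <- regnet_body_forward(x, p)
  for (m in C) expect_equal(max(abs(m - m[1, 1, 1])), 0)
})

test_that("too-small input for the downsampling depth raises a size error", {
  cfg <- fregnet_config(in_channels = 1L, stem_width = 2L,
                        widths = c(2L, 2L, 2L, 2L, 2L),
                        depths = rep(1L, 5L), fpn_channels = 2L)
  set.seed(7)
  p <- fregnet_init(cfg)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_error(regnet_body_forward(x, p$stages), "too small")
})

test_that("default backbone is far smaller than a 50-block bottleneck design", {
  set.seed(8)
  p <- fregnet_init(fregnet_config())
  n_ours <- n_parameters(p)
  # reference: 50 bottleneck blocks (1x1 / 3x3 / 1x1, expansion 4) at the
  # same stage widths, counted arithmetically
  widths <- c(32, 64, 128)
  n_ref <- 0
  for (w in rep(widths, length.out = 50)) {
    n_ref <- n_ref + w * 4 * w + 9 * w * w + w * 4 * w + 9 * w
  }
  expect_lt(n_ours, n_ref)
})

test_that("cubic upsampling reproduces constants exactly and accepts only factors 1-3", {
  x <- array(3.5, c(4, 5, 2))
  for (f in c(2L, 3L)) {
    up <- bicubic_upsample(x, f)
    expect_equal(dim(up), c(4L * f, 5L * f, 2L))
    expect_equal(max(abs(up - 3.5)), 0, tolerance = 1e-12)
  }
  expect_identical(bicubic_upsample(x, 1L), x)
  expect_error(bicubic_upsample(x, 4L), "factor")
})

test_that("cubic upsampling matches the textbook scalar implementation", {
  set.seed(9)
  for (f in c(2L, 3L)) {
    x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
    expect_lt(max(abs(bicubic_upsample(x, f) - oracle_bicubic(x, f))), 1e-6)
  }
  ramp <- array(seq_len(16), c(4, 4, 1))
  expect_lt(max(abs(bicubic_upsample(ramp, 2L) - oracle_bicubic(ramp, 2L))),
            1e-6)
})

test_that("cubic upsampling is linear in its input", {
  set.seed(10)
  x <- array(rnorm(5 * 5 * 1), c(5, 5, 1))
  y <- array(rnorm(5 * 5 * 1), c(5, 5, 1))
  a <- 2.7; b <- -1.3
  lhs <- bicubic_upsample(a * x + b * y, 2L)
  rhs <- a * bicubic_upsample(x, 2L) + b * bicubic_upsample(y, 2L)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("pyramid zero input with zero biases yields zero fused maps", {
  set.seed(11)
  cfg <- fregnet_config(in_channels = 1L, stem_width = 2L,
                        widths = c(3L, 4L), depths = c(1L, 1L),
                        fpn_channels = 3L)
  p <- facesurv:::map_params(fregnet_init(cfg)$fpn, function(v) v)
  C <- list(array(0, c(4, 4, 3)), array(0, c(2, 2, 4)))
  Fm <- fpafpn_forward(C, p)
  for (m in Fm) expect_equal(max(abs(m)), 0)
})

test_that("two-level toy pyramid with identity convolutions matches hand sums", {
  # 1-channel levels, 1x1 identity lateral/out convs, zero agg weights:
  # P2 = C2, P1 = C1 + up(C2); F1 = P1, F2 = P2 (agg contributes nothing)
  C1 <- array(rnorm(16), c(4, 4, 1))
  C2 <- array(rnorm(4), c(2, 2, 1))
  idconv <- list(w = array(1, c(1, 1, 1, 1)), b = 0)
  p <- list(lateral = list(idconv, idconv), out = list(idconv, idconv),
            agg = list(list(w = array(0, c(3, 3, 1, 1)), b = 0)))
  Fm <- fpafpn_forward(list(C1, C2), p)
  up <- bicubic_upsample(C2, 2L)
  expect_lt(max(abs(Fm[[1]] - (C1 + up))), 1e-9)
  expect_lt(max(abs(Fm[[2]] - C2)), 1e-9)
})

test_that("fused levels share the configured output width in both pass directions", {
  set.seed(12)
  cfg <- fregnet_config(in_channels = 1L, stem_width = 2L,
                        widths = c(3L, 4L, 5L), depths = c(1L, 1L, 1L),
                        fpn_channels = 6L)
  p <- fregnet_init(cfg)$fpn
  C <- list(array(rnorm(8 * 8 * 3), c(8, 8, 3)),
            array(rnorm(4 * 4 * 4), c(4, 4, 4)),
            array(rnorm(2 * 2 * 5), c(2, 2, 5)))
  for (dir in c("bottomup", "topdown")) {
    Fm <- fpafpn_forward(C, p, dir)
    expect_equal(vapply(Fm, function(m) dim(m)[3], 1), rep(6, 3))
    expect_equal(vapply(Fm, function(m) dim(m)[1], 1), c(8, 4, 2))
  }
})

test_that("backbone passes a finite-difference gradient check at tiny size", {
  set.seed(13)
  cfg <- fregnet_config(in_channels = 1L, stem_width = 2L,
                        widths = c(2L, 3L), depths = c(1L, 1L),
                        fpn_channels = 2L)
  params <- fregnet_init(cfg)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  lossfun <- function(p) {
    Fm <- facesurv:::fregnet_forward(x, p, cfg)
    sum(vapply(Fm, function(m) sum(facesurv:::ag_val(m)^2), 1))
  }
  tape <- facesurv:::ag_tape()
  wp <- facesurv:::ag_wrap_params(tape, params)
  Fm <- facesurv:::fregnet_forward(x, wp, cfg)
  loss <- facesurv:::ag_sum(facesurv:::ag_pow_const(Fm[[1]], 2))
  for (i in 2:length(Fm)) {
    loss <- facesurv:::ag_add(loss, facesurv:::ag_sum(facesurv:::ag_pow_const(Fm[[i]], 2)))
  }
  facesurv:::ag_backward(tape, loss)
  gfl <- facesurv:::flatten_params(facesurv:::ag_unwrap_grads(wp))
  fl <- facesurv:::flatten_params(params)
  worst <- 0
  for (nm in sample(names(fl), 12)) {
    j <- sample(length(fl[[nm]]), 1)
    fd <- fd_grad(lossfun, params, nm, j)
    worst <- max(worst, abs(fd - gfl[[nm]][j]) / max(1, abs(fd)))
  }
  expect_lt(worst, 1e-3)
})
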