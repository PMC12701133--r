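test_that("group comparison returns exact means and a null p-value near 1", {
  co <- data.frame(v = rep(c(1, 2, 3, 4), 2), label = rep(c(0, 1), each = 4))
  row <- group_comparison(co, "v")
  expect_equal(row$mean_died, 2.5)
  expect_equal(row$mean_survived, 2.5)
  expect_gt(row$p_value, 0.99)
})

test_that("a large group difference is overwhelmingly significant", {
  set.seed(81)
  co <- data.frame(v = c(rnorm(200, 0), rnorm(200, 3)),
                   label = rep(c(0, 1), each = 200))
  expect_lt(group_comparison(co, "v")$p_value, 1e-10)
  expect_lt(group_comparison(co, "v", test = "wilcoxon")$p_value, 1e-10)
})

test_that("degenerate groups are rejected", {
  co <- data.frame(v = c(1, 2, 3), label = c(0, 0, 1))
  expect_error(group_comparison(co, "v"), "degenerate")
})

test_that("group table covers the canonical indicators with optional adjustment", {
  co <- generate_clinical_cohort(synthetic_cohort_spec(80, seed = 82))
  tab <- group_comparison_table(co)
  expect_equal(nrow(tab), 36L)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  tab2 <- group_comparison_table(co, adjust = "BH")
  expect_true(all(tab2$p_adjusted >= tab2$p_value - 1e-12))
})

test_that("intercept-only fit on balanced labels gives a zero intercept", {
  set.seed(83)
  x <- matrix(rnorm(100), 100, 1)
  colnames(x) <- "noise"
  y <- rep(c(0, 1), 50)
  fit <- logistic_fit(x * 0 + rnorm(100, sd = 1e-8) + x, y)
  # balanced outcome, uninformative predictor: intercept ~ 0
  ic <- fit$table[fit$table$variable == "(Intercept)", ]
  expect_lt(abs(ic$B), 0.5)
  expect_equal(fit$table$OR, exp(fit$table$B), tolerance = 1e-9)
})

test_that("2x2 table odds ratio equals the cross-product ratio exactly", {
  # cells: a=30 (x=1,y=1), b=10 (x=1,y=0), c=20, d=40
  x <- matrix(c(rep(1, 40), rep(0, 60)), ncol = 1)
  colnames(x) <- "exposure"
  y <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  fit <- logistic_fit(x, y)
  or <- fit$table$OR[fit$table$variable == "exposure"]
  expect_equal(or, (30 * 40) / (10 * 20), tolerance = 1e-6)
})

test_that("estimates and standard errors match glm as an independent oracle", {
  set.seed(84)
  x <- matrix(rnorm(300 * 4), 300, 4)
  colnames(x) <- paste0("v", 1:4)
  y <- rbinom(300, 1, plogis(0.5 + x %*% c(1, -0.7, 0, 0.3)))
  fit <- logistic_fit(x, y)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  sr <- summary(ref)$coefficients
  ours <- fit$table
  expect_equal(ours$B[ours$variable == "(Intercept)"],
               unname(sr["(Intercept)", 1]), tolerance = 1e-6)
  for (j in 1:4) {
    r <- ours[ours$variable == paste0("v", j), ]
    expect_equal(r$B, unname(sr[paste0("xv", j), 1]), tolerance = 1e-6)
    expect_equal(r$SE, unname(sr[paste0("xv", j), 2]), tolerance = 1e-5)
  }
})

test_that("the IRLS log-likelihood trace is non-decreasing", {
  set.seed(85)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- rbinom(200, 1, plogis(x %*% c(2, -1, 0.5)))
  fit <- logistic_fit(x, y)
  expect_true(all(diff(fit$loglik) > -1e-8))
})

test_that("zero-variance columns are dropped and separation is flagged", {
  set.seed(86)
  x <- cbind(const = rep(1, 50), v = rnorm(50))
  y <- rbinom(50, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  expect_warning(fit <- logistic_fit(x, y), "zero-variance")
  expect_false("const" %in% fit$table$variable)
  # perfectly separated data
  xs <- matrix(c(rep(-1, 25), rep(1, 25)), ncol = 1)
  colnames(xs) <- "sep"
  ys <- c(rep(0, 25), rep(1, 25))
  expect_warning(fs <- logistic_fit(xs, ys), "separation")
  expect_false(fs$converged)
})

test_that("coefficient recovery: quick replicate check at n = 2000", {
  set.seed(87)
  beta <- c(0.8, -0.5, 0, 0.3)
  ok <- 0L
  for (r in 1:10) {
    x <- matrix(rnorm(2000 * 4), 2000, 4)
    colnames(x) <- paste0("v", 1:4)
    y <- rbinom(2000, 1, plogis(-0.3 + x %*% beta))
    fit <- logistic_fit(x, y)
    tab <- fit$table[match(paste0("v", 1:4), fit$table$variable), ]
    if (all(abs(tab$B - beta) <= 3 * tab$SE)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("permutation impact: constants are exactly zero, null features small", {
  set.seed(88)
  n <- 300
  x <- cbind(strong = rnorm(n), null = rnorm(n), const = rep(2, n))
  y <- rbinom(n, 1, plogis(2.5 * x[, "strong"]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  cfg <- eted_config(hidden_size = 8L, epochs = 40L, val_fraction = 0,
                     seed = 5L)
  fit <- train_eted(x, y, cfg)
  imp <- feature_impact_ranking(fit, x, n_permutations = 3L, seed = 9L)
  expect_equal(imp$impact[imp$feature == "const"], 0)
  expect_equal(imp$feature[1], "strong")
  expect_gt(imp$impact[imp$feature == "strong"],
            2 * imp$impact[imp$feature == "null"])
  expect_error(feature_impact_ranking(fit, x, n_permutations = 0L),
               "n_permutations")
})

test_that("impact ranking tracks the generative coefficient magnitudes", {
  set.seed(89)
  n <- 400
  p <- 8
  beta <- c(2, -1.5, 1, 0.5, 0, 0, 0, 0)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("v", 1:p)
  y <- rbinom(n, 1, plogis(x %*% beta))
  cfg <- eted_config(hidden_size = 12L, epochs = 30L, val_fraction = 0,
                     seed = 6L)
  fit <- train_eted(x, y, cfg)
  imp <- feature_impact_ranking(fit, x, n_permutations = 3L, seed = 10L)
  rk <- match(paste0("v", 1:p), imp$feature)
  expect_gt(stats::cor(rank(-abs(beta)), rk, method = "kendall"), 0.5)
})
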