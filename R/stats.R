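# Survival-factor statistics: group comparison of indicators between the
# died and survived groups, dichotomous logistic regression with Wald
# inference, and permutation-based feature-impact ranking for a trained
# classifier.

#' Group comparison of one indicator between outcome groups
#'
#' Means in the died (label 1) and survived (label 0) groups with a
#' two-sided Welch two-sample p-value (default) or a Mann-Whitney test.
#'
#' @param cohort Data frame with the indicator column and `label`.
#' @param variable Indicator column name.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return Data frame row with `variable`, `mean_died`, `mean_survived`,
#'   `p_value`.
#' @export
group_comparison <- function(cohort, variable, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  x <- cohort[[variable]]
  stopifnot(is.numeric(x))
  died <- x[cohort$label == 1]
  surv <- x[cohort$label == 0]
  if (length(died) < 2L || length(surv) < 2L) {
    stop("degenerate group: need at least 2 observations per outcome group")
  }
  p <- if (test == "welch") {
    stats::t.test(died, surv)$p.value
  } else {
    stats::wilcox.test(died, surv, exact = FALSE)$p.value
  }
  data.frame(variable = variable, mean_died = mean(died),
             mean_survived = mean(surv), p_value = p)
}

#' Group-comparison table for many indicators
#'
#' @param cohort Cohort data frame with a binary `label` column.
#' @param variables Indicator names (default: all 36 canonical indicators
#'   present in the cohort).
#' @param test Passed to [group_comparison()].
#' @param adjust Optional p-value adjustment method (e.g. `"BH"`); `"none"`
#'   (default) reports marginal p-values.
#' @return Data frame, one row per variable.
#' @export
group_comparison_table <- function(cohort, variables = NULL,
                                   test = c("welch", "wilcoxon"),
                                   adjust = "none") {
  if (is.null(variables)) {
    variables <- intersect(clinical_indicator_names(), names(cohort))
  }
  out <- do.call(rbind, lapply(variables, group_comparison, cohort = cohort,
                               test = test))
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  out
}

#' Dichotomous logistic regression with Wald inference
#'
#' Maximum likelihood by iteratively reweighted least squares. Per
#' coefficient: estimate `B`, standard error from the observed information,
#' standardized coefficient `Beta = B * sd(column)`, Wald `t = B / SE`, 95
#' percent Wald interval `B +/- 1.96 SE`, and odds ratio `exp(B)`.
#' Zero-variance columns are dropped with a warning; likely separation is
#' flagged via `converged`.
#'
#' @param x `n x p` numeric design matrix (no intercept column; one is
#'   added).
#' @param y Binary 0/1 response.
#' @param max_iter,tol IRLS iteration control.
#' @return Object of class `"logistic_fit"`: coefficient `table` (intercept
#'   row last), `loglik` trace, `converged`, `n`.
#' @export
logistic_fit <- function(x, y, max_iter = 50L, tol = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (nrow(x) <= ncol(x)) stop("need more observations than predictors")
  sds <- apply(x, 2L, stats::sd)
  drop <- which(sds == 0 | is.na(sds))
  if (length(drop)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, -drop, drop = FALSE]
    sds <- sds[-drop]
  }
  X <- cbind(x, `(Intercept)` = 1)
  p <- ncol(X)
  beta <- numeric(p)
  ll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  lls <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    # IRLS update with step halving so the log-likelihood never decreases
    z <- eta + (y - mu) / w
    xtw <- t(X * w)
    new_beta <- tryCatch(solve(xtw %*% X, xtw %*% z),
                         error = function(e) NULL)
    if (is.null(new_beta)) break
    new_beta <- as.vector(new_beta)
    step <- 1
    while (ll(beta + step * (new_beta - beta)) < ll(beta) && step > 1e-4) {
      step <- step / 2
    }
    new_beta <- beta + step * (new_beta - beta)
    lls <- c(lls, ll(new_beta))
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  # fitted log-odds pinned at extreme values indicate separation
  separated <- max(abs(X %*% beta)) > 25
  if (separated) {
    warning("possible perfect separation: coefficients diverged; ",
            "estimates reported as non-converged")
    converged <- FALSE
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X
  se <- sqrt(diag(tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })))
  sd_cols <- c(sds, NA_real_)   # intercept has no scale
  tab <- data.frame(
    variable = colnames(X),
    B = beta, SE = se, Beta = beta * sd_cols, t = beta / se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    OR = exp(beta))
  structure(list(table = tab, loglik = lls, converged = converged,
                 n = nrow(X)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Dichotomous logistic regression (n = %d, %sconverged)\n",
              x$n, if (x$converged) "" else "NOT "))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Permutation feature-impact ranking
#'
#' Mean absolute change of a model's predicted probability when one feature
#' column is permuted within itself, averaged over `n_permutations` draws;
#' features are returned sorted by decreasing impact. Model-agnostic: any
#' `predict(model, x)` returning probabilities works.
#'
#' @param model A trained model (e.g. an `"eted"` fit).
#' @param x Feature matrix or data frame to evaluate on.
#' @param n_permutations Permutations per feature (must be >= 1).
#' @param top_k Report the `top_k` largest impacts (default all).
#' @param seed Integer seed for the permutations.
#' @return Data frame with `feature` and `impact`, sorted descending.
#' @export
feature_impact_ranking <- function(model, x, n_permutations = 5L,
                                   top_k = NULL, seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  x <- as.matrix(x)
  set.seed(seed)
  base <- as.vector(predict(model, x))
  imp <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    acc <- 0
    for (r in seq_len(n_permutations)) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      acc <- acc + mean(abs(as.vector(predict(model, xp)) - base))
    }
    imp[j] <- acc / n_permutations
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  out <- data.frame(feature = nm, impact = imp)
  out <- out[order(-out$impact), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
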