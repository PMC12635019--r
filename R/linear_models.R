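# Elastic-net (cyclic coordinate descent with soft-thresholding) and OLS
# clock fitting, plus the repeated 80/20 split evaluation scheme and the
# under-tuned EN vs OLS demonstration on the 5-CpG archetype block.
#
# The EN objective is
#   (1/2n) * sum_i (y_i - b - x_i . w)^2
#     + alpha * ( l1_ratio * ||w||_1 + (1 - l1_ratio)/2 * ||w||_2^2 ),
# with an unpenalized intercept. Features are standardized internally
# (mean 0, population SD 1) and coefficients reported on the original scale.

#' Elastic-net configuration
#'
#' @param alpha Penalty strength (>= 0). `alpha = 0` reduces the fit to OLS
#'   on a full-rank design; a very small alpha (preset `"ols-like"`, 0.001)
#'   behaves like OLS.
#' @param l1_ratio Lasso/ridge mix in \[0,1\]; 1 is pure lasso, 0 pure
#'   ridge. The `"lasso-heavy"` preset uses 0.8.
#' @param max_iter Maximum coordinate-descent sweeps; default 10000.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   update (standardized scale); default 1e-6.
#' @param standardize Standardize columns internally (default `TRUE`).
#' @param seed Integer seed recorded with the fit (the fitter itself is
#'   deterministic; the seed feeds split schemes).
#' @return An object of class `en_config`.
#' @export
en_config <- function(alpha = 0.01, l1_ratio = 0.5, max_iter = 10000L,
                      tol = 1e-6, standardize = TRUE, seed = 1L) {
  if (!is_scalar_num(alpha) || alpha < 0) stop_input("alpha must be >= 0")
  if (!is_scalar_num(l1_ratio) || l1_ratio < 0 || l1_ratio > 1) {
    stop_input("l1_ratio must lie in [0,1]")
  }
  if (!is_scalar_num(tol) || tol <= 0) stop_input("tol must be > 0")
  structure(list(alpha = alpha, l1_ratio = l1_ratio,
                 max_iter = as.integer(max_iter), tol = tol,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "en_config")
}

#' Named elastic-net presets
#'
#' `"ols-like"`: alpha 0.001, l1_ratio 0.5 — so weakly penalized the fit
#' behaves like OLS. `"lasso-heavy"`: alpha 0.01 with the 0.8/0.2 L1/L2
#' mix. `"under-tuned"`: deliberately over-penalized pure lasso (alpha 2,
#' l1_ratio 1) so that redundant collinear features are zeroed outright and
#' predictions shrink toward the training mean. (Any ridge admixture spreads
#' weight across exactly collinear features instead of zeroing them.)
#'
#' @param name One of `"ols-like"`, `"lasso-heavy"`, `"under-tuned"`.
#' @return An [en_config()].
#' @export
en_preset <- function(name = c("ols-like", "lasso-heavy", "under-tuned")) {
  switch(match.arg(name),
         "ols-like" = en_config(alpha = 0.001, l1_ratio = 0.5),
         "lasso-heavy" = en_config(alpha = 0.01, l1_ratio = 0.8),
         "under-tuned" = en_config(alpha = 2, l1_ratio = 1))
}

as_design <- function(X) {
  X <- as.matrix(unclass(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Ordinary least-squares fit
#'
#' Minimizes the residual sum of squares with an intercept; matches the
#' normal-equations solution. OLS keeps every feature and preserves
#' collinearity structure, so an exactly rank-deficient design is an error
#' (the offending columns are named) rather than a silently dropped
#' coefficient.
#'
#' @param X Numeric matrix (samples x features) or [beta_matrix()].
#' @param y Numeric response vector.
#' @return An object of class `fit_result`: `weights` (named, original
#'   scale), `intercept`, `n_selected`, `objective` (per-iteration RSS/2n),
#'   `converged`, `method`.
#' @export
fit_ols <- function(X, y) {
  X <- as_design(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_input("length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y)) stop_input("missing values not supported")
  if (n <= p + 1L) {
    stop_input("n_samples (%d) must exceed n_features + 1 (%d); use ridge or elastic net",
               n, p + 1L)
  }
  qx <- qr(cbind(`(Intercept)` = 1, X))
  if (qx$rank < p + 1L) {
    names0 <- c("(Intercept)", colnames(X))
    dep <- names0[qx$pivot[(qx$rank + 1L):(p + 1L)]]
    stop_input("design is rank deficient; collinear column(s): %s",
               paste(dep, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  w <- coefs[-1L]
  rss <- sum((y - qr.fitted(qx, y))^2)
  structure(list(weights = w, intercept = unname(coefs[1L]),
                 n_selected = sum(w != 0), objective = rss / (2 * n),
                 converged = TRUE, method = "ols", config = NULL),
            class = "fit_result")
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Elastic-net fit by cyclic coordinate descent
#'
#' Minimizes the elastic-net objective (see module header) by cyclic
#' coordinate descent with soft-thresholding, on internally standardized
#' columns (population SD), stopping when the largest absolute coefficient
#' update falls below `config$tol`. The objective value is recorded after
#' every sweep and is non-increasing by construction; the intercept is
#' never penalized. Coefficients are returned on the original scale.
#'
#' @param X Numeric matrix (samples x features) or [beta_matrix()].
#' @param y Numeric response vector.
#' @param config An [en_config()].
#' @return A `fit_result` with `weights`, `intercept`, `n_selected`,
#'   `objective` (numeric vector, one value per sweep), `converged`,
#'   `n_iter`, `config`.
#' @export
fit_elastic_net <- function(X, y, config = en_config()) {
  stopifnot(inherits(config, "en_config"))
  X <- as_design(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_input("length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y)) stop_input("missing values not supported")

  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  xs <- if (config$standardize) sqrt(colMeans(Xc^2)) else rep(1, p)
  const <- xs < 1e-12
  xs[const] <- 1              # constant columns stay at weight zero
  Xs <- sweep(Xc, 2L, xs, "/")
  ym <- mean(y)
  yc <- y - ym

  a <- config$alpha
  l1 <- config$l1_ratio
  lam1 <- a * l1
  lam2 <- a * (1 - l1)
  w <- rep(0, p)
  r <- yc                      # residual = yc - Xs %*% w
  xss <- colMeans(Xs^2)        # = 1 for standardized non-constant columns
  denom <- xss + lam2

  obj <- function() {
    mean(r^2) / 2 + a * (l1 * sum(abs(w)) + (1 - l1) / 2 * sum(w^2))
  }
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    max_delta <- 0
    for (j in seq_len(p)) {
      if (const[j]) next
      wj_old <- w[j]
      rho <- mean(Xs[, j] * r) + xss[j] * wj_old
      wj_new <- soft_threshold(rho, lam1) / denom[j]
      if (wj_new != wj_old) {
        r <- r - Xs[, j] * (wj_new - wj_old)
        w[j] <- wj_new
        max_delta <- max(max_delta, abs(wj_new - wj_old))
      }
    }
    objective <- c(objective, obj())
    if (max_delta < config$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("elastic net did not converge in %d sweeps (last update %.3g)",
                    config$max_iter, max_delta))
  }
  w_orig <- w / xs
  names(w_orig) <- colnames(X)
  intercept <- ym - sum(w_orig * xm)
  structure(list(weights = w_orig, intercept = intercept,
                 n_selected = sum(w_orig != 0), objective = objective,
                 converged = converged, n_iter = iter, method = "elastic_net",
                 config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result:%s> %d/%d features selected, intercept %.4g%s\n",
              x$method, x$n_selected, length(x$weights), x$intercept,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict from a fit result
#'
#' @param object A `fit_result`.
#' @param newdata Matrix of features (samples x features).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.fit_result <- function(object, newdata, ...) {
  X <- as_design(newdata)
  drop(X[, names(object$weights), drop = FALSE] %*% object$weights) +
    object$intercept
}

eval_metrics <- function(pred, actual) {
  list(mae = mean(abs(pred - actual)),
       pearson_r = if (stats::sd(pred) > 0 && stats::sd(actual) > 0) {
         stats::cor(pred, actual)
       } else NA_real_,
       residuals = pred - actual)
}

#' Repeated train/test split evaluation
#'
#' The standard clock-training protocol: the cohort is split into training
#' and test folds (default 80/20) `n_repeats` times with independent random
#' assignments, the fitter is trained on each training fold and evaluated
#' on the held-out fold. Per-repeat and pooled MAE / Pearson r / residuals
#' are reported. Deterministic under a fixed seed.
#'
#' @param X Feature matrix (samples x features).
#' @param y Response vector.
#' @param fitter Function `(X, y) -> fit_result`; e.g. [fit_ols()] or a
#'   closure around [fit_elastic_net()].
#' @param n_repeats Number of independent splits (>= 1); default 5.
#' @param test_fraction Held-out proportion in (0,1); default 0.2.
#' @param seed Integer seed.
#' @return A list with `per_repeat` (data.frame: repeat, n_test, mae,
#'   pearson_r), `pooled` (mae, pearson_r over all held-out predictions),
#'   `residuals` (list per repeat, named by sample), `splits` (test indices
#'   per repeat).
#' @export
repeated_split_eval <- function(X, y, fitter, n_repeats = 5,
                                test_fraction = 0.2, seed = 1L) {
  X <- as_design(X); y <- as.numeric(y)
  if (!is_count(n_repeats) || n_repeats < 1) stop_input("n_repeats must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_input("test_fraction must lie in (0,1)")
  }
  n <- nrow(X)
  n_test <- round(n * test_fraction)
  if (n_test < 2) stop_input("test fold would have < 2 samples")
  with_seed(seed, {
    splits <- lapply(seq_len(n_repeats), function(i) sort(sample.int(n, n_test)))
    per <- vector("list", n_repeats)
    resids <- vector("list", n_repeats)
    all_pred <- numeric(0); all_act <- numeric(0)
    for (i in seq_len(n_repeats)) {
      test <- splits[[i]]
      fit <- fitter(X[-test, , drop = FALSE], y[-test])
      pred <- predict(fit, X[test, , drop = FALSE])
      m <- eval_metrics(pred, y[test])
      per[[i]] <- data.frame(repeat_id = i, n_test = n_test, mae = m$mae,
                             pearson_r = m$pearson_r)
      resids[[i]] <- stats::setNames(m$residuals,
                                     rownames(X)[test] %||% as.character(test))
      all_pred <- c(all_pred, pred); all_act <- c(all_act, y[test])
    }
    pooled <- eval_metrics(all_pred, all_act)
    list(per_repeat = do.call(rbind, per),
         pooled = list(mae = pooled$mae, pearson_r = pooled$pearson_r),
         residuals = resids, splits = splits)
  })
}

#' Under-tuned elastic net versus OLS on the archetype block
#'
#' Reproduces the didactic contrast: on the 5-CpG archetype block an
#' over-penalized elastic net zeroes collinear age-tracking CpGs and
#' shrinks predictions toward the training mean (underpredicting older
#' samples), while OLS keeps every feature. OLS requires the full-rank
#' (noisy-collinear) variant; with an exactly collinear block the OLS
#' column drops the redundant CpG 3 (reported in the record).
#'
#' @param cohort A `synthetic_cohort` containing the 5-CpG archetype block
#'   (archetypes age_linear/collinear/normal/uniform), or a list with
#'   `beta` and `metadata`.
#' @param config Elastic-net configuration; default `en_preset("under-tuned")`.
#' @param test_fraction Held-out fraction for the prediction comparison.
#' @param seed Split seed.
#' @return A list: `en_fit`, `ols_fit` (or `NULL` with `ols_error` when the
#'   block is exactly collinear), `weights` (per-CpG side-by-side),
#'   `zeroed_collinear` (collinear-group CpGs EN zeroed), `test_predictions`
#'   (data.frame: sample_id, age, status, en_pred, ols_pred).
#' @export
under_tuned_en_demo <- function(cohort, config = en_preset("under-tuned"),
                                test_fraction = 0.2, seed = 1L) {
  labels <- cohort$archetype_labels
  keep <- names(labels)[labels %in% c("age_linear", "collinear", "normal", "uniform")]
  if (length(keep) < 5L) {
    stop_input("cohort lacks the 5-CpG archetype block (age_linear/collinear/normal/uniform)")
  }
  X <- as_design(cohort$beta)[, keep, drop = FALSE]
  y <- cohort$metadata$age
  n <- nrow(X)
  with_seed(seed, {
    test <- sort(sample.int(n, max(2L, round(n * test_fraction))))
  })
  Xtr <- X[-test, , drop = FALSE]; ytr <- y[-test]
  en_fit <- fit_elastic_net(Xtr, ytr, config)
  ols_fit <- NULL; ols_error <- NULL
  ols_fit <- tryCatch(fit_ols(Xtr, ytr), error = function(e) {
    ols_error <<- conditionMessage(e); NULL
  })
  collinear_group <- names(labels)[labels %in% c("age_linear", "collinear")]
  zeroed <- intersect(collinear_group, names(en_fit$weights)[en_fit$weights == 0])
  preds <- data.frame(
    sample_id = rownames(X)[test] %||% as.character(test),
    age = y[test],
    status = cohort$metadata$status[test],
    en_pred = predict(en_fit, X[test, , drop = FALSE]),
    ols_pred = if (!is.null(ols_fit)) predict(ols_fit, X[test, , drop = FALSE]) else NA_real_,
    stringsAsFactors = FALSE)
  weights <- data.frame(
    cpg = keep,
    archetype = unname(labels[keep]),
    en_weight = unname(en_fit$weights[keep]),
    ols_weight = if (!is.null(ols_fit)) unname(ols_fit$weights[keep]) else NA_real_,
    stringsAsFactors = FALSE)
  list(en_fit = en_fit, ols_fit = ols_fit, ols_error = ols_error,
       weights = weights, zeroed_collinear = zeroed,
       test_predictions = preds)
}

#' Convert a fit result to a clock model
#'
#' @param fit A `fit_result`.
#' @param name Model name.
#' @param response_proxy Response description.
#' @return A [clock_model()] (zero weights dropped).
#' @export
as_clock_model <- function(fit, name,
                           response_proxy = "chronological age (years)") {
  stopifnot(inherits(fit, "fit_result"))
  clock_model(name, fit$intercept, fit$weights[fit$weights != 0],
              response_proxy = response_proxy)
}
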