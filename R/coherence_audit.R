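# Coefficient-sign coherence audit.
#
# A clock feature is "misaligned" (incoherent) when its model coefficient
# sign opposes the sign of its univariate Pearson correlation with age in a
# reference cohort. The audit quantifies, per model, the share of misaligned
# features and the share of total absolute model weight they carry, supports
# rectification (dropping or sign-constraining misaligned features), and
# measures the resulting trade-off between chronological-age accuracy and
# healthy-vs-disease residual separation.

#' Per-CpG univariate statistics against age
#'
#' Pearson correlation of each CpG's beta values with chronological age over
#' the chosen sample subset, plus mean/SD. The healthy-labeled subset is the
#' default anchor, mirroring the practice of anchoring univariate
#' correlations to a healthy reference cohort.
#'
#' @param beta A [beta_matrix()] (samples x CpGs).
#' @param metadata Metadata data.frame (`sample_id`, `age`, `status`).
#' @param subset `"healthy-only"` (default) or `"all"`.
#' @return A data.frame of class `univariate_stats`: `cpg`, `pearson_r`,
#'   `mean_beta`, `sd_beta`, `n_used`, `degenerate` (zero-variance flag;
#'   such CpGs get `pearson_r = 0`).
#' @export
univariate_stats <- function(beta, metadata,
                             subset = c("healthy-only", "all")) {
  subset <- match.arg(subset)
  stopifnot(inherits(beta, "beta_matrix"))
  md <- metadata[match(rownames(beta), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop_input("metadata does not cover all samples")
  keep <- if (subset == "healthy-only") md$status == "healthy" else rep(TRUE, nrow(md))
  if (sum(keep) < 3L) stop_input("need >= 3 samples after subsetting")
  age <- md$age[keep]
  if (stats::sd(age) == 0) stop_input("constant ages: correlation undefined")
  B <- unclass(beta)[keep, , drop = FALSE]
  sds <- apply(B, 2L, stats::sd)
  degenerate <- sds == 0
  r <- rep(0, ncol(B))
  if (any(!degenerate)) {
    r[!degenerate] <- drop(stats::cor(B[, !degenerate, drop = FALSE], age))
  }
  out <- data.frame(cpg = colnames(B), pearson_r = r,
                    mean_beta = colMeans(B), sd_beta = sds,
                    n_used = sum(keep), degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("univariate_stats", "data.frame")
  out
}

#' Audit a clock model for coefficient-sign coherence
#'
#' Each model CpG found in the reference statistics is classified:
#' `misaligned` if `sign(coefficient) * sign(r) < 0` and `|r| >=
#' neutral_band`; `coherent` if the signs agree (and `|r| >= neutral_band`);
#' `neutral` if `|r| < neutral_band` (with the default band of 0, only
#' exactly-zero correlations are neutral). Model CpGs absent from the
#' statistics are `unmatched` and excluded from all denominators.
#' Coefficients are additionally max-normalized per model (divided by the
#' largest absolute coefficient among audited CpGs).
#'
#' @param model A [clock_model()].
#' @param stats_df A [univariate_stats()] data.frame.
#' @param neutral_band Nonnegative |r| threshold below which a CpG is
#'   `neutral`; default 0 (strict sign comparison).
#' @return A list of class `coherence_report`: `model`, `n_audited`,
#'   `n_misaligned`, `n_coherent`, `n_neutral`, `n_unmatched`,
#'   `pct_misaligned`, `total_abs_weight`, `misaligned_abs_weight`,
#'   `pct_weight_misaligned`, and `records` (per-CpG data.frame: `cpg`,
#'   `coefficient`, `max_norm_coefficient`, `univariate_r`, `flag`).
#' @examples
#' st <- data.frame(cpg = c("cg1", "cg2"), pearson_r = c(0.5, -0.5))
#' m <- clock_model("toy", 0, c(cg1 = 1, cg2 = 1))
#' audit_model(m, st)$pct_misaligned  # cg2 opposes its correlation: 50
#' @export
audit_model <- function(model, stats_df, neutral_band = 0) {
  stopifnot(inherits(model, "clock_model"))
  if (neutral_band < 0) stop_input("neutral_band must be >= 0")
  w <- model$coefficients
  if (!length(w) || all(w == 0)) stop_input("model '%s' has no nonzero coefficients",
                                            model$name)
  ridx <- match(names(w), stats_df$cpg)
  matched <- !is.na(ridx)
  if (!any(matched)) stop_input("no overlap between model '%s' and reference stats",
                                model$name)
  r <- ifelse(matched, stats_df$pearson_r[ridx], NA_real_)
  flag <- rep("unmatched", length(w))
  is_neutral <- matched & abs(r) < neutral_band | (matched & r == 0)
  flag[matched] <- ifelse(is_neutral[matched], "neutral",
                          ifelse(sign(w[matched]) * sign(r[matched]) < 0,
                                 "misaligned", "coherent"))
  audited <- flag != "unmatched"
  max_abs <- max(abs(w[audited]))
  records <- data.frame(
    cpg = names(w), coefficient = unname(w),
    max_norm_coefficient = unname(w) / max_abs,
    univariate_r = unname(r), flag = flag,
    stringsAsFactors = FALSE, row.names = NULL)
  n_audited <- sum(audited)
  n_mis <- sum(flag == "misaligned")
  total_w <- sum(abs(w[audited]))
  mis_w <- sum(abs(w[flag == "misaligned"]))
  structure(list(
    model = model$name, n_audited = n_audited, n_misaligned = n_mis,
    n_coherent = sum(flag == "coherent"), n_neutral = sum(flag == "neutral"),
    n_unmatched = sum(!audited),
    pct_misaligned = 100 * n_mis / n_audited,
    total_abs_weight = total_w, misaligned_abs_weight = mis_w,
    pct_weight_misaligned = 100 * mis_w / total_w,
    neutral_band = neutral_band, records = records),
    class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf(
    "<coherence_report> %s: %d/%d misaligned (%.1f%%), %.1f%% of model weight%s\n",
    x$model, x$n_misaligned, x$n_audited, x$pct_misaligned,
    x$pct_weight_misaligned,
    if (x$n_unmatched) sprintf(", %d unmatched", x$n_unmatched) else ""))
  invisible(x)
}

#' Rectify an incoherent clock model
#'
#' Produces a model whose every audited coefficient agrees in sign with its
#' univariate age correlation (a simplified stand-in for full
#' incoherence-rectified retraining).
#'
#' `"drop"` mode removes misaligned CpGs; if `beta`/`metadata` are supplied
#' the intercept is re-centered so residuals average zero on that data
#' (and optionally all weights are refit by OLS on the retained set).
#' `"sign-constrained-refit"` refits every retained weight by least squares
#' subject to `sign(w_j) = sign(r_j)` (neutral CpGs unconstrained), which
#' requires `beta` and `metadata`.
#'
#' @param model A [clock_model()].
#' @param stats_df Reference [univariate_stats()].
#' @param mode `"drop"` (default) or `"sign-constrained-refit"`.
#' @param beta,metadata Optional (drop) / required (refit) training data.
#' @param refit_weights In drop mode, also refit retained weights by OLS;
#'   default `FALSE` (published weights are kept).
#' @param neutral_band Passed to the audit; default 0.
#' @return A rectified [clock_model()]; re-auditing it yields
#'   `pct_misaligned == 0`.
#' @export
rectify_model <- function(model, stats_df,
                          mode = c("drop", "sign-constrained-refit"),
                          beta = NULL, metadata = NULL,
                          refit_weights = FALSE, neutral_band = 0) {
  mode <- match.arg(mode)
  report <- audit_model(model, stats_df, neutral_band)
  rec <- report$records
  keep <- rec$cpg[rec$flag %in% c("coherent", "neutral")]
  if (!length(keep)) stop_input("all audited features are misaligned; empty model")
  name <- paste0(model$name, "_rectified")

  if (mode == "drop") {
    w <- model$coefficients[keep]
    intercept <- model$intercept
    if (!is.null(beta) && !is.null(metadata)) {
      md <- metadata[match(rownames(beta), metadata$sample_id), ]
      present <- intersect(keep, colnames(beta))
      if (refit_weights) {
        fit <- fit_ols(unclass(beta)[, present, drop = FALSE], md$age)
        w <- fit$weights
        intercept <- fit$intercept
      } else {
        lin <- drop(unclass(beta)[, present, drop = FALSE] %*% w[present])
        intercept <- mean(md$age) - mean(lin)
      }
    }
    out <- clock_model(name, intercept, w, model$response_proxy)
  } else {
    if (is.null(beta) || is.null(metadata)) {
      stop_input("sign-constrained refit requires beta and metadata")
    }
    md <- metadata[match(rownames(beta), metadata$sample_id), ]
    present <- intersect(keep, colnames(beta))
    if (!length(present)) stop_input("no retained CpGs present in training data")
    r <- stats_df$pearson_r[match(present, stats_df$cpg)]
    s <- sign(r)
    X <- unclass(beta)[, present, drop = FALSE]
    y <- md$age
    Xc <- sweep(X, 2L, colMeans(X)); yc <- y - mean(y)
    # sign constraints via NNLS on sign-flipped columns; neutral (r == 0)
    # CpGs enter twice with both orientations, making their weight free.
    free <- s == 0
    A <- sweep(Xc, 2L, ifelse(free, 1, s), "*")
    cols <- present
    if (any(free)) {
      A <- cbind(A, -Xc[, free, drop = FALSE])
      cols <- c(cols, paste0(present[free], "_neg"))
    }
    sol <- nnls_solve(A, yc)
    w <- sol$x[seq_along(present)] * ifelse(free, 1, s)
    if (any(free)) {
      w[free] <- w[free] - sol$x[(length(present) + 1L):length(sol$x)]
    }
    names(w) <- present
    w <- w[w != 0]
    if (!length(w)) stop_input("sign-constrained refit zeroed every feature")
    intercept <- mean(y) - sum(w * colMeans(X)[names(w)])
    out <- clock_model(name, intercept, w, model$response_proxy)
  }
  # postcondition: the rectified model is audit-clean
  post <- audit_model(out, stats_df, neutral_band)
  stopifnot(post$n_misaligned == 0L)
  out
}

#' Residual separation between healthy and disease samples
#'
#' Residuals (`prediction - age`, i.e. apparent age acceleration) are
#' compared between status groups: group means, their difference
#' (disease minus healthy), the standardized effect size (Cohen's d with
#' pooled SD), a rank-based two-sample (Wilcoxon) test, and overall MAE
#' against chronological age.
#'
#' @param model A [clock_model()].
#' @param beta A [beta_matrix()].
#' @param metadata Metadata with both status groups (>= 3 samples each).
#' @param missing_policy Forwarded to [apply_clock()].
#' @return A list of class `separation_result`: `mean_resid_healthy`,
#'   `mean_resid_disease`, `difference`, `effect_size`, `statistic`,
#'   `p_value`, `mae`, `n_healthy`, `n_disease`, `residuals`.
#' @export
residual_separation <- function(model, beta, metadata,
                                missing_policy = "zero") {
  md <- metadata[match(rownames(beta), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop_input("metadata does not cover all samples")
  groups <- split(seq_len(nrow(md)), md$status)
  for (g in c("healthy", "disease")) {
    if (length(groups[[g]] %||% integer(0)) < 3L) {
      stop_input("need >= 3 samples with status '%s'", g)
    }
  }
  pred <- apply_clock(model, beta, missing_policy = missing_policy)$predictions
  resid <- pred - md$age
  rh <- resid[groups$healthy]; rd <- resid[groups$disease]
  pooled_sd <- sqrt(((length(rh) - 1) * stats::var(rh) +
                       (length(rd) - 1) * stats::var(rd)) /
                      (length(rh) + length(rd) - 2))
  d <- if (pooled_sd > 0) (mean(rd) - mean(rh)) / pooled_sd else 0
  wt <- stats::wilcox.test(rd, rh, exact = FALSE)
  structure(list(
    mean_resid_healthy = mean(rh), mean_resid_disease = mean(rd),
    difference = mean(rd) - mean(rh), effect_size = d,
    statistic = unname(wt$statistic), p_value = wt$p.value,
    mae = mean(abs(resid)), n_healthy = length(rh), n_disease = length(rd),
    residuals = resid), class = "separation_result")
}

#' Accuracy versus biological-resolution trade-off experiment
#'
#' Trains an elastic-net age clock on a synthetic inflammaging cohort,
#' audits it against healthy-subset univariate statistics, rectifies it
#' (drop mode), and compares the original and rectified models on held-out
#' samples: chronological-age MAE and healthy-vs-disease residual
#' separation. On cohorts whose disease-informative CpGs let the fitter
#' cancel the disease signal, rectification is expected to increase
#' separation at the cost of accuracy.
#'
#' @param cohort A `synthetic_cohort` with both status groups.
#' @param config Elastic-net configuration; default
#'   `en_config(alpha = 0.1, l1_ratio = 0.5)`.
#' @param train_fraction Training proportion; default 0.7.
#' @param neutral_band Audit neutral band; default 0.
#' @param seed Split seed.
#' @return A list of class `tradeoff_result`: `original`, `rectified`
#'   (each a `separation_result` on the held-out set), `audit` (the
#'   original model's `coherence_report`), `model`, `rectified_model`,
#'   `delta_mae` (rectified - original), `delta_effect_size`.
#' @export
tradeoff_experiment <- function(cohort, config = en_config(alpha = 0.1,
                                                           l1_ratio = 0.5),
                                train_fraction = 0.7, neutral_band = 0,
                                seed = 1L) {
  beta <- cohort$beta
  md <- cohort$metadata
  n <- nrow(beta)
  with_seed(seed, {
    train <- sort(sample.int(n, round(n * train_fraction)))
  })
  test <- setdiff(seq_len(n), train)
  btr <- beta_matrix(unclass(beta)[train, , drop = FALSE])
  bte <- beta_matrix(unclass(beta)[test, , drop = FALSE])
  mtr <- md[train, ]; mte <- md[test, ]

  fit <- fit_elastic_net(btr, mtr$age, config)
  model <- as_clock_model(fit, "en_clock")
  st <- univariate_stats(btr, mtr, subset = "healthy-only")
  audit <- audit_model(model, st, neutral_band)
  rect <- rectify_model(model, st, mode = "drop", beta = btr, metadata = mtr,
                        neutral_band = neutral_band)
  orig_sep <- residual_separation(model, bte, mte)
  rect_sep <- residual_separation(rect, bte, mte)
  structure(list(original = orig_sep, rectified = rect_sep, audit = audit,
                 model = model, rectified_model = rect,
                 delta_mae = rect_sep$mae - orig_sep$mae,
                 delta_effect_size = rect_sep$effect_size - orig_sep$effect_size),
            class = "tradeoff_result")
}
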