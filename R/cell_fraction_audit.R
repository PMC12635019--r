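# Leukocyte-composition audit.
#
# Reference-based deconvolution of bulk beta values into 12 immune cell
# fractions (nonnegative least squares with sum-to-one renormalization, a
# documented stand-in for reference-based deconvolution tools), per-CpG
# Spearman correlations against each fraction, and the baseline-vs-augmented
# variance inflation factor (VIF) audit quantifying how much of a clock's
# CpG collinearity is attributable to each cell type.

#' Deconvolve bulk beta values into cell-type fractions
#'
#' For every sample solves `min || beta_sample - t(f) %*% reference ||^2`
#' subject to `f >= 0`, then renormalizes to the unit simplex. Only CpGs
#' shared between the matrix and the reference are used.
#'
#' @param beta A [beta_matrix()] (samples x CpGs).
#' @param reference Cell_type x CpG matrix of mean beta profiles.
#' @param estimator Optional replacement estimator, a function
#'   `(A, b) -> list(x, residual_norm)` with `A` = t(reference-subset);
#'   defaults to [nnls_solve()].
#' @return A list of class `cell_fraction_estimate`: `fractions` (samples x
#'   cell types, rows on the simplex), `residual_norm` (per sample),
#'   `shared_cpgs`.
#' @export
deconvolve <- function(beta, reference, estimator = nnls_solve) {
  stopifnot(inherits(beta, "beta_matrix"))
  reference <- as.matrix(reference)
  shared <- intersect(colnames(beta), colnames(reference))
  k <- nrow(reference)
  if (length(shared) < k) {
    stop_input("only %d shared CpG(s) with the reference; need >= %d (one per cell type)",
               length(shared), k)
  }
  A <- t(reference[, shared, drop = FALSE])      # CpGs x cell types
  qa <- qr(A)
  if (qa$rank < k) {
    dep <- rownames(reference)[setdiff(seq_len(k), qa$pivot[seq_len(qa$rank)])]
    stop_input("reference profiles are linearly dependent (row(s): %s)",
               paste(dep, collapse = ", "))
  }
  B <- unclass(beta)[, shared, drop = FALSE]
  n <- nrow(B)
  fr <- matrix(0, n, k, dimnames = list(rownames(B), rownames(reference)))
  rn <- numeric(n)
  for (i in seq_len(n)) {
    sol <- estimator(A, B[i, ])
    x <- sol$x
    if (sum(x) <= 0) x <- rep(1 / k, k)  # degenerate sample: uninformative
    fr[i, ] <- x / sum(x)
    rn[i] <- sol$residual_norm
  }
  structure(list(fractions = fr, residual_norm = rn, shared_cpgs = shared),
            class = "cell_fraction_estimate")
}

#' @export
print.cell_fraction_estimate <- function(x, ...) {
  cat(sprintf("<cell_fraction_estimate> %d samples x %d cell types (%d shared CpGs)\n",
              nrow(x$fractions), ncol(x$fractions), length(x$shared_cpgs)))
  invisible(x)
}

as_fraction_matrix <- function(fractions) {
  if (inherits(fractions, "cell_fraction_estimate")) fractions$fractions
  else as.matrix(fractions)
}

#' Spearman correlations between CpGs and cell fractions
#'
#' Rank correlation (average ranks for ties) of each CpG against each
#' estimated cell-type fraction. Constant fraction columns are flagged and
#' excluded from summaries rather than reported as 0.
#'
#' @param beta A [beta_matrix()], typically restricted to one model's CpGs.
#' @param fractions A `cell_fraction_estimate` or samples x cell-types
#'   matrix.
#' @param low_threshold Reporting threshold on `max |rho|` per CpG;
#'   default 0.4.
#' @return A list of class `fraction_correlation`: `rho` (CpG x cell type),
#'   `constant_cell_types`, `max_abs_rho` (per CpG over valid columns),
#'   `share_below_threshold`, `low_threshold`.
#' @export
fraction_correlations <- function(beta, fractions, low_threshold = 0.4) {
  stopifnot(inherits(beta, "beta_matrix"))
  f <- as_fraction_matrix(fractions)
  if (nrow(f) != nrow(beta)) stop_input("fractions and beta disagree on samples")
  if (nrow(beta) < 5L) stop_input("need >= 5 samples")
  const <- apply(f, 2L, function(x) stats::sd(x) == 0)
  rho <- suppressWarnings(
    stats::cor(unclass(beta), f, method = "spearman"))
  rho[, const] <- NA_real_
  valid <- rho[, !const, drop = FALSE]
  max_abs <- if (ncol(valid)) apply(abs(valid), 1L, max) else rep(NA_real_, nrow(rho))
  structure(list(rho = rho, constant_cell_types = colnames(f)[const],
                 max_abs_rho = max_abs,
                 share_below_threshold = mean(max_abs < low_threshold),
                 low_threshold = low_threshold),
            class = "fraction_correlation")
}

# R^2 of y regressed (with intercept) on predictor matrix Z.
r_squared <- function(y, Z) {
  fit <- stats::lm.fit(cbind(1, Z), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - rss / tss
}

#' VIF audit of a clock's CpGs against cell fractions
#'
#' For each model CpG j, the baseline VIF is `1 / (1 - R^2_j)` from
#' regressing CpG j on the other model CpGs (no age, no fractions). The
#' augmented VIF appends one cell-type fraction as an extra predictor, and
#' `delta_vif = augmented - baseline` is binned per cell type into
#' small/moderate/large/very-large by three ascending thresholds
#' (defaults 0.025, 0.05, 0.1).
#'
#' @param beta A [beta_matrix()] restricted to one model's CpGs (>= 2).
#' @param fractions A `cell_fraction_estimate` or samples x cell-types
#'   matrix.
#' @param thresholds Three ascending delta-VIF bin edges.
#' @param max_cpgs When `n_samples <= n_CpGs + 1` the audit runs on a seeded
#'   random CpG subsample of this size (default
#'   `min(n_CpGs, floor(n_samples / 5))`), with a warning.
#' @param seed Seed for the high-dimensional subsample.
#' @return A list of class `vif_audit`: `records` (data.frame: cpg,
#'   baseline_vif, then per-cell-type delta and bin), `delta` (CpG x cell
#'   type), `bins` (CpG x cell type, factor levels small/moderate/large/
#'   very large), `infinite_cpgs` (perfectly collinear CpGs reported as
#'   `Inf` and excluded from bins), `thresholds`.
#' @export
vif_audit <- function(beta, fractions, thresholds = c(0.025, 0.05, 0.1),
                      max_cpgs = NULL, seed = 1L) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0)) {
    stop_input("thresholds must be 3 ascending values")
  }
  f <- as_fraction_matrix(fractions)
  if (nrow(f) != nrow(beta)) stop_input("fractions and beta disagree on samples")
  B <- unclass(beta)
  if (ncol(B) < 2L) stop_input("VIF audit needs >= 2 model CpGs")
  if (nrow(B) <= ncol(B) + 1L) {
    keep_n <- max_cpgs %||% min(ncol(B), floor(nrow(B) / 5))
    if (keep_n < 2L) stop_input("too few samples for a VIF audit")
    warning(sprintf("n_samples <= n_CpGs + 1: auditing a seeded subsample of %d CpGs",
                    keep_n))
    keep <- with_seed(seed, sort(sample.int(ncol(B), keep_n)))
    B <- B[, keep, drop = FALSE]
  }
  p <- ncol(B); k <- ncol(f)
  baseline <- numeric(p)
  delta <- matrix(NA_real_, p, k, dimnames = list(colnames(B), colnames(f)))
  for (j in seq_len(p)) {
    others <- B[, -j, drop = FALSE]
    r2 <- r_squared(B[, j], others)
    if (r2 >= 1 - 1e-12) {
      baseline[j] <- Inf
      next
    }
    baseline[j] <- 1 / (1 - r2)
    for (c in seq_len(k)) {
      r2a <- r_squared(B[, j], cbind(others, f[, c]))
      vif_a <- if (r2a >= 1 - 1e-12) Inf else 1 / (1 - r2a)
      delta[j, c] <- vif_a - baseline[j]
    }
  }
  names(baseline) <- colnames(B)
  lv <- c("small", "moderate", "large", "very large")
  bin_one <- function(d) {
    if (!is.finite(d)) return(NA_character_)
    lv[findInterval(d, thresholds) + 1L]
  }
  bins <- matrix(vapply(delta, bin_one, character(1)), p, k,
                 dimnames = dimnames(delta))
  records <- data.frame(cpg = colnames(B), baseline_vif = baseline,
                        stringsAsFactors = FALSE, row.names = NULL)
  for (c in seq_len(k)) {
    records[[paste0("delta_", colnames(f)[c])]] <- delta[, c]
    records[[paste0("bin_", colnames(f)[c])]] <- bins[, c]
  }
  structure(list(records = records, baseline_vif = baseline, delta = delta,
                 bins = bins,
                 infinite_cpgs = colnames(B)[!is.finite(baseline)],
                 thresholds = thresholds, bin_levels = lv),
            class = "vif_audit")
}

#' Compare delta-VIF bin distributions across clock models
#'
#' Runs [vif_audit()] per model (on the model's CpGs present in the beta
#' matrix) and tabulates the share of CpGs per bin, per cell type and
#' pooled over cell types — the machine-readable form of a per-model VIF
#' distribution comparison.
#'
#' @param models A list of [clock_model()] objects.
#' @param beta A [beta_matrix()] covering the models' CpGs.
#' @param fractions A `cell_fraction_estimate` or fraction matrix.
#' @param thresholds Passed to [vif_audit()].
#' @return A list of class `vif_comparison`: `per_model` (named list of
#'   `vif_audit`), `distribution` (data.frame: model, cell_type, bin,
#'   share), `pooled` (data.frame: model, bin, share over all cell types).
#' @export
compare_models_vif <- function(models, beta, fractions,
                               thresholds = c(0.025, 0.05, 0.1)) {
  if (inherits(models, "clock_model")) models <- list(models)
  lv <- c("small", "moderate", "large", "very large")
  audits <- list(); dist <- list(); pooled <- list()
  for (m in models) {
    cpgs <- intersect(names(m$coefficients), colnames(beta))
    if (length(cpgs) < 2L) stop_input("model '%s': < 2 CpGs present in matrix",
                                      m$name)
    sub <- beta_matrix(unclass(beta)[, cpgs, drop = FALSE])
    va <- vif_audit(sub, fractions, thresholds)
    audits[[m$name]] <- va
    for (ct in colnames(va$bins)) {
      tab <- table(factor(va$bins[, ct], levels = lv))
      n_ok <- sum(tab)
      dist[[length(dist) + 1L]] <- data.frame(
        model = m$name, cell_type = ct, bin = lv,
        share = if (n_ok) as.numeric(tab) / n_ok else NA_real_,
        stringsAsFactors = FALSE)
    }
    tab_all <- table(factor(va$bins, levels = lv))
    pooled[[length(pooled) + 1L]] <- data.frame(
      model = m$name, bin = lv,
      share = as.numeric(tab_all) / sum(tab_all),
      stringsAsFactors = FALSE)
  }
  structure(list(per_model = audits,
                 distribution = do.call(rbind, dist),
                 pooled = do.call(rbind, pooled)),
            class = "vif_comparison")
}
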