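# Variability-based aging metrics ("noise barometer").
#
# Per-CpG mean/SD/CV in sliding age windows, detection of loci with stable
# means but age-rising dispersion, continuous piecewise-linear fitting of
# the aggregate noise trajectory with free breakpoints, and healthy-vs-
# disease noise comparison.

#' Windowed per-CpG noise profile
#'
#' Slides age windows of `window_width` years in steps of `step` years over
#' the cohort and computes, per CpG per window, the mean beta, the unbiased
#' SD and the coefficient of variation CV = SD/mean. CV is reported as `NA`
#' (undefined, not zero) when the window mean is at or below `mean_floor`.
#' Windows holding fewer than `min_per_window` samples are skipped.
#'
#' @param beta A [beta_matrix()].
#' @param metadata Metadata covering the samples.
#' @param window_width Window width in years; default 6.
#' @param step Step between window starts in years; default 3.
#' @param min_per_window Minimum samples per emitted window; default 20.
#' @param mean_floor Mean-beta floor below which CV is undefined;
#'   default 0.05.
#' @param subset Optional status filter (`"healthy"`, `"disease"`); default
#'   all samples.
#' @param anchor_age Age at which the window grid starts; default
#'   `floor(min(age))`. Fixing it puts different cohorts on a common grid.
#' @return A list of class `noise_profile`: `midpoints` (years), `n_per_window`,
#'   `mean` / `sd` / `cv` (CpG x window matrices), `window_width`, `step`,
#'   `mean_floor`.
#' @export
windowed_noise <- function(beta, metadata, window_width = 6, step = 3,
                           min_per_window = 20, mean_floor = 0.05,
                           subset = NULL, anchor_age = NULL) {
  stopifnot(inherits(beta, "beta_matrix"))
  md <- metadata[match(rownames(beta), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop_input("metadata does not cover all samples")
  keep <- if (is.null(subset)) rep(TRUE, nrow(md)) else md$status == subset
  B <- unclass(beta)[keep, , drop = FALSE]
  age <- md$age[keep]
  anchor <- anchor_age %||% floor(min(age))
  starts <- seq(anchor, max(age) - window_width, by = step)
  if (!length(starts)) stop_input("age range narrower than one window")
  mids <- c(); counts <- c(); mu <- list(); sg <- list()
  for (s in starts) {
    inw <- age >= s & age < s + window_width
    if (sum(inw) < min_per_window) next
    mids <- c(mids, s + window_width / 2)
    counts <- c(counts, sum(inw))
    mu[[length(mu) + 1L]] <- colMeans(B[inw, , drop = FALSE])
    sg[[length(sg) + 1L]] <- apply(B[inw, , drop = FALSE], 2L, stats::sd)
  }
  if (!length(mids)) {
    stop_input("no window holds >= %d samples; widen the windows", min_per_window)
  }
  mean_m <- do.call(cbind, mu)
  sd_m <- do.call(cbind, sg)
  colnames(mean_m) <- colnames(sd_m) <- sprintf("w%.1f", mids)
  cv_m <- sd_m / mean_m
  cv_m[mean_m <= mean_floor] <- NA_real_
  structure(list(midpoints = mids, n_per_window = counts, mean = mean_m,
                 sd = sd_m, cv = cv_m, window_width = window_width,
                 step = step, mean_floor = mean_floor),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> %d CpGs x %d windows (midpoints %.1f..%.1f y)\n",
              nrow(x$mean), length(x$midpoints), min(x$midpoints),
              max(x$midpoints)))
  invisible(x)
}

#' Flag stable-mean / rising-SD CpGs
#'
#' The barometer's target loci: nearly constant mean beta across age but
#' progressively increasing dispersion. A CpG is `stable_mean` when the
#' absolute slope of its windowed mean against the window midpoint is at
#' most `mean_slope_tol` (beta units/year), and `rising_sd` when the
#' Spearman correlation of its windowed SD with the midpoint is at least
#' `sd_trend_threshold`.
#'
#' @param profile A [windowed_noise()] profile with >= 3 windows.
#' @param mean_slope_tol Default 0.002 beta units/year (a quarter of the
#'   canonical age-CpG slope).
#' @param sd_trend_threshold Default 0.5.
#' @return A data.frame: `cpg`, `mean_slope`, `sd_trend_rho`, `stable_mean`,
#'   `rising_sd`, `flagged` (both).
#' @export
flag_stable_mean_rising_sd <- function(profile, mean_slope_tol = 0.002,
                                       sd_trend_threshold = 0.5) {
  stopifnot(inherits(profile, "noise_profile"))
  if (length(profile$midpoints) < 3L) stop_input("need >= 3 windows")
  mids <- profile$midpoints
  slope <- apply(profile$mean, 1L, function(m) {
    stats::cov(m, mids) / stats::var(mids)
  })
  rho <- suppressWarnings(apply(profile$sd, 1L, function(s) {
    if (stats::sd(s) == 0) 0 else stats::cor(s, mids, method = "spearman")
  }))
  data.frame(cpg = rownames(profile$mean), mean_slope = slope,
             sd_trend_rho = rho,
             stable_mean = abs(slope) <= mean_slope_tol,
             rising_sd = rho >= sd_trend_threshold,
             flagged = abs(slope) <= mean_slope_tol & rho >= sd_trend_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate noise score across CpGs
#'
#' Default aggregate for trajectory fitting: per window, the median across
#' CpGs of the windowed SD after z-scoring each CpG's SD series (robust to
#' scale differences between loci).
#'
#' @param profile A [windowed_noise()] profile.
#' @param stat `"sd"` (default) or `"cv"`.
#' @param zscore Z-score per CpG before taking the median; default `TRUE`.
#' @return A data.frame: `midpoint`, `score`.
#' @export
aggregate_noise <- function(profile, stat = c("sd", "cv"), zscore = TRUE) {
  stat <- match.arg(stat)
  m <- profile[[stat]]
  if (zscore) {
    m <- t(apply(m, 1L, function(x) {
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
      (x - mean(x, na.rm = TRUE)) / s
    }))
  }
  data.frame(midpoint = profile$midpoints,
             score = apply(m, 2L, stats::median, na.rm = TRUE),
             row.names = NULL)
}

# Continuous piecewise-linear least squares with fixed breakpoints via a
# truncated-power basis; returns fit + RSS.
pwl_fit <- function(x, y, breaks) {
  basis <- cbind(1, x)
  for (b in breaks) basis <- cbind(basis, pmax(x - b, 0))
  fit <- stats::lm.fit(basis, y)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

pwl_predict <- function(coef, x, breaks) {
  basis <- cbind(1, x)
  for (b in breaks) basis <- cbind(basis, pmax(x - b, 0))
  drop(basis %*% ifelse(is.na(coef), 0, coef))
}

#' Fit a piecewise-linear noise trajectory
#'
#' Continuous piecewise-linear least squares with `n_breakpoints` free
#' breakpoints, selected by exhaustive grid search over the observed
#' midpoints (interior points only, so each segment contains data).
#' Deterministic and exact on the candidate grid.
#'
#' @param aggregate Data.frame with columns `midpoint`, `score` (e.g. from
#'   [aggregate_noise()]), or a `noise_profile` (aggregated with defaults).
#' @param n_breakpoints Number of free breakpoints (0-3).
#' @return A list of class `trajectory_fit`: `breakpoints`, `slopes` (one
#'   per segment), `intercept`, `rss`, `r_squared`, `fitted`,
#'   `n_breakpoints`.
#' @export
fit_noise_trajectory <- function(aggregate, n_breakpoints = 3) {
  if (inherits(aggregate, "noise_profile")) aggregate <- aggregate_noise(aggregate)
  x <- aggregate$midpoint; y <- aggregate$score
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is_count(n_breakpoints) || n_breakpoints > 3) {
    stop_input("n_breakpoints must be an integer in 0..3")
  }
  need <- 2 * (n_breakpoints + 1) + 1
  if (length(x) < need) {
    stop_input("need >= %d aggregate points for %d breakpoint(s), have %d",
               need, n_breakpoints, length(x))
  }
  o <- order(x); x <- x[o]; y <- y[o]
  if (n_breakpoints == 0) {
    f <- pwl_fit(x, y, numeric(0))
    best <- list(breaks = numeric(0), fit = f)
  } else {
    candidates <- unique(x)[-c(1L, length(unique(x)))]
    combos <- utils::combn(candidates, n_breakpoints, simplify = FALSE)
    best <- NULL
    for (br in combos) {
      f <- pwl_fit(x, y, br)
      if (anyNA(f$coef)) next
      if (is.null(best) || f$rss < best$fit$rss) best <- list(breaks = br, fit = f)
    }
    if (is.null(best)) stop_input("no admissible breakpoint placement")
  }
  coef <- best$fit$coef
  slopes <- cumsum(coef[-1L])   # segment slopes from truncated-power deltas
  tss <- sum((y - mean(y))^2)
  structure(list(breakpoints = as.numeric(best$breaks),
                 slopes = as.numeric(slopes), intercept = unname(coef[1L]),
                 rss = best$fit$rss,
                 r_squared = if (tss > 0) 1 - best$fit$rss / tss else NA_real_,
                 fitted = pwl_predict(coef, x, best$breaks),
                 midpoints = x, score = y,
                 n_breakpoints = n_breakpoints),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> breaks [%s], slopes [%s], R2 %.3f\n",
              paste(sprintf("%.1f", x$breakpoints), collapse = ", "),
              paste(sprintf("%.4g", x$slopes), collapse = ", "),
              x$r_squared))
  invisible(x)
}

#' Compare noise between status groups
#'
#' Profiles each status group on a common window grid and reports the
#' per-window disease-minus-healthy difference in the aggregate noise
#' score, with a seeded bootstrap interval (resampling samples within each
#' group).
#'
#' @param beta A [beta_matrix()].
#' @param metadata Metadata with both groups.
#' @param stat `"sd"` or `"cv"` aggregate; default `"sd"` (not z-scored, so
#'   differences are in beta units).
#' @param n_boot Bootstrap replicates; default 200.
#' @param seed Bootstrap seed.
#' @param ... Window scheme arguments passed to [windowed_noise()].
#' @return A data.frame of class `noise_comparison`: `midpoint`,
#'   `healthy`, `disease`, `difference`, `lower`, `upper` (95% bootstrap
#'   interval for the difference).
#' @export
compare_noise_by_status <- function(beta, metadata, stat = "sd",
                                    n_boot = 200, seed = 1L, ...) {
  groups <- c("healthy", "disease")
  md0 <- metadata[match(rownames(beta), metadata$sample_id), ]
  anchor <- floor(min(md0$age))
  agg_for <- function(b, md) {
    pr <- windowed_noise(b, md, anchor_age = anchor, ...)
    stats::setNames(aggregate_noise(pr, stat = stat, zscore = FALSE)$score,
                    sprintf("%.3f", pr$midpoints))
  }
  md <- metadata[match(rownames(beta), metadata$sample_id), ]
  idx <- lapply(groups, function(g) which(md$status == g))
  names(idx) <- groups
  if (any(lengths(idx) == 0)) stop_input("both status groups required")
  scores <- lapply(groups, function(g) {
    agg_for(beta_matrix(unclass(beta)[idx[[g]], , drop = FALSE]), md[idx[[g]], ])
  })
  names(scores) <- groups
  common <- intersect(names(scores$healthy), names(scores$disease))
  if (!length(common)) stop_input("no common windows between the groups")
  diff_obs <- scores$disease[common] - scores$healthy[common]
  boot <- with_seed(seed, {
    replicate(n_boot, {
      s <- lapply(groups, function(g) {
        take <- sample(idx[[g]], length(idx[[g]]), replace = TRUE)
        # keep ids unique so beta_matrix/metadata matching stays valid
        b <- unclass(beta)[take, , drop = FALSE]
        rownames(b) <- sprintf("b%06d", seq_along(take))
        m <- md[take, ]; m$sample_id <- rownames(b)
        tryCatch(agg_for(beta_matrix(b), m), error = function(e) NULL)
      })
      names(s) <- groups
      if (is.null(s$healthy) || is.null(s$disease)) return(rep(NA_real_, length(common)))
      ok <- common %in% names(s$healthy) & common %in% names(s$disease)
      out <- rep(NA_real_, length(common))
      out[ok] <- s$disease[common[ok]] - s$healthy[common[ok]]
      out
    })
  })
  boot <- matrix(boot, nrow = length(common))
  qs <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(midpoint = as.numeric(common),
                    healthy = unname(scores$healthy[common]),
                    disease = unname(scores$disease[common]),
                    difference = unname(diff_obs),
                    lower = qs[1L, ], upper = qs[2L, ], row.names = NULL)
  class(out) <- c("noise_comparison", "data.frame")
  out
}
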