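# Deconvolution, fraction correlations, and the VIF audit.

test_that("NNLS solves small nonnegative systems", {
  set.seed(41)
  A <- matrix(runif(50 * 4), 50, 4)
  x_true <- c(0.5, 0, 1.2, 0.3)
  sol <- nnls_solve(A, drop(A %*% x_true))
  expect_equal(sol$x, x_true, tolerance = 1e-8)
  expect_lt(sol$residual_norm, 1e-8)
  # active constraint: unconstrained optimum would be negative
  A2 <- cbind(c(1, 0), c(1, 1e-3))
  sol2 <- nnls_solve(A2, c(-1, 1))
  expect_true(all(sol2$x >= 0))
})

test_that("noiseless mixtures are recovered exactly", {
  ref <- make_reference_profiles(30, seed = 50)
  # 0.7 neutrophil + 0.3 naive CD4 T
  mix <- 0.7 * ref["Neutrophils", ] + 0.3 * ref["CD4T_naive", ]
  b <- tiny_beta(rbind(mix, ref["Neutrophils", ]),
                 sample_ids = c("blend", "pure"), cpg_ids = colnames(ref))
  est <- deconvolve(b, ref)
  expect_equal(unname(est$fractions["blend", "Neutrophils"]), 0.7,
               tolerance = 1e-6)
  expect_equal(unname(est$fractions["blend", "CD4T_naive"]), 0.3,
               tolerance = 1e-6)
  expect_equal(sum(est$fractions["blend", c("Neutrophils", "CD4T_naive")]), 1,
               tolerance = 1e-6)
  # pure profile maps to a unit fraction
  expect_equal(unname(est$fractions["pure", "Neutrophils"]), 1,
               tolerance = 1e-6)
  expect_simplex(est$fractions)
})

test_that("noisy cohorts are recovered within the error budget", {
  spec <- cohort_spec(300, seed = 51,
                      n_cpgs_by_archetype = c(mixture = 40),
                      noise = piecewise_noise_spec(base_sd = 0.02,
                                                   slopes = c(0, 0, 0, 0)))
  co <- generate_cohort(spec)
  est <- deconvolve(co$beta, co$reference_profiles)
  expect_lt(mean(abs(est$fractions - co$true_fractions)), 0.05)
  expect_simplex(est$fractions)
})

test_that("deconvolution input validation", {
  ref <- make_reference_profiles(20, seed = 1)
  b <- tiny_beta(matrix(runif(10), 1), cpg_ids = paste0("other", 1:10))
  expect_error(deconvolve(b, ref), "shared")
  ref_bad <- ref
  ref_bad["Basophils", ] <- ref_bad["Neutrophils", ]  # dependent rows
  b2 <- tiny_beta(matrix(runif(20), 1), cpg_ids = colnames(ref))
  expect_error(deconvolve(b2, ref_bad), "dependent")
})

test_that("Spearman correlations respect rank invariance and flag constants", {
  set.seed(52)
  n <- 100
  f <- matrix(runif(n * 12), n, 12,
              dimnames = list(NULL, paste0("ct", 1:12)))
  f <- f / rowSums(f)
  # CpG = monotone transform of fraction 1 -> rho exactly 1
  b <- tiny_beta(cbind(mono = plogis(5 * f[, 1]), indep = runif(n)))
  fc <- fraction_correlations(b, f)
  expect_equal(unname(fc$rho["mono", "ct1"]), 1, tolerance = 1e-12)
  # constant fraction column flagged, others unaffected
  f2 <- f; f2[, 3] <- 0.2
  fc2 <- fraction_correlations(b, f2)
  expect_equal(fc2$constant_cell_types, "ct3")
  expect_true(all(is.na(fc2$rho[, "ct3"])))
  expect_equal(fc2$rho["mono", "ct1"], fc$rho["mono", "ct1"])
})

test_that("composition-independent CpGs show near-zero max rho", {
  co <- generate_cohort(cohort_spec(2000, seed = 53,
                                    n_cpgs_by_archetype = c(normal = 1,
                                                            mixture = 20)))
  est <- deconvolve(co$beta, co$reference_profiles)
  sub <- beta_matrix(unclass(co$beta)[, "cg_nrm0001", drop = FALSE])
  fc <- fraction_correlations(sub, est)
  expect_lt(fc$max_abs_rho[["cg_nrm0001"]], 0.1)
})

test_that("two-variable VIF matches the closed form 1/(1 - r^2)", {
  set.seed(54)
  n <- 200
  x1 <- runif(n)
  x2 <- 0.6 * x1 + 0.1 * rnorm(n)
  b <- tiny_beta(cbind(cg1 = clip01(x1), cg2 = clip01(x2 + 0.2)))
  f <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("ctA", "ctB")))
  va <- vif_audit(b, f)
  r <- cor(unclass(b)[, 1], unclass(b)[, 2])
  expect_equal(unname(va$baseline_vif), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
})

test_that("orthogonal predictors give VIF 1 and zero delta", {
  n <- 64
  # exactly orthogonal, mean-centered design from a Hadamard-like pattern
  x1 <- rep(c(0.4, 0.6), n / 2)
  x2 <- rep(c(0.4, 0.4, 0.6, 0.6), n / 4)
  f1 <- rep(c(0.4, 0.6, 0.6, 0.4, 0.6, 0.4, 0.4, 0.6), n / 8)
  b <- tiny_beta(cbind(cg1 = x1, cg2 = x2))
  va <- vif_audit(b, cbind(ct1 = f1))
  expect_equal(unname(va$baseline_vif), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(va$delta[, "ct1"]), c(0, 0), tolerance = 1e-10)
})

test_that("delta VIF is nonnegative and bins follow the thresholds", {
  co <- small_cohort(n = 250, seed = 55)
  est <- deconvolve(co$beta, co$reference_profiles)
  keep <- names(co$archetype_labels)[co$archetype_labels %in%
                                       c("age_linear", "normal", "mixture")][1:10]
  sub <- beta_matrix(unclass(co$beta)[, keep])
  va <- vif_audit(sub, est)
  expect_true(all(va$delta >= -1e-9, na.rm = TRUE))
  expect_true(all(is.finite(va$baseline_vif) & va$baseline_vif >= 1))
  # bin arithmetic at the default thresholds 0.025 / 0.05 / 0.1
  bin_of <- function(d) {
    lv <- c("small", "moderate", "large", "very large")
    lv[findInterval(d, va$thresholds) + 1]
  }
  expect_equal(bin_of(0.03), "moderate")
  expect_equal(bin_of(0.01), "small")
  expect_equal(bin_of(0.07), "large")
  expect_equal(bin_of(0.2), "very large")
  flat <- va$delta[is.finite(va$delta)]
  expect_equal(unname(va$bins[which(va$delta == flat[1], arr.ind = TRUE)][1]),
               bin_of(flat[1]))
})

test_that("perfect collinearity yields an infinity sentinel", {
  set.seed(56)
  x <- runif(50)
  b <- tiny_beta(cbind(cg1 = x, cg2 = 0.5 * x, cg3 = runif(50)))
  f <- cbind(ct1 = runif(50))
  va <- vif_audit(b, f)
  expect_setequal(va$infinite_cpgs, c("cg1", "cg2"))
  expect_true(all(is.na(va$bins[c("cg1", "cg2"), ])))
})

test_that("high-dimensional audits fall back to a seeded subsample", {
  set.seed(57)
  b <- tiny_beta(matrix(runif(30 * 40), 30, 40))
  f <- cbind(ct1 = runif(30))
  expect_warning(va <- vif_audit(b, f), "subsample")
  expect_equal(nrow(va$records), 6L)  # floor(30 / 5)
})

test_that("model VIF comparison separates mixture from independent clocks", {
  co <- suppressWarnings(
    generate_cohort(cohort_spec(1000, seed = 58, disease_fraction = 0.3,
                                n_cpgs_by_archetype = c(normal = 6,
                                                        uniform = 4,
                                                        mixture = 30))))
  est <- deconvolve(co$beta, co$reference_profiles)
  mix_cpgs <- names(co$archetype_labels)[co$archetype_labels == "mixture"][1:8]
  ind_cpgs <- names(co$archetype_labels)[co$archetype_labels %in%
                                           c("normal", "uniform")][1:8]
  m_mix <- clock_model("mixture_clock", 0, setNames(rep(1, 8), mix_cpgs))
  m_ind <- clock_model("independent_clock", 0, setNames(rep(1, 8), ind_cpgs))
  cmp <- compare_models_vif(list(m_mix, m_ind), co$beta, est)
  pooled <- cmp$pooled
  share <- function(model, bins) {
    sum(pooled$share[pooled$model == model & pooled$bin %in% bins])
  }
  # composition-independent clock: deltas overwhelmingly "small"
  expect_gte(share("independent_clock", "small"), 0.9)
  # mixture-readout clock is strictly more collinear with fractions
  expect_gt(share("mixture_clock", c("large", "very large")),
            share("independent_clock", c("large", "very large")))
  # duplicate model gives identical distributions (one block per copy)
  cmp2 <- compare_models_vif(list(m_mix, m_mix), co$beta, est)
  shares <- cmp2$pooled$share[cmp2$pooled$model == "mixture_clock"]
  expect_length(shares, 8L)
  expect_equal(shares[1:4], shares[5:8])
  expect_equal(shares[1:4],
               cmp$pooled$share[cmp$pooled$model == "mixture_clock"])
})
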