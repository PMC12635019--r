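# Coefficient-sign coherence audit: univariate stats, the audit arithmetic,
# rectification, residual separation, trade-off experiment.

hand_stats <- function() {
  data.frame(cpg = paste0("cg", 1:4),
             pearson_r = c(0.5, 0.5, -0.5, -0.5),
             stringsAsFactors = FALSE)
}
hand_model <- function() {
  clock_model("hand", 0, c(cg1 = 1, cg2 = -1, cg3 = 2, cg4 = -0.5))
}

test_that("univariate stats match direct correlation", {
  md <- tiny_metadata(10, ages = seq(30, 75, by = 5))
  b <- tiny_beta(cbind(exact = md$age / 100, flat = rep(0.4, 10)),
                 sample_ids = md$sample_id)
  st <- univariate_stats(b, md, subset = "all")
  expect_equal(st$pearson_r[st$cpg == "exact"], 1, tolerance = 1e-12)
  expect_equal(st$pearson_r[st$cpg == "flat"], 0)
  expect_true(st$degenerate[st$cpg == "flat"])
  expect_error(univariate_stats(b, tiny_metadata(10, ages = rep(50, 10)),
                                subset = "all"),
               "constant ages")
})

test_that("univariate stats default to the healthy subset", {
  md <- tiny_metadata(20, ages = seq(21, 78, length.out = 20),
                      status = rep(c("healthy", "disease"), 10))
  set.seed(3)
  b <- tiny_beta(cbind(x = runif(20)), sample_ids = md$sample_id)
  st <- univariate_stats(b, md)
  expect_equal(st$n_used[1L], 10)
  # an age-independent archetype CpG shows |r| < 0.1 at n = 2000
  co <- generate_cohort(cohort_spec(2000, seed = 4,
                                    n_cpgs_by_archetype = c(age_linear = 1,
                                                            normal = 1)))
  st2 <- univariate_stats(co$beta, co$metadata)
  expect_lt(abs(st2$pearson_r[st2$cpg == "cg_nrm0001"]), 0.1)
  expect_gt(st2$pearson_r[st2$cpg == "cg_age0001"], 0.5)
})

test_that("audit arithmetic matches the hand oracle", {
  rep_ <- audit_model(hand_model(), hand_stats(), neutral_band = 0)
  # cg2 (-, +) and cg3 (+, -) oppose their univariate correlation
  mis <- rep_$records$cpg[rep_$records$flag == "misaligned"]
  expect_setequal(mis, c("cg2", "cg3"))
  expect_equal(rep_$pct_misaligned, 50)
  expect_equal(rep_$pct_weight_misaligned, 100 * 3 / 4.5, tolerance = 1e-12)
  # max-normalization: the largest |coefficient| maps to +-1
  expect_equal(max(abs(rep_$records$max_norm_coefficient)), 1)
  expect_equal(rep_$records$max_norm_coefficient[rep_$records$cpg == "cg3"], 1)
})

test_that("all-coherent models audit clean", {
  m <- clock_model("ok", 0, c(cg1 = 1, cg3 = -2))
  rep_ <- audit_model(m, hand_stats())
  expect_equal(rep_$pct_misaligned, 0)
  expect_equal(rep_$pct_weight_misaligned, 0)
})

test_that("audit partitions and excludes unmatched CpGs", {
  m <- clock_model("mix", 0, c(cg1 = 1, cg3 = 2, cgZ = 5))
  rep_ <- audit_model(m, hand_stats())
  expect_equal(rep_$n_unmatched, 1L)
  expect_equal(rep_$n_audited,
               rep_$n_coherent + rep_$n_misaligned + rep_$n_neutral)
  expect_equal(rep_$n_audited, 2L)
  # unmatched weight not in the denominator
  expect_equal(rep_$total_abs_weight, 3)
  expect_error(audit_model(clock_model("none", 0, c(cgQ = 1)), hand_stats()),
               "overlap")
})

test_that("neutral band and exact-zero correlations give neutral flags", {
  st <- data.frame(cpg = c("cg1", "cg2", "cg3"), pearson_r = c(0, 0.05, 0.5))
  m <- clock_model("nb", 0, c(cg1 = -1, cg2 = -1, cg3 = 1))
  r0 <- audit_model(m, st, neutral_band = 0)
  expect_equal(r0$records$flag, c("neutral", "misaligned", "coherent"))
  r1 <- audit_model(m, st, neutral_band = 0.1)
  expect_equal(r1$records$flag, c("neutral", "neutral", "coherent"))
})

test_that("joint sign flip leaves the misaligned set unchanged", {
  set.seed(21)
  for (i in 1:10) {
    p <- 15
    w <- setNames(rnorm(p), paste0("cg", seq_len(p)))
    st <- data.frame(cpg = names(w), pearson_r = runif(p, -1, 1))
    m1 <- clock_model("a", 0, w)
    m2 <- clock_model("b", 0, -w)
    st2 <- st; st2$pearson_r <- -st2$pearson_r
    r1 <- audit_model(m1, st)
    r2 <- audit_model(m2, st2)
    expect_identical(r1$records$flag, r2$records$flag)
  }
})

test_that("independent random signs misalign about half the features", {
  set.seed(22)
  n <- 4000
  w <- setNames(sample(c(-1, 1), n, TRUE) * runif(n, 0.1, 1),
                paste0("cg", seq_len(n)))
  st <- data.frame(cpg = names(w),
                   pearson_r = sample(c(-1, 1), n, TRUE) * runif(n, 0.01, 1))
  rep_ <- audit_model(clock_model("rand", 0, w), st)
  expect_lt(abs(rep_$pct_misaligned - 50), 3)
})

test_that("drop-mode rectification follows the hand oracle", {
  rect <- rectify_model(hand_model(), hand_stats(), mode = "drop")
  expect_equal(rect$n_features, 2L)
  expect_setequal(names(rect$coefficients), c("cg1", "cg4"))
  # retained weights unchanged; re-audit is clean
  expect_equal(rect$coefficients[["cg1"]], 1)
  expect_equal(audit_model(rect, hand_stats())$pct_misaligned, 0)
  # fixed point: a clean model passes through (up to intercept refit)
  clean <- clock_model("ok", 7, c(cg1 = 1, cg3 = -2))
  rect2 <- rectify_model(clean, hand_stats(), mode = "drop")
  expect_equal(rect2$coefficients, clean$coefficients)
  expect_equal(rect2$intercept, 7)
  # all-misaligned model cannot be rectified
  allbad <- clock_model("bad", 0, c(cg1 = -1, cg3 = 1))
  expect_error(rectify_model(allbad, hand_stats()), "misaligned")
})

test_that("sign-constrained refit produces an audit-clean model", {
  co <- small_cohort(n = 400, seed = 17)
  st <- univariate_stats(co$beta, co$metadata)
  fit <- fit_elastic_net(unclass(co$beta), co$metadata$age,
                         en_config(alpha = 0.1))
  m <- as_clock_model(fit, "en")
  rect <- rectify_model(m, st, mode = "sign-constrained-refit",
                        beta = co$beta, metadata = co$metadata)
  post <- audit_model(rect, st)
  expect_equal(post$n_misaligned, 0L)
  # every retained weight agrees in sign with its univariate correlation
  r <- st$pearson_r[match(names(rect$coefficients), st$cpg)]
  expect_true(all(sign(rect$coefficients) * sign(r) >= 0))
})

test_that("residual separation recovers a planted group shift", {
  md <- tiny_metadata(400, ages = rep(seq(30, 69, length.out = 200), 2),
                      status = rep(c("healthy", "disease"), each = 200))
  set.seed(23)
  # model: age = 100 * beta; disease betas shifted by +5 years equivalent
  beta_v <- md$age / 100 + ifelse(md$status == "disease", 0.05, 0) +
    rnorm(400, 0, 0.02)
  b <- tiny_beta(cbind(cg1 = beta_v), sample_ids = md$sample_id)
  m <- clock_model("perfect", 0, c(cg1 = 100))
  sep <- residual_separation(m, b, md)
  expect_equal(sep$difference, 5, tolerance = 0.6)
  expect_gt(sep$effect_size, 1)
  expect_lt(sep$p_value, 1e-6)

  # identical residual distributions: paired samples share age and noise,
  # one of each pair in each group
  noise0 <- rep(rnorm(200, 0, 0.02), each = 2)
  md0 <- tiny_metadata(400, ages = rep(seq(30, 69, length.out = 200), each = 2),
                       status = rep(c("healthy", "disease"), 200))
  b0 <- tiny_beta(cbind(cg1 = md0$age / 100 + noise0),
                  sample_ids = md0$sample_id)
  sep0 <- residual_separation(m, b0, md0)
  expect_equal(sep0$difference, 0, tolerance = 1e-10)
  expect_equal(sep0$effect_size, 0, tolerance = 1e-10)

  expect_error(residual_separation(m, b, transform(md, status = "healthy")),
               "disease")
})

test_that("trade-off experiment runs and reports paired results", {
  co <- small_cohort(n = 400, seed = 31)
  tr <- tradeoff_experiment(co, seed = 5)
  expect_s3_class(tr$audit, "coherence_report")
  expect_gt(tr$audit$n_misaligned, 0)
  expect_equal(tr$delta_effect_size,
               tr$rectified$effect_size - tr$original$effect_size)
  # null case: no disease effect anywhere -> both separations near zero
  co0 <- generate_cohort(cohort_spec(
    400, seed = 32, disease_fraction = 0.5,
    n_cpgs_by_archetype = c(age_linear = 3, normal = 2, homeostatic = 3,
                            mixture = 10),
    noise = piecewise_noise_spec(disease_sd_multiplier = 1),
    cell_mix = cell_mix_spec(disease_shift = rep(0, 12))))
  tr0 <- tradeoff_experiment(co0, seed = 5)
  expect_lt(abs(tr0$original$effect_size), 0.6)
  expect_lt(abs(tr0$rectified$effect_size), 0.6)
})
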