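test_that("log2 transform applies the pseudo-count and rejects negatives", {
  expect_equal(log2_transform(0), 0)
  expect_equal(log2_transform(3), 2)
  expect_equal(log2_transform(1023), log2(1024))
  expect_equal(log2_transform(matrix(c(0, 1, 3, 7), 2)), matrix(c(0, 1, 2, 3), 2))
  expect_error(log2_transform(-1), "domain")
})

test_that("Hedges g matches the hand-worked example and is antisymmetric", {
  eff <- compute_smd(c(3, 4, 5), c(1, 2, 3))
  expect_equal(eff$g, 1.6)               # d = 2, J = 0.8
  expect_equal(eff$var_g, 2 / 3 + 1.6^2 / 12)  # 0.6667 + 0.2133 = 0.8800
  expect_equal(eff$var_g, 0.88, tolerance = 1e-4)
  swapped <- compute_smd(c(1, 2, 3), c(3, 4, 5))
  expect_equal(swapped$g, -eff$g)
  expect_equal(compute_smd(c(1, 2, 3), c(1, 2, 3))$g, 0)
  expect_error(compute_smd(c(1, 1), c(1, 1)), "degenerate")
  expect_error(compute_smd(1, c(1, 2)), "at least 2")
})

test_that("fixed-effect pooling is the inverse-variance weighted mean", {
  eff <- data.frame(study_id = c("a", "b", "c"), g = c(1, 2, 3),
                    var_g = c(1, 0.5, 0.25))
  res <- pool_fixed(eff)
  expect_equal(res$pooled, (1 + 4 + 12) / 7)
  expect_equal(res$se, 1 / sqrt(7))
  expect_equal(res$tau2, 0)
  expect_identical(res$model, "fixed")
  # symmetry: equal variances average the effects
  expect_equal(pool_fixed(data.frame(g = c(1, 3), var_g = c(1, 1)))$pooled, 2)
  # single study passes through
  one <- pool_fixed(data.frame(g = 1.5, var_g = 0.3))
  expect_equal(one$pooled, 1.5)
  expect_equal(one$se, sqrt(0.3))
  # oracle: direct summation on random inputs
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    e <- data.frame(g = rnorm(k), var_g = runif(k, 0.1, 2))
    w <- 1 / e$var_g
    expect_equal(pool_fixed(e)$pooled, sum(w * e$g) / sum(w))
  }
})

test_that("DerSimonian-Laird pooling matches the hand formula and truncates tau2", {
  eff <- data.frame(g = c(0, 4), var_g = c(1, 1))
  res <- pool_random(eff)
  expect_equal(res$Q, 8)           # w = 1,1; pooled_f = 2
  expect_equal(res$df, 1L)
  expect_equal(res$tau2, 7)        # (8 - 1) / (2 - 2/2)
  expect_equal(res$pooled, 2)      # symmetric
  # homogeneous effects: Q = 0, tau2 = 0, equals fixed
  same <- data.frame(g = c(1, 1, 1), var_g = c(0.5, 0.5, 0.5))
  expect_equal(pool_random(same)$tau2, 0)
  expect_equal(pool_random(same)$pooled, pool_fixed(same)$pooled)
  # Q <= df truncates to zero
  mild <- data.frame(g = c(1, 1.01), var_g = c(1, 1))
  expect_equal(pool_random(mild)$tau2, 0)
  expect_error(pool_random(data.frame(g = 1, var_g = 1)), "two studies")
})

test_that("DL and fixed pooling agree with metafor on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:10) {
    k <- sample(3:9, 1)
    e <- data.frame(g = rnorm(k, 1), var_g = runif(k, 0.05, 1))
    rd <- pool_random(e)
    fx <- pool_fixed(e)
    m_rd <- metafor::rma(yi = e$g, vi = e$var_g, method = "DL")
    m_fx <- metafor::rma(yi = e$g, vi = e$var_g, method = "FE")
    expect_equal(rd$pooled, as.numeric(m_rd$beta), tolerance = 1e-8)
    expect_equal(rd$tau2, m_rd$tau2, tolerance = 1e-8)
    expect_equal(rd$I2, m_rd$I2, tolerance = 1e-6)
    expect_equal(fx$pooled, as.numeric(m_fx$beta), tolerance = 1e-8)
  }
})

test_that("heterogeneity is reported on the percent scale and scales with variance", {
  same <- data.frame(g = c(2, 2, 2), var_g = c(1, 1, 1))
  expect_equal(heterogeneity(same)$I2, 0)
  het <- data.frame(g = c(0, 1, 5), var_g = c(0.2, 0.2, 0.2))
  h1 <- heterogeneity(het)
  expect_true(h1$I2 > 0 && h1$I2 <= 100)
  # doubling every variance halves Q
  het2 <- transform(het, var_g = 2 * var_g)
  expect_equal(heterogeneity(het2)$Q, h1$Q / 2)
  expect_error(heterogeneity(same[1, ]), "two studies")
})

test_that("model selection follows the printed rule with strict boundaries", {
  expect_identical(select_model(p_Q = 0.5, I2 = 88), "random")
  expect_identical(select_model(p_Q = 0.2, I2 = 30), "fixed")
  expect_identical(select_model(p_Q = 0.06, I2 = 50), "fixed")  # boundary I2
  expect_identical(select_model(p_Q = 0.05, I2 = 0), "fixed")   # boundary p
  expect_identical(select_model(p_Q = 0.049, I2 = 0), "random")
})

test_that("Egger test is near zero for symmetric funnels and errors below k=3", {
  # effects symmetric about the mean with matched SEs
  eff <- data.frame(g = c(1.8, 2.2, 1.5, 2.5), var_g = c(0.2, 0.2, 0.5, 0.5))
  res <- egger_test(eff)
  expect_lt(abs(res$intercept), 1e-8)
  expect_false(res$significant)
  # minimal k = 3 input returns finite numbers
  res3 <- egger_test(data.frame(g = c(0.5, 1, 2), var_g = c(0.1, 0.3, 0.6)))
  expect_true(is.finite(res3$intercept) && is.finite(res3$p))
  expect_identical(res3$df, 1L)
  expect_error(egger_test(eff[1:2, ]), "insufficient")
  # significance is the strict 0.1 rule
  expect_identical(res3$significant, res3$p < 0.1)
})

test_that("Egger intercept agrees with metafor's classical regression form", {
  skip_if_not_installed("metafor")
  set.seed(7)
  e <- data.frame(g = rnorm(6, 1, 0.5), var_g = runif(6, 0.05, 0.4))
  ours <- egger_test(e)
  m <- metafor::regtest(x = e$g, vi = e$var_g, model = "lm", predictor = "sei")
  expect_equal(ours$p, m$pval, tolerance = 1e-6)
})

test_that("leave-one-out influence flags a constructed outlier and only then", {
  same <- data.frame(study_id = paste0("s", 1:4), g = rep(1.2, 4),
                     var_g = rep(0.2, 4))
  res <- influence_loo(same)
  expect_identical(nrow(res), 4L)
  expect_false(attr(res, "any_flagged"))
  # one extreme study drives significance; omitting it flips the conclusion
  drv <- data.frame(study_id = paste0("s", 1:4), g = c(0.05, -0.05, 0.02, 6),
                    var_g = c(0.02, 0.02, 0.02, 0.02))
  res2 <- influence_loo(drv, model = "fixed")
  expect_true(res2$flagged[res2$omitted_study == "s4"])
  expect_error(influence_loo(same[1:2, ]), "at least 3")
  # duplicated-study omission never changes the pooled sign
  dup <- data.frame(study_id = paste0("s", 1:4), g = c(1, 1, 2, 2),
                    var_g = rep(0.3, 4))
  res3 <- influence_loo(dup)
  expect_true(all(sign(res3$pooled) == 1))
})

test_that("fixed/random sensitivity switch reports width and consistency", {
  same <- data.frame(g = c(1, 1), var_g = c(0.2, 0.2))
  s1 <- sensitivity_switch(same)
  expect_equal(s1$fixed$pooled, s1$random$pooled)
  expect_true(s1$consistent)
  het <- data.frame(g = c(0.5, 3, 2.5, 0.2), var_g = rep(0.1, 4))
  s2 <- sensitivity_switch(het)
  expect_gt(s2$random$tau2, 0)
  expect_gte(s2$random$ci_high - s2$random$ci_low,
             s2$fixed$ci_high - s2$fixed$ci_low)
})

test_that("subgroup pooling partitions cleanly", {
  eff <- data.frame(study_id = paste0("s", 1:4), g = c(1, 1.1, 3, 3.2),
                    var_g = rep(0.1, 4),
                    subgroup = c("squamous", "squamous", "adeno", "adeno"))
  res <- subgroup_pool(eff)
  expect_setequal(names(res), c("squamous", "adeno"))
  # internally homogeneous subgroups have I2 = 0
  expect_equal(res$squamous$I2, 0, tolerance = 1e-6)
  expect_equal(res$adeno$I2, 0, tolerance = 1e-6)
  # all in one subgroup equals overall pooling
  eff$subgroup <- "all"
  one <- subgroup_pool(eff)
  expect_equal(one$all$pooled, .pool <- pool_random(eff)$pooled, tolerance = 1e-8)
  # permuting rows leaves the multiset of subgroup estimates unchanged
  eff2 <- eff[c(3, 1, 4, 2), ]
  eff2$subgroup <- c("adeno", "squamous", "adeno", "squamous")
  eff$subgroup <- c("squamous", "squamous", "adeno", "adeno")
  r1 <- subgroup_pool(eff)
  r2 <- subgroup_pool(eff2)
  expect_equal(sort(vapply(r1, `[[`, 0, "pooled")),
               sort(vapply(r2, `[[`, 0, "pooled")))
})

test_that("study effects recover a null and a planted marker shift", {
  cfg0 <- synthetic_config(seed = 5, planted_smd = 0, study_n_tumor = 200,
                           study_n_normal = 200)
  eff0 <- study_effects(gen_expression_studies(cfg0))
  expect_true(all(abs(eff0$g) < 0.35))  # near 0 within Monte-Carlo error
  cfg <- synthetic_config(seed = 6)
  eff <- study_effects(gen_expression_studies(cfg))
  expect_identical(nrow(eff), 4L)
  expect_true(all(eff$var_g > 0))
})
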