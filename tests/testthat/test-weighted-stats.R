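test_that("weighted t-test reduces to classical tests at equal weights", {
  set.seed(61)
  x <- rnorm(12, 0.3); y <- rnorm(9)
  got <- weighted_t_test(x, y)
  want <- t.test(x, y)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$df, unname(want$parameter))
  expect_equal(got$p_value, want$p.value)

  one <- weighted_t_test(x, mu = 0.1)
  wone <- t.test(x, mu = 0.1)
  expect_equal(one$t, unname(wone$statistic))
  expect_equal(one$p_value, wone$p.value)

  same <- weighted_t_test(x, x, paired = TRUE)
  expect_equal(same$p_value, 1)
})

test_that("weighted t-test matches hand arithmetic on a 4-point case", {
  x <- c(1, 2, 3, 4); w <- c(4, 3, 2, 1)
  wn <- w * 4 / sum(w)
  mu <- sum(wn * x) / 4
  v <- sum(wn * (x - mu)^2) / 3
  t_hand <- mu / sqrt(v / 4)
  got <- weighted_t_test(x, weights = w)
  expect_equal(got$t, t_hand)
  expect_equal(got$df, 3)
  expect_equal(got$p_value, 2 * pt(abs(t_hand), 3, lower.tail = FALSE))
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.3), 0.3)
  # order invariance
  p <- c(0.8, 0.01, 0.04, 0.02)
  expect_equal(bh_fdr(p), bh_fdr(rev(p))[4:1])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("weighted least squares matches closed forms", {
  set.seed(67)
  d <- data.frame(x = rnorm(20), weight = 1)
  d$y <- 1 + 2 * d$x + rnorm(20, 0, 0.3)
  fit <- wls_fit(y ~ x, d)
  plain <- lm(y ~ x, d)
  expect_equal(fit$coefficients$estimate, unname(coef(plain)))

  # 5-point weighted normal equations evaluated by hand
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  w <- c(5, 1, 1, 1, 2)
  X <- cbind(1, x)
  beta_hand <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
  fit2 <- wls_fit(y ~ x, data.frame(x = x, y = y), weights = w)
  expect_equal(fit2$coefficients$estimate, as.numeric(beta_hand))

  dd <- data.frame(x = 1:6, x2 = 2 * (1:6), y = rnorm(6))
  expect_error(wls_fit(y ~ x + x2, dd), "collinear")
})

test_that("weighted regression recovers a simulated effect", {
  set.seed(71)
  est <- replicate(200, {
    d <- data.frame(x = rnorm(40))
    d$weight <- runif(40, 0.5, 2)
    d$y <- 0.05 * d$x + rnorm(40, 0, 1 / sqrt(d$weight)) * 0.1
    wls_fit(y ~ x, d)$coefficients$estimate[2]
  })
  expect_lt(abs(mean(est) - 0.05), 2 * sd(est) / sqrt(200))
})

test_that("mixed model collapses to WLS when group variance is zero", {
  set.seed(73)
  d <- data.frame(g = rep(sprintf("g%d", 1:10), each = 4),
                  x = rnorm(40), weight = runif(40, 0.5, 2))
  d$y <- 1 + 0.5 * d$x + rnorm(40, 0, 0.2)   # no group effect
  mm <- wlmm_fit(y ~ x + (1 | g), d)
  ww <- wls_fit(y ~ x, d)
  expect_lt(max(abs(mm$coefficients$estimate - ww$coefficients$estimate)),
            0.02)

  # balanced two-group design: contrast equals the difference of means
  d2 <- data.frame(trt = rep(c("a", "b"), each = 20),
                   g = rep(sprintf("s%d", 1:10), each = 4))
  set.seed(74)
  d2$y <- ifelse(d2$trt == "b", 0.3, 0) + rnorm(40, 0, 0.1)
  mm2 <- wlmm_fit(y ~ trt + (1 | g), d2)
  diff_means <- mean(d2$y[d2$trt == "b"]) - mean(d2$y[d2$trt == "a"])
  expect_equal(mm2$coefficients$estimate[2], diff_means,
               tolerance = 1e-6)
})

test_that("treatment mixed model recovers known treatment effects", {
  set.seed(79)
  treatments <- default_treatments()
  effects <- c(CM_diploid_1to1000 = 0, CM_EtOH_1to1000 = -0.02,
               CM_NaCl_1to1000 = 0.05, CM_diploid_1to4000 = 0,
               CM_diploid_1to250 = 0, CM_haploid_1to1000 = 0.03)
  est <- replicate(30, {
    strains <- sprintf("s%03d", 1:152)
    trt <- rep(rep(treatments$treatment_id, treatments$n_populations),
               each = 2)
    strain_eff <- rnorm(152, 0, 0.01)
    d <- data.frame(strain = rep(strains, each = 4),
                    treatment_id = rep(trt, each = 4))
    d$delta_w <- effects[d$treatment_id] +
      rep(strain_eff, each = 4) + rnorm(nrow(d), 0, 0.043)
    d$contamination <- runif(nrow(d), 0, 1e-3)
    d$weight <- runif(nrow(d), 0.5, 2)
    fit <- fit_treatment_model(d)
    co <- fit$coefficients
    c(nacl = co$estimate[co$term == "treatment_idCM_NaCl_1to1000"],
      etoh = co$estimate[co$term == "treatment_idCM_EtOH_1to1000"],
      hap = co$estimate[co$term == "treatment_idCM_haploid_1to1000"])
  })
  means <- rowMeans(est)
  expect_lt(abs(means["nacl"] - 0.05), 0.01)
  expect_lt(abs(means["etoh"] + 0.02), 0.01)
  expect_lt(abs(means["hap"] - 0.03), 0.01)
})

test_that("null covariates are dropped by the p > 0.05 rule", {
  set.seed(83)
  dropped <- replicate(40, {
    dyn <- data.frame(
      treatment_id = rep(c("CM_diploid_1to1000", "CM_NaCl_1to1000"),
                         each = 20),
      initial_abundance = runif(40, 0.4, 0.6),
      t_max = rnorm(40, 150, 50), weight = 1)
    dyn[c("m_max", "t_max_rate", "m_max_rate", "t_max_diff",
          "m_max_diff", "total_change")] <- rnorm(40)
    fits <- fit_dynamics_models(dyn)
    identical(fits$t_max$dropped, "initial_abundance")
  })
  expect_gt(mean(dropped), 0.8)
})

test_that("fit tables carry significance stars", {
  set.seed(89)
  d <- data.frame(x = rnorm(30))
  d$y <- 2 * d$x + rnorm(30, 0, 0.1)
  tab <- tidy_fit(wls_fit(y ~ x, d))
  expect_equal(tab$signif[tab$term == "x"], "***")
  expect_true(all(c("term", "estimate", "se", "p_value") %in% names(tab)))
})
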