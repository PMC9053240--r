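test_that("partial correlation reduces to Pearson and matches the matrix oracle", {
  withr::with_seed(1, {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  })
  pc0 <- partial_corr(x, y)
  expect_equal(pc0$estimate, cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)

  # residualizing y on itself leaves nothing to correlate
  pc_self <- partial_corr(x, z, covariates = cbind(z))
  expect_lt(abs(pc_self$estimate), 1e-10)

  # 6-point worked example vs inverse-correlation-matrix oracle
  x6 <- c(1.2, 3.1, 2.2, 5.0, 4.1, 6.3)
  y6 <- c(2.0, 4.2, 3.1, 6.1, 5.5, 8.0)
  z6 <- c(0.5, 1.0, 1.4, 2.1, 2.4, 3.2)
  pc <- partial_corr(x6, y6, covariates = cbind(age = z6))
  expect_equal(pc$estimate, oracle_partial_corr(x6, y6, z6),
               tolerance = 1e-10)
  expect_equal(pc$df, 3)

  # symmetric in its two arguments
  expect_equal(partial_corr(y6, x6, cbind(z6))$estimate, pc$estimate,
               tolerance = 1e-12)
  expect_error(partial_corr(x6, y6, covariates = cbind(z6, z6)),
               class = "boldband_error_rank")
})

test_that("mediation paths satisfy the exact OLS identity and recover truth", {
  withr::with_seed(2, {
    d <- tibble::tibble(age = rnorm(40, 50, 10))
    d$feat <- 3 - 0.04 * d$age + rnorm(40, 0, 0.5)
    d$nfl <- 1 + 0.2 * d$age - 1.5 * d$feat + rnorm(40)
  })
  mr <- mediate(d, "age", "feat", "nfl", n_boot = 500, seed = 3)
  p <- tidy(mr)
  est <- setNames(p$estimate, p$term)
  expect_equal(est[["c_total"]], est[["c_prime"]] + est[["ab"]],
               tolerance = 1e-10)
  # path coefficients agree with direct lm fits
  expect_equal(est[["a"]], unname(coef(lm(feat ~ age, d))["age"]),
               tolerance = 1e-12)
  expect_equal(est[["b"]], unname(coef(lm(nfl ~ age + feat, d))["feat"]),
               tolerance = 1e-12)

  # generative recovery at large n (known paths)
  big <- gen_mediation_data(2000, a = -0.05, b = -2.2, c_prime = 0.16,
                            seed = 4)
  mb <- mediate(big, "x", "m", "y", n_boot = 300, seed = 5)
  eb <- setNames(mb$paths$estimate, mb$paths$term)
  expect_lt(abs(eb[["a"]] - (-0.05)) / 0.05, 0.1)
  expect_lt(abs(eb[["b"]] - (-2.2)) / 2.2, 0.1)
  expect_lt(abs(eb[["c_prime"]] - 0.16) / 0.16, 0.1)

  expect_error(mediate(d, "age", "feat", "nfl", n_boot = 10),
               class = "boldband_error_seed")
  d$flat <- 1
  expect_error(mediate(d, "age", "flat", "nfl", n_boot = 10, seed = 1),
               class = "boldband_error_zerovar")
})

test_that("bootstrap p-values are reproducible and sized under the null", {
  # same seed, same resamples
  d <- gen_mediation_data(60, seed = 6)
  m1 <- mediate(d, "x", "m", "y", n_boot = 200, seed = 7)
  m2 <- mediate(d, "x", "m", "y", n_boot = 200, seed = 7)
  expect_identical(m1$paths$p_boot, m2$paths$p_boot)

  # null mediation (a = 0): false-positive rate for ab near the nominal level
  hits <- vapply(1:200, function(s) {
    dn <- gen_mediation_data(50, a = 0, b = -2.2, c_prime = 0.16,
                             seed = 100 + s)
    mm <- mediate(dn, "x", "m", "y", n_boot = 300, seed = 500 + s)
    mm$paths$p_boot[mm$paths$term == "ab"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.09)
})

test_that("suppression: opposing direct and indirect paths mask the total effect", {
  d <- gen_mediation_data(200, a = -0.052, b = 4.353, c_prime = 0.2193,
                          m_sd = 0.15, y_sd = 1, seed = 8)
  mr <- mediate(d, "x", "m", "y", n_boot = 500, seed = 9)
  est <- setNames(mr$paths$estimate, mr$paths$term)
  pb <- setNames(mr$paths$p_boot, mr$paths$term)
  expect_lt(est[["ab"]], 0)          # indirect effect negative
  expect_gt(est[["c_prime"]], 0)     # direct effect positive
  expect_lt(pb[["ab"]], 0.05)        # indirect effect significant
  # total effect much smaller than either opposing component
  expect_lt(abs(est[["c_total"]]), 0.5 * min(abs(est[["ab"]]),
                                             est[["c_prime"]]))
})

test_that("moderation recovers the interaction and is centering-invariant", {
  d0 <- gen_moderation_data(400, b_int = 0, seed = 10)
  m0 <- moderate(d0, "y", "x", "w", covariates = "age")
  expect_lt(abs(m0$interaction), 3 * m0$coefficients$std_error[
    m0$coefficients$term == ".x:.w"])

  d1 <- gen_moderation_data(500, b_int = 16.495, seed = 11)
  mc <- moderate(d1, "y", "x", "w", covariates = "age", center = TRUE)
  mu <- moderate(d1, "y", "x", "w", covariates = "age", center = FALSE)
  expect_equal(mc$interaction, mu$interaction, tolerance = 1e-10)
  expect_lt(abs(mc$interaction - 16.495) / 16.495, 0.05)

  # simple slopes: slope at moderator value w equals b_x + b_int * w_centered
  ss <- mc$simple_slopes
  w_sd <- sd(d1$w)
  b_x <- unname(mc$coefficients$estimate[mc$coefficients$term == ".x"])
  expect_equal(ss$slope[2], b_x, tolerance = 1e-12)
  expect_equal(ss$slope[3] - ss$slope[1], 2 * w_sd * mc$interaction,
               tolerance = 1e-10)
})

test_that("FDR over a declared family carries its metadata", {
  out <- fdr_over_tests(c(t1 = 0.01, t2 = 0.02, t3 = 0.04),
                        family = "assoc_tests")
  expect_equal(out$q_value, c(0.03, 0.03, 0.04), tolerance = 1e-12)
  expect_identical(unique(out$family), "assoc_tests")
  single <- fdr_over_tests(c(only = 0.03))
  expect_equal(single$q_value, 0.03)
  expect_error(fdr_over_tests(numeric(0)), class = "boldband_error_family")
})
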