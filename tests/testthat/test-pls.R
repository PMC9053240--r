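sim_xy <- function(n, p, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    list(x = x, y = rnorm(n))
  })
}

test_that("the first PLS weight vector is proportional to t(X) y", {
  d <- sim_xy(15, 6, seed = 1)
  m <- fit_pls(d$x, d$y, 1)
  xs <- scale(d$x); ys <- drop(scale(d$y))
  w_closed <- crossprod(xs, ys)
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  cosine <- sum(m$W[, 1] * w_closed)
  expect_equal(abs(cosine), 1, tolerance = 1e-10)
})

test_that("full-rank PLS reproduces the OLS fit and exact signals give R2 = 1", {
  d <- sim_xy(30, 4, seed = 2)
  m <- fit_pls(d$x, d$y, 4)
  expect_equal(m$r_squared, summary(lm(d$y ~ d$x))$r.squared,
               tolerance = 1e-8)
  y_lin <- 3 * d$x[, 2] - 1
  m1 <- fit_pls(d$x[, 2, drop = FALSE], y_lin, 1)
  expect_equal(m1$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_pls(d$x, d$y, 10), class = "boldband_error_rank")
  expect_error(fit_pls(d$x, rep(2, 30), 1), class = "boldband_error_zerovar")
})

test_that("predictions invert the stored standardization", {
  d <- sim_xy(25, 5, seed = 3)
  m <- fit_pls(d$x, d$y, 2)
  # training R2 from predictions on the original scale agrees with the model
  yhat <- predict(m, d$x)
  r2 <- 1 - sum((d$y - yhat)^2) / sum((d$y - mean(d$y))^2)
  expect_equal(r2, m$r_squared, tolerance = 1e-10)
  expect_error(predict(m, d$x[, 1:3]), class = "boldband_error_features")
})

test_that("LOO-MSEP component selection finds planted latent dimensionality", {
  withr::with_seed(4, {
    n <- 50
    t1 <- rnorm(n); t2 <- rnorm(n)
    x <- cbind(t1 + 0.01 * rnorm(n), t1 - 0.01 * rnorm(n),
               t2 + 0.01 * rnorm(n), t2 - 0.01 * rnorm(n))
    y <- t1 + t2
  })
  expect_equal(as.integer(select_ncomp(x, y, max_comp = 4)), 2L)
  # pure noise: most replicates settle on a single component
  sel <- vapply(1:10, function(s) {
    d <- sim_xy(20, 6, seed = s)
    as.integer(select_ncomp(d$x, d$y, max_comp = 4))
  }, integer(1))
  expect_gt(mean(sel == 1L), 0.5)
  d <- sim_xy(20, 6, seed = 5)
  expect_identical(select_ncomp(d$x, d$y, force_one = TRUE), 1L)
})

test_that("VIP scores obey the normalization identity and the hand formula", {
  d <- sim_xy(20, 1, seed = 6)
  expect_equal(vip(fit_pls(d$x, d$y, 1))$vip, 1, tolerance = 1e-12)
  for (seed in 1:5) {
    dd <- sim_xy(18, 7, seed = 10 + seed)
    v <- vip(fit_pls(dd$x, dd$y, 2))$vip
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
  }
  # two orthogonal features, y correlated only with the first
  withr::with_seed(7, {
    x1 <- drop(scale(rnorm(40)))
    x2 <- drop(scale(resid(lm(rnorm(40) ~ x1))))
    y <- x1 + 0.1 * rnorm(40)
  })
  m <- fit_pls(cbind(a = x1, b = x2), y, 1)
  v <- vip(m)
  # hand formula at one component: VIP_j = sqrt(p) * |w_j| / ||w||
  w <- m$W[, 1]
  expect_equal(v$vip, sqrt(2) * abs(w) / sqrt(sum(w^2)), tolerance = 1e-10)
  expect_gt(v$vip[v$feature == "a"], 1)
  expect_lt(v$vip[v$feature == "b"], 1)
})

test_that("the permutation gate is seed-reproducible and flags wide models", {
  d <- sim_xy(20, 132, seed = 8)
  g1 <- permutation_gate(d$x, d$y, n_perm = 300, seed = 9)
  g2 <- permutation_gate(d$x, d$y, n_perm = 300, seed = 9)
  expect_identical(g1$null_r2, g2$null_r2)
  expect_true(g1$is_overfit)   # p >> n fits shuffled outcomes well
  expect_equal(g1$p_observed, mean(g1$null_r2 >= g1$observed_r2))
  g3 <- permutation_gate(d$x, d$y, n_perm = 300, seed = 10)
  expect_false(identical(g1$null_r2, g3$null_r2))
  expect_error(permutation_gate(d$x, d$y, n_perm = 10),
               class = "boldband_error_seed")
  expect_error(permutation_gate(d$x, rep(1, 20), n_perm = 10, seed = 1),
               class = "boldband_error_zerovar")
})

test_that("the VIP sweep spans from the full set to skipped empty subsets", {
  d <- sim_xy(16, 8, seed = 11)
  sw <- vip_sweep(d$x, d$y, thresholds = c(0, 1, 100), seed = 12,
                  gate = FALSE)
  expect_equal(sw$n_features[sw$threshold == 0], 8L)
  expect_false(100 %in% sw$threshold)  # empty subset skipped
  # a strong planted feature survives every threshold below its VIP
  withr::with_seed(13, {
    x <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(NULL, sprintf("f%02d", 1:10)))
    y <- 2 * x[, 4] + 0.3 * rnorm(20)
  })
  sw2 <- vip_sweep(x, y, thresholds = seq(0.8, 2.0, 0.4), seed = 14,
                   gate = FALSE)
  planted_vip <- attr(sw2, "vip_full")$vip[4]
  for (i in seq_len(nrow(sw2))) {
    if (sw2$threshold[i] < planted_vip) {
      expect_true("f04" %in% sw2$features[[i]])
    }
  }
})

test_that("cross-validated Q2 recovers noiseless signals and stays <= 1", {
  withr::with_seed(15, {
    x <- matrix(rnorm(20 * 12), 20, 12,
                dimnames = list(NULL, sprintf("f%02d", 1:12)))
    y <- 1.5 * x[, 3]
  })
  cv <- loocv_q2(x, y, seed = 16, gate_n_perm = 60)
  expect_equal(cv$q2, 1, tolerance = 1e-6)
  expect_true(all(cv$inclusion["f03", ]))
  expect_identical(dim(cv$inclusion), c(12L, 20L))
  expect_lte(cv$q2, 1)
})

test_that("Q2 is invariant to affine rescaling of the outcome", {
  d <- sim_xy(12, 8, seed = 17)
  cv1 <- loocv_q2(d$x, d$y, seed = 18, gate_n_perm = 50)
  cv2 <- loocv_q2(d$x, 10 * d$y - 4, seed = 18, gate_n_perm = 50)
  expect_equal(cv1$q2, cv2$q2, tolerance = 1e-8)
})

test_that("the held-out-error fold rule is optimistic relative to the leak-free rule on null data", {
  q_leak <- numeric(3); q_clean <- numeric(3)
  for (s in 1:3) {
    d <- sim_xy(12, 15, seed = 20 + s)
    q_leak[s] <- loocv_q2(d$x, d$y, seed = 30 + s, gate_n_perm = 50,
                          rule = "test_error")$q2
    q_clean[s] <- loocv_q2(d$x, d$y, seed = 30 + s, gate_n_perm = 50,
                           rule = "train_msep")$q2
  }
  expect_gt(mean(q_leak), mean(q_clean))
})

test_that("transfer R2 and VIP agreement behave at the boundaries", {
  d <- sim_xy(25, 6, seed = 24)
  m <- fit_pls(d$x, d$y, 1)
  expect_equal(transfer_r2(m, d$x, d$y), m$r_squared, tolerance = 1e-10)
  v <- vip(m)
  expect_equal(vip_agreement(v, v), 1)
  rev_v <- v
  rev_v$vip <- max(v$vip) + min(v$vip) - v$vip   # exactly reversed ranking
  expect_equal(vip_agreement(v, rev_v), -1)
  other <- v; other$feature <- paste0("x_", other$feature)
  expect_error(vip_agreement(v, other), class = "boldband_error_features")
  # independent profiles: tau concentrates near zero at p = 132
  taus <- vapply(1:10, function(s) {
    withr::with_seed(s, vip_agreement(setNames(runif(132), paste0("f", 1:132)),
                                      setNames(runif(132), paste0("f", 1:132))))
  }, numeric(1))
  expect_lt(stats::median(abs(taus)), 0.2)
})

test_that("tidy and glance methods summarize fitted objects", {
  d <- sim_xy(15, 5, seed = 25)
  m <- fit_pls(d$x, d$y, 1)
  td <- tidy(m)
  expect_identical(names(td), c("feature", "weight", "coefficient", "vip"))
  expect_equal(nrow(td), 5)
  gl <- glance(m)
  expect_equal(gl$n, 15)
  cv <- loocv_q2(d$x, d$y, seed = 26, gate_n_perm = 40)
  expect_equal(glance(cv)$q2, cv$q2)
  expect_equal(nrow(tidy(cv)), 15)
})
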