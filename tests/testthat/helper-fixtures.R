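# Shared fixtures and independent oracles.

path3_connectome <- function() {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 1
  a[2, 3] <- a[3, 2] <- 1
  validate_connectome(a, c("a", "b", "c"), subject_id = "p3")
}

k2_connectome <- function() {
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  validate_connectome(a, c("a", "b"), subject_id = "k2")
}

random_connectome <- function(n, seed, labels = NULL) {
  withr::with_seed(seed, {
    a <- matrix(rpois(n * n, 5), n, n)
    a <- a + t(a)
    diag(a) <- 0
    validate_connectome(a + 0.0, labels %||% sprintf("r%02d", seq_len(n)),
                        subject_id = sprintf("rand%d", seed))
  })
}

random_zscored_series <- function(basis, t_len, seed) {
  withr::with_seed(seed, {
    n <- length(basis$eigenvalues)
    bold_series(matrix(rnorm(n * t_len), n, t_len,
                       dimnames = list(basis$region_labels, NULL)),
                tr = 2, region_labels = basis$region_labels,
                subject_id = basis$subject_id, stage = "zscored")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple-regression F via explicit two-model residual sums of squares.
oracle_anova_f <- function(x, y) {
  rss0 <- sum((y - mean(y))^2)
  fit <- lm(y ~ x)
  rss1 <- sum(resid(fit)^2)
  f <- (rss0 - rss1) / (rss1 / (length(y) - 2))
  c(f = f, p = pf(f, 1, length(y) - 2, lower.tail = FALSE))
}

# Brute-force BH step-up rejection set from the defining inequality.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * alpha / m)
  rejected <- logical(m)
  if (length(k)) rejected[ord[seq_len(max(k))]] <- TRUE
  rejected
}

# Exact two-sided rank-sum p by enumerating all group assignments.
oracle_ranksum_exact <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  obs_u <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combs <- utils::combn(n, length(a))
  us <- apply(combs, 2, function(idx) {
    sum(ranks[idx]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs_u - mu) - 1e-12)
}

# Partial correlation via the inverse of the joint correlation matrix.
oracle_partial_corr <- function(x, y, z) {
  r <- cor(cbind(x, y, z))
  pinv <- solve(r)
  -pinv[1, 2] / sqrt(pinv[1, 1] * pinv[2, 2])
}
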