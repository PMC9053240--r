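# Age-adjusted partial correlation, bootstrap mediation, and moderation
# with simple slopes.

#' Partial correlation between two variables given covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on an intercept
#' plus the covariates; with no covariates this is the plain Pearson
#' correlation. The p-value uses the t distribution on `n - k - 2` degrees
#' of freedom (k covariates), two-sided.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (e.g. age), or `NULL`.
#' @return Tibble `estimate`, `statistic`, `p_value`, `n`, `df`,
#'   `covariates`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(n == length(y))
  if (is.null(covariates)) {
    z <- matrix(numeric(0), n, 0)
  } else {
    z <- as.matrix(covariates)
    stopifnot(nrow(z) == n)
  }
  k <- ncol(z)
  if (n <= k + 2) {
    abort("Need n > number of covariates + 2.",
          class = "boldband_error_dimension")
  }
  design <- cbind(1, z)
  if (qr(design)$rank < ncol(design)) {
    abort("Covariates are rank deficient.", class = "boldband_error_rank")
  }
  rx <- resid(stats::lm.fit(design, x))
  ry <- resid(stats::lm.fit(design, y))
  if (sd(rx) < 1e-14 || sd(ry) < 1e-14) {
    rho <- 0; tstat <- 0; p <- 1
  } else {
    rho <- cor(rx, ry)
    df <- n - k - 2
    tstat <- rho * sqrt(df / max(1 - rho^2, 1e-300))
    p <- 2 * pt(-abs(tstat), df)
  }
  tibble(
    estimate = rho, statistic = tstat, p_value = p, n = n, df = n - k - 2,
    covariates = if (k) paste(colnames(z) %||% sprintf("z%d", 1:k),
                              collapse = ",") else ""
  )
}

# Closed-form OLS paths (centered normal equations); hot path for the
# bootstrap loop.
.mediation_paths <- function(x, m, y) {
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc^2); sxm <- sum(xc * mc); smm <- sum(mc^2)
  sxy <- sum(xc * yc); smy <- sum(mc * yc)
  a <- sxm / sxx
  det <- sxx * smm - sxm^2
  c_prime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  c(a = a, b = b, c_prime = c_prime, ab = a * b, c_total = sxy / sxx)
}

#' Bootstrap mediation analysis
#'
#' Simple (X, M, Y) mediation by ordinary least squares in raw units:
#' path `a` from `M ~ X`, paths `b` and `c'` from `Y ~ X + M`, total effect
#' `c` from `Y ~ X`, indirect effect `ab = a * b`. The OLS identity
#' `c = c' + ab` holds exactly. Significance per path comes from
#' case-resampling bootstrap percentile p-values (two-sided: twice the
#' smaller tail proportion around zero), with a bias-corrected option.
#'
#' @param data Data frame holding the variables.
#' @param x,m,y Column names for predictor, mediator, outcome.
#' @param n_boot Bootstrap resamples (protocol default 10000).
#' @param seed Integer seed (required).
#' @param boot_type `"percentile"` or `"bias_corrected"`.
#' @return A `mediation_result`; `tidy()` returns the path table with OLS
#'   standard errors, bootstrap standard errors and bootstrap p-values.
#' @export
mediate <- function(data, x, m, y, n_boot = 10000, seed,
                    boot_type = c("percentile", "bias_corrected")) {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  boot_type <- match.arg(boot_type)
  d <- tibble(x = as.numeric(data[[x]]), m = as.numeric(data[[m]]),
              y = as.numeric(data[[y]]))
  if (anyNA(d)) abort("Complete cases required.",
                      class = "boldband_error_missing")
  if (any(vapply(d, sd, numeric(1)) < .Machine$double.eps^0.5)) {
    abort("A mediation variable has zero variance.",
          class = "boldband_error_zerovar")
  }
  est <- .mediation_paths(d$x, d$m, d$y)
  fa <- summary(lm(m ~ x, data = d))$coefficients
  fb <- summary(lm(y ~ x + m, data = d))$coefficients
  fc <- summary(lm(y ~ x, data = d))$coefficients
  se_ols <- c(a = fa["x", 2], b = fb["m", 2], c_prime = fb["x", 2],
              ab = NA_real_, c_total = fc["x", 2])
  p_ols <- c(a = fa["x", 4], b = fb["m", 4], c_prime = fb["x", 4],
             ab = NA_real_, c_total = fc["x", 4])
  n <- nrow(d)
  boot <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      .mediation_paths(d$x[idx], d$m[idx], d$y[idx])
    }, numeric(5)))
  })
  boot_p <- vapply(seq_len(5), function(j) {
    bj <- boot[, j]
    if (boot_type == "percentile") {
      2 * min(mean(bj <= 0), mean(bj >= 0))
    } else {
      z0 <- qnorm(pmin(pmax(mean(bj < est[j]), 1 / n_boot),
                       1 - 1 / n_boot))
      pr0 <- pmin(pmax(mean(bj <= 0), 1 / n_boot), 1 - 1 / n_boot)
      zp <- qnorm(pr0) - 2 * z0
      2 * min(pnorm(zp), 1 - pnorm(zp))
    }
  }, numeric(1))
  paths <- tibble(
    term = names(est), estimate = unname(est),
    std_error_ols = unname(se_ols), p_ols = unname(p_ols),
    std_error_boot = apply(boot, 2, sd),
    p_boot = pmin(boot_p, 1)
  )
  structure(
    list(paths = paths, n = n, n_boot = n_boot, seed = seed,
         boot_type = boot_type, boot = boot,
         roles = c(x = x, m = m, y = y)),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s (n = %d, %d bootstrap resamples)\n",
              x$roles[["x"]], x$roles[["m"]], x$roles[["y"]], x$n, x$n_boot))
  print(x$paths)
  invisible(x)
}

#' @export
tidy.mediation_result <- function(x, ...) x$paths

#' @export
glance.mediation_result <- function(x, ...) {
  ab <- x$paths[x$paths$term == "ab", ]
  tibble(ab = ab$estimate, p_ab = ab$p_boot, n = x$n, n_boot = x$n_boot,
         boot_type = x$boot_type)
}

#' Moderation analysis with simple slopes
#'
#' OLS of `Y` on covariates, the focal predictor `X`, the moderator `W`,
#' and their product. The interaction coefficient — the moderation effect —
#' is invariant to translating (centering) `X` and `W`; centering (the
#' default) only makes the main effects interpretable at the means. Simple
#' slopes of `Y` on `X` are reported at moderator values mean - SD, mean,
#' and mean + SD.
#'
#' @param data Data frame.
#' @param y,x,w Column names for outcome, focal predictor, moderator.
#' @param covariates Character vector of covariate column names.
#' @param center Mean-center `x` and `w` before fitting.
#' @return A `moderation_result` with `coefficients` and `simple_slopes`
#'   tibbles.
#' @export
moderate <- function(data, y, x, w, covariates = character(), center = TRUE) {
  d <- data[, c(y, x, w, covariates), drop = FALSE]
  if (anyNA(d)) abort("Complete cases required.",
                      class = "boldband_error_missing")
  n <- nrow(d)
  if (n <= length(covariates) + 5) {
    abort("Too few observations for the moderation model.",
          class = "boldband_error_dimension")
  }
  w_mean <- mean(d[[w]]); w_sd <- sd(d[[w]])
  xv <- d[[x]]; wv <- d[[w]]
  if (center) {
    xv <- xv - mean(xv)
    wv <- wv - w_mean
  }
  dd <- data.frame(.y = d[[y]], .x = xv, .w = wv,
                   d[covariates], check.names = FALSE)
  fml <- stats::reformulate(c(covariates, ".x", ".w", ".x:.w"),
                            response = ".y")
  fit <- lm(fml, data = dd)
  mm <- stats::model.matrix(fit)
  kap <- kappa(mm, exact = TRUE)
  if (kap > 1e8) {
    warn(sprintf("Design condition number %.3g suggests collinearity.", kap),
         class = "boldband_warning_collinear")
  }
  cf <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(cf),
    estimate = cf[, 1], std_error = cf[, 2],
    statistic = cf[, 3], p_value = cf[, 4]
  )
  b_x <- cf[".x", 1]; b_int <- cf[".x:.w", 1]
  vc <- stats::vcov(fit)
  w_eval <- c(w_mean - w_sd, w_mean, w_mean + w_sd)
  w_code <- if (center) w_eval - w_mean else w_eval
  slopes <- b_x + b_int * w_code
  slope_se <- sqrt(vc[".x", ".x"] + w_code^2 * vc[".x:.w", ".x:.w"] +
                     2 * w_code * vc[".x", ".x:.w"])
  simple_slopes <- tibble(
    moderator_value = w_eval,
    label = c("mean - sd", "mean", "mean + sd"),
    slope = slopes, std_error = slope_se,
    p_value = 2 * pt(-abs(slopes / slope_se), fit$df.residual)
  )
  structure(
    list(coefficients = coefs, simple_slopes = simple_slopes,
         interaction = unname(b_int), fit = fit, centered = center,
         roles = c(y = y, x = x, w = w),
         covariates = covariates, n = n),
    class = "moderation_result"
  )
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("<moderation_result> %s ~ %s * %s (n = %d): interaction = %.4g\n",
              x$roles[["y"]], x$roles[["x"]], x$roles[["w"]], x$n,
              x$interaction))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.moderation_result <- function(x, ...) x$coefficients

#' @export
glance.moderation_result <- function(x, ...) {
  int <- x$coefficients[x$coefficients$term == ".x:.w", ]
  tibble(interaction = int$estimate, p_interaction = int$p_value,
         n = x$n, centered = x$centered)
}

#' FDR correction over a declared family of tests
#'
#' Benjamini-Hochberg adjustment over an explicitly named test family; the
#' family membership is recorded in the output so downstream reports state
#' exactly which tests were corrected together.
#'
#' @param p_values Named numeric vector of p-values (names identify tests).
#' @param alpha FDR level.
#' @param family Label for the test family.
#' @return Tibble as [bh_fdr()] plus a `family` attribute/column.
#' @export
fdr_over_tests <- function(p_values, alpha = 0.05, family = "unnamed_family") {
  if (!length(p_values)) abort("Empty test family.",
                               class = "boldband_error_family")
  out <- bh_fdr(p_values, alpha = alpha)
  out$family <- family
  out
}
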