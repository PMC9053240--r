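# Partial least squares regression protocol for a univariate outcome:
# NIPALS fit, LOO-MSEP component selection, VIP scores, permutation-null
# overfit gate, VIP-threshold sweep, leave-one-out Q2, transfer R2.

# NIPALS on pre-standardized matrices; the hot path for permutation nulls.
.pls_core <- function(xs, ys, ncomp, tol = 1e-12) {
  n <- nrow(xs); p <- ncol(xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp); TT <- matrix(0, n, ncomp); tts <- numeric(ncomp)
  xd <- xs; yd <- ys
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < tol) {
      abort(sprintf("n_components = %d exceeds the effective rank (%d).",
                    ncomp, a - 1L),
            class = "boldband_error_rank")
    }
    w <- w / wn
    t_sc <- xd %*% w
    tt <- sum(t_sc^2)
    if (tt < tol) {
      abort(sprintf("n_components = %d exceeds the effective rank (%d).",
                    ncomp, a - 1L),
            class = "boldband_error_rank")
    }
    p_load <- crossprod(xd, t_sc) / tt
    q <- sum(yd * t_sc) / tt
    xd <- xd - t_sc %*% t(p_load)
    yd <- yd - q * t_sc
    W[, a] <- w; P[, a] <- p_load; Q[a] <- q
    TT[, a] <- t_sc; tts[a] <- tt
  }
  list(W = W, P = P, Q = Q, scores = TT, tt = tts,
       r_squared = 1 - sum(yd^2) / sum(ys^2))
}

# Training R-squared only, used inside permutation loops.
.pls_r2 <- function(xs, ys, ncomp) {
  tss <- sum(ys^2)
  xd <- xs; yd <- ys
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    t_sc <- xd %*% (w / wn)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    yd <- yd - (sum(yd * t_sc) / tt) * t_sc
    if (a < ncomp) xd <- xd - t_sc %*% (crossprod(xd, t_sc) / tt)
  }
  1 - sum(yd^2) / tss
}

.standardize <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  sds[sds < .Machine$double.eps^0.5] <- 1  # constant columns become all-zero
  list(xs = sweep(sweep(x, 2, mu), 2, sds, "/"), mean = mu, sd = sds)
}

#' Fit a partial least squares regression model
#'
#' Univariate-response PLS via the NIPALS algorithm. Predictors and outcome
#' are z-scored internally (sample SD); the standardization parameters are
#' stored so the model can score new data on the original scale. PLS is the
#' regression of choice here because the feature count (132 band energies)
#' far exceeds the cohort sizes and the features are highly collinear.
#'
#' @param X Numeric matrix or data frame of predictors (n x p), or a wide
#'   feature tibble from [widen_features()].
#' @param y Numeric outcome of length n.
#' @param n_components Number of latent components (>= 1).
#' @return A `pls_model` with per-component weights (`W`, unit norm),
#'   x-loadings (`P`), y-loadings (`Q`), `scores`, standardized-scale
#'   coefficients, training `r_squared`, and the standardization parameters.
#' @export
fit_pls <- function(X, y, n_components = 1) {
  x <- feature_matrix_any(X)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(n == length(y))
  if (n < 3) abort("At least 3 observations required.",
                   class = "boldband_error_dimension")
  if (n_components < 1) abort("n_components must be >= 1.",
                              class = "boldband_error_rank")
  if (sd(y) < .Machine$double.eps^0.5) {
    abort("Outcome has zero variance.", class = "boldband_error_zerovar")
  }
  std <- .standardize(x)
  ys <- (y - mean(y)) / sd(y)
  core <- .pls_core(std$xs, ys, n_components)
  pw <- crossprod(core$P, core$W)
  coefs_std <- core$W %*% solve(pw, core$Q)
  features <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  structure(
    list(n_components = n_components,
         W = core$W, P = core$P, Q = core$Q,
         scores = core$scores, tt = core$tt,
         coefficients_std = drop(coefs_std),
         features = features,
         x_mean = std$mean, x_sd = std$sd,
         y_mean = mean(y), y_sd = sd(y),
         r_squared = core$r_squared, n = n),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d features, n = %d, R2 = %.4f\n",
              x$n_components, length(x$features), x$n, x$r_squared))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix/data frame with the model's feature columns.
#' @param ... Unused.
#' @return Numeric predictions on the original outcome scale.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  x <- feature_matrix_any(newdata)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(object$features)) {
      abort("newdata has the wrong number of columns.",
            class = "boldband_error_features")
    }
  } else {
    missing <- setdiff(object$features, colnames(x))
    if (length(missing)) {
      abort(sprintf("newdata is missing feature(s): %s.",
                    paste(head(missing, 5), collapse = ", ")),
            class = "boldband_error_features")
    }
    x <- x[, object$features, drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, object$x_mean), 2, object$x_sd, "/")
  drop(object$y_mean + object$y_sd * (xs %*% object$coefficients_std))
}

#' Select the number of PLS components by leave-one-out MSEP
#'
#' Computes the leave-one-out mean squared error of prediction for 1 to
#' `max_comp` components and returns the minimizer, with ties broken toward
#' fewer components. With very small cohorts the protocol forces a single
#' component (`force_one = TRUE`) rather than trusting the MSEP curve.
#'
#' @inheritParams fit_pls
#' @param max_comp Largest component count to evaluate.
#' @param force_one Return 1 regardless (the small-sample override).
#' @return Integer component count, with the MSEP curve as attribute
#'   `"msep"`.
#' @export
select_ncomp <- function(X, y, max_comp = 5, force_one = FALSE) {
  if (force_one) return(1L)
  x <- feature_matrix_any(X)
  y <- as.numeric(y)
  n <- nrow(x)
  press <- matrix(NA_real_, n, max_comp)
  for (i in seq_len(n)) {
    fit <- fit_pls(x[-i, , drop = FALSE], y[-i], n_components = max_comp)
    for (a in seq_len(max_comp)) {
      pw <- crossprod(fit$P[, 1:a, drop = FALSE], fit$W[, 1:a, drop = FALSE])
      b <- fit$W[, 1:a, drop = FALSE] %*% solve(pw, fit$Q[1:a])
      xs <- (x[i, ] - fit$x_mean) / fit$x_sd
      pred <- fit$y_mean + fit$y_sd * sum(xs * b)
      press[i, a] <- (y[i] - pred)^2
    }
  }
  msep <- colMeans(press)
  best <- which.min(msep)  # first minimum = fewest components on ties
  structure(as.integer(best), msep = msep)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_aj^2 / sum_a SSY_a )` with unit-norm
#' component weights `w_a` and `SSY_a` the outcome variance explained by
#' component `a`. By construction `mean(VIP^2) = 1`, so scores above 1 mark
#' features of above-average importance.
#'
#' @param model A `pls_model`.
#' @return Tibble `feature`, `vip`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$Q^2 * model$tt
  p <- length(model$features)
  w2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  scores <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  tibble(feature = model$features, vip = scores)
}

#' Permutation-null overfit gate for a PLS model
#'
#' Refits the model to `n_perm` random permutations of the outcome and
#' records the training R-squared of each refit. A model whose null
#' distribution of explained variance has mean above 0.5 fits noise well
#' enough to be declared overfit, whatever its observed R-squared. The
#' observed R-squared's one-sided significance is the fraction of null
#' values greater than or equal to it.
#'
#' @inheritParams fit_pls
#' @param n_perm Number of permutations (protocol default 5000).
#' @param seed Integer seed (required; recorded in the result).
#' @param overfit_mean Null-mean threshold above which the gate fires.
#' @return A `permutation_null`: `null_r2`, `null_mean`, `observed_r2`,
#'   `is_overfit`, `p_observed`, `n_perm`, `seed`.
#' @export
permutation_gate <- function(X, y, n_components = 1, n_perm = 5000, seed,
                             overfit_mean = 0.5) {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  x <- feature_matrix_any(X)
  y <- as.numeric(y)
  if (sd(y) < .Machine$double.eps^0.5) {
    abort("Outcome has zero variance; the permutation null is degenerate.",
          class = "boldband_error_zerovar")
  }
  std <- .standardize(x)
  ys <- (y - mean(y)) / sd(y)
  observed <- .pls_r2(std$xs, ys, n_components)
  null_r2 <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      .pls_r2(std$xs, sample(ys), n_components)
    }, numeric(1))
  })
  structure(
    list(n_perm = n_perm, seed = seed, null_r2 = null_r2,
         null_mean = mean(null_r2), observed_r2 = observed,
         is_overfit = mean(null_r2) > overfit_mean,
         p_observed = mean(null_r2 >= observed)),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> n_perm = %d: observed R2 = %.4f, null mean = %.4f (%s), p = %.4f\n",
    x$n_perm, x$observed_r2, x$null_mean,
    if (x$is_overfit) "OVERFIT" else "not overfit", x$p_observed))
  invisible(x)
}

#' Sweep VIP thresholds to form candidate reduced PLS models
#'
#' VIP scores from the full-feature one-component model rank the features;
#' for each threshold the features with VIP strictly above it form a
#' candidate one-component model, optionally gated by a permutation null.
#' Thresholds whose feature set is empty are skipped with a note.
#'
#' @inheritParams permutation_gate
#' @param thresholds Ascending VIP thresholds (the grid 0.8–2.0 by 0.1 by
#'   default; VIP = 1 is average importance).
#' @param gate Attach a permutation-null overfit flag per candidate.
#' @param gate_n_perm Permutations per candidate gate.
#' @return Tibble with one row per evaluated threshold: `threshold`,
#'   `n_features`, `features` (list), `r_squared`, `null_mean`, `overfit`,
#'   `model` (list of `pls_model`).
#' @export
vip_sweep <- function(X, y, thresholds = seq(0.8, 2.0, by = 0.1),
                      seed, gate = TRUE, gate_n_perm = 200) {
  if (gate && missing(seed)) {
    abort("`seed` is required when gating.", class = "boldband_error_seed")
  }
  x <- feature_matrix_any(X)
  y <- as.numeric(y)
  full <- fit_pls(x, y, n_components = 1)
  vips <- vip(full)
  rows <- purrr::imap(thresholds, function(th, i) {
    keep <- vips$feature[vips$vip > th]
    if (!length(keep)) {
      inform(sprintf("VIP threshold %.2f leaves no features; skipped.", th),
             class = "boldband_note_empty_subset")
      return(NULL)
    }
    m <- fit_pls(x[, keep, drop = FALSE], y, n_components = 1)
    nullmean <- NA_real_; overfit <- NA
    if (gate) {
      g <- permutation_gate(x[, keep, drop = FALSE], y, n_components = 1,
                            n_perm = gate_n_perm, seed = seed + i)
      nullmean <- g$null_mean; overfit <- g$is_overfit
    }
    tibble(threshold = th, n_features = length(keep),
           features = list(keep), r_squared = m$r_squared,
           null_mean = nullmean, overfit = overfit, model = list(m))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "vip_full") <- vips
  out
}

#' Leave-one-out cross-validated Q2 with per-fold VIP selection
#'
#' The protocol's outer loop. For each held-out subject, the VIP-threshold
#' sweep (with permutation overfit gates) runs on the training subjects
#' only; among the non-overfit candidate models, the fold's model is then
#' chosen either by the smallest absolute error on the held-out subject
#' (`rule = "test_error"`, the protocol's stated rule — note this consults
#' the held-out outcome, an information leak that biases Q2 upward) or by
#' the smallest training-set leave-one-out MSEP (`rule = "train_msep"`, the
#' leak-free alternative, reported for comparison). If no candidate passes
#' the gate the fold predicts the training mean.
#'
#' @inheritParams vip_sweep
#' @param rule Fold-model selection rule (see Description).
#' @return A `cv_result`: `q2`, per-fold `predictions` tibble, logical
#'   `inclusion` matrix (features x subjects, the carpet-plot data), `rule`,
#'   `seed`.
#' @export
loocv_q2 <- function(X, y, thresholds = seq(0.8, 2.0, by = 0.1),
                     seed, gate_n_perm = 200,
                     rule = c("test_error", "train_msep")) {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  rule <- match.arg(rule)
  x <- feature_matrix_any(X)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 5) abort("At least 5 subjects required.",
                   class = "boldband_error_dimension")
  feats <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  colnames(x) <- feats
  inclusion <- matrix(FALSE, ncol(x), n,
                      dimnames = list(feats, rownames(x) %||% as.character(seq_len(n))))
  preds <- numeric(n)
  fold_rows <- vector("list", n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    cand <- vip_sweep(xtr, ytr, thresholds = thresholds,
                      seed = seed + 1000L * i, gate = TRUE,
                      gate_n_perm = gate_n_perm)
    ok <- cand[!is.na(cand$overfit) & !cand$overfit, , drop = FALSE]
    if (!nrow(ok)) {
      preds[i] <- mean(ytr)
      fold_rows[[i]] <- tibble(subject = i, y = y[i], y_pred = preds[i],
                               threshold = NA_real_, n_features = 0L)
      inform(sprintf("Fold %d: no non-overfit candidate; predicting the training mean.", i),
             class = "boldband_note_no_candidate")
      next
    }
    cand_pred <- vapply(ok$model, function(m) {
      predict(m, x[i, m$features, drop = FALSE])
    }, numeric(1))
    pick <- if (rule == "test_error") {
      which.min(abs(y[i] - cand_pred))
    } else {
      msep <- vapply(seq_len(nrow(ok)), function(j) {
        fs <- ok$features[[j]]
        mean((ytr - .loo_pred_1comp(xtr[, fs, drop = FALSE], ytr))^2)
      }, numeric(1))
      which.min(msep)
    }
    preds[i] <- cand_pred[pick]
    inclusion[ok$features[[pick]], i] <- TRUE
    fold_rows[[i]] <- tibble(subject = i, y = y[i], y_pred = preds[i],
                             threshold = ok$threshold[pick],
                             n_features = ok$n_features[pick])
  }
  q2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  structure(
    list(q2 = q2, predictions = dplyr::bind_rows(fold_rows),
         inclusion = inclusion, rule = rule, seed = seed,
         thresholds = thresholds),
    class = "cv_result"
  )
}

# Inner leave-one-out predictions of a 1-component PLS on a feature subset.
.loo_pred_1comp <- function(x, y) {
  n <- nrow(x)
  vapply(seq_len(n), function(j) {
    m <- fit_pls(x[-j, , drop = FALSE], y[-j], n_components = 1)
    predict(m, x[j, , drop = FALSE])
  }, numeric(1))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> Q2 = %.4f over %d folds (rule: %s)\n",
              x$q2, nrow(x$predictions), x$rule))
  invisible(x)
}

#' Out-of-sample explained variance of a PLS model on a new cohort
#'
#' Applies a fitted model (with its stored standardization) to another
#' cohort and returns `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; the
#' value may be negative when the model transfers poorly.
#'
#' @param model A `pls_model`.
#' @param X_new,y_new The new cohort's features and outcome.
#' @return Numeric transfer R-squared.
#' @export
transfer_r2 <- function(model, X_new, y_new) {
  yhat <- predict(model, X_new)
  y <- as.numeric(y_new)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Kendall rank agreement between two VIP profiles
#'
#' Kendall's tau over the paired per-feature VIP scores of two models on
#' the same feature namespace; near-zero values mean the two cohorts rank
#' feature importance inconsistently.
#'
#' @param vip_a,vip_b Tibbles from [vip()] or named numeric vectors.
#' @return Kendall's tau (numeric scalar).
#' @export
vip_agreement <- function(vip_a, vip_b) {
  to_named <- function(v) {
    if (is.data.frame(v)) setNames(v$vip, v$feature) else v
  }
  a <- to_named(vip_a); b <- to_named(vip_b)
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b))) {
    abort("VIP vectors must share the same feature namespace.",
          class = "boldband_error_features")
  }
  b <- b[names(a)]
  unname(cor(a, b, method = "kendall"))
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble(
    feature = x$features,
    weight = x$W[, 1],
    coefficient = x$coefficients_std,
    vip = vip(x)$vip
  )
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble(n_components = x$n_components, r_squared = x$r_squared,
         n = x$n, p = length(x$features))
}

#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @export
glance.cv_result <- function(x, ...) {
  tibble(q2 = x$q2, n = nrow(x$predictions), rule = x$rule,
         mean_features = mean(x$predictions$n_features))
}

#' @export
tidy.permutation_null <- function(x, ...) {
  tibble(null_r2 = x$null_r2)
}

#' @export
glance.permutation_null <- function(x, ...) {
  tibble(n_perm = x$n_perm, null_mean = x$null_mean,
         observed_r2 = x$observed_r2, is_overfit = x$is_overfit,
         p_observed = x$p_observed)
}
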