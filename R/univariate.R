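#' Univariate F-test feature selection
#'
#' Regresses the outcome on each feature separately and reports the
#' one-degree-of-freedom F statistic `F = (n - 2) r^2 / (1 - r^2)` with its
#' p-value on (1, n - 2) df — identical to the two-model ANOVA comparison of
#' the intercept-only fit against the simple regression. Benjamini-Hochberg
#' q-values are attached over the full feature family.
#'
#' @param features Wide feature tibble (from [widen_features()]), a numeric
#'   matrix, or a data frame of numeric feature columns.
#' @param y Numeric outcome (e.g. serum NfL, pg/mL), one value per row of
#'   `features`.
#' @param alpha FDR level used for the `significant` flag.
#' @return A `univariate_result` tibble sorted by F descending: `feature`,
#'   `f_value`, `p_value`, `q_value`, `rank`, `significant`, `constant`.
#'   Constant features are flagged, not dropped; an exact linear
#'   relationship reports `f_value = Inf`, `p_value = 0`.
#' @export
f_select <- function(features, y, alpha = 0.05) {
  x <- if (is.matrix(features)) features else feature_matrix_any(features)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n != length(y)) {
    abort("`y` length must match the number of rows in `features`.",
          class = "boldband_error_dimension")
  }
  if (n < 3) abort("At least 3 subjects required.",
                   class = "boldband_error_dimension")
  if (anyNA(x) || anyNA(y)) {
    abort("Missing values are not supported.",
          class = "boldband_error_missing")
  }
  sds <- apply(x, 2, sd)
  constant <- sds < .Machine$double.eps^0.5
  r2 <- rep(NA_real_, ncol(x))
  r <- suppressWarnings(cor(x[, !constant, drop = FALSE], y))
  r2[!constant] <- drop(r)^2
  fval <- (n - 2) * r2 / (1 - r2)
  fval[!constant & r2 > 1 - 1e-14] <- Inf
  pval <- ifelse(is.infinite(fval), 0, pf(fval, 1, n - 2, lower.tail = FALSE))
  qval <- rep(NA_real_, ncol(x))
  qval[!constant] <- p.adjust(pval[!constant], method = "BH")
  out <- tibble(
    feature = colnames(x) %||% sprintf("V%d", seq_len(ncol(x))),
    f_value = fval, p_value = pval, q_value = qval,
    constant = constant
  ) |>
    dplyr::arrange(dplyr::desc(.data$f_value)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  significant = !is.na(.data$q_value) & .data$q_value <= alpha,
                  .after = "q_value")
  class(out) <- c("univariate_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n") <- n
  out
}

feature_matrix_any <- function(features) {
  if (is.data.frame(features)) {
    if (all(c("subject_id") %in% names(features))) {
      feature_matrix(features)
    } else {
      as.matrix(features)
    }
  } else {
    as.matrix(features)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone by construction) with the rejection
#' set at `q <= alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`, optionally named.
#' @param alpha FDR level.
#' @return Tibble `test`, `p_value`, `q_value`, `rejected` in input order.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.",
          class = "boldband_error_pvalue")
  }
  q <- p.adjust(p, method = "BH")
  tibble(
    test = names(p_values) %||% sprintf("test_%d", seq_along(p)),
    p_value = p, q_value = q, rejected = q <= alpha
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) group comparison
#'
#' Two-sided rank-based comparison of two independent groups with midrank
#' tie handling. P-values come from exact enumeration when the combined
#' sample size is at most 12 and there are no ties, and from the normal
#' approximation with tie correction otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return Tibble with the Mann-Whitney `statistic_u` (for `group_a`), the
#'   classical rank-sum `statistic_w` (sum of `group_a` midranks),
#'   `p_value`, group sizes, and the method used.
#' @export
rank_sum_test <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) {
    abort("Both groups must be nonempty.", class = "boldband_error_dimension")
  }
  n_total <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- n_total <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact)
  )
  ranks <- rank(c(a, b))
  tibble(
    statistic_u = unname(wt$statistic),
    statistic_w = sum(ranks[seq_along(a)]),
    p_value = wt$p.value,
    n_a = length(a), n_b = length(b),
    method = if (exact) "exact" else "normal_approx"
  )
}
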