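# ggplot2 displays for the main result types.

#' @export
autoplot.univariate_result <- function(object, top = 20, ...) {
  d <- utils::head(object, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$f_value, y = .data$feature,
                                  colour = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "F value", y = NULL, colour = "FDR significant",
                  title = "Univariate association with the outcome") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cv_result <- function(object, min_folds = 1, ...) {
  keep <- rowSums(object$inclusion) >= min_folds
  d <- as.data.frame.table(object$inclusion[keep, , drop = FALSE],
                           responseName = "selected")
  names(d)[1:2] <- c("feature", "subject")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subject, y = .data$feature,
                                  fill = .data$selected)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c("FALSE" = "white",
                                          "TRUE" = "grey20")) +
    ggplot2::labs(x = "Held-out subject", y = NULL, fill = "In fold model",
                  title = sprintf("Fold-model feature inclusion (Q2 = %.3f)",
                                  object$q2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.permutation_null <- function(object, ...) {
  ggplot2::ggplot(tibble(null_r2 = object$null_r2),
                  ggplot2::aes(x = .data$null_r2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_r2,
                        colour = "firebrick") +
    ggplot2::labs(x = expression(Null ~ R^2),
                  title = sprintf("Permutation null (mean %.3f, %s)",
                                  object$null_mean,
                                  if (object$is_overfit) "overfit"
                                  else "not overfit")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.moderation_result <- function(object, ...) {
  ss <- object$simple_slopes
  xr <- range(object$fit$model$.x)
  d <- purrr::pmap_dfr(ss, function(moderator_value, label, slope, ...) {
    tibble(x = xr, y = slope * xr, label = label)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$roles[["x"]],
                  y = sprintf("%s (centered partial effect)",
                              object$roles[["y"]]),
                  colour = object$roles[["w"]],
                  title = "Simple slopes at moderator mean ± SD") +
    ggplot2::theme_minimal()
}

#' Eigenvalue spectrum of a connectome basis
#'
#' @param basis A `spectral_basis`.
#' @param K Band size to shade (low and high bands).
#' @return A ggplot.
#' @export
plot_spectrum <- function(basis, K = 10) {
  n <- length(basis$eigenvalues)
  d <- tibble(
    index = seq_len(n) - 1L,
    eigenvalue = basis$eigenvalues,
    band = dplyr::case_when(
      seq_len(n) <= K ~ "high graph frequency",
      seq_len(n) > n - K ~ "low graph frequency",
      TRUE ~ "mid"
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$eigenvalue,
                                  colour = .data$band)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Sorted eigenmode index", y = "Adjacency eigenvalue",
                  title = "Connectome spectrum and band membership") +
    ggplot2::theme_minimal()
}
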