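#' Validate a structural connectome matrix
#'
#' Checks a raw streamline-count matrix against the structural-connectome
#' contract: square, finite, nonnegative, symmetric (within a relative
#' tolerance), with one region label per row. Tiny numerical asymmetry is
#' repaired by averaging `(A + t(A))/2`; the diagonal is zeroed.
#'
#' @param raw_matrix Square numeric matrix of nonnegative edge weights
#'   (streamline counts between cortical parcels).
#' @param labels Character vector of region names, one per row/column.
#' @param subject_id Identifier carried through the pipeline.
#' @param tol Relative tolerance for symmetry, on the scale of the largest
#'   absolute weight.
#'
#' @return A `connectome` object: list with `weights` (symmetric, zero
#'   diagonal), `region_labels`, and `subject_id`.
#' @export
#' @examples
#' a <- matrix(c(0, 3, 1, 3, 0, 2, 1, 2, 0), 3, 3)
#' validate_connectome(a, c("a", "b", "c"))
validate_connectome <- function(raw_matrix, labels, subject_id = "subject",
                                tol = 1e-8) {
  if (!is.matrix(raw_matrix) || !is.numeric(raw_matrix)) {
    abort("`raw_matrix` must be a numeric matrix.",
          class = "boldband_error_dimension")
  }
  n <- nrow(raw_matrix)
  if (ncol(raw_matrix) != n) {
    abort(sprintf("Connectome matrix must be square, got %d x %d.",
                  n, ncol(raw_matrix)),
          class = "boldband_error_dimension")
  }
  if (length(labels) != n) {
    abort(sprintf("%d region labels supplied for a %d x %d matrix.",
                  length(labels), n, n),
          class = "boldband_error_dimension")
  }
  if (!all(is.finite(raw_matrix))) {
    abort("Connectome contains non-finite entries.",
          class = "boldband_error_nonfinite")
  }
  if (any(raw_matrix < 0)) {
    abort("Connectome contains negative weights.",
          class = "boldband_error_negative")
  }
  scale <- max(abs(raw_matrix), 1e-300)
  asym <- max(abs(raw_matrix - t(raw_matrix))) / scale
  if (asym > tol) {
    abort(sprintf("Connectome asymmetry %.3g exceeds tolerance %.3g.",
                  asym, tol),
          class = "boldband_error_asymmetry")
  }
  w <- (raw_matrix + t(raw_matrix)) / 2
  diag(w) <- 0
  dimnames(w) <- list(labels, labels)
  structure(
    list(weights = w, region_labels = as.character(labels),
         subject_id = subject_id),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s: %d regions, total weight %.4g\n",
              x$subject_id, length(x$region_labels), sum(x$weights) / 2))
  invisible(x)
}

#' Eigendecompose a connectome into its spectral basis
#'
#' Computes the eigenmodes of the (symmetric) adjacency matrix `A = V L V'`.
#' Eigenvalues are sorted ascending; this ordering defines the graph
#' frequencies: the largest adjacency eigenvalues belong to the smoothest
#' (low graph frequency) modes, the smallest to the most spatially variable
#' (high graph frequency) modes. A deterministic sign convention is applied:
#' each eigenvector's entry of largest magnitude is made positive (ties
#' broken by lowest index), so serialized bases are reproducible. Band
#' energies downstream are invariant to sign and to ordering within a
#' degenerate eigenvalue block.
#'
#' @param connectome A `connectome` from [validate_connectome()].
#' @return A `spectral_basis`: list with ascending `eigenvalues`, orthonormal
#'   `eigenvectors` (columns paired with eigenvalues), `region_labels`, and
#'   `subject_id`.
#' @export
eigendecompose <- function(connectome) {
  stopifnot(inherits(connectome, "connectome"))
  e <- eigen(connectome$weights, symmetric = TRUE)
  # eigen() returns descending order for symmetric input; flip to ascending
  ord <- rev(seq_along(e$values))
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  if (!all(is.finite(values)) || !all(is.finite(vectors))) {
    abort("Eigendecomposition produced non-finite results.",
          class = "boldband_error_numeric")
  }
  for (k in seq_along(values)) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  rownames(vectors) <- connectome$region_labels
  structure(
    list(eigenvalues = values, eigenvectors = vectors,
         region_labels = connectome$region_labels,
         subject_id = connectome$subject_id),
    class = "spectral_basis"
  )
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> subject %s: %d modes, lambda in [%.4g, %.4g]\n",
              x$subject_id, length(x$eigenvalues),
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Graph Fourier transform
#'
#' Projects a node signal (or a region x time matrix, columnwise per
#' timepoint) onto the eigenvectors of the connectome adjacency matrix:
#' forward is `t(V) %*% x`, inverse is `V %*% xhat`. Because `V` is
#' orthonormal the transform is an isometry (Parseval) and
#' `gft(gft(x, b), b, "inverse")` recovers `x`.
#'
#' @param x Numeric vector of length n, or n x T matrix.
#' @param basis A `spectral_basis`.
#' @param direction `"forward"` (signal to spectrum) or `"inverse"`.
#' @return Vector or matrix of the same shape as `x`.
#' @export
gft <- function(x, basis, direction = c("forward", "inverse")) {
  stopifnot(inherits(basis, "spectral_basis"))
  direction <- match.arg(direction)
  v <- basis$eigenvectors
  was_vector <- is.null(dim(x))
  xm <- if (was_vector) matrix(x, ncol = 1) else x
  if (nrow(xm) != nrow(v)) {
    abort(sprintf("Signal has %d rows but basis has %d modes.",
                  nrow(xm), nrow(v)),
          class = "boldband_error_dimension")
  }
  out <- if (direction == "forward") crossprod(v, xm) else v %*% xm
  if (was_vector) drop(out) else out
}
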