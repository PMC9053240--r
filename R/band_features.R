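#' Build a binary graph-frequency band filter
#'
#' Selects K eigenmodes by sorted position in the ascending eigenvalue
#' ordering. For the adjacency-based transform, large eigenvalues carry the
#' smoothest signal patterns, so the LOW graph-frequency band is the K
#' largest eigenvalues (sorted indices n-K+1..n) and the HIGH band is the K
#' smallest (indices 1..K). Membership is by sorted index, not eigenvalue:
#' if the eigenvalue at a band boundary is degenerate the passed subspace
#' depends on solver ordering, and a warning is raised.
#'
#' @param basis A `spectral_basis`.
#' @param band `"low"` or `"high"` graph frequency, or `"custom"` with an
#'   explicit `modes` index set (e.g. the mid-band complement).
#' @param K Band size; the protocol default is 10 modes. Ignored for
#'   `"custom"`.
#' @param modes Sorted-position indices passed by a `"custom"` filter.
#' @return A `graph_filter`: binary `response` over modes, `band`, `K`, and
#'   the index set passed.
#' @export
make_band_filter <- function(basis, band = c("low", "high", "custom"),
                             K = 10, modes = NULL) {
  stopifnot(inherits(basis, "spectral_basis"))
  band <- match.arg(band)
  n <- length(basis$eigenvalues)
  if (band == "custom") {
    if (is.null(modes) || !all(modes %in% seq_len(n))) {
      abort("A custom filter needs valid `modes` indices.",
            class = "boldband_error_K")
    }
    response <- numeric(n)
    response[modes] <- 1
    return(structure(
      list(response = response, band = "custom", K = length(modes),
           mode_index = sort(unique(modes)), subject_id = basis$subject_id),
      class = "graph_filter"))
  }
  if (K < 1 || K > n) {
    abort(sprintf("K = %d out of range 1..%d.", K, n),
          class = "boldband_error_K")
  }
  idx <- if (band == "high") seq_len(K) else (n - K + 1):n
  if (K < n) {
    lam <- basis$eigenvalues
    boundary_tied <- if (band == "high") {
      isTRUE(all.equal(lam[K], lam[K + 1]))
    } else {
      isTRUE(all.equal(lam[n - K], lam[n - K + 1]))
    }
    if (boundary_tied) {
      warn(paste0("Degenerate eigenvalue at the ", band,
                  "-band boundary: the passed subspace depends on solver ",
                  "ordering."),
           class = "boldband_warning_degenerate")
    }
  }
  response <- numeric(n)
  response[idx] <- 1
  structure(
    list(response = response, band = band, K = K, mode_index = idx,
         subject_id = basis$subject_id),
    class = "graph_filter"
  )
}

#' Apply a graph filter to a BOLD series
#'
#' Projects every timepoint column onto the filter's eigenmode subspace:
#' `y = V F t(V) x`. The input must be analysis-ready (stage `"zscored"`);
#' synthetic series planted directly in spectral space carry that tag.
#'
#' @param s A `bold_series` at stage `"zscored"`.
#' @param basis The subject's `spectral_basis`.
#' @param filter A `graph_filter` from [make_band_filter()].
#' @return A `filtered_series`: the n x T filtered matrix plus band tag.
#' @export
apply_filter <- function(s, basis, filter) {
  stopifnot(inherits(s, "bold_series"), inherits(basis, "spectral_basis"),
            inherits(filter, "graph_filter"))
  .check_stage(s, "apply_filter", "zscored")
  v <- basis$eigenvectors
  if (nrow(s$values) != nrow(v)) {
    abort("Series and basis dimensions differ.",
          class = "boldband_error_dimension")
  }
  if (!identical(s$region_labels, basis$region_labels)) {
    abort("Series and basis region labels differ.",
          class = "boldband_error_labels")
  }
  keep <- filter$response > 0
  vb <- v[, keep, drop = FALSE]
  vals <- vb %*% crossprod(vb, s$values)
  structure(
    list(values = vals, band = filter$band, K = filter$K,
         region_labels = s$region_labels, subject_id = s$subject_id,
         tr = s$tr),
    class = "filtered_series"
  )
}

#' Per-region band energy
#'
#' The l2 norm over time of each region's filtered component,
#' `E_i = sqrt(sum_t y_i(t)^2)`. With `squared = TRUE` the summed squares
#' are returned instead (downstream linear models are not invariant to this
#' monotone transform, so the choice is explicit).
#'
#' @param fs A `filtered_series`.
#' @param squared Return squared energies instead of l2 norms.
#' @return Tibble with `region`, `band`, `energy`.
#' @export
band_energy <- function(fs, squared = FALSE) {
  stopifnot(inherits(fs, "filtered_series"))
  e2 <- unname(rowSums(fs$values^2))
  tibble(
    region = fs$region_labels,
    band = fs$band,
    energy = if (squared) e2 else sqrt(e2)
  )
}

#' Build the subject x region x band energy table
#'
#' For each subject: eigendecompose the structural connectome, apply the
#' subject-specific low and high band filters to the (preprocessed) BOLD
#' series, and record per-region band energies. At n regions this yields
#' `2 n` features per subject (132 at the atlas's 66 cortical regions).
#'
#' @param subjects List of per-subject lists with elements `connectome`
#'   (a `connectome`), `bold` (a `bold_series`), and optional `covariates`
#'   (named list or one-row data frame; a `cohort` entry is carried into
#'   the table).
#' @param K Band size (modes per band).
#' @param squared Report squared energies.
#' @param preprocess Run [preprocess_bold()] on series still at stage
#'   `"raw"`; series already `"zscored"` are used as-is.
#' @return A tidy tibble `subject_id, cohort, region, band, energy`, ordered
#'   by subject, then region (connectome order), then band (low before
#'   high). See [widen_features()] for the subject x feature matrix form.
#' @export
build_feature_table <- function(subjects, K = 10, squared = FALSE,
                                preprocess = TRUE) {
  rows <- purrr::map(subjects, function(sub) {
    con <- sub$connectome
    s <- sub$bold
    stopifnot(inherits(con, "connectome"), inherits(s, "bold_series"))
    if (!identical(con$region_labels, s$region_labels)) {
      abort(sprintf(
        "Subject %s: connectome and BOLD region labels differ.",
        con$subject_id),
        class = "boldband_error_labels")
    }
    if (s$stage == "raw" && preprocess) s <- preprocess_bold(s)
    basis <- eigendecompose(con)
    cohort <- sub$covariates$cohort %||% NA_character_
    purrr::map_dfr(c("low", "high"), function(b) {
      fs <- apply_filter(s, basis, make_band_filter(basis, b, K))
      band_energy(fs, squared = squared) |>
        dplyr::mutate(subject_id = con$subject_id, cohort = cohort,
                      .before = 1)
    })
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      band = factor(.data$band, levels = c("low", "high")),
      region = factor(.data$region, levels = unique(.data$region))
    ) |>
    dplyr::arrange(.data$subject_id, .data$region, .data$band) |>
    dplyr::mutate(band = as.character(.data$band),
                  region = as.character(.data$region))
}

#' Pivot a tidy band-energy table to the wide feature matrix
#'
#' Produces one row per subject and one `band__region` column per feature
#' (e.g. `low__rh_isthmuscingulate`), the input form expected by the
#' univariate-selection and PLS stages.
#'
#' @param energy_table Tidy tibble from [build_feature_table()].
#' @return Wide tibble: `subject_id`, `cohort`, then feature columns.
#' @export
widen_features <- function(energy_table) {
  energy_table |>
    dplyr::mutate(feature = paste(.data$band, .data$region, sep = "__")) |>
    dplyr::select("subject_id", "cohort", "feature", "energy") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "energy")
}

#' Feature-matrix helper
#'
#' Extracts the numeric feature matrix (rownames = subject ids) from a wide
#' feature tibble.
#' @param wide Wide tibble from [widen_features()].
#' @return Numeric matrix, subjects x features.
#' @export
feature_matrix <- function(wide) {
  cols <- setdiff(names(wide), c("subject_id", "cohort"))
  m <- as.matrix(wide[cols])
  rownames(m) <- wide$subject_id
  m
}
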