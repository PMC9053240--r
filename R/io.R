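# Delimited-text readers/writers and the end-to-end pipeline runner.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.read_labelled_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "boldband_error_io")
  }
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad)) {
      abort(sprintf("Non-numeric cell at row %d ('%s'), column %d ('%s') of %s.",
                    bad[1] + 1L, rownames(df)[bad[1]], j + 1L,
                    colnames(df)[j], path),
            class = "boldband_error_parse")
    }
    m[, j] <- v
  }
  m
}

.write_labelled_matrix <- function(m, path, sep = ",") {
  utils::write.table(cbind(region = rownames(m), as.data.frame(m)),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a structural connectome from delimited text
#'
#' Expects a labelled square matrix (first row and first column are region
#' names; comma- or tab-delimited, auto-detected) and routes it through
#' [validate_connectome()].
#'
#' @param path File path.
#' @param subject_id Identifier (defaults to the file stem).
#' @return A `connectome`.
#' @export
read_connectome <- function(path, subject_id = NULL) {
  m <- .read_labelled_matrix(path)
  validate_connectome(
    unname(m), rownames(m),
    subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a connectome as labelled CSV
#' @param connectome A `connectome`.
#' @param path File path.
#' @export
write_connectome <- function(connectome, path) {
  .write_labelled_matrix(connectome$weights, path)
  invisible(path)
}

#' Read a BOLD series from delimited text
#'
#' Rows are labelled regions, columns timepoints. The repetition time and
#' stage tag come from a `<path>.json` sidecar when present, else from the
#' arguments.
#'
#' @param path File path.
#' @param tr Repetition time in seconds (used when no sidecar exists).
#' @param stage Stage tag (used when no sidecar exists).
#' @param subject_id Identifier.
#' @return A `bold_series`.
#' @export
read_bold <- function(path, tr = 2, stage = "raw", subject_id = NULL) {
  m <- .read_labelled_matrix(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tr <- meta$tr %||% tr
    stage <- meta$stage %||% stage
    subject_id <- subject_id %||% meta$subject_id
  }
  bold_series(m, tr = tr, region_labels = rownames(m),
              subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
              stage = stage)
}

#' Write a BOLD series as labelled CSV plus a JSON sidecar
#' @param s A `bold_series`.
#' @param path File path; the sidecar goes to `<path>.json`.
#' @export
write_bold <- function(s, path) {
  m <- s$values
  colnames(m) <- sprintf("t%03d", seq_len(ncol(m)))
  .write_labelled_matrix(m, path)
  jsonlite::write_json(
    list(tr = s$tr, stage = s$stage, subject_id = s$subject_id),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a spectral basis (JSON eigenvalues + CSV eigenvectors)
#' @param basis A `spectral_basis`.
#' @param stem Output path stem; writes `<stem>_eigenvalues.json` and
#'   `<stem>_eigenvectors.csv`.
#' @export
write_spectral_basis <- function(basis, stem) {
  jsonlite::write_json(
    list(subject_id = basis$subject_id, eigenvalues = basis$eigenvalues),
    paste0(stem, "_eigenvalues.json"), auto_unbox = TRUE, digits = NA)
  v <- basis$eigenvectors
  colnames(v) <- sprintf("mode_%02d", seq_len(ncol(v)) - 1L)
  .write_labelled_matrix(v, paste0(stem, "_eigenvectors.csv"))
  invisible(stem)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the protocol end to end: band-energy extraction, univariate
#' F-selection with FDR, the full-feature permutation overfit gate, and
#' VIP-gated leave-one-out cross-validation, returning all results plus a
#' run manifest (seeds, parameters, package version, timestamp) for
#' provenance.
#'
#' @param cohort A cohort list as returned by [gen_cohort()] (or the same
#'   shape built from files: `subjects` + `records`).
#' @param outcome Column of `cohort$records` to model (default serum NfL).
#' @param k Band size.
#' @param seed Integer seed for all stochastic stages (required).
#' @param thresholds VIP threshold grid.
#' @param gate_n_perm Permutations per nested gate.
#' @param full_gate_n_perm Permutations for the full-feature-model gate.
#' @param rule Fold-model selection rule (see [loocv_q2()]).
#' @return List: `features_wide`, `univariate`, `full_gate`, `cv`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, outcome = "serum_nfl", k = 10, seed,
                         thresholds = seq(0.8, 2.0, by = 0.1),
                         gate_n_perm = 200, full_gate_n_perm = 1000,
                         rule = "test_error") {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  if (!outcome %in% names(cohort$records)) {
    abort(sprintf("Outcome column '%s' missing from the records.", outcome),
          class = "boldband_error_missing")
  }
  wide <- cohort$features_wide %||%
    widen_features(build_feature_table(cohort$subjects, K = k))
  stopifnot(identical(wide$subject_id, cohort$records$subject_id))
  x <- feature_matrix(wide)
  y <- cohort$records[[outcome]]
  univariate <- f_select(x, y)
  full_gate <- permutation_gate(x, y, n_components = 1,
                                n_perm = full_gate_n_perm, seed = seed)
  cv <- loocv_q2(x, y, thresholds = thresholds, seed = seed,
                 gate_n_perm = gate_n_perm, rule = rule)
  manifest <- list(
    command = "run_pipeline", outcome = outcome, k = k, seed = seed,
    thresholds = thresholds, gate_n_perm = gate_n_perm,
    full_gate_n_perm = full_gate_n_perm, rule = rule,
    n_subjects = nrow(wide), n_features = ncol(x),
    package_version = as.character(packageVersion("boldband")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  list(features_wide = wide, univariate = univariate,
       full_gate = full_gate, cv = cv, manifest = manifest)
}

#' Write a run manifest as JSON
#' @param manifest Manifest list from [run_pipeline()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
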