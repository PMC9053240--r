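zscored <- function(values, basis) {
  bold_series(values, tr = 2, region_labels = basis$region_labels,
              subject_id = basis$subject_id, stage = "zscored")
}

test_that("band filters select sorted-index mode sets", {
  con <- random_connectome(66, seed = 2)
  b <- eigendecompose(con)
  hi <- make_band_filter(b, "high", 10)
  expect_identical(hi$mode_index, 1:10)  # ten smallest eigenvalues
  lo <- make_band_filter(b, "low", 10)
  expect_identical(lo$mode_index, 57:66) # ten largest
  expect_equal(sum(hi$response), 10)
  expect_true(all(hi$response %in% c(0, 1)))
  all_pass <- make_band_filter(b, "low", 66)
  expect_equal(sum(all_pass$response), 66)
  expect_error(make_band_filter(b, "low", 0), class = "boldband_error_K")
  expect_error(make_band_filter(b, "low", 67), class = "boldband_error_K")

  # P3: the low band at K = 1 passes only the lambda = sqrt(2) mode
  b3 <- eigendecompose(path3_connectome())
  lo3 <- make_band_filter(b3, "low", 1)
  expect_identical(lo3$mode_index, 3L)
  expect_equal(b3$eigenvalues[lo3$mode_index], sqrt(2), tolerance = 1e-12)
})

test_that("a degenerate eigenvalue at a band boundary raises a warning", {
  e <- eigendecompose(validate_connectome(matrix(0, 5, 5), letters[1:5]))
  expect_warning(make_band_filter(e, "low", 2),
                 class = "boldband_warning_degenerate")
})

test_that("filtering is a projection and the bands partition the signal", {
  con <- random_connectome(12, seed = 3)
  b <- eigendecompose(con)
  s <- random_zscored_series(b, 30, seed = 4)
  ident <- make_band_filter(b, "low", 12)
  expect_equal(apply_filter(s, b, ident)$values, s$values, tolerance = 1e-10)

  lo <- apply_filter(s, b, make_band_filter(b, "low", 3))
  hi <- apply_filter(s, b, make_band_filter(b, "high", 3))
  mid <- apply_filter(s, b, make_band_filter(b, "custom", modes = 4:9))
  expect_equal(lo$values + hi$values + mid$values, s$values,
               tolerance = 1e-10)

  # idempotence: filtering a filtered signal changes nothing
  lo_s <- zscored(lo$values, b)
  expect_equal(apply_filter(lo_s, b, make_band_filter(b, "low", 3))$values,
               lo$values, tolerance = 1e-10)

  # P3 check: x = (1, 0, -1) is orthogonal to the lambda = sqrt(2) mode
  b3 <- eigendecompose(path3_connectome())
  s3 <- zscored(matrix(c(1, 0, -1), 3, 5), b3)
  out <- apply_filter(s3, b3, make_band_filter(b3, "low", 1))
  expect_lt(max(abs(out$values)), 1e-10)

  # stage and dimension guards
  raw <- bold_series(s$values, tr = 2, region_labels = b$region_labels,
                     stage = "raw")
  expect_error(apply_filter(raw, b, ident), class = "boldband_error_stage")
})

test_that("band energy is the l2 norm over time", {
  con <- random_connectome(4, seed = 5)
  b <- eigendecompose(con)
  fs <- structure(list(values = matrix(0, 4, 6), band = "low", K = 2,
                       region_labels = b$region_labels, subject_id = "t",
                       tr = 2),
                  class = "filtered_series")
  expect_equal(band_energy(fs)$energy, rep(0, 4))
  fs$values[2, 1:2] <- c(3, 4)
  expect_equal(band_energy(fs)$energy[2], 5)  # 3-4-5 triangle
  expect_equal(band_energy(fs, squared = TRUE)$energy[2], 25)
})

test_that("energies are invariant to eigenvector sign flips", {
  con <- random_connectome(10, seed = 6)
  b <- eigendecompose(con)
  s <- random_zscored_series(b, 25, seed = 7)
  e0 <- band_energy(apply_filter(s, b, make_band_filter(b, "low", 3)))$energy
  for (seed in 1:5) {
    b2 <- b
    flips <- withr::with_seed(seed, sample(c(-1, 1), 10, replace = TRUE))
    b2$eigenvectors <- sweep(b$eigenvectors, 2, flips, "*")
    e1 <- band_energy(apply_filter(s, b2, make_band_filter(b2, "low", 3)))$energy
    expect_equal(e1, e0, tolerance = 1e-10)
  }
})

test_that("the feature table has one row per subject, region and band", {
  labs <- desikan_killiany_labels()
  subjects <- lapply(1:2, function(i) {
    con <- random_connectome(66, seed = 10 + i, labels = labs)
    b <- eigendecompose(con)
    list(connectome = con, bold = random_zscored_series(b, 40, seed = 20 + i),
         covariates = list(cohort = "HC"))
  })
  tab <- build_feature_table(subjects, K = 10)
  expect_equal(nrow(tab), 264)  # 2 subjects x 66 regions x 2 bands
  expect_equal(sum(tab$subject_id == subjects[[1]]$connectome$subject_id), 132)
  expect_true(all(tab$energy >= 0))
  # deterministic order: subject, region (connectome order), band low/high
  expect_identical(tab$region[1:2], rep(labs[1], 2))
  expect_identical(tab$band[1:2], c("low", "high"))

  wide <- widen_features(tab)
  expect_equal(dim(feature_matrix(wide)), c(2L, 132L))
  expect_true("low__rh_isthmuscingulate" %in% names(wide))

  # permuted BOLD rows vs connectome labels is an error
  bad <- subjects[[1]]
  bad$bold$region_labels <- rev(bad$bold$region_labels)
  expect_error(build_feature_table(list(bad)), class = "boldband_error_labels")
})

test_that("global Parseval: band energies partition total signal energy", {
  for (seed in 1:3) {
    con <- random_connectome(20, seed = 30 + seed)
    b <- eigendecompose(con)
    s <- random_zscored_series(b, 50, seed = 40 + seed)
    tot <- sum(s$values^2)
    parts <- vapply(
      list(make_band_filter(b, "low", 5), make_band_filter(b, "high", 5),
           make_band_filter(b, "custom", modes = 6:15)),
      function(f) sum(band_energy(apply_filter(s, b, f))$energy^2),
      numeric(1))
    expect_equal(sum(parts), tot, tolerance = 1e-8)
  }
})
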