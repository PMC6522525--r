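test_that("DCT truncation is exact at full order and for basis functions", {
  fit <- dct_config()$fit_grid
  n <- length(fit)
  expect_equal(n, 294)
  set.seed(4)
  x <- rnorm(n)
  expect_equal(dct_smooth(x, n), x, tolerance = 1e-9)
  expect_equal(dct_smooth(rep(7, n), 1), rep(7, n), tolerance = 1e-12)
  # pure cosine of basis index 5: kept with 6 coefficients, zeroed with 5
  j <- seq_len(n) - 1
  c5 <- cos(pi * 5 * (j + 0.5) / n)
  expect_equal(dct_smooth(c5, 6), c5, tolerance = 1e-9)
  expect_lt(max(abs(dct_smooth(c5, 5))), 1e-9)
  expect_error(dct_smooth(x, 0), "n_coef")
  expect_error(dct_smooth(x, n + 1), "n_coef")
})

test_that("DCT error distribution matches an independent per-spectrum loop", {
  dirs <- direction_grid(lateral_angles = c(-30, 30),
                         polar_angles = c(0, 90, 180))
  wide <- frequency_grid(350, 50, 15000)
  set <- to_dtf(generate_synthetic_hrtf_set(
    planted_basis(noise_sd = 0.3, n_persons = 2, seed = 13), dirs, wide))
  cfg <- dct_config()
  got <- dct_error_distribution(set, c(4, 16, 294))
  # full order: zero error
  expect_lt(got$q3[got$k == 294], 1e-9)
  expect_true(all(diff(got$median) <= 1e-12))
  # brute-force loop oracle at n_coef = 16
  errs <- numeric(ncol(set$mag_db))
  for (j in seq_len(ncol(set$mag_db))) {
    sp <- stats::spline(set$freq, set$mag_db[, j], xout = cfg$fit_grid,
                        method = "natural")$y
    sm <- dct_smooth(sp, 16)
    rec <- stats::spline(cfg$fit_grid, sm, xout = cfg$eval_grid,
                         method = "natural")$y
    ref <- stats::spline(set$freq, set$mag_db[, j], xout = cfg$eval_grid,
                         method = "natural")$y
    errs[j] <- sqrt(mean((ref - rec)^2))
  }
  q <- stats::quantile(errs, c(0.25, 0.5, 0.75), names = FALSE)
  row <- got[got$k == 16, ]
  expect_equal(c(row$q1, row$median, row$q3), q, tolerance = 1e-9)
})

test_that("correspondence matching picks closest summaries with small-k ties", {
  pca <- tibble::tibble(k = 1:10, q1 = 10 - (1:10) * 0.9,
                        median = 11 - (1:10) * 0.9,
                        q3 = 12 - (1:10) * 0.9, n = 100)
  # an exact copy of one PCA row must be matched at distance 0
  dct <- pca[c(3, 7), ]
  m <- match_correspondence(dct, pca)
  expect_equal(m$k_pca, c(3, 7))
  expect_equal(m$distance, c(0, 0))
  # ties break toward the smaller k
  flat <- tibble::tibble(k = c(2, 5), q1 = 1, median = 1, q3 = 1, n = 10)
  const <- tibble::tibble(k = 1:4, q1 = 1, median = 1, q3 = 1, n = 10)
  expect_equal(match_correspondence(flat, const)$k_pca, c(1, 1))
  # monotone inputs give non-decreasing matched k (exhaustive check)
  set.seed(5)
  dct2 <- tibble::tibble(k = c(4, 8, 16), q1 = c(3, 2, 1),
                         median = c(3.5, 2.5, 1.5), q3 = c(4, 3, 2),
                         n = 10)
  m2 <- match_correspondence(dct2, pca)
  expect_true(all(diff(m2$k_pca) >= 0))
})

test_that("PCA beats DCT at matched counts and the gap narrows", {
  dtf <- fx_planted_dtf()
  basis <- fx_planted_basis()
  counts <- c(2, 4, 8, 16)
  pe <- error_distribution(dtf, basis, counts)
  # DCT computed on the same per-pinna-mean-removed spectra; the set lives
  # on the analysis grid, so fit the DCT there too for commensurable errors
  de <- dct_error_distribution(
    dtf, counts, dct_config(fit_start = 500, fit_stop = 14000))
  expect_true(all(pe$median <= de$median + 1e-12))
  gap <- de$median - pe$median
  expect_lt(gap[length(gap)], gap[1])
  # full-pipeline correspondence: matched k non-decreasing in n_dct
  m <- match_correspondence(de, error_distribution(dtf, basis, 1:30))
  expect_true(all(diff(m$k_pca) >= 0))
})
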