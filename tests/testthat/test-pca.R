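test_that("fit_pca matches a brute-force covariance eigendecomposition", {
  set.seed(1)
  x <- matrix(rnorm(20 * 50), 20, 50)
  basis <- fit_pca(x)
  # independent dense-covariance oracle
  ev <- eigen(stats::cov(t(x)), symmetric = TRUE)
  expect_equal(basis$values, ev$values[seq_along(basis$values)],
               tolerance = 1e-8)
  # orthonormality
  G <- crossprod(basis$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-9)
  # eigenvalues non-increasing, fractions sum to 1
  expect_true(all(diff(basis$values) <= 1e-12))
  expect_equal(sum(basis$var_fractions), 1)
  # sign convention: largest-magnitude element positive
  peaks <- apply(basis$vectors, 2, function(v) v[which.max(abs(v))])
  expect_true(all(peaks > 0))
})

test_that("rank-1 noiseless data yields a single mode", {
  u <- sin(seq_len(40))
  w <- seq(-2, 2, length.out = 30)
  x <- outer(u, w)
  basis <- fit_pca(x)
  expect_equal(basis$var_fractions[1], 1)
  expect_error(fit_pca(matrix(3, 10, 5)), "degenerate")
})

test_that("reconstruction is exact at full rank and obeys Parseval", {
  set.seed(2)
  x <- matrix(rnorm(30 * 80), 30, 80)
  basis <- fit_pca(x)
  W <- project_weights(x, basis)
  expect_lt(max(abs(reconstruct(W, basis, 30) - x)), 1e-9)
  expect_equal(reconstruct(W, basis, 0),
               matrix(basis$grand_mean, 30, 80))
  # per-column squared error at k = unexplained variance, summed
  for (k in c(3, 11)) {
    res <- x - reconstruct(W, basis, k)
    expect_equal(sum(res^2), sum(basis$values[-seq_len(k)]) * (80 - 1),
                 tolerance = 1e-6)
  }
  expect_error(reconstruct(W, basis, 31), "k")
})

test_that("rms_error_db matches a hand-rolled loop and closed forms", {
  set.seed(3)
  f <- frequency_grid()
  a <- matrix(rnorm(271 * 4), 271, 4)
  b <- matrix(rnorm(271 * 4), 271, 4)
  got <- rms_error_db(a, b, f)
  want <- numeric(4)
  for (j in 1:4) {
    s <- 0
    for (i in 1:271) s <- s + (a[i, j] - b[i, j])^2
    want[j] <- sqrt(s / 271)
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(rms_error_db(a, a, f), rep(0, 4))
  expect_equal(rms_error_db(a, a + 2, f), rep(2, 4))
  expect_error(rms_error_db(a, b, f, band = c(20000, 30000)), "empty band")
})

test_that("error distributions behave across k and match a quantile oracle", {
  dtf <- fx_planted_dtf()
  basis <- fx_planted_basis()
  ed <- error_distribution(dtf, basis, k = c(1, 2, 3, 5, 271),
                           method = "reconstruct")
  expect_true(all(ed$q1 <= ed$median & ed$median <= ed$q3))
  expect_true(all(diff(ed$median) <= 1e-12))
  expect_lt(ed$q3[ed$k == 271], 1e-9)   # full rank: exact
  # the Parseval shortcut agrees with explicit reconstruction
  ep <- error_distribution(dtf, basis, k = c(1, 2, 3, 5, 271),
                           method = "parseval")
  expect_equal(ep$median, ed$median, tolerance = 1e-8)
  expect_equal(ep$q3, ed$q3, tolerance = 1e-8)
  # sort-based linear-interpolation quantile oracle at k = 2
  W <- project_weights(dtf, basis)
  err <- rms_error_db(dtf$mag_db, reconstruct(W, basis, 2), dtf$freq)
  s <- unname(sort(err))
  n <- length(s)
  lin_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  row <- ed[ed$k == 2, ]   # reconstruct-path quartiles vs the sort oracle
  expect_equal(c(row$q1, row$median, row$q3),
               c(lin_q(0.25), lin_q(0.5), lin_q(0.75)), tolerance = 1e-12)
})

test_that("leave-one-person-out reduces to the all-inclusive analysis for a duplicated person", {
  dirs <- direction_grid(lateral_angles = c(-45, 0, 45),
                         polar_angles = c(0, 90, 180, 270))
  one <- generate_synthetic_hrtf_set(
    planted_basis(noise_sd = 0.2, n_persons = 1, seed = 8),
    dirs, frequency_grid())
  dup <- to_dtf(duplicate_person_set(one))
  basis <- fit_pca(dup)
  ks <- c(1, 2, 3)
  cv <- loocv(dup, ks)
  all_in <- error_distribution(dup, basis, ks)
  expect_equal(cv$q1, all_in$q1, tolerance = 1e-9)
  expect_equal(cv$median, all_in$median, tolerance = 1e-9)
  expect_equal(cv$q3, all_in$q3, tolerance = 1e-9)
  # pooled error count bookkeeping: persons x 2 pinnae x directions
  expect_equal(unique(cv$n), 2 * 2 * nrow(dirs))
  expect_error(loocv(to_dtf(one), 2), "2 persons")
})

test_that("cross-validation is mild on a homogeneous planted population", {
  dtf <- fx_planted_dtf()
  basis <- fx_planted_basis()
  cv <- loocv(dtf, 3)
  all_in <- error_distribution(dtf, basis, 3)
  expect_lt(abs(cv$median - all_in$median) / all_in$median, 0.10)
})
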