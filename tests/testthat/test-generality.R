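test_that("mode correlations reproduce self, sign, and the textbook formula", {
  basis <- fx_planted_basis()
  ref <- reference_eigenmodes(basis$freq, basis$vectors[, 1:5])
  expect_equal(correlate_modes(basis, ref)$r, rep(1, 5), tolerance = 1e-9)
  neg <- reference_eigenmodes(basis$freq, -basis$vectors[, 1:5])
  expect_equal(correlate_modes(basis, neg)$r, rep(-1, 5), tolerance = 1e-9)
  # textbook covariance-formula oracle on a random 50-point pair
  set.seed(6)
  f <- seq(3000, 14000, by = 50)
  a <- rnorm(length(f))
  b <- rnorm(length(f))
  fake_basis <- structure(list(vectors = cbind(a, a, a, a, a), freq = f,
                               grand_mean = rep(0, length(f))),
                          class = "eigen_basis")
  ref2 <- reference_eigenmodes(f, cbind(b, b, b, b, b))
  r <- correlate_modes(fake_basis, ref2)$r[1]
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, r_hand, tolerance = 1e-12)
  far <- reference_eigenmodes(seq(13000, 20000, 100),
                              matrix(1:71, 71, 5))
  expect_error(correlate_modes(basis, far, band = c(3000, 12000)), "overlap")
})

test_that("optimal scaling recovers identity and planted shifts", {
  basis <- fx_planted_basis()
  ref <- reference_eigenmodes(basis$freq, basis$vectors[, 1:5])
  sc <- optimal_frequency_scaling(basis, ref)
  expect_equal(sc$percent_shift, 0, tolerance = 1e-9)
  expect_equal(sc$mean_r_scaled, 1, tolerance = 1e-9)
  # reference built at frequencies x1.05: recovered shift within 0.2%
  ref5 <- reference_eigenmodes(basis$freq * 1.05, basis$vectors[, 1:5])
  sc5 <- optimal_frequency_scaling(basis, ref5)
  expect_lt(abs(sc5$percent_shift - 5), 0.2)
  # scaling never hurts: s = 1 is in the candidate set
  expect_gte(sc5$mean_r_scaled, sc5$mean_r_unscaled)
})

test_that("coarse search maximum agrees with a 10x-finer search", {
  basis <- fx_planted_basis()
  ref <- reference_eigenmodes(basis$freq * 1.037, basis$vectors[, 1:5])
  coarse <- optimal_frequency_scaling(basis, ref, step = 0.005)
  fine <- optimal_frequency_scaling(basis, ref, step = 0.0005)
  expect_lt(abs(log(coarse$scale_factor / fine$scale_factor)),
            log(1.005) + 1e-9)
})

test_that("Pearson correlations are invariant to affine profile rescaling", {
  basis <- fx_planted_basis()
  ref <- reference_eigenmodes(basis$freq * 1.02,
                              basis$vectors[, 1:5] %*% diag(c(3, -2, 5, 1, 9)) + 4)
  plain <- reference_eigenmodes(basis$freq * 1.02, basis$vectors[, 1:5])
  a <- optimal_frequency_scaling(basis, ref)
  b <- optimal_frequency_scaling(basis, plain)
  expect_equal(a$scale_factor, b$scale_factor)
  expect_equal(abs(a$by_mode$r_scaled), abs(b$by_mode$r_scaled),
               tolerance = 1e-9)
})

test_that("reference CSV reader round-trips the bundled synthetic reference", {
  path <- system.file("extdata", "synthetic_reference_eigenmodes.csv",
                      package = "hrtfeigen")
  ref <- read_reference_eigenmodes(path)
  expect_s3_class(ref, "reference_eigenmodes")
  expect_equal(ncol(ref$profiles), 5)
  basis <- fx_planted_basis()
  r <- correlate_modes(basis, ref)
  expect_true(all(is.finite(r$r)))
})
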