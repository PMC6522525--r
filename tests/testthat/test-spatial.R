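test_that("mirroring right pinnae fixes the median plane and is an involution", {
  dtf <- fx_planted_dtf()
  basis <- fx_planted_basis()
  w <- eigenmode_weights(dtf, basis, n_modes = 3)
  m <- mirror_right_pinnae(w, dtf$directions)
  # median-plane rows unchanged
  w0 <- dplyr::arrange(w[w$lateral == 0, ], person, side, direction, mode)
  m0 <- dplyr::arrange(m[m$lateral == 0, ], person, side, direction, mode)
  expect_equal(m0$weight, w0$weight)
  expect_equal(m0$direction, w0$direction)
  # involution
  mm <- dplyr::arrange(mirror_right_pinnae(m, dtf$directions),
                       person, side, direction, mode)
  ww <- dplyr::arrange(w, person, side, direction, mode)
  expect_equal(mm$weight, ww$weight)
  expect_equal(mm$direction, ww$direction)
  # asymmetric grid: mirrored direction missing
  asym <- direction_grid(lateral_angles = c(-30, 0, 45),
                         polar_angles = c(0, 90))
  wbad <- tibble::tibble(side = "right", lateral = 45, polar = 0,
                         direction = 5, mode = 1, weight = 1,
                         person = 1)
  expect_error(mirror_right_pinnae(wbad, asym), "symmetry")
})

test_that("mean weight maps average across pinnae with sensible SD", {
  dtf <- fx_planted_dtf()
  basis <- fx_planted_basis()
  w <- mirror_right_pinnae(eigenmode_weights(dtf, basis, 3),
                           dtf$directions)
  # single pinna: map equals its weights with zero SD
  w1 <- w[w$person == 1 & w$side == "left", ]
  m1 <- mean_weight_map(w1, 1)
  expect_equal(m1$sd, rep(0, nrow(m1)))
  joined <- dplyr::left_join(m1, w1[w1$mode == 1, ],
                             by = c("direction", "lateral", "polar"))
  expect_equal(joined$mean, joined$weight)
  # two pinnae with opposite weights cancel
  w2 <- dplyr::mutate(w1, weight = -weight, side = "flipped")
  m0 <- mean_weight_map(dplyr::bind_rows(w1, w2), 1)
  expect_lt(max(abs(m0$mean)), 1e-12)
  expect_error(mean_weight_map(w1, 9), "out of range")
  # full map counts every pinna once per direction
  mfull <- mean_weight_map(w, 2)
  expect_equal(unique(mfull$n), 20)
})

test_that("planted weight fields reappear in the spatial maps", {
  set <- fx_planted()
  dtf <- fx_planted_dtf()
  basis <- fx_planted_basis()
  planted <- attr(set, "planted")
  w <- mirror_right_pinnae(eigenmode_weights(dtf, basis, 3),
                           dtf$directions)
  # sign convention of the fitted basis relative to the planted profiles
  sgn <- sign(diag(stats::cor(basis$vectors[, 1:3], planted$profiles)))
  left <- set$index$side == "left"
  for (mode in 1:3) {
    map <- mean_weight_map(w, mode)
    ord <- match(map$direction, set$index$direction[left])
    planted_field <- planted$weights[which(left)[ord], mode]
    expect_gt(stats::cor(sgn[mode] * map$mean, planted_field), 0.99)
  }
  # mode 1: ipsilateral (positive lateral after mirroring) vs contralateral
  m1 <- mean_weight_map(w, 1)
  v1 <- sgn[1] * m1$mean
  expect_gt(mean(v1[m1$lateral > 0]), 0)
  expect_lt(mean(v1[m1$lateral < 0]), 0)
  # mode 2: high vs low elevation
  m2 <- mean_weight_map(w, 2)
  z <- direction_to_cartesian(m2$lateral, m2$polar)[, "z"]
  v2 <- sgn[2] * m2$mean
  expect_gt(mean(v2[z > 0.3]), mean(v2[z < -0.3]))
  # mode 3: upper-front vs lower-back along the tilted axis
  m3 <- mean_weight_map(w, 3)
  u <- direction_to_cartesian(m3$lateral, m3$polar)
  t3 <- u[, "x"] * cos(35 * pi / 180) + u[, "z"] * sin(35 * pi / 180)
  v3 <- sgn[3] * m3$mean
  expect_gt(mean(v3[t3 > 0.3]), mean(v3[t3 < -0.3]))
})

test_that("Hammer projection is centered, symmetric and equal-area", {
  expect_equal(as.numeric(hammer_project(0, 0)[, c("x", "y")]),
               c(0, 0))
  # lon -> -lon mirrors x and keeps y: compare (lat, pol) with lat negated
  a <- hammer_project(30, 40)
  b <- hammer_project(-30, 40)
  expect_equal(a$y, b$y)
  expect_equal(a$x, -b$x)
  # equal-area: |d(x,y)/d(lateral, polar)| / cos(lateral) constant
  set.seed(7)
  lat <- runif(100, -75, 75)
  pol <- runif(100, -40, 220)
  eps <- 1e-5
  jac <- vapply(seq_along(lat), function(i) {
    p0 <- hammer_project(lat[i], pol[i])
    pl <- hammer_project(lat[i] + eps, pol[i])
    pp <- hammer_project(lat[i], pol[i] + eps)
    det(matrix(c(pl$x - p0$x, pl$y - p0$y,
                 pp$x - p0$x, pp$y - p0$y) / eps, 2, 2)) /
      cos(lat[i] * pi / 180)
  }, numeric(1))
  expect_lt(diff(range(abs(jac))) / mean(abs(jac)), 1e-4)
})

test_that("plot builders return ggplot objects", {
  dtf <- fx_planted_dtf()
  basis <- fx_planted_basis()
  w <- mirror_right_pinnae(eigenmode_weights(dtf, basis, 2),
                           dtf$directions)
  expect_s3_class(autoplot(mean_weight_map(w, 1)), "ggplot")
  expect_s3_class(autoplot(error_distribution(dtf, basis, 1:3)), "ggplot")
  expect_s3_class(autoplot(basis), "ggplot")
})
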