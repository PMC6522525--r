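test_that("sphere head voxelization matches the analytic volume", {
  g <- make_sphere_head(60, 4)
  vol <- sum(g$occ) * g$spacing^3
  expect_lt(abs(vol - 4 / 3 * pi * 60^3) / (4 / 3 * pi * 60^3), 0.02)
  # occupancy symmetric under the three axis reflections
  occ <- g$occ
  expect_identical(occ, occ[rev(seq_len(dim(occ)[1])), , ])
  expect_identical(occ, occ[, rev(seq_len(dim(occ)[2])), ])
  expect_identical(occ, occ[, , rev(seq_len(dim(occ)[3]))])
  expect_error(make_sphere_head(2, 4), "degenerate")
})

test_that("voxel volume converges to the analytic volume as spacing shrinks", {
  rel_err <- vapply(c(6, 3), function(h) {
    g <- make_sphere_head(60, h)
    abs(sum(g$occ) * h^3 - 4 / 3 * pi * 60^3) / (4 / 3 * pi * 60^3)
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])
})

test_that("parametric head builds flanges, honors symmetry and angles", {
  g <- make_parametric_head(head_params(), spacing = 4)
  occ <- g$occ
  # mirror symmetry about the median plane for identical pinna settings
  expect_identical(occ, occ[, rev(seq_len(dim(occ)[2])), ])
  # pinna flanges: solid voxels beyond the ellipsoid on both sides
  ax <- voxel_axes(g)
  r <- head_params()$head_radii
  X <- array(ax[[1]], dim(occ))
  Y <- array(rep(ax[[2]], each = dim(occ)[1]), dim(occ))
  Z <- array(rep(ax[[3]], each = prod(dim(occ)[1:2])), dim(occ))
  outside <- (X / r[1])^2 + (Y / r[2])^2 + (Z / r[3])^2 > 1.05
  expect_gt(sum(occ & outside & Y > 0), 20)
  expect_gt(sum(occ & outside & Y < 0), 20)

  # flare = rotation = 0: plate plane normal to the interaural axis,
  # i.e. plate voxels span few distinct y layers
  g0 <- make_parametric_head(head_params(pinna_flare_deg = 0,
                                         pinna_rotation_deg = 0),
                             spacing = 4)
  ax0 <- voxel_axes(g0)
  X0 <- array(ax0[[1]], dim(g0$occ))
  Y0 <- array(rep(ax0[[2]], each = dim(g0$occ)[1]), dim(g0$occ))
  Z0 <- array(rep(ax0[[3]], each = prod(dim(g0$occ)[1:2])), dim(g0$occ))
  out0 <- (X0 / r[1])^2 + (Y0 / r[2])^2 + (Z0 / r[3])^2 > 1.05
  plate_y <- unique(Y0[g0$occ & out0 & Y0 > 0])
  expect_lte(length(plate_y), 3)

  expect_error(make_parametric_head(head_params(), spacing = 4,
                                    extent = c(120, 100, 130)), "clearance")
  expect_error(head_params(pinna_flare_deg = 95), "flare")
})

test_that("voxel grid text serialization round-trips exactly", {
  g <- make_parametric_head(head_params(), spacing = 8)
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  write_voxel_grid(g, tf)
  g2 <- read_voxel_grid(tf)
  expect_identical(g2$occ, g$occ)
  expect_equal(g2$spacing, g$spacing)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$meta$ear_left, g$meta$ear_left)
})
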