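test_that("free-space pulse matches the analytic monopole at a probe", {
  # fine grid and a mid-frequency pulse keep numerical dispersion well
  # below the 1% target over the probe path
  g <- voxel_grid(array(FALSE, c(41, 41, 41)), 1,
                  origin = c(-20, -20, -20))
  cfg <- simulation_config(duration = 6e-4)
  rec <- run_fdtd(g, cfg, source_spec(position = c(0, 0, 0),
                                      center_frequency = 3500),
                  probes = rbind(c(12, 0, 0)))
  cc <- cfg$sound_speed
  r <- 0.012
  tg <- (seq_len(rec$nsteps) - 1) * rec$dt
  sdot <- c(0, diff(rec$source_wave, lag = 2) / (2 * rec$dt), 0)
  pan <- stats::approx(tg + r / cc,
                       rec$h^3 * sdot / (4 * pi * r * cc^2 * rec$dt),
                       xout = tg, rule = 2, yleft = 0)$y
  pn <- rec$probe_p[, 1]
  # L2 over a window covering the wavefront passage
  i1 <- which.max(abs(pan))
  win <- max(1, i1 - 200):min(length(pn), i1 + 400)
  l2 <- sqrt(sum((pn[win] - pan[win])^2) / sum(pan[win]^2))
  expect_lt(l2, 0.01)
})

test_that("zero-amplitude source produces identically zero fields", {
  g <- voxel_grid(array(FALSE, c(21, 21, 21)), 4,
                  origin = c(-40, -40, -40))
  rec <- run_fdtd(g, simulation_config(duration = 3e-4),
                  source_spec(position = c(0, 0, 0), amplitude = 0),
                  probes = rbind(c(20, 0, 0)))
  expect_equal(max(abs(rec$p_surf)), 0)
  expect_equal(max(abs(rec$v_surf)), 0)
  expect_equal(max(abs(rec$probe_p)), 0)
})

test_that("acoustic energy is non-increasing once the source has ended", {
  g <- make_sphere_head(40, 8, clearance = 40)
  cfg <- simulation_config(duration = 2e-3)
  rec <- run_fdtd(g, cfg, source_spec(side = "left"),
                  record_energy = TRUE)
  tg <- (seq_len(rec$nsteps) - 1) * rec$dt
  after <- rec$energy[tg > 6e-4]
  expect_lt(max(diff(after)), 1e-9 * max(rec$energy))
  expect_true(all(is.finite(rec$p_surf)))
})

test_that("PML reflection at the domain center stays below 1e-3", {
  g <- voxel_grid(array(FALSE, c(41, 41, 41)), 4,
                  origin = c(-80, -80, -80))
  cfg <- simulation_config(duration = 2.5e-3)
  rec <- run_fdtd(g, cfg, source_spec(position = c(-40, 0, 0)),
                  probes = rbind(c(0, 0, 0)))
  pp <- rec$probe_p[, 1]
  tg <- (seq_along(pp) - 1) * rec$dt
  incident <- max(abs(pp[tg < 0.8e-3]))
  reflected <- max(abs(pp[tg > 1.3e-3]))
  expect_lt(reflected / incident, 1e-3)
})

test_that("invalid configurations are rejected", {
  g <- make_sphere_head(40, 8, clearance = 40)
  expect_error(run_fdtd(g, simulation_config(dt = 1e-4)), "CFL")
  expect_error(run_fdtd(g, simulation_config(duration = 3e-4),
                        source_spec(position = c(0, 0, 0))),
               "placement")
})

test_that("left and mirrored right HRTFs agree for a symmetric head", {
  g <- make_parametric_head(head_params(), spacing = 8)
  cfg <- simulation_config(duration = 4e-3)
  dirs <- direction_grid(lateral_angles = c(-60, -30, 0, 30, 60),
                         polar_angles = c(0, 90, 180))
  hm <- function(side) {
    rec <- run_fdtd(g, cfg, source_spec(side = side))
    hrtf_db(compute_hrtf(kirchhoff_helmholtz_farfield(rec, dirs),
                         free_field_response(rec, dirs)))
  }
  ml <- hm("left")
  mr <- hm("right")
  mir <- match(paste(-dirs$lateral, dirs$polar),
               paste(dirs$lateral, dirs$polar))
  expect_lt(max(abs(ml - mr[, mir])), 1e-6)
})
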