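# Shared fixtures; heavy simulation results are computed once per run.
.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# mirror-symmetric reduced direction grid (13 x 25 = 325 directions)
small_dirs <- function() {
  direction_grid(
    lateral_angles = c(-80, -65, -55, -45, -30, -15, 0, 15, 30, 45, 55,
                       65, 80),
    polar_angles = seq(-45, 225, by = 11.25))
}

# planted 3-mode population on the analysis grid, 10 persons
fx_planted <- function(noise = 0.1, seed = 42) {
  fx(paste0("planted_", noise, "_", seed), function() {
    generate_synthetic_hrtf_set(
      planted_basis(noise_sd = noise, n_persons = 10, seed = seed),
      small_dirs(), frequency_grid())
  })
}

fx_planted_dtf <- function(noise = 0.1, seed = 42) {
  fx(paste0("dtf_", noise, "_", seed),
     function() to_dtf(fx_planted(noise, seed)))
}

fx_planted_basis <- function(noise = 0.1, seed = 42) {
  fx(paste0("basis_", noise, "_", seed),
     function() fit_pca(fx_planted_dtf(noise, seed)))
}

# FDTD sphere-vs-series comparison at one spacing (mm)
fx_sphere_cmp <- function(spacing) {
  fx(paste0("sphere_", spacing), function() {
    dirs <- direction_grid(lateral_angles = seq(-80, 80, by = 40),
                           polar_angles = c(0, 90, 180))
    g <- make_sphere_head(60, spacing)
    rec <- run_fdtd(g, simulation_config(), source_spec(side = "left"))
    H <- compute_hrtf(kirchhoff_helmholtz_farfield(rec, dirs),
                      free_field_response(rec, dirs))
    b <- sqrt(sum(rec$source_pos_mm^2)) / 1000
    ref <- analytic_sphere_hrtf(0.060, 1.48e6, dirs, H$freq,
                                receiver_radius = b)
    list(freq = H$freq, sim = hrtf_db(H), ref = ref)
  })
}

# empty-domain monopole run at 1 mm spacing (KH oracle geometry)
fx_monopole <- function() {
  fx("monopole", function() {
    g <- voxel_grid(array(FALSE, c(41, 41, 41)), 1,
                    origin = c(-20, -20, -20))
    dirs <- direction_grid(lateral_angles = c(-45, 0, 45),
                           polar_angles = c(0, 120))
    rec <- run_fdtd(g, simulation_config(duration = 1e-3),
                    source_spec(position = c(0, 0, 0)))
    list(grid = g, dirs = dirs, rec = rec,
         kh = kirchhoff_helmholtz_farfield(rec, dirs, radius = 1),
         an = free_field_response(rec, dirs, radius = 1))
  })
}

# duplicate a one-person set into an identical second person
duplicate_person_set <- function(set) {
  idx2 <- dplyr::mutate(set$index, person = 2L,
                        obs = obs + nrow(set$index))
  hrtf_set(cbind(set$mag_db, set$mag_db), set$freq,
           dplyr::bind_rows(set$index, idx2), set$directions,
           pinna_means = if (!is.null(set$pinna_means)) {
             pm <- set$pinna_means
             pm2 <- pm
             colnames(pm2) <- sub("^1:", "2:", colnames(pm))
             cbind(pm, pm2)
           })
}
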