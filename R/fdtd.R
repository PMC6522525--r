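#' FDTD simulation configuration
#'
#' Physical and numerical settings for the acoustic solver. Sound speed
#' and air density are derived from the ambient temperature. The time
#' step defaults to `spacing / (4 c sqrt(3))` — a 4x margin on the CFL
#' stability limit (about 1.3 MHz sampling at 2 mm spacing) — and must
#' always satisfy `dt < spacing / (c sqrt(3))`.
#'
#' @param dt Time step in seconds, or `NULL` for the default above.
#' @param duration Timeline length in seconds (default 5 ms). Internally
#'   the step count is rounded up so the downsample factor divides it.
#' @param temperature Ambient air temperature, degrees Celsius.
#' @param boundary_impedance Frequency-independent normal impedance of
#'   air-solid faces, rayl; default is the air-water interface value
#'   (rho_w c_w, about 1.48e6).
#' @param pml_cells Thickness of the perfectly matched layer, cells.
#' @param pml_order Polynomial grading order of the PML conductivity.
#' @param pml_target_reflection Design normal-incidence reflection used to
#'   set the peak PML conductivity.
#' @param downsample_factor Integer decimation factor applied to farfield
#'   time series (spectral truncation at the new Nyquist).
#' @param surface_offset Gap (cells) between the PML and the recording
#'   surface used for Kirchhoff-Helmholtz integration.
#' @param max_record_rate Surface time series are stored at the largest
#'   stride keeping the record rate at or above this (Hz); the source
#'   pulse carries no energy near such rates, so this is lossless in
#'   practice.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(dt = NULL, duration = 5e-3, temperature = 20,
                              boundary_impedance = 1.48e6,
                              pml_cells = 10, pml_order = 3,
                              pml_target_reflection = 1e-6,
                              downsample_factor = 10,
                              surface_offset = 2,
                              max_record_rate = 1.5e5) {
  stopifnot(is.null(dt) || dt > 0, duration > 0, pml_cells >= 1,
            downsample_factor >= 1, boundary_impedance > 0)
  tk <- temperature + 273.15
  structure(list(dt = dt, duration = duration, temperature = temperature,
                 sound_speed = 331.3 * sqrt(tk / 273.15),
                 air_density = 101325 / (287.058 * tk),
                 boundary_impedance = boundary_impedance,
                 pml_cells = as.integer(pml_cells),
                 pml_order = as.integer(pml_order),
                 pml_target_reflection = pml_target_reflection,
                 downsample_factor = as.integer(downsample_factor),
                 surface_offset = as.integer(surface_offset),
                 max_record_rate = max_record_rate),
            class = "simulation_config")
}

#' Broadband source specification
#'
#' A "soft" (additive) pressure source with a differentiated-Gaussian
#' pulse: zero DC component, spectrum non-vanishing over 0.35-15 kHz.
#'
#' @param position Source position in grid coordinates (mm), or `NULL` to
#'   place the source at the first air voxel directly adjacent to the
#'   blocked ear-canal entrance of `side`.
#' @param side "left" or "right" ear (used when `position` is `NULL`).
#' @param center_frequency Spectral peak of the pulse, Hz.
#' @param amplitude Peak pulse amplitude, Pa.
#' @return A list of class `source_spec`.
#' @export
source_spec <- function(position = NULL, side = c("left", "right"),
                        center_frequency = 7000, amplitude = 1) {
  side <- match.arg(side)
  stopifnot(center_frequency > 0)
  structure(list(position = position, side = side,
                 center_frequency = center_frequency,
                 amplitude = amplitude),
            class = "source_spec")
}

# sampled differentiated-Gaussian pulse
.source_wave <- function(source, dt, nsteps) {
  tau <- 1 / (2 * pi * source$center_frequency)
  t0 <- 6 * tau
  t <- (seq_len(nsteps) - 1) * dt
  -source$amplitude * ((t - t0) / tau) * exp(0.5 - (t - t0)^2 / (2 * tau^2))
}

#' Locate the source cell next to a blocked ear canal
#'
#' Marches outward from the ear-canal entrance along the outward normal
#' and returns the center (mm) of the first air voxel.
#'
#' @param grid A `voxel_grid` with `meta$ear_left` / `meta$ear_right`.
#' @param side "left" or "right".
#' @return Numeric length-3 position in mm.
#' @export
ear_source_cell <- function(grid, side = "left") {
  ear <- grid$meta[[paste0("ear_", side)]]
  if (is.null(ear)) stop("grid has no ear metadata for side ", side)
  u <- ear / sqrt(sum(ear^2))
  ax <- voxel_axes(grid)
  for (step in seq(0, 20)) {
    pt <- ear + u * step * grid$spacing
    ii <- vapply(1:3, function(a) which.min(abs(ax[[a]] - pt[a])), 1L)
    if (!grid$occ[ii[1], ii[2], ii[3]]) {
      return(c(ax[[1]][ii[1]], ax[[2]][ii[2]], ax[[3]][ii[3]]))
    }
  }
  stop("no air voxel found near the ear-canal entrance")
}

#' Run the FDTD simulation
#'
#' Explicit leap-frog integration of linear acoustics on a staggered grid.
#' Pressure and velocity are updated only at air cells; every air-solid
#' face carries the frequency-independent normal-impedance condition; the
#' domain is terminated by a split-field PML. Pressure and outward normal
#' velocity are recorded on a closed rectangular surface between the head
#' and the PML for subsequent farfield integration.
#'
#' @param grid A `voxel_grid` (clearance of about 3 cm assumed; the PML
#'   is added outside the grid).
#' @param config A [simulation_config()].
#' @param source A [source_spec()].
#' @param probes Optional matrix of probe positions (mm, one row per
#'   probe); full-rate pressure series are returned for each.
#' @param record_energy If `TRUE`, the total acoustic energy in the
#'   domain is recorded each step (slow; for validation runs).
#' @return A list of class `surface_record`.
#' @export
run_fdtd <- function(grid, config = simulation_config(),
                     source = source_spec(), probes = NULL,
                     record_energy = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(config, "simulation_config"))
  h <- grid$spacing / 1000
  cc <- config$sound_speed
  dt <- config$dt %||% (h / (4 * cc * sqrt(3)))
  if (dt >= h / (cc * sqrt(3))) {
    stop("stability error: dt violates the CFL condition dt < h/(c*sqrt(3))")
  }
  ds <- config$downsample_factor
  stride <- max(1L, floor(1 / dt / config$max_record_rate))
  blk <- stride * ds
  nsteps <- as.integer(ceiling(config$duration / dt / blk) * blk)

  d <- dim(grid$occ)
  npml <- config$pml_cells
  pd <- d + 2L * npml
  solid <- array(FALSE, pd)
  solid[npml + seq_len(d[1]), npml + seq_len(d[2]), npml + seq_len(d[3])] <-
    grid$occ

  # positions (mm) -> 0-based padded cell indices
  to_cell <- function(pos_mm) {
    ax <- voxel_axes(grid)
    vapply(1:3, function(a) which.min(abs(ax[[a]] - pos_mm[a])) - 1L +
             npml, 1L)
  }
  src_pos <- source$position %||% ear_source_cell(grid, source$side)
  src_cell <- to_cell(src_pos)
  if (solid[src_cell[1] + 1, src_cell[2] + 1, src_cell[3] + 1]) {
    stop("placement error: source position lies inside the solid")
  }

  off <- config$surface_offset
  box <- c(npml + off, pd[1] - 1L - npml - off,
           npml + off, pd[2] - 1L - npml - off,
           npml + off, pd[3] - 1L - npml - off)
  if (any(box[c(2, 4, 6)] <= box[c(1, 3, 5)])) {
    stop("domain too small for the recording surface")
  }
  idxs <- which(solid, arr.ind = TRUE) - 1L
  encl <- rbind(idxs, src_cell)
  if (any(sweep(encl, 2, box[c(1, 3, 5)], `<=`)) ||
      any(sweep(encl, 2, box[c(2, 4, 6)], `>=`))) {
    stop("recording surface does not strictly enclose the solid and source")
  }

  sigma_max <- (config$pml_order + 1) * cc *
    log(1 / config$pml_target_reflection) / (2 * npml * h)
  wave <- .source_wave(source, dt, nsteps)

  probe_cells <- if (is.null(probes)) {
    matrix(0L, 0, 3)
  } else {
    t(apply(probes, 1, to_cell))
  }

  res <- fdtd_run_cpp(as.integer(pd), as.logical(solid), h, dt,
                      nsteps, cc, config$air_density,
                      config$boundary_impedance, npml, sigma_max,
                      config$pml_order, as.integer(src_cell), wave,
                      as.integer(box), as.integer(stride),
                      probe_cells, record_energy)

  orig <- grid$origin / 1000
  pos <- res$pos_idx
  for (a in 1:3) pos[, a] <- orig[a] + (pos[, a] - npml) * h

  structure(list(p_surf = res$p_surf, v_surf = res$v_surf,
                 pos = pos, normal = res$normal,
                 dt = dt, stride = stride, nrec = res$nrec,
                 nsteps = nsteps, h = h,
                 probe_p = res$probe_p, energy = res$energy,
                 source_wave = wave, source_pos_mm = src_pos,
                 config = config),
            class = "surface_record")
}

#' @export
print.surface_record <- function(x, ...) {
  cat(sprintf(
    "<surface_record: %d surface cells, %d samples at %.3g kHz (dt %.3g us)>\n",
    ncol(x$p_surf), x$nrec, 1e-3 / (x$dt * x$stride), x$dt * 1e6))
  invisible(x)
}

# continuous-FT approximations of the surface records at the uniform FFT
# bin grid df = 1/duration, bins 0..nb-1
.surface_spectra <- function(record, nb) {
  dtr <- record$dt * record$stride
  Pf <- stats::mvfft(record$p_surf)[seq_len(nb), , drop = FALSE] * dtr
  Vf <- stats::mvfft(record$v_surf)[seq_len(nb), , drop = FALSE] * dtr
  list(P = Pf, V = Vf, df = 1 / (record$nrec * dtr))
}

#' Kirchhoff-Helmholtz farfield integration
#'
#' Propagates the recorded surface pressure and normal velocity to
#' farfield points by integrating against the free-space Green's
#' function, one frequency bin at a time, then reassembles per-direction
#' time series decimated by the configured downsample factor.
#'
#' @param record A `surface_record` from [run_fdtd()].
#' @param directions A [direction_grid()] (its Cartesian unit vectors,
#'   scaled by `radius`, are the field points).
#' @param radius Farfield distance in metres (default 1).
#' @param max_frequency Highest bin evaluated (Hz); default the Nyquist
#'   frequency of the decimated output.
#' @return A list of class `farfield_response` with elements `p` (time
#'   series matrix, one column per direction), `fs`, `spectra` (complex,
#'   bins x directions), `freq`, `directions`, `radius`.
#' @export
kirchhoff_helmholtz_farfield <- function(record, directions, radius = 1,
                                         max_frequency = NULL) {
  stopifnot(inherits(record, "surface_record"), radius > 0)
  cfg <- record$config
  fs_out <- 1 / (record$dt * cfg$downsample_factor)
  fmax <- max_frequency %||% (fs_out / 2)
  nout <- record$nsteps / cfg$downsample_factor
  dtr <- record$dt * record$stride
  df <- 1 / (record$nrec * dtr)
  nb <- min(floor(fmax / df), record$nrec %/% 2 - 1, nout %/% 2 - 1) + 1
  sp <- .surface_spectra(record, nb)

  u <- direction_to_cartesian(directions$lateral, directions$polar)
  pts <- u * radius
  cc <- cfg$sound_speed
  S <- kh_farfield_cpp(sp$P, sp$V, record$pos, record$normal,
                       record$h^2, 0, 2 * pi * df / cc,
                       cfg$air_density, cc, pts)
  .farfield_from_spectra(S, df, nout, fs_out, directions, radius)
}

# assemble a real time series (rate fs_out, length nout) from one-sided
# continuous-FT bin values S (nb x nd, bins b*df)
.farfield_from_spectra <- function(S, df, nout, fs_out, directions, radius) {
  nb <- nrow(S)
  full <- matrix(0 + 0i, nout, ncol(S))
  full[seq_len(nb), ] <- S * fs_out          # back to DFT scaling
  full[1, ] <- Re(full[1, ])
  if (nb > 1) {
    full[nout + 2 - seq(2, nb), ] <- Conj(full[seq(2, nb), , drop = FALSE])
  }
  p <- Re(stats::mvfft(full, inverse = TRUE)) / nout
  structure(list(p = p, fs = fs_out, spectra = S,
                 freq = (seq_len(nb) - 1) * df,
                 directions = directions, radius = radius),
            class = "farfield_response")
}

#' Analytic free-field farfield response
#'
#' Closed-form monopole response of the additive FDTD source in free
#' space: `p(r, t) = h^3 s'(t - r/c) / (4 pi r c^2 dt)`, evaluated on the
#' same frequency bins and decimated timeline as the scattered response.
#' This is the free-field reference used for HRTF normalization (an
#' empty-domain simulation agrees with it and is available for
#' validation).
#'
#' @param record The `surface_record` whose source and timing to mirror.
#' @param directions Direction grid (the free field is identical in all
#'   directions; one column per direction is returned).
#' @param radius Distance in metres.
#' @param max_frequency As in [kirchhoff_helmholtz_farfield()].
#' @return A `farfield_response`.
#' @export
free_field_response <- function(record, directions, radius = 1,
                                max_frequency = NULL) {
  stopifnot(inherits(record, "surface_record"))
  cfg <- record$config
  fs_out <- 1 / (record$dt * cfg$downsample_factor)
  fmax <- max_frequency %||% (fs_out / 2)
  nout <- record$nsteps / cfg$downsample_factor
  df <- 1 / (record$nsteps * record$dt)
  nb <- min(floor(fmax / df), record$nrec %/% 2 - 1, nout %/% 2 - 1) + 1
  f <- (seq_len(nb) - 1) * df
  Sw <- stats::fft(record$source_wave)[seq_len(nb)] * record$dt
  cc <- record$config$sound_speed
  amp <- record$h^3 / (4 * pi * radius * cc^2 * record$dt)
  S1 <- amp * (1i * 2 * pi * f) * Sw * exp(-1i * 2 * pi * f * radius / cc)
  S <- matrix(S1, nb, nrow(directions))
  .farfield_from_spectra(S, df, nout, fs_out, directions, radius)
}

#' Head-related transfer functions from farfield responses
#'
#' Per direction, `HRTF(f) = FFT(scattered) / FFT(free_field)`. Both
#' responses must share direction grid and sample rate. The division is
#' restricted to bins where the free-field magnitude is above
#' `tol` times its in-band maximum.
#'
#' @param scattered,free_field `farfield_response` objects (the free
#'   field may have a single column, broadcast across directions).
#' @param band Frequency band (Hz, length 2) over which the
#'   normalization must be well conditioned; returned bins are restricted
#'   to it.
#' @param tol Relative free-field magnitude tolerance.
#' @return A list of class `hrtf_spectra`: complex matrix `h` (bins x
#'   directions), `freq`, `directions`, `radius`.
#' @export
compute_hrtf <- function(scattered, free_field, band = c(350, 15000),
                         tol = 1e-6) {
  stopifnot(inherits(scattered, "farfield_response"),
            inherits(free_field, "farfield_response"))
  if (abs(scattered$fs - free_field$fs) > 1e-9 ||
      nrow(scattered$directions) %% ncol(free_field$spectra) != 0) {
    stop("scattered and free-field responses are not compatible")
  }
  nb <- min(nrow(scattered$spectra), nrow(free_field$spectra))
  freq <- scattered$freq[seq_len(nb)]
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("empty band")
  Ff <- free_field$spectra[seq_len(nb), , drop = FALSE]
  if (ncol(Ff) == 1) {
    Ff <- matrix(Ff[, 1], nb, nrow(scattered$directions))
  }
  mag <- abs(Ff[keep, 1])
  if (min(mag) < tol * max(mag)) {
    stop("ill-conditioned normalization: free-field spectrum vanishes in band")
  }
  H <- scattered$spectra[seq_len(nb), , drop = FALSE][keep, , drop = FALSE] /
    Ff[keep, , drop = FALSE]
  structure(list(h = H, freq = freq[keep], directions = scattered$directions,
                 radius = scattered$radius),
            class = "hrtf_spectra")
}

#' Magnitude of HRTF spectra in dB
#' @param spectra An `hrtf_spectra` object.
#' @return Matrix (bins x directions) of `20 log10 |H|`.
#' @export
hrtf_db <- function(spectra) {
  stopifnot(inherits(spectra, "hrtf_spectra"))
  20 * log10(abs(spectra$h))
}

#' Convert HRTF spectra of one pinna into an `hrtf_set`
#'
#' @param spectra An `hrtf_spectra` object.
#' @param person Person id.
#' @param side "left" or "right".
#' @return An `hrtf_set` on the spectra's native frequency bins.
#' @export
hrtf_spectra_to_set <- function(spectra, person = 1L, side = "left") {
  dirs <- spectra$directions
  index <- tibble::tibble(obs = seq_len(nrow(dirs)), person = person,
                          side = side, direction = dirs$direction,
                          lateral = dirs$lateral, polar = dirs$polar)
  hrtf_set(hrtf_db(spectra), spectra$freq, index, dirs)
}
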