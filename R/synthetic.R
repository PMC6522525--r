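#' Planted low-rank basis plan for synthetic HRTF sets
#'
#' Describes a synthetic population whose directional transfer functions
#' are exact linear combinations of a small number of smooth frequency
#' profiles weighted by direction-dependent fields, plus Gaussian noise —
#' the low-rank structure that eigenmode (PCA) analysis assumes.
#'
#' Default mode profiles mimic the familiar shapes: mode 1 a head-shadow
#' low-pass contrast, mode 2 a mid-frequency (~4-9 kHz) emphasis versus
#' high frequencies, mode 3 an 8-11 kHz band emphasis versus its
#' neighbours; higher modes are slow cosines in log-frequency. Default
#' weight fields plant a left-right (ipsi/contralateral) contrast on
#' mode 1, an elevation contrast on mode 2, and a front-back contrast
#' tilted upward by 35 degrees on mode 3.
#'
#' @param n_modes Number of planted modes (>= 1).
#' @param mode_profiles List of functions `f(Hz) -> value`; defaults
#'   described above. Profiles are orthonormalized (order-preserving
#'   Gram-Schmidt) on the realized frequency grid.
#' @param weight_fields List of functions
#'   `(lateral, polar, side_sign) -> weight` (degrees; side_sign +1 for
#'   left, -1 for right pinnae). Fields are centered and orthogonalized on
#'   the realized observation set so planted variance fractions are exact.
#' @param weight_scale_db RMS weight per mode (dB); decreasing values
#'   separate the planted eigenvalues.
#' @param noise_sd Independent Gaussian noise per (observation, bin), dB.
#' @param n_persons Number of synthetic persons (two pinnae each).
#' @param inter_person_scale_sd Fractional frequency-scale jitter across
#'   persons; per-person scale factors are log-uniform with this standard
#'   deviation. 0 (default) disables jitter.
#' @param person_mean_sd Amplitude (dB) of the smooth random per-person,
#'   direction-independent mean spectrum (removed by [to_dtf()]).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   plan (the seed is stored in the output metadata).
#' @return A list of class `planted_basis`.
#' @export
planted_basis <- function(n_modes = 3,
                          mode_profiles = default_mode_profiles(n_modes),
                          weight_fields = default_weight_fields(n_modes),
                          weight_scale_db = 6 * 0.65^(seq_len(n_modes) - 1),
                          noise_sd = 0.1,
                          n_persons = 10,
                          inter_person_scale_sd = 0,
                          person_mean_sd = 3,
                          seed = 1L) {
  stopifnot(n_modes >= 1, length(mode_profiles) == n_modes,
            length(weight_fields) == n_modes,
            length(weight_scale_db) == n_modes, all(weight_scale_db > 0),
            noise_sd >= 0, n_persons >= 1, inter_person_scale_sd >= 0)
  structure(list(n_modes = as.integer(n_modes),
                 mode_profiles = mode_profiles,
                 weight_fields = weight_fields,
                 weight_scale_db = weight_scale_db,
                 noise_sd = noise_sd, n_persons = as.integer(n_persons),
                 inter_person_scale_sd = inter_person_scale_sd,
                 person_mean_sd = person_mean_sd, seed = as.integer(seed)),
            class = "planted_basis")
}

#' Default smooth mode profiles
#' @param n_modes Number of profiles to return.
#' @return List of functions of frequency (Hz).
#' @export
default_mode_profiles <- function(n_modes) {
  lgauss <- function(f0, w) function(f) exp(-((log(f / f0)) / w)^2)
  base <- list(
    function(f) -1 / (1 + exp(-(log(f / 4000)) / 0.35)),
    function(f) lgauss(6000, 0.30)(f) - 0.8 * lgauss(12500, 0.18)(f),
    function(f) lgauss(9500, 0.14)(f) - 0.6 * lgauss(5000, 0.25)(f) -
      0.5 * lgauss(13200, 0.10)(f)
  )
  extra <- lapply(seq_len(max(0, n_modes - 3)), function(m) {
    function(f) cos((m + 2) * pi * log(f / 350) / log(15000 / 350))
  })
  c(base, extra)[seq_len(n_modes)]
}

#' Default planted weight fields on the direction sphere
#'
#' Mode 1: ipsilateral/contralateral contrast (`side_sign * sin(lateral)`).
#' Mode 2: elevation contrast (z component of the direction).
#' Mode 3: front-back contrast tilted upward by 35 degrees.
#' Higher modes: low-order angular harmonics.
#'
#' @param n_modes Number of fields to return.
#' @return List of functions `(lateral, polar, side_sign)`.
#' @export
default_weight_fields <- function(n_modes) {
  alpha <- 35 * pi / 180
  base <- list(
    function(lateral, polar, side_sign) {
      side_sign * sin(lateral * pi / 180)
    },
    function(lateral, polar, side_sign) {
      cos(lateral * pi / 180) * sin(polar * pi / 180)
    },
    function(lateral, polar, side_sign) {
      xyz <- direction_to_cartesian(lateral, polar)
      xyz[, "x"] * cos(alpha) + xyz[, "z"] * sin(alpha)
    }
  )
  extra <- lapply(seq_len(max(0, n_modes - 3)), function(m) {
    function(lateral, polar, side_sign) {
      cos((m + 1) * polar * pi / 180) * cos(lateral * pi / 180)^m
    }
  })
  c(base, extra)[seq_len(n_modes)]
}

# Order-preserving Gram-Schmidt; returns orthonormal columns aligned in
# sign with the inputs.
.gram_schmidt <- function(M) {
  Q <- qr.Q(qr(M))
  R <- qr.R(qr(M))
  s <- sign(diag(R))
  s[s == 0] <- 1
  sweep(Q, 2, s, `*`)
}

#' Generate a synthetic HRTF set with planted eigenstructure
#'
#' For each person p and pinna, `HRTF(d, f) = person_mean_p(f) +
#' sum_m w_m(d) * e_m(f / s_p) + noise`, where the `e_m` are orthonormal
#' smooth profiles, the `w_m` are centered, mutually orthogonal weight
#' fields, `s_p` is an optional per-person frequency scale, and the noise
#' is iid Gaussian in dB. The planted profiles, weights and closed-form
#' variance fractions are attached as attribute `planted`.
#'
#' @param plan A [planted_basis()] plan.
#' @param directions A [direction_grid()].
#' @param freqs A [frequency_grid()] (or numeric vector of Hz).
#' @return An `hrtf_set` with attribute `planted` (list: `profiles`
#'   orthonormal n_bins x n_modes matrix, `weights` n_obs x n_modes,
#'   `var_fractions`, `seed`).
#' @examples
#' set <- generate_synthetic_hrtf_set(planted_basis(noise_sd = 0),
#'                                    direction_grid(), frequency_grid())
#' @export
generate_synthetic_hrtf_set <- function(plan = planted_basis(),
                                        directions = direction_grid(),
                                        freqs = frequency_grid()) {
  stopifnot(inherits(plan, "planted_basis"))
  nf <- length(freqs)
  if (plan$n_modes > nf) {
    stop("rank error: more planted modes than frequency bins")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(plan$seed)

  # orthonormal profiles on the analysis grid
  P0 <- vapply(plan$mode_profiles, function(g) g(as.numeric(freqs)),
               numeric(nf))
  if (qr(P0)$rank < plan$n_modes) {
    stop("mode profiles are not linearly independent on this grid")
  }
  E <- .gram_schmidt(P0)

  # observation index: persons x sides x directions
  sides <- c("left", "right")
  index <- tidyr::expand_grid(person = seq_len(plan$n_persons),
                              side = sides,
                              direction = directions$direction)
  index <- dplyr::left_join(index, directions, by = "direction")
  index <- dplyr::mutate(index, obs = dplyr::row_number(), .before = 1)
  n_obs <- nrow(index)

  # centered, orthogonalized weight fields with planted RMS scales
  ss <- ifelse(index$side == "left", 1, -1)
  W0 <- vapply(plan$weight_fields,
               function(g) g(index$lateral, index$polar, ss),
               numeric(n_obs))
  W0 <- scale(W0, center = TRUE, scale = FALSE)
  W <- .gram_schmidt(W0)
  W <- sweep(W, 2, plan$weight_scale_db * sqrt(n_obs), `*`)

  # per-person smooth mean spectra and frequency-scale factors
  lf <- log(as.numeric(freqs) / min(freqs)) / log(max(freqs) / min(freqs))
  person_means <- vapply(seq_len(plan$n_persons), function(p) {
    a <- stats::rnorm(4, 0, plan$person_mean_sd / sqrt(4))
    a[1] + a[2] * cos(pi * lf) + a[3] * cos(2 * pi * lf) +
      a[4] * cos(3 * pi * lf)
  }, numeric(nf))
  scale_p <- if (plan$inter_person_scale_sd > 0) {
    half <- sqrt(3) * plan$inter_person_scale_sd
    exp(stats::runif(plan$n_persons, -half, half))
  } else {
    rep(1, plan$n_persons)
  }

  mag <- matrix(0, nf, n_obs)
  for (p in seq_len(plan$n_persons)) {
    cols <- which(index$person == p)
    Ep <- if (scale_p[p] == 1) E else {
      apply(E, 2, function(e) {
        stats::spline(as.numeric(freqs), e,
                      xout = as.numeric(freqs) / scale_p[p],
                      method = "natural")$y
      })
    }
    mag[, cols] <- person_means[, p] +
      Ep %*% t(W[cols, , drop = FALSE])
  }
  if (plan$noise_sd > 0) {
    mag <- mag + stats::rnorm(length(mag), 0, plan$noise_sd)
  }

  out <- hrtf_set(mag, freqs, index, directions)
  sig2 <- colMeans(W^2)
  attr(out, "planted") <- list(profiles = E, weights = W,
                               var_fractions = sig2 / sum(sig2),
                               scale_factors = scale_p, seed = plan$seed)
  out
}

#' Closed-form planted variance fractions of a synthetic set
#' @param set A set from [generate_synthetic_hrtf_set()].
#' @return Numeric vector of per-mode variance fractions.
#' @export
planted_variance_fractions <- function(set) {
  pl <- attr(set, "planted")
  if (is.null(pl)) stop("set carries no planted structure")
  pl$var_fractions
}
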