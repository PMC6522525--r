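# Partial-wave series for scattering of a point source by an impedance
# sphere. Used as the independent oracle for the FDTD + farfield pipeline
# via reciprocity: the simulated configuration (source on the sphere at
# the "ear", receiver far away) equals the series configuration (point
# source far away, receiver at the ear point).

# spherical Bessel functions j_n, y_n for vector x, orders 0..nmax
.sph_bessel <- function(nmax, x, kind = c("j", "y")) {
  kind <- match.arg(kind)
  out <- matrix(0, nmax + 1, length(x))
  fac <- sqrt(pi / (2 * x))
  for (n in 0:nmax) {
    out[n + 1, ] <- fac * if (kind == "j") besselJ(x, n + 0.5) else
      besselY(x, n + 0.5)
  }
  out
}

# derivative via f_n'(x) = f_{n-1}(x) - (n+1)/x f_n(x); f_0' = -f_1
.sph_bessel_deriv <- function(fn, x) {
  nmax <- nrow(fn) - 1
  d <- matrix(0, nmax + 1, length(x))
  d[1, ] <- -fn[2, ]
  for (n in 1:nmax) {
    d[n + 1, ] <- fn[n, ] - (n + 1) / x * fn[n + 1, ]
  }
  d
}

# Legendre polynomials P_0..P_nmax at mu (vector)
.legendre <- function(nmax, mu) {
  P <- matrix(0, nmax + 1, length(mu))
  P[1, ] <- 1
  if (nmax >= 1) P[2, ] <- mu
  if (nmax >= 2) {
    for (n in 1:(nmax - 1)) {
      P[n + 2, ] <- ((2 * n + 1) * mu * P[n + 1, ] - n * P[n, ]) / (n + 1)
    }
  }
  P
}

#' Analytic HRTF of an impedance sphere (series oracle)
#'
#' Exact partial-wave solution for the transfer function between a far
#' point source and a receiver on (or just off) the surface of a sphere
#' with a locally reacting, frequency-independent surface impedance,
#' normalized by the free-field pressure at the sphere center. By
#' acoustic reciprocity this equals the simulated configuration with the
#' source at the ear and farfield receivers.
#'
#' @param radius Sphere radius in metres.
#' @param impedance Surface impedance in rayl (`Inf` for a rigid sphere).
#' @param directions A [direction_grid()] (source directions).
#' @param freqs Frequencies in Hz.
#' @param source_distance Source distance in metres (default 1).
#' @param ear Unit vector to the ear point on the sphere (default +y).
#' @param receiver_radius Receiver radius in metres (default `radius`;
#'   set slightly larger to mirror a source cell just off the surface).
#' @param temperature Air temperature, degrees Celsius.
#' @param n_terms Series truncation order; `NULL` for an automatic
#'   ka-dependent choice.
#' @param rel_tol Relative magnitude of the last retained term above
#'   which a truncation error is raised.
#' @return Matrix of magnitudes in dB, `length(freqs)` rows by
#'   `nrow(directions)` columns.
#' @export
analytic_sphere_hrtf <- function(radius, impedance = 1.48e6,
                                 directions = direction_grid(),
                                 freqs, source_distance = 1,
                                 ear = c(0, 1, 0),
                                 receiver_radius = radius,
                                 temperature = 20,
                                 n_terms = NULL, rel_tol = 1e-8) {
  stopifnot(radius > 0, source_distance > 2 * radius,
            receiver_radius >= radius)
  cc <- 331.3 * sqrt(1 + temperature / 273.15)
  rho <- 101325 / (287.058 * (temperature + 273.15))
  ear <- ear / sqrt(sum(ear^2))
  u <- direction_to_cartesian(directions$lateral, directions$polar)
  mu <- pmin(1, pmax(-1, as.vector(u %*% ear)))

  k <- 2 * pi * freqs / cc
  ka_max <- max(k) * radius
  nmax <- n_terms %||% max(20, ceiling(ka_max + 8 * ka_max^(1 / 3) + 12))
  P <- .legendre(nmax, mu)

  out <- matrix(NA_real_, length(freqs), nrow(directions))
  for (fi in seq_along(freqs)) {
    kk <- k[fi]
    if (kk <= 0) {
      out[fi, ] <- 0
      next
    }
    ka <- kk * radius
    kb <- kk * receiver_radius
    kr0 <- kk * source_distance
    ja <- .sph_bessel(nmax, ka, "j"); ya <- .sph_bessel(nmax, ka, "y")
    jb <- .sph_bessel(nmax, kb, "j"); yb <- .sph_bessel(nmax, kb, "y")
    j0 <- .sph_bessel(nmax, kr0, "j"); y0 <- .sph_bessel(nmax, kr0, "y")
    ha <- ja + 1i * ya
    hb <- jb + 1i * yb
    h0 <- j0 + 1i * y0
    dja <- .sph_bessel_deriv(ja, ka)
    dha <- .sph_bessel_deriv(ha, ka)
    # locally reacting surface: p(a) = -Z v_r(a)  (e^{-i omega t} sign)
    A <- if (is.infinite(impedance)) {
      -dja / dha
    } else {
      zeta <- 1i * impedance / (rho * cc)
      -(ja - zeta * dja) / (ha - zeta * dha)
    }
    n <- 0:nmax
    term <- (2 * n + 1) * (jb + A * hb)[, 1] * h0[, 1]
    if (abs(term[nmax + 1]) > rel_tol * max(abs(term))) {
      stop("truncation error: series not converged at ka = ",
           signif(ka, 4), "; increase n_terms")
    }
    # ratio to free field at the center: ik r0 e^{-ik r0} sum term_n P_n
    series <- drop(term %*% P)
    ratio <- 1i * kr0 * exp(-1i * kr0) * series
    out[fi, ] <- 20 * log10(abs(ratio))
  }
  out
}
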