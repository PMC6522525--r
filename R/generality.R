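#' Reference eigenmode profiles
#'
#' A container for externally published eigenmode frequency profiles
#' (arbitrary units) used to test the generality of fitted eigenmodes.
#'
#' @param freq Frequency grid, Hz; must overlap 3-14 kHz.
#' @param profiles Matrix, `length(freq)` rows by one column per mode.
#' @param label Source label.
#' @return A list of class `reference_eigenmodes`.
#' @export
reference_eigenmodes <- function(freq, profiles, label = "reference") {
  profiles <- as.matrix(profiles)
  stopifnot(length(freq) == nrow(profiles), all(is.finite(profiles)),
            min(freq) <= 14000, max(freq) >= 3000)
  structure(list(freq = as.numeric(freq), profiles = profiles,
                 label = label),
            class = "reference_eigenmodes")
}

#' Read reference eigenmodes from CSV
#'
#' Expects columns `frequency_hz, mode1, mode2, ...`.
#'
#' @param path CSV path.
#' @param label Source label (default the file name).
#' @return A [reference_eigenmodes()] object.
#' @export
read_reference_eigenmodes <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  stopifnot(names(d)[1] == "frequency_hz")
  reference_eigenmodes(d$frequency_hz, as.matrix(d[-1]), label)
}

# common in-band grid; modes are compared after spline resampling to it
.common_grid <- function(basis_freq, ref_freq, band, scale = 1) {
  lo <- max(band[1], min(ref_freq), min(basis_freq) * scale)
  hi <- min(band[2], max(ref_freq), max(basis_freq) * scale)
  if (hi <= lo) return(NULL)
  seq(lo, hi, by = 50)
}

#' Correlate fitted eigenmodes with reference profiles
#'
#' Both profile sets are spline-resampled to a common grid on the band
#' (default 3-14 kHz) and compared by Pearson correlation, mode index by
#' mode index.
#'
#' @param basis An `eigen_basis` with a frequency grid.
#' @param ref A [reference_eigenmodes()] object.
#' @param band Comparison band, Hz.
#' @param n_modes Number of leading modes compared (default: number of
#'   reference profiles).
#' @return Tibble with columns `mode`, `r`.
#' @export
correlate_modes <- function(basis, ref, band = c(3000, 14000),
                            n_modes = ncol(ref$profiles)) {
  stopifnot(inherits(basis, "eigen_basis"),
            inherits(ref, "reference_eigenmodes"),
            ncol(basis$vectors) >= n_modes)
  grid <- .common_grid(basis$freq, ref$freq, band)
  if (is.null(grid)) stop("empty overlap between basis, reference and band")
  r <- vapply(seq_len(n_modes), function(m) {
    a <- stats::spline(basis$freq, basis$vectors[, m], xout = grid,
                       method = "natural")$y
    b <- stats::spline(ref$freq, ref$profiles[, m], xout = grid,
                       method = "natural")$y
    stats::cor(a, b)
  }, numeric(1))
  tibble::tibble(mode = seq_len(n_modes), r = r)
}

#' Optimal log-frequency scaling of eigenmodes against a reference
#'
#' Searches a multiplicative frequency scale factor `s` (a rigid shift
#' along the logarithmic frequency axis, common to all modes) maximizing
#' the mean per-mode Pearson correlation between the scaled fitted
#' eigenmodes and the reference profiles. A factor `s > 1` shifts the
#' fitted modes' features upward in frequency, the expected direction
#' when the fitted population's heads are proportionally larger than the
#' reference population's.
#'
#' @param basis An `eigen_basis`.
#' @param ref A [reference_eigenmodes()] object.
#' @param band Comparison band, Hz (default 3-14 kHz).
#' @param search Length-2 factor range searched (default 0.80-1.25).
#' @param step Relative step of the factor grid (default 0.001 = 0.1%).
#' @param n_modes Number of leading modes (default: reference count).
#' @return A list of class `scaling_result`: `scale_factor`,
#'   `percent_shift`, `mean_r_unscaled`, `mean_r_scaled`, and a tibble
#'   `by_mode` (columns mode, r_unscaled, r_scaled).
#' @export
optimal_frequency_scaling <- function(basis, ref, band = c(3000, 14000),
                                      search = c(0.80, 1.25),
                                      step = 0.001,
                                      n_modes = ncol(ref$profiles)) {
  stopifnot(search[1] > 0, search[2] > search[1], step > 0)
  cand <- exp(seq(log(search[1]), log(search[2]), by = log(1 + step)))
  if (!any(abs(cand - 1) < 1e-12)) cand <- sort(c(cand, 1))

  eval_scale <- function(s) {
    # scaled mode value at f is the fitted profile evaluated at f / s
    grid <- .common_grid(basis$freq, ref$freq, band, scale = s)
    if (is.null(grid)) return(NULL)
    r <- vapply(seq_len(n_modes), function(m) {
      a <- stats::spline(basis$freq, basis$vectors[, m], xout = grid / s,
                         method = "natural")$y
      b <- stats::spline(ref$freq, ref$profiles[, m], xout = grid,
                         method = "natural")$y
      stats::cor(a, b)
    }, numeric(1))
    r
  }

  means <- vapply(cand, function(s) {
    r <- eval_scale(s)
    if (is.null(r)) -Inf else mean(r)
  }, numeric(1))
  if (all(!is.finite(means))) {
    stop("overlap vanishes over the whole search range")
  }
  best <- which.max(means)
  r1 <- eval_scale(1)
  rb <- eval_scale(cand[best])
  structure(list(scale_factor = cand[best],
                 percent_shift = 100 * (cand[best] - 1),
                 mean_r_unscaled = mean(r1),
                 mean_r_scaled = means[best],
                 by_mode = tibble::tibble(mode = seq_len(n_modes),
                                          r_unscaled = r1, r_scaled = rb)),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf(
    "<scaling_result: %+.1f%% shift; mean r %.3f -> %.3f>\n",
    x$percent_shift, x$mean_r_unscaled, x$mean_r_scaled))
  invisible(x)
}

#' Tidy a scaling result
#' @param x A `scaling_result`.
#' @param ... Unused.
#' @return The per-mode tibble with the scale factor attached.
#' @export
tidy.scaling_result <- function(x, ...) {
  dplyr::mutate(x$by_mode, percent_shift = x$percent_shift)
}

#' @export
glance.scaling_result <- function(x, ...) {
  tibble::tibble(scale_factor = x$scale_factor,
                 percent_shift = x$percent_shift,
                 mean_r_unscaled = x$mean_r_unscaled,
                 mean_r_scaled = x$mean_r_scaled)
}
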