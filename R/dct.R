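#' DCT smoothing configuration
#'
#' DCT coefficients are computed on dB spectra over a uniform grid
#' spanning the fit band (350 Hz to 15 kHz by default, 50 Hz steps, 294
#' bins); representation errors are evaluated on the slightly narrower
#' analysis band (500 Hz to 14 kHz).
#'
#' @param fit_start,fit_stop Fit band edges, Hz.
#' @param fit_step Uniform fit grid step, Hz.
#' @param eval_band Length-2 evaluation band, Hz; must lie inside the fit
#'   band.
#' @param eval_grid Frequency grid on which errors are evaluated.
#' @return A list of class `dct_config`.
#' @export
dct_config <- function(fit_start = 350, fit_step = 50, fit_stop = 15000,
                       eval_band = c(500, 14000),
                       eval_grid = frequency_grid()) {
  stopifnot(eval_band[1] >= fit_start, eval_band[2] <= fit_stop)
  structure(list(fit_grid = seq(fit_start, fit_stop, by = fit_step),
                 eval_band = eval_band, eval_grid = eval_grid),
            class = "dct_config")
}

# orthonormal DCT-II basis matrix (N x N); rows are basis functions
.dct_matrix <- function(n) {
  key <- as.character(n)
  cached <- .dct_cache[[key]]
  if (!is.null(cached)) return(cached)
  j <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(pi * outer(j, j + 0.5) / n)
  C[1, ] <- sqrt(1 / n)
  .dct_cache[[key]] <- C
  C
}
.dct_cache <- new.env(parent = emptyenv())

#' Smooth spectra by truncating their DCT
#'
#' Computes the orthonormal type-II DCT of each dB spectrum on its
#' uniform grid, zeroes all coefficients beyond `n_coef`, and inverts the
#' transform.
#'
#' @param mag_db Numeric vector or matrix (grid bins x spectra).
#' @param n_coef Number of retained coefficients, between 1 and the
#'   number of grid bins.
#' @return Smoothed spectra, same shape as the input.
#' @export
dct_smooth <- function(mag_db, n_coef) {
  v <- is.null(dim(mag_db))
  if (v) mag_db <- matrix(mag_db)
  n <- nrow(mag_db)
  if (n_coef < 1 || n_coef > n) stop("n_coef out of range 1..", n)
  C <- .dct_matrix(n)
  coef <- C %*% mag_db
  sm <- crossprod(C[seq_len(n_coef), , drop = FALSE],
                  coef[seq_len(n_coef), , drop = FALSE])
  if (v) drop(sm) else sm
}

#' DCT representation-error distribution
#'
#' Each spectrum is spline-resampled to the uniform fit grid, smoothed by
#' retaining `n_coef` DCT coefficients, resampled to the evaluation grid,
#' and compared to the original (also resampled to the evaluation grid)
#' by RMS dB error over the evaluation band; quartiles are returned per
#' coefficient count.
#'
#' @param set An `hrtf_set` or `dtf_set` whose frequency range covers the
#'   fit band.
#' @param n_coef Vector of coefficient counts.
#' @param config A [dct_config()].
#' @return An `error_summary` tibble (columns `k`, `q1`, `median`, `q3`,
#'   `n`; `k` is the coefficient count) with attribute `method = "dct"`.
#' @export
dct_error_distribution <- function(set, n_coef, config = dct_config()) {
  stopifnot(inherits(set, "hrtf_set"))
  fit <- resample_spectrum(set$freq, set$mag_db, config$fit_grid)
  ref <- resample_spectrum(set$freq, set$mag_db, config$eval_grid)
  out <- purrr::map_dfr(sort(unique(as.integer(n_coef))), function(nc) {
    sm <- dct_smooth(fit, nc)
    rec <- resample_spectrum(config$fit_grid, sm, config$eval_grid)
    .quartile_row(rms_error_db(ref, rec, config$eval_grid,
                               config$eval_band), nc)
  })
  attr(out, "method") <- "dct"
  class(out) <- c("error_summary", class(out))
  out
}

#' Match DCT coefficient counts to eigenmode counts
#'
#' For each DCT error summary, finds the eigenmode count whose error
#' quartile triplet (q1, median, q3) is closest in total absolute
#' difference, mirroring the horizontal extension of DCT error statistics
#' to the closest-matching PCA statistics. Ties break toward the smaller
#' mode count.
#'
#' @param dct An `error_summary` from [dct_error_distribution()].
#' @param pca An `error_summary` from [error_distribution()] (one row per
#'   candidate k).
#' @return A tibble with columns `n_dct`, `k_pca`, `distance`, and the
#'   matched quartile triplets.
#' @export
match_correspondence <- function(dct, pca) {
  stopifnot(nrow(dct) >= 1, nrow(pca) >= 1)
  purrr::map_dfr(seq_len(nrow(dct)), function(i) {
    d <- abs(pca$q1 - dct$q1[i]) + abs(pca$median - dct$median[i]) +
      abs(pca$q3 - dct$q3[i])
    best <- which(d <= min(d) + 1e-12)
    best <- best[which.min(pca$k[best])]
    tibble::tibble(n_dct = dct$k[i], k_pca = pca$k[best],
                   distance = d[best],
                   dct_q1 = dct$q1[i], dct_median = dct$median[i],
                   dct_q3 = dct$q3[i],
                   pca_q1 = pca$q1[best], pca_median = pca$median[best],
                   pca_q3 = pca$q3[best])
  })
}
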