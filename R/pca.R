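#' Fit the eigenmode basis of a DTF matrix
#'
#' Removes the grand mean over observations and computes the ordered
#' eigenvectors of the bin-by-bin covariance via thin SVD of the centered
#' frequency-by-observation matrix (numerically equivalent to the dense
#' covariance eigendecomposition). Eigenvector signs are fixed so each
#' vector's largest-magnitude element is positive.
#'
#' @param x A `dtf_set` / `hrtf_set`, the result of [assemble_matrix()],
#'   or a numeric matrix (frequency bins x observations, at least 2
#'   columns).
#' @param freq Frequency grid of the rows (taken from `x` when it is a
#'   set; required for plain matrices without attributes).
#' @return An object of class `eigen_basis`: `grand_mean`, `vectors`
#'   (orthonormal columns), `values` (covariance eigenvalues, divisor
#'   n - 1), `var_fractions`, `cum_var_fractions`, `freq`, `n_obs`.
#' @export
fit_pca <- function(x, freq = NULL) {
  if (inherits(x, "hrtf_set")) {
    freq <- x$freq
    x <- assemble_matrix(x)$matrix
  } else if (is.list(x) && !is.null(x$matrix)) {
    x <- x$matrix
  }
  stopifnot(is.matrix(x), ncol(x) >= 2)
  n <- ncol(x)
  gm <- rowMeans(x)
  xc <- x - gm
  if (max(abs(xc)) == 0) stop("degenerate input: all observations identical")
  sv <- svd(xc, nu = min(dim(xc)), nv = 0)
  V <- sv$u
  sgn <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  V <- sweep(V, 2, sgn, `*`)
  vals <- sv$d^2 / (n - 1)
  vf <- sv$d^2 / sum(sv$d^2)
  structure(list(grand_mean = gm, vectors = V, values = vals,
                 var_fractions = vf, cum_var_fractions = cumsum(vf),
                 freq = if (is.null(freq)) NULL else as.numeric(freq),
                 n_obs = n),
            class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("<eigen_basis: %d modes over %d bins; top-5 variance %.1f%%>\n",
              ncol(x$vectors), nrow(x$vectors),
              100 * x$cum_var_fractions[min(5, length(x$values))]))
  invisible(x)
}

#' Tidy eigenmode profiles into a long tibble
#' @param x An `eigen_basis`.
#' @param n_modes Number of leading modes to return (default 5).
#' @param ... Unused.
#' @return Tibble with columns mode, frequency, value, variance_fraction.
#' @export
tidy.eigen_basis <- function(x, n_modes = 5, ...) {
  m <- min(n_modes, ncol(x$vectors))
  freq <- x$freq %||% seq_len(nrow(x$vectors))
  tibble::tibble(
    mode = rep(seq_len(m), each = length(freq)),
    frequency = rep(freq, m),
    value = as.vector(x$vectors[, seq_len(m)]),
    variance_fraction = rep(x$var_fractions[seq_len(m)], each = length(freq))
  )
}

#' One-row summary of an eigen basis
#' @param x An `eigen_basis`.
#' @param ... Unused.
#' @return Tibble with mode counts and cumulative variance fractions of
#'   the top 3 and top 5 modes.
#' @export
glance.eigen_basis <- function(x, ...) {
  cum <- x$cum_var_fractions
  tibble::tibble(n_modes = length(x$values), n_obs = x$n_obs,
                 var_top3 = cum[min(3, length(cum))],
                 var_top5 = cum[min(5, length(cum))])
}

#' Project observations onto an eigen basis
#'
#' @param x A set, [assemble_matrix()] result, or matrix (bins x
#'   observations) on the basis's frequency grid.
#' @param basis An `eigen_basis`.
#' @return Weight matrix, observations x modes. For set input, rows
#'   follow the set's own observation order.
#' @export
project_weights <- function(x, basis) {
  if (inherits(x, "hrtf_set")) x <- x$mag_db
  if (is.list(x) && !is.null(x$matrix)) x <- x$matrix
  stopifnot(nrow(x) == nrow(basis$vectors))
  t(crossprod(basis$vectors, x - basis$grand_mean))
}

#' Reconstruct spectra from k eigenmode weights
#'
#' Returns `grand_mean + sum_{m <= k} w_m e_m` per observation. `k = 0`
#' gives the grand mean alone. Per-pinna DTF means are added back
#' separately when full HRTFs are required.
#'
#' @param weights Observations x modes matrix from [project_weights()].
#' @param basis An `eigen_basis`.
#' @param k Number of modes used, `0 <= k <= n_modes`.
#' @return Matrix (bins x observations).
#' @export
reconstruct <- function(weights, basis, k) {
  stopifnot(k >= 0, k <= ncol(basis$vectors))
  if (k == 0) {
    return(matrix(basis$grand_mean, nrow(basis$vectors), nrow(weights)))
  }
  basis$grand_mean +
    basis$vectors[, seq_len(k), drop = FALSE] %*%
    t(weights[, seq_len(k), drop = FALSE])
}

#' Per-observation RMS spectral error in dB
#'
#' `sqrt(mean((orig - recon)^2))` over the in-band frequency bins.
#'
#' @param original,reconstructed Matrices (bins x observations) of dB
#'   magnitudes, equal shapes.
#' @param freq Frequency of each row, Hz.
#' @param band Length-2 band limits in Hz (default 500-14000, the
#'   evaluation range of the analyses).
#' @return Numeric vector, one RMS error (dB) per observation.
#' @export
rms_error_db <- function(original, reconstructed, freq,
                         band = c(500, 14000)) {
  stopifnot(all(dim(original) == dim(reconstructed)),
            nrow(original) == length(freq))
  sel <- freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9
  if (!any(sel)) stop("empty band")
  d <- (original - reconstructed)[sel, , drop = FALSE]
  sqrt(colMeans(d^2))
}

.quartile_row <- function(err, k) {
  q <- stats::quantile(err, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(k = k, q1 = q[1], median = q[2], q3 = q[3],
                 n = length(err))
}

#' Reconstruction-error distribution at k eigenmodes
#'
#' Reconstructs every observation with the top-k modes and summarizes the
#' per-observation RMS dB errors by quartiles (linear-interpolation
#' definition).
#'
#' @param set A `dtf_set` (or `hrtf_set`) on the basis frequency grid.
#' @param basis An `eigen_basis` fitted on a compatible grid.
#' @param k Vector of mode counts.
#' @param band Error band in Hz.
#' @param method "reconstruct" forms each k-mode reconstruction
#'   explicitly; "parseval" uses the orthonormal-basis identity (residual
#'   energy = total minus explained, exact when the band covers the whole
#'   grid, and much faster for many k at scale); "auto" picks "parseval"
#'   when applicable.
#' @return A tibble of class `error_summary` with columns `k`, `q1`,
#'   `median`, `q3`, `n` and attribute `method = "pca"`.
#' @export
error_distribution <- function(set, basis, k, band = c(500, 14000),
                               method = c("auto", "reconstruct",
                                          "parseval")) {
  stopifnot(inherits(set, "hrtf_set"))
  method <- match.arg(method)
  full_band <- min(set$freq) >= band[1] - 1e-9 &&
    max(set$freq) <= band[2] + 1e-9
  if (method == "auto") method <- if (full_band) "parseval" else "reconstruct"
  if (method == "parseval" && !full_band) {
    stop("parseval method needs the band to cover the whole grid")
  }
  W <- project_weights(set, basis)
  k <- sort(unique(as.integer(k)))
  out <- if (method == "parseval") {
    e0 <- colSums((set$mag_db - basis$grand_mean)^2)
    cum <- cbind(0, t(apply(W^2, 1, cumsum)))
    purrr::map_dfr(k, function(kk) {
      err <- sqrt(pmax(e0 - cum[, min(kk, ncol(W)) + 1], 0) /
                    nrow(set$mag_db))
      .quartile_row(err, kk)
    })
  } else {
    purrr::map_dfr(k, function(kk) {
      rec <- reconstruct(W, basis, kk)
      .quartile_row(rms_error_db(set$mag_db, rec, set$freq, band), kk)
    })
  }
  attr(out, "method") <- "pca"
  class(out) <- c("error_summary", class(out))
  out
}

#' Leave-one-person-out cross-validated error distributions
#'
#' For each person, an eigen basis is fitted on all other persons' DTFs;
#' the held-out person's DTFs are projected onto it and reconstructed
#' with the top-k modes. Held-out errors are pooled over persons per k.
#'
#' @param set A `dtf_set` with at least 2 persons.
#' @param k Vector of mode counts.
#' @param band Error band in Hz.
#' @param by_person If `TRUE`, also return per-person quartiles.
#' @return An `error_summary` tibble (pooled); with `by_person = TRUE`, a
#'   list with elements `pooled` and `by_person`.
#' @export
loocv <- function(set, k, band = c(500, 14000), by_person = FALSE) {
  stopifnot(inherits(set, "hrtf_set"))
  persons <- unique(set$index$person)
  if (length(persons) < 2) stop("cross-validation needs at least 2 persons")
  k <- sort(unique(as.integer(k)))
  per <- purrr::map(persons, function(p) {
    hold <- set$index$person == p
    basis <- fit_pca(set$mag_db[, !hold, drop = FALSE], freq = set$freq)
    W <- t(crossprod(basis$vectors,
                     set$mag_db[, hold, drop = FALSE] - basis$grand_mean))
    purrr::map(k, function(kk) {
      rec <- reconstruct(W, basis, min(kk, ncol(basis$vectors)))
      rms_error_db(set$mag_db[, hold, drop = FALSE], rec, set$freq, band)
    })
  })
  pooled <- purrr::map_dfr(seq_along(k), function(i) {
    .quartile_row(unlist(purrr::map(per, i)), k[i])
  })
  attr(pooled, "method") <- "pca_cv"
  class(pooled) <- c("error_summary", class(pooled))
  if (!by_person) return(pooled)
  bp <- purrr::map_dfr(seq_along(persons), function(pi) {
    dplyr::mutate(
      purrr::map_dfr(seq_along(k),
                     function(i) .quartile_row(per[[pi]][[i]], k[i])),
      person = persons[pi], .before = 1)
  })
  list(pooled = pooled, by_person = bp)
}
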