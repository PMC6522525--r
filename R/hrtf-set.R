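#' HRTF magnitude set container
#'
#' Magnitude-dB spectra indexed by pinna (person + side) and direction.
#' Spectra are stored as a frequency-by-observation matrix; `index` maps
#' columns to (person, side, direction) with one row per observation,
#' ordered by person, then side, then direction.
#'
#' @param mag_db Numeric matrix, `length(freq)` rows, one column per
#'   (pinna, direction) observation.
#' @param freq Frequency grid (Hz) of the rows.
#' @param index Tibble with columns `obs`, `person`, `side` ("left" or
#'   "right"), `direction`, `lateral`, `polar`.
#' @param directions The `direction_grid` the set is sampled on.
#' @param pinna_means Optional matrix of per-pinna mean spectra (one
#'   column per pinna) stored when the set holds directional transfer
#'   functions (DTFs).
#' @return An object of class `hrtf_set` (additionally `dtf_set` when
#'   `pinna_means` is given).
#' @export
hrtf_set <- function(mag_db, freq, index, directions, pinna_means = NULL) {
  stopifnot(is.matrix(mag_db), nrow(mag_db) == length(freq),
            ncol(mag_db) == nrow(index), all(is.finite(mag_db)),
            all(c("obs", "person", "side", "direction", "lateral", "polar")
                %in% names(index)))
  cls <- if (is.null(pinna_means)) "hrtf_set" else c("dtf_set", "hrtf_set")
  structure(list(mag_db = mag_db, freq = as.numeric(freq),
                 index = tibble::as_tibble(index),
                 directions = directions, pinna_means = pinna_means),
            class = cls)
}

#' @export
print.hrtf_set <- function(x, ...) {
  np <- nrow(dplyr::distinct(x$index, .data$person, .data$side))
  cat(sprintf("<%s: %d pinnae x %d directions, %d frequency bins (%g-%g Hz)>\n",
              class(x)[1], np, nrow(x$directions), length(x$freq),
              min(x$freq), max(x$freq)))
  invisible(x)
}

#' Tidy an HRTF set into a long tibble
#'
#' @param x An `hrtf_set`.
#' @param ... Unused.
#' @return Tibble with columns person, side, direction, lateral, polar,
#'   frequency, mag_db.
#' @export
tidy.hrtf_set <- function(x, ...) {
  dplyr::mutate(
    tidyr::uncount(x$index, length(x$freq), .id = "bin"),
    frequency = x$freq[.data$bin],
    mag_db = as.vector(x$mag_db),
    bin = NULL, obs = NULL
  ) |> tibble::as_tibble()
}

#' Pinna labels of a set (person:side), one per observation
#' @noRd
.pinna_id <- function(index) paste(index$person, index$side, sep = ":")

#' Resample magnitude spectra onto a target frequency grid
#'
#' Natural cubic-spline interpolation at each target bin. The input grid
#' must cover the target grid; no extrapolation is performed.
#'
#' @param freqs_in Input frequencies (Hz), strictly increasing.
#' @param mag_db_in Numeric vector (one spectrum) or matrix with
#'   `length(freqs_in)` rows (one spectrum per column).
#' @param target Target frequencies, e.g. [frequency_grid()].
#' @return Vector or matrix of magnitudes on the target grid.
#' @export
resample_spectrum <- function(freqs_in, mag_db_in, target = frequency_grid()) {
  stopifnot(!is.unsorted(freqs_in, strictly = TRUE))
  if (min(freqs_in) > min(target) + 1e-9 ||
      max(freqs_in) < max(target) - 1e-9) {
    stop("coverage error: input grid does not span the target grid")
  }
  interp1 <- function(y) {
    stats::spline(freqs_in, y, xout = target, method = "natural")$y
  }
  if (is.matrix(mag_db_in)) {
    stopifnot(nrow(mag_db_in) == length(freqs_in))
    apply(mag_db_in, 2, interp1)
  } else {
    stopifnot(length(mag_db_in) == length(freqs_in))
    interp1(mag_db_in)
  }
}

#' Resample every spectrum of a set onto a target grid
#'
#' @param set An `hrtf_set`.
#' @param target Target frequency grid.
#' @return An `hrtf_set` on the target grid (pinna means, if present, are
#'   resampled too).
#' @export
resample_set <- function(set, target = frequency_grid()) {
  stopifnot(inherits(set, "hrtf_set"))
  pm <- set$pinna_means
  if (!is.null(pm)) pm <- resample_spectrum(set$freq, pm, target)
  hrtf_set(resample_spectrum(set$freq, set$mag_db, target), target,
           set$index, set$directions, pinna_means = pm)
}

#' Convert HRTFs to directional transfer functions (DTFs)
#'
#' Subtracts, for each pinna, its mean dB spectrum over all directions.
#' The means are stored in the result for exact reconstruction.
#'
#' @param set An `hrtf_set` with complete direction coverage per pinna.
#' @return A `dtf_set`.
#' @export
to_dtf <- function(set) {
  stopifnot(inherits(set, "hrtf_set"))
  pid <- .pinna_id(set$index)
  nd <- nrow(set$directions)
  counts <- table(pid)
  if (any(counts != nd)) {
    stop("coverage error: every pinna must cover all directions")
  }
  pinnae <- unique(pid)
  means <- vapply(pinnae, function(p) rowMeans(set$mag_db[, pid == p,
                                                          drop = FALSE]),
                  numeric(length(set$freq)))
  colnames(means) <- pinnae
  mag <- set$mag_db - means[, pid, drop = FALSE]
  prev <- set$pinna_means
  if (!is.null(prev)) means <- means + prev[, pinnae, drop = FALSE]
  hrtf_set(mag, set$freq, set$index, set$directions, pinna_means = means)
}

#' Assemble the frequency-by-observation analysis matrix
#'
#' Columns are ordered (person, side, direction); the returned index makes
#' the mapping reversible.
#'
#' @param set An `hrtf_set` or `dtf_set`.
#' @return List with `matrix` (n_bins x n_observations) and `index`
#'   (tibble, one row per column).
#' @examples
#' # 19 persons x 2 sides x 1250 directions -> 47,500 columns
#' @export
assemble_matrix <- function(set) {
  stopifnot(inherits(set, "hrtf_set"))
  ord <- order(set$index$person, set$index$side, set$index$direction)
  list(matrix = set$mag_db[, ord, drop = FALSE],
       index = dplyr::mutate(set$index[ord, ], column = dplyr::row_number()))
}

#' Rebuild a set from an assembled matrix and its index
#'
#' Inverse of [assemble_matrix()]; column order is restored from the
#' index's `obs` field.
#'
#' @param mat Matrix as returned by [assemble_matrix()].
#' @param index Index tibble as returned by [assemble_matrix()].
#' @param template The original set (for freq/directions/pinna means).
#' @return An `hrtf_set` equal to the original.
#' @export
set_from_matrix <- function(mat, index, template) {
  inv <- order(index$obs)
  hrtf_set(mat[, inv, drop = FALSE], template$freq, index[inv, ],
           template$directions, pinna_means = template$pinna_means)
}

#' Write an HRTF/DTF set as tab-separated text
#'
#' One row per observation with metadata columns followed by one column
#' per frequency bin; per-pinna means (for DTF sets) are stored in a
#' trailing block. Round-trips exactly through [read_hrtf_set()].
#'
#' @param set An `hrtf_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hrtf_set <- function(set, path) {
  stopifnot(inherits(set, "hrtf_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hrtfeigen-hrtf 1",
               paste("# radius", attr(set$directions, "radius") %||% 1)), con)
  hdr <- c("person", "side", "direction", "lateral", "polar",
           paste0("f", format(set$freq, trim = TRUE, scientific = FALSE)))
  writeLines(paste(hdr, collapse = "\t"), con)
  body <- cbind(set$index[c("person", "side", "direction", "lateral",
                            "polar")],
                as.data.frame(t(set$mag_db)))
  utils::write.table(format(body, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(set$pinna_means)) {
    writeLines("# pinna-means", con)
    pm <- data.frame(pinna = colnames(set$pinna_means),
                     t(set$pinna_means))
    utils::write.table(format(pm, digits = 17, trim = TRUE), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a set written by [write_hrtf_set()]
#' @param path File path.
#' @return An `hrtf_set` (or `dtf_set` if pinna means are present).
#' @export
read_hrtf_set <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "# hrtfeigen-hrtf 1") stop("not a hrtfeigen HRTF file")
  radius <- as.numeric(strsplit(ln[2], " ")[[1]][3])
  hdr <- strsplit(ln[3], "\t")[[1]]
  freq <- as.numeric(sub("^f", "", hdr[-(1:5)]))
  means_at <- which(ln == "# pinna-means")
  body_end <- if (length(means_at)) means_at - 1L else length(ln)
  rows <- strsplit(ln[4:body_end], "\t")
  m <- do.call(rbind, rows)
  index <- tibble::tibble(obs = seq_len(nrow(m)),
                          person = as.integer(m[, 1]),
                          side = m[, 2],
                          direction = as.integer(m[, 3]),
                          lateral = as.numeric(m[, 4]),
                          polar = as.numeric(m[, 5]))
  mag <- t(matrix(as.numeric(m[, -(1:5)]), nrow = nrow(m)))
  dirs <- dplyr::distinct(index, .data$direction, .data$lateral, .data$polar)
  dirs <- dirs[order(dirs$direction), ]
  attr(dirs, "radius") <- radius
  class(dirs) <- c("direction_grid", class(dirs))
  pm <- NULL
  if (length(means_at)) {
    mm <- do.call(rbind, strsplit(ln[(means_at + 1L):length(ln)], "\t"))
    pm <- t(matrix(as.numeric(mm[, -1]), nrow = nrow(mm)))
    colnames(pm) <- mm[, 1]
  }
  hrtf_set(mag, freq, index, dirs, pinna_means = pm)
}
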