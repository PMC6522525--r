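#' Default lateral angles of the interaural-polar direction grid
#'
#' The 25 lateral angles (degrees) of the CIPIC-style interaural-polar
#' sampling: -80, -65, -55, then -45 to 45 in 5 degree steps, then 55, 65,
#' 80. Positive lateral is toward the left ear.
#'
#' @return Numeric vector of length 25.
#' @export
default_lateral_angles <- function() {
  c(-80, -65, -55, seq(-45, 45, by = 5), 55, 65, 80)
}

#' Default polar angles of the interaural-polar direction grid
#'
#' The 50 polar angles (degrees): -45 to 230.625 in steps of 5.625,
#' sweeping front (0), up (90), back (180) and below.
#'
#' @return Numeric vector of length 50.
#' @export
default_polar_angles <- function() {
  seq(-45, 230.625, by = 5.625)
}

#' Build an interaural-polar direction grid
#'
#' Directions are the Cartesian product of lateral angles (rotation toward
#' an ear, positive left) and polar angles (rotation about the interaural
#' axis; 0 = front, 90 = up, 180 = back). The default grid has
#' 25 x 50 = 1250 directions at 1 m radius.
#'
#' @param lateral_angles Lateral angles in degrees, each in \[-90, 90\].
#' @param polar_angles Polar angles in degrees.
#' @param radius Source distance from head center in metres.
#' @return A tibble of class `direction_grid` with columns `direction`
#'   (integer id), `lateral`, `polar` (degrees) and an attribute `radius`.
#' @examples
#' dirs <- direction_grid()
#' nrow(dirs)  # 1250
#' @export
direction_grid <- function(lateral_angles = default_lateral_angles(),
                           polar_angles = default_polar_angles(),
                           radius = 1) {
  stopifnot(all(lateral_angles >= -90 & lateral_angles <= 90),
            !anyDuplicated(lateral_angles), !anyDuplicated(polar_angles),
            radius > 0)
  g <- tidyr::expand_grid(lateral = as.numeric(lateral_angles),
                          polar = as.numeric(polar_angles))
  g <- tibble::add_column(g, direction = seq_len(nrow(g)), .before = 1)
  attr(g, "radius") <- radius
  class(g) <- c("direction_grid", class(g))
  g
}

#' Convert interaural-polar directions to Cartesian unit vectors
#'
#' Axes: x forward, y toward the left ear, z up (left-handed
#' interaural-polar convention with positive lateral toward the left ear).
#'
#' @param lateral,polar Angles in degrees (vectors of equal length, or a
#'   `direction_grid` passed as `lateral` with `polar` missing).
#' @return A numeric matrix with columns x, y, z and unit rows.
#' @export
direction_to_cartesian <- function(lateral, polar) {
  if (missing(polar) && is.data.frame(lateral)) {
    polar <- lateral$polar
    lateral <- lateral$lateral
  }
  lat <- lateral * pi / 180
  pol <- polar * pi / 180
  cbind(x = cos(lat) * cos(pol), y = sin(lat), z = cos(lat) * sin(pol))
}

#' Build a uniform analysis frequency grid
#'
#' The default grid spans 500 Hz to 14 kHz in 50 Hz steps, giving 271 bins;
#' HRTF spectra are spline-resampled onto it before eigenmode analysis.
#'
#' @param start,stop Band edges in Hz.
#' @param step Bin spacing in Hz; must divide `stop - start`.
#' @return Numeric vector of bin frequencies with class `frequency_grid`.
#' @examples
#' length(frequency_grid())  # 271
#' @export
frequency_grid <- function(start = 500, step = 50, stop = 14000) {
  stopifnot(start > 0, stop > start, step > 0)
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-9) {
    stop("`step` must divide `stop - start` exactly")
  }
  f <- seq(start, stop, by = step)
  class(f) <- c("frequency_grid", "numeric")
  f
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf("<direction_grid: %d directions, radius %g m>\n",
              nrow(x), attr(x, "radius")))
  NextMethod()
}
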