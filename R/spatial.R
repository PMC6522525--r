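#' Eigenmode weights of every observation as a tidy table
#'
#' Projects a DTF set onto an eigen basis and returns one row per
#' (pinna, direction, mode).
#'
#' @param set A `dtf_set` (or `hrtf_set`) on the basis grid.
#' @param basis An `eigen_basis`.
#' @param n_modes Number of leading modes to keep.
#' @return Tibble with columns person, side, direction, lateral, polar,
#'   mode, weight.
#' @export
eigenmode_weights <- function(set, basis, n_modes = 3) {
  W <- project_weights(set, basis)[, seq_len(n_modes), drop = FALSE]
  dplyr::mutate(
    tidyr::uncount(set$index[c("person", "side", "direction", "lateral",
                               "polar")], n_modes, .id = "mode"),
    weight = as.vector(t(W))
  ) |> tibble::as_tibble()
}

#' Mirror right-pinna weights about the median plane
#'
#' Re-indexes right-pinna weights to the direction with negated lateral
#' angle (so that, after mirroring, positive lateral means ipsilateral
#' for every pinna); left-pinna weights are unchanged. The direction grid
#' must be symmetric in lateral angle.
#'
#' @param weights A tibble from [eigenmode_weights()] (columns side,
#'   lateral, polar at minimum).
#' @param directions The `direction_grid` of the set.
#' @return The weights tibble with right-pinna rows re-mapped.
#' @export
mirror_right_pinnae <- function(weights, directions) {
  stopifnot(all(c("side", "lateral", "polar") %in% names(weights)))
  right <- weights$side == "right"
  mirrored <- dplyr::mutate(weights[right, ], lateral = -.data$lateral)
  lookup <- dplyr::select(tibble::as_tibble(directions),
                          new_direction = "direction", "lateral", "polar")
  mirrored <- dplyr::left_join(dplyr::select(mirrored, -"direction"),
                               lookup, by = c("lateral", "polar"))
  if (anyNA(mirrored$new_direction)) {
    stop("grid-symmetry error: mirrored direction absent from the grid")
  }
  mirrored <- dplyr::rename(mirrored, direction = "new_direction")
  dplyr::bind_rows(weights[!right, ],
                   mirrored[names(weights)])
}

#' Per-direction mean and SD of eigenmode weights
#'
#' Averages one mode's weights across all pinnae at each direction
#' (mirroring across the median plane should be applied first). The
#' attached color-scale bound is +/- 1 standard deviation of the
#' per-direction means, pooled over directions.
#'
#' @param weights A (mirrored) tibble from [eigenmode_weights()].
#' @param mode Mode index to map.
#' @return A tibble of class `spatial_map` with columns direction,
#'   lateral, polar, mean, sd, n and attributes `mode`, `color_bound`.
#' @export
mean_weight_map <- function(weights, mode = 1) {
  if (!mode %in% weights$mode) stop("mode index out of range")
  w <- weights[weights$mode == mode, ]
  map <- dplyr::summarise(
    dplyr::group_by(w, .data$direction, .data$lateral, .data$polar),
    mean = mean(.data$weight),
    sd = if (dplyr::n() > 1) stats::sd(.data$weight) else 0,
    n = dplyr::n(), .groups = "drop")
  attr(map, "mode") <- mode
  attr(map, "color_bound") <- stats::sd(map$mean)
  class(map) <- c("spatial_map", class(map))
  map
}

#' Hammer equal-area projection of interaural-polar directions
#'
#' Directions are converted to longitude (azimuth, 0 at front, positive
#' toward the left) and latitude (elevation), then mapped by the standard
#' Hammer forward formulas; the front direction projects to the origin
#' and the projection is equal-area.
#'
#' @param lateral,polar Angles in degrees (vectors, or a data frame with
#'   those columns passed as `lateral`).
#' @return Tibble with columns `x`, `y` (and the inputs).
#' @export
hammer_project <- function(lateral, polar) {
  if (missing(polar) && is.data.frame(lateral)) {
    df <- lateral
    lateral <- df$lateral
    polar <- df$polar
  } else {
    df <- tibble::tibble(lateral = lateral, polar = polar)
  }
  u <- direction_to_cartesian(lateral, polar)
  lon <- atan2(u[, "y"], u[, "x"])
  lat <- asin(pmin(1, pmax(-1, u[, "z"])))
  den <- sqrt(1 + cos(lat) * cos(lon / 2))
  dplyr::mutate(tibble::as_tibble(df),
                x = 2 * sqrt(2) * cos(lat) * sin(lon / 2) / den,
                y = sqrt(2) * sin(lat) / den)
}

#' Plot a spatial eigenmode-weight map
#'
#' Hammer projection of the per-direction mean weights with the color
#' scale clipped at +/- 1 pooled standard deviation. Reference lines mark
#' the median plane (vertical), the frontal plane (horizontal borders)
#' and the horizontal plane (curved line); they are drawing metadata only.
#'
#' @param object A `spatial_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spatial_map <- function(object, ...) {
  pr <- hammer_project(object)
  bound <- attr(object, "color_bound")
  horiz <- hammer_project(tibble::tibble(
    lateral = rep(seq(-89, 89, by = 2), 2),
    polar = rep(c(0, 180), each = 90)))
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = pmin(pmax(.data$mean, -bound),
                                                   bound)),
                        size = 2) +
    ggplot2::geom_path(data = horiz, colour = "black", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red",
                                    limits = c(-bound, bound),
                                    name = "weight") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Eigenmode %d mean weights",
                                  attr(object, "mode")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot error distributions against mode or coefficient count
#'
#' Median with a first-to-third quartile ribbon per count.
#'
#' @param object An `error_summary` tibble.
#' @param ... Further `error_summary` objects to overlay.
#' @return A ggplot object.
#' @export
autoplot.error_summary <- function(object, ...) {
  extra <- list(...)
  all <- dplyr::bind_rows(purrr::map(
    c(list(object), extra),
    function(e) dplyr::mutate(tibble::as_tibble(e),
                              method = attr(e, "method") %||% "errors")))
  ggplot2::ggplot(all, ggplot2::aes(x = .data$k, colour = .data$method,
                                    fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "number of modes / coefficients",
                  y = "RMS representation error (dB)") +
    ggplot2::theme_minimal()
}

#' Plot leading eigenmode profiles
#'
#' @param object An `eigen_basis`.
#' @param n_modes Number of leading modes shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eigen_basis <- function(object, n_modes = 5, ...) {
  d <- tidy.eigen_basis(object, n_modes = n_modes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency / 1000,
                                  y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "frequency (kHz)", y = "eigenmode value") +
    ggplot2::theme_minimal()
}
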