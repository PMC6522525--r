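#' Voxel occupancy grid
#'
#' A `voxel_grid` is a binary air/solid occupancy array on an isotropic 3D
#' lattice, the geometry input to the FDTD solver. Coordinates are in mm;
#' `origin` is the position of the center of voxel `[1, 1, 1]`.
#'
#' @param occ Logical 3D array, `TRUE` for solid voxels.
#' @param spacing Voxel edge length in mm.
#' @param origin Numeric length-3, mm.
#' @param meta Named list of metadata (e.g. `ear_left`, `ear_right`
#'   positions in mm).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(occ, spacing, origin = c(0, 0, 0), meta = list()) {
  stopifnot(is.array(occ), length(dim(occ)) == 3, is.logical(occ),
            spacing > 0, length(origin) == 3)
  structure(list(occ = occ, spacing = spacing, origin = as.numeric(origin),
                 meta = meta),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$occ)
  cat(sprintf("<voxel_grid: %d x %d x %d voxels, %.3g mm spacing, %d solid>\n",
              d[1], d[2], d[3], x$spacing, sum(x$occ)))
  invisible(x)
}

#' Voxel center coordinates along each axis (mm)
#' @param grid A `voxel_grid`.
#' @return List of three numeric vectors (x, y, z coordinates).
#' @export
voxel_axes <- function(grid) {
  d <- dim(grid$occ)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 1) * grid$spacing)
}

# Symmetric coordinate axis covering [-half, half] with a voxel centered at 0.
.sym_axis <- function(half, spacing) {
  n <- ceiling(half / spacing)
  (-n:n) * spacing
}

#' Voxelize a sphere head (solver validation geometry)
#'
#' Marks as solid exactly the voxels whose centers lie within `radius` of
#' the grid center. The grid extends `clearance` mm beyond the sphere on
#' all sides (absorbing layers are added separately by the solver).
#'
#' @param radius Sphere radius in mm; must be at least `4 * spacing`.
#' @param spacing Voxel edge length in mm.
#' @param clearance Air margin around the sphere in mm (default 30, i.e.
#'   about 3 cm).
#' @param ear Unit direction (length-3) from the center to the surface
#'   point treated as the blocked ear-canal entrance; default +y (left).
#' @return A `voxel_grid` with `meta$ear_left` at the surface point.
#' @examples
#' g <- make_sphere_head(60, 4)
#' sum(g$occ) * g$spacing^3 / (4 / 3 * pi * 60^3)  # ~1
#' @export
make_sphere_head <- function(radius, spacing, clearance = 30,
                             ear = c(0, 1, 0)) {
  if (radius < 4 * spacing) {
    stop("degenerate geometry: radius must be at least 4 * spacing")
  }
  stopifnot(clearance >= 0)
  ax <- .sym_axis(radius + clearance, spacing)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  occ <- r2 <= radius^2
  ear <- ear / sqrt(sum(ear^2))
  voxel_grid(occ, spacing, origin = c(ax[1], ax[1], ax[1]),
             meta = list(ear_left = radius * ear, radius = radius))
}

#' Parametric head geometry parameters
#'
#' An ellipsoidal head with two thin pinna flanges. The pinna flare angle
#' is the laterally outward tilt of the pinna plate from a parasagittal
#' plane (hinged at its height axis); the rotation angle is the backward
#' tilt of the plate's major axis from vertical. Defaults follow typical
#' adult values (flare 23 degrees, rotation 13 degrees).
#'
#' @param head_radii Ellipsoid semi-axes in mm: front-back (x),
#'   interaural (y), vertical (z).
#' @param pinna_flare_deg Flare angle, degrees, in \[0, 90).
#' @param pinna_rotation_deg Rotation angle, degrees, in \[0, 90).
#' @param pinna_size Height and width of the pinna plate, mm.
#' @param pinna_thickness_mm Plate thickness, mm.
#' @param concha_radius_mm Radius of the hemispherical concha depression
#'   carved into the plate at the ear-canal entrance, mm.
#' @param seed Integer stored with the parameters (for reproducibility
#'   metadata only; the geometry itself is deterministic).
#' @return A list of class `head_params`.
#' @export
head_params <- function(head_radii = c(95, 75, 110),
                        pinna_flare_deg = 23,
                        pinna_rotation_deg = 13,
                        pinna_size = c(60, 50),
                        pinna_thickness_mm = 4,
                        concha_radius_mm = 9,
                        seed = 1L) {
  stopifnot(length(head_radii) == 3, all(head_radii > 0),
            pinna_flare_deg >= 0, pinna_flare_deg < 90,
            pinna_rotation_deg >= 0, pinna_rotation_deg < 90,
            all(pinna_size > 0), pinna_thickness_mm > 0)
  structure(list(head_radii = as.numeric(head_radii),
                 pinna_flare_deg = pinna_flare_deg,
                 pinna_rotation_deg = pinna_rotation_deg,
                 pinna_size = as.numeric(pinna_size),
                 pinna_thickness_mm = pinna_thickness_mm,
                 concha_radius_mm = concha_radius_mm,
                 seed = as.integer(seed)),
            class = "head_params")
}

# Rotation matrix about a unit axis (Rodrigues).
.rot_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Voxelize a parametric head with pinna flanges
#'
#' Builds an ellipsoidal head with two thin pinna plates anchored at the
#' ear-canal entrances on the interaural axis. Each plate's major axis is
#' tilted backward by the rotation angle and the plate is flared laterally
#' outward by the flare angle. A hemispherical concha depression is carved
#' from the plate next to the canal entrance; the entrance plane itself is
#' the (solid) head surface, i.e. the canal is blocked. With identical
#' left/right parameters the grid is mirror-symmetric about the median
#' plane.
#'
#' @param params A [head_params()] object.
#' @param spacing Voxel edge length in mm.
#' @param clearance Required air margin in mm (default 30).
#' @param extent Optional fixed half-extents of the grid (mm, length 3);
#'   by default the grid is sized to fit the head plus clearance. A fixed
#'   extent that leaves less than `clearance` around the geometry (e.g. a
#'   pinna flange reaching the boundary) raises a clearance error.
#' @return A `voxel_grid` with `meta$ear_left` / `meta$ear_right` set to
#'   the ear-canal entrance centers (mm).
#' @export
make_parametric_head <- function(params = head_params(), spacing = 4,
                                 clearance = 30, extent = NULL) {
  stopifnot(inherits(params, "head_params"), spacing > 0)
  r <- params$head_radii
  hs <- params$pinna_size[1]   # plate height (along major axis)
  ws <- params$pinna_size[2]   # plate width (front-back)
  th <- max(params$pinna_thickness_mm, spacing) / 2
  phi <- params$pinna_flare_deg * pi / 180
  rho <- params$pinna_rotation_deg * pi / 180

  # plate frames per side (s = +1 left, -1 right)
  frames <- lapply(c(1, -1), function(s) {
    # major axis: vertical tilted backward (toward -x) by rho
    h1 <- c(-sin(rho), 0, cos(rho))
    R2 <- .rot_axis(h1, -s * phi)    # flare: hinge about the major axis
    list(s = s,
         h = as.numeric(R2 %*% h1),
         v = as.numeric(R2 %*% c(cos(rho), 0, sin(rho))),  # width axis
         n = as.numeric(R2 %*% c(0, s, 0)),                # outward normal
         anchor = c(0, s * r[2], 0))
  })

  # grid extents: ellipsoid plus plate bounding box plus clearance
  plate_pts <- do.call(rbind, lapply(frames, function(fr) {
    corners <- as.matrix(expand.grid(u = c(-0.35, 0.65) * hs,
                                     v = c(-0.8, 0.2) * ws,
                                     w = c(-th, th)))
    t(fr$anchor + t(corners %*% rbind(fr$h, fr$v, fr$n)))
  }))
  half <- extent %||% (pmax(r, apply(abs(plate_pts), 2, max)) + clearance)
  stopifnot(length(half) == 3, all(half > 0))
  ax <- lapply(half, .sym_axis, spacing = spacing)
  d <- lengths(ax)

  X <- array(ax[[1]], d)
  Y <- array(rep(ax[[2]], each = d[1]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)

  occ <- (X / r[1])^2 + (Y / r[2])^2 + (Z / r[3])^2 <= 1
  for (fr in frames) {
    px <- X - fr$anchor[1]; py <- Y - fr$anchor[2]; pz <- Z - fr$anchor[3]
    u <- px * fr$h[1] + py * fr$h[2] + pz * fr$h[3]
    v <- px * fr$v[1] + py * fr$v[2] + pz * fr$v[3]
    w <- px * fr$n[1] + py * fr$n[2] + pz * fr$n[3]
    plate <- u >= -0.35 * hs & u <= 0.65 * hs &
             v >= -0.8 * ws & v <= 0.2 * ws & abs(w) <= th
    # concha bowl carved from the plate just outside the canal entrance
    cc <- fr$anchor + fr$n * (params$concha_radius_mm / 2)
    bowl <- (X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2 <=
      params$concha_radius_mm^2
    occ <- occ | (plate & !bowl)
  }

  # clearance check: no solid voxel within `clearance` of the boundary
  idx <- which(occ, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("degenerate geometry: no solid voxels")
  for (a in 1:3) {
    co <- ax[[a]][range(idx[, a])]
    if (co[1] - ax[[a]][1] < clearance - spacing ||
        ax[[a]][d[a]] - co[2] < clearance - spacing) {
      stop("clearance error: head geometry extends into the boundary margin")
    }
  }

  voxel_grid(occ, spacing,
             origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]),
             meta = list(ear_left = c(0, r[2], 0),
                         ear_right = c(0, -r[2], 0),
                         params = params))
}

#' Write a voxel grid as plain text
#'
#' Header lines (dimensions, spacing, origin, ear metadata) followed by a
#' run-length encoding of the column-major flattened occupancy.
#'
#' @param grid A `voxel_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  rl <- rle(as.integer(grid$occ))
  ears <- format(c(grid$meta$ear_left %||% rep(NA_real_, 3),
                   grid$meta$ear_right %||% rep(NA_real_, 3)),
                 digits = 17, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("hrtfeigen-voxel 1",
               paste("dims", paste(dim(grid$occ), collapse = " ")),
               paste("spacing", format(grid$spacing, digits = 17)),
               paste("origin", paste(format(grid$origin, digits = 17,
                                            trim = TRUE),
                                     collapse = " ")),
               paste("ears", paste(ears, collapse = " ")),
               paste("rle", length(rl$lengths)),
               paste(rl$values, rl$lengths, collapse = " ")), con)
  invisible(path)
}

#' Read a voxel grid written by [write_voxel_grid()]
#' @param path File path.
#' @return A `voxel_grid`.
#' @export
read_voxel_grid <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "hrtfeigen-voxel 1") stop("not a hrtfeigen voxel file")
  fld <- function(i, key) {
    parts <- strsplit(trimws(ln[i]), "[ \t]+")[[1]]
    stopifnot(parts[1] == key)
    suppressWarnings(as.numeric(parts[-1]))
  }
  d <- as.integer(fld(2, "dims"))
  spacing <- fld(3, "spacing")
  origin <- fld(4, "origin")
  ears <- fld(5, "ears")
  toks <- as.numeric(strsplit(ln[7], " ")[[1]])
  vals <- toks[seq(1, length(toks), by = 2)]
  lens <- toks[seq(2, length(toks), by = 2)]
  occ <- array(as.logical(inverse.rle(list(values = vals, lengths = lens))), d)
  meta <- list()
  if (!anyNA(ears[1:3])) meta$ear_left <- ears[1:3]
  if (!anyNA(ears[4:6])) meta$ear_right <- ears[4:6]
  voxel_grid(occ, spacing, origin, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
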