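#' Spherocylinder cell geometry
#'
#' Constructs the rigid-body model of a single rod-shaped bacterium: a
#' cylinder of radius `radius` capped by two hemispheres, with pole-to-pole
#' length `length` (caps included). The medial axis runs through `center`
#' at angle `axis_angle` in the image plane; the third dimension (optical
#' axis) is orthogonal to that plane. All membrane points lie at distance
#' `radius` from the medial-axis segment.
#'
#' @param length Pole-to-pole cell length, µm. Must satisfy
#'   `length >= 2 * radius`.
#' @param radius Cell radius, µm (> 0).
#' @param center Numeric length-2, in-plane position of the cell center, µm.
#' @param axis_angle Orientation of the medial axis in the image plane,
#'   radians.
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry(length = 3, radius = 0.4)
#' cell_volume(geom)
#' @export
cell_geometry <- function(length = 3, radius = 0.4, center = c(0, 0),
                          axis_angle = 0) {
  stopifnot(is.numeric(length), is.numeric(radius), is.numeric(center),
            base::length(center) == 2, is.numeric(axis_angle))
  if (radius <= 0) stop("radius must be > 0")
  if (length < 2 * radius) stop("length must be >= 2 * radius")
  structure(
    list(length = length, radius = radius, center = as.numeric(center),
         axis_angle = axis_angle,
         half_axis = length / 2 - radius),  # half-length of the medial axis segment
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> length %.2f um, radius %.2f um, center (%.2f, %.2f), angle %.2f rad\n",
    x$length, x$radius, x$center[1], x$center[2], x$axis_angle))
  invisible(x)
}

#' Spherocylinder volume
#'
#' V = pi r^2 (L - 2r) + (4/3) pi r^3.
#'
#' @param geometry A [cell_geometry()].
#' @return Volume in µm³.
#' @export
cell_volume <- function(geometry) {
  r <- geometry$radius
  L <- geometry$length
  pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
}

#' Spherocylinder surface area
#'
#' A = 2 pi r (L - 2r) + 4 pi r^2 (cylinder wall plus two hemispherical
#' caps).
#'
#' @inheritParams cell_volume
#' @return Area in µm².
#' @export
cell_surface_area <- function(geometry) {
  r <- geometry$radius
  L <- geometry$length
  2 * pi * r * (L - 2 * r) + 4 * pi * r^2
}

# --- internal 3-D frame -----------------------------------------------------
# Local frame: medial axis along x, optical axis along z, origin at the cell
# center. Points are n x 3 matrices. Conversion to the image plane applies
# the in-plane rotation and translation and drops z (orthographic
# projection).

#' @noRd
local_to_image <- function(geometry, pts) {
  a <- geometry$axis_angle
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- pts[, 1:2, drop = FALSE] %*% t(R)
  cbind(xy[, 1] + geometry$center[1], xy[, 2] + geometry$center[2])
}

#' @noRd
image_to_local <- function(geometry, xy) {
  a <- geometry$axis_angle
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  xy0 <- cbind(xy[, 1] - geometry$center[1], xy[, 2] - geometry$center[2])
  xy0 %*% t(R)
}

# Closest point on the medial axis segment (local frame), vectorised.
#' @noRd
axis_foot <- function(geometry, pts) {
  h <- geometry$half_axis
  cbind(pmin(pmax(pts[, 1], -h), h), 0, 0)
}

# Project arbitrary local 3-D points radially onto the membrane surface.
#' @noRd
project_to_surface <- function(geometry, pts) {
  foot <- axis_foot(geometry, pts)
  d <- pts - foot
  nr <- sqrt(rowSums(d^2))
  # points exactly on the axis have no defined normal; nudge along +z
  degen <- nr < 1e-12
  if (any(degen)) {
    d[degen, ] <- matrix(rep(c(0, 0, 1), sum(degen)), ncol = 3, byrow = TRUE)
    nr[degen] <- 1
  }
  foot + d * (geometry$radius / nr)
}

# Outward unit normal at surface points (local frame).
#' @noRd
surface_normal <- function(geometry, pts) {
  foot <- axis_foot(geometry, pts)
  d <- pts - foot
  d / sqrt(rowSums(d^2))
}

#' Sample points uniformly on the membrane surface
#'
#' Area-uniform sampling over the spherocylinder surface (cylinder wall and
#' the two hemispherical caps weighted by their areas), in the cell's local
#' frame (axis = x, optical axis = z).
#'
#' @inheritParams cell_volume
#' @param n Number of points.
#' @return An `n x 3` matrix of local coordinates, µm.
#' @export
sample_surface <- function(geometry, n) {
  r <- geometry$radius
  h <- geometry$half_axis
  a_cyl <- 2 * pi * r * (2 * h)
  a_caps <- 4 * pi * r^2
  on_cyl <- stats::runif(n) < a_cyl / (a_cyl + a_caps)
  pts <- matrix(0, n, 3)
  ncy <- sum(on_cyl)
  if (ncy > 0) {
    phi <- stats::runif(ncy, 0, 2 * pi)
    pts[on_cyl, ] <- cbind(stats::runif(ncy, -h, h), r * cos(phi), r * sin(phi))
  }
  nca <- n - ncy
  if (nca > 0) {
    # uniform on the unit sphere, split into two hemispheres glued to the ends
    v <- matrix(stats::rnorm(3 * nca), nca, 3)
    v <- v / sqrt(rowSums(v^2))
    s <- sample(c(-1, 1), nca, replace = TRUE)
    v[, 1] <- abs(v[, 1]) * s
    pts[!on_cyl, ] <- cbind(s * h + r * v[, 1], r * v[, 2], r * v[, 3])
  }
  pts
}

#' Test whether image-plane points fall inside the projected cell outline
#'
#' The projected outline of a spherocylinder lying in the focal plane is a
#' rectangle with two semicircular end caps (a 2-D stadium).
#'
#' @inheritParams cell_volume
#' @param xy `n x 2` matrix of image-plane coordinates, µm.
#' @return Logical vector.
#' @export
in_cell_outline <- function(geometry, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  loc <- image_to_local(geometry, xy)
  h <- geometry$half_axis
  ax <- pmin(pmax(loc[, 1], -h), h)
  (loc[, 1] - ax)^2 + loc[, 2]^2 <= geometry$radius^2 + 1e-12
}

#' Normalized axial (polar) position of a punctum
#'
#' Distance of a point from the nearer cell pole measured along the medial
#' axis, divided by the cell length: 0 at a pole tip, 0.5 at midcell. Used
#' to quantify the polar preference of condensates.
#'
#' @inheritParams cell_volume
#' @param punctum_center Length-2 image-plane coordinate of the punctum
#'   center, µm; must lie inside the projected cell outline.
#' @return A number in `[0, 0.5]`.
#' @examples
#' geom <- cell_geometry(length = 3, radius = 0.4)
#' punctum_polar_position(c(0, 0), geom)  # midcell -> 0.5
#' @export
punctum_polar_position <- function(punctum_center, geometry) {
  xy <- matrix(as.numeric(punctum_center), ncol = 2)
  if (!in_cell_outline(geometry, xy))
    stop("punctum center lies outside the cell outline")
  loc <- image_to_local(geometry, xy)
  L <- geometry$length
  # axial coordinate measured from the nearer pole tip, clamped to [0, L/2]
  d_pole <- pmin(pmax(L / 2 - abs(loc[, 1]), 0), L / 2)
  as.numeric(d_pole / L)
}
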