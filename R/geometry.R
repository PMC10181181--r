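# Grid geometry, coordinate conventions, and the two shared primitives
# (isotropic 2D Gaussian, polar bias index).
#
# Coordinate frame: column index j runs along the anterior->posterior (AP)
# axis, row index i along the medial->lateral (ML) axis.  Pixel (i, j) sits at
# ((j - 0.5) * pixel_um, (i - 0.5) * pixel_um) so the default nose position
# [250, 1000] um lies in the anterior quarter at the ML midline.  Directions
# are radians in (-pi, pi]; orientations are degrees in [0, 180).

#' Lattice geometry of the two-layer retina-SC model
#'
#' Describes the square lattice shared by the model retina, the superior
#' colliculus (SC) and (after scaling) the visual field.  Under the identity
#' retinotopy a retina pixel, the SC pixel with the same index, and the
#' visual-field point at \code{vf_scale_m} times its position all refer to the
#' same site.
#'
#' @param n_rows,n_cols Lattice size (rows run along the medial-lateral axis,
#'   columns along the anterior-posterior axis).
#' @param pixel_um Pixel pitch in micrometres.
#' @param nose_um Putative nose position (center of vision) in SC coordinates,
#'   as \code{c(AP, ML)} in micrometres.
#' @param vf_scale_m Scale factor from retina pixels to visual-field pixels.
#' @param vf_deg_per_pixel Degrees of visual angle per visual-field pixel.
#'
#' @return An object of class \code{grid_spec}.
#' @examples
#' g <- grid_spec()
#' head(pixel_positions(g))
#' @export
grid_spec <- function(n_rows = 40, n_cols = 40, pixel_um = 50,
                      nose_um = c(250, 1000), vf_scale_m = 2.5,
                      vf_deg_per_pixel = 0.6) {
  stopifnot(n_rows >= 2, n_cols >= 2, pixel_um > 0,
            length(nose_um) == 2, vf_scale_m > 0, vf_deg_per_pixel > 0)
  if (nose_um[1] < 0 || nose_um[1] > n_cols * pixel_um ||
      nose_um[2] < 0 || nose_um[2] > n_rows * pixel_um)
    stop("'nose_um' must lie within the grid extent")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_um = pixel_um, nose_um = as.numeric(nose_um),
                 vf_scale_m = vf_scale_m,
                 vf_deg_per_pixel = vf_deg_per_pixel),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d lattice, %g um/pixel\n",
              x$n_rows, x$n_cols, x$pixel_um))
  cat(sprintf("  nose (AP, ML): [%g, %g] um; VF scale m = %g (%g deg/VF px)\n",
              x$nose_um[1], x$nose_um[2], x$vf_scale_m, x$vf_deg_per_pixel))
  invisible(x)
}

n_pixels <- function(grid) grid$n_rows * grid$n_cols

#' Pixel centre positions
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param unit \code{"um"} (default) or \code{"px"} (pixel units).
#' @return An \code{n_rows * n_cols} by 2 matrix of \code{(AP, ML)} centre
#'   positions, rows in column-major pixel-index order.
#' @export
pixel_positions <- function(grid, unit = c("um", "px")) {
  unit <- match.arg(unit)
  i <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  j <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  p <- cbind(ap = j - 0.5, ml = i - 0.5)
  if (unit == "um") p <- p * grid$pixel_um
  p
}

#' @rdname pixel_positions
#' @param i,j Row and column indices.
#' @export
pixel_index <- function(grid, i, j) (j - 1L) * grid$n_rows + i

#' @rdname pixel_positions
#' @param idx Linear (column-major) pixel index.
#' @export
pixel_rc <- function(grid, idx) {
  idx <- as.integer(idx)
  cbind(i = (idx - 1L) %% grid$n_rows + 1L,
        j = (idx - 1L) %/% grid$n_rows + 1L)
}

#' Isotropic two-dimensional Gaussian density
#'
#' \code{gaussian2d(p, c, sigma)} returns
#' \eqn{(2\pi\sigma^2)^{-1} \exp(-\|p - c\|^2 / 2\sigma^2)}.
#'
#' @param point A 2-vector, or a matrix with one point per row.
#' @param center A 2-vector.
#' @param sigma Positive spread.
#' @return Density value(s); strictly positive, maximal at
#'   \code{point == center}.
#' @examples
#' gaussian2d(c(0, 0), c(0, 0), 1)  # 1 / (2 * pi)
#' @export
gaussian2d <- function(point, center, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  d2 <- (point[, 1] - center[1])^2 + (point[, 2] - center[2])^2
  exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
}

#' Discrete direction distribution
#'
#' A probability distribution over a finite set of propagation directions,
#' used for wave-heading ensembles and the polar bias index.
#'
#' @param angles Directions in radians in \code{(-pi, pi]}; must be distinct.
#' @param probabilities Nonnegative weights summing to 1 (within 1e-12).
#' @return An object of class \code{direction_distribution}.
#' @export
direction_distribution <- function(angles, probabilities) {
  angles <- wrap_angle(as.numeric(angles))
  probabilities <- as.numeric(probabilities)
  if (length(angles) != length(probabilities))
    stop("'angles' and 'probabilities' must have equal length")
  if (anyDuplicated(round(angles, 12)))
    stop("'angles' must be distinct")
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-12)
    stop("'probabilities' must be nonnegative and sum to 1 within 1e-12")
  structure(list(angles = angles, probabilities = probabilities),
            class = "direction_distribution")
}

#' Polar bias index of a direction distribution
#'
#' The resultant-vector magnitude \eqn{B = |\sum_\theta p(\theta)
#' e^{i\theta}|}: 0 for a balanced (e.g. uniform) distribution, 1 for a point
#' mass.  Invariant to a global rotation of all angles.
#'
#' @param d A \code{\link{direction_distribution}}, or a numeric vector of
#'   angles (radians) in which case \code{probabilities} must be supplied.
#' @param probabilities Optional weights when \code{d} is a plain vector.
#' @return A scalar in \code{[0, 1]}.
#' @examples
#' polar_bias_index(direction_distribution(2 * pi * (1:8) / 8 - pi, rep(1/8, 8)))
#' @export
polar_bias_index <- function(d, probabilities = NULL) {
  if (!inherits(d, "direction_distribution"))
    d <- direction_distribution(d, probabilities)
  min(1, Mod(sum(d$probabilities * exp(1i * d$angles))))
}

#' Acute difference between two orientations
#'
#' Orientations are degree-valued and periodic modulo 180; the acute
#' difference is \code{min(|d| mod 180, 180 - |d| mod 180)}, in
#' \code{[0, 90]}.
#'
#' @param theta1,theta2 Orientations in degrees (recycled to common length).
#' @return Acute difference(s) in degrees.
#' @examples
#' acute_orientation_diff(10, 170)  # 20
#' @export
acute_orientation_diff <- function(theta1, theta2) {
  d <- abs(theta1 - theta2) %% 180
  pmin(d, 180 - d)
}

#' Concentric angle of a position about the nose
#'
#' The orientation of the tangent to the circle centred at the nose position
#' passing through \code{pos}: the radial orientation plus 90 degrees, modulo
#' 180.  Undefined at the nose itself.
#'
#' @param pos SC position(s) in micrometres: a 2-vector or a matrix with one
#'   position per row, as \code{(AP, ML)}.
#' @param nose_um Nose position, \code{c(AP, ML)} in micrometres.
#' @return Orientation(s) in degrees in \code{[0, 180)}.
#' @export
concentric_angle <- function(pos, nose_um) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  v <- sweep(pos, 2, nose_um)
  if (any(rowSums(v^2) == 0))
    stop("concentric angle undefined at the nose position")
  radial <- (atan2(v[, 2], v[, 1]) * 180 / pi) %% 180
  (radial + 90) %% 180
}

# wrap radians into (-pi, pi]
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# direction of 2-vector(s) as arg(v_x + i v_y)
vector_angle <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  atan2(v[, 2], v[, 1])
}
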