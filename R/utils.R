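#' @keywords internal
"_PACKAGE"

# Small vector helpers shared across the package. All geometry is carried out
# in world coordinates, in millimeters.

vec_norm <- function(v) sqrt(sum(v * v))

#' Normalize a 3-vector to unit length
#' @param v numeric length-3 vector.
#' @return unit vector.
#' @export
unitize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Marker for an undefined axis
#'
#' Operations that return an orientation axis (e.g. the endpoint orientation
#' of a closed loop) return this marker when the axis is not defined.
#'
#' @return length-3 vector of `NA_real_`.
#' @export
undefined_axis <- function() rep(NA_real_, 3)

#' Test whether an axis value is the undefined-axis marker
#' @param v candidate axis.
#' @return logical scalar.
#' @export
is_undefined_axis <- function(v) is.numeric(v) && length(v) == 3 && all(is.na(v))

stopifnot_unit <- function(v, name = "vector", tol = 1e-6) {
  if (!is.numeric(v) || length(v) != 3 || any(!is.finite(v)))
    stop(name, " must be a finite numeric 3-vector", call. = FALSE)
  if (abs(vec_norm(v) - 1) > tol)
    stop(name, " must have unit norm (got ", format(vec_norm(v)), ")", call. = FALSE)
  invisible(v)
}

# Rotation taking unit vector `from` onto unit vector `to` (Rodrigues).
rotation_between <- function(from, to) {
  from <- unitize(from); to <- unitize(to)
  v <- cross3(from, to)
  s <- vec_norm(v)
  c_ <- sum(from * to)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate pi about any axis orthogonal to `from`
    ax <- if (abs(from[1]) < 0.9) unitize(cross3(from, c(1, 0, 0))) else
      unitize(cross3(from, c(0, 1, 0)))
    return(rotation_axis_angle(ax, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

rotation_axis_angle <- function(axis, angle) {
  axis <- unitize(axis)
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Clip |n.t| values to [0,1] after checking they are within floating-point
# slack of the valid range; values further out signal non-unit inputs upstream.
check_dot <- function(dot, tol = 1e-9) {
  if (any(!is.finite(dot)) || any(dot < -tol) || any(dot > 1 + tol))
    stop("|n.t| values must lie in [0, 1]; got values outside by more than ",
         format(tol), " (non-unit axes upstream?)", call. = FALSE)
  clamp01(dot)
}
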