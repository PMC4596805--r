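# Orientation-dependent opacity.
#
# Opacity alpha in [0,1] (1 = fully opaque) is a function of the alignment
# |n.t| between a streamline orientation n (local per point, or one global
# axis per streamline) and a chosen opacity axis t. Two one-parameter power
# functions cover the common cases -- fade pathways parallel to t, or show
# only pathways parallel to t -- and a two-parameter clamped linear ramp in
# the angle theta = acos|n.t| allows independent control of steepness and
# cut-off.

#' Decreasing power opacity function
#'
#' `alpha = (1 - |n.t|)^c`: fully opaque when the orientation is orthogonal to
#' the opacity axis, fully transparent when parallel. Larger `c` makes the
#' fall-off steeper, so more segments become transparent.
#'
#' @param dot `|n.t|` values in \[0, 1\].
#' @param c positive exponent tuning the steepness (default 3).
#' @return opacities in \[0, 1\].
#' @export
power_decreasing <- function(dot, c = 3) {
  check_exponent(c)
  (1 - check_dot(dot))^c
}

#' Increasing power opacity function
#'
#' `alpha = |n.t|^c`: fully opaque when the orientation is parallel to the
#' opacity axis, fully transparent when orthogonal. Used to display only the
#' pathways running along a chosen direction.
#'
#' @inheritParams power_decreasing
#' @return opacities in \[0, 1\].
#' @export
power_increasing <- function(dot, c = 3) {
  check_exponent(c)
  check_dot(dot)^c
}

check_exponent <- function(c) {
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c <= 0)
    stop("exponent c must be a single positive number", call. = FALSE)
}

#' Clamped linear opacity ramp in the angle
#'
#' `alpha(theta) = a * theta + b` for angles `theta = acos|n.t|` in
#' \[0, pi/2\], clamped to 1 for `theta > (1 - b)/a` and to 0 for
#' `theta < -b/a`. Unlike the power functions, slope `a` and intercept `b`
#' tune the steepness and the cut-off independently.
#'
#' @param theta angles in radians, in \[0, pi/2\].
#' @param a slope (must be positive; radians^-1). Default `2/pi` which with
#'   `b = 0` ramps from 0 at theta = 0 to 1 at theta = pi/2.
#' @param b intercept. Default 0.
#' @return opacities in \[0, 1\].
#' @export
linear_theta <- function(theta, a = 2 / pi, b = 0) {
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a == 0)
    stop("linear opacity function requires a non-zero slope a", call. = FALSE)
  if (a < 0)
    stop("linear opacity function requires a positive slope a", call. = FALSE)
  if (any(!is.finite(theta)) || any(theta < -1e-9) || any(theta > pi / 2 + 1e-9))
    stop("theta must lie in [0, pi/2]", call. = FALSE)
  clamp01(a * theta + b)
}

#' Opacity configuration
#'
#' Bundles the options of orientation-dependent transparency rendering: the
#' orientation scale (local per point, or global per streamline via the
#' endpoint chord or the scatter-matrix axis), how the opacity axis `t` is
#' chosen (fixed, or coupled to the camera's viewing axis), which opacity
#' function maps `|n.t|` to alpha, and an optional dispersion gate `T_cl`
#' below which a streamline is rendered fully opaque regardless of its
#' orientation (so strongly curved pathways stay visible in every view).
#'
#' @param scale `"local"`, `"global_endpoints"` or `"global_scatter"`.
#' @param axis_mode `"fixed"` (supply `t`) or `"view"` (use the camera's
#'   viewing axis).
#' @param t unit opacity axis; required when `axis_mode = "fixed"`.
#' @param fun `"power_decreasing"`, `"power_increasing"` or `"linear_theta"`.
#' @param c exponent for the power functions (default 3).
#' @param a,b slope and intercept for `linear_theta` (defaults `2/pi`, 0).
#' @param T_cl optional threshold in \[0, 1\] on the linear coefficient c_l;
#'   streamlines with `c_l < T_cl` get alpha = 1. `NULL` disables the gate.
#' @return object of class `opacity_config`.
#' @export
opacity_config <- function(scale = c("local", "global_endpoints", "global_scatter"),
                           axis_mode = c("fixed", "view"), t = NULL,
                           fun = c("power_decreasing", "power_increasing",
                                   "linear_theta"),
                           c = 3, a = 2 / pi, b = 0, T_cl = NULL) {
  scale <- match.arg(scale)
  axis_mode <- match.arg(axis_mode)
  fun <- match.arg(fun)
  if (axis_mode == "fixed") {
    if (is.null(t)) stop("axis_mode = 'fixed' requires an opacity axis t", call. = FALSE)
    stopifnot_unit(t, "opacity axis t")
  } else if (!is.null(t)) {
    stop("axis_mode = 'view' derives t from the camera; do not supply t", call. = FALSE)
  }
  if (fun != "linear_theta") check_exponent(c)
  if (fun == "linear_theta" && (!is.numeric(a) || a <= 0))
    stop("linear_theta requires a positive slope a", call. = FALSE)
  if (!is.null(T_cl)) {
    if (!is.numeric(T_cl) || length(T_cl) != 1 || is.na(T_cl) ||
        T_cl < 0 || T_cl > 1)
      stop("T_cl must be a single value in [0, 1]", call. = FALSE)
  }
  structure(list(scale = scale, axis_mode = axis_mode, t = t, fun = fun,
                 c = c, a = a, b = b, T_cl = T_cl),
            class = "opacity_config")
}

apply_opacity_fun <- function(config, dot) {
  switch(config$fun,
    power_decreasing = power_decreasing(dot, config$c),
    power_increasing = power_increasing(dot, config$c),
    linear_theta = linear_theta(acos(check_dot(dot)), config$a, config$b)
  )
}

#' Assign orientation-dependent opacity to a tractogram
#'
#' Computes an `"alpha"` scalar channel. With `scale = "local"` each point
#' gets its own alpha from its local orientation; with a global scale one
#' alpha per streamline (from the endpoint chord or the scatter-matrix first
#' eigenvector) is broadcast to all its points, which preserves the continuous
#' appearance of each pathway. When `config$T_cl` is set, streamlines whose
#' linear coefficient c_l falls below the threshold are made fully opaque.
#' Streamlines whose global axis is undefined (closed loops under the
#' endpoints method) also get alpha = 1, with a report.
#'
#' @param tg a [tractogram()].
#' @param config an [opacity_config()].
#' @param view_axis unit viewing axis; required iff
#'   `config$axis_mode == "view"`.
#' @return the tractogram with an `"alpha"` channel.
#' @export
assign_opacity <- function(tg, config, view_axis = NULL) {
  stopifnot(inherits(tg, "tractogram"), inherits(config, "opacity_config"))
  if (config$axis_mode == "view") {
    if (is.null(view_axis))
      stop("axis_mode = 'view' requires a view_axis", call. = FALSE)
    stopifnot_unit(view_axis, "view_axis")
    t_axis <- view_axis
  } else {
    t_axis <- config$t
  }
  gate <- !is.null(config$T_cl)
  n_undef <- 0L
  alpha <- vector("list", n_streamlines(tg))
  for (i in seq_len(n_streamlines(tg))) {
    sl <- tg$streamlines[[i]]
    npt <- nrow(sl)
    if (gate || config$scale == "global_scatter") {
      summ <- streamline_summary(sl)
    }
    if (gate && summ$c_l < config$T_cl) {
      alpha[[i]] <- rep(1, npt)
      next
    }
    if (config$scale == "local") {
      dots <- abs(local_orientations(sl) %*% t_axis)[, 1]
      alpha[[i]] <- apply_opacity_fun(config, dots)
    } else {
      axis <- if (config$scale == "global_endpoints") endpoint_orientation(sl)
              else summ$s1
      if (is_undefined_axis(axis)) {
        n_undef <- n_undef + 1L
        alpha[[i]] <- rep(1, npt)
      } else {
        alpha[[i]] <- rep(apply_opacity_fun(config, abs(sum(axis * t_axis))), npt)
      }
    }
  }
  if (n_undef > 0)
    message("assign_opacity: ", n_undef,
            " streamline(s) with undefined global axis rendered opaque")
  set_scalar_channel(tg, "alpha", alpha)
}

#' Histogram of orientation alignment |n.t|
#'
#' Distribution of the alignment between streamline orientations and an axis
#' `t`, either over all local orientations or over one global orientation per
#' streamline. Useful for choosing an opacity function: the histogram shows
#' which alignments dominate the tractogram for a candidate opacity axis.
#'
#' @param tg a [tractogram()] (non-empty).
#' @param scale `"local"`, `"global_endpoints"` or `"global_scatter"`.
#' @param t unit axis.
#' @param nbins number of equal-width bins on \[0, 1\] (>= 1).
#' @return list with `breaks` (length `nbins + 1`), `counts` (length `nbins`,
#'   summing to the number of contributing orientations), and `n_undefined`
#'   (global orientations skipped because they were undefined).
#' @export
dot_histogram <- function(tg, scale = c("local", "global_endpoints",
                                        "global_scatter"),
                          t, nbins = 20) {
  scale <- match.arg(scale)
  stopifnot(inherits(tg, "tractogram"))
  if (n_streamlines(tg) == 0) stop("empty tractogram", call. = FALSE)
  if (!is.numeric(nbins) || nbins < 1) stop("nbins must be >= 1", call. = FALSE)
  nbins <- as.integer(nbins)
  stopifnot_unit(t, "axis t")
  n_undefined <- 0L
  if (scale == "local") {
    dots <- unlist(lapply(tg$streamlines, function(sl)
      abs(local_orientations(sl) %*% t)[, 1]), use.names = FALSE)
  } else {
    method <- sub("global_", "", scale)
    axes <- lapply(tg$streamlines, global_orientation, method = method)
    ok <- !vapply(axes, is_undefined_axis, logical(1))
    n_undefined <- sum(!ok)
    dots <- vapply(axes[ok], function(ax) abs(sum(ax * t)), numeric(1))
  }
  dots <- check_dot(dots)
  breaks <- seq(0, 1, length.out = nbins + 1L)
  idx <- pmin(pmax(findInterval(dots, breaks, rightmost.closed = TRUE), 1L), nbins)
  counts <- tabulate(idx, nbins)
  list(breaks = breaks, counts = counts, n_undefined = n_undefined)
}
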