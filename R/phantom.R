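# Synthetic fiber phantoms.
#
# Deterministic generators for the geometric regimes that matter when judging
# orientation-dependent transparency: straight bundles (corticospinal-tract
# like), planar arcs (U-shaped, callosal-like; a 90 degree arc has linear
# coefficient 2/pi and a 180 degree arc has c_l = 0), helices, and two
# straight bundles crossing at a set angle. Per-streamline principal axes can
# be jittered with Watson-distributed angular noise to emulate the dispersion
# of real bundles.

#' Generate a synthetic fiber phantom
#'
#' Builds a [tractogram()] of a chosen shape with reproducible randomness.
#' Ground truth (shape, true axis/axes, bundle membership, parameters) is
#' attached as attribute `"ground_truth"`.
#'
#' Shapes:
#' * `"straight"`: parallel lines along +z, offset within a square bundle
#'   cross-section of side `spread_mm`.
#' * `"arc"`: planar circular arcs of `arc_angle_deg` degrees and radius
#'   `radius_mm` in the xy-plane (chord along x), stacked within the spread.
#' * `"helix"`: constant-pitch helices around +z with `helix_turns` turns
#'   over an axial length of `length_mm`.
#' * `"crossing"`: two straight bundles in the xy-plane crossing at
#'   `crossing_angle_deg`; bundle A runs along +x, bundle B along the rotated
#'   axis. Bundle membership (1 or 2) is in the ground truth.
#'
#' With a finite `jitter_kappa`, each streamline's principal axis (line
#' direction, arc plane normal, or helix axis) is drawn from a bipolar Watson
#' distribution around the nominal axis; `jitter_kappa = Inf` (the default)
#' produces exact geometry so closed-form orientation statistics hold.
#'
#' @param shape one of `"straight"`, `"arc"`, `"helix"`, `"crossing"`.
#' @param n_streamlines number of streamlines (>= 1).
#' @param points_per_streamline points per streamline (>= 2).
#' @param length_mm streamline (or axial) length in mm.
#' @param arc_angle_deg arc angle in degrees, in (0, 360).
#' @param radius_mm arc/helix radius in mm.
#' @param spread_mm transverse extent of the bundle in mm.
#' @param crossing_angle_deg angle between the two crossing bundles, degrees.
#' @param helix_turns number of full turns of the helix.
#' @param jitter_kappa Watson concentration of per-streamline axis jitter;
#'   `Inf` disables jitter.
#' @param seed integer seed fixing all randomness.
#' @return a [tractogram()] with attribute `"ground_truth"`.
#' @export
make_phantom <- function(shape = c("straight", "arc", "helix", "crossing"),
                         n_streamlines = 20, points_per_streamline = 100,
                         length_mm = 80, arc_angle_deg = 90, radius_mm = 30,
                         spread_mm = 10, crossing_angle_deg = 90,
                         helix_turns = 2, jitter_kappa = Inf, seed = 1) {
  shape <- match.arg(shape)
  if (n_streamlines < 1 || points_per_streamline < 2)
    stop("need n_streamlines >= 1 and points_per_streamline >= 2", call. = FALSE)
  if (shape == "arc" && (arc_angle_deg <= 0 || arc_angle_deg >= 360))
    stop("arc_angle_deg must lie in (0, 360)", call. = FALSE)
  if (length_mm <= 0 || radius_mm <= 0 || spread_mm < 0)
    stop("lengths and radii must be positive", call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  n <- n_streamlines
  npt <- points_per_streamline
  jitter_axis <- function(axis) {
    if (is.infinite(jitter_kappa)) return(axis)
    as.vector(sample_watson(1, axis, jitter_kappa))
  }

  streamlines <- vector("list", n)
  bundle <- rep(1L, n)
  true_axes <- NULL

  if (shape == "straight") {
    base <- c(0, 0, 1)
    true_axes <- matrix(base, 1)
    s <- seq(-length_mm / 2, length_mm / 2, length.out = npt)
    for (i in seq_len(n)) {
      off <- c(stats::runif(2, -spread_mm / 2, spread_mm / 2), 0)
      d <- jitter_axis(base)
      streamlines[[i]] <- sweep(outer(s, d), 2, off, "+")
    }
  } else if (shape == "arc") {
    # symmetric about +y so the chord runs along x; plane normal is +z
    half <- arc_angle_deg / 2 * pi / 180
    th <- seq(pi / 2 - half, pi / 2 + half, length.out = npt)
    true_axes <- matrix(c(0, 0, 1), 1)  # nominal plane normal
    for (i in seq_len(n)) {
      r_i <- radius_mm + stats::runif(1, -spread_mm / 2, spread_mm / 2)
      z_i <- stats::runif(1, -spread_mm / 2, spread_mm / 2)
      pts <- cbind(r_i * cos(th), r_i * sin(th), z_i)
      nrm <- jitter_axis(c(0, 0, 1))
      streamlines[[i]] <- pts %*% t(rotation_between(c(0, 0, 1), nrm))
    }
  } else if (shape == "helix") {
    base <- c(0, 0, 1)
    true_axes <- matrix(base, 1)
    t_par <- seq(0, 2 * pi * helix_turns, length.out = npt)
    z <- seq(-length_mm / 2, length_mm / 2, length.out = npt)
    for (i in seq_len(n)) {
      off <- c(stats::runif(2, -spread_mm / 2, spread_mm / 2), 0)
      ph <- stats::runif(1, 0, 2 * pi)
      pts <- cbind(radius_mm * cos(t_par + ph), radius_mm * sin(t_par + ph), z)
      ax <- jitter_axis(base)
      streamlines[[i]] <- sweep(pts %*% t(rotation_between(base, ax)), 2, off, "+")
    }
  } else { # crossing
    phi <- crossing_angle_deg * pi / 180
    axis_a <- c(1, 0, 0)
    axis_b <- c(cos(phi), sin(phi), 0)
    true_axes <- rbind(axis_a, axis_b)
    rownames(true_axes) <- NULL
    n_a <- ceiling(n / 2)
    bundle <- rep(c(1L, 2L), c(n_a, n - n_a))
    s <- seq(-length_mm / 2, length_mm / 2, length.out = npt)
    for (i in seq_len(n)) {
      base <- if (bundle[i] == 1L) axis_a else axis_b
      # offset perpendicular to the bundle axis
      perp1 <- unitize(cross3(base, c(0, 0, 1)))
      perp2 <- c(0, 0, 1)
      off <- stats::runif(1, -spread_mm / 2, spread_mm / 2) * perp1 +
        stats::runif(1, -spread_mm / 2, spread_mm / 2) * perp2
      d <- jitter_axis(base)
      streamlines[[i]] <- sweep(outer(s, d), 2, off, "+")
    }
  }

  tg <- tractogram(streamlines)
  attr(tg, "ground_truth") <- list(
    shape = shape, true_axes = true_axes, bundle = bundle,
    arc_angle_deg = if (shape == "arc") arc_angle_deg else NULL,
    crossing_angle_deg = if (shape == "crossing") crossing_angle_deg else NULL,
    jitter_kappa = jitter_kappa, seed = seed
  )
  tg
}
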