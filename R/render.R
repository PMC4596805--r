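# Software rasterizer for transparent streamline rendering.
#
# The pipeline mirrors what an interactive GL implementation does per frame:
# assign per-point opacities, project points to the image plane, build line
# segments (one per consecutive point pair) colored by directional encoding,
# sort all segments of the whole tractogram back-to-front by their mean
# distance from the eye (painter's algorithm), and composite them with the
# "over" operator. Rasterization is 1-pixel analytic lines without
# antialiasing so renders are bit-reproducible.

#' Camera definition
#'
#' @param eye 3D eye position (mm).
#' @param view_axis unit vector normal to the image plane, pointing from the
#'   eye into the scene.
#' @param up unit up vector; must not be parallel to `view_axis`.
#' @param projection `"orthographic"` (default) or `"perspective"`.
#' @param width,height image size in pixels.
#' @param mm_per_pixel image-plane scale for orthographic projection.
#' @param focal_mm focal length for perspective projection (image-plane mm at
#'   unit depth are `mm_per_pixel * depth / focal_mm` wide).
#' @return object of class `camera`.
#' @export
camera <- function(eye, view_axis, up = c(0, 0, 1),
                   projection = c("orthographic", "perspective"),
                   width = 400, height = 400, mm_per_pixel = 0.5,
                   focal_mm = 100) {
  projection <- match.arg(projection)
  view_axis <- unitize(view_axis)
  up <- unitize(up)
  if (abs(sum(view_axis * up)) > 1 - 1e-9)
    stop("view_axis and up must not be parallel", call. = FALSE)
  right <- unitize(cross3(up, view_axis))
  true_up <- cross3(view_axis, right)
  structure(list(eye = as.numeric(eye), view_axis = view_axis, up = up,
                 right = right, true_up = true_up, projection = projection,
                 width = as.integer(width), height = as.integer(height),
                 mm_per_pixel = mm_per_pixel, focal_mm = focal_mm),
            class = "camera")
}

#' Frame a tractogram automatically
#'
#' Places the eye on the given viewing axis behind the tractogram's bounding
#' sphere and scales the orthographic image plane so everything is in view.
#'
#' @param tg a [tractogram()].
#' @param view_axis desired unit viewing axis.
#' @param width,height image size in pixels.
#' @param margin fractional margin around the bounding sphere.
#' @return a [camera()].
#' @export
auto_camera <- function(tg, view_axis = c(0, 0, 1), width = 400, height = 400,
                        margin = 0.05) {
  pts <- do.call(rbind, tg$streamlines)
  center <- colMeans(pts)
  rad <- sqrt(max(rowSums(sweep(pts, 2, center)^2)))
  rad <- max(rad, 1)
  view_axis <- unitize(view_axis)
  up <- if (abs(view_axis[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  camera(eye = center - view_axis * 2 * rad, view_axis = view_axis, up = up,
         width = width, height = height,
         mm_per_pixel = 2 * rad * (1 + margin) / min(width, height))
}

#' Project world points through a camera
#'
#' @param pts M x 3 matrix of world points (mm).
#' @param cam a [camera()].
#' @return M x 3 matrix with columns `px`, `py` (pixel coordinates, origin at
#'   the image center offset to width/2, height/2) and `dist` (Euclidean
#'   distance from the eye).
#' @export
project_points <- function(pts, cam) {
  rel <- sweep(as.matrix(pts), 2, cam$eye)
  u <- as.vector(rel %*% cam$right)
  w <- as.vector(rel %*% cam$true_up)
  depth <- as.vector(rel %*% cam$view_axis)
  if (cam$projection == "perspective") {
    f <- cam$focal_mm / pmax(depth, 1e-6)
    u <- u * f
    w <- w * f
  }
  px <- u / cam$mm_per_pixel + cam$width / 2
  py <- cam$height / 2 - w / cam$mm_per_pixel
  dist <- sqrt(rowSums(rel * rel))
  cbind(px = px, py = py, dist = dist)
}

#' Build renderable segments from a tractogram
#'
#' One segment per consecutive point pair. Segment opacity is the arithmetic
#' mean of its two endpoint alphas (from the `"alpha"` channel; 1 when the
#' channel is absent); segment color is the directional encoding
#' ([dec_color()]) of its normalized endpoint difference; `mean_depth` is the
#' mean of the two endpoints' distances from the eye.
#'
#' @param tg a [tractogram()], typically after [assign_opacity()].
#' @param cam a [camera()].
#' @return data frame with columns `x0, y0, x1, y1, r, g, b, alpha,
#'   mean_depth`.
#' @export
tract_segments <- function(tg, cam) {
  stopifnot(inherits(tg, "tractogram"), inherits(cam, "camera"))
  alpha_ch <- tg$scalars[["alpha"]]
  segs <- vector("list", n_streamlines(tg))
  for (i in seq_len(n_streamlines(tg))) {
    sl <- tg$streamlines[[i]]
    n <- nrow(sl)
    proj <- project_points(sl, cam)
    d <- sl[-1, , drop = FALSE] - sl[-n, , drop = FALSE]
    dn <- d / sqrt(rowSums(d * d))
    a <- if (is.null(alpha_ch)) rep(1, n) else alpha_ch[[i]]
    segs[[i]] <- data.frame(
      x0 = proj[-n, "px"], y0 = proj[-n, "py"],
      x1 = proj[-1, "px"], y1 = proj[-1, "py"],
      r = abs(dn[, 1]), g = abs(dn[, 2]), b = abs(dn[, 3]),
      alpha = (a[-n] + a[-1]) / 2,
      mean_depth = (proj[-n, "dist"] + proj[-1, "dist"]) / 2
    )
  }
  do.call(rbind, segs)
}

#' Directionally encoded color of an orientation
#'
#' Standard diffusion-MRI color convention: RGB = (|n_x|, |n_y|, |n_z|), i.e.
#' red for left-right, green for antero-posterior, blue for inferior-superior.
#'
#' @param n unit 3-vector.
#' @return numeric RGB triple in \[0, 1\].
#' @export
dec_color <- function(n) {
  stopifnot_unit(n, "orientation")
  abs(n)
}

#' Depth-sort segments back-to-front
#'
#' Orders segments by decreasing mean distance from the point of observation
#' (painter's algorithm). The sort is stable: equal depths preserve input
#' order.
#'
#' @param segments segment data frame from [tract_segments()].
#' @param eye ignored when segments already carry `mean_depth` (kept in the
#'   signature so callers can re-sort after moving the eye by rebuilding
#'   segments).
#' @return the segments reordered far-to-near.
#' @export
depth_sort_segments <- function(segments, eye = NULL) {
  if (any(!is.finite(segments$mean_depth)))
    stop("segment depths must be finite", call. = FALSE)
  segments[order(-segments$mean_depth, seq_len(nrow(segments))), , drop = FALSE]
}

#' Alpha-composite pre-sorted segments into a raster image
#'
#' Each segment is rasterized as a 1-pixel line and blended with the standard
#' "over" operator, `C <- alpha * C_seg + (1 - alpha) * C`, in the given
#' (back-to-front) order. No antialiasing, so output is deterministic.
#'
#' @param segments segment data frame, already sorted back-to-front.
#' @param width,height image size in pixels.
#' @param background background RGB triple in \[0, 1\].
#' @return height x width x 3 numeric array in \[0, 1\].
#' @export
composite <- function(segments, width, height, background = c(0, 0, 0)) {
  img <- array(rep(background, each = height * width), c(height, width, 3))
  if (is.null(segments) || nrow(segments) == 0) return(img)
  npix <- height * width
  for (s in seq_len(nrow(segments))) {
    a <- segments$alpha[s]
    if (a <= 0) next
    idx <- line_pixels(segments$x0[s], segments$y0[s],
                       segments$x1[s], segments$y1[s], width, height)
    if (!length(idx)) next
    col <- c(segments$r[s], segments$g[s], segments$b[s])
    for (ch in 1:3) {
      at <- idx + (ch - 1L) * npix
      img[at] <- a * col[ch] + (1 - a) * img[at]
    }
  }
  img
}

# Linear indices (column-major, h x w) of the 1-px line between two pixel
# coordinates; simple DDA stepping, clipped to the image.
line_pixels <- function(x0, y0, x1, y1, width, height) {
  n <- max(abs(round(x1) - round(x0)), abs(round(y1) - round(y0))) + 1L
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  ok <- xs >= 0 & xs < width & ys >= 0 & ys < height
  xs <- xs[ok]; ys <- ys[ok]
  if (!length(xs)) return(integer(0))
  idx <- ys + 1 + xs * height
  idx[!duplicated(idx)]
}

#' Render a tractogram to a raster image
#'
#' Full pipeline: opacity assignment (with the opacity axis coupled to the
#' camera's viewing axis when `config$axis_mode == "view"`), projection,
#' segment construction, back-to-front depth sorting, and "over" compositing.
#'
#' @param tg a [tractogram()].
#' @param cam a [camera()].
#' @param config an [opacity_config()].
#' @param background background RGB triple.
#' @param alpha_off render conventionally (every segment fully opaque)
#'   instead of applying the opacity function; useful for comparison.
#' @return list with `image` (height x width x 3 array) and `alpha` (the
#'   per-point opacity channel used).
#' @export
render_scene <- function(tg, cam, config, background = c(0, 0, 0),
                         alpha_off = FALSE) {
  stopifnot(inherits(tg, "tractogram"), inherits(cam, "camera"),
            inherits(config, "opacity_config"))
  if (alpha_off) {
    tg <- set_scalar_channel(tg, "alpha", 1)
  } else {
    view_axis <- if (config$axis_mode == "view") cam$view_axis else NULL
    tg <- assign_opacity(tg, config, view_axis = view_axis)
  }
  segs <- tract_segments(tg, cam)
  segs <- depth_sort_segments(segs)
  img <- composite(segs, cam$width, cam$height, background)
  list(image = img, alpha = tg$scalars[["alpha"]])
}

#' Write a raster image to a PNG file
#'
#' @param image height x width x 3 array in \[0, 1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
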