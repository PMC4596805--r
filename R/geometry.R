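# Streamline orientation geometry.
#
# A streamline's local orientation at an interior point is the normalized
# central difference of its neighbors; the first and last points use forward
# and backward differences. Orientations are axial quantities: n and -n carry
# the same information, which is why dispersion is summarized through the
# scatter matrix S = mean(n_i n_i') rather than a mean vector.

#' Local orientations along a streamline
#'
#' At interior points the orientation is the normalized vector connecting the
#' two neighboring points; the first point uses the forward difference and the
#' last the backward difference.
#'
#' @param sl streamline (N x 3 matrix, N >= 2).
#' @return N x 3 matrix of unit row vectors, one per point.
#' @export
local_orientations <- function(sl) {
  pts <- as_points(sl)
  n <- nrow(pts)
  d <- rbind(pts[2, ] - pts[1, ],
             if (n > 2) pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
             pts[n, ] - pts[n - 1, ])
  len <- sqrt(rowSums(d * d))
  bad <- which(len < 1e-12)
  if (length(bad))
    stop("degenerate geometry: zero-length orientation at point index ",
         bad[1], " (coincident neighbors)", call. = FALSE)
  d / len
}

#' Endpoint (chord) orientation of a streamline
#'
#' The normalized vector connecting the streamline's first and last points.
#' Returns the [undefined_axis()] marker when the endpoints (nearly)
#' coincide, i.e. for closed loops, where no chord direction exists.
#'
#' @param sl streamline (N x 3 matrix).
#' @return unit 3-vector, or [undefined_axis()].
#' @export
endpoint_orientation <- function(sl) {
  pts <- as_points(sl)
  v <- pts[nrow(pts), ] - pts[1, ]
  if (vec_norm(v) < 1e-9) return(undefined_axis())
  v / vec_norm(v)
}

#' Scatter-matrix summary of an orientation set
#'
#' Computes the orientation scatter matrix `S = mean(n_i n_i')`, its sorted
#' eigenvalues `beta1 >= beta2 >= beta3`, the first eigenvector `s1` (the
#' maximum-likelihood mean axis of a bipolar Watson distribution fitted to the
#' axes), and the linear coefficient
#' `c_l = (beta1 - beta2) / (beta1 + beta2 + beta3)`, which is 1 for a
#' perfectly unidirectional set and 0 when no single direction dominates.
#'
#' The eigenvector sign is fixed so that its largest-magnitude component is
#' positive (ties broken by the first such component), making the reported
#' axis deterministic even though +/- s1 are equivalent.
#'
#' @param orientations M x 3 matrix of unit axes (rows), e.g. from
#'   [local_orientations()].
#' @param endpoint_axis optional endpoint axis to carry along in the summary
#'   (may be [undefined_axis()]).
#' @return object of class `scatter_summary`: list with `S`, `betas`, `s1`,
#'   `c_l`, `n_endpoints`.
#' @export
scatter_summary <- function(orientations, endpoint_axis = undefined_axis()) {
  o <- as.matrix(orientations)
  if (nrow(o) < 1 || ncol(o) != 3)
    stop("orientations must be a non-empty M x 3 matrix", call. = FALSE)
  nrm <- sqrt(rowSums(o * o))
  if (any(abs(nrm - 1) > 1e-6))
    stop("orientation vectors must be unit length", call. = FALSE)
  S <- crossprod(o) / nrow(o)
  e <- eigen(S, symmetric = TRUE)
  betas <- e$values
  s1 <- fix_axis_sign(e$vectors[, 1])
  structure(
    list(S = S, betas = betas, s1 = s1,
         c_l = (betas[1] - betas[2]) / sum(betas),
         n_endpoints = endpoint_axis),
    class = "scatter_summary"
  )
}

#' @export
print.scatter_summary <- function(x, ...) {
  cat("scatter summary: c_l =", format(x$c_l, digits = 4),
      " betas =", paste(format(x$betas, digits = 4), collapse = ", "), "\n")
  cat("  s1 = (", paste(format(x$s1, digits = 4), collapse = ", "), ")\n")
  invisible(x)
}

# Deterministic sign: largest-|component| positive, first index on ties.
fix_axis_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Scatter summary of a whole streamline
#'
#' Convenience wrapper: local orientations -> [scatter_summary()], with the
#' endpoint axis attached.
#'
#' @param sl streamline (N x 3 matrix).
#' @return a `scatter_summary`.
#' @export
streamline_summary <- function(sl) {
  scatter_summary(local_orientations(sl), endpoint_orientation(sl))
}

#' Global orientation of a streamline
#'
#' Two estimators of a single direction for the whole pathway: the endpoint
#' chord, or the first eigenvector of the local-orientation scatter matrix.
#' The two disagree strongly for U-shaped fibers, where the chord runs along
#' the short connecting direction while most segments run along the limbs.
#'
#' @param sl streamline.
#' @param method `"endpoints"` or `"scatter"`.
#' @return unit 3-vector, or [undefined_axis()] (endpoints method on a closed
#'   loop).
#' @export
global_orientation <- function(sl, method = c("endpoints", "scatter")) {
  method <- match.arg(method)
  switch(method,
    endpoints = endpoint_orientation(sl),
    scatter = streamline_summary(sl)$s1
  )
}

#' Compress a streamline by removing nearly collinear points
#'
#' Greedy sequential scan: starting from the first point, the next kept point
#' is pushed as far forward as possible while every spanned point stays within
#' `tolerance_mm` (perpendicular distance) of the segment joining the two kept
#' points. The last point is always kept. Every removed point is guaranteed to
#' lie within the tolerance of the compressed polyline.
#'
#' @param sl streamline (N x 3 matrix).
#' @param tolerance_mm maximum allowed deviation in mm (default 0.01).
#' @return the compressed streamline; the kept row indices are attached as
#'   attribute `"kept"` so parallel scalar channels can be subset.
#' @export
compress_streamline <- function(sl, tolerance_mm = 0.01) {
  if (!is.numeric(tolerance_mm) || length(tolerance_mm) != 1 ||
      is.na(tolerance_mm) || tolerance_mm < 0)
    stop("tolerance_mm must be a single non-negative number", call. = FALSE)
  pts <- as_points(sl)
  n <- nrow(pts)
  kept <- 1L
  anchor <- 1L
  while (anchor < n) {
    j <- anchor + 1L
    while (j < n && span_within_tol(pts, anchor, j + 1L, tolerance_mm))
      j <- j + 1L
    kept <- c(kept, j)
    anchor <- j
  }
  out <- pts[kept, , drop = FALSE]
  attr(out, "kept") <- kept
  class(out) <- c("streamline", "matrix", "array")
  out
}

# Are all interior points between indices a and b within tol of segment a-b?
span_within_tol <- function(pts, a, b, tol) {
  if (b - a < 2) return(TRUE)
  p0 <- pts[a, ]; p1 <- pts[b, ]
  mid <- pts[(a + 1):(b - 1), , drop = FALSE]
  all(point_segment_distance(mid, p0, p1) <= tol)
}

# Perpendicular distance from points (rows of p) to the segment p0-p1.
point_segment_distance <- function(p, p0, p1) {
  d <- p1 - p0
  len2 <- sum(d * d)
  rel <- sweep(p, 2, p0)
  if (len2 < 1e-24) return(sqrt(rowSums(rel * rel)))
  t <- clamp01(as.vector(rel %*% d) / len2)
  foot <- outer(t, d)
  res <- rel - foot
  sqrt(rowSums(res * res))
}

#' Compress every streamline of a tractogram
#'
#' Applies [compress_streamline()] to each streamline and subsets all scalar
#' channels to the kept points.
#'
#' @param tg a [tractogram()].
#' @param tolerance_mm deviation tolerance in mm (default 0.01).
#' @return compressed tractogram.
#' @export
compress_tractogram <- function(tg, tolerance_mm = 0.01) {
  stopifnot(inherits(tg, "tractogram"))
  comp <- lapply(tg$streamlines, compress_streamline, tolerance_mm = tolerance_mm)
  scalars <- tg$scalars
  for (nm in names(scalars))
    scalars[[nm]] <- Map(function(ch, sl) ch[attr(sl, "kept")], scalars[[nm]], comp)
  comp <- lapply(comp, function(sl) { attr(sl, "kept") <- NULL; sl })
  tractogram(comp, scalars = scalars, space = tg$space)
}

as_points <- function(sl) {
  pts <- unclass(as.matrix(sl))
  if (ncol(pts) != 3 || nrow(pts) < 2)
    stop("streamline must be an N x 3 matrix with N >= 2", call. = FALSE)
  pts
}
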