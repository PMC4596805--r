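#' Construct a streamline
#'
#' A streamline is an ordered polyline through 3D space, stored as an
#' N x 3 numeric matrix of world coordinates in millimeters. Streamlines
#' must have at least two points, all coordinates finite, and no two
#' consecutive points coincident (coincident points would make the local
#' orientation undefined).
#'
#' @param points N x 3 numeric matrix (or coercible) of mm coordinates.
#' @param dedupe drop consecutive duplicate points instead of erroring.
#' @return N x 3 numeric matrix of class `streamline`.
#' @export
streamline <- function(points, dedupe = FALSE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("streamline points must be an N x 3 matrix", call. = FALSE)
  storage.mode(pts) <- "double"
  if (any(!is.finite(pts))) stop("streamline coordinates must be finite", call. = FALSE)
  if (nrow(pts) >= 2) {
    d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
    dup <- rowSums(d * d) == 0
    if (any(dup)) {
      if (!dedupe)
        stop("streamline has coincident consecutive points at index ",
             which(dup)[1] + 1L, call. = FALSE)
      pts <- pts[c(TRUE, !dup), , drop = FALSE]
    }
  }
  if (nrow(pts) < 2) stop("a streamline needs at least 2 points", call. = FALSE)
  dimnames(pts) <- NULL
  class(pts) <- c("streamline", class(pts))
  pts
}

#' Construct a tractogram
#'
#' A tractogram is a collection of streamlines with optional named per-point
#' scalar channels (one value per point per streamline), e.g. an `"alpha"`
#' opacity channel, plus voxel-to-world metadata carried over from the source
#' file format.
#'
#' @param streamlines list of N x 3 matrices (each passed through
#'   [streamline()]).
#' @param scalars named list of channels; each channel is a list of numeric
#'   vectors parallel to the streamlines' points.
#' @param space list with elements `voxel_size` (length 3), `vox_to_ras`
#'   (4 x 4 matrix) and `voxel_order` (string), as carried by TRK headers.
#'   Defaults to unit voxels with an identity transform.
#' @param dedupe passed to [streamline()]: drop coincident consecutive
#'   points (with a reported count) instead of erroring.
#' @return object of class `tractogram`.
#' @export
tractogram <- function(streamlines, scalars = list(),
                       space = default_space(), dedupe = FALSE) {
  if (inherits(streamlines, "tractogram")) return(streamlines)
  if (!is.list(streamlines)) streamlines <- list(streamlines)
  before <- vapply(streamlines, nrow, integer(1))
  streamlines <- lapply(streamlines, streamline, dedupe = dedupe)
  removed <- sum(before - vapply(streamlines, nrow, integer(1)))
  if (removed > 0)
    message("tractogram: removed ", removed, " coincident consecutive point(s)")
  obj <- structure(
    list(streamlines = streamlines, scalars = scalars, space = space),
    class = "tractogram"
  )
  validate_tractogram(obj)
  obj
}

default_space <- function() {
  list(voxel_size = c(1, 1, 1), vox_to_ras = diag(4), voxel_order = "RAS")
}

#' Validate tractogram invariants
#'
#' Checks that every scalar channel has exactly one value per streamline
#' point and that an `"alpha"` channel, when present, lies in \[0, 1\].
#'
#' @param x a `tractogram`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_tractogram <- function(x) {
  stopifnot(inherits(x, "tractogram"))
  npts <- n_points(x)
  for (nm in names(x$scalars)) {
    ch <- x$scalars[[nm]]
    if (length(ch) != length(x$streamlines))
      stop("scalar channel '", nm, "' has ", length(ch),
           " streamlines; tractogram has ", length(x$streamlines), call. = FALSE)
    got <- vapply(ch, length, integer(1))
    if (!all(got == npts))
      stop("scalar channel '", nm, "' point counts do not match streamlines (",
           "first mismatch at streamline ", which(got != npts)[1], ")", call. = FALSE)
  }
  if ("alpha" %in% names(x$scalars)) {
    a <- unlist(x$scalars[["alpha"]], use.names = FALSE)
    if (length(a) && (any(!is.finite(a)) || any(a < 0) || any(a > 1)))
      stop("opacity channel 'alpha' must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param x a `tractogram`.
#' @return integer count.
#' @export
n_streamlines <- function(x) length(x$streamlines)

#' Per-streamline point counts
#' @param x a `tractogram`.
#' @return integer vector, one count per streamline.
#' @export
n_points <- function(x) vapply(x$streamlines, nrow, integer(1))

#' Attach or replace a scalar channel
#' @param x a `tractogram`.
#' @param name channel name, e.g. `"alpha"`.
#' @param values list of numeric vectors parallel to streamline points, or a
#'   single number recycled to every point.
#' @return the modified tractogram.
#' @export
set_scalar_channel <- function(x, name, values) {
  stopifnot(inherits(x, "tractogram"))
  if (is.numeric(values) && length(values) == 1)
    values <- lapply(n_points(x), function(n) rep(values, n))
  x$scalars[[name]] <- values
  validate_tractogram(x)
  x
}

#' @export
print.tractogram <- function(x, ...) {
  np <- n_points(x)
  cat("tractogram:", n_streamlines(x), "streamlines,",
      sum(np), "points\n")
  if (length(np))
    cat("  points per streamline:", min(np), "-", max(np), "\n")
  if (length(x$scalars))
    cat("  scalar channels:", paste(names(x$scalars), collapse = ", "), "\n")
  invisible(x)
}
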