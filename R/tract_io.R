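# Tractogram file I/O.
#
# TRK (TrackVis) and TCK (MRtrix) are read and written directly against their
# public binary layouts. All points are exposed in world coordinates (mm):
# TRK stores voxel-mm coordinates with a corner-of-voxel origin, so on read we
# apply   world = vox_to_ras %*% (p / voxel_size - 0.5)   and the inverse on
# write; TCK stores scanner-space mm natively. A plain-text polyline dialect
# ("x y z" per line, blank line between streamlines) is provided so tests and
# small fixtures stay human-readable.

TRK_HDR_SIZE <- 1000L

#' Read a tractogram from disk
#'
#' Supported formats: TrackVis `.trk` (per-point scalar channels are loaded
#' into named channels), MRtrix `.tck`, and a plain-text polyline format with
#' one `x y z` triple per line and a blank line between streamlines. For TCK
#' and txt, which carry no scalars, an `<path>.alpha.txt` sidecar written by
#' [write_tractogram()] is picked up automatically as the `"alpha"` channel.
#'
#' Streamlines with fewer than 2 points are dropped (a count is reported), and
#' coincident consecutive points are deduplicated, so every returned
#' streamline supports local-orientation estimation.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"trk"`, `"tck"`, `"txt"`. With `"auto"` the
#'   format is taken from the file extension.
#' @return a [tractogram()] in world (mm) coordinates.
#' @export
read_tractogram <- function(path, format = c("auto", "trk", "tck", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("trk", "tck", "txt"))
      stop("cannot infer tractogram format from extension '", ext,
           "'; pass format= explicitly", call. = FALSE)
    format <- ext
  }
  raw <- switch(format,
    trk = read_trk(path),
    tck = read_tck(path),
    txt = read_txt_polylines(path)
  )
  keep <- vapply(raw$streamlines, nrow, integer(1)) >= 2
  if (any(!keep)) {
    message("read_tractogram: dropped ", sum(!keep),
            " streamline(s) with fewer than 2 points")
    raw$streamlines <- raw$streamlines[keep]
    raw$scalars <- lapply(raw$scalars, function(ch) ch[keep])
  }
  # deduplicate coincident consecutive points, keeping scalars aligned
  ndup <- 0L
  for (i in seq_along(raw$streamlines)) {
    pts <- raw$streamlines[[i]]
    d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
    keep_pt <- c(TRUE, rowSums(d * d) > 0)
    if (!all(keep_pt)) {
      ndup <- ndup + sum(!keep_pt)
      raw$streamlines[[i]] <- pts[keep_pt, , drop = FALSE]
      for (nm in names(raw$scalars))
        raw$scalars[[nm]][[i]] <- raw$scalars[[nm]][[i]][keep_pt]
    }
  }
  if (ndup > 0)
    message("read_tractogram: deduplicated ", ndup,
            " coincident consecutive point(s)")
  tg <- tractogram(raw$streamlines, scalars = raw$scalars, space = raw$space)
  if (format %in% c("tck", "txt")) {
    sidecar <- sidecar_path(path)
    if (file.exists(sidecar)) {
      alpha <- read_sidecar_alpha(sidecar)
      if (any(!keep)) alpha <- alpha[keep]
      tg <- set_scalar_channel(tg, "alpha", alpha)
    }
  }
  tg
}

#' Write a tractogram to disk
#'
#' TRK embeds per-point scalar channels natively (up to 10, names truncated to
#' 20 bytes). TCK and txt carry no scalars; when an `"alpha"` channel is
#' present it is written to a plain-text sidecar `<path>.alpha.txt` (one value
#' per point, blank line between streamlines) so opacity survives those
#' formats. The tractogram is validated before any bytes are written.
#'
#' @param tg a [tractogram()].
#' @param path output file.
#' @param format one of `"trk"`, `"tck"`, `"txt"`, or `"auto"` (from the
#'   extension).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(tg, path, format = c("auto", "trk", "tck", "txt")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("trk", "tck", "txt"))
      stop("cannot infer tractogram format from extension '", ext, "'", call. = FALSE)
    format <- ext
  }
  validate_tractogram(tg)
  switch(format,
    trk = write_trk(tg, path),
    tck = write_tck(tg, path),
    txt = write_txt_polylines(tg, path)
  )
  if (format %in% c("tck", "txt") && "alpha" %in% names(tg$scalars))
    write_sidecar_alpha(tg$scalars[["alpha"]], sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".alpha.txt")

## ---- TRK (TrackVis) ---------------------------------------------------

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop("not a TRK file: bad magic at offset 0 in ", path, call. = FALSE)
  dim3 <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  scalar_names <- read_name_block(con, 10, 20)
  n_properties <- readBin(con, "integer", 1, size = 2, endian = "little")
  prop_names <- read_name_block(con, 10, 20)
  m <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
              4, 4, byrow = TRUE)
  readBin(con, "raw", 444)                       # reserved
  voxel_order <- read_fixed_string(con, 4)
  readBin(con, "raw", 4)                         # pad2
  readBin(con, "numeric", 6, size = 4, endian = "little")  # image orientation
  readBin(con, "raw", 2)                         # pad1
  readBin(con, "raw", 6)                         # invert/swap flags
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != TRK_HDR_SIZE)
    stop("corrupt TRK header in ", path, ": hdr_size field at offset 996 is ",
         hdr_size, call. = FALSE)
  if (all(m == 0)) m <- diag(4)  # version-1 files carry no transform
  if (all(voxel_size == 0)) voxel_size <- c(1, 1, 1)

  streamlines <- list()
  scalars <- rep(list(list()), n_scalars)
  offset <- TRK_HDR_SIZE
  repeat {
    npt <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npt) == 0) break
    if (is.na(npt) || npt < 0 || npt > 1e7)
      stop("corrupt TRK track header at byte offset ", offset, " in ", path,
           call. = FALSE)
    nval <- npt * (3 + n_scalars)
    vals <- readBin(con, "numeric", nval, size = 4, endian = "little")
    if (length(vals) != nval)
      stop("truncated TRK track data at byte offset ", offset + 4, " in ",
           path, call. = FALSE)
    if (n_properties > 0)
      readBin(con, "numeric", n_properties, size = 4, endian = "little")
    rec <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)
    pts <- trk_voxmm_to_world(rec[, 1:3, drop = FALSE], m, voxel_size)
    streamlines[[length(streamlines) + 1L]] <- pts
    if (n_scalars > 0)
      for (k in seq_len(n_scalars))
        scalars[[k]][[length(streamlines)]] <- rec[, 3 + k]
    offset <- offset + 4 + 4 * (nval + n_properties)
  }
  if (n_count > 0 && length(streamlines) != n_count)
    message("TRK header announced ", n_count, " streamlines; file contains ",
            length(streamlines))
  names(scalars) <- scalar_names[seq_len(n_scalars)]
  list(streamlines = streamlines, scalars = scalars,
       space = list(voxel_size = voxel_size, vox_to_ras = m,
                    voxel_order = voxel_order))
}

write_trk <- function(tg, path) {
  scal <- tg$scalars
  if (length(scal) > 10) stop("TRK supports at most 10 scalar channels", call. = FALSE)
  n_scalars <- length(scal)
  space <- tg$space
  m <- space$vox_to_ras
  voxel_size <- space$voxel_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(c(1, 1, 1)), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")          # origin
  writeBin(as.integer(n_scalars), con, size = 2, endian = "little")
  write_name_block(con, names(scal), 10, 20)
  writeBin(0L, con, size = 2, endian = "little")                  # n_properties
  write_name_block(con, character(0), 10, 20)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeBin(fixed_string_raw(space$voxel_order, 4), con)
  writeBin(raw(4), con)
  writeBin(numeric(6), con, size = 4, endian = "little")
  writeBin(raw(2), con)
  writeBin(raw(6), con)
  writeBin(as.integer(n_streamlines(tg)), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")                  # version
  writeBin(TRK_HDR_SIZE, con, size = 4, endian = "little")
  for (i in seq_len(n_streamlines(tg))) {
    pts <- world_to_trk_voxmm(tg$streamlines[[i]], m, voxel_size)
    rec <- pts
    for (nm in names(scal)) rec <- cbind(rec, scal[[nm]][[i]])
    writeBin(nrow(pts), con, size = 4, endian = "little")
    writeBin(as.numeric(t(rec)), con, size = 4, endian = "little")
  }
  invisible(path)
}

trk_voxmm_to_world <- function(pts, m, voxel_size) {
  vox <- sweep(pts, 2, voxel_size, "/") - 0.5
  out <- cbind(vox, 1) %*% t(m)
  out[, 1:3, drop = FALSE]
}

world_to_trk_voxmm <- function(pts, m, voxel_size) {
  vox <- cbind(pts, 1) %*% t(solve(m))
  sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, voxel_size, "*")
}

read_name_block <- function(con, n, width) {
  vapply(seq_len(n), function(i) {
    b <- readBin(con, "raw", width)
    nul <- which(b == 0)
    end <- if (length(nul)) nul[1] - 1L else width
    if (end == 0) "" else rawToChar(b[seq_len(end)])
  }, character(1))
}

write_name_block <- function(con, names, n, width) {
  for (i in seq_len(n)) {
    nm <- if (i <= length(names) && !is.null(names[i])) names[i] else ""
    writeBin(fixed_string_raw(nm, width), con)
  }
}

fixed_string_raw <- function(s, width) {
  b <- charToRaw(if (is.na(s) || is.null(s)) "" else s)
  if (length(b) > width) b <- b[seq_len(width)]
  c(b, raw(width - length(b)))
}

read_fixed_string <- function(con, width) {
  b <- readBin(con, "raw", width)
  nul <- which(b == 0)
  end <- if (length(nul)) nul[1] - 1L else width
  if (end == 0) "" else rawToChar(b[seq_len(end)])
}

## ---- TCK (MRtrix) -----------------------------------------------------

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1, warn = FALSE)
  if (!identical(first, "mrtrix tracks"))
    stop("not a TCK file: bad magic at offset 0 in ", path, call. = FALSE)
  offset <- NA_real_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0)
      stop("corrupt TCK header (no END) in ", path, call. = FALSE)
    if (identical(line, "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "file") offset <- as.numeric(sub("^\\.\\s+", "", val))
      if (key == "datatype") datatype <- val
    }
  }
  if (!identical(datatype, "Float32LE"))
    stop("unsupported TCK datatype '", datatype, "' in ", path, call. = FALSE)
  if (is.na(offset)) stop("corrupt TCK header: no file offset in ", path, call. = FALSE)
  close(con); on.exit()
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  seek(con, offset)
  vals <- readBin(con, "numeric", (sz - offset) / 4, size = 4, endian = "little")
  if (length(vals) %% 3 != 0)
    stop("truncated TCK data block at byte offset ", offset, " in ", path,
         call. = FALSE)
  trip <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- 1L
  for (r in seq_len(nrow(trip))) {
    if (all(is.infinite(trip[r, ]))) break
    if (all(is.nan(trip[r, ]))) {
      if (r > cur)
        streamlines[[length(streamlines) + 1L]] <- trip[cur:(r - 1L), , drop = FALSE]
      cur <- r + 1L
    }
  }
  list(streamlines = streamlines, scalars = list(), space = default_space())
}

write_tck <- function(tg, path) {
  n <- n_streamlines(tg)
  hdr_for <- function(offset) paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    "count: ", n, "\n",
    "file: . ", offset, "\n",
    "END\n")
  offset <- nchar(hdr_for(0), type = "bytes")
  while (nchar(hdr_for(offset), type = "bytes") != offset)
    offset <- nchar(hdr_for(offset), type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr_for(offset)), con)
  for (sl in tg$streamlines) {
    writeBin(as.numeric(t(sl)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

## ---- plain-text polylines ---------------------------------------------

read_txt_polylines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  streamlines <- list()
  buf <- list()
  flush <- function() {
    if (length(buf))
      streamlines[[length(streamlines) + 1L]] <<- do.call(rbind, buf)
    buf <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { flush(); next }
    xyz <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:],]+")[[1]]))
    if (length(xyz) != 3 || any(is.na(xyz)))
      stop("corrupt txt polyline at line ", i, " in ", path, call. = FALSE)
    buf[[length(buf) + 1L]] <- xyz
  }
  flush()
  list(streamlines = streamlines, scalars = list(), space = default_space())
}

write_txt_polylines <- function(tg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_streamlines(tg))) {
    sl <- tg$streamlines[[i]]
    writeLines(apply(sl, 1, function(p)
      paste(format(p, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")), con)
    if (i < n_streamlines(tg)) writeLines("", con)
  }
  invisible(path)
}

read_sidecar_alpha <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  buf <- numeric(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") {
      if (length(buf)) out[[length(out) + 1L]] <- buf
      buf <- numeric(0)
    } else buf <- c(buf, as.numeric(ln))
  }
  if (length(buf)) out[[length(out) + 1L]] <- buf
  out
}

write_sidecar_alpha <- function(alpha, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alpha)) {
    writeLines(format(alpha[[i]], digits = 17, scientific = FALSE, trim = TRUE), con)
    if (i < length(alpha)) writeLines("", con)
  }
  invisible(path)
}
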