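# Minimal C3D reader/writer for labeled 3D point data.
#
# Covers the subset of the C3D standard needed for optical marker
# trajectories: Intel (little-endian) byte order, floating-point or
# integer-scaled point storage, POINT group with USED / LABELS / RATE /
# SCALE / UNITS parameters, no analog channels.  Block size is 512 bytes.

C3D_BLOCK <- 512L

#' Read labeled marker trajectories from a C3D file
#'
#' Reads all labeled 3D point trajectories and returns them as a
#' [marker_sequence()] in millimetres at the file's frame rate.  Points
#' flagged invalid (negative residual) are treated as gaps; because
#' downstream reduction assumes gap-filled input, the reader rejects files
#' containing gaps, naming the marker and the frame span of the first gap.
#'
#' Only Intel-byte-order files are supported; both floating-point and
#' integer-scaled point storage are handled.
#'
#' @param path Path to a C3D file.
#' @param validate Reject marker gaps (default `TRUE`); with
#'   `validate = FALSE` gaps are returned as `NaN` positions.
#' @return A `marker_sequence`.
#' @export
read_c3d <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr <- readBin(con, "raw", 2L)
  param_block <- as.integer(hdr[1L])
  if (as.integer(hdr[2L]) != 0x50L) stop("not a C3D file (bad magic byte): ", path)
  w <- readBin(con, "integer", 9L, size = 2L, signed = FALSE, endian = "little")
  n_points <- w[1L]
  first_frame <- w[3L]
  last_frame <- w[4L]
  n_frames <- last_frame - first_frame + 1L
  if (n_points < 1L) stop("C3D file contains no 3D points: ", path)
  if (n_frames < 1L) stop("C3D file contains zero frames: ", path)
  seek(con, 12L)
  point_scale <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  data_block <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  analog_per_frame <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  frame_rate <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  analog_words <- w[2L]   # total analog measurements per frame

  params <- .c3d_read_params(con, param_block)
  if (!is.null(params[["POINT:SCALE"]])) point_scale <- params[["POINT:SCALE"]][1L]
  if (!is.null(params[["POINT:USED"]])) n_points <- as.integer(params[["POINT:USED"]][1L])
  labels <- params[["POINT:LABELS"]]
  if (is.null(labels) || !length(labels) || !any(nzchar(trimws(labels))))
    stop("C3D file has no labeled points (POINT:LABELS missing or empty): ", path)
  labels <- trimws(labels)[seq_len(n_points)]
  units <- if (!is.null(params[["POINT:UNITS"]])) trimws(params[["POINT:UNITS"]][1L]) else "mm"

  # --- point data ---
  seek(con, (data_block - 1L) * C3D_BLOCK)
  use_float <- point_scale < 0
  vals_per_frame <- 4L * n_points
  if (use_float) {
    raw <- readBin(con, "numeric", (vals_per_frame + analog_words) * n_frames,
                   size = 4L, endian = "little")
  } else {
    raw <- readBin(con, "integer", (vals_per_frame + analog_words) * n_frames,
                   size = 2L, signed = TRUE, endian = "little")
  }
  if (length(raw) < (vals_per_frame + analog_words) * n_frames)
    stop("truncated C3D point data section: ", path)
  raw <- matrix(raw, nrow = vals_per_frame + analog_words)[seq_len(vals_per_frame), ,
                                                           drop = FALSE]
  dim(raw) <- c(4L, n_points, n_frames)
  xyz <- raw[1:3, , , drop = FALSE]
  resid <- raw[4L, , ]
  if (!use_float) xyz <- xyz * abs(point_scale)
  xyz[rep(resid < 0, each = 3L)] <- NaN
  pos <- aperm(xyz, c(3L, 2L, 1L))    # frames x markers x 3
  dimnames(pos) <- list(NULL, labels, c("x", "y", "z"))

  scale_to_mm <- switch(units, mm = 1, cm = 10, m = 1000,
                        stop("unsupported POINT:UNITS '", units, "'"))
  pos <- pos * scale_to_mm

  if (validate) .c3d_check_gaps(pos)
  marker_sequence(pos, frame_rate = frame_rate)
}

.c3d_check_gaps <- function(pos) {
  for (m in dimnames(pos)[[2L]]) {
    bad <- which(!is.finite(pos[, m, 1L]))
    if (length(bad)) {
      runs <- split(bad, cumsum(c(1L, diff(bad) != 1L)))
      r <- runs[[1L]]
      stop("marker '", m, "' has a gap (invalid/NaN positions) at frames ",
           r[1L], "-", r[length(r)],
           "; gap filling must be done upstream before reading")
    }
  }
  invisible(TRUE)
}

# Parse the parameter section into a named list "GROUP:PARAM" -> value.
.c3d_read_params <- function(con, param_block) {
  seek(con, (param_block - 1L) * C3D_BLOCK)
  ph <- readBin(con, "raw", 4L)
  n_param_blocks <- as.integer(ph[3L])
  proc <- as.integer(ph[4L])
  if (proc != 84L)
    stop("unsupported C3D processor type ", proc, " (only Intel/84 is supported)")
  buf <- readBin(con, "raw", n_param_blocks * C3D_BLOCK - 4L)
  groups <- character()   # id -> name
  out <- list()
  pos <- 1L
  i8 <- function(r) { v <- as.integer(r); ifelse(v > 127L, v - 256L, v) }
  i16 <- function(r) {
    v <- as.integer(r[1L]) + 256L * as.integer(r[2L])
    if (v > 32767L) v - 65536L else v
  }
  while (pos + 1L <= length(buf)) {
    nname <- i8(buf[pos])
    gid <- i8(buf[pos + 1L])
    if (nname == 0L || gid == 0L) break
    nch <- abs(nname)
    name <- rawToChar(buf[pos + 1L + seq_len(nch)])
    p <- pos + 2L + nch
    offset <- i16(buf[p + 0:1])
    next_pos <- p + 2L + offset - 2L  # offset measured from the offset word
    if (gid < 0L) {                    # group record
      groups[as.character(-gid)] <- name
    } else {                           # parameter record
      tp <- i8(buf[p + 2L])
      nd <- i8(buf[p + 3L])
      dims <- if (nd > 0L) as.integer(buf[p + 3L + seq_len(nd)]) else integer()
      dp <- p + 4L + nd
      nel <- prod(c(1L, dims))
      esz <- abs(tp)
      bytes <- buf[dp - 1L + seq_len(nel * esz)]
      val <- switch(as.character(tp),
        `-1` = {  # characters; first dimension is string width
          if (length(dims) <= 1L) rawToChar(bytes)
          else {
            wdt <- dims[1L]
            n <- nel / wdt
            vapply(seq_len(n), function(k)
              rawToChar(bytes[(k - 1L) * wdt + seq_len(wdt)]), "")
          }
        },
        `1` = as.integer(bytes),
        `2` = readBin(bytes, "integer", nel, size = 2L, signed = TRUE,
                      endian = "little"),
        `4` = readBin(bytes, "numeric", nel, size = 4L, endian = "little"),
        stop("unknown C3D parameter type ", tp))
      gname <- groups[as.character(gid)]
      if (is.na(gname)) gname <- paste0("G", gid)
      out[[paste0(gname, ":", name)]] <- val
    }
    if (offset <= 0L) break
    pos <- next_pos
  }
  out
}

#' Write a marker sequence as a C3D file
#'
#' Writes Intel byte order, floating-point point storage, no analog
#' channels, with POINT:USED, POINT:LABELS, POINT:RATE, POINT:SCALE and
#' POINT:UNITS parameters.  Non-finite positions are stored as invalid
#' points (negative residual), which [read_c3d()] reports as gaps.
#'
#' @param seq A `marker_sequence` (positions in mm).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_c3d <- function(seq, path) {
  stopifnot(inherits(seq, "marker_sequence"))
  pos <- seq$positions
  n_frames <- dim(pos)[1L]
  n_points <- dim(pos)[2L]
  labels <- dimnames(pos)[[2L]]
  lw <- max(4L, max(nchar(labels)))
  labpad <- formatC(labels, width = lw, flag = "-")

  # ---- parameter section ----
  rec <- function(...) unlist(list(...))
  u8 <- function(x) as.raw(bitwAnd(as.integer(x), 0xFFL))
  i16r <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  f32r <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
  grp <- function(name, gid) {
    body <- c(u8(nchar(name)), u8(256L - gid), charToRaw(name))
    c(body, i16r(3L), u8(0L))      # offset: 2 (offset word) + 1 (descr len)
  }
  par <- function(name, gid, type, dims, databytes) {
    tail <- c(u8(type), u8(length(dims)), u8(dims), databytes, u8(0L))
    body <- c(u8(nchar(name)), u8(gid), charToRaw(name))
    c(body, i16r(2L + length(tail)), tail)
  }
  pdata <- c(
    grp("POINT", 1L),
    par("USED",  1L, 2L, integer(), i16r(n_points)),
    par("FRAMES", 1L, 2L, integer(), i16r(n_frames)),
    par("RATE",  1L, 4L, integer(), f32r(seq$frame_rate)),
    par("SCALE", 1L, 4L, integer(), f32r(-1)),
    par("UNITS", 1L, -1L, 2L, charToRaw("mm")),
    par("LABELS", 1L, -1L, c(lw, n_points), charToRaw(paste(labpad, collapse = ""))))
  # terminate: a zero name-length / zero group id pair
  pdata <- c(pdata, u8(0L), u8(0L))
  n_param_blocks <- ceiling((length(pdata) + 4L) / C3D_BLOCK)
  data_block <- 2L + n_param_blocks

  con <- file(path, "wb")
  on.exit(close(con))
  # ---- header block ----
  writeBin(as.raw(c(2L, 0x50L)), con)
  writeBin(as.integer(c(n_points, 0L, 1L, n_frames, 0L)), con,
           size = 2L, endian = "little")
  writeBin(-1, con, size = 4L, endian = "little")             # POINT:SCALE
  writeBin(as.integer(c(data_block, 0L)), con, size = 2L, endian = "little")
  writeBin(as.numeric(seq$frame_rate), con, size = 4L, endian = "little")
  writeBin(raw(C3D_BLOCK - 24L), con)
  # ---- parameter blocks ----
  writeBin(as.raw(c(1L, 0x50L, n_param_blocks, 84L)), con)
  writeBin(pdata, con)
  pad <- n_param_blocks * C3D_BLOCK - 4L - length(pdata)
  if (pad > 0L) writeBin(raw(pad), con)
  # ---- point data ----
  xyz <- aperm(pos, c(3L, 2L, 1L))            # 3 x markers x frames
  resid <- matrix(0, n_points, n_frames)
  invalid <- apply(!is.finite(xyz), c(2L, 3L), any)
  resid[invalid] <- -1
  xyz[!is.finite(xyz)] <- 0
  out <- array(0, c(4L, n_points, n_frames))
  out[1:3, , ] <- xyz
  out[4L, , ] <- resid
  writeBin(as.numeric(out), con, size = 4L, endian = "little")
  invisible(path)
}
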