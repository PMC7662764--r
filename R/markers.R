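#' Construct a marker sequence
#'
#' Container for raw optical motion-capture marker trajectories: per-frame 3D
#' positions (in millimetres) of a named marker set, e.g. the 39-marker
#' Plug-in-Gait body set plus 7 racket markers.
#'
#' @param positions Numeric array `frames x markers x 3` with marker names as
#'   the second dimnames and coordinates ordered x, y, z (mm).
#' @param frame_rate Frames per second.
#' @param subject Optional subject label.
#' @return An object of class `marker_sequence`.
#' @export
marker_sequence <- function(positions, frame_rate = 100, subject = NA_character_) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3L] == 3L)
  if (dim(positions)[1L] < 1L) stop("marker sequence must contain at least one frame")
  if (is.null(dimnames(positions)[[2L]]))
    stop("markers must be named (second dimnames)")
  dimnames(positions)[[3L]] <- c("x", "y", "z")
  structure(list(positions = positions,
                 markers = dimnames(positions)[[2L]],
                 frame_rate = frame_rate,
                 subject = subject),
            class = "marker_sequence")
}

#' @export
print.marker_sequence <- function(x, ...) {
  cat("Marker sequence:", dim(x$positions)[1L], "frames,",
      length(x$markers), "markers @", x$frame_rate, "Hz\n")
  invisible(x)
}

#' Default marker names of the capture protocol
#'
#' The 39 Plug-in-Gait body markers plus the 7 racket markers (head top, two
#' pairs of side markers, head bottom, handle bottom) used as the default
#' source marker set for [reduction_rules()].
#'
#' @return Character vector of 46 marker names.
#' @export
default_marker_set <- function() {
  body <- c("LFHD", "RFHD", "LBHD", "RBHD",
            "C7", "T10", "CLAV", "STRN", "RBAK",
            "LSHO", "LUPA", "LELB", "LFRM", "LWRA", "LWRB", "LFIN",
            "RSHO", "RUPA", "RELB", "RFRM", "RWRA", "RWRB", "RFIN",
            "LASI", "RASI", "LPSI", "RPSI",
            "LTHI", "LKNE", "LTIB", "LANK", "LHEE", "LTOE",
            "RTHI", "RKNE", "RTIB", "RANK", "RHEE", "RTOE")
  racket <- c("RKT_TOP", "RKT_SIDE_L1", "RKT_SIDE_R1",
              "RKT_SIDE_L2", "RKT_SIDE_R2", "RKT_HEAD_BOT", "RKT_HANDLE")
  c(body, racket)
}

#' Marker-to-node reduction rules
#'
#' Maps every canonical skeleton node to one or more source markers; nodes
#' with several sources take their arithmetic mean per frame.  The default
#' reduces the 46-marker capture set (Plug-in-Gait body plus racket) to the
#' 19 canonical nodes: the four head markers collapse to one interpolated
#' head point, the racket's seven markers to a handle node and a head node
#' (head = mean of the four rim markers), and limb landmarks to single
#' joint nodes.
#'
#' @param map Named list: canonical node name to character vector of source
#'   markers.  Defaults to the built-in Plug-in-Gait + racket mapping.
#' @return An object of class `reduction_rules` (named list in canonical
#'   node order).
#' @export
reduction_rules <- function(map = NULL) {
  if (is.null(map)) {
    map <- list(
      head         = c("LFHD", "RFHD", "LBHD", "RBHD"),
      neck         = "C7",
      spine_upper  = c("CLAV", "RBAK"),
      spine_lower  = c("STRN", "T10"),
      pelvis       = c("LASI", "RASI", "LPSI", "RPSI"),
      shoulder_l   = "LSHO",
      shoulder_r   = "RSHO",
      elbow_l      = "LELB",
      elbow_r      = "RELB",
      hand_l       = c("LWRA", "LWRB", "LFIN"),
      hand_r       = c("RWRA", "RWRB", "RFIN"),
      hip_l        = c("LASI", "LPSI"),
      hip_r        = c("RASI", "RPSI"),
      knee_l       = "LKNE",
      knee_r       = "RKNE",
      foot_l       = c("LANK", "LHEE", "LTOE"),
      foot_r       = c("RANK", "RHEE", "RTOE"),
      racket_handle = "RKT_HANDLE",
      racket_head  = c("RKT_TOP", "RKT_SIDE_L1", "RKT_SIDE_R1", "RKT_HEAD_BOT"))
  }
  canon <- tennis_skeleton()$nodes
  if (!setequal(names(map), canon))
    stop("reduction rules must map exactly the 19 canonical nodes")
  if (any(lengths(map) < 1L)) stop("every node needs at least one source marker")
  structure(map[canon], class = "reduction_rules")
}

#' Reduce a marker sequence to the 19-node skeleton
#'
#' Replaces the excess capture markers by the reduced node set: each
#' canonical node is the per-frame arithmetic mean of its source markers.
#' The frame count is preserved and the output always has exactly 19 nodes.
#'
#' @param seq A `marker_sequence`.
#' @param rules A `reduction_rules` mapping; default [reduction_rules()].
#' @return A `node_sequence` with 3D coordinates.
#' @export
reduce_markers <- function(seq, rules = reduction_rules()) {
  stopifnot(inherits(seq, "marker_sequence"), inherits(rules, "reduction_rules"))
  missing <- setdiff(unique(unlist(rules)), seq$markers)
  if (length(missing))
    stop("source marker(s) missing from input: ", paste(missing, collapse = ", "))
  F <- dim(seq$positions)[1L]
  nodes <- names(rules)
  coords <- array(NA_real_, c(F, length(nodes), 3L),
                  dimnames = list(NULL, nodes, c("x", "y", "z")))
  for (i in seq_along(rules)) {
    src <- rules[[i]]
    block <- seq$positions[, src, , drop = FALSE]
    coords[, i, ] <- if (length(src) == 1L) block[, 1L, ]
                     else apply(block, c(1L, 3L), mean)
  }
  node_sequence(coords, frame_rate = seq$frame_rate)
}

#' Construct a node sequence
#'
#' Per-frame positions of the 19 canonical skeleton nodes, in 3D (before
#' projection) or 2D (after), with an optional stroke phase annotation.
#'
#' @param coords Numeric array `frames x 19 x k` (k = 2 or 3) with canonical
#'   node names as second dimnames (filled in automatically when absent).
#' @param frame_rate Frames per second.
#' @param phase One of `"preparation"`, `"shot"`, `"after_shot"`, `"none"`.
#' @param stroke Class label the phase belongs to (`"forehand"`,
#'   `"backhand"`, `"no_shot"`) or `NA`.
#' @return An object of class `node_sequence`.
#' @export
node_sequence <- function(coords, frame_rate = 10, phase = "none", stroke = NA_character_) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  canon <- tennis_skeleton()$nodes
  if (dim(coords)[2L] != length(canon))
    stop("a node sequence must contain exactly ", length(canon), " nodes")
  if (is.null(dimnames(coords)[[2L]])) dimnames(coords)[[2L]] <- canon
  phase <- match.arg(phase, c("preparation", "shot", "after_shot", "none"))
  structure(list(coords = coords, nodes = dimnames(coords)[[2L]],
                 frame_rate = frame_rate, phase = phase, stroke = stroke),
            class = "node_sequence")
}

#' @export
print.node_sequence <- function(x, ...) {
  cat("Node sequence:", dim(x$coords)[1L], "frames x", dim(x$coords)[2L],
      "nodes x", dim(x$coords)[3L], "coords; phase:", x$phase,
      if (!is.na(x$stroke)) paste0("(", x$stroke, ")") else "", "\n")
  invisible(x)
}

#' Project a 3D node sequence onto a coordinate plane
#'
#' Keeps the two selected world axes, reducing each node to 2 channels.
#' The default sagittal view keeps x (direction of travel) and z (vertical).
#' Projection of an already-2D sequence onto its own axes is the identity.
#'
#' @param seq A `node_sequence`.
#' @param plane Character vector of two distinct axis names among the
#'   sequence's coordinate axes, default `c("x", "z")`.
#' @return A `node_sequence` with 2 coordinate channels.
#' @export
project_to_plane <- function(seq, plane = c("x", "z")) {
  stopifnot(inherits(seq, "node_sequence"))
  axes <- dimnames(seq$coords)[[3L]]
  if (length(plane) != 2L || anyDuplicated(plane) || !all(plane %in% axes))
    stop("'plane' must name two distinct axes among: ", paste(axes, collapse = ", "))
  out <- seq
  out$coords <- seq$coords[, , plane, drop = FALSE]
  out
}

#' Mirror the lateral axis for left-handed subjects
#'
#' Negates the lateral world axis and swaps left/right node labels so that
#' the dominant (racket) hand of a left-handed subject maps onto the
#' canonical right side.
#'
#' @param seq A 3D `node_sequence`.
#' @param lateral Name of the lateral axis (default `"y"`).
#' @return A mirrored `node_sequence`.
#' @export
mirror_lateral <- function(seq, lateral = "y") {
  stopifnot(inherits(seq, "node_sequence"))
  axes <- dimnames(seq$coords)[[3L]]
  if (!lateral %in% axes) stop("no axis named '", lateral, "'")
  out <- seq
  out$coords[, , lateral] <- -out$coords[, , lateral]
  swapped <- sub("_l$", "_TMP", out$nodes)
  swapped <- sub("_r$", "_l", swapped)
  swapped <- sub("_TMP$", "_r", swapped)
  perm <- match(out$nodes, swapped)
  out$coords <- out$coords[, perm, , drop = FALSE]
  dimnames(out$coords)[[2L]] <- out$nodes
  out
}

# Nearest-frame uniform resampling index map: output frame t draws the input
# frame nearest the centre of the t-th of T equal subdivisions of the input.
.resample_index <- function(n, t_out) {
  pmin(n, pmax(1L, ceiling((seq_len(t_out) - 0.5) / t_out * n)))
}

#' Assemble a labeled motion sample from three stroke phases
#'
#' Concatenates the preparation, shot and after-shot phase sequences of a
#' single stroke class, resamples the concatenation uniformly to `t_out`
#' frames (nearest-frame rule) and applies per-sample coordinate
#' normalization: every frame is centred on the pelvis node and all
#' coordinates are divided by the first frame's pelvis-to-neck distance,
#' so absolute position and body size cannot leak into the class label.
#'
#' @param prep,shot,after `node_sequence` objects of the three phases,
#'   sharing node order and stroke class.
#' @param t_out Number of output frames (default 14).
#' @param normalize Apply pelvis centring / size scaling (default `TRUE`).
#' @param label Class label; defaults to the shared stroke annotation.
#' @return A `motion_sample`: list with `x` (array `C x V x T`, channels
#'   first), `label`, `nodes`, `channels` and `phase_ids` (which phase each
#'   output frame came from: 1 = preparation, 2 = shot, 3 = after-shot).
#' @export
assemble_sample <- function(prep, shot, after, t_out = 14L, normalize = TRUE,
                            label = NULL) {
  phases <- list(prep, shot, after)
  for (p in phases) stopifnot(inherits(p, "node_sequence"))
  if (any(vapply(phases, function(p) dim(p$coords)[1L], 1L) < 1L))
    stop("empty phase sequence")
  nodes <- prep$nodes
  if (!all(vapply(phases, function(p) identical(p$nodes, nodes), TRUE)))
    stop("phases disagree on node order")
  strokes <- vapply(phases, `[[`, "", "stroke")
  known <- strokes[!is.na(strokes)]
  if (length(unique(known)) > 1L)
    stop("phases from different stroke classes must not be mixed: ",
         paste(unique(known), collapse = " vs "))
  if (is.null(label)) label <- if (length(known)) known[1L] else NA_character_
  coords <- do.call(abind3, lapply(phases, `[[`, "coords"))
  n <- dim(coords)[1L]
  lens <- vapply(phases, function(p) dim(p$coords)[1L], 1L)
  src_phase <- rep(1:3, lens)
  idx <- .resample_index(n, t_out)
  coords <- coords[idx, , , drop = FALSE]
  if (normalize) {
    pel <- coords[, "pelvis", , drop = FALSE]
    scale <- sqrt(sum((coords[1L, "neck", ] - coords[1L, "pelvis", ])^2))
    if (!is.finite(scale) || scale <= .Machine$double.eps)
      stop("degenerate pose: pelvis and neck coincide in the first frame")
    coords <- sweep(coords, c(1L, 3L), pel[, 1L, ]) / scale
  }
  x <- aperm(coords, c(3L, 2L, 1L))   # C x V x T
  dimnames(x) <- list(dimnames(coords)[[3L]], nodes, NULL)
  structure(list(x = x, label = label, nodes = nodes,
                 channels = dimnames(x)[[1L]],
                 phase_ids = src_phase[idx]),
            class = "motion_sample")
}

#' @export
print.motion_sample <- function(x, ...) {
  d <- dim(x$x)
  cat("Motion sample: C=", d[1L], " V=", d[2L], " T=", d[3L],
      "; label: ", x$label, "\n", sep = "")
  invisible(x)
}

# bind frame-major arrays along dimension 1
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1L], 1L)), d[2L], d[3L]))
  dimnames(out) <- c(list(NULL), dimnames(arrs[[1L]])[2:3])
  at <- 0L
  for (a in arrs) {
    f <- dim(a)[1L]
    out[at + seq_len(f), , ] <- a
    at <- at + f
  }
  out
}

#' Marker and node CSV interchange
#'
#' `write_markers_csv`/`read_markers_csv` store a marker sequence as plain
#' text with one row per frame and columns `<marker>_x`, `<marker>_y`,
#' `<marker>_z` in millimetres.  `write_nodes_csv` does the same for a node
#' sequence in canonical node order.
#'
#' @param seq A `marker_sequence` or `node_sequence`.
#' @param path CSV file path.
#' @param frame_rate Frame rate recorded alongside when reading (the CSV
#'   itself carries no rate).
#' @return Readers return the reconstructed object.
#' @export
write_markers_csv <- function(seq, path) {
  stopifnot(inherits(seq, "marker_sequence"))
  .write_coords_csv(seq$positions, path)
}

#' @rdname write_markers_csv
#' @export
read_markers_csv <- function(path, frame_rate = 100) {
  marker_sequence(.read_coords_csv(path), frame_rate = frame_rate)
}

#' @rdname write_markers_csv
#' @export
write_nodes_csv <- function(seq, path) {
  stopifnot(inherits(seq, "node_sequence"))
  .write_coords_csv(seq$coords, path)
}

#' @rdname write_markers_csv
#' @export
read_nodes_csv <- function(path, frame_rate = 10) {
  node_sequence(.read_coords_csv(path), frame_rate = frame_rate)
}

.write_coords_csv <- function(coords, path) {
  d <- dim(coords)
  axes <- dimnames(coords)[[3L]]
  flat <- matrix(aperm(coords, c(1L, 3L, 2L)), nrow = d[1L])
  colnames(flat) <- paste(rep(dimnames(coords)[[2L]], each = d[3L]),
                          rep(axes, d[2L]), sep = "_")
  utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
  invisible(path)
}

.read_coords_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)
  axes <- sub("^.*_", "", cols)
  marks <- sub("_[^_]+$", "", cols)
  u_axes <- unique(axes)
  u_marks <- unique(marks)
  arr <- array(NA_real_, c(nrow(df), length(u_marks), length(u_axes)),
               dimnames = list(NULL, u_marks, u_axes))
  for (j in seq_along(cols)) arr[, marks[j], axes[j]] <- df[[j]]
  arr
}
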