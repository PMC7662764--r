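#' Per-joint velocity and acceleration series
#'
#' Movement descriptors of single joints: velocity is the central finite
#' difference of position per frame (one-sided at the sequence ends) and
#' acceleration the second finite difference.  Magnitudes (Euclidean norm
#' over the coordinate channels) are reported per joint and frame, in
#' channel units per frame and per frame squared.
#'
#' @param s A `motion_sample` or a `C x V x T` array.
#' @return List with matrices `speed` (V x T) and `accel` (V x T), plus the
#'   raw difference arrays `velocity` and `acceleration` (`C x V x T`).
#' @export
joint_kinematics <- function(s) {
  x <- if (inherits(s, "motion_sample")) s$x else s
  d <- dim(x)
  if (length(d) != 3L) stop("expected a C x V x T array")
  T <- d[3L]
  if (T < 3L) stop("kinematics need at least 3 frames, got ", T)
  vel <- array(0, d)
  vel[, , 2:(T - 1L)] <- (x[, , 3:T, drop = FALSE] - x[, , 1:(T - 2L), drop = FALSE]) / 2
  vel[, , 1L] <- x[, , 2L] - x[, , 1L]
  vel[, , T] <- x[, , T] - x[, , T - 1L]
  acc <- array(0, d)
  acc[, , 2:(T - 1L)] <- x[, , 3:T, drop = FALSE] - 2 * x[, , 2:(T - 1L), drop = FALSE] +
    x[, , 1:(T - 2L), drop = FALSE]
  acc[, , 1L] <- acc[, , 2L]
  acc[, , T] <- acc[, , T - 1L]
  dimnames(vel) <- dimnames(acc) <- dimnames(x)
  list(speed = sqrt(apply(vel^2, c(2L, 3L), sum)),
       accel = sqrt(apply(acc^2, c(2L, 3L), sum)),
       velocity = vel, acceleration = acc)
}

#' Side lengths and interior angles of a joint triangle
#'
#' Posture descriptors over a triangle of three joints: per-frame Euclidean
#' side lengths and interior angles computed by the law of cosines.  For
#' degenerate (collinear) frames the angles take their limit values
#' `{0, 0, pi}`.
#'
#' @param s A `motion_sample` or `C x V x T` array.
#' @param triple Three distinct node names or indices (the triangle's
#'   vertices, in order).
#' @return List of `T x 3` matrices `sides` (opposite each vertex) and
#'   `angles` (radians, at each vertex; rows sum to pi).
#' @export
triangle_features <- function(s, triple) {
  x <- if (inherits(s, "motion_sample")) s$x else s
  nodes <- dimnames(x)[[2L]]
  if (is.character(triple)) triple <- match(triple, nodes)
  if (length(triple) != 3L || anyNA(triple) || anyDuplicated(triple))
    stop("'triple' must name three distinct nodes")
  p <- lapply(1:3, function(k) x[, triple[k], , drop = TRUE])  # C x T each
  len <- function(a, b) sqrt(colSums((a - b)^2))
  # side k is opposite vertex k
  sides <- cbind(len(p[[2L]], p[[3L]]), len(p[[1L]], p[[3L]]), len(p[[1L]], p[[2L]]))
  ang <- function(opp, s1, s2) {
    cosv <- (s1^2 + s2^2 - opp^2) / (2 * s1 * s2)
    cosv[!is.finite(cosv)] <- 1        # coincident points: zero angle limit
    acos(pmin(1, pmax(-1, cosv)))
  }
  angles <- cbind(ang(sides[, 1L], sides[, 2L], sides[, 3L]),
                  ang(sides[, 2L], sides[, 1L], sides[, 3L]),
                  ang(sides[, 3L], sides[, 1L], sides[, 2L]))
  colnames(sides) <- colnames(angles) <-
    if (!is.null(nodes)) nodes[triple] else paste0("v", 1:3)
  list(sides = sides, angles = angles)
}

# Triangle vertex sets of the active-features knowledge base.
.lower_triangle <- c("foot_l", "spine_lower", "foot_r")
.upper_triangle <- c("hand_l", "head", "hand_r")

#' Active feature vector of a motion sample
#'
#' The handcrafted knowledge-base descriptors fused with the network
#' output: per-joint mean speed and mean acceleration magnitude (movement
#' parameters), and time-averaged side lengths and interior angles of the
#' lower posture triangle (left foot, lower spine, right foot) and the
#' upper posture triangle (left hand, head, right hand).  The vector length
#' is `2 V + 12` (50 for the 19-node skeleton).
#'
#' Standardization with training-split statistics is applied later, at
#' model-fitting time, not here.
#'
#' @param s A `motion_sample` with canonical node names.
#' @return Named numeric vector of length `2 V + 12`.
#' @export
active_features <- function(s) {
  x <- if (inherits(s, "motion_sample")) s$x else s
  nodes <- dimnames(x)[[2L]]
  needed <- unique(c(.lower_triangle, .upper_triangle))
  if (is.null(nodes) || !all(needed %in% nodes))
    stop("sample lacks canonical node names: ",
         paste(setdiff(needed, nodes), collapse = ", "))
  kin <- joint_kinematics(x)
  lo <- triangle_features(x, .lower_triangle)
  up <- triangle_features(x, .upper_triangle)
  out <- c(rowMeans(kin$speed), rowMeans(kin$accel),
           colMeans(lo$sides), colMeans(lo$angles),
           colMeans(up$sides), colMeans(up$angles))
  names(out) <- c(paste0("speed_", nodes), paste0("accel_", nodes),
                  paste0("lower_side_", .lower_triangle),
                  paste0("lower_angle_", .lower_triangle),
                  paste0("upper_side_", .upper_triangle),
                  paste0("upper_angle_", .upper_triangle))
  out
}

#' Active features for a whole dataset
#'
#' @param dataset A `motion_dataset` or list of `motion_sample`s.
#' @return Numeric matrix, one row per sample, stable column names.
#' @export
active_features_matrix <- function(dataset) {
  samples <- if (inherits(dataset, "motion_dataset")) .dataset_samples(dataset)
             else dataset
  t(vapply(samples, active_features, numeric(2L * 19L + 12L)))
}
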