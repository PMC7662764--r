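sample_from_coords <- function(coords) {
  # coords: T x V x C -> motion_sample-shaped array (C, V, T)
  x <- aperm(coords, c(3L, 2L, 1L))
  dimnames(x) <- list(c("x", "z"), tennis_skeleton()$nodes, NULL)
  x
}

test_that("kinematics of canonical motions match finite-difference arithmetic", {
  V <- 19L; T <- 10L
  # static pose: zero speed and acceleration
  static <- array(3, c(2, V, T),
                  dimnames = list(c("x", "z"), tennis_skeleton()$nodes, NULL))
  k <- joint_kinematics(static)
  expect_equal(k$speed, matrix(0, V, T, dimnames = dimnames(k$speed)))
  expect_equal(k$accel, matrix(0, V, T, dimnames = dimnames(k$accel)))
  # uniform linear motion with step delta: speed delta, acceleration 0
  delta <- 0.25
  lin <- static
  for (t in seq_len(T)) lin[1, , t] <- delta * t
  k <- joint_kinematics(lin)
  expect_equal(unname(k$speed), matrix(delta, V, T), tolerance = 1e-12)
  expect_equal(unname(k$accel), matrix(0, V, T), tolerance = 1e-12)
  # quadratic trajectory x(t) = t^2: second difference exactly 2 inside
  quad <- static
  for (t in seq_len(T)) quad[1, , t] <- t^2
  k <- joint_kinematics(quad)
  expect_equal(unname(k$accel[, 2:(T - 1)]), matrix(2, V, T - 2),
               tolerance = 1e-12)
  expect_error(joint_kinematics(array(0, c(2, V, 2))), "at least 3")
})

test_that("triangle features match law-of-cosines geometry", {
  V <- 19L; T <- 4L
  base <- array(0, c(T, V, 2))
  # equilateral triangle of side 1 at three fixed nodes
  tri <- c("foot_l", "spine_lower", "foot_r")
  idx <- match(tri, tennis_skeleton()$nodes)
  base[, idx[1], ] <- matrix(c(0, 0), T, 2, byrow = TRUE)
  base[, idx[2], ] <- matrix(c(1, 0), T, 2, byrow = TRUE)
  base[, idx[3], ] <- matrix(c(0.5, sqrt(3) / 2), T, 2, byrow = TRUE)
  x <- sample_from_coords(base)
  tf <- triangle_features(x, tri)
  expect_equal(unname(tf$sides), matrix(1, T, 3), tolerance = 1e-12)
  expect_equal(unname(tf$angles), matrix(pi / 3, T, 3), tolerance = 1e-12)
  # right isoceles with legs 1: sides (1, 1, sqrt(2)), angles (pi/2, pi/4, pi/4)
  base[, idx[3], ] <- matrix(c(0, 1), T, 2, byrow = TRUE)
  tf <- triangle_features(sample_from_coords(base), tri)
  expect_equal(unname(tf$sides[1, ]), c(sqrt(2), 1, 1), tolerance = 1e-12)
  expect_equal(unname(tf$angles[1, ]), c(pi / 2, pi / 4, pi / 4),
               tolerance = 1e-12)
  # collinear limit: angles {0, 0, pi}
  base[, idx[3], ] <- matrix(c(2, 0), T, 2, byrow = TRUE)
  tf <- triangle_features(sample_from_coords(base), tri)
  expect_equal(sort(unname(tf$angles[1, ])), c(0, 0, pi), tolerance = 1e-9)
  expect_error(triangle_features(x, c("head", "head", "neck")), "distinct")
})

test_that("random triangles close to angle sum pi", {
  set.seed(12)
  for (rep in 1:20) {
    base <- array(rnorm(3 * 19 * 2), c(3, 19, 2))
    tf <- triangle_features(sample_from_coords(base),
                            c("hand_l", "head", "hand_r"))
    expect_equal(unname(rowSums(tf$angles)), rep(pi, 3), tolerance = 1e-9)
  }
})

test_that("triangle features are invariant to rigid motions; speeds scale", {
  set.seed(13)
  base <- array(rnorm(6 * 19 * 2), c(6, 19, 2))
  x <- sample_from_coords(base)
  tri <- c("hand_l", "head", "hand_r")
  t0 <- triangle_features(x, tri)
  # rotation + translation of every frame
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- base
  for (f in 1:6) moved[f, , ] <- base[f, , ] %*% t(R) +
      matrix(c(5, -2), 19, 2, byrow = TRUE)
  t1 <- triangle_features(sample_from_coords(moved), tri)
  expect_equal(t1$sides, t0$sides, tolerance = 1e-9)
  expect_equal(t1$angles, t0$angles, tolerance = 1e-9)
  # uniform spatial scaling scales speeds linearly
  k1 <- joint_kinematics(x)
  k3 <- joint_kinematics(x * 3)
  expect_equal(k3$speed, 3 * k1$speed, tolerance = 1e-12)
})

test_that("active feature vectors have the documented layout and length", {
  set.seed(14)
  base <- array(rnorm(14 * 19 * 2), c(14, 19, 2))
  x <- sample_from_coords(base)
  af <- active_features(x)
  expect_length(af, 2 * 19 + 2 * (3 + 3))
  expect_identical(af, active_features(x))   # deterministic
  expect_true(all(af[grepl("side", names(af))] >= 0))
  # angle means of each triangle sum to pi
  expect_equal(sum(af[grepl("^lower_angle", names(af))]), pi, tolerance = 1e-9)
  expect_equal(sum(af[grepl("^upper_angle", names(af))]), pi, tolerance = 1e-9)
  bad <- x
  dimnames(bad)[[2]][1] <- "skull"
  expect_error(active_features(bad), "canonical node")
})

test_that("mirroring swaps left/right joint features, triangles unchanged", {
  set.seed(15)
  coords <- array(rnorm(8 * 19 * 3), c(8, 19, 3),
                  dimnames = list(NULL, tennis_skeleton()$nodes,
                                  c("x", "y", "z")))
  ns <- node_sequence(coords)
  nsm <- mirror_lateral(ns)
  to_sample <- function(s) {
    x <- aperm(s$coords[, , c("x", "z")], c(3, 2, 1))
    dimnames(x) <- list(c("x", "z"), s$nodes, NULL)
    x
  }
  af0 <- active_features(to_sample(ns))
  af1 <- active_features(to_sample(nsm))
  # per-joint blocks swap between left and right
  expect_equal(unname(af1["speed_hand_l"]), unname(af0["speed_hand_r"]),
               tolerance = 1e-12)
  expect_equal(unname(af1["accel_knee_r"]), unname(af0["accel_knee_l"]),
               tolerance = 1e-12)
  # triangle side/angle sets are invariant up to the left-right relabeling
  expect_equal(sort(unname(af1[grepl("^upper_side", names(af1))])),
               sort(unname(af0[grepl("^upper_side", names(af0))])),
               tolerance = 1e-9)
  expect_equal(sort(unname(af1[grepl("^lower_angle", names(af1))])),
               sort(unname(af0[grepl("^lower_angle", names(af0))])),
               tolerance = 1e-9)
})
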