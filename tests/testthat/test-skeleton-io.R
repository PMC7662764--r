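# fixture generator: a plausible random marker recording
make_fixture <- function(frames = 20, seed = 1) {
  set.seed(seed)
  mk <- default_marker_set()
  pos <- array(rnorm(frames * length(mk) * 3, sd = 200),
               c(frames, length(mk), 3),
               dimnames = list(NULL, mk, c("x", "y", "z")))
  pos[, , 3] <- pos[, , 3] + 1000
  marker_sequence(pos, frame_rate = 120, subject = "fixture")
}

test_that("C3D files round-trip through the writer and reader", {
  ms <- make_fixture(120)
  f <- withr::local_tempfile(fileext = ".c3d")
  write_c3d(ms, f)
  ms2 <- read_c3d(f)
  expect_identical(ms2$markers, ms$markers)          # 46 labeled markers
  expect_equal(dim(ms2$positions), dim(ms$positions))
  expect_equal(ms2$frame_rate, 120)
  # float32 storage: relative tolerance of single precision
  expect_lt(max(abs(ms2$positions - ms$positions)), 1e-3)
})

test_that("C3D reader rejects degenerate files with clear messages", {
  expect_error(read_c3d(file.path(tempdir(), "nope.c3d")), "no such file")
  # a marker gap is reported with the marker name and frame span
  ms <- make_fixture(30)
  ms$positions[7:9, "RKNE", ] <- NaN
  f <- withr::local_tempfile(fileext = ".c3d")
  write_c3d(ms, f)
  expect_error(read_c3d(f), "RKNE.*frames 7-9")
  expect_silent(read_c3d(f, validate = FALSE))
  # unlabeled-only file: blank labels are rejected
  ms2 <- make_fixture(5)
  dimnames(ms2$positions)[[2]] <- rep(" ", 46)
  ms2$markers <- rep(" ", 46)
  f2 <- withr::local_tempfile(fileext = ".c3d")
  write_c3d(ms2, f2)
  expect_error(read_c3d(f2), "no labeled points")
  # not a C3D at all
  f3 <- withr::local_tempfile(fileext = ".c3d")
  writeBin(as.raw(c(9, 9, 9, 9)), f3)
  expect_error(read_c3d(f3), "magic|truncated|C3D")
})

test_that("marker CSV fallback round-trips", {
  ms <- make_fixture(10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(ms, f)
  ms2 <- read_markers_csv(f, frame_rate = 120)
  expect_identical(ms2$markers, ms$markers)
  expect_equal(ms2$positions, ms$positions, tolerance = 1e-12)
})

test_that("marker reduction yields exactly 19 nodes and means of sources", {
  ms <- make_fixture(15)
  ns <- reduce_markers(ms)
  expect_equal(dim(ns$coords), c(15L, 19L, 3L))
  expect_identical(ns$nodes, tennis_skeleton()$nodes)
  # head from 4 coincident markers at p reduces to p
  p <- c(11, -22, 333)
  for (m in c("LFHD", "RFHD", "LBHD", "RBHD"))
    ms$positions[3, m, ] <- p
  ns <- reduce_markers(ms)
  expect_equal(unname(ns$coords[3, "head", ]), p)
  # racket head markers at corners of a square reduce to its center
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)) * 50
  ctr <- c(700, 80, 1500)
  rim <- c("RKT_TOP", "RKT_SIDE_L1", "RKT_SIDE_R1", "RKT_HEAD_BOT")
  for (k in 1:4) ms$positions[5, rim[k], ] <- ctr + sq[k, ]
  ns <- reduce_markers(ms)
  expect_equal(unname(ns$coords[5, "racket_head", ]), ctr)
  # missing sources are named
  short <- marker_sequence(ms$positions[, -1, , drop = FALSE], 120)
  expect_error(reduce_markers(short), "LFHD")
})

test_that("mean-based reduction commutes with rigid translation", {
  ms <- make_fixture(8)
  t_vec <- c(100, -50, 20)
  shifted <- ms
  shifted$positions <- ms$positions +
    rep(t_vec, each = prod(dim(ms$positions)[1:2]))
  n0 <- reduce_markers(ms)
  n1 <- reduce_markers(shifted)
  expect_equal(n1$coords,
               n0$coords + rep(t_vec, each = prod(dim(n0$coords)[1:2])),
               tolerance = 1e-9)
})

test_that("plane projection keeps the selected axes and is idempotent", {
  coords <- array(seq_len(2 * 19 * 3), c(2, 19, 3),
                  dimnames = list(NULL, tennis_skeleton()$nodes,
                                  c("x", "y", "z")))
  coords[1, 1, ] <- c(1, 2, 3)
  ns <- node_sequence(coords)
  pr <- project_to_plane(ns, c("x", "z"))
  expect_equal(unname(pr$coords[1, 1, ]), c(1, 3))
  expect_equal(dim(pr$coords)[3], 2L)
  # idempotent on already-2D input
  pr2 <- project_to_plane(pr, c("x", "z"))
  expect_identical(pr2$coords, pr$coords)
  # projection never increases a node's norm
  expect_true(all(sqrt(rowSums(matrix(pr$coords, ncol = 2)^2)) <=
                    sqrt(rowSums(matrix(coords, ncol = 3)^2)) + 1e-12))
  expect_error(project_to_plane(ns, c("x", "x")), "distinct")
  expect_error(project_to_plane(pr, c("x", "y")), "axes")
})

make_phase <- function(frames, stroke, phase, seed = 2, constant = FALSE) {
  set.seed(seed)
  coords <- array(rnorm(frames * 19 * 2, sd = 100), c(frames, 19, 2),
                  dimnames = list(NULL, tennis_skeleton()$nodes, c("x", "z")))
  if (constant) coords <- array(rep(coords[1, , ], each = frames),
                                dim(coords), dimnames(coords))
  coords[, "pelvis", ] <- 0
  coords[, "neck", ] <- rep(c(0, 450), each = frames)
  node_sequence(coords, phase = phase, stroke = stroke)
}

test_that("assembled samples have exactly T frames with phases recorded", {
  prep <- make_phase(5, "forehand", "preparation", 3)
  shot <- make_phase(5, "forehand", "shot", 4)
  after <- make_phase(4, "forehand", "after_shot", 5)
  s <- assemble_sample(prep, shot, after, t_out = 14)
  expect_s3_class(s, "motion_sample")
  expect_equal(dim(s$x), c(2L, 19L, 14L))
  expect_equal(s$label, "forehand")
  expect_identical(s$phase_ids, rep(1:3, c(5, 5, 4)))
  # arbitrary phase lengths still give exactly T frames
  for (lens in list(c(1, 1, 1), c(2, 7, 3), c(9, 1, 2))) {
    s2 <- assemble_sample(make_phase(lens[1], "backhand", "preparation"),
                          make_phase(lens[2], "backhand", "shot"),
                          make_phase(lens[3], "backhand", "after_shot"),
                          t_out = 14)
    expect_equal(dim(s2$x)[3], 14L)
  }
})

test_that("nearest-frame resampling at T = 28 uses every original frame", {
  prep <- make_phase(5, "forehand", "preparation", 6)
  shot <- make_phase(5, "forehand", "shot", 7)
  after <- make_phase(4, "forehand", "after_shot", 8)
  s <- assemble_sample(prep, shot, after, t_out = 28, normalize = FALSE)
  # brute-force index map oracle: with T = 2n each input frame appears twice
  n <- 14L
  oracle <- vapply(seq_len(28), function(t)
    as.integer(min(n, max(1, ceiling((t - 0.5) / 28 * n)))), 1L)
  expect_identical(sort(unique(oracle)), seq_len(n))
  all_frames <- c(prep$coords[, 2, 1], shot$coords[, 2, 1],
                  after$coords[, 2, 1])
  expect_equal(unname(s$x[1, 2, ]), all_frames[oracle])
})

test_that("constant poses assemble into identical frames", {
  prep <- make_phase(5, "no_shot", "preparation", 9, constant = TRUE)
  shot <- make_phase(5, "no_shot", "shot", 9, constant = TRUE)
  after <- make_phase(4, "no_shot", "after_shot", 9, constant = TRUE)
  s <- assemble_sample(prep, prep, prep, t_out = 14)
  for (t in 2:14) expect_equal(s$x[, , t], s$x[, , 1], tolerance = 1e-12)
})

test_that("assembly rejects mixed classes and empty phases", {
  prep <- make_phase(5, "forehand", "preparation")
  shot <- make_phase(5, "backhand", "shot")
  after <- make_phase(4, "forehand", "after_shot")
  expect_error(assemble_sample(prep, shot, after), "not be mixed")
})

test_that("normalization centres the pelvis and fixes the body scale", {
  prep <- make_phase(5, "forehand", "preparation", 10)
  shot <- make_phase(5, "forehand", "shot", 11)
  after <- make_phase(4, "forehand", "after_shot", 12)
  s <- assemble_sample(prep, shot, after, t_out = 14)
  expect_equal(unname(s$x[, "pelvis", ]), matrix(0, 2, 14), tolerance = 1e-12)
  expect_equal(sqrt(sum((s$x[, "neck", 1] - s$x[, "pelvis", 1])^2)), 1,
               tolerance = 1e-12)
})
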