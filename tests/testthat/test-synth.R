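test_that("default configuration reproduces the study composition", {
  cfg <- generator_config()
  expect_equal(cfg$n_forehand + cfg$n_backhand + cfg$n_noshot, 1080L)
  expect_equal(c(cfg$n_forehand, cfg$n_backhand, cfg$n_noshot),
               c(348L, 354L, 378L))
  expect_error(generator_config(n_forehand = 0), "at least 1")
  expect_error(generator_config(noise_sd = -1), "nonnegative")
  expect_error(generator_config(separation = 0), "positive")
})

test_that("generated datasets have exact counts, dims and labels", {
  cfg <- generator_config(n_forehand = 20, n_backhand = 15, n_noshot = 10,
                          pool_per_phase = 5, seed = 5)
  ds <- generate_dataset(cfg)
  expect_s3_class(ds, "motion_dataset")
  expect_equal(dim(ds$x), c(2L, 19L, 14L, 45L))
  expect_equal(as.vector(table(ds$y)), c(20L, 15L, 10L))
  expect_false(anyNA(ds$x))
  expect_equal(nrow(ds$provenance), 45L)
  expect_true(all(as.matrix(ds$provenance) >= 1 &
                    as.matrix(ds$provenance) <= 5))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_forehand = 8, n_backhand = 8, n_noshot = 8,
                          pool_per_phase = 4, seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$provenance, d2$provenance)
  d3 <- generate_dataset(generator_config(n_forehand = 8, n_backhand = 8,
                                          n_noshot = 8, pool_per_phase = 4,
                                          seed = 78))
  expect_false(identical(d1$x, d3$x))
})

test_that("pose templates have rigid limbs across progress", {
  sk <- tennis_skeleton()
  seg_lengths <- function(p)
    apply(sk$edges, 1, function(e) sqrt(sum((p[e[1], ] - p[e[2], ])^2)))
  for (cl in c("forehand", "backhand", "no_shot")) {
    l0 <- NULL
    for (ph in c("preparation", "shot", "after_shot"))
      for (u in seq(0, 1, by = 0.25)) {
        p <- pose_template(cl, ph, u)
        l <- seg_lengths(p)
        if (is.null(l0)) l0 <- l else expect_equal(l, l0, tolerance = 1e-9)
      }
  }
})

test_that("stroke classes start on opposite lateral sides; no-shot stays low", {
  fh <- pose_template("forehand", "preparation", 0)
  bh <- pose_template("backhand", "preparation", 0)
  # racket head relative to the spine axis (y = 0)
  expect_gt(fh["racket_head", "y"], 0)
  expect_lt(bh["racket_head", "y"], 0)
  # no-shot: racket stays within a small lateral band around its carry pose
  ys <- vapply(seq(0, 1, by = 0.1), function(u)
    pose_template("no_shot", "shot", u)["racket_head", "y"], 1)
  expect_lt(diff(range(ys)), 200)   # mm; far below a stroke's sweep
  swing <- vapply(seq(0, 1, by = 0.1), function(u)
    pose_template("forehand", "shot", u)["racket_head", "y"], 1)
  expect_gt(diff(range(swing)), 300)
})

test_that("zero noise and variability give identical repeated samples", {
  cfg <- generator_config(n_forehand = 2, n_backhand = 2, n_noshot = 2,
                          noise_sd = 0, outlier_rate = 0, subject_sd = 0,
                          pool_per_phase = 1, seed = 9)
  ds <- generate_dataset(cfg)
  # one pool instance per phase: samples of a class share phase indices
  expect_equal(ds$x[, , , 1], ds$x[, , , 2], tolerance = 1e-12)
})

test_that("noise magnitude matches the configured standard deviation", {
  base_cfg <- generator_config(n_forehand = 1, n_backhand = 1, n_noshot = 1,
                               noise_sd = 0, outlier_rate = 0, subject_sd = 0,
                               pool_per_phase = 1, seed = 33)
  clean <- generate_dataset(base_cfg)$x[, , , 1]
  sigma <- 0.35
  noisy_cfg <- generator_config(n_forehand = 120, n_backhand = 1, n_noshot = 1,
                                noise_sd = sigma, outlier_rate = 0,
                                subject_sd = 0, pool_per_phase = 1, seed = 33)
  noisy <- generate_dataset(noisy_cfg)
  dev <- sweep(noisy$x[, , , noisy$y == "forehand"], 1:3, clean)
  # Monte-Carlo estimate over > 100 draws of every coordinate
  expect_equal(stats::sd(dev), sigma, tolerance = 0.05)
  expect_equal(mean(dev), 0, tolerance = 0.02)
})

test_that("samples generated without pools have the documented shape", {
  set.seed(21)
  s <- generate_sample("backhand", generator_config(noise_sd = 0.1,
                                                    outlier_rate = 0))
  expect_s3_class(s, "motion_sample")
  expect_equal(dim(s$x), c(2L, 19L, 14L))
  expect_equal(s$label, "backhand")
  expect_error(generate_sample("volley"), "arg")
})

test_that("datasets export as CSV bundles with a manifest", {
  cfg <- generator_config(n_forehand = 2, n_backhand = 2, n_noshot = 2,
                          pool_per_phase = 2, seed = 13)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset_csv(ds, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6L)
  expect_true(all(file.exists(file.path(dir, man$file))))
  s1 <- utils::read.csv(file.path(dir, man$file[1]))
  expect_equal(nrow(s1), 2 * 19)
  expect_equal(ncol(s1), 1 + 14)
})
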