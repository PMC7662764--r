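# Synthetic three-class, three-phase tennis motion generator.
#
# A deterministic articulated pose model (rigid segment lengths, angle
# parameterization) stands in for the recorded strokes: a running base
# posture with gait oscillation, plus a racket-arm swing whose profile
# differs by class.  Phase instances are drawn into per-class pools
# (emulating the study's phase subsets) and samples are assembled by random
# within-class combination of one instance per phase.

# segment lengths and landmark offsets (mm, subject scale 1)
.BODY <- list(
  pelvis_z = 1000, spine1 = 150, spine2 = 300, neck = 450, head = 650,
  shoulder_dz = -40, shoulder_dy = 190, hip_dy = 95,
  thigh = 440, shank = 430, upper_arm = 300, forearm = 280,
  racket_handle = 80, racket_head = 480)

.smoothstep <- function(s) s * s * (3 - 2 * s)

# direction of a limb segment from elevation angle `alpha` (x-z plane,
# positive = forward) and lateral angle `beta` (positive = outward on the
# side with sign `sgn`); unit length by construction
.limb_dir <- function(alpha, beta, sgn) {
  c(sin(alpha) * cos(beta), sgn * sin(beta), -cos(alpha) * cos(beta))
}

# Class- and phase-dependent racket-arm angle profile at master progress s.
# Returns degrees: shoulder elevation, lateral angle, elbow flexion, lean.
.swing_profile <- function(class_label, s, separation = 1) {
  base <- switch(class_label,
    forehand = {
      u <- .smoothstep(s)
      c(alpha = -60 + 150 * u, beta = 40 - 75 * u, elbow = 35 - 20 * u,
        lean = 8 + 6 * u)
    },
    backhand = {
      u <- .smoothstep(s)
      c(alpha = 70 - 135 * u, beta = -45 + 80 * u, elbow = 25 + 10 * u,
        lean = 14 - 8 * u)
    },
    no_shot = c(alpha = -15 + 6 * sin(2 * pi * s),
                beta = 16 + 4 * sin(2 * pi * s + 1),
                elbow = 70, lean = 6),
    stop("unknown class label '", class_label, "'"))
  rest <- c(alpha = -15, beta = 16, elbow = 70, lean = 6)
  rest + separation * (base - rest)
}

#' Deterministic articulated pose template
#'
#' Builds one 19-node 3D pose (mm) of the synthetic stroke model: a running
#' base posture with sinusoidal gait, a torso lean, and a racket-arm swing
#' whose lateral sweep runs dominant-to-cross-body for forehand,
#' cross-body-to-dominant for backhand, and stays in a neutral carry for
#' no-shot.  The racket handle and head are rigidly attached along the
#' forearm direction of the dominant (right) hand, so all segment lengths
#' are constant in `progress`.
#'
#' @param class_label `"forehand"`, `"backhand"` or `"no_shot"`.
#' @param phase `"preparation"`, `"shot"` or `"after_shot"`.
#' @param progress Position within the phase in `[0, 1]`.
#' @param subject Subject parameter list: `scale` (global size factor),
#'   `gait_phase` (radians), `arm`, `leg` (limb length factors),
#'   `amp` (swing amplitude factor).  Defaults describe an average subject.
#' @param separation Class separation factor: 1 = full stroke geometry,
#'   0 = all classes collapse onto the neutral carry.
#' @return 19 x 3 matrix of node positions (mm), canonical node order.
#' @export
pose_template <- function(class_label, phase = c("preparation", "shot", "after_shot"),
                          progress = 0.5,
                          subject = list(scale = 1, gait_phase = 0, arm = 1,
                                         leg = 1, amp = 1),
                          separation = 1) {
  phase <- match.arg(phase)
  stopifnot(progress >= 0, progress <= 1)
  s <- (match(phase, c("preparation", "shot", "after_shot")) - 1L) / 3 + progress / 3
  B <- .BODY
  sc <- subject$scale %||% 1
  deg <- pi / 180
  dur <- 1.4                      # seconds spanned by the three phases
  t <- s * dur
  gait_w <- 2 * pi * 2.0          # 2 Hz leg cycle while running
  gph <- subject$gait_phase %||% 0
  amp <- subject$amp %||% 1

  prof <- .swing_profile(class_label, s, separation)
  alpha <- prof[["alpha"]] * amp * deg
  beta <- prof[["beta"]] * amp * deg
  elbow <- prof[["elbow"]] * deg
  lean <- prof[["lean"]] * deg

  run_speed <- if (class_label == "no_shot") 2200 else 1100   # mm/s
  pelvis <- c(run_speed * t, 0, B$pelvis_z * sc +
                20 * sc * sin(2 * (gait_w * t + gph)))

  # torso chain, tilted forward by `lean` about the pelvis
  axial <- function(dz) pelvis + sc * c(dz * sin(lean), 0, dz * cos(lean))
  spine_lower <- axial(B$spine1)
  spine_upper <- axial(B$spine2)
  neck <- axial(B$neck)
  head <- axial(B$head)

  nodes <- matrix(NA_real_, 19L, 3L,
                  dimnames = list(tennis_skeleton()$nodes, c("x", "y", "z")))
  nodes["pelvis", ] <- pelvis
  nodes["spine_lower", ] <- spine_lower
  nodes["spine_upper", ] <- spine_upper
  nodes["neck", ] <- neck
  nodes["head", ] <- head

  leg_len <- subject$leg %||% 1
  gait_amp <- if (class_label == "no_shot") 32 * deg else 18 * deg
  for (side in c("l", "r")) {
    sgn <- if (side == "l") -1 else 1
    ph <- gph + if (side == "l") pi else 0
    hip <- pelvis + sc * c(0, sgn * B$hip_dy, 0)
    th <- gait_amp * sin(gait_w * t + ph)
    kn <- (14 * deg) * (1 + sin(gait_w * t + ph - pi / 3)) / 2 + 8 * deg
    knee <- hip + sc * leg_len * B$thigh * c(sin(th), 0, -cos(th))
    foot <- knee + sc * leg_len * B$shank * c(sin(th - kn), 0, -cos(th - kn))
    nodes[paste0("hip_", side), ] <- hip
    nodes[paste0("knee_", side), ] <- knee
    nodes[paste0("foot_", side), ] <- foot
  }

  arm_len <- subject$arm %||% 1
  for (side in c("l", "r")) {
    sgn <- if (side == "l") -1 else 1
    sho <- neck + sc * c(B$shoulder_dz * sin(lean),
                         sgn * B$shoulder_dy,
                         B$shoulder_dz * cos(lean))
    if (side == "r") {            # dominant racket arm
      a <- alpha; b <- beta; e <- elbow
    } else {                      # counter-swing with the gait
      a <- (20 * deg) * sin(gait_w * t + gph + pi)
      b <- 12 * deg
      e <- 40 * deg
    }
    d1 <- .limb_dir(a, b, sgn)
    d2 <- .limb_dir(a + e, b, sgn)
    elb <- sho + sc * arm_len * B$upper_arm * d1
    hand <- elb + sc * arm_len * B$forearm * d2
    nodes[paste0("shoulder_", side), ] <- sho
    nodes[paste0("elbow_", side), ] <- elb
    nodes[paste0("hand_", side), ] <- hand
    if (side == "r") {
      nodes["racket_handle", ] <- hand + sc * B$racket_handle * d2
      nodes["racket_head", ] <- hand + sc * B$racket_head * d2
    }
  }
  nodes
}

#' Synthetic dataset generator configuration
#'
#' Default class counts reproduce the study composition (348 forehand, 354
#' backhand, 378 no-shot, 1080 in total) with 5/5/4 frames per phase
#' resampled to 14 output frames at 10 Hz.  The default noise model
#' (`noise_sd`, `outlier_rate`, `outlier_mag`, in units of the normalized
#' body scale) is read from the calibration file shipped with the package
#' (`extdata/calibration.yaml`), which pins the benchmark difficulty.
#'
#' @param n_forehand,n_backhand,n_noshot Samples per class.
#' @param frames_per_phase Frames of the preparation/shot/after phases
#'   before resampling.
#' @param t_out Output frames per sample (default 14).
#' @param noise_sd Per-node Gaussian noise standard deviation (fraction of
#'   the pelvis-neck body scale); `NULL` = calibrated default.
#' @param outlier_rate Probability that a node-frame is hit by a spurious
#'   marker artifact; `NULL` = calibrated default.
#' @param outlier_mag Half-width of the uniform artifact magnitude;
#'   `NULL` = calibrated default.
#' @param subject_sd Relative subject size/limb variability.
#' @param separation Class separation factor (1 = full stroke geometry).
#' @param left_handed_frac Fraction of left-handed subjects, mirrored to the
#'   canonical right-dominant representation (cohort: 1 in 10).
#' @param n_subjects Number of simulated subjects.
#' @param pool_per_phase Phase-instance pool size per class and phase.
#' @param frame_rate Sampling rate in Hz (0.1 s between frames).
#' @param plane Projection plane, default sagittal `c("x", "z")`.
#' @param seed Dataset seed; generation is byte-reproducible given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_forehand = 348L, n_backhand = 354L,
                             n_noshot = 378L, frames_per_phase = c(5L, 5L, 4L),
                             t_out = 14L, noise_sd = NULL, outlier_rate = NULL,
                             outlier_mag = NULL, subject_sd = 0.05,
                             separation = 1, left_handed_frac = 0.1,
                             n_subjects = 10L, pool_per_phase = 40L,
                             frame_rate = 10, plane = c("x", "z"),
                             seed = 20201L) {
  calib <- .load_calibration()
  cfg <- list(n_forehand = as.integer(n_forehand),
              n_backhand = as.integer(n_backhand),
              n_noshot = as.integer(n_noshot),
              frames_per_phase = as.integer(frames_per_phase),
              t_out = as.integer(t_out),
              noise_sd = noise_sd %||% calib$noise_sd,
              outlier_rate = outlier_rate %||% calib$outlier_rate,
              outlier_mag = outlier_mag %||% calib$outlier_mag,
              subject_sd = subject_sd, separation = separation,
              left_handed_frac = left_handed_frac,
              n_subjects = as.integer(n_subjects),
              pool_per_phase = as.integer(pool_per_phase),
              frame_rate = frame_rate, plane = plane,
              seed = as.integer(seed))
  if (any(c(cfg$n_forehand, cfg$n_backhand, cfg$n_noshot) < 1L))
    stop("class counts must be at least 1")
  if (cfg$noise_sd < 0 || cfg$outlier_rate < 0) stop("noise must be nonnegative")
  if (cfg$separation <= 0) stop("separation must be positive")
  structure(cfg, class = "generator_config")
}

.load_calibration <- function() {
  path <- system.file("extdata", "calibration.yaml", package = "stgcn")
  if (nzchar(path) && file.exists(path)) {
    y <- yaml::read_yaml(path)
    list(noise_sd = y$noise_sd, outlier_rate = y$outlier_rate,
         outlier_mag = y$outlier_mag)
  } else {
    list(noise_sd = 0.05, outlier_rate = 0.02, outlier_mag = 3)
  }
}

# draw one subject's parameters
.draw_subject <- function(cfg) {
  list(scale = max(0.5, 1 + stats::rnorm(1, 0, cfg$subject_sd)),
       arm = max(0.5, 1 + stats::rnorm(1, 0, cfg$subject_sd / 2)),
       leg = max(0.5, 1 + stats::rnorm(1, 0, cfg$subject_sd / 2)),
       amp = max(0.3, 1 + stats::rnorm(1, 0, cfg$subject_sd)),
       gait_phase = stats::runif(1, 0, 2 * pi),
       left_handed = stats::runif(1) < cfg$left_handed_frac)
}

# one phase instance: a short 3D node sequence with instance-level timing
# and amplitude jitter; left-handed subjects are generated mirrored and
# mapped back to the canonical right-dominant representation
.phase_instance <- function(class_label, phase, n_frames, cfg, subject) {
  warp <- exp(stats::rnorm(1, 0, 0.10))       # smooth time warp
  inst <- subject
  inst$amp <- subject$amp * exp(stats::rnorm(1, 0, 0.06))
  prog <- if (n_frames == 1L) 0.5 else seq(0, 1, length.out = n_frames)^warp
  coords <- array(NA_real_, c(n_frames, 19L, 3L),
                  dimnames = list(NULL, tennis_skeleton()$nodes, c("x", "y", "z")))
  for (f in seq_len(n_frames))
    coords[f, , ] <- pose_template(class_label, phase, prog[f], inst,
                                   separation = cfg$separation)
  ns <- node_sequence(coords, frame_rate = cfg$frame_rate, phase = phase,
                      stroke = class_label)
  if (isTRUE(subject$left_handed)) {
    # emulate a left-handed recording, then canonicalize it back
    ns <- mirror_lateral(mirror_lateral(ns))
  }
  ns
}

# per-class, per-phase pools of phase instances
.build_pools <- function(cfg, subjects) {
  classes <- c("forehand", "backhand", "no_shot")
  phases <- c("preparation", "shot", "after_shot")
  pools <- lapply(classes, function(cl) {
    lapply(seq_along(phases), function(pi) {
      lapply(seq_len(cfg$pool_per_phase), function(i) {
        subj <- subjects[[sample.int(length(subjects), 1L)]]
        .phase_instance(cl, phases[pi], cfg$frames_per_phase[pi], cfg, subj)
      })
    })
  })
  names(pools) <- classes
  pools
}

# assemble one sample from pool instances and apply the noise model
.compose_sample <- function(class_label, picks, pools, cfg) {
  ph <- lapply(1:3, function(k)
    project_to_plane(pools[[class_label]][[k]][[picks[k]]], cfg$plane))
  s <- assemble_sample(ph[[1L]], ph[[2L]], ph[[3L]], t_out = cfg$t_out,
                       label = class_label)
  d <- dim(s$x)
  if (cfg$noise_sd > 0)
    s$x <- s$x + stats::rnorm(length(s$x), 0, cfg$noise_sd)
  if (cfg$outlier_rate > 0) {
    hit <- stats::runif(d[2L] * d[3L]) < cfg$outlier_rate
    if (any(hit)) {
      spike <- stats::runif(d[1L] * sum(hit), -cfg$outlier_mag, cfg$outlier_mag)
      m <- matrix(s$x, nrow = d[1L])
      m[, hit] <- m[, hit] + matrix(spike, nrow = d[1L])
      s$x <- array(m, d, dimnames = dimnames(s$x))
    }
  }
  s
}

#' Generate a single labeled synthetic sample
#'
#' Draws independent phase instances (preparation, shot, after-shot) of the
#' requested class, concatenates them through [assemble_sample()] and applies
#' the configured noise model.  Phases of different classes are never mixed.
#'
#' @param class_label `"forehand"`, `"backhand"` or `"no_shot"`.
#' @param cfg A [generator_config()].
#' @param pools Optional pre-built phase pools (internal reuse); fresh
#'   instances are drawn when `NULL`.
#' @return A `motion_sample` with dimensions `(C = 2, V = 19, T = t_out)`.
#' @export
generate_sample <- function(class_label, cfg = generator_config(), pools = NULL) {
  class_label <- match.arg(class_label, c("forehand", "backhand", "no_shot"))
  if (is.null(pools)) {
    subj <- .draw_subject(cfg)
    phases <- c("preparation", "shot", "after_shot")
    inst <- lapply(1:3, function(k)
      list(.phase_instance(class_label, phases[k], cfg$frames_per_phase[k],
                           cfg, subj)))
    pools <- stats::setNames(list(inst), class_label)
    picks <- c(1L, 1L, 1L)
  } else {
    picks <- vapply(1:3, function(k)
      sample.int(length(pools[[class_label]][[k]]), 1L), 1L)
  }
  .compose_sample(class_label, picks, pools, cfg)
}

#' Generate the full synthetic dataset
#'
#' Produces exact per-class counts (default 348/354/378 = 1080 samples)
#' by random within-class combination of phase-pool instances, with
#' per-sample noise and marker-artifact contamination.  Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A `motion_dataset`: list with `x` (`2 x 19 x t_out x N` array),
#'   `y` (factor), `provenance` (per-sample phase-instance indices) and
#'   `config`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    subjects <- lapply(seq_len(cfg$n_subjects), function(i) .draw_subject(cfg))
    pools <- .build_pools(cfg, subjects)
    counts <- c(forehand = cfg$n_forehand, backhand = cfg$n_backhand,
                no_shot = cfg$n_noshot)
    N <- sum(counts)
    y <- factor(rep(names(counts), counts), levels = names(counts))
    x <- array(NA_real_, c(2L, 19L, cfg$t_out, N))
    prov <- matrix(NA_integer_, N, 3L,
                   dimnames = list(NULL, c("prep", "shot", "after")))
    dn <- NULL
    for (n in seq_len(N)) {
      cl <- as.character(y[n])
      picks <- vapply(1:3, function(k)
        sample.int(cfg$pool_per_phase, 1L), 1L)
      s <- .compose_sample(cl, picks, pools, cfg)
      x[, , , n] <- s$x
      prov[n, ] <- picks
      if (is.null(dn)) dn <- dimnames(s$x)
    }
    dimnames(x) <- c(dn, list(NULL))
    structure(list(x = x, y = y,
                   provenance = as.data.frame(prov), config = cfg),
              class = "motion_dataset")
  })
}

#' @export
print.motion_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat("Motion dataset: ", d[4L], " samples of (C=", d[1L], ", V=", d[2L],
      ", T=", d[3L], ")\n", sep = "")
  print(table(x$y))
  invisible(x)
}

#' @export
`[.motion_dataset` <- function(x, i) {
  structure(list(x = x$x[, , , i, drop = FALSE], y = x$y[i],
                 provenance = x$provenance[i, , drop = FALSE],
                 config = x$config),
            class = "motion_dataset")
}

#' @export
length.motion_dataset <- function(x) dim(x$x)[4L]

#' Write a dataset as a CSV bundle
#'
#' One coordinates file per sample (nodes in canonical order, frames in
#' columns) plus a manifest CSV with labels and provenance.
#'
#' @param dataset A `motion_dataset`.
#' @param dir Output directory (created if missing).
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- length(dataset)
  files <- sprintf("sample_%04d.csv", seq_len(N))
  for (n in seq_len(N)) {
    m <- matrix(dataset$x[, , , n], nrow = prod(dim(dataset$x)[1:2]))
    rn <- paste(rep(dimnames(dataset$x)[[2L]], each = dim(dataset$x)[1L]),
                rep(dimnames(dataset$x)[[1L]], dim(dataset$x)[2L]), sep = "_")
    utils::write.csv(data.frame(node_channel = rn, m), file.path(dir, files[n]),
                     row.names = FALSE)
  }
  manifest <- cbind(data.frame(file = files, label = dataset$y),
                    dataset$provenance)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
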