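quick_ctl <- function(...) stgcn_control(batch_size = 32L, ...)

test_that("model structure matches the published architecture", {
  ds <- tiny_dataset(4)
  fit <- stgcn(ds, control = quick_ctl(max_epochs = 2), seed = 1)
  cf <- coef(fit)
  # first-layer spatial weights map 2 input channels to 32 kernels
  expect_equal(dim(cf$u1.Ws), c(32L, 2L))
  expect_equal(dim(cf$u2.Ws), c(64L, 32L))
  expect_equal(dim(cf$u3.Ws), c(64L, 64L))
  expect_equal(nrow(cf$W5), 3L)            # 3 classes
  # fuzzy variant differs only in the input-channel count
  fitf <- stgcn(ds, fuzzy = TRUE, control = quick_ctl(max_epochs = 2), seed = 1)
  expect_equal(dim(coef(fitf)$u1.Ws), c(32L, 6L))
  expect_equal(dim(coef(fitf)$u2.Ws), dim(cf$u2.Ws))
})

test_that("parameter count equals the closed-form total", {
  ds <- tiny_dataset(4)
  count_for <- function(fit, c_in, n_feats) {
    ch <- c(c_in, 32, 64, 64)
    units <- sum(vapply(1:3, function(l)
      ch[l + 1] * ch[l] +        # spatial channel map
        ch[l + 1] * 3 +          # depthwise temporal kernel (extent 3)
        3 * ch[l + 1],           # bias + BN gamma/beta
      1))
    units + 64 * 64 + 64 +       # 1x1 convolution
      3 * (64 + n_feats) + 3     # fusion layer to 3 logits
  }
  fit <- stgcn(ds, control = quick_ctl(max_epochs = 1), seed = 1)
  expect_equal(sum(vapply(coef(fit), length, 1L)), count_for(fit, 2, 50))
  fitf <- stgcn(ds, fuzzy = TRUE, control = quick_ctl(max_epochs = 1), seed = 1)
  expect_equal(sum(vapply(coef(fitf), length, 1L)), count_for(fitf, 6, 50))
  # disabling active features shrinks only the fusion layer input
  fit0 <- stgcn(ds, use_features = FALSE, control = quick_ctl(max_epochs = 1),
                seed = 1)
  expect_equal(sum(vapply(coef(fit0), length, 1L)), count_for(fit0, 2, 0))
})

test_that("predicted probabilities are valid and deterministic", {
  ds <- tiny_dataset(5)
  fit <- stgcn(ds, control = quick_ctl(max_epochs = 3), seed = 2)
  pr <- predict(fit, ds, type = "prob")
  expect_equal(dim(pr), c(length(ds), 3L))
  expect_true(all(pr >= 0))
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
  expect_identical(pr, predict(fit, ds, type = "prob"))
})

test_that("a zero final layer yields uniform class probabilities", {
  ds <- tiny_dataset(3)
  fit <- stgcn(ds, control = quick_ctl(max_epochs = 1), seed = 3)
  fit$params$W5[] <- 0
  fit$params$b5[] <- 0
  pr <- predict(fit, ds, type = "prob")
  expect_equal(unname(pr), matrix(1 / 3, nrow(pr), 3), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  # tiny configuration on a 3-node path graph
  set.seed(31)
  g <- path_graph(3)
  cfg <- stgcn:::.nn_cfg(c_in = 2, n_feats = 4, channels = c(3L, 4L, 4L),
                         V = 3L, T = 5L)
  params <- stgcn:::.nn_init(cfg)
  state <- stgcn:::.nn_state_init(cfg)
  N <- 6L
  X <- array(rnorm(2 * 5 * N * 3), c(2, 5, N, 3))
  feats <- matrix(rnorm(4 * N), 4, N)
  y <- rep(1:3, 2)
  loss_at <- function(p) {
    fwd <- stgcn:::.nn_forward(X, feats, p, state, g$A_norm, cfg, train = TRUE)
    stgcn:::.nn_loss(fwd$probs, y)
  }
  fwd <- stgcn:::.nn_forward(X, feats, params, state, g$A_norm, cfg,
                             train = TRUE)
  grads <- stgcn:::.nn_backward(y, fwd, params, g$A_norm, cfg)
  eps <- 1e-6
  for (nm in c("u1.Ws", "u2.Wt", "u3.gamma", "u2.beta", "u1.b",
               "W4", "W5", "b5")) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("training is bit-reproducible from the seed", {
  ds <- tiny_dataset(6, noise_sd = 0.2)
  f1 <- stgcn(ds, control = quick_ctl(max_epochs = 5, patience = 99), seed = 11)
  f2 <- stgcn(ds, control = quick_ctl(max_epochs = 5, patience = 99), seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  f3 <- stgcn(ds, control = quick_ctl(max_epochs = 5, patience = 99), seed = 12)
  expect_false(identical(f1$history, f3$history))
})

test_that("zero learning rate leaves parameters unchanged and stops early", {
  ds <- tiny_dataset(5)
  ctl <- quick_ctl(lr = 0, max_epochs = 50, patience = 4, min_epochs = 1)
  fit <- stgcn(ds, control = ctl, seed = 13)
  init <- stgcn:::.with_seed(13, stgcn:::.nn_init(fit$cfg))
  expect_equal(coef(fit), init, tolerance = 1e-15, ignore_attr = TRUE)
  # no improvement from epoch 2 on: stops after patience more epochs
  expect_equal(fit$epochs, ctl$patience + 1L)
})

test_that("training reaches perfect accuracy on separable data", {
  # zero noise, full class separation: 30 samples per class
  ds <- tiny_dataset(30, noise_sd = 0, subject_sd = 0.03, pool = 8)
  fit <- stgcn(ds, control = stgcn_control(max_epochs = 200), seed = 14)
  expect_lte(fit$epochs, 200)
  acc <- evaluate(fit, ds)$accuracy
  expect_equal(acc, 1.0)
  # loss decreased overall
  expect_lt(fit$history[fit$epochs], fit$history[1])
})

test_that("forward pass is invariant to consistent node permutation", {
  ds <- tiny_dataset(4, noise_sd = 0.1)
  fm <- active_features_matrix(ds)
  fit <- stgcn(ds, feats = fm, control = quick_ctl(max_epochs = 3), seed = 15)
  p0 <- predict(fit, ds, type = "prob", feats = fm)
  # permute graph nodes and sample rows consistently
  set.seed(16)
  P <- sample(19)
  g <- fit$graph
  gp <- skeleton_graph(g$nodes[P],
                       matrix(match(g$nodes[g$edges], g$nodes[P]), ncol = 2))
  fitp <- fit
  fitp$graph <- gp
  dsp <- ds
  dsp$x <- ds$x[, P, , , drop = FALSE]
  pp <- predict(fitp, dsp, type = "prob", feats = fm)
  expect_equal(pp, p0, tolerance = 1e-9)
})

test_that("evaluation metrics follow confusion-matrix arithmetic", {
  truth <- factor(rep(c("forehand", "backhand", "no_shot"), each = 10),
                  levels = c("forehand", "backhand", "no_shot"))
  # perfect predictions
  m <- classification_metrics(truth, truth)
  expect_equal(unname(m$tp_rate), rep(1, 3))
  expect_equal(m$accuracy, 1)
  # constant no-shot predictor on a balanced set
  allno <- factor(rep("no_shot", 30), levels = levels(truth))
  m2 <- classification_metrics(truth, allno)
  expect_equal(m2$accuracy, 1 / 3)
  expect_equal(unname(m2$tp_rate), c(0, 0, 1))
  # random confusions: accuracy equals hand-summed trace ratio
  set.seed(17)
  pred <- factor(sample(levels(truth), 30, replace = TRUE),
                 levels = levels(truth))
  m3 <- classification_metrics(truth, pred)
  cm <- m3$confusion
  expect_equal(m3$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(unname(m3$tp_rate), unname(diag(cm) / rowSums(cm)))
  expect_error(classification_metrics(truth, rep("volley", 30)), "outside")
})

test_that("fit objects expose the standard S3 surface", {
  ds <- tiny_dataset(5, noise_sd = 0.1)
  fit <- stgcn(ds, control = quick_ctl(max_epochs = 3), seed = 18)
  expect_output(print(fit), "ST-GCN")
  expect_output(print(summary(fit)), "parameters")
  expect_equal(dim(fitted(fit)), c(length(ds), 3L))
  r <- residuals(fit)
  expect_equal(dim(r), c(length(ds), 3L))
  expect_equal(unname(rowSums(r)), rep(0, length(ds)), tolerance = 1e-9)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
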