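# Internal neural-network engine: forward/backward passes and SGD.
#
# Internally, activations are (C, T, N, V) arrays — channel-major with the
# node axis last — so that (a) a channel map is one BLAS product on the
# (C, T*N*V) matricization, and (b) the spatial graph aggregation is one
# BLAS product on the (C*T*N, V) matricization against the (symmetric)
# normalized adjacency; neither needs a permute.  The depthwise temporal
# convolution and the fused batch-norm + ReLU run in compiled code
# (src/kernels.cpp).  Each ST-GCN unit computes
#   spatial graph conv (A_norm aggregation + channel map W)
#   -> depthwise temporal conv (extent K, zero padding)
#   -> batch normalization -> ReLU,
# and the head global-average-pools over nodes and time, applies a 1x1
# convolution (a linear map on the pooled channel vector), concatenates the
# standardized active-feature vector and maps to 3 logits + softmax.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

.nn_cfg <- function(c_in, n_feats, channels = c(32L, 64L, 64L),
                    temporal_kernel = 3L, n_classes = 3L, V = 19L, T = 14L,
                    use_features = TRUE) {
  if (temporal_kernel %% 2L != 1L) stop("temporal kernel extent must be odd")
  list(c_in = as.integer(c_in), channels = as.integer(channels),
       K = as.integer(temporal_kernel), n_classes = as.integer(n_classes),
       V = as.integer(V), T = as.integer(T),
       n_feats = if (use_features) as.integer(n_feats) else 0L,
       use_features = isTRUE(use_features))
}

# Seeded uniform fan-in initialization: U(-s, s), s = sqrt(6 / fan_in).
.nn_init <- function(cfg) {
  runifm <- function(nr, nc, fan_in) {
    s <- sqrt(6 / fan_in)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  params <- list()
  cin <- cfg$c_in
  for (l in seq_along(cfg$channels)) {
    cout <- cfg$channels[l]
    params[[paste0("u", l, ".Ws")]] <- runifm(cout, cin, cin)
    params[[paste0("u", l, ".Wt")]] <- runifm(cout, cfg$K, cfg$K)
    params[[paste0("u", l, ".b")]] <- numeric(cout)
    params[[paste0("u", l, ".gamma")]] <- rep(1, cout)
    params[[paste0("u", l, ".beta")]] <- numeric(cout)
    cin <- cout
  }
  ctop <- cfg$channels[length(cfg$channels)]
  params$W4 <- runifm(ctop, ctop, ctop)
  params$b4 <- numeric(ctop)
  fuse <- ctop + cfg$n_feats
  params$W5 <- runifm(cfg$n_classes, fuse, fuse)
  params$b5 <- numeric(cfg$n_classes)
  params
}

.nn_state_init <- function(cfg) {
  lapply(seq_along(cfg$channels), function(l)
    list(mu = numeric(cfg$channels[l]), var = rep(1, cfg$channels[l])))
}

# One ST-GCN unit, forward.
# Activations travel between units as (C * T * N, V) matrices, which share
# their linear layout with the (C, T * N * V) and (C, T, N * V) views the
# channel map and the compiled kernels use — only dim attributes differ,
# and they are only ever set on freshly allocated objects (no copies).
.unit_forward <- function(X, l, params, state, A_norm, cfg, train, N) {
  V <- cfg$V; T <- cfg$T
  cin <- nrow(X) / (T * N)
  cout <- cfg$channels[l]
  p <- function(nm) params[[paste0("u", l, ".", nm)]]

  S <- X %*% A_norm                        # spatial aggregation (A symmetric)
  dim(S) <- c(cin, T * N * V)
  H <- p("Ws") %*% S                       # channel map
  dim(H) <- c(cout, T, N * V)
  st <- state[[l]]
  fr <- unit_fwd_cpp(H, p("Wt"), p("b"), p("gamma"), p("beta"),
                     st$mu, st$var, train, .BN_EPS,
                     c(cout * T * N, V))
  if (train) {
    st$mu <- .BN_MOMENTUM * st$mu + (1 - .BN_MOMENTUM) * fr$mu
    st$var <- .BN_MOMENTUM * st$var + (1 - .BN_MOMENTUM) * fr$var
    state[[l]] <- st
  }
  list(out = fr$out, state = state,
       cache = if (train) list(S = S, H = H, xhat = fr$xhat, istd = fr$istd,
                               out = fr$out, cin = cin, cout = cout,
                               N = N) else NULL)
}

# One ST-GCN unit, backward.  dOut: (C_out * T * N, V); returns dX and grads.
.unit_backward <- function(dOut, l, params, cache, A_norm, cfg) {
  V <- cfg$V; T <- cfg$T; N <- cache$N
  cin <- cache$cin; cout <- cache$cout
  p <- function(nm) params[[paste0("u", l, ".", nm)]]
  g <- list()

  ub <- unit_bwd_cpp(dOut, cache$out, cache$xhat, cache$istd, p("gamma"),
                     cache$H, p("Wt"))
  g$gamma <- ub$dgamma
  g$beta <- ub$dbeta
  g$Wt <- ub$dw
  g$b <- as.numeric(ub$db)
  dH <- ub$dH                              # (C_out, T * N * V)

  g$Ws <- tcrossprod(dH, cache$S)
  dS <- crossprod(p("Ws"), dH)
  dim(dS) <- c(cin * T * N, V)
  dX <- dS %*% A_norm                      # A_norm is symmetric
  names(g) <- paste0("u", l, ".", names(g))
  list(dX = dX, grads = g)
}

# Global average pooling over nodes and time: (C * T * N, V) -> (C, N).
.gap_forward <- function(X, C, T, N) {
  s <- X %*% rep(1 / ncol(X), ncol(X))     # mean over nodes
  dim(s) <- c(C, T, N)
  p <- vapply(seq_len(N),
              function(n) rowMeans(s[, , n, drop = FALSE], dims = 1L),
              numeric(C))
  matrix(p, nrow = C)
}

# Full forward pass.  X: (C_in, T, N, V); feats: (F, N) standardized or NULL.
.nn_forward <- function(X, feats, params, state, A_norm, cfg, train = TRUE) {
  caches <- vector("list", length(cfg$channels))
  N <- length(X) / (dim(X)[1L] * cfg$T * cfg$V)
  cur <- X
  dim(cur) <- c(dim(X)[1L] * cfg$T * N, cfg$V)
  for (l in seq_along(cfg$channels)) {
    u <- .unit_forward(cur, l, params, state, A_norm, cfg, train, N)
    cur <- u$out
    state <- u$state
    caches[[l]] <- u$cache
  }
  ctop <- cfg$channels[length(cfg$channels)]
  p <- .gap_forward(cur, ctop, cfg$T, N)
  qpre <- params$W4 %*% p + params$b4
  q <- qpre * (qpre > 0)
  r <- if (cfg$use_features) rbind(q, feats) else q
  logits <- params$W5 %*% r + params$b5
  mx <- apply(logits, 2L, max)
  e <- exp(logits - rep(mx, each = nrow(logits)))
  probs <- e / rep(colSums(e), each = nrow(e))
  list(probs = probs, state = state,
       cache = if (train) list(units = caches, p = p, q = q, r = r)
               else NULL)
}

# Full backward pass from class labels y (integer 1..n_classes).
.nn_backward <- function(y, fwd, params, A_norm, cfg) {
  probs <- fwd$probs
  N <- ncol(probs)
  G <- probs
  G[cbind(y, seq_len(N))] <- G[cbind(y, seq_len(N))] - 1
  G <- G / N
  grads <- list()
  grads$W5 <- tcrossprod(G, fwd$cache$r)
  grads$b5 <- rowSums(G)
  dr <- crossprod(params$W5, G)
  ctop <- nrow(fwd$cache$q)
  dq <- dr[seq_len(ctop), , drop = FALSE] * (fwd$cache$q > 0)
  grads$W4 <- tcrossprod(dq, fwd$cache$p)
  grads$b4 <- rowSums(dq)
  dp <- crossprod(params$W4, dq)           # (C_top, N)
  V <- cfg$V; T <- cfg$T
  e1 <- aperm(array(dp / (T * V), c(ctop, N, T)), c(1L, 3L, 2L))  # (C, T, N)
  cur <- matrix(as.vector(e1), ctop * T * N, V)    # replicate over nodes
  for (l in rev(seq_along(cfg$channels))) {
    ub <- .unit_backward(cur, l, params, fwd$cache$units[[l]], A_norm, cfg)
    cur <- ub$dX
    grads <- c(grads, ub$grads)
  }
  grads
}

.nn_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(y, seq_len(ncol(probs)))], 1e-12)))
}

# Split N indices into balanced batches: ceiling(n / bs) batches whose sizes
# differ by at most one.  Fixed-size chunking would leave a small trailing
# remainder whose batch-norm statistics and gradient are wildly noisy; a
# near-empty batch once per epoch is enough to destabilize training.
.nn_batches <- function(idx, bs) {
  n <- length(idx)
  k <- max(1L, ceiling(n / bs))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) idx[starts[i]:ends[i]])
}

# SGD with classical momentum and early stopping on the epoch training loss.
.nn_train <- function(X, y, feats, params, state, A_norm, cfg, control) {
  N <- dim(X)[3L]
  vel <- lapply(params, function(p) p * 0)   # zero, preserving shape
  history <- numeric(0)
  best <- Inf
  streak <- 0L
  min_ep <- control$min_epochs %||% 1L
  clip <- control$clip_norm %||% Inf
  wu <- control$warmup %||% 0L
  for (epoch in seq_len(control$max_epochs)) {
    lr <- control$lr *
      (control$decay_factor %||% 1)^sum(epoch > (control$decay_epochs %||% integer()))
    if (epoch <= wu) lr <- lr * epoch / (wu + 1)   # linear warmup
    idx <- if (control$shuffle) sample.int(N) else seq_len(N)
    ep_loss <- 0
    for (b in .nn_batches(idx, control$batch_size)) {
      Xb <- X[, , b, , drop = FALSE]
      fb <- if (cfg$use_features) feats[, b, drop = FALSE] else NULL
      fwd <- .nn_forward(Xb, fb, params, state, A_norm, cfg, train = TRUE)
      state <- fwd$state
      loss <- .nn_loss(fwd$probs, y[b])
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; reduce the learning rate")
      ep_loss <- ep_loss + loss * length(b)
      grads <- .nn_backward(y[b], fwd, params, A_norm, cfg)
      if (is.finite(clip)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 1)))
        if (gn > clip) grads <- lapply(grads, `*`, clip / gn)
      }
      for (nm in names(params)) {
        vel[[nm]] <- control$momentum * vel[[nm]] - lr * grads[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    ep_loss <- ep_loss / N
    history <- c(history, ep_loss)
    if (best - ep_loss < control$tol) streak <- streak + 1L else streak <- 0L
    if (ep_loss < best) best <- ep_loss
    if (epoch >= min_ep && streak >= control$patience) break
  }
  list(params = params, state = state, history = history,
       epochs = length(history))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
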