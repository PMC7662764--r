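#' Trapezoidal membership functions
#'
#' The three trapezoidal membership functions used to fuzzify coordinate
#' channels.  `mu_low` is the right-shoulder "low" set (1 below `c`, linear
#' ramp down on `[c, d]`, 0 above `d`), `mu_mid` the full trapezoid with
#' breakpoints `a < b <= c < d`, and `mu_high` the left-shoulder "high" set
#' (0 below `a`, ramp up on `[a, b]`, 1 above `b`).  All are piecewise-linear,
#' continuous and bounded in `[0, 1]`.
#'
#' @param x Numeric vector (or array) of channel values.
#' @param p A list with the needed breakpoints: `mu_low` uses `c`, `d`;
#'   `mu_mid` uses `a`, `b`, `c`, `d`; `mu_high` uses `a`, `b`.
#' @return Memberships in `[0, 1]`, same shape as `x`.
#' @seealso [fit_fuzzy_bank()], [fuzzify()]
#' @export
#' @examples
#' mu_low(1.5, list(c = 1, d = 2))              # 0.5
#' mu_mid(2.25, list(a = 0, b = 1, c = 2, d = 3))  # 0.75
#' mu_high(1.5, list(a = 1, b = 2))             # 0.5
mu_low <- function(x, p) {
  if (!(p$c < p$d)) stop("mu_low requires c < d")
  y <- (p$d - x) / (p$d - p$c)
  out <- pmin(1, pmax(0, y))
  dim(out) <- dim(x)
  out
}

#' @rdname mu_low
#' @export
mu_mid <- function(x, p) {
  if (!(p$a < p$b && p$b <= p$c && p$c < p$d))
    stop("mu_mid requires a < b <= c < d")
  up <- (x - p$a) / (p$b - p$a)
  down <- (p$d - x) / (p$d - p$c)
  out <- pmin(1, pmax(0, pmin(up, down)))
  dim(out) <- dim(x)
  out
}

#' @rdname mu_low
#' @export
mu_high <- function(x, p) {
  if (!(p$a < p$b)) stop("mu_high requires a < b")
  y <- (x - p$a) / (p$b - p$a)
  out <- pmin(1, pmax(0, y))
  dim(out) <- dim(x)
  out
}

#' Fit a per-channel fuzzy bank from data quantiles
#'
#' For every input channel, places trapezoid breakpoints at empirical
#' quantiles of the observed channel values so that the low / mid / high
#' membership functions tile the observed range and form a partition of
#' unity: the low set's falling ramp coincides with the mid set's rising
#' ramp, and the mid set's falling ramp with the high set's rising ramp,
#' so the three memberships sum to exactly 1 at every value.
#'
#' The bank should be fitted on the training split only, so that test data
#' never influence the breakpoints.
#'
#' @param x A `motion_sample`, a list of them, or a numeric array whose
#'   first dimension indexes channels (`C x V x T` or `C x V x T x N`).
#' @param anchors Four increasing probabilities in (0, 1) giving the quantile
#'   anchors of the mid trapezoid `(a, b, c, d)`; defaults to the 10th, 35th,
#'   65th and 90th percentiles.
#' @return An object of class `fuzzy_bank`: per channel, a list with `low`
#'   (`c`, `d`), `mid` (`a`, `b`, `c`, `d`) and `high` (`a`, `b`).
#' @export
fit_fuzzy_bank <- function(x, anchors = c(0.10, 0.35, 0.65, 0.90)) {
  stopifnot(length(anchors) == 4L, all(diff(anchors) > 0),
            all(anchors > 0), all(anchors < 1))
  arr <- .as_sample_array(x)
  C <- dim(arr)[1L]
  flat <- matrix(arr, nrow = C)   # channel-major: one row per channel
  chan_names <- dimnames(arr)[[1L]]
  if (is.null(chan_names)) chan_names <- paste0("channel", seq_len(C))
  bank <- vector("list", C)
  names(bank) <- chan_names
  for (ch in seq_len(C)) {
    q <- unname(stats::quantile(flat[ch, ], probs = anchors, na.rm = FALSE))
    if (!all(diff(q) > 0))
      stop("degenerate fuzzy bank: channel '", chan_names[ch],
           "' has (near-)zero spread at the requested quantile anchors")
    bank[[ch]] <- list(
      low  = list(c = q[1L], d = q[2L]),
      mid  = list(a = q[1L], b = q[2L], c = q[3L], d = q[4L]),
      high = list(a = q[3L], b = q[4L]))
  }
  structure(bank, class = "fuzzy_bank", anchors = anchors)
}

#' Fuzzify coordinate channels into membership channels
#'
#' Replaces each input channel by its three membership channels (low, mid,
#' high in that order), so the channel count triples (2 coordinate channels
#' become 6 membership channels) while node and time dimensions are
#' unchanged.  All output values lie in `[0, 1]`, and because the bank is a
#' partition of unity the three memberships of a channel sum to 1 at every
#' node and frame.
#'
#' @param x A `motion_sample` or a numeric array with channels first
#'   (`C x V x T` or `C x V x T x N`).
#' @param bank A `fuzzy_bank` fitted on matching channels.
#' @return Same type as the input with `3 * C` channels.
#' @export
fuzzify <- function(x, bank) {
  stopifnot(inherits(bank, "fuzzy_bank"))
  if (inherits(x, "motion_sample")) {
    out <- x
    out$x <- fuzzify(x$x, bank)
    return(out)
  }
  arr <- x
  d <- dim(arr)
  C <- d[1L]
  if (C != length(bank))
    stop("bank has ", length(bank), " channels but data have ", C)
  out <- array(0, c(3L * C, d[-1L]))
  flat <- matrix(arr, nrow = C)
  oflat <- matrix(out, nrow = 3L * C)
  for (ch in seq_len(C)) {
    p <- bank[[ch]]
    oflat[3L * ch - 2L, ] <- mu_low(flat[ch, ], p$low)
    oflat[3L * ch - 1L, ] <- mu_mid(flat[ch, ], p$mid)
    oflat[3L * ch, ]      <- mu_high(flat[ch, ], p$high)
  }
  dim(oflat) <- c(3L * C, d[-1L])
  cn <- names(bank)
  dn <- dimnames(arr)
  dimnames(oflat) <- c(list(paste0(rep(cn, each = 3L), c("_low", "_mid", "_high"))),
                       if (!is.null(dn)) dn[-1L] else
                         rep(list(NULL), length(d) - 1L))
  oflat
}

#' @export
print.fuzzy_bank <- function(x, ...) {
  cat("Fuzzy bank:", length(x), "channel(s), quantile anchors",
      paste(attr(x, "anchors"), collapse = "/"), "\n")
  for (ch in names(x)) {
    m <- x[[ch]]$mid
    cat(sprintf("  %s: a=%.4g b=%.4g c=%.4g d=%.4g\n",
                ch, m$a, m$b, m$c, m$d))
  }
  invisible(x)
}

#' Read and write fuzzy banks as YAML
#'
#' Serializes the per-channel breakpoints to a small YAML file so fuzzified
#' runs are reproducible bit-exactly.
#'
#' @param bank A `fuzzy_bank`.
#' @param path File path.
#' @return `read_fuzzy_bank` returns a `fuzzy_bank`.
#' @export
write_fuzzy_bank <- function(bank, path) {
  stopifnot(inherits(bank, "fuzzy_bank"))
  obj <- list(anchors = as.numeric(attr(bank, "anchors")),
              channels = lapply(unclass(bank), function(ch)
                lapply(ch, function(p) lapply(p, as.numeric))))
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_fuzzy_bank
#' @export
read_fuzzy_bank <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(obj$channels, class = "fuzzy_bank",
            anchors = as.numeric(obj$anchors))
}

# Coerce motion samples / lists of samples / arrays to one C x ... array.
.as_sample_array <- function(x) {
  if (inherits(x, "motion_sample")) return(x$x)
  if (inherits(x, "motion_dataset")) return(x$x)
  if (is.list(x) && length(x) && inherits(x[[1L]], "motion_sample")) {
    arrs <- lapply(x, `[[`, "x")
    d <- dim(arrs[[1L]])
    out <- array(unlist(arrs, use.names = FALSE), c(d, length(arrs)))
    dimnames(out) <- c(dimnames(arrs[[1L]]), list(NULL))
    return(out)
  }
  if (is.array(x)) return(x)
  stop("cannot interpret input as motion sample data")
}
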