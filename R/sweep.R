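#' Stratified train/test split
#'
#' Randomly divides samples into a training and a test set while preserving
#' class proportions to within one sample per class.  The split is
#' reproducible from the seed and never leaves a class empty on either side.
#'
#' @param y Class labels (factor/character) or a `motion_dataset`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(y, fraction, seed = 1L) {
  if (inherits(y, "motion_dataset")) y <- y$y
  y <- factor(y)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  .with_seed(seed, {
    train <- integer(0)
    for (lev in levels(y)) {
      idx <- which(y == lev)
      k <- round(fraction * length(idx))
      if (k < 1L || k >= length(idx))
        stop("fraction ", fraction, " leaves class '", lev,
             "' empty on one side of the split")
      train <- c(train, sample(idx, k))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

#' Specify a train-fraction sweep
#'
#' The benchmark protocol: for every training fraction and replicate, the
#' data are split stratified at that fraction and both network variants
#' (raw coordinate input and fuzzified input) are trained on the identical
#' split with the identical initialization seed (paired design) and
#' evaluated on the held-out test set.
#'
#' @param fractions Training fractions, default 10\% to 65\% in steps of 5\%.
#' @param replicates Independent replicate splits per fraction (default 3).
#' @param variants Subset of `c("raw", "fuzzy")`.
#' @param base_seed Seed from which all split/init seeds are derived.
#' @param control [stgcn_control()] used for every fit.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(fractions = seq(0.10, 0.65, by = 0.05),
                       replicates = 3L, variants = c("raw", "fuzzy"),
                       base_seed = 1L, control = stgcn_control()) {
  if (any(fractions <= 0 | fractions >= 1)) stop("fractions must be in (0, 1)")
  if (replicates < 1L) stop("need at least one replicate")
  variants <- match.arg(variants, c("raw", "fuzzy"), several.ok = TRUE)
  structure(list(fractions = fractions, replicates = as.integer(replicates),
                 variants = variants, base_seed = as.integer(base_seed),
                 control = control),
            class = "sweep_spec")
}

#' Run the train-fraction sweep
#'
#' Executes the full protocol of [sweep_spec()] on a dataset (or on a
#' freshly generated one when given a [generator_config()]).  The fuzzy
#' bank and the active-feature standardization are fitted on each training
#' split only, so no test information leaks into the model.  Failed fits
#' are recorded as `NA` rows and the sweep continues.
#'
#' @param spec A `sweep_spec`.
#' @param data A `motion_dataset` or a `generator_config`.
#' @param verbose Print one line per run.
#' @return An object of class `stgcn_sweep`: `results` (one row per
#'   variant x fraction x replicate with accuracy, per-class true-positive
#'   rates and epochs), `confusions` (list of confusion matrices), `spec`.
#' @export
run_sweep <- function(spec, data, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  dataset <- if (inherits(data, "generator_config")) generate_dataset(data)
             else data
  stopifnot(inherits(dataset, "motion_dataset"))
  feats_all <- active_features_matrix(dataset)
  nf <- length(spec$fractions)
  seeds <- .with_seed(spec$base_seed,
                      matrix(sample.int(.Machine$integer.max - 1L,
                                        2L * nf * spec$replicates),
                             nrow = 2L))
  rows <- list()
  confusions <- list()
  run <- 0L
  for (fi in seq_len(nf)) {
    frac <- spec$fractions[fi]
    for (rep_i in seq_len(spec$replicates)) {
      col <- (fi - 1L) * spec$replicates + rep_i
      split_seed <- seeds[1L, col]
      init_seed <- seeds[2L, col]
      sp <- stratified_split(dataset$y, frac, seed = split_seed)
      for (variant in spec$variants) {
        run <- run + 1L
        rec <- data.frame(variant = variant, fraction = frac,
                          replicate = rep_i, accuracy = NA_real_,
                          tp_forehand = NA_real_, tp_backhand = NA_real_,
                          tp_no_shot = NA_real_, epochs = NA_integer_,
                          split_seed = split_seed, init_seed = init_seed,
                          error = NA_character_)
        res <- tryCatch({
          fit <- stgcn(dataset[sp$train], fuzzy = (variant == "fuzzy"),
                       feats = feats_all[sp$train, , drop = FALSE],
                       control = spec$control, seed = init_seed)
          ev <- evaluate(fit, dataset[sp$test],
                         feats = feats_all[sp$test, , drop = FALSE])
          list(fit = fit, ev = ev)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          rec$error <- conditionMessage(res)
          confusions[[run]] <- NULL
        } else {
          rec$accuracy <- res$ev$accuracy
          rec$tp_forehand <- res$ev$tp_rate[["forehand"]]
          rec$tp_backhand <- res$ev$tp_rate[["backhand"]]
          rec$tp_no_shot <- res$ev$tp_rate[["no_shot"]]
          rec$epochs <- res$fit$epochs
          confusions[[run]] <- res$ev$confusion
        }
        if (verbose)
          message(sprintf("fraction %.0f%% rep %d %-5s acc %.3f (%s epochs)",
                          100 * frac, rep_i, variant,
                          rec$accuracy, rec$epochs))
        rows[[run]] <- rec
      }
    }
  }
  structure(list(results = do.call(rbind, rows), confusions = confusions,
                 spec = spec), class = "stgcn_sweep")
}

#' Per-fraction mean true-positive table of one variant
#'
#' Aggregates a sweep into the benchmark's reporting shape: one row per
#' training fraction with replicate-mean per-class true-positive rates and
#' overall accuracy.
#'
#' @param sweep An `stgcn_sweep`.
#' @param variant `"raw"` or `"fuzzy"`.
#' @return data.frame with columns `fraction`, `tp_forehand`,
#'   `tp_backhand`, `tp_no_shot`, `accuracy`, `epochs`.
#' @export
sweep_table <- function(sweep, variant = c("raw", "fuzzy")) {
  variant <- match.arg(variant)
  r <- sweep$results[sweep$results$variant == variant, , drop = FALSE]
  if (!nrow(r)) stop("variant '", variant, "' is not present in this sweep")
  agg <- stats::aggregate(
    r[, c("tp_forehand", "tp_backhand", "tp_no_shot", "accuracy", "epochs")],
    by = list(fraction = r$fraction), FUN = mean, na.rm = TRUE)
  agg[order(agg$fraction), , drop = FALSE]
}

#' Paired fuzzy-versus-raw comparison
#'
#' Per-fraction paired differences (fuzzy minus raw) of replicate-mean test
#' accuracy and epochs-to-stop, with a sign summary.  Requires both variants
#' at matched fractions and replicates.
#'
#' @param sweep An `stgcn_sweep` containing both variants.
#' @return data.frame of class `stgcn_comparison` with columns `fraction`,
#'   `acc_raw`, `acc_fuzzy`, `acc_diff`, `epochs_raw`, `epochs_fuzzy`,
#'   `epochs_diff`; attribute `mean_acc_diff`.
#' @export
compare_variants <- function(sweep) {
  stopifnot(inherits(sweep, "stgcn_sweep"))
  for (v in c("raw", "fuzzy"))
    if (!any(sweep$results$variant == v))
      stop("sweep is missing the '", v, "' arm")
  tr <- sweep_table(sweep, "raw")
  tf <- sweep_table(sweep, "fuzzy")
  if (!identical(tr$fraction, tf$fraction))
    stop("raw and fuzzy arms do not cover matching fractions")
  out <- data.frame(fraction = tr$fraction,
                    acc_raw = tr$accuracy, acc_fuzzy = tf$accuracy,
                    acc_diff = tf$accuracy - tr$accuracy,
                    epochs_raw = tr$epochs, epochs_fuzzy = tf$epochs,
                    epochs_diff = tf$epochs - tr$epochs)
  attr(out, "mean_acc_diff") <- mean(out$acc_diff, na.rm = TRUE)
  class(out) <- c("stgcn_comparison", "data.frame")
  out
}

#' @export
print.stgcn_comparison <- function(x, ...) {
  cat("Paired fuzzy - raw comparison (replicate means per fraction)\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  d <- attr(x, "mean_acc_diff")
  cat(sprintf("Mean accuracy difference (fuzzy - raw): %+.3f (%s)\n", d,
              if (is.na(d)) "NA" else if (d >= 0) "fuzzy >= raw" else "fuzzy < raw"))
  invisible(x)
}

#' @export
print.stgcn_sweep <- function(x, ...) {
  cat("ST-GCN train-fraction sweep:",
      length(x$spec$fractions), "fractions x", x$spec$replicates,
      "replicates x {", paste(x$spec$variants, collapse = ", "), "}\n")
  for (v in x$spec$variants) {
    cat("\n", v, " variant:\n", sep = "")
    print(format(sweep_table(x, v), digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.stgcn_sweep <- function(x, ...) {
  cols <- c(raw = "grey40", fuzzy = "firebrick")
  tabs <- lapply(x$spec$variants, function(v) sweep_table(x, v))
  ylim <- range(unlist(lapply(tabs, `[[`, "accuracy")), na.rm = TRUE)
  graphics::plot(NULL, xlim = range(x$spec$fractions), ylim = ylim,
                 xlab = "training fraction", ylab = "mean test accuracy",
                 main = "ST-GCN classifier efficiency", ...)
  for (i in seq_along(tabs))
    graphics::lines(tabs[[i]]$fraction, tabs[[i]]$accuracy, type = "b",
                    pch = 19, col = cols[[x$spec$variants[i]]])
  graphics::legend("bottomright", legend = x$spec$variants, lty = 1, pch = 19,
                   col = cols[x$spec$variants], bty = "n")
  invisible(x)
}

#' Export sweep results
#'
#' Writes the per-run results as CSV and the aggregate tables plus the
#' paired comparison as JSON.
#'
#' @param sweep An `stgcn_sweep`.
#' @param dir Output directory (created if missing).
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sweep$results, file.path(dir, "runs.csv"), row.names = FALSE)
  agg <- lapply(stats::setNames(nm = sweep$spec$variants),
                function(v) sweep_table(sweep, v))
  out <- list(aggregate = agg)
  if (all(c("raw", "fuzzy") %in% sweep$spec$variants)) {
    cmp <- compare_variants(sweep)
    out$comparison <- as.data.frame(cmp)
    out$mean_acc_diff <- attr(cmp, "mean_acc_diff")
  }
  jsonlite::write_json(out, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
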