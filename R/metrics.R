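# Dataset splitting, error metrics, cross-validation, serialization.

#' Split a dataset into train and test indices
#'
#' Train size is `round(n * train_fraction)` with half-up rounding (so 398
#' molecules at 80\% give the 318:80 split), drawn as a uniformly random
#' permutation under `seed`.
#'
#' @param n Number of records.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test` and the
#'   `seed` used.
#' @export
split_dataset <- function(n, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(n) || n < 2) stop("need n >= 2 records to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- as.integer(n)
  n_train <- as.integer(floor(n * train_fraction + 0.5))  # half-up
  n_train <- max(1L, min(n - 1L, n_train))
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]),
       seed = as.integer(seed))
}

#' Root-mean-square error between predicted and observed retention times
#'
#' @param predicted,observed Numeric vectors of equal nonzero length (minutes).
#' @return RMSE in minutes.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0)
    stop("predicted and observed must have equal nonzero length")
  sqrt(mean((predicted - observed)^2))
}

#' Fraction of predictions within a retention-time tolerance
#'
#' Uses a strict inequality (|error| < tolerance), matching the convention
#' of counting predictions with errors of less than 2 minutes.
#'
#' @param predicted,observed Numeric vectors of equal length (minutes).
#' @param tolerance_min Tolerance in minutes (default 2).
#' @return Proportion in \[0, 1\].
#' @export
fraction_within <- function(predicted, observed, tolerance_min = 2.0) {
  if (length(predicted) != length(observed) || length(predicted) == 0)
    stop("predicted and observed must have equal nonzero length")
  mean(abs(predicted - observed) < tolerance_min)
}

#' Cross-validate the retention-time model
#'
#' By default performs k independent random 80/20 resplits, each trained
#' from scratch (five differently seeded training/test sets); set
#' `method = "fold"` for disjoint k-fold partitions instead.
#'
#' @param graphs List of `mmrt_graph` objects or SMILES strings.
#' @param rt Retention times in minutes.
#' @param k Number of repeats/folds (default 5).
#' @param config An [mmrt_config()].
#' @param seeds Optional integer vector of length `k`; defaults to
#'   `config$seed + 1:k`.
#' @param train_fraction Train fraction for `method = "resplit"`.
#' @param method `"resplit"` (independent random splits) or `"fold"`.
#' @return An object of class `mmrt_cv`: `mean_rmse`, `sd_rmse`, per-fold
#'   `fold_rmse`, and per-fold fraction within 2 minutes.
#' @export
mmrt_cv <- function(graphs, rt, k = 5L, config = mmrt_config(),
                    seeds = NULL, train_fraction = 0.8,
                    method = c("resplit", "fold")) {
  method <- match.arg(method)
  graphs <- .as_graph_list(graphs)
  rt <- as.numeric(rt)
  n <- length(graphs)
  stopifnot(k >= 2, n >= k, n == length(rt))
  if (is.null(seeds)) seeds <- config$seed + seq_len(k)
  stopifnot(length(seeds) == k)

  if (method == "fold") {
    set.seed(seeds[1L])
    fold_id <- sample(rep(seq_len(k), length.out = n))
  }
  fold_rmse <- numeric(k)
  fold_frac <- numeric(k)
  for (f in seq_len(k)) {
    if (method == "resplit") {
      sp <- split_dataset(n, train_fraction, seeds[f])
      tr <- sp$train; te <- sp$test
    } else {
      te <- which(fold_id == f); tr <- which(fold_id != f)
    }
    cfg <- config
    cfg$seed <- as.integer(seeds[f])
    fit <- tryCatch(
      mmrt(graphs = graphs[tr], rt = rt[tr], config = cfg),
      error = function(e) stop("training failed in fold ", f, ": ",
                               conditionMessage(e)))
    pred <- predict(fit, graphs[te])
    fold_rmse[f] <- rmse(pred, rt[te])
    fold_frac[f] <- fraction_within(pred, rt[te], 2)
  }
  structure(list(mean_rmse = mean(fold_rmse),
                 sd_rmse = stats::sd(fold_rmse),
                 fold_rmse = fold_rmse,
                 fold_fraction_within_2min = fold_frac,
                 k = k, method = method, seeds = seeds),
            class = "mmrt_cv")
}

#' @export
print.mmrt_cv <- function(x, ...) {
  cat(sprintf("%d-%s cross-validation: held-out RMSE %.3f +/- %.3f min\n",
              x$k, if (x$method == "resplit") "resplit" else "fold",
              x$mean_rmse, x$sd_rmse))
  cat("  per fold:", paste(sprintf("%.3f", x$fold_rmse), collapse = ", "), "\n")
  invisible(x)
}

.MMRT_MODEL_FORMAT <- "mmrt-model-1"

#' Save / load a fitted retention-time model
#'
#' The file stores the learned parameters together with JSON metadata (the
#' training configuration, target scaling and feature-layout version tag).
#' Loading validates the format and the feature-layout version and fails
#' loudly on mismatch.
#'
#' @param model A fitted `mmrt` object.
#' @param path File path.
#' @param keep_graphs Keep the training graphs inside the file (default
#'   `FALSE`; predictions do not need them).
#' @return `mmrt_save` returns `path` invisibly; `mmrt_load` returns the
#'   restored `mmrt` model.
#' @export
mmrt_save <- function(model, path, keep_graphs = FALSE) {
  stopifnot(inherits(model, "mmrt"))
  meta <- jsonlite::toJSON(list(
    format = .MMRT_MODEL_FORMAT,
    layout_version = model$layout_version,
    config = unclass(model$config),
    scaling = model$scaling,
    n_train = length(model$rt)
  ), auto_unbox = TRUE, digits = NA)
  obj <- model
  if (!keep_graphs) { obj$graphs <- NULL; obj$fitted.values <- NULL }
  saveRDS(list(format = .MMRT_MODEL_FORMAT, metadata_json = as.character(meta),
               model = obj), path)
  invisible(path)
}

#' @rdname mmrt_save
#' @export
mmrt_load <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, .MMRT_MODEL_FORMAT))
    stop("'", path, "' is not a ", .MMRT_MODEL_FORMAT, " model file")
  model <- obj$model
  if (!identical(model$layout_version, feature_layout()$version))
    stop("feature-layout version mismatch: file has '",
         model$layout_version, "', package uses '",
         feature_layout()$version, "'")
  class(model) <- "mmrt"
  model
}

#' Library coverage percentage
#'
#' Percent of library metabolites retained by the chromatographic method,
#' rounded to one decimal (398 of 607 gives 65.6).
#'
#' @param n_retained,n_total Counts of retained and injected metabolites.
#' @return Percentage rounded to one decimal.
#' @export
library_coverage <- function(n_retained, n_total) {
  stopifnot(n_total > 0, n_retained >= 0, n_retained <= n_total)
  round(100 * n_retained / n_total, 1)
}
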