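# User-facing model fitting: mmrt() trains the message-passing network on
# (SMILES, retention time) pairs and returns a classed model object.

#' Training configuration for the retention-time network
#'
#' Defaults follow the training protocol of the underlying method: four
#' rounds of message passing, a four-stage set2set readout, 100 epochs with
#' mini-batches of 64, and an adaptive-gradient (Adam) optimizer at learning
#' rate 1e-3. `hidden_dim` is the node-state width and must be at least the
#' atom feature length (32).
#'
#' @param hidden_dim Node state width (default 64).
#' @param message_steps Rounds of message passing T (default 4).
#' @param set2set_steps Set2set processing steps M (default 4).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed controlling initialization and batch order.
#' @return A list of class `mmrt_config`.
#' @export
mmrt_config <- function(hidden_dim = 64L, message_steps = 4L,
                        set2set_steps = 4L, epochs = 100L, batch_size = 64L,
                        learning_rate = 1e-3, seed = 1L) {
  lay <- feature_layout()
  stopifnot(hidden_dim >= lay$atom_len, message_steps >= 1,
            set2set_steps >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 message_steps = as.integer(message_steps),
                 set2set_steps = as.integer(set2set_steps),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "mmrt_config")
}

.as_graph_list <- function(x, strip_salts = FALSE) {
  if (inherits(x, "mmrt_graph")) return(list(x))
  if (is.character(x)) return(lapply(x, parse_smiles, strip_salts = strip_salts))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "mmrt_graph"))) return(x)
  stop("expected SMILES strings or mmrt_graph objects")
}

#' Fit a retention-time model to molecules
#'
#' Trains a message-passing neural network that predicts chromatographic
#' retention time (minutes) from the heavy-atom connectivity graph of each
#' molecule. Targets are z-scored internally; the scaling constants are
#' stored on the model so predictions are returned in minutes.
#'
#' @param formula A formula of the form `rt_min ~ smiles` naming the
#'   retention-time and SMILES columns of `data`.
#' @param data A data frame holding those columns.
#' @param graphs Alternatively, a list of `mmrt_graph` objects (or character
#'   SMILES); used with `rt` when `formula`/`data` are omitted.
#' @param rt Numeric retention times in minutes, parallel to `graphs`.
#' @param config An `mmrt_config`; individual settings can also be passed as
#'   `...` shortcuts (e.g. `epochs = 30`).
#' @param verbose Print the running epoch loss.
#' @param ... Overrides forwarded to [mmrt_config()].
#' @return An object of class `mmrt` with components `params`, `config`,
#'   `scaling`, `loss` (per-epoch training MSE on scaled targets),
#'   `fitted.values`, `graphs` and `rt`. Methods: `print`, `summary`,
#'   `predict`, `residuals`, `coef`, `plot`.
#' @examples
#' \donttest{
#' d <- generate_molecules(synthetic_spec(n = 40, seed = 1))
#' fit <- mmrt(rt_min ~ smiles, d, epochs = 5, hidden_dim = 32)
#' predict(fit, "CCO")
#' }
#' @export
mmrt <- function(formula = NULL, data = NULL, graphs = NULL, rt = NULL,
                 config = NULL, verbose = FALSE, ...) {
  cl <- match.call()
  if (!is.null(formula)) {
    stopifnot(inherits(formula, "formula"), is.data.frame(data))
    vars <- all.vars(formula)
    if (length(vars) != 2L)
      stop("formula must have the form rt_min ~ smiles")
    rt <- data[[vars[1L]]]
    graphs <- data[[vars[2L]]]
    if (is.null(rt) || is.null(graphs))
      stop("columns '", vars[1L], "' and '", vars[2L], "' not both in data")
  }
  if (is.null(config)) config <- mmrt_config(...)
  stopifnot(inherits(config, "mmrt_config"))
  graphs <- .as_graph_list(graphs)
  rt <- as.numeric(rt)
  n <- length(graphs)
  if (n != length(rt)) stop("graphs and rt lengths differ")
  if (any(!is.finite(rt))) stop("non-finite retention times in training data")
  if (n < 2L) stop("need at least 2 training molecules")

  lay <- feature_layout()
  bad <- which(vapply(graphs, function(g) g$layout_version, "") != lay$version)
  if (length(bad))
    stop("feature-layout version mismatch in graphs: ", toString(bad))

  mu <- mean(rt)
  sdv <- stats::sd(rt)
  if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
  z <- (rt - mu) / sdv

  if (n < config$batch_size)
    warning("dataset (", n, ") smaller than one batch (", config$batch_size,
            "); training with a single smaller batch")

  set.seed(config$seed)
  par <- .mpnn_init(config$hidden_dim, lay$atom_len, lay$bond_len)
  state <- new.env(parent = emptyenv())
  state$m <- .zero_like(par)
  state$v <- .zero_like(par)
  state$t <- 0L

  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      g <- list2env(.zero_like(par), parent = emptyenv())
      for (k in idx) {
        fw <- .mpnn_forward(par, graphs[[k]], config, keep_cache = TRUE)
        err <- fw$ys - z[k]
        ep_loss <- ep_loss + err^2
        .mpnn_backward(par, graphs[[k]], config, fw$cache,
                       2 * err / length(idx), g)
      }
      par <- .adam_update(par, g, state, config$learning_rate)
    }
    losses[ep] <- ep_loss / n
    if (verbose) cat(sprintf("epoch %3d  loss %.5f\n", ep, losses[ep]))
  }

  fitted <- vapply(graphs, function(gr)
    .mpnn_forward(par, gr, config)$ys * sdv + mu, numeric(1))

  structure(list(
    params = par,
    config = config,
    layout_version = lay$version,
    scaling = list(mean = mu, sd = sdv),
    loss = losses,
    fitted.values = fitted,
    graphs = graphs,
    rt = rt,
    call = cl
  ), class = "mmrt")
}

#' Predict retention times for new molecules
#'
#' @param object A fitted `mmrt` model.
#' @param newdata SMILES strings, a data frame with a `smiles` column, an
#'   `mmrt_graph`, or a list of graphs. Defaults to the training molecules.
#' @param ... Unused.
#' @return Predicted retention times in minutes.
#' @export
predict.mmrt <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.data.frame(newdata)) {
    if (is.null(newdata$smiles)) stop("newdata must have a 'smiles' column")
    newdata <- newdata$smiles
  }
  graphs <- .as_graph_list(newdata)
  vv <- vapply(graphs, function(g) g$layout_version, "")
  if (any(vv != object$layout_version))
    stop("feature-layout version mismatch: model '", object$layout_version,
         "' vs graph '", vv[vv != object$layout_version][1L], "'")
  vapply(graphs, function(g)
    .mpnn_forward(object$params, g, object$config)$ys *
      object$scaling$sd + object$scaling$mean, numeric(1))
}

#' @export
print.mmrt <- function(x, ...) {
  cat("Mixed-mode retention-time MPNN\n")
  cat(sprintf("  %d molecules, hidden dim %d, %d message steps, %d set2set steps\n",
              length(x$graphs), x$config$hidden_dim, x$config$message_steps,
              x$config$set2set_steps))
  cat(sprintf("  trained %d epochs (batch %d, lr %g, seed %d); final loss %.4f\n",
              x$config$epochs, x$config$batch_size, x$config$learning_rate,
              x$config$seed, x$loss[length(x$loss)]))
  cat(sprintf("  training RMSE %.3f min; %.1f%% of molecules within 2 min\n",
              rmse(x$fitted.values, x$rt),
              100 * fraction_within(x$fitted.values, x$rt, 2)))
  invisible(x)
}

#' @export
summary.mmrt <- function(object, ...) {
  res <- object$rt - object$fitted.values
  out <- list(
    n = length(object$rt),
    rmse = rmse(object$fitted.values, object$rt),
    mae = mean(abs(res)),
    fraction_within_2min = fraction_within(object$fitted.values, object$rt, 2),
    residual_quantiles = stats::quantile(res, c(0, .25, .5, .75, 1)),
    config = object$config,
    final_loss = object$loss[length(object$loss)]
  )
  class(out) <- "summary.mmrt"
  out
}

#' @export
print.summary.mmrt <- function(x, ...) {
  cat("Retention-time MPNN fit summary\n")
  cat(sprintf("  n = %d   training RMSE = %.3f min   MAE = %.3f min\n",
              x$n, x$rmse, x$mae))
  cat(sprintf("  fraction with |error| < 2 min: %.3f\n", x$fraction_within_2min))
  cat("  residuals (min):\n")
  print(round(x$residual_quantiles, 3))
  invisible(x)
}

#' @export
residuals.mmrt <- function(object, ...) object$rt - object$fitted.values

#' @export
coef.mmrt <- function(object, ...) object$params

#' Observed-vs-predicted plot for a fitted retention-time model
#'
#' @param x A fitted `mmrt` model.
#' @param tolerance_min Error band drawn around the identity line (minutes).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mmrt <- function(x, tolerance_min = 2, ...) {
  ok <- abs(x$fitted.values - x$rt) < tolerance_min
  graphics::plot(x$rt, x$fitted.values,
                 col = ifelse(ok, "steelblue", "darkorange"), pch = 16,
                 xlab = "observed RT (min)", ylab = "predicted RT (min)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(tolerance_min, 1, lty = 3, col = "grey50")
  graphics::abline(-tolerance_min, 1, lty = 3, col = "grey50")
  invisible(x)
}
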