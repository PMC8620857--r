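# Descriptor-based baseline models (linear regression and random forest)
# for comparison against the graph network.

.HALOGENS <- c("F", "Cl", "Br", "I")

#' Compute a hand-picked molecular descriptor vector
#'
#' A fixed, deterministic descriptor set: heavy-atom count; element counts
#' (N, O, P, S, halogens); ring count (cyclomatic number); aromatic-atom
#' count; hydrogen-bond donor and acceptor counts; formal-charge sum; and
#' counts of five functional groups (carboxylic acid, phosphate, amide,
#' amine, hydroxyl). This set is a documented stand-in for unpublished
#' hand-picked feature lists used in descriptor-based retention models.
#'
#' @param graph An `mmrt_graph`.
#' @return A named numeric vector of length 15.
#' @export
compute_descriptors <- function(graph) {
  stopifnot(inherits(graph, "mmrt_graph"))
  el <- graph$element
  grp <- count_groups(graph)
  n_comp <- 1L  # parse_smiles guarantees one covalent unit
  c(
    n_heavy = graph$n_atoms,
    n_N = sum(el == "N"),
    n_O = sum(el == "O"),
    n_P = sum(el == "P"),
    n_S = sum(el == "S"),
    n_halogen = sum(el %in% .HALOGENS),
    n_rings = max(0L, nrow(graph$bonds) - graph$n_atoms + n_comp),
    n_aromatic_atoms = sum(graph$aromatic),
    hbd = sum((el == "O" | el == "N") & graph$n_h >= 1L),
    hba = sum(el == "O" | el == "N"),
    charge_sum = sum(graph$charge),
    n_carboxylic_acid = unname(grp["carboxylic_acid"]),
    n_phosphate = unname(grp["phosphate"]),
    n_amide = unname(grp["amide"]),
    n_amine = unname(grp["amine"]),
    n_hydroxyl = unname(grp["hydroxyl"])
  )
}

#' Fit a descriptor-based baseline retention model
#'
#' @param kind `"linear"` (ordinary least squares, with a small ridge
#'   fallback when the design matrix is singular) or `"random_forest"`
#'   (bagged trees, 200 trees, seeded).
#' @param graphs List of `mmrt_graph` objects or SMILES strings.
#' @param rt Retention times (minutes).
#' @param seed Seed for the forest.
#' @param ntree Number of trees for the forest.
#' @return An object of class `mmrt_baseline` with a `predict` method.
#' @export
fit_baseline <- function(kind = c("linear", "random_forest"), graphs, rt,
                         seed = 1L, ntree = 200L) {
  kind <- match.arg(kind)
  graphs <- .as_graph_list(graphs)
  rt <- as.numeric(rt)
  stopifnot(length(graphs) == length(rt), length(rt) >= 2)
  X <- t(vapply(graphs, compute_descriptors,
                numeric(length(compute_descriptors(graphs[[1L]])))))
  fit <- NULL
  ridge_used <- FALSE
  if (kind == "linear") {
    df <- data.frame(rt = rt, X)
    fit <- stats::lm(rt ~ ., data = df)
    if (anyNA(stats::coef(fit))) {
      # rank-deficient design: fall back to a small ridge penalty
      warning("singular design matrix; using ridge fallback (lambda = 1e-6)")
      ridge_used <- TRUE
      Xc <- cbind(1, X)
      lambda <- 1e-6
      beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)), crossprod(Xc, rt))
      fit <- list(beta = drop(beta))
    }
  } else {
    set.seed(seed)
    fit <- randomForest::randomForest(x = X, y = rt, ntree = ntree)
  }
  structure(list(kind = kind, fit = fit, ridge = ridge_used,
                 descriptor_names = colnames(X)),
            class = "mmrt_baseline")
}

#' @export
predict.mmrt_baseline <- function(object, newdata, ...) {
  graphs <- .as_graph_list(newdata)
  X <- t(vapply(graphs, compute_descriptors,
                numeric(length(object$descriptor_names))))
  colnames(X) <- object$descriptor_names
  if (object$kind == "linear") {
    if (object$ridge) return(drop(cbind(1, X) %*% object$fit$beta))
    return(unname(stats::predict(object$fit, newdata = as.data.frame(X))))
  }
  unname(stats::predict(object$fit, newdata = X))
}

#' @export
print.mmrt_baseline <- function(x, ...) {
  cat("Baseline retention model (", x$kind, "), ",
      length(x$descriptor_names), " descriptors\n", sep = "")
  invisible(x)
}

#' Compare the graph model against descriptor baselines by cross-validation
#'
#' Runs the same k random resplits for the MPNN, the linear baseline, and
#' the random forest, and tabulates held-out RMSE and the fraction of
#' held-out predictions within 2 minutes.
#'
#' @param graphs Molecules (graphs or SMILES).
#' @param rt Retention times (minutes).
#' @param k Number of random resplits.
#' @param config [mmrt_config()] for the network.
#' @param seeds Optional seeds, length `k`.
#' @param train_fraction Train fraction per resplit.
#' @return A data frame: model, mean_rmse, sd_rmse, mean_fraction_2min.
#' @export
compare_baselines <- function(graphs, rt, k = 5L, config = mmrt_config(),
                              seeds = NULL, train_fraction = 0.8) {
  graphs <- .as_graph_list(graphs)
  rt <- as.numeric(rt)
  n <- length(graphs)
  if (is.null(seeds)) seeds <- config$seed + seq_len(k)
  res <- list()
  for (model_name in c("mpnn", "linear", "random_forest")) {
    rm_ <- numeric(k); fr_ <- numeric(k)
    for (f in seq_len(k)) {
      sp <- split_dataset(n, train_fraction, seeds[f])
      if (model_name == "mpnn") {
        cfg <- config; cfg$seed <- as.integer(seeds[f])
        fit <- mmrt(graphs = graphs[sp$train], rt = rt[sp$train], config = cfg)
        pred <- predict(fit, graphs[sp$test])
      } else {
        fit <- fit_baseline(model_name, graphs[sp$train], rt[sp$train],
                            seed = seeds[f])
        pred <- predict(fit, graphs[sp$test])
      }
      rm_[f] <- rmse(pred, rt[sp$test])
      fr_[f] <- fraction_within(pred, rt[sp$test], 2)
    }
    res[[model_name]] <- data.frame(model = model_name,
                                    mean_rmse = mean(rm_),
                                    sd_rmse = stats::sd(rm_),
                                    mean_fraction_2min = mean(fr_))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
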