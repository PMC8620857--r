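# Synthetic data with known group-contribution ground truth. Molecules are
# random carbon scaffolds decorated with functional groups; the true
# retention time is linear in group counts, which is exactly the structure
# the attribution method is meant to detect.

.GROUP_SMILES <- c(phosphate = "OP(=O)(O)O",
                   carboxylic_acid = "C(=O)O",
                   amide = "C(=O)N",
                   amine = "N",
                   hydroxyl = "O")

#' Specification for the synthetic group-contribution generator
#'
#' Ground-truth retention time is `intercept + sum(counts * effects)` with
#' additive Gaussian noise. Default group effects take the reported
#' magnitudes for phosphate (+15 min), carboxylic acid (+4 min) and amide
#' (-7 min); the amine (-3 min) and hydroxyl (+0.5 min) values are chosen
#' for coverage of weak negative and weak positive contributors.
#'
#' @param n Number of molecules.
#' @param effects Named vector of group effects in minutes.
#' @param intercept Baseline retention (minutes, default 8).
#' @param noise_sd Gaussian noise sd in minutes (default 0.5).
#' @param seed Integer seed.
#' @param interaction If nonzero, adds `interaction` minutes whenever a
#'   molecule carries both a phosphate and an amide (a deliberate
#'   non-additive term for robustness experiments; default 0).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 300L,
                           effects = c(phosphate = 15.0,
                                       carboxylic_acid = 4.0,
                                       amide = -7.0,
                                       amine = -3.0,
                                       hydroxyl = 0.5),
                           intercept = 8.0, noise_sd = 0.5, seed = 1L,
                           interaction = 0) {
  stopifnot(n >= 1, noise_sd >= 0,
            all(names(.GROUP_SMILES) %in% names(effects)))
  structure(list(n = as.integer(n), effects = effects,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed), interaction = interaction),
            class = "synthetic_spec")
}

# one random decorated scaffold; returns smiles + group counts
.random_molecule <- function() {
  L <- sample(3:10, 1L)
  # free substituent slots: terminal carbons have 3, interior have 2
  slots <- ifelse(seq_len(L) %in% c(1L, L), 3L, 2L)
  counts <- c(phosphate = stats::rbinom(1, 1, 0.40),
              carboxylic_acid = stats::rbinom(1, 2, 0.30),
              amide = stats::rbinom(1, 1, 0.35),
              amine = stats::rbinom(1, 1, 0.30),
              hydroxyl = stats::rbinom(1, 3, 0.35))
  total <- sum(counts)
  if (total > sum(slots)) return(NULL)
  decorations <- rep(names(counts), counts)
  if (length(decorations) > 0) decorations <- sample(decorations)
  at <- integer(0)
  avail <- slots
  for (d in seq_along(decorations)) {
    open <- which(avail > 0)
    if (length(open) == 0) return(NULL)
    pos <- if (length(open) == 1L) open else sample(open, 1L)
    avail[pos] <- avail[pos] - 1L
    at <- c(at, pos)
  }
  parts <- character(L)
  for (k in seq_len(L)) {
    subs <- decorations[at == k]
    parts[k] <- paste0("C", paste0("(", .GROUP_SMILES[subs], ")",
                                   collapse = ""))
    if (length(subs) == 0) parts[k] <- "C"
  }
  list(smiles = paste(parts, collapse = ""), counts = counts)
}

#' Generate synthetic molecules with known retention ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame: `name`, `smiles`, `rt_min` (observed, noisy) plus
#'   hidden-truth columns `rt_true` and per-group counts
#'   (`n_phosphate`, ...). Deterministic under the spec seed; every SMILES
#'   round-trips through [parse_smiles()].
#' @export
generate_molecules <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    mol <- NULL
    for (try_i in 1:100) {
      mol <- .random_molecule()
      if (!is.null(mol)) break
    }
    if (is.null(mol)) stop("molecule generation failed after 100 retries")
    rt_true <- spec$intercept +
      sum(spec$effects[names(mol$counts)] * mol$counts) +
      spec$interaction * (mol$counts["phosphate"] > 0 &&
                            mol$counts["amide"] > 0)
    rows[[i]] <- data.frame(
      name = sprintf("syn%04d", i),
      smiles = mol$smiles,
      rt_true = rt_true,
      n_phosphate = mol$counts[["phosphate"]],
      n_carboxylic_acid = mol$counts[["carboxylic_acid"]],
      n_amide = mol$counts[["amide"]],
      n_amine = mol$counts[["amine"]],
      n_hydroxyl = mol$counts[["hydroxyl"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$rt_min <- out$rt_true +
    if (spec$noise_sd > 0) stats::rnorm(spec$n, 0, spec$noise_sd) else 0
  out[, c("name", "smiles", "rt_min", "rt_true", "n_phosphate",
          "n_carboxylic_acid", "n_amide", "n_amine", "n_hydroxyl")]
}

#' Generate a synthetic untargeted feature table with matching database
#'
#' Emulates the inputs of the annotation workflow: each designed "true hit"
#' feature carries the \[M-H\]- m/z of one database molecule perturbed by
#' less than 2 ppm, qualifies under the default statistical filter
#' (p < 0.01, fold change > 2, intensity > 1e6), and its observed retention
#' time equals the true candidate's database RT plus `rt_noise_sd` noise.
#' The database adds `n_decoys` isomeric decoys per true molecule (same
#' scaffold and group multiset placed differently, hence the same formula
#' and exact mass) with different generated RTs. Remaining features are
#' designed to fail the filter.
#'
#' @param n_features Total feature rows.
#' @param n_true_hits How many features are designed true hits
#'   (must be <= `n_features`).
#' @param seed Integer seed.
#' @param n_decoys Isomeric decoys per true molecule (default 2).
#' @param rt_noise_sd Noise on observed feature RT in minutes (default 0).
#' @param min_rt_gap Minimum |decoy RT - true RT| (default 4 min).
#' @return A list: `features` (data frame `mz`, `rt_min`, `intensity`,
#'   `p_value`, `fold_change`, `true_name`), `db` (data frame `name`,
#'   `formula`, `smiles`, `monoisotopic_mass`, `rt_db`).
#' @export
generate_feature_table <- function(n_features = 12L, n_true_hits = 6L,
                                   seed = 1L, n_decoys = 2L,
                                   rt_noise_sd = 0, min_rt_gap = 4) {
  stopifnot(n_true_hits <= n_features, n_true_hits >= 1)
  set.seed(seed)
  db_rows <- list()
  feat_rows <- list()
  made <- 0L
  guard <- 0L
  while (made < n_true_hits && guard < 1000L) {
    guard <- guard + 1L
    mol <- .random_molecule()
    if (is.null(mol) || sum(mol$counts) == 0) next
    g <- tryCatch(parse_smiles(mol$smiles), error = function(e) NULL)
    if (is.null(g)) next
    formula <- .graph_formula(g)
    rt_true <- stats::runif(1, 5, 40)
    # isomeric decoys: same group multiset on the same scaffold length,
    # different placement -> same formula, different structure and RT
    decoys <- list()
    tries <- 0L
    while (length(decoys) < n_decoys && tries < 50L) {
      tries <- tries + 1L
      d <- .random_isomer(mol)
      if (is.null(d)) next
      dg <- tryCatch(parse_smiles(d), error = function(e) NULL)
      if (is.null(dg) || dg$smiles_canonical == g$smiles_canonical) next
      if (any(vapply(decoys, function(x) x$can == dg$smiles_canonical,
                     logical(1)))) next
      rt_d <- rt_true + sample(c(-1, 1), 1) * stats::runif(1, min_rt_gap, 15)
      decoys[[length(decoys) + 1L]] <- list(smiles = d,
                                            can = dg$smiles_canonical,
                                            rt = rt_d)
    }
    # a true hit must come with its designed decoys; otherwise resample
    if (length(decoys) < n_decoys) next
    made <- made + 1L
    base <- sprintf("true%02d", made)
    mass <- monoisotopic_mass(formula)
    db_rows[[length(db_rows) + 1L]] <- data.frame(
      name = base, formula = formula, smiles = mol$smiles,
      monoisotopic_mass = mass, rt_db = rt_true, stringsAsFactors = FALSE)
    for (di in seq_along(decoys))
      db_rows[[length(db_rows) + 1L]] <- data.frame(
        name = sprintf("%s_decoy%d", base, di), formula = formula,
        smiles = decoys[[di]]$smiles, monoisotopic_mass = mass,
        rt_db = decoys[[di]]$rt, stringsAsFactors = FALSE)
    mz_obs <- (mass - 1.007276) * (1 + stats::runif(1, -1.9, 1.9) * 1e-6)
    feat_rows[[length(feat_rows) + 1L]] <- data.frame(
      mz = mz_obs,
      rt_min = rt_true + if (rt_noise_sd > 0) stats::rnorm(1, 0, rt_noise_sd) else 0,
      intensity = stats::runif(1, 2e6, 5e7),
      p_value = stats::runif(1, 1e-6, 0.009),
      fold_change = stats::runif(1, 2.1, 8),
      true_name = base, stringsAsFactors = FALSE)
  }
  # non-qualifying filler features: each fails at least one strict threshold
  for (k in seq_len(n_features - n_true_hits)) {
    fail_mode <- k %% 3L
    feat_rows[[length(feat_rows) + 1L]] <- data.frame(
      mz = stats::runif(1, 80, 900),
      rt_min = stats::runif(1, 1, 55),
      intensity = if (fail_mode == 2L) stats::runif(1, 1e4, 9e5) else stats::runif(1, 2e6, 1e7),
      p_value = if (fail_mode == 0L) stats::runif(1, 0.02, 0.9) else stats::runif(1, 1e-5, 0.009),
      fold_change = if (fail_mode == 1L) stats::runif(1, 0.2, 1.9) else stats::runif(1, 2.1, 6),
      true_name = NA_character_, stringsAsFactors = FALSE)
  }
  list(features = do.call(rbind, feat_rows), db = do.call(rbind, db_rows))
}

# re-place the same decoration multiset on the same scaffold length
.random_isomer <- function(mol) {
  counts <- mol$counts
  L <- nchar(gsub("\\(.*", "", mol$smiles))  # leading chain length not robust; recompute
  # scaffold length = number of chain carbons = count of top-level 'C'
  depth <- 0L; L <- 0L
  for (ch in strsplit(mol$smiles, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "C" && depth == 0L) L <- L + 1L
  }
  slots <- ifelse(seq_len(L) %in% c(1L, L), 3L, 2L)
  decorations <- rep(names(counts), counts)
  if (length(decorations) == 0) return(NULL)
  decorations <- sample(decorations)
  at <- integer(0)
  avail <- slots
  for (d in seq_along(decorations)) {
    open <- which(avail > 0)
    if (length(open) == 0) return(NULL)
    pos <- if (length(open) == 1L) open else sample(open, 1L)
    avail[pos] <- avail[pos] - 1L
    at <- c(at, pos)
  }
  parts <- character(L)
  for (k in seq_len(L)) {
    subs <- decorations[at == k]
    parts[k] <- if (length(subs) == 0) "C" else
      paste0("C", paste0("(", .GROUP_SMILES[subs], ")", collapse = ""))
  }
  paste(parts, collapse = "")
}

.graph_formula <- function(graph) {
  el <- c(graph$element, rep("H", sum(graph$n_h)))
  tb <- table(el)
  ord <- c("C", "H", sort(setdiff(names(tb), c("C", "H"))))
  ord <- ord[ord %in% names(tb)]
  paste0(vapply(ord, function(e)
    paste0(e, if (tb[[e]] > 1) tb[[e]] else ""), ""), collapse = "")
}

#' Generate a synthetic calibration series
#'
#' Thirteen amounts in 3-fold increments by default, with linear response
#' and a fixed noise floor, so the analytic detection limit (the smallest
#' level with signal/noise_floor >= 3) is known by construction.
#'
#' @param n_levels Number of amount levels (default 13).
#' @param start_pmole Lowest amount (default 0.0254 pmole).
#' @param fold Step factor between levels (default 3).
#' @param slope Response per pmole (default 1e5).
#' @param noise_floor Additive noise amplitude defining S:N (default 1e4).
#' @param response_cv Multiplicative response noise (fraction, default 0).
#' @param n_replicates Replicates per level (default 3).
#' @param seed Integer seed.
#' @return A list of class `calibration_series`: `amounts`, `responses`
#'   (levels x replicates), `sn` (levels x replicates),
#'   `analytic_llod_pmole`.
#' @export
generate_calibration <- function(n_levels = 13L, start_pmole = 0.0254,
                                 fold = 3, slope = 1e5, noise_floor = 1e4,
                                 response_cv = 0, n_replicates = 3L,
                                 seed = 1L) {
  stopifnot(n_levels >= 3)
  set.seed(seed)
  amounts <- start_pmole * fold^(seq_len(n_levels) - 1L)
  signal <- slope * amounts
  responses <- matrix(rep(signal, n_replicates), ncol = n_replicates)
  if (response_cv > 0)
    responses <- responses *
      matrix(1 + stats::rnorm(n_levels * n_replicates, 0, response_cv),
             ncol = n_replicates)
  sn <- responses / noise_floor
  qualifying <- amounts[slope * amounts / noise_floor >= 3]
  structure(list(amounts = amounts, responses = responses, sn = sn,
                 analytic_llod_pmole = if (length(qualifying)) min(qualifying) else Inf),
            class = "calibration_series")
}
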