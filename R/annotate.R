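# Untargeted-feature annotation: statistical filtering of feature tables,
# adduct-corrected ppm mass matching against a candidate database, and
# ranking of candidates by predicted-retention proximity.

# monoisotopic masses of the most abundant isotopes (Da)
.ISOTOPE_MASS <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, F = 18.99840322, Cl = 34.96885268,
  Br = 78.9183371, I = 126.904473, Na = 22.9897692809, K = 38.96370668,
  Se = 73.9224764, Si = 27.9769265325, B = 11.0093054
)

#' Parse a molecular formula into element counts
#'
#' Handles CHNOPS plus halogens and a few common hetero-elements; no
#' parentheses or isotope labels.
#'
#' @param formula e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  counts <- integer(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    if (!el %in% names(.ISOTOPE_MASS))
      stop("unknown element '", el, "' in formula '", formula, "'")
    cnt <- gsub("[^0-9]", "", t)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + cnt
  }
  counts
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' @param formula Molecular formula string.
#' @return Mass in Da, from standard most-abundant-isotope masses.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.ISOTOPE_MASS[names(counts)] * counts)
}

#' Built-in negative-mode adducts
#'
#' Observed m/z = neutral monoisotopic mass + shift, singly charged negative
#' mode. The proton shift (-1.007276) folds in the electron mass.
#'
#' @return Data frame with columns `name` and `shift` for deprotonated
#'   (\[M-H\]-) and chloride (\[M+Cl\]-) species.
#' @export
mmrt_adducts <- function() {
  data.frame(name = c("[M-H]-", "[M+Cl]-"),
             shift = c(-1.007276, 34.968853),
             stringsAsFactors = FALSE)
}

#' Parts-per-million mass error
#'
#' (observed - theoretical) / theoretical * 1e6.
#'
#' @param observed_mz,theoretical_mz Positive m/z values (Th).
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(observed_mz <= 0) || any(theoretical_mz <= 0))
    stop("m/z values must be positive")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Theoretical m/z of a candidate under an adduct
#'
#' @param x A molecular formula string or an explicit neutral monoisotopic
#'   mass (Da).
#' @param adduct An adduct name from [mmrt_adducts()], or a list/row with
#'   `name` and `shift`.
#' @return m/z in Th.
#' @export
theoretical_mz <- function(x, adduct = "[M-H]-") {
  mass <- if (is.numeric(x)) x else monoisotopic_mass(x)
  if (is.character(adduct)) {
    tab <- mmrt_adducts()
    k <- match(adduct, tab$name)
    if (is.na(k)) stop("unknown adduct '", adduct, "'")
    shift <- tab$shift[k]
  } else shift <- adduct$shift
  mass + shift
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Filter an untargeted feature table
#'
#' Keeps features with p-value strictly below `p_max`, fold change strictly
#' above `fc_min`, and intensity strictly above `intensity_min` (fold change
#' is assumed already direction-folded upstream), then orders by ascending
#' p-value (stable).
#'
#' @param features Data frame with columns `mz`, `rt_min`, `intensity`,
#'   `p_value`, `fold_change`.
#' @param p_max,fc_min,intensity_min Strict thresholds (defaults 0.01, 2,
#'   1e6).
#' @param sort_by_p Order the result by ascending p-value (default `TRUE`).
#' @return The qualifying rows.
#' @export
filter_features <- function(features, p_max = 0.01, fc_min = 2.0,
                            intensity_min = 1e6, sort_by_p = TRUE) {
  .require_columns(features, c("mz", "rt_min", "intensity", "p_value",
                               "fold_change"), "feature table")
  keep <- features$p_value < p_max & features$fold_change > fc_min &
    features$intensity > intensity_min
  keep[is.na(keep)] <- FALSE
  out <- features[keep, , drop = FALSE]
  if (sort_by_p && nrow(out) > 1)
    out <- out[order(out$p_value, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match a feature to database candidates and rank by retention proximity
#'
#' For each adduct, database candidates whose theoretical m/z lies within
#' `ppm_tol` of the observed m/z are retained; each retained candidate's
#' retention time is predicted from its structure, and candidates are ranked
#' by |predicted - observed| RT (ties broken by |ppm error|, then name).
#'
#' @param feature A one-row data frame or list with `mz` and `rt_min`.
#' @param db Candidate table with columns `name`, `formula`, `smiles` and
#'   optionally `monoisotopic_mass`.
#' @param model A fitted `mmrt` model, an [rt_oracle()], or any object whose
#'   `predict` method maps SMILES to minutes.
#' @param ppm_tol Mass tolerance in ppm (default 3).
#' @param adducts Adduct table as from [mmrt_adducts()].
#' @return Data frame of matches: `name`, `formula`, `smiles`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, `predicted_rt`, `rt_delta`, `rank`.
#'   Candidates whose SMILES fail to parse are skipped with a warning.
#' @export
match_and_rank <- function(feature, db, model, ppm_tol = 3.0,
                           adducts = mmrt_adducts()) {
  if (is.data.frame(feature)) feature <- as.list(feature[1L, ])
  stopifnot(!is.null(feature$mz), !is.null(feature$rt_min))
  empty <- data.frame(name = character(0), formula = character(0),
                      smiles = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      predicted_rt = numeric(0), rt_delta = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (is.null(db) || nrow(db) == 0) return(empty)
  .require_columns(db, c("name", "smiles"), "candidate database")
  if (is.null(db$formula) && is.null(db$monoisotopic_mass))
    stop("schema error in candidate database: need 'formula' or 'monoisotopic_mass'")

  rows <- list()
  for (ci in seq_len(nrow(db))) {
    mass <- if (!is.null(db$monoisotopic_mass) &&
                is.finite(db$monoisotopic_mass[ci]))
      db$monoisotopic_mass[ci] else monoisotopic_mass(db$formula[ci])
    for (ai in seq_len(nrow(adducts))) {
      mz_t <- mass + adducts$shift[ai]
      pe <- ppm_error(feature$mz, mz_t)
      if (abs(pe) <= ppm_tol) {
        pred <- tryCatch(predict(model, db$smiles[ci]), error = function(e) {
          warning("skipping candidate '", db$name[ci],
                  "' (SMILES failed to parse: ", conditionMessage(e), ")")
          NA_real_
        })
        if (is.na(pred)) next
        rows[[length(rows) + 1L]] <- data.frame(
          name = db$name[ci],
          formula = if (!is.null(db$formula)) db$formula[ci] else NA_character_,
          smiles = db$smiles[ci],
          adduct = adducts$name[ai],
          theoretical_mz = mz_t,
          ppm_error = pe,
          predicted_rt = pred,
          rt_delta = abs(pred - feature$rt_min),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  ord <- order(out$rt_delta, abs(out$ppm_error), out$name)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Annotate a filtered feature table against a candidate database
#'
#' Convenience wrapper running [match_and_rank()] for every feature row.
#'
#' @inheritParams match_and_rank
#' @param features Feature table (typically output of [filter_features()]).
#' @return One data frame with a `feature_mz` / `feature_rt_min` prefix
#'   identifying the feature each match belongs to.
#' @export
annotate_features <- function(features, db, model, ppm_tol = 3.0,
                              adducts = mmrt_adducts()) {
  out <- list()
  for (fi in seq_len(nrow(features))) {
    m <- match_and_rank(features[fi, ], db, model, ppm_tol, adducts)
    if (nrow(m) > 0) {
      m <- cbind(feature_mz = features$mz[fi],
                 feature_rt_min = features$rt_min[fi], m)
      out[[length(out) + 1L]] <- m
    }
  }
  if (length(out) == 0)
    return(data.frame(feature_mz = numeric(0), feature_rt_min = numeric(0)))
  do.call(rbind, out)
}

#' Retention-time oracle from a lookup table
#'
#' A trivial "model" that returns stored retention times by canonical
#' SMILES. Used to test the annotation workflow with a perfect predictor
#' and as a baseline for ranking experiments.
#'
#' @param smiles Character vector of SMILES.
#' @param rt Retention times (minutes), parallel to `smiles`.
#' @return An object of class `rt_oracle` with a `predict` method.
#' @export
rt_oracle <- function(smiles, rt) {
  stopifnot(length(smiles) == length(rt))
  can <- vapply(smiles, .canonical_smiles, "")
  structure(list(table = stats::setNames(as.numeric(rt), can)),
            class = "rt_oracle")
}

#' @export
predict.rt_oracle <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$smiles
  if (inherits(newdata, "mmrt_graph")) newdata <- newdata$smiles_canonical
  if (is.list(newdata))
    newdata <- vapply(newdata, function(g)
      if (inherits(g, "mmrt_graph")) g$smiles_canonical else as.character(g), "")
  can <- vapply(as.character(newdata), .canonical_smiles, "")
  out <- unname(object$table[can])
  if (anyNA(out))
    stop("rt_oracle: no stored retention time for ",
         toString(newdata[is.na(out)]))
  out
}
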