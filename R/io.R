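# CSV readers with schema validation, and the subset evaluation report.

.read_csv_checked <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("schema error in ", what, ": '", path,
                          "' has no data rows")
  df
}

.check_numeric_column <- function(df, col, what, lines_offset = 1L) {
  v <- df[[col]]
  suppressWarnings(num <- as.numeric(v))
  bad <- which(!is.na(v) & nzchar(as.character(v)) & is.na(num))
  if (length(bad))
    stop("schema error in ", what, ": non-numeric '", col, "' at line(s) ",
         toString(bad + lines_offset))
  num
}

#' Read a molecule table (name, smiles, optional rt_min)
#'
#' @param path CSV path with header `name,smiles[,rt_min]`.
#' @param require_rt Require the `rt_min` column (for training input).
#' @param strict If `TRUE` (default) any SMILES that fails to parse is a
#'   schema error naming the offending line; otherwise such rows are dropped
#'   with a warning.
#' @param strip_salts Passed to [parse_smiles()].
#' @return Data frame with `name`, `smiles`, optional `rt_min`, and a list
#'   column `graph` of parsed `mmrt_graph` objects.
#' @export
read_molecule_csv <- function(path, require_rt = FALSE, strict = TRUE,
                              strip_salts = FALSE) {
  df <- .read_csv_checked(path, "molecule table")
  .require_columns(df, c("name", "smiles"), "molecule table")
  if (require_rt) .require_columns(df, "rt_min", "molecule table")
  if ("rt_min" %in% names(df))
    df$rt_min <- .check_numeric_column(df, "rt_min", "molecule table")
  graphs <- vector("list", nrow(df))
  bad <- integer(0)
  msgs <- character(0)
  for (i in seq_len(nrow(df))) {
    g <- tryCatch(parse_smiles(df$smiles[i], name = df$name[i],
                               strip_salts = strip_salts),
                  error = function(e) conditionMessage(e))
    if (is.character(g)) { bad <- c(bad, i); msgs <- c(msgs, g) }
    else graphs[[i]] <- g
  }
  if (length(bad)) {
    detail <- paste0("line ", bad + 1L, ": ", msgs, collapse = "; ")
    if (strict) stop("schema error in molecule table: ", detail)
    warning("dropping ", length(bad), " unparseable molecule(s): ", detail)
    df <- df[-bad, , drop = FALSE]
    graphs <- graphs[-bad]
  }
  df$graph <- I(graphs)
  df
}

#' Read an untargeted feature table
#'
#' @param path CSV with header `mz,rt_min,intensity,p_value,fold_change`.
#' @param scan_range m/z scan range; rows outside it draw a warning
#'   (default 65-975 Th). `NULL` disables the check.
#' @return Validated data frame.
#' @export
read_feature_csv <- function(path, scan_range = c(65, 975)) {
  df <- .read_csv_checked(path, "feature table")
  cols <- c("mz", "rt_min", "intensity", "p_value", "fold_change")
  .require_columns(df, cols, "feature table")
  for (cc in cols) df[[cc]] <- .check_numeric_column(df, cc, "feature table")
  if (any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE))
    stop("schema error in feature table: p_value outside [0, 1]")
  if (!is.null(scan_range)) {
    out <- which(df$mz < scan_range[1] | df$mz > scan_range[2])
    if (length(out))
      warning("feature m/z outside scan range [", scan_range[1], ", ",
              scan_range[2], "] at line(s) ", toString(out + 1L))
  }
  df
}

#' Read a candidate metabolite database
#'
#' @param path CSV with header `name,formula,smiles[,monoisotopic_mass]`.
#' @return Validated data frame; formulas are checked for parseability.
#' @export
read_candidate_csv <- function(path) {
  df <- .read_csv_checked(path, "candidate database")
  .require_columns(df, c("name", "formula", "smiles"), "candidate database")
  if ("monoisotopic_mass" %in% names(df))
    df$monoisotopic_mass <- .check_numeric_column(df, "monoisotopic_mass",
                                                  "candidate database")
  bad <- integer(0)
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ parse_formula(df$formula[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) bad <- c(bad, i)
  }
  if (length(bad))
    stop("schema error in candidate database: unparseable formula at line(s) ",
         toString(bad + 1L))
  df
}

#' Per-subset performance report
#'
#' Tabulates n, RMSE and the count/fraction of predictions within 2 minutes
#' for named metabolite subsets (e.g. sugars, sugar phosphates, carboxylic
#' acids, isomers), split into training and test partitions when a split is
#' supplied, plus an overall row.
#'
#' @param model A fitted `mmrt` model (or compatible predictor).
#' @param data Data frame with `name`, `smiles`, `rt_min`.
#' @param subsets Named list; each element is a character vector of
#'   metabolite names (matched against `data$name`). Unknown members draw a
#'   warning and are skipped.
#' @param split Optional list with `train`/`test` index vectors as from
#'   [split_dataset()].
#' @param tolerance_min Error tolerance (default 2 minutes).
#' @return Data frame: subset, partition, n, rmse_min, n_within, fraction_within.
#' @export
evaluate_report <- function(model, data, subsets = list(), split = NULL,
                            tolerance_min = 2.0) {
  .require_columns(data, c("name", "smiles", "rt_min"), "molecule table")
  pred <- predict(model, data$smiles)
  parts <- if (is.null(split)) list(all = seq_len(nrow(data)))
           else list(train = split$train, test = split$test)
  subsets <- c(list(overall = data$name), subsets)
  rows <- list()
  for (sn in names(subsets)) {
    members <- subsets[[sn]]
    unknown <- setdiff(members, data$name)
    if (length(unknown)) {
      warning("subset '", sn, "': unknown member(s) skipped: ",
              toString(unknown))
      members <- setdiff(members, unknown)
    }
    midx <- which(data$name %in% members)
    for (pn in names(parts)) {
      idx <- intersect(midx, parts[[pn]])
      if (length(idx) == 0) next
      err <- pred[idx] - data$rt_min[idx]
      rows[[length(rows) + 1L]] <- data.frame(
        subset = sn, partition = pn, n = length(idx),
        rmse_min = sqrt(mean(err^2)),
        n_within = sum(abs(err) < tolerance_min),
        fraction_within = mean(abs(err) < tolerance_min),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a run configuration next to outputs
#'
#' Serializes the resolved configuration (paths, model settings, tolerances,
#' seed) plus the package version as JSON so a run can be reproduced.
#'
#' @param config A named list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("mmrt"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
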