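# Method-validation statistics: calibration linearity, lower limit of
# detection, coefficient of variation, and the packaged 33-standard QC
# fixture with its summary counts.

.TABLE1_MD5 <- "cffcd57aaf8f3a6b009b8e26b0e2f003"

#' Linearity of a calibration series
#'
#' Squared Pearson correlation of the ordinary least-squares fit of peak
#' response against amount.
#'
#' @param amounts Amounts (pmole), strictly increasing, length >= 3.
#' @param responses Peak responses, same length (for replicated series pass
#'   the per-level mean or one replicate).
#' @return R-squared in \[0, 1\].
#' @export
linearity_r2 <- function(amounts, responses) {
  stopifnot(length(amounts) == length(responses), length(amounts) >= 3)
  if (any(diff(amounts) <= 0)) stop("amounts must be strictly increasing")
  if (stats::sd(responses) < .Machine$double.eps ||
      stats::sd(amounts) < .Machine$double.eps)
    stop("zero variance: cannot assess linearity")
  stats::cor(amounts, responses)^2
}

#' Lower limit of detection from per-level signal-to-noise
#'
#' The smallest amount whose signal-to-noise ratio reaches `sn_min` (3:1 by
#' default) in all replicates; `Inf` if no level qualifies.
#'
#' @param amounts Amounts (pmole), ascending.
#' @param sn A matrix of signal-to-noise values (levels x replicates) or a
#'   vector with one value per level.
#' @param sn_min Required signal-to-noise (default 3).
#' @return LLOD in pmole, or `Inf`.
#' @export
llod <- function(amounts, sn, sn_min = 3) {
  if (is.vector(sn)) sn <- matrix(sn, ncol = 1L)
  stopifnot(nrow(sn) == length(amounts))
  ok <- apply(sn, 1L, function(x) all(x >= sn_min))
  if (!any(ok)) return(Inf)
  min(amounts[ok])
}

#' Coefficient of variation in percent
#'
#' Sample standard deviation over mean, times 100.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (abs(m) < .Machine$double.eps) stop("zero mean: CV undefined")
  stats::sd(values) / m * 100
}

# median defined explicitly: midpoint element for odd n, mean of the
# central pair for even n (stats::median does exactly this; kept as the
# documented contract)
.median_mid <- function(x) stats::median(x)

#' Load the packaged 33-standard QC table
#'
#' Reads the packaged method-validation fixture (33 metabolite standards
#' with LOD, CV, linear range, R-squared and mass error), verifying its
#' checksum. The one known typographical artifact in the printed source
#' (lactate's CV "z12.4") is cleaned to 12.4 at load with a message.
#'
#' @return Data frame with 33 rows and columns `metabolite`, `lod_pmole`,
#'   `cv_percent`, `linear_range_pmole`, `r_squared`, `mass_error_ppm`.
#' @export
table1_standards <- function() {
  path <- system.file("extdata", "table1_standards.tsv", package = "mmrt")
  if (!nzchar(path)) stop("packaged QC fixture not found")
  if (!identical(unname(tools::md5sum(path)), .TABLE1_MD5))
    stop("QC fixture integrity check failed (checksum mismatch)")
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "character",
                                         "character", "numeric", "numeric"))
  dirty <- grepl("[^0-9.]", tb$cv_percent)
  if (any(dirty)) {
    message("cleaning non-numeric CV entries at row(s) ",
            toString(which(dirty)), ": ",
            toString(tb$cv_percent[dirty]))
    tb$cv_percent <- gsub("[^0-9.]", "", tb$cv_percent)
  }
  tb$cv_percent <- as.numeric(tb$cv_percent)
  stopifnot(nrow(tb) == 33L)
  tb
}

#' Summary counts over the packaged QC table
#'
#' @param fixture The data frame from [table1_standards()].
#' @param r2_thresholds R-squared thresholds to count standards above.
#' @param lod_pmole LOD threshold (pmole) to count standards below.
#' @return A list: `n_r2_above` (named by threshold), `n_lod_below`,
#'   `median_cv`, `median_abs_mass_error`, `n`.
#' @export
table1_summaries <- function(fixture = table1_standards(),
                             r2_thresholds = c(0.96, 0.98),
                             lod_pmole = 1.0) {
  stopifnot(is.data.frame(fixture))
  n_r2 <- vapply(r2_thresholds, function(th) sum(fixture$r_squared > th),
                 integer(1))
  names(n_r2) <- as.character(r2_thresholds)
  list(
    n = nrow(fixture),
    n_r2_above = n_r2,
    n_lod_below = sum(fixture$lod_pmole < lod_pmole),
    median_cv = .median_mid(fixture$cv_percent),
    median_abs_mass_error = .median_mid(abs(fixture$mass_error_ppm))
  )
}
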