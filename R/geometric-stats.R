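#' Geometric mean
#'
#' Back-transformed arithmetic mean of natural-log concentrations. All
#' log-scale statistics in this package use natural logs internally; the
#' back-transformed results are base-invariant.
#'
#' @param x Numeric vector of strictly positive values.
#' @return The geometric mean, a positive scalar in the units of `x`.
#' @export
#' @examples
#' gmean(c(1, 100)) # 10
gmean <- function(x) {
  check_positive_values(x)
  exp(mean(log(x)))
}

#' Geometric standard deviation
#'
#' Back-transformed sample standard deviation (n - 1 denominator) of the
#' natural-log values. Multiplicative and unitless: gSD >= 1, with 1 meaning
#' no dispersion. Invariant to rescaling the data by a positive constant.
#'
#' @param x Numeric vector of strictly positive values, length >= 2.
#' @return The geometric standard deviation (>= 1).
#' @export
#' @examples
#' gsd(c(1, exp(1), exp(2))) # exp(1)
gsd <- function(x) {
  check_positive_values(x)
  if (length(x) < 2) {
    stop("gsd() needs at least 2 values; got ", length(x), call. = FALSE)
  }
  exp(stats::sd(log(x)))
}

#' Geometric standard error
#'
#' The multiplicative standard error of a geometric mean:
#' `gSE = gSD^(1 / sqrt(n))`, i.e. the back-transformed standard error of the
#' mean log value.
#'
#' @param gsd_value Geometric standard deviation (>= 1).
#' @param n Number of observations (>= 1).
#' @return The geometric standard error (>= 1).
#' @export
#' @examples
#' gse(1.32, 32) # about 1.05
gse <- function(gsd_value, n) {
  stopifnot(is.numeric(gsd_value), is.numeric(n))
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(gsd_value < 1)) stop("gsd_value must be >= 1", call. = FALSE)
  gsd_value^(1 / sqrt(n))
}

#' Geometric compatibility (confidence) interval
#'
#' Multiplicative interval around a geometric mean:
#' `gMean / gSE^z` to `gMean * gSE^z`, with z the standard-normal quantile of
#' `(1 + level) / 2` (1.96 for 95%). Symmetric on the log scale, so
#' `lower * upper == gmean^2`. A normal (z) quantile is used rather than a
#' t quantile; pass `use_t = TRUE` and `n` for the t-based variant.
#'
#' @param gmean_value Geometric mean (> 0).
#' @param gse_value Geometric standard error (>= 1).
#' @param level Coverage level in (0, 1); default 0.95.
#' @param use_t Use a t quantile with `n - 1` degrees of freedom instead of z.
#' @param n Number of observations; required when `use_t = TRUE`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' gci(10, 1.05) # about (9.09, 11.00)
gci <- function(gmean_value, gse_value, level = 0.95, use_t = FALSE, n = NULL) {
  stopifnot(gmean_value > 0, level > 0, level < 1)
  if (any(gse_value < 1)) stop("gse_value must be >= 1", call. = FALSE)
  q <- if (use_t) {
    if (is.null(n) || n < 2) stop("use_t = TRUE requires n >= 2", call. = FALSE)
    stats::qt((1 + level) / 2, df = n - 1)
  } else {
    stats::qnorm((1 + level) / 2)
  }
  half <- gse_value^q
  c(lower = gmean_value / half, upper = gmean_value * half)
}

#' Geometric summary of a positive sample
#'
#' Composes [gmean()], [gsd()], [gse()] and [gci()] into one row. With a
#' single observation the dispersion quantities are undefined and reported as
#' `NA` (the geometric mean is still returned).
#'
#' @param x Numeric vector of strictly positive values, length >= 1.
#' @param level Coverage level for the compatibility interval; default 0.95.
#' @return A one-row tibble with columns `n`, `gmean`, `gsd`, `gse`,
#'   `gci_lower`, `gci_upper`, `level`.
#' @export
#' @examples
#' geo_summarize(c(2, 2, 2, 2))
geo_summarize <- function(x, level = 0.95) {
  check_positive_values(x)
  n <- length(x)
  gm <- gmean(x)
  if (n >= 2) {
    gs <- gsd(x)
    ge <- gse(gs, n)
    ci <- gci(gm, ge, level)
    lo <- ci[["lower"]]
    hi <- ci[["upper"]]
  } else {
    gs <- NA_real_
    ge <- NA_real_
    lo <- NA_real_
    hi <- NA_real_
  }
  tibble::tibble(
    n = n, gmean = gm, gsd = gs, gse = ge,
    gci_lower = lo, gci_upper = hi, level = level
  )
}

#' Substitute below-LOD values with LOD/2
#'
#' Concentrations below the limit of detection are replaced by half the limit
#' of detection before log-transformation; detected values pass through
#' unchanged. Vectorised over all three arguments.
#'
#' @param value Numeric vector of concentrations; `NA` where censored.
#' @param below_lod Logical vector flagging censored entries.
#' @param lod Limit(s) of detection; must be > 0 wherever `below_lod` is TRUE.
#' @return Numeric vector of imputed concentrations.
#' @export
#' @examples
#' impute_lod(c(3.4, NA), c(FALSE, TRUE), lod = 0.2) # 3.4, 0.1
impute_lod <- function(value, below_lod, lod) {
  stopifnot(is.logical(below_lod))
  k <- max(length(value), length(below_lod), length(lod))
  value <- rep_len(value, k)
  below_lod <- rep_len(below_lod, k)
  lod <- rep_len(lod, k)
  if (any(below_lod & lod <= 0)) {
    stop("below-LOD value with non-positive LOD: cannot impute LOD/2", call. = FALSE)
  }
  if (any(!below_lod & is.na(value))) {
    stop("missing concentration not flagged below LOD", call. = FALSE)
  }
  ifelse(below_lod, lod / 2, value)
}

#' Apply the LOD/2 rule to a record table
#'
#' Fills the `concentration` column of a long-format record table, replacing
#' censored entries with each metabolite's LOD/2 as defined in `specs`.
#'
#' @param records Long-format tibble as produced by [simulate_trajectories()]
#'   or [read_long_table()].
#' @param specs Metabolite panel tibble (see [metabolite_spec()]); must cover
#'   every metabolite appearing in `records`.
#' @return `records` with `concentration` imputed and `below_lod` retained.
#' @export
impute_lod_records <- function(records, specs) {
  check_records(records)
  missing_spec <- setdiff(unique(records$metabolite), specs$metabolite_id)
  if (length(missing_spec)) {
    stop("no spec for metabolite(s): ", paste(missing_spec, collapse = ", "),
      call. = FALSE
    )
  }
  lod_for <- specs$lod[match(records$metabolite, specs$metabolite_id)]
  records$concentration <- impute_lod(records$concentration, records$below_lod, lod_for)
  records
}

# shared argument checks ------------------------------------------------------

check_positive_values <- function(x) {
  if (length(x) == 0) stop("empty value vector", call. = FALSE)
  if (anyNA(x)) stop("values contain NA; impute or drop first", call. = FALSE)
  if (any(x <= 0)) stop("all values must be > 0 for log-scale statistics", call. = FALSE)
  invisible(x)
}

check_records <- function(records) {
  needed <- c(
    "subject_id", "sex", "metabolite", "timepoint",
    "minutes", "concentration", "below_lod"
  )
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("record table missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(records)
}
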