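#' Two-way additive ANOVA mean squares
#'
#' Decomposes a balanced complete subjects x timepoints matrix under the
#' additive (no-interaction) two-way model: rows (subjects) with n - 1
#' degrees of freedom, columns (timepoints) with k - 1, and residual error
#' with nk - n - k + 1. The sums of squares partition the total exactly.
#'
#' @param mat Numeric matrix, subjects in rows, timepoints in columns; no
#'   missing cells; at least 2 rows and 2 columns.
#' @return Named list with `msr`, `msc`, `mse`, `n`, `k`.
#' @export
#' @examples
#' anova_mean_squares(rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
anova_mean_squares <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete (no missing cells)", call. = FALSE)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) {
    stop("need at least 2 subjects and 2 timepoints (got ", n, " x ", k, ")",
      call. = FALSE
    )
  }
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  list(
    msr = ssr / (n - 1),
    msc = ssc / (k - 1),
    mse = sse / (n * k - n - k + 1),
    n = n, k = k
  )
}

#' Absolute-agreement ICC from ANOVA mean squares
#'
#' Intraclass correlation under the two-way random-effects no-interaction
#' model for absolute agreement:
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`,
#' the proportion of total log-scale variance (subject + timepoint + error)
#' attributable to between-subject variance. Moment estimates of the
#' variance components are `var_subject = (MSR - MSE) / k`,
#' `var_time = (MSC - MSE) / n`, `var_error = MSE`; negative component
#' estimates are truncated at zero for reporting, and the ICC itself is
#' clamped to `[0, 1]` (the unclamped value is kept in `icc_raw`).
#'
#' @param msr,msc,mse Mean squares from [anova_mean_squares()].
#' @param n,k Numbers of subjects and timepoints.
#' @return One-row tibble with columns `n_subjects`, `k_timepoints`, `msr`,
#'   `msc`, `mse`, `var_subject`, `var_time`, `var_error`, `icc_raw`, `icc`.
#' @export
#' @examples
#' icc_agreement(msr = 3, msc = 3, mse = 0, n = 3, k = 3) # icc 0.5
icc_agreement <- function(msr, msc, mse, n, k) {
  stopifnot(msr >= 0, msc >= 0, mse >= 0, n >= 2, k >= 2)
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) {
    warning("all mean squares zero: ICC undefined", call. = FALSE)
    icc_raw <- NA_real_
  } else {
    icc_raw <- (msr - mse) / denom
  }
  tibble::tibble(
    n_subjects = n, k_timepoints = k,
    msr = msr, msc = msc, mse = mse,
    var_subject = max((msr - mse) / k, 0),
    var_time = max((msc - mse) / n, 0),
    var_error = mse,
    icc_raw = icc_raw,
    icc = if (is.na(icc_raw)) NA_real_ else min(max(icc_raw, 0), 1)
  )
}

#' Within-person reproducibility ICC for one metabolite
#'
#' Builds the subjects x timepoints matrix of log concentrations and returns
#' the absolute-agreement ICC. Subjects with any missing timepoint are
#' dropped (complete-case) to restore balance; the drop count is reported
#' via a message. By default the ICC is computed across all timepoints
#' including baseline; set `include_baseline = FALSE` for the post-meal set.
#'
#' @param records LOD-imputed long-format record tibble.
#' @param metabolite Metabolite id.
#' @param include_baseline Include the pre-meal draw in the timepoint set.
#' @return One-row tibble as from [icc_agreement()], with a `metabolite`
#'   column prepended and `n_dropped` appended.
#' @export
icc_for_metabolite <- function(records, metabolite, include_baseline = TRUE) {
  check_records(records)
  rec <- records[records$metabolite == metabolite, ]
  if (nrow(rec) == 0) stop("no records for metabolite ", metabolite, call. = FALSE)
  if (!include_baseline) rec <- rec[!is_baseline(rec$minutes), ]
  if (anyNA(rec$concentration)) {
    stop("missing concentrations: apply impute_lod_records() first", call. = FALSE)
  }
  wide <- rec |>
    dplyr::select("subject_id", "timepoint", "concentration") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "concentration")
  mat <- log(as.matrix(wide[-1]))
  rownames(mat) <- wide$subject_id
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) with incomplete timepoints dropped for ICC")
    mat <- mat[complete, , drop = FALSE]
  }
  if (nrow(mat) < 2) {
    stop("fewer than 2 complete subjects for ", metabolite, call. = FALSE)
  }
  ms <- anova_mean_squares(mat)
  res <- icc_agreement(ms$msr, ms$msc, ms$mse, ms$n, ms$k)
  dplyr::bind_cols(
    tibble::tibble(metabolite = metabolite), res,
    tibble::tibble(n_dropped = n_dropped)
  )
}

#' Reproducibility ICC for every metabolite in a table
#'
#' @inheritParams icc_for_metabolite
#' @return Tibble with one row per metabolite (see [icc_for_metabolite()]).
#' @export
icc_table <- function(records, include_baseline = TRUE) {
  check_records(records)
  mets <- unique(records$metabolite)
  dplyr::bind_rows(lapply(
    mets,
    function(m) icc_for_metabolite(records, m, include_baseline = include_baseline)
  ))
}
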