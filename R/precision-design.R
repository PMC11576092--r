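#' gSE bound implied by a multiplicative margin of error
#'
#' The multiplicative margin of error of a geometric mean is `gSE^z` (the
#' x/÷ half-width of the geometric compatibility interval). Inverting,
#' a target margin implies the gSE bound `margin^(1/z)`: a margin below
#' 1.10 at z = 1.96 corresponds to a gSE below about 1.05.
#'
#' @param margin Multiplicative margin of error (> 1).
#' @param z Normal quantile; default 1.96 (95% interval).
#' @return The gSE threshold (> 1).
#' @export
#' @examples
#' gse_bound_from_margin(1.10, 1.96) # about 1.05
gse_bound_from_margin <- function(margin, z = 1.96) {
  if (any(margin <= 1)) stop("margin must be > 1", call. = FALSE)
  stopifnot(z > 0)
  margin^(1 / z)
}

#' Required sample size for a target geometric precision
#'
#' Accuracy-in-parameter-estimation planning: solve
#' `gse_target = gsd^(1 / sqrt(n))` for n, giving
#' `n = (ln(assumed_gsd) / ln(gse_target))^2`, then apply the rounding rule.
#' The default rounds to the nearest integer (a planning gSD of 1.32 and a
#' gSE target of 1.05 give n = 32.38, reported as 32); `rounding = "up"` is
#' the strict variant that guarantees the achieved gSE does not exceed the
#' target.
#'
#' @param assumed_gsd Planning geometric SD (> 1).
#' @param gse_target Target geometric SE, with 1 < gse_target. If
#'   `gse_target >= assumed_gsd` a single observation already achieves the
#'   precision: 1 is returned with a warning.
#' @param rounding `"nearest"` (default) or `"up"`.
#' @return Integer sample size (>= 1).
#' @export
#' @examples
#' required_n(1.32, 1.05) # 32
#' required_n(1.32, 1.05, rounding = "up") # 33
required_n <- function(assumed_gsd, gse_target, rounding = c("nearest", "up")) {
  rounding <- match.arg(rounding)
  stopifnot(assumed_gsd > 1, gse_target > 1)
  if (gse_target >= assumed_gsd) {
    warning("gse_target >= assumed_gsd: a single observation suffices",
      call. = FALSE
    )
    return(1L)
  }
  n_exact <- (log(assumed_gsd) / log(gse_target))^2
  n <- switch(rounding,
    nearest = round(n_exact),
    up = ceiling(n_exact - 1e-9)
  )
  as.integer(max(n, 1))
}

#' Inflate a sample size for expected dropout
#'
#' Returns the number of participants to recruit so that the required number
#' is expected to complete: `ceiling(n_required / (1 - dropout_rate))`.
#'
#' @param n_required Completers needed (>= 1).
#' @param dropout_rate Expected dropout fraction in `[0, 1)`.
#' @return Integer recruitment target (>= `n_required`).
#' @export
#' @examples
#' inflate_for_dropout(32, 0.10) # 36
inflate_for_dropout <- function(n_required, dropout_rate) {
  stopifnot(n_required >= 1)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  as.integer(ceiling(n_required / (1 - dropout_rate) - 1e-9))
}

#' Empirical quantiles of a reference gSD table
#'
#' Summarises a user-supplied table of geometric standard deviations (for
#' example, per-metabolite-per-timepoint gSDs from a reference metabolomics
#' challenge study) by empirical quantiles, used to pick a planning gSD.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param reference_gsds Numeric vector of gSD values (all >= 1).
#' @param probs Probabilities in (0, 1); default median and 80th percentile.
#' @return Named numeric vector of quantiles.
#' @export
#' @examples
#' gsd_quantiles(c(1.1, 1.2, 1.3), probs = 0.5) # 1.2
gsd_quantiles <- function(reference_gsds, probs = c(0.5, 0.8)) {
  if (length(reference_gsds) == 0) stop("empty gSD table", call. = FALSE)
  if (any(reference_gsds < 1)) stop("gSD values must be >= 1", call. = FALSE)
  stopifnot(all(probs > 0), all(probs < 1))
  stats::quantile(reference_gsds, probs = probs, type = 7, names = TRUE)
}

#' Full precision-based design
#'
#' Chains [gse_bound_from_margin()], [required_n()] and
#' [inflate_for_dropout()] into one planning summary. The gSE threshold the
#' sample size is solved against is, by default, the margin-implied bound
#' quoted to two decimals (a 1.10 margin at z = 1.96 gives the conventional
#' 1.05 threshold); pass `gse_target` explicitly to solve against the exact
#' bound or any other threshold.
#'
#' @param margin Target multiplicative margin of error (> 1); default 1.10.
#' @param z Normal quantile; default 1.96.
#' @param assumed_gsd Planning gSD; default 1.32.
#' @param dropout_rate Expected dropout fraction; default 0.10.
#' @param rounding Rounding rule for [required_n()].
#' @param gse_target gSE threshold to solve against; defaults to the
#'   margin-implied bound rounded to two decimals.
#' @return One-row tibble with columns `margin`, `z`, `gse_bound`,
#'   `gse_target`, `assumed_gsd`, `n_required`, `achieved_gse`,
#'   `achieved_margin`, `dropout_rate`, `n_recruit`.
#' @export
#' @examples
#' precision_design()
precision_design <- function(margin = 1.10, z = 1.96, assumed_gsd = 1.32,
                             dropout_rate = 0.10,
                             rounding = c("nearest", "up"),
                             gse_target = NULL) {
  rounding <- match.arg(rounding)
  bound <- gse_bound_from_margin(margin, z)
  if (is.null(gse_target)) gse_target <- round(bound, 2)
  n_req <- required_n(assumed_gsd, gse_target, rounding)
  achieved <- gse(assumed_gsd, n_req)
  tibble::tibble(
    margin = margin, z = z, gse_bound = bound, gse_target = gse_target,
    assumed_gsd = assumed_gsd, n_required = n_req,
    achieved_gse = achieved, achieved_margin = achieved^z,
    dropout_rate = dropout_rate,
    n_recruit = inflate_for_dropout(n_req, dropout_rate)
  )
}
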