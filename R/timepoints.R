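#' The standard single-meal sampling grid
#'
#' One pre-meal baseline draw plus thirteen post-meal draws. Time zero is the
#' completion of the meal; the baseline draw is coded at a nominal -20 minutes
#' (a pre-meal blood draw taken before a 15-minute breakfast). Minutes are the
#' authoritative time axis; labels are human-readable aliases.
#'
#' @return A tibble with columns `label` (character) and `minutes` (integer),
#'   14 rows ordered by time.
#' @export
#' @examples
#' timepoint_grid()
timepoint_grid <- function() {
  tibble::tibble(
    label = c(
      "baseline", "15m", "30m", "45m", "60m", "90m",
      "2h", "3h", "4h", "6h", "8h", "10h", "12h", "24h"
    ),
    minutes = c(
      -20L, 15L, 30L, 45L, 60L, 90L,
      120L, 180L, 240L, 360L, 480L, 600L, 720L, 1440L
    )
  )
}

#' Minutes for timepoint labels
#'
#' @param labels Character vector of timepoint labels from [timepoint_grid()].
#' @return Integer minutes, same length as `labels`.
#' @export
timepoint_minutes <- function(labels) {
  grid <- timepoint_grid()
  idx <- match(labels, grid$label)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  grid$minutes[idx]
}

#' @keywords internal
baseline_minutes <- function() -20L

#' @keywords internal
is_baseline <- function(minutes) minutes < 0
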