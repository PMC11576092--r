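#' Per-subject ratio-to-baseline time courses
#'
#' Each subject's pre-meal draw is used as their own reference: for every
#' timepoint the ratio `concentration(t) / concentration(baseline)` is
#' returned. Subjects lacking a baseline value are excluded with a warning.
#' Records must already be LOD-imputed (no missing concentrations).
#'
#' @param records Long-format record tibble (see [simulate_trajectories()]).
#' @param metabolite Metabolite id to extract.
#' @return Tibble with columns `metabolite`, `subject_id`, `timepoint`,
#'   `minutes`, `ratio` (baseline rows have ratio exactly 1).
#' @export
subject_ratios <- function(records, metabolite) {
  check_records(records)
  rec <- records[records$metabolite == metabolite, ]
  if (nrow(rec) == 0) {
    stop("no records for metabolite ", metabolite, call. = FALSE)
  }
  if (anyNA(rec$concentration)) {
    stop("missing concentrations: apply impute_lod_records() first", call. = FALSE)
  }
  dup <- duplicated(rec[c("subject_id", "timepoint")])
  if (any(dup)) {
    d <- rec[dup, ][1, ]
    stop(
      "duplicate record for subject ", d$subject_id, " at timepoint ",
      d$timepoint, " (", metabolite, ")",
      call. = FALSE
    )
  }
  base <- rec[is_baseline(rec$minutes), c("subject_id", "concentration")]
  names(base)[2] <- "baseline_concentration"
  no_base <- setdiff(unique(rec$subject_id), base$subject_id)
  if (length(no_base)) {
    warning(
      length(no_base), " subject(s) without a baseline value excluded: ",
      paste(no_base, collapse = ", "),
      call. = FALSE
    )
    rec <- rec[!rec$subject_id %in% no_base, ]
  }
  out <- dplyr::inner_join(rec, base, by = "subject_id")
  tibble::tibble(
    metabolite = out$metabolite,
    subject_id = out$subject_id,
    timepoint = out$timepoint,
    minutes = out$minutes,
    ratio = out$concentration / out$baseline_concentration
  )
}

#' Aggregate per-subject ratios into cohort percent changes
#'
#' For each post-meal timepoint the per-subject ratios are combined as their
#' geometric mean; the cohort percent change is `100 * (gMean(ratio) - 1)`,
#' with a geometric compatibility interval from the gSE of the log ratios,
#' transformed to the percent scale. Baseline rows (ratio identically 1) are
#' excluded. Timepoints with a single pair get `NA` interval bounds.
#'
#' @param ratios Tibble from [subject_ratios()].
#' @param level Coverage level; default 0.95.
#' @return Tibble with columns `metabolite`, `timepoint`, `minutes`,
#'   `n_pairs`, `pct_change`, `gci_lower_pct`, `gci_upper_pct`.
#' @export
aggregate_relative <- function(ratios, level = 0.95) {
  stopifnot(all(c("metabolite", "timepoint", "minutes", "ratio") %in% names(ratios)))
  post <- ratios[!is_baseline(ratios$minutes), ]
  if (nrow(post) == 0) stop("no post-meal ratios to aggregate", call. = FALSE)
  post |>
    dplyr::group_by(.data$metabolite, .data$timepoint, .data$minutes) |>
    dplyr::group_modify(function(d, key) {
      s <- geo_summarize(d$ratio, level = level)
      tibble::tibble(
        n_pairs = s$n,
        pct_change = 100 * (s$gmean - 1),
        gci_lower_pct = 100 * (s$gci_lower - 1),
        gci_upper_pct = 100 * (s$gci_upper - 1)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$metabolite, .data$minutes)
}

#' Locate the postprandial peak and nadir
#'
#' The peak is the post-meal timepoint with the largest percent change and
#' the nadir the smallest; ties are broken by the earliest timepoint. The
#' baseline (ratio identically 1) is not a candidate.
#'
#' @param summaries Tibble from [aggregate_relative()] for one metabolite.
#' @return Two-row tibble with columns `metabolite`, `kind` (`"peak"`,
#'   `"nadir"`), `timepoint`, `minutes`, `pct_change`.
#' @export
find_extrema <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  s <- summaries[order(summaries$minutes), ]
  peak <- s[which.max(s$pct_change), ]
  nadir <- s[which.min(s$pct_change), ]
  tibble::tibble(
    metabolite = c(peak$metabolite, nadir$metabolite),
    kind = c("peak", "nadir"),
    timepoint = c(peak$timepoint, nadir$timepoint),
    minutes = c(peak$minutes, nadir$minutes),
    pct_change = c(peak$pct_change, nadir$pct_change)
  )
}

#' Cohort relative-change summary table
#'
#' One block per metabolite (optionally per sex stratum): the baseline
#' reference geometric mean, the geometric mean percent change (with
#' compatibility interval) at every post-meal timepoint, and the
#' within-person reproducibility ICC across timepoints. Subjects missing a
#' given timepoint are dropped from that timepoint only (available pairs).
#'
#' @param records Long-format record tibble; LOD-imputed records are
#'   expected (censored rows with missing concentrations are an error).
#' @param stratify_by_sex Also summarise male and female strata separately.
#' @param level Coverage level; default 0.95.
#' @param include_icc Attach the absolute-agreement ICC per metabolite
#'   (computed on log concentrations across all timepoints, complete
#'   subjects only); `NA` when fewer than two complete subjects.
#' @return Long tibble with columns `metabolite`, `stratum`,
#'   `reference_gmean`, `icc`, `timepoint`, `minutes`, `n_pairs`,
#'   `pct_change`, `gci_lower_pct`, `gci_upper_pct`.
#' @export
relative_change_table <- function(records, stratify_by_sex = FALSE,
                                  level = 0.95, include_icc = TRUE) {
  check_records(records)
  strata <- list(all = records)
  if (stratify_by_sex) {
    strata <- c(strata, split(records, records$sex))
  }
  blocks <- lapply(names(strata), function(nm) {
    rec <- strata[[nm]]
    mets <- unique(rec$metabolite)
    dplyr::bind_rows(lapply(mets, function(m) {
      ratios <- subject_ratios(rec, m)
      agg <- aggregate_relative(ratios, level = level)
      base <- rec[rec$metabolite == m & is_baseline(rec$minutes), ]
      ref <- gmean(base$concentration)
      icc <- NA_real_
      if (include_icc) {
        icc <- tryCatch(
          icc_for_metabolite(rec, m)$icc,
          error = function(e) NA_real_
        )
      }
      tibble::tibble(
        metabolite = m, stratum = nm,
        reference_gmean = ref, icc = icc,
        agg[setdiff(names(agg), "metabolite")]
      )
    }))
  })
  dplyr::bind_rows(blocks)
}

#' Absolute-concentration summary table
#'
#' Geometric mean concentration with compatibility interval per metabolite,
#' timepoint and (optionally) sex stratum — the companion of
#' [relative_change_table()] on the concentration scale.
#'
#' @inheritParams relative_change_table
#' @return Tibble with columns `metabolite`, `stratum`, `timepoint`,
#'   `minutes`, `n`, `gmean`, `gsd`, `gci_lower`, `gci_upper`.
#' @export
concentration_table <- function(records, stratify_by_sex = FALSE, level = 0.95) {
  check_records(records)
  if (anyNA(records$concentration)) {
    stop("missing concentrations: apply impute_lod_records() first", call. = FALSE)
  }
  strata <- list(all = records)
  if (stratify_by_sex) {
    strata <- c(strata, split(records, records$sex))
  }
  dplyr::bind_rows(lapply(names(strata), function(nm) {
    strata[[nm]] |>
      dplyr::group_by(.data$metabolite, .data$timepoint, .data$minutes) |>
      dplyr::group_modify(function(d, key) {
        s <- geo_summarize(d$concentration, level = level)
        tibble::tibble(
          n = s$n, gmean = s$gmean, gsd = s$gsd,
          gci_lower = s$gci_lower, gci_upper = s$gci_upper
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(stratum = nm, .after = "metabolite") |>
      dplyr::arrange(.data$metabolite, .data$minutes)
  }))
}
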