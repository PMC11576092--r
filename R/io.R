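#' Read a long-format concentration table
#'
#' Expects the CSV schema written by [write_long_table()]:
#' `subject_id,sex,metabolite,timepoint,minutes,concentration,below_lod`,
#' with an empty concentration field for below-LOD rows. Timepoint labels
#' are validated against [timepoint_grid()] and `minutes` is taken as the
#' authoritative time axis (recomputed from the label). Duplicate
#' (subject, metabolite, timepoint) rows are rejected.
#'
#' @param path CSV file path.
#' @return A validated record tibble.
#' @export
read_long_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  rec <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      metabolite = readr::col_character(),
      timepoint = readr::col_character(),
      minutes = readr::col_integer(),
      concentration = readr::col_double(),
      below_lod = readr::col_logical()
    )
  )
  check_records(rec)
  bad_sex <- setdiff(unique(rec$sex), c("male", "female"))
  if (length(bad_sex)) {
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  rec$minutes <- timepoint_minutes(rec$timepoint) # errors on unknown labels
  dup <- duplicated(rec[c("subject_id", "metabolite", "timepoint")])
  if (any(dup)) {
    d <- rec[dup, ][1, ]
    stop(
      "duplicate row (first at line ", which(dup)[1] + 1L, "): subject ",
      d$subject_id, ", metabolite ", d$metabolite, ", timepoint ", d$timepoint,
      call. = FALSE
    )
  }
  if (any(!rec$below_lod & is.na(rec$concentration))) {
    i <- which(!rec$below_lod & is.na(rec$concentration))[1]
    stop("missing concentration without below_lod flag at line ", i + 1L,
      call. = FALSE
    )
  }
  if (any(!is.na(rec$concentration) & rec$concentration <= 0)) {
    i <- which(!is.na(rec$concentration) & rec$concentration <= 0)[1]
    stop("non-positive concentration at line ", i + 1L, call. = FALSE)
  }
  rec
}

#' Write a long-format concentration table
#'
#' @param records Record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(records, path) {
  check_records(records)
  readr::write_csv(records[, c(
    "subject_id", "sex", "metabolite", "timepoint",
    "minutes", "concentration", "below_lod"
  )], path, na = "")
  invisible(path)
}

#' Write report tables to a directory
#'
#' Writes each table in a named list as `<name>.csv` under `outdir` with
#' fixed numeric formatting: percent-scale columns (names ending `_pct` or
#' equal to `pct_change`) to one decimal place, all other numeric columns to
#' three significant figures. Deterministic: identical inputs give
#' byte-identical files.
#'
#' @param tables Named list of tibbles/data frames.
#' @param outdir Output directory; created if absent.
#' @return Tibble manifest with columns `name`, `path`.
#' @export
write_reports <- function(tables, outdir) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) {
    stop("tables must be a named list", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    tab <- as.data.frame(tables[[nm]])
    for (col in names(tab)) {
      if (!is.numeric(tab[[col]]) || is.integer(tab[[col]])) next
      pct <- grepl("(_pct$|^pct_change$)", col)
      tab[[col]] <- if (pct) round(tab[[col]], 1) else signif(tab[[col]], 3)
    }
    p <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(tab, p, na = "")
    p
  }, character(1))
  tibble::tibble(name = names(tables), path = unname(paths))
}

#' Write a metabolite panel to a TOML-style config file
#'
#' One section per metabolite; scalar keys plus a compact `knots` string of
#' `label:effect` pairs. [read_panel()] reads the format back; the
#' write-read round trip is the identity.
#'
#' @param specs Panel tibble (see [metabolite_spec()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(specs, path) {
  lines <- c("# metabolite panel")
  for (j in seq_len(nrow(specs))) {
    s <- specs[j, ]
    kn <- s$knots[[1]]
    lines <- c(
      lines, "",
      sprintf("[%s]", s$metabolite_id),
      sprintf('unit = "%s"', s$unit),
      sprintf("baseline_male = %.15g", s$baseline_male),
      sprintf("baseline_female = %.15g", s$baseline_female),
      sprintf("between_gsd = %.15g", s$between_gsd),
      sprintf("within_gsd = %.15g", s$within_gsd),
      sprintf("lod = %.15g", s$lod),
      sprintf(
        'knots = "%s"',
        paste(sprintf("%s:%.15g", kn$label, kn$effect), collapse = ", ")
      )
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolite panel from a TOML-style config file
#'
#' @param path Config file path (format of [write_panel()]).
#' @return Panel tibble.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NULL
  fields <- list()
  out <- list()
  flush <- function() {
    if (is.null(section)) {
      return()
    }
    needed <- c(
      "unit", "baseline_male", "baseline_female",
      "between_gsd", "within_gsd", "lod", "knots"
    )
    miss <- setdiff(needed, names(fields))
    if (length(miss)) {
      stop(
        "panel section [", section, "] missing key(s): ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    pairs <- strsplit(strsplit(fields$knots, ",")[[1]], ":")
    knots <- vapply(pairs, function(p) as.numeric(trimws(p[2])), numeric(1))
    names(knots) <- vapply(pairs, function(p) trimws(p[1]), character(1))
    out[[length(out) + 1]] <<- metabolite_spec(
      metabolite_id = section,
      unit = fields$unit,
      baseline_male = as.numeric(fields$baseline_male),
      baseline_female = as.numeric(fields$baseline_female),
      between_gsd = as.numeric(fields$between_gsd),
      within_gsd = as.numeric(fields$within_gsd),
      knots = knots,
      lod = as.numeric(fields$lod)
    )
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      fields <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key outside a section: ", ln, call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      fields[[key]] <- gsub('^"|"$', "", val)
    } else {
      stop("unparseable panel line: ", ln, call. = FALSE)
    }
  }
  flush()
  if (!length(out)) stop("panel file contains no metabolite sections", call. = FALSE)
  dplyr::bind_rows(out)
}
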