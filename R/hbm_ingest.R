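#' Read aggregated biomonitoring percentile records
#'
#' Reads a CSV of aggregated urinary TCPy percentile summaries, one row per
#' study/population group, with columns `study_id`, `country`, `population`,
#' `years`, `n`, `p50`, `p95`, `upper_ci_p95`, `max`, `adjusted`.
#' Concentrations are ug/L unless `adjusted` is `TRUE` (ug/g creatinine, to
#' be corrected with [correct_creatinine()]). The literal token `"n.r."`
#' (not reported) or an empty cell both map to missing: studies with a high
#' fraction of samples below the detection limit report percentiles this way.
#'
#' @param path File path; defaults to the packaged transcription of the
#'   HBM4EU-aligned study summaries.
#'
#' @return A tibble of HBM records (unvalidated; see [validate_records()]).
#' @export
read_hbm_records <- function(path = biomoe_example("hbm4eu_tcpy.csv")) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("study_id", "country", "population")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("HBM file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  parse_conc <- function(x) {
    x <- trimws(x %||% rep(NA_character_, nrow(raw)))
    x[x %in% c("n.r.", "n.r", "nr", "")] <- NA_character_
    as.numeric(x)
  }
  tibble::tibble(
    study_id = raw$study_id,
    country = raw$country,
    population = raw$population,
    years = raw[["years"]] %||% NA_character_,
    n = suppressWarnings(as.integer(raw[["n"]] %||% NA_character_)),
    p50 = parse_conc(raw[["p50"]]),
    p95 = parse_conc(raw[["p95"]]),
    upper_ci_p95 = parse_conc(raw[["upper_ci_p95"]]),
    max = parse_conc(raw[["max"]]),
    adjusted = tolower(raw[["adjusted"]] %||% "false") %in% c("true", "1", "yes")
  )
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
biomoe_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "biomoe")))
  }
  path <- system.file("extdata", file, package = "biomoe")
  if (!nzchar(path)) abort(paste0("No packaged file named '", file, "'."))
  path
}

#' Read published per-study margin-of-exposure summaries
#'
#' Loads a table of study metadata plus published overall-endpoint margins
#' of exposure per exposure tier, in the shape used by literature-derived
#' study comparisons. The `tier_*_stat` columns disclose which statistic
#' stands in for each tier when a study does not report the canonical one
#' (geometric mean for the median slot, 75th percentile for the P95 slot,
#' maximum or upper confidence bound for the top slot). Margins for other
#' endpoints follow by [endpoint_rescale()].
#'
#' @param path File path; defaults to the packaged transcription of
#'   published Spanish-population studies (plus the Portuguese aligned
#'   study for comparison).
#'
#' @return A tibble.
#' @export
read_study_moes <- function(path = biomoe_example("spanish_studies_moe.csv")) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Convert creatinine-adjusted concentrations to volume-based units
#'
#' Some studies report urinary metabolite levels only per gram of creatinine
#' (ug/g); comparing them with volume-based records requires a study-specific
#' linear correlation `ug/L = a + b * ug/g` fitted on paired
#' adjusted/unadjusted data. No such correlation is packaged - the
#' coefficients must come from the user - and calling this with the identity
#' default warns that no correlation was configured.
#'
#' @param value Concentration(s) in ug/g creatinine (positive).
#' @param a,b Intercept and slope of the linear correction model.
#'
#' @return Corrected concentration(s) in ug/L, same order and length.
#' @export
#'
#' @examples
#' correct_creatinine(2.0, a = 0.1, b = 0.9)  # 1.9
correct_creatinine <- function(value, a = 0, b = 1) {
  if (any(value <= 0, na.rm = TRUE)) abort("`value` must be positive.")
  if (identical(a, 0) && identical(b, 1)) {
    warn("No creatinine correlation configured; returning values unchanged (a = 0, b = 1).")
  }
  out <- a + b * value
  if (any(out < 0, na.rm = TRUE)) {
    abort("Creatinine correction produced negative concentrations; check coefficients.")
  }
  out
}

#' Validate aggregated biomonitoring records
#'
#' Screens records for use in margin-of-exposure computation. Records with
#' missing percentiles are retained but flagged per exposure tier; records
#' violating the percentile ordering (p50 <= p95 <= upper CI where present)
#' or carrying non-positive concentrations are rejected to the issue log.
#' Numeric values of clean records pass through unaltered.
#'
#' @param records Tibble from [read_hbm_records()].
#'
#' @return A list with `records` (clean, with logical columns `usable_p50`,
#'   `usable_p95`, `usable_upper_ci`, `usable_max`) and `issues` (tibble
#'   `study_id`, `country`, `population`, `problem`).
#' @export
validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  for (col in c("p50", "p95", "upper_ci_p95", "max")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  issues <- tibble::tibble(study_id = character(), country = character(),
                           population = character(), problem = character())
  note <- function(row, problem) {
    tibble::tibble(study_id = row$study_id, country = row$country %||% NA_character_,
                   population = row$population %||% NA_character_, problem = problem)
  }
  bad <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    vals <- c(row$p50, row$p95, row$upper_ci_p95, row$max)
    if (any(vals <= 0, na.rm = TRUE)) {
      issues <- dplyr::bind_rows(issues, note(row, "non-positive concentration"))
      bad[i] <- TRUE
      next
    }
    if (!is.na(row$p50) && !is.na(row$p95) && row$p50 > row$p95) {
      issues <- dplyr::bind_rows(issues, note(row, "p50 exceeds p95"))
      bad[i] <- TRUE
      next
    }
    if (!is.na(row$p95) && !is.na(row$upper_ci_p95) && row$p95 > row$upper_ci_p95) {
      issues <- dplyr::bind_rows(issues, note(row, "p95 exceeds upper CI of p95"))
      bad[i] <- TRUE
      next
    }
    if (all(is.na(vals))) {
      issues <- dplyr::bind_rows(
        issues, note(row, "all percentiles missing (n.r.); unusable for MoE")
      )
    }
  }
  clean <- records[!bad, , drop = FALSE] |>
    dplyr::mutate(
      usable_p50 = !is.na(.data$p50),
      usable_p95 = !is.na(.data$p95),
      usable_upper_ci = !is.na(.data$upper_ci_p95),
      usable_max = !is.na(.data$max)
    )
  list(records = clean, issues = issues)
}
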