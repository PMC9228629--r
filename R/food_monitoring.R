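#' Default ADI table for the TCPy-sharing pesticide pair
#'
#' Maps (pesticide, report year) to the acceptable daily intake in
#' mg/kg bw/day used to back-convert dietary risk reported as % of ADI into
#' an external dose. For chlorpyrifos the ADI of 0.01 mg/kg bw/day applies to
#' report years 2012-2015 and the revised 0.001 mg/kg bw/day from 2016
#' onwards (the regulatory reduction entered EU legislation in 2016); for
#' chlorpyrifos-methyl 0.01 mg/kg bw/day is kept throughout. Fully
#' overridable because annual reports do not state which ADI underlies each
#' year's % figures.
#'
#' @param years Report years to cover.
#'
#' @return A tibble with columns `pesticide`, `year`, `adi`.
#' @export
#'
#' @examples
#' default_adi_table()
default_adi_table <- function(years = 2012:2019) {
  dplyr::bind_rows(
    tibble::tibble(
      pesticide = "chlorpyrifos", year = years,
      adi = ifelse(years >= 2016, 0.001, 0.01)
    ),
    tibble::tibble(
      pesticide = "chlorpyrifos-methyl", year = years, adi = 0.01
    )
  )
}

adi_for <- function(pesticide, year, adi_table) {
  idx <- match(paste(pesticide, year), paste(adi_table$pesticide, adi_table$year))
  if (anyNA(idx)) {
    miss <- unique(paste0("(", pesticide, ", ", year, ")")[is.na(idx)])
    abort(paste0("No ADI defined for: ", paste(miss, collapse = ", ")))
  }
  adi <- adi_table$adi[idx]
  if (any(adi <= 0)) abort("ADIs must be positive.")
  adi
}

#' Convert dietary risk in % of ADI to an external dose
#'
#' The annual monitoring reports express the highest calculated chronic
#' exposure for each diet as a percentage of the ADI; the external dose is
#' recovered as `dose = percent_adi / 100 * ADI(pesticide, year)`.
#'
#' @param percent_adi Exposure as % of ADI (non-negative, vectorised).
#' @param pesticide,year Keys into the ADI table (vectorised, recycled).
#' @param adi_table See [default_adi_table()].
#'
#' @return Dose in mg/kg bw/day.
#' @export
#'
#' @examples
#' percent_adi_to_dose(100, "chlorpyrifos", 2016)  # 0.001
percent_adi_to_dose <- function(percent_adi, pesticide, year,
                                adi_table = default_adi_table()) {
  if (any(percent_adi < 0)) abort("`percent_adi` must be non-negative.")
  percent_adi / 100 * adi_for(pesticide, year, adi_table)
}

#' Predict urinary TCPy for one diet-year from %-of-ADI records
#'
#' Converts each pesticide's % of ADI into an external dose, sums the molar
#' metabolite contributions of chlorpyrifos and chlorpyrifos-methyl, and
#' applies the food-model forward dosimetry (excretion fraction 0.7, urinary
#' output 0.024 L/kg bw/day) to obtain a single urinary concentration. A diet
#' reported for only one of the pair contributes zero from the other (a notice
#' is emitted).
#'
#' @param records Tibble with columns `diet_label`, `year`, `pesticide`,
#'   `percent_adi` for a single diet-year.
#' @param adi_table See [default_adi_table()].
#' @param tk A [tk_params()] object.
#' @param pesticides Molar-ratio lookup.
#' @param quiet Suppress the single-pesticide notice.
#'
#' @return Predicted urinary TCPy in ug/L.
#' @export
predict_diet_tcpy <- function(records,
                              adi_table = default_adi_table(),
                              tk = default_toxicokinetics(),
                              pesticides = default_pesticides(),
                              quiet = FALSE) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("diet_label", "year", "pesticide", "percent_adi") %in% names(records)))
  if (dplyr::n_distinct(records$diet_label) != 1L ||
      dplyr::n_distinct(records$year) != 1L) {
    abort("`records` must describe a single diet label and year.")
  }
  both <- pesticides$pesticide[1:2]
  missing_pest <- setdiff(both, records$pesticide)
  if (length(missing_pest) > 0 && !quiet) {
    inform(paste0(
      "Diet '", records$diet_label[1], "' (", records$year[1],
      "): no record for ", paste(missing_pest, collapse = ", "),
      "; treated as zero contribution."
    ))
  }
  doses <- percent_adi_to_dose(records$percent_adi, records$pesticide,
                               records$year, adi_table)
  dose_to_urine_conc(setNames(doses, records$pesticide),
                     tk = tk, urine_output = tk$urine_output_food_model,
                     pesticides = pesticides)
}

#' Predict urinary TCPy for every diet-year in a dietary-risk table
#'
#' Batch form of [predict_diet_tcpy()]: groups the records by diet label,
#' year and population and returns one predicted concentration per group.
#'
#' @param records Tibble with columns `diet_label`, `year`, `population`,
#'   `pesticide`, `percent_adi`.
#' @inheritParams predict_diet_tcpy
#'
#' @return A tibble with columns `diet_label`, `year`, `population`,
#'   `tcpy_ugL`.
#' @export
predict_food_tcpy <- function(records,
                              adi_table = default_adi_table(),
                              tk = default_toxicokinetics(),
                              pesticides = default_pesticides(),
                              quiet = TRUE) {
  records <- tibble::as_tibble(records)
  if (!"population" %in% names(records)) records$population <- "general"
  records |>
    dplyr::group_by(.data$diet_label, .data$year, .data$population) |>
    dplyr::summarise(
      tcpy_ugL = {
        key <- dplyr::cur_group()
        pest <- .data$pesticide
        pa <- .data$percent_adi
        predict_diet_tcpy(
          tibble::tibble(diet_label = key$diet_label, year = key$year,
                         pesticide = pest, percent_adi = pa),
          adi_table = adi_table, tk = tk, pesticides = pesticides,
          quiet = quiet
        )
      },
      .groups = "drop"
    )
}

#' Box-and-whisker summary of predicted concentrations for one year
#'
#' Computes the summary statistics behind a yearly box-whisker panel:
#' minimum, lower quartile, median, mean, upper quartile and maximum of the
#' predicted concentrations across diets. Quartiles use the
#' linear-interpolation convention (`stats::quantile` type 7) by default.
#'
#' @param values Numeric vector of predicted concentrations (ug/L), length
#'   >= 1.
#' @param year,population Carried into the output for labelling.
#' @param type Quantile algorithm passed to [stats::quantile()].
#'
#' @return A one-row tibble with `year`, `population`, `n`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`.
#' @export
#'
#' @examples
#' summarize_year(1:5, year = 2015, population = "general")
summarize_year <- function(values, year = NA_integer_,
                           population = NA_character_, type = 7) {
  if (length(values) < 1L || anyNA(values)) {
    abort("`values` must contain at least one non-missing prediction.")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = type))
  tibble::tibble(
    year = year, population = population, n = length(values),
    min = min(values), q1 = q[1], median = q[2],
    mean = mean(values), q3 = q[3], max = max(values)
  )
}

#' Yearly summaries for a table of per-diet predictions
#'
#' @param predictions Output of [predict_food_tcpy()].
#' @inheritParams summarize_year
#'
#' @return One row per (year, population), see [summarize_year()].
#' @export
summarize_food_years <- function(predictions, type = 7) {
  predictions |>
    dplyr::group_by(.data$year, .data$population) |>
    dplyr::reframe(summarize_year(.data$tcpy_ugL, year = .data$year[1],
                                  population = .data$population[1],
                                  type = type)[-(1:2)]) |>
    dplyr::ungroup()
}

#' Read a dietary-risk CSV
#'
#' Expected columns: `diet_label`, `year`, `population`, `pesticide`,
#' `percent_adi`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_diet_records <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("diet_label", "year", "pesticide", "percent_adi")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0) {
    abort(paste0("Dietary-risk file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(rec$percent_adi < 0, na.rm = TRUE)) abort("`percent_adi` must be non-negative.")
  rec
}
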