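#' Toxicokinetic parameters for urinary-metabolite reverse dosimetry
#'
#' Bundles the constants that link an external oral dose of an organophosphate
#' parent compound to the urinary concentration of its metabolite: the molar
#' urinary excretion fraction `fue` (fraction of the absorbed parent excreted
#' in urine as the metabolite, in moles) with its plausible range, and the
#' body-weight-adjusted daily urinary output conventions. Two urinary-output
#' conventions coexist and are deliberately kept as separate named constants:
#' the guidance-value convention (0.02 L/kg bw/day for adults, 0.03 for
#' children) used when deriving biomonitoring points of departure, and the
#' single central value (0.024 L/kg bw/day) used by the food-monitoring
#' forward model. They are never silently interchanged.
#'
#' @param fue Central molar urinary excretion fraction (dimensionless).
#' @param fue_low,fue_high Lower and upper bounds of the excretion fraction.
#' @param urine_output_adult,urine_output_child Daily urinary output in
#'   L/kg bw/day for the two guidance-value populations.
#' @param urine_output_food_model Daily urinary output in L/kg bw/day used by
#'   the food-monitoring forward model.
#'
#' @return An object of class `tk_params` (a validated list).
#' @export
#'
#' @examples
#' tk_params()
tk_params <- function(fue = 0.7,
                      fue_low = 0.5,
                      fue_high = 0.93,
                      urine_output_adult = 0.02,
                      urine_output_child = 0.03,
                      urine_output_food_model = 0.024) {
  tk <- list(
    fue = fue, fue_low = fue_low, fue_high = fue_high,
    urine_output_adult = urine_output_adult,
    urine_output_child = urine_output_child,
    urine_output_food_model = urine_output_food_model
  )
  for (nm in names(tk)) {
    x <- tk[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      abort(paste0("`", nm, "` must be a single positive finite number."))
    }
  }
  if (!(fue_low <= fue && fue <= fue_high && fue_high <= 1)) {
    abort("Excretion fractions must satisfy fue_low <= fue <= fue_high <= 1.")
  }
  structure(tk, class = "tk_params")
}

#' Default toxicokinetic parameters for TCPy
#'
#' The packaged central estimates for the chlorpyrifos/TCPy system: molar
#' urinary excretion fraction 0.7 (range 0.5-0.93, from human volunteer
#' studies), urinary output 0.02 L/kg bw/day for adults and 0.03 for children
#' (the harmonised guidance-value convention), and 0.024 L/kg bw/day for the
#' food-monitoring forward model.
#'
#' @return A [tk_params()] object.
#' @export
default_toxicokinetics <- function() tk_params()

#' Pesticide identities and molar conversion ratios
#'
#' One row per parent compound sharing the urinary metabolite, with the molar
#' mass ratio MW(metabolite)/MW(parent) used to convert an external parent
#' dose into a metabolite amount. For TCPy the packaged parents are
#' chlorpyrifos (ratio 0.566, as used in guidance-value derivation) and
#' chlorpyrifos-methyl (ratio 0.615 = 198.43/322.53 from standard molecular
#' weights; configurable because no authoritative printed value exists).
#'
#' @param extra Optional tibble with columns `pesticide` and `molar_ratio` to
#'   append or override defaults.
#'
#' @return A tibble with columns `pesticide`, `molar_ratio`.
#' @export
#'
#' @examples
#' default_pesticides()
default_pesticides <- function(extra = NULL) {
  tbl <- tibble::tibble(
    pesticide = c("chlorpyrifos", "chlorpyrifos-methyl"),
    molar_ratio = c(0.566, 0.615)
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    stopifnot(all(c("pesticide", "molar_ratio") %in% names(extra)))
    tbl <- dplyr::bind_rows(
      dplyr::filter(tbl, !.data$pesticide %in% extra$pesticide),
      extra
    )
  }
  if (any(tbl$molar_ratio <= 0 | tbl$molar_ratio >= 1)) {
    abort("Molar ratios must lie in (0, 1).")
  }
  tbl
}

molar_ratio_for <- function(pesticide, pesticides = default_pesticides()) {
  idx <- match(pesticide, pesticides$pesticide)
  if (anyNA(idx)) {
    abort(paste0(
      "No molar ratio defined for pesticide(s): ",
      paste(unique(pesticide[is.na(idx)]), collapse = ", ")
    ))
  }
  pesticides$molar_ratio[idx]
}

#' Animal points of departure for chlorpyrifos
#'
#' The endpoint-specific points of departure (PoD) selected for the
#' chlorpyrifos risk assessment: the overall PoD is the developmental
#' neurotoxicity LOAEL of 0.3 mg/kg bw/day (effects were seen at the lowest
#' tested dose); the remaining endpoints are NOAELs (long-term/maternal 0.1,
#' short-term red-blood-cell AChE inhibition 0.1, offspring 1, reproductive 5,
#' carcinogenicity 10 mg/kg bw/day).
#'
#' @return A tibble with columns `endpoint`, `value` (mg/kg bw/day), `basis`
#'   (`"NOAEL"` or `"LOAEL"`), `pesticide`.
#' @export
#'
#' @examples
#' chlorpyrifos_pods()
chlorpyrifos_pods <- function() {
  tibble::tibble(
    endpoint = c("overall", "long_term", "short_term_ache",
                 "offspring", "reproductive", "carcinogenicity"),
    value = c(0.3, 0.1, 0.1, 1, 5, 10),
    basis = c("LOAEL", rep("NOAEL", 5)),
    pesticide = "chlorpyrifos"
  )
}

#' Animal points of departure for chlorpyrifos-methyl
#'
#' The closely related compound shares the overall and long-term PoDs with
#' chlorpyrifos; no short-term AChE value is proposed, and the offspring,
#' reproductive and carcinogenicity NOAELs are 3, 10 and 40 mg/kg bw/day.
#'
#' @return A tibble in the same shape as [chlorpyrifos_pods()].
#' @export
chlorpyrifos_methyl_pods <- function() {
  tibble::tibble(
    endpoint = c("overall", "long_term", "offspring",
                 "reproductive", "carcinogenicity"),
    value = c(0.3, 0.1, 3, 10, 40),
    basis = c("LOAEL", rep("NOAEL", 4)),
    pesticide = "chlorpyrifos-methyl"
  )
}

check_pod <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    abort("PoD values must be positive finite numbers.")
  }
  invisible(value)
}

urine_output_for <- function(population, tk) {
  if (!is.character(population) || anyNA(population)) {
    abort("`population` must be \"adults\" or \"children\".")
  }
  out <- c(adults = tk$urine_output_adult,
           children = tk$urine_output_child)[population]
  if (anyNA(out)) {
    abort(paste0(
      "Unknown population label(s): ",
      paste(unique(population[is.na(out)]), collapse = ", "),
      ". Use \"adults\" or \"children\"."
    ))
  }
  unname(out)
}

#' Derive a biomonitoring point of departure (HBM-PoD)
#'
#' Converts an external animal point of departure (mg/kg bw/day) into the
#' equivalent urinary metabolite concentration for a monitored population:
#'
#' \deqn{HBM\text{-}PoD = \frac{PoD \times R_{mol} \times F_{ue}}{V_{urine}}}
#'
#' where \eqn{R_{mol}} is the molar mass ratio metabolite/parent,
#' \eqn{F_{ue}} the molar urinary excretion fraction and \eqn{V_{urine}} the
#' body-weight-adjusted daily urinary output (0.02 L/kg bw/day for adults,
#' 0.03 for children). The result is in mg/L of urine; full precision is
#' returned, rounding to 2 decimals happens only in reporting helpers.
#'
#' @param pod_value PoD in mg/kg bw/day (vectorised).
#' @param population `"adults"` or `"children"` (vectorised, recycled).
#' @param tk A [tk_params()] object.
#' @param molar_ratio Metabolite/parent molar mass ratio; defaults to the
#'   chlorpyrifos value.
#' @param fue Excretion fraction override; defaults to `tk$fue`.
#'
#' @return HBM-PoD in mg/L (numeric, full precision).
#' @export
#'
#' @examples
#' hbm_pod(0.3, "adults")   # 5.943 mg/L -> printed as 5.94
#' hbm_pod(10, "children")  # 132.07 mg/L
hbm_pod <- function(pod_value, population,
                    tk = default_toxicokinetics(),
                    molar_ratio = 0.566,
                    fue = tk$fue) {
  check_pod(pod_value)
  if (any(molar_ratio <= 0 | molar_ratio >= 1)) abort("`molar_ratio` must lie in (0, 1).")
  if (any(fue <= 0 | fue > 1)) abort("`fue` must lie in (0, 1].")
  out <- urine_output_for(population, tk)
  pod_value * molar_ratio * fue / out
}

#' Tabulate HBM-PoDs for a PoD set and both populations
#'
#' Applies [hbm_pod()] to every endpoint of a PoD table for adults and
#' children, returning the full-precision values plus the 2-decimal reported
#' values (half-to-even rounding) that downstream margin-of-exposure
#' computations use as their default basis.
#'
#' @param pods A PoD tibble such as [chlorpyrifos_pods()].
#' @param tk A [tk_params()] object.
#' @param molar_ratio Metabolite/parent molar mass ratio.
#'
#' @return A tibble with columns `endpoint`, `pod`, `basis`, `population`,
#'   `hbm_pod_mgL` (full precision) and `hbm_pod_reported` (2 decimals).
#' @export
#'
#' @examples
#' derive_hbm_pods(chlorpyrifos_pods())
derive_hbm_pods <- function(pods = chlorpyrifos_pods(),
                            tk = default_toxicokinetics(),
                            molar_ratio = 0.566) {
  pods <- tibble::as_tibble(pods)
  stopifnot(all(c("endpoint", "value") %in% names(pods)))
  tidyr::crossing(pods, population = c("adults", "children")) |>
    dplyr::mutate(
      hbm_pod_mgL = hbm_pod(.data$value, .data$population,
                            tk = tk, molar_ratio = molar_ratio),
      hbm_pod_reported = round(.data$hbm_pod_mgL, 2)
    ) |>
    dplyr::rename(pod = "value") |>
    dplyr::arrange(match(.data$endpoint, pods$endpoint), .data$population)
}

#' Predict a urinary metabolite concentration from external doses
#'
#' Forward dosimetry: converts external doses of one or more parent
#' pesticides sharing the metabolite into the total urinary metabolite
#' concentration. Doses are converted on a molar basis and summed, so the
#' result is additive across parents:
#' \eqn{C = 1000 \sum_i d_i R_i \cdot F_{ue} / V_{urine}} in ug/L.
#'
#' @param doses Named numeric vector of doses in mg/kg bw/day, names are
#'   pesticide identities; or a tibble with columns `pesticide`, `dose`.
#' @param tk A [tk_params()] object.
#' @param urine_output Urinary output in L/kg bw/day; defaults to the
#'   food-model convention 0.024.
#' @param pesticides Molar-ratio lookup, see [default_pesticides()].
#'
#' @return Total metabolite concentration in ug/L.
#' @export
#'
#' @examples
#' dose_to_urine_conc(c(chlorpyrifos = 0.001))  # 16.51 ug/L
dose_to_urine_conc <- function(doses,
                               tk = default_toxicokinetics(),
                               urine_output = tk$urine_output_food_model,
                               pesticides = default_pesticides()) {
  if (is.data.frame(doses)) {
    nm <- doses$pesticide
    doses <- setNames(doses$dose, nm)
  }
  if (length(doses) == 0L) return(0)
  if (is.null(names(doses)) || any(!nzchar(names(doses)))) {
    abort("`doses` must be named by pesticide identity.")
  }
  if (any(doses < 0)) abort("Doses must be non-negative.")
  if (urine_output <= 0) abort("`urine_output` must be positive.")
  ratios <- molar_ratio_for(names(doses), pesticides)
  1000 * sum(doses * ratios) * tk$fue / urine_output
}

#' Reconstruct an external dose from a urinary metabolite concentration
#'
#' Reverse dosimetry for a single parent compound: the exact algebraic
#' inverse of [dose_to_urine_conc()], attributing the whole measured
#' concentration to one pesticide.
#'
#' @param conc Urinary metabolite concentration in ug/L (non-negative).
#' @param pesticide Parent compound identity.
#' @inheritParams dose_to_urine_conc
#'
#' @return External dose in mg/kg bw/day.
#' @export
#'
#' @examples
#' urine_conc_to_dose(16.51, "chlorpyrifos")  # ~0.001 mg/kg bw/day
urine_conc_to_dose <- function(conc, pesticide = "chlorpyrifos",
                               tk = default_toxicokinetics(),
                               urine_output = tk$urine_output_food_model,
                               pesticides = default_pesticides()) {
  if (any(conc < 0)) abort("`conc` must be non-negative.")
  ratio <- molar_ratio_for(pesticide, pesticides)
  if (urine_output <= 0 || ratio <= 0) {
    abort("Urine output and molar ratio must be positive.")
  }
  conc * urine_output / (1000 * ratio * tk$fue)
}
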