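#' Four-colour margin-of-exposure threshold scheme
#'
#' Encodes the uncertainty-factor reasoning behind the traffic-light risk
#' categories. The baseline for any animal-study PoD is the factor of 100
#' covering inter- and intraspecies extrapolation. The overall endpoint rests
#' on a LOAEL, adding a LOAEL-to-NOAEL factor of 3 (RED below 300) extendable
#' to 10 (ORANGE below 1000); the short-term AChE endpoint adds a
#' subacute-to-subchronic factor of 3 (ORANGE below 300); generic NOAEL
#' endpoints keep RED below 100 with no ORANGE band; carcinogenicity of a
#' substance with unresolved genotoxicity uses RED below 10,000. GREEN
#' requires an additional margin of at least 10 over the most severe
#' applicable concern threshold (the ORANGE cutoff where defined, else the
#' RED cutoff); anything in between is YELLOW. Classification boundaries are
#' strict: a margin exactly at a cutoff belongs to the safer class.
#'
#' @return A tibble with columns `category`, `red_below`, `orange_below`
#'   (NA where the category has no ORANGE band) and `yellow_below`.
#' @export
#'
#' @examples
#' default_thresholds()
default_thresholds <- function() {
  tibble::tibble(
    category = c("loael_overall", "st_ache", "noael_generic", "carcinogenicity"),
    red_below = c(300, 100, 100, 10000),
    orange_below = c(1000, 300, NA, NA),
    yellow_below = c(10000, 3000, 1000, 100000)
  )
}

check_thresholds <- function(scheme) {
  ok <- with(scheme, ifelse(
    is.na(orange_below),
    red_below < yellow_below,
    red_below < orange_below & orange_below < yellow_below
  ))
  if (!all(ok)) abort("Thresholds must increase: red < orange (if any) < yellow.")
  invisible(scheme)
}

#' Map an endpoint label to its threshold category
#'
#' `overall` carries the LOAEL-based category, `short_term_ache` its own
#' subacute category, `carcinogenicity` the genotoxicity-driven category, and
#' every other NOAEL endpoint the generic one.
#'
#' @param endpoint Character vector of endpoint labels.
#' @return Character vector of category labels.
#' @export
endpoint_category <- function(endpoint) {
  dplyr::case_match(
    endpoint,
    "overall" ~ "loael_overall",
    "short_term_ache" ~ "st_ache",
    "carcinogenicity" ~ "carcinogenicity",
    c("long_term", "offspring", "reproductive") ~ "noael_generic",
    .default = NA_character_
  )
}

endpoint_abbrev <- c(
  overall = "OA", long_term = "LT", short_term_ache = "ST",
  carcinogenicity = "C", offspring = "OF", reproductive = "RE"
)

moe_colors <- c("RED", "ORANGE", "YELLOW", "GREEN")

#' Margin of exposure of a biomonitoring level against an HBM-PoD
#'
#' \deqn{MoE = \frac{HBM\text{-}PoD}{exposure}}
#'
#' The HBM-PoD is supplied in mg/L (as tabulated) and the measured exposure
#' in ug/L; units are harmonised internally. Full precision is returned;
#' reported margins are rounded half-to-even to the nearest integer with
#' [round()]. By convention the reported 2-decimal HBM-PoD values are the
#' default basis for published margins (see [derive_hbm_pods()]).
#'
#' @param hbm_pod_mgL HBM-PoD in mg/L.
#' @param exposure_ugL Measured or predicted urinary concentration in ug/L
#'   (strictly positive).
#'
#' @return The margin of exposure (dimensionless, full precision).
#' @export
#'
#' @examples
#' moe(3.96, 6.52)  # ~607
moe <- function(hbm_pod_mgL, exposure_ugL) {
  if (any(!is.finite(exposure_ugL)) || any(exposure_ugL <= 0)) {
    abort("`exposure_ugL` must be strictly positive.")
  }
  if (any(hbm_pod_mgL <= 0)) abort("`hbm_pod_mgL` must be strictly positive.")
  hbm_pod_mgL * 1000 / exposure_ugL
}

#' Classify a margin of exposure into a risk colour
#'
#' Applies the four-colour scheme with strict-inequality boundaries: RED if
#' the margin is below the category's red cutoff, ORANGE below the orange
#' cutoff (categories without an orange band skip straight to YELLOW),
#' YELLOW below the yellow cutoff, GREEN otherwise. Classification always
#' uses unrounded margins.
#'
#' @param moe Margin(s) of exposure (positive).
#' @param category Threshold category label(s), see [endpoint_category()].
#' @param scheme Threshold tibble, see [default_thresholds()].
#'
#' @return Character vector of `"RED"`, `"ORANGE"`, `"YELLOW"`, `"GREEN"`.
#' @export
#'
#' @examples
#' classify(607, "loael_overall")  # ORANGE
#' classify(100, "noael_generic")  # YELLOW (boundary goes to the safer class)
classify <- function(moe, category, scheme = default_thresholds()) {
  check_thresholds(scheme)
  if (any(moe <= 0)) abort("`moe` must be strictly positive.")
  idx <- match(category, scheme$category)
  if (anyNA(idx)) {
    abort(paste0("Unknown threshold category: ",
                 paste(unique(category[is.na(idx)]), collapse = ", ")))
  }
  red <- scheme$red_below[idx]
  orange <- scheme$orange_below[idx]
  yellow <- scheme$yellow_below[idx]
  dplyr::case_when(
    moe < red ~ "RED",
    !is.na(orange) & moe < orange ~ "ORANGE",
    moe < yellow ~ "YELLOW",
    .default = "GREEN"
  )
}

#' Margin-of-exposure table for validated biomonitoring records
#'
#' Computes, for every record x endpoint x exposure tier, the margin of
#' exposure and its colour. Children records use the children HBM-PoDs;
#' every other population group (adults, adolescents, pregnant or lactating
#' women) uses the adult values. By default the four endpoints reported in
#' study summaries are used (overall, long-term, short-term AChE,
#' carcinogenicity) with the reported 2-decimal HBM-PoDs as basis.
#'
#' @param records Clean records from [validate_records()].
#' @param hbm_pods Output of [derive_hbm_pods()].
#' @param scheme Threshold tibble.
#' @param endpoints Endpoints to report.
#' @param tiers Exposure tiers, a subset of `c("p50", "p95", "upper_ci_p95",
#'   "max")`.
#' @param basis Which HBM-PoD column to use: `"reported"` (2-decimal, the
#'   publication convention) or `"full"` precision.
#'
#' @return A tidy tibble: `study_id`, `country`, `population`, `endpoint`,
#'   `tier`, `exposure_ugL`, `hbm_pod_mgL`, `moe`, `moe_reported`,
#'   `category`, `color`.
#' @export
moe_table <- function(records,
                      hbm_pods = derive_hbm_pods(),
                      scheme = default_thresholds(),
                      endpoints = c("overall", "long_term",
                                    "short_term_ache", "carcinogenicity"),
                      tiers = c("p50", "p95", "upper_ci_p95", "max"),
                      basis = c("reported", "full")) {
  basis <- match.arg(basis)
  records <- tibble::as_tibble(records)
  pod_col <- if (basis == "reported") "hbm_pod_reported" else "hbm_pod_mgL"
  long <- records |>
    dplyr::select(dplyr::any_of(c("study_id", "country", "population",
                                  "p50", "p95", "upper_ci_p95", "max"))) |>
    tidyr::pivot_longer(dplyr::any_of(tiers), names_to = "tier",
                        values_to = "exposure_ugL") |>
    dplyr::filter(!is.na(.data$exposure_ugL)) |>
    dplyr::mutate(pod_population = ifelse(.data$population == "children",
                                          "children", "adults"))
  pods <- hbm_pods |>
    dplyr::filter(.data$endpoint %in% endpoints) |>
    dplyr::select("endpoint", pod_population = "population",
                  hbm_pod_mgL = dplyr::all_of(pod_col))
  long |>
    dplyr::inner_join(pods, by = "pod_population",
                      relationship = "many-to-many") |>
    dplyr::mutate(
      moe = moe(.data$hbm_pod_mgL, .data$exposure_ugL),
      moe_reported = round(.data$moe),
      category = endpoint_category(.data$endpoint),
      color = classify(.data$moe, .data$category, scheme),
      tier = factor(.data$tier, levels = c("p50", "p95", "upper_ci_p95", "max"))
    ) |>
    dplyr::select(-"pod_population") |>
    dplyr::arrange(.data$study_id, .data$tier,
                   match(.data$endpoint, endpoints))
}

#' Range of margins of exposure across studies
#'
#' Minimum and maximum reported margin over all records carrying the given
#' tier, for one endpoint - the computation behind published cross-study
#' range tables. The contributing studies for each bound are listed.
#'
#' @param moe_tbl Output of [moe_table()].
#' @param endpoint,tier Which slice to summarise.
#'
#' @return A one-row tibble: `endpoint`, `tier`, `n_studies`, `moe_min`,
#'   `moe_max`, `study_min`, `study_max`.
#' @export
moe_range <- function(moe_tbl, endpoint, tier) {
  sub <- moe_tbl |>
    dplyr::filter(.data$endpoint == !!endpoint, .data$tier == !!tier)
  if (nrow(sub) == 0L) {
    abort(paste0("No usable record for endpoint '", endpoint,
                 "' at tier '", tier, "'."))
  }
  tibble::tibble(
    endpoint = endpoint, tier = tier, n_studies = nrow(sub),
    moe_min = min(sub$moe_reported), moe_max = max(sub$moe_reported),
    study_min = sub$study_id[which.min(sub$moe_reported)],
    study_max = sub$study_id[which.max(sub$moe_reported)]
  )
}

#' Range table across all endpoint x tier x population slices
#'
#' @param moe_tbl Output of [moe_table()].
#' @return A tibble with one row per population x endpoint x tier.
#' @export
moe_ranges <- function(moe_tbl) {
  moe_tbl |>
    dplyr::mutate(pop_class = ifelse(.data$population == "children",
                                     "children", "adults")) |>
    dplyr::group_by(.data$pop_class, .data$endpoint, .data$tier) |>
    dplyr::summarise(
      n_studies = dplyr::n(),
      moe_min = min(.data$moe_reported),
      moe_max = max(.data$moe_reported),
      study_min = .data$study_id[which.min(.data$moe_reported)],
      study_max = .data$study_id[which.max(.data$moe_reported)],
      .groups = "drop"
    )
}

#' Rescale a known margin of exposure to another endpoint
#'
#' At fixed exposure the margin is proportional to the HBM-PoD, so a margin
#' published for one endpoint determines the margin for any other:
#' `MoE(to) = MoE(from) * HBM-PoD(to) / HBM-PoD(from)`. Uses the reported
#' (2-decimal) HBM-PoD values by default, matching the publication
#' convention.
#'
#' @param moe_known Margin of exposure for `from_endpoint`.
#' @param from_endpoint,to_endpoint Endpoint labels.
#' @param population `"adults"` or `"children"`.
#' @param hbm_pods Output of [derive_hbm_pods()].
#' @param basis `"reported"` or `"full"` precision HBM-PoDs.
#'
#' @return The rescaled margin (full precision; round for reporting).
#' @export
#'
#' @examples
#' endpoint_rescale(2970, "overall", "carcinogenicity", "adults")  # 99050
endpoint_rescale <- function(moe_known, from_endpoint, to_endpoint,
                             population = "adults",
                             hbm_pods = derive_hbm_pods(),
                             basis = c("reported", "full")) {
  basis <- match.arg(basis)
  pod_col <- if (basis == "reported") "hbm_pod_reported" else "hbm_pod_mgL"
  pick <- function(ep) {
    v <- hbm_pods[[pod_col]][hbm_pods$endpoint == ep &
                               hbm_pods$population == population]
    if (length(v) != 1L) {
      abort(paste0("Endpoint '", ep, "' not defined for population '",
                   population, "'."))
    }
    v
  }
  moe_known * pick(to_endpoint) / pick(from_endpoint)
}

#' Per-study risk roll-up across endpoints
#'
#' For each exposure tier of one study, reports the worst (most severe)
#' colour across the assessed endpoints together with the endpoint
#' abbreviations attaining it (`OA` overall, `LT` long-term, `ST` short-term
#' AChE, `C` carcinogenicity), or `"All"` when every endpoint sits at the
#' worst colour - the structure of a published per-study summary table.
#'
#' @param moe_tbl Output of [moe_table()] filtered to one study (or a tibble
#'   with columns `tier`, `endpoint`, `color`).
#'
#' @return A tibble with columns `tier`, `color`, `endpoints`.
#' @export
summarize_study <- function(moe_tbl) {
  if (nrow(moe_tbl) == 0L) abort("No margin-of-exposure results to summarise.")
  if ("study_id" %in% names(moe_tbl) &&
      dplyr::n_distinct(moe_tbl$study_id) > 1L) {
    abort("`summarize_study()` expects results for a single study.")
  }
  moe_tbl |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(
      endpoints = {
        worst <- moe_colors[min(match(.data$color, moe_colors))]
        at <- .data$endpoint[.data$color == worst]
        if (length(at) == dplyr::n()) "All" else
          paste(endpoint_abbrev[at], collapse = "/")
      },
      color = moe_colors[min(match(.data$color, moe_colors))],
      .groups = "drop"
    ) |>
    dplyr::select("tier", "color", "endpoints")
}
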