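pods <- derive_hbm_pods()

test_that("margins of exposure reproduce published spot values", {
  # children overall vs the Cyprus median; adults overall vs the German median
  expect_equal(round(moe(3.96, 6.52)), 607)
  expect_equal(round(moe(5.94, 0.82)), 7244)
  expect_equal(round(moe(198.10, 0.82)), 241585)
  expect_equal(round(moe(5.94, 55.22)), 108)  # Israel adults, upper CI
  expect_equal(round(moe(5.94, 7.35)), 808)   # Portugal adults, P95
  expect_equal(moe(3.96, 3960), 1)
  expect_error(moe(3.96, 0), "positive")
  expect_error(moe(3.96, -2), "positive")
  expect_error(moe(0, 5), "positive")
})

test_that("margin is decreasing in exposure and increasing in the HBM-PoD", {
  set.seed(3)
  for (i in 1:20) {
    hp <- runif(1, 0.5, 200)
    ex <- runif(1, 0.05, 60)
    k <- runif(1, 1.01, 4)
    expect_true(moe(hp, ex * k) < moe(hp, ex))
    expect_true(moe(hp * k, ex) > moe(hp, ex))
  }
})

test_that("colour classification follows the threshold prose with strict boundaries", {
  expect_equal(classify(607, "loael_overall"), "ORANGE")
  expect_equal(classify(100, "noael_generic"), "YELLOW")  # boundary -> safer class
  expect_equal(classify(99.999, "noael_generic"), "RED")
  expect_equal(classify(100000, "carcinogenicity"), "GREEN")
  expect_equal(classify(99999, "carcinogenicity"), "YELLOW")
  expect_equal(classify(300, "loael_overall"), "ORANGE")
  expect_equal(classify(1000, "loael_overall"), "YELLOW")
  expect_equal(classify(10000, "loael_overall"), "GREEN")
  expect_equal(classify(299, "st_ache"), "ORANGE")
  expect_equal(classify(2999, "st_ache"), "YELLOW")
  expect_equal(classify(3000, "st_ache"), "GREEN")
  # categories without an orange band skip straight from red to yellow
  expect_equal(classify(150, "noael_generic"), "YELLOW")
  expect_error(classify(100, "mystery"), "Unknown threshold category")
  expect_error(classify(0, "st_ache"), "positive")
})

test_that("the green boundary sits a factor of 10 above the severest concern cutoff", {
  sch <- default_thresholds()
  severest <- ifelse(is.na(sch$orange_below), sch$red_below, sch$orange_below)
  expect_equal(sch$yellow_below, 10 * severest)
})

test_that("classification is monotone: a larger margin is never more severe", {
  severity <- function(col) match(col, c("RED", "ORANGE", "YELLOW", "GREEN"))
  set.seed(8)
  for (cat in default_thresholds()$category) {
    m <- sort(exp(runif(50, log(10), log(1e6))))
    sev <- severity(classify(m, cat))
    expect_true(all(diff(sev) >= 0), info = cat)
  }
})

test_that("endpoint rescaling exploits proportionality at fixed exposure", {
  # published overall margin for lactating women -> carcinogenicity margin
  expect_equal(round(endpoint_rescale(2970, "overall", "carcinogenicity")), 99050)
  expect_equal(round(endpoint_rescale(2970, "overall", "long_term")), 990)
  expect_equal(endpoint_rescale(123, "overall", "overall"), 123)
  fwd <- endpoint_rescale(500, "overall", "carcinogenicity", "children")
  expect_equal(endpoint_rescale(fwd, "carcinogenicity", "overall", "children"),
               500, tolerance = 1e-12)
  expect_error(endpoint_rescale(1, "overall", "bmd10"), "not defined")
})

test_that("margin ratios across endpoints match PoD ratios at fixed exposure", {
  recs <- validate_records(read_hbm_records())$records
  tbl <- moe_table(recs, basis = "full")
  wide <- tidyr::pivot_wider(
    tbl[, c("study_id", "population", "tier", "endpoint", "moe")],
    names_from = "endpoint", values_from = "moe"
  )
  expect_equal(wide$overall / wide$long_term, rep(3, nrow(wide)))
  expect_equal(wide$carcinogenicity / wide$overall,
               rep(10 / 0.3, nrow(wide)))
})

test_that("within a study margins fall as the exposure tier rises", {
  recs <- validate_records(read_hbm_records())$records
  tbl <- moe_table(recs)
  ordered <- tbl |>
    dplyr::group_by(study_id, endpoint) |>
    dplyr::summarise(ok = all(diff(moe[order(tier)]) <= 0),
                     .groups = "drop")
  expect_true(all(ordered$ok))
})

test_that("cross-study ranges report extremes with their contributing studies", {
  recs <- validate_records(read_hbm_records())$records
  children <- moe_table(recs[recs$population == "children", ])
  r <- moe_range(children, "overall", "p50")
  expect_equal(r$moe_min, 607)
  expect_equal(r$study_min, "CY_Organiko")
  expect_equal(r$n_studies, 5)

  single <- moe_range(children[children$study_id == "BE_3xG", ], "overall", "p50")
  expect_equal(single$moe_min, single$moe_max)

  # an intermediate exposure must not move the extremes
  extra <- tibble::tibble(study_id = "mid", country = "X", population = "children",
                          p50 = 2.0, p95 = NA_real_, upper_ci_p95 = NA_real_,
                          max = NA_real_)
  with_mid <- moe_table(dplyr::bind_rows(recs[recs$population == "children", ], extra))
  r2 <- moe_range(with_mid, "overall", "p50")
  expect_equal(c(r2$moe_min, r2$moe_max), c(r$moe_min, r$moe_max))
  expect_error(moe_range(children, "overall", "max"), "No usable record")
})

test_that("study roll-up reports the worst colour and the endpoints attaining it", {
  mk <- function(ep, col) tibble::tibble(tier = "p50", endpoint = ep, color = col)
  all_green <- mk(c("overall", "long_term", "short_term_ache", "carcinogenicity"),
                  "GREEN")
  s <- summarize_study(all_green)
  expect_equal(s$color, "GREEN")
  expect_equal(s$endpoints, "All")

  mixed <- mk(c("overall", "short_term_ache", "long_term", "carcinogenicity"),
              c("ORANGE", "ORANGE", "YELLOW", "GREEN"))
  s <- summarize_study(mixed)
  expect_equal(s$color, "ORANGE")
  expect_equal(s$endpoints, "OA/ST")

  one <- summarize_study(mk("long_term", "YELLOW"))
  expect_equal(one$color, "YELLOW")
  expect_equal(one$endpoints, "All")
  expect_error(summarize_study(all_green[0, ]), "No margin")
})
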