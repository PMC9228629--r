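test_that("population simulation honours its median/spread parameterisation", {
  flat <- simulate_population(2.5, 0, n = 50, seed = 1)
  expect_true(all(flat$value == 2.5))

  sim <- simulate_population(1.5, 0.8431, n = 1e5, seed = 10)
  expect_equal(median(sim$value), 1.5, tolerance = 0.02)
  ratio <- quantile(sim$value, 0.95, names = FALSE) / median(sim$value)
  expect_equal(ratio, 4.0, tolerance = 0.05)

  sim10 <- simulate_population(1.5, 1.3998, n = 1e5, seed = 11)
  ratio10 <- quantile(sim10$value, 0.95, names = FALSE) / median(sim10$value)
  expect_equal(ratio10, 10.0, tolerance = 0.05)

  expect_identical(simulate_population(1, 0.5, 100, seed = 3),
                   simulate_population(1, 0.5, 100, seed = 3))
  expect_error(simulate_population(0, 1, 10, seed = 1), "positive")
  expect_error(simulate_population(1, -1, 10, seed = 1), "non-negative")
  expect_error(simulate_population(1, 1, 10), "seed")
})

test_that("detection-limit censoring flags values below the limit", {
  sim <- simulate_population(1, 1, n = 1000, seed = 4, lod = 1)
  expect_equal(mean(sim$censored), 0.5, tolerance = 0.1)
  expect_true(all(sim$value[sim$censored] < 1))
})

test_that("aggregation produces ordered percentile records with bootstrap CIs", {
  const <- tibble::tibble(value = rep(3.3, 40), censored = FALSE)
  rec <- aggregate_to_record(const, "const", seed = 1)
  expect_equal(c(rec$p50, rec$p95, rec$upper_ci_p95), rep(3.3, 3))

  for (s in 1:10) {
    sim <- simulate_population(2, 1, n = 120, seed = s)
    rec <- aggregate_to_record(sim, "s", seed = s + 100)
    expect_true(rec$p50 <= rec$p95 && rec$p95 <= rec$upper_ci_p95)
    expect_equal(rec$p50, naive_quantile(sim$value, 0.5))
    expect_equal(rec$p95, naive_quantile(sim$value, 0.95))
  }
  expect_error(aggregate_to_record(1:5, "tiny", seed = 1), "At least 20")
})

test_that("heavily censored populations report missing percentiles", {
  sim <- simulate_population(1, 0.5, n = 500, seed = 6, lod = 3)
  expect_true(mean(sim$censored) > 0.6)
  rec <- aggregate_to_record(sim, "below_lod", seed = 7)
  expect_true(all(is.na(c(rec$p50, rec$p95, rec$upper_ci_p95))))
  val <- validate_records(rec)
  expect_match(val$issues$problem, "unusable for MoE")
})

test_that("parameter recovery from large simulated samples", {
  m <- 3.2
  sigma <- 0.8431
  sim <- simulate_population(m, sigma, n = 1e5, seed = 42)
  expect_equal(median(sim$value), m, tolerance = 0.02)
  est_ratio <- quantile(sim$value, 0.95, names = FALSE) / median(sim$value)
  expect_equal(est_ratio, exp(1.645 * sigma), tolerance = 0.05)
})

test_that("simulated diet tables honour eras, counts and seeds", {
  d <- simulate_diet_table(years = 2012:2019, n_diets = 7, seed = 9)
  expect_equal(nrow(d), 7 * 8 * 2)
  expect_identical(d, simulate_diet_table(years = 2012:2019, n_diets = 7, seed = 9))

  fixed <- simulate_diet_table(years = 2015:2016, n_diets = 5,
                               range_pre = c(100, 100), range_post = c(100, 100),
                               pesticides = "chlorpyrifos", seed = 1)
  expect_true(all(fixed$percent_adi == 100))
  pred <- predict_food_tcpy(fixed)
  med <- tapply(pred$tcpy_ugL, pred$year, median)
  # the 2016 tenfold ADI reduction propagates exactly through the linear model
  expect_equal(med[["2015"]], 10 * med[["2016"]])

  shifted <- simulate_diet_table(years = 2014:2017, n_diets = 20,
                                 range_pre = c(50, 90), range_post = c(5, 9),
                                 pesticides = "chlorpyrifos", seed = 2)
  expect_true(all(shifted$percent_adi[shifted$year >= 2016] < 10))
})

test_that("synthetic records run the whole pipeline end to end", {
  recs <- dplyr::bind_rows(lapply(1:4, function(i) {
    sim <- simulate_population(median = c(0.5, 1.5, 3, 7)[i], sigma_log = 1,
                               n = 150, seed = 20 + i)
    aggregate_to_record(sim, study_id = paste0("synth_", i),
                        country = "Synthland",
                        population = c("adults", "children")[1 + i %% 2],
                        seed = 30 + i)
  }))
  res <- run_pipeline(hbm = recs)
  expect_true(all(res$moe$moe > 0))
  expect_true(all(res$moe$color %in% c("RED", "ORANGE", "YELLOW", "GREEN")))
  expect_true(all(res$moe$moe_reported == round(res$moe$moe)))
  # classification consistent with the scheme on every row
  expect_identical(res$moe$color,
                   classify(res$moe$moe, res$moe$category))
})
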