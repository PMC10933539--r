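test_that("carbon conversion reproduces the printed arithmetic", {
  expect_equal(round(carbon_rate(156), 1), 84.2)
  expect_equal(round(carbon_rate(30), 1), 16.2)
  expect_equal(carbon_rate(150), 81)
  expect_equal(round(carbon_rate(26)), 14)
  expect_error(carbon_rate(100, carbon_fraction = 0.9), "outside")
})

test_that("per-tree rates follow the constant-growth definitions", {
  metrics <- tibble::tibble(tree_id = c("a", "b"), h_m = c(44.3, 30),
                            dbh_m = c(1.8, 1.0), v_m3 = c(34.9, 10))
  records <- tree_records(tibble::tibble(site = "S", tree_id = c("a", "b"),
                                         planting_year = 1863, scan_year = 2022))
  r <- growth_rates(metrics, records)
  expect_equal(r$height_rate_m_yr, c(44.3, 30) / 159)
  expect_equal(r$dbh_rate_cm_yr, 100 * c(1.8, 1.0) / 159)
  expect_equal(r$agb_rate_kg_yr, 1000 * c(34.9, 10) * 0.34 / 159)
  # carbon/AGB ratio is exactly the carbon fraction for every tree
  expect_equal(r$carbon_rate_kg_yr / r$agb_rate_kg_yr, rep(0.54, 2))
  # doubling age halves every rate
  records2 <- tree_records(tibble::tibble(site = "S", tree_id = c("a", "b"),
                                          planting_year = 2022 - 318, scan_year = 2022))
  r2 <- growth_rates(metrics, records2)
  expect_equal(r2$height_rate_m_yr, r$height_rate_m_yr / 2)
  expect_equal(r2$agb_rate_kg_yr, r$agb_rate_kg_yr / 2)
  expect_equal(r2$carbon_rate_kg_yr, r$carbon_rate_kg_yr / 2)
})

test_that("missing metrics yield NA rates, never imputation", {
  metrics <- tibble::tibble(tree_id = "a", h_m = 20, dbh_m = NA_real_, v_m3 = 5)
  records <- tree_records(tibble::tibble(site = "S", tree_id = "a",
                                         planting_year = 2000, scan_year = 2022))
  r <- growth_rates(metrics, records)
  expect_true(is.na(r$dbh_rate_cm_yr))
  expect_false(is.na(r$height_rate_m_yr))
})

test_that("site summaries reproduce the mean-over-age arithmetic", {
  metrics <- tibble::tibble(tree_id = sprintf("b%d", 1:4),
                            h_m = c(44, 44.6, 44.2, 44.4),
                            dbh_m = 1.8, v_m3 = 34.9)
  records <- tree_records(tibble::tibble(site = "Benmore", tree_id = metrics$tree_id,
                                         planting_year = 1863, scan_year = 2022))
  s <- site_summary(growth_rates(metrics, records))
  expect_equal(round(s$rate_height_m_yr, 2), 0.28) # 44.3 / 159
  expect_equal(s$rate_agb_kg_yr, 1000 * 34.9 * 0.34 / 159)
  # uniform ages: the two rate conventions coincide
  expect_equal(s$rate_height_m_yr, s$rate_height_m_yr_treemean)

  m2 <- tibble::tibble(tree_id = "h1", h_m = 24.5, dbh_m = 1.1, v_m3 = 11.8)
  rec2 <- tree_records(tibble::tibble(site = "Havering", tree_id = "h1",
                                      planting_year = 1870, scan_year = 2022))
  s2 <- site_summary(growth_rates(m2, rec2))
  expect_equal(round(s2$rate_height_m_yr, 2), 0.16) # 24.5 / 152
  # a single-tree site just reports that tree
  expect_equal(s2$mean_h_m, 24.5)
  expect_equal(s2$n_trees, 1L)
})

test_that("cohort rules split sites by age", {
  metrics <- tibble::tibble(tree_id = c("y1", "y2", "o1", "o2"),
                            h_m = c(20, 22, 35, 36), dbh_m = 0.8, v_m3 = 10)
  records <- tree_records(tibble::tibble(
    site = "Wakehurst", tree_id = metrics$tree_id,
    planting_year = c(1989, 1989, 1900, 1900), scan_year = 2022))
  s <- site_summary(growth_rates(metrics, records),
                    cohorts = function(age) ifelse(age < 50, "<50 yr", ">=50 yr"))
  expect_equal(nrow(s), 2)
  expect_setequal(s$cohort, c("<50 yr", ">=50 yr"))
  expect_equal(s$n_trees, c(2L, 2L))
})

test_that("rate comparisons use the Welch t-test", {
  x <- c(1, 2, 3, 4)
  expect_equal(compare_rates(x, x)$statistic, 0)
  expect_equal(compare_rates(x, x)$p_value, 1)
  set.seed(8)
  res <- compare_rates(rnorm(30, 0, 1), rnorm(30, 5, 1))
  expect_lt(res$p_value, 1e-5)
  ref <- t.test(c(1, 2, 6), c(3, 3.5, 9), var.equal = FALSE)
  got <- compare_rates(c(1, 2, 6), c(3, 3.5, 9))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_error(compare_rates(1, c(1, 2)), class = "tlscarbon_degenerate")
})

test_that("the long rate table is box-plot ready", {
  metrics <- tibble::tibble(tree_id = c("a", "b"), h_m = c(20, 30),
                            dbh_m = c(0.5, 1), v_m3 = c(5, 10))
  records <- tree_records(tibble::tibble(site = "S", tree_id = c("a", "b"),
                                         planting_year = 2000, scan_year = 2022))
  long <- rates_long(growth_rates(metrics, records))
  expect_equal(nrow(long), 8) # 2 trees x 4 rate metrics
  expect_setequal(unique(long$metric),
                  c("height_rate_m_yr", "dbh_rate_cm_yr", "agb_rate_kg_yr",
                    "carbon_rate_kg_yr"))
})
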