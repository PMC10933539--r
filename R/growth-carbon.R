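#' Growth and carbon parameters
#'
#' Wood density (Mg m^-3) converts woody volume to aboveground biomass;
#' the carbon fraction converts biomass to carbon. Defaults are the adopted
#' *Sequoiadendron giganteum* values: density 0.34 (published component
#' densities span ~0.2 bark to ~0.45 branch wood) and carbon fraction 0.54,
#' among the highest measured for North American species.
#'
#' @param wood_density Mg m^-3, must lie in (0.2, 0.6).
#' @param carbon_fraction Dimensionless, must lie in (0.4, 0.6).
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(wood_density = 0.34, carbon_fraction = 0.54) {
  if (wood_density <= 0.2 || wood_density >= 0.6)
    stop_bad_arg("wood_density %.3f outside (0.2, 0.6) Mg m^-3", wood_density)
  if (carbon_fraction <= 0.4 || carbon_fraction >= 0.6)
    stop_bad_arg("carbon_fraction %.3f outside (0.4, 0.6)", carbon_fraction)
  structure(list(wood_density = wood_density, carbon_fraction = carbon_fraction),
            class = "growth_params")
}

#' Per-tree annual growth and carbon rates
#'
#' Joins structural metrics to tree records and computes lifetime-average
#' annual rates under the constant-growth assumption:
#' height `H/age` (m/yr), DBH `100*DBH/age` (cm/yr), AGB
#' `1000*(V*rho)/age` (kg/yr) and carbon `AGB rate * CF` (kg/yr).
#' A missing metric leaves the corresponding rates `NA` (no imputation).
#'
#' @param metrics Data frame with `tree_id`, `h_m`, `dbh_m`, `v_m3` (as
#'   from [compute_all_metrics()]).
#' @param records Tree records with `tree_id`, `site`, `age` (as from
#'   [read_tree_table()] / [tree_records()]).
#' @param params A [growth_params()].
#' @return Tibble with one row per tree: metrics, `age`, `agb_mg`,
#'   `height_rate_m_yr`, `dbh_rate_cm_yr`, `agb_rate_kg_yr`,
#'   `carbon_rate_kg_yr`.
#' @export
growth_rates <- function(metrics, records, params = growth_params()) {
  stopifnot(inherits(params, "growth_params"))
  out <- dplyr::inner_join(tibble::as_tibble(metrics), tibble::as_tibble(records),
                           by = "tree_id")
  if (nrow(out) == 0) stop_bad_arg("no tree_id in common between metrics and records")
  if (any(out$age <= 0)) stop_bad_arg("tree age must be positive")
  dplyr::mutate(out,
    agb_mg = .data$v_m3 * params$wood_density,
    height_rate_m_yr = .data$h_m / .data$age,
    dbh_rate_cm_yr = 100 * .data$dbh_m / .data$age,
    agb_rate_kg_yr = 1000 * .data$agb_mg / .data$age,
    carbon_rate_kg_yr = .data$agb_rate_kg_yr * params$carbon_fraction)
}

#' Carbon uptake rate from a biomass accumulation rate
#'
#' `carbon = AGB rate x carbon fraction`, in the same rate units.
#'
#' @param agb_rate Biomass accumulation rate (e.g. kg/yr).
#' @param carbon_fraction Dimensionless carbon fraction (default 0.54).
#' @return Carbon accumulation rate.
#' @export
carbon_rate <- function(agb_rate, carbon_fraction = 0.54) {
  if (carbon_fraction <= 0.4 || carbon_fraction >= 0.6)
    stop_bad_arg("carbon_fraction %.3f outside (0.4, 0.6)", carbon_fraction)
  agb_rate * carbon_fraction
}

#' Site and cohort summaries of growth and carbon
#'
#' Arithmetic means of the structural metrics per site (optionally split
#' into age cohorts), with annual rates reported two ways: from the cohort
#' mean metric divided by the cohort mean age (`rate_* `, the
#' mean-over-age convention) and as the mean of the per-tree rates
#' (`rate_*_treemean`). The two coincide when all trees in a cohort share
#' one age, and are both reported because neither is canonical for mixed
#' ages.
#'
#' @param rates Output of [growth_rates()].
#' @param cohorts Either `NULL` (one summary per site) or a function
#'   mapping an age vector to cohort labels (e.g.
#'   `function(age) ifelse(age < 50, "<50 yr", ">=50 yr")`).
#' @param min_trees Cohorts with fewer trees are dropped with a message.
#' @return Tibble with one row per site x cohort.
#' @export
site_summary <- function(rates, cohorts = NULL, min_trees = 1L) {
  rates <- tibble::as_tibble(rates)
  rates$cohort <- if (is.null(cohorts)) "all" else cohorts(rates$age)
  grouped <- dplyr::group_by(rates, .data$site, .data$cohort)
  out <- dplyr::summarise(grouped,
    n_trees = dplyr::n(),
    mean_age = mean(.data$age),
    mean_h_m = mean(.data$h_m, na.rm = TRUE),
    mean_dbh_m = mean(.data$dbh_m, na.rm = TRUE),
    mean_v_m3 = mean(.data$v_m3, na.rm = TRUE),
    mean_agb_mg = mean(.data$agb_mg, na.rm = TRUE),
    rate_height_m_yr = mean(.data$h_m, na.rm = TRUE) / mean(.data$age),
    rate_dbh_cm_yr = 100 * mean(.data$dbh_m, na.rm = TRUE) / mean(.data$age),
    rate_agb_kg_yr = 1000 * mean(.data$agb_mg, na.rm = TRUE) / mean(.data$age),
    rate_height_m_yr_treemean = mean(.data$height_rate_m_yr, na.rm = TRUE),
    rate_dbh_cm_yr_treemean = mean(.data$dbh_rate_cm_yr, na.rm = TRUE),
    rate_agb_kg_yr_treemean = mean(.data$agb_rate_kg_yr, na.rm = TRUE),
    .groups = "drop")
  small <- out$n_trees < min_trees
  if (any(small)) {
    message(sprintf("dropping %d cohort(s) with fewer than %d trees: %s",
                    sum(small), min_trees,
                    paste(out$site[small], out$cohort[small], sep = "/", collapse = ", ")))
    out <- out[!small, ]
  }
  out
}

#' Welch t-test between two groups of accumulation rates
#'
#' Two-sided Welch (unequal-variance) two-sample t-test, the comparison
#' used for per-tree AGB accumulation rates between sites/cohorts.
#'
#' @param rates_a,rates_b Numeric vectors, each with >= 2 values.
#' @return One-row tibble: `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_rates <- function(rates_a, rates_b) {
  rates_a <- rates_a[!is.na(rates_a)]
  rates_b <- rates_b[!is.na(rates_b)]
  if (length(rates_a) < 2 || length(rates_b) < 2)
    stop_bad_arg("each group needs >= 2 non-missing rates (got %d and %d)",
                 length(rates_a), length(rates_b), class = "tlscarbon_degenerate")
  tt <- t.test(rates_a, rates_b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter),
                 mean_a = mean(rates_a), mean_b = mean(rates_b))
}

#' Long-format rate table for plotting
#'
#' Reshapes per-tree rates into (tree_id, site, cohort, metric, rate) rows,
#' ready for box plots.
#'
#' @inheritParams site_summary
#' @return A long tibble.
#' @export
rates_long <- function(rates, cohorts = NULL) {
  rates <- tibble::as_tibble(rates)
  rates$cohort <- if (is.null(cohorts)) "all" else cohorts(rates$age)
  tidyr::pivot_longer(
    rates[, c("tree_id", "site", "cohort", "height_rate_m_yr",
              "dbh_rate_cm_yr", "agb_rate_kg_yr", "carbon_rate_kg_yr")],
    cols = tidyr::ends_with("_yr"), names_to = "metric", values_to = "rate")
}
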