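#' Pipeline configuration
#'
#' Validated, serialisable configuration for [run_pipeline()]. Defaults are
#' the adopted study constants: breast-height slice 1.2-1.4 m and
#' above-buttress slice 4.0-4.5 m above the lowest point, wood density
#' 0.34 Mg m^-3, carbon fraction 0.54, 10 volume repeats, 100 bootstrap
#' samples.
#'
#' @param input Either a directory of per-tree point-cloud files (with a
#'   `tree_records.csv`), or `NULL` to run on `clouds`/`records` passed to
#'   [run_pipeline()] directly.
#' @param dbh_slice,dtb_slice Half-open slice intervals (m above lowest point).
#' @param wood_density,carbon_fraction See [growth_params()].
#' @param slice_height,n_repeats,branch_allowance Volume estimator settings
#'   (see [estimate_volume()]).
#' @param n_boot Bootstrap refits for UK model envelopes.
#' @param uk_forms UK model forms to fit.
#' @param published_models Published model ids to evaluate (those whose
#'   required metrics are available are used; others are skipped with a log
#'   entry).
#' @param cohorts Optional cohort rule, see [site_summary()].
#' @param seed Integer master seed.
#' @param out_dir Output directory for CSVs and the manifest, or `NULL` to
#'   skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, dbh_slice = c(1.2, 1.4),
                            dtb_slice = c(4.0, 4.5), wood_density = 0.34,
                            carbon_fraction = 0.54, slice_height = 0.5,
                            n_repeats = 10L, branch_allowance = 0.15,
                            n_boot = 100L,
                            uk_forms = c("dbh_h", "dtb_h", "dbh_only", "h_only"),
                            published_models = allometric_models()$model_id,
                            cohorts = NULL, seed = 1L, out_dir = NULL) {
  params <- growth_params(wood_density, carbon_fraction) # validates both
  if (length(dbh_slice) != 2 || dbh_slice[2] <= dbh_slice[1])
    stop_bad_arg("dbh_slice must be an increasing length-2 interval")
  if (length(dtb_slice) != 2 || dtb_slice[2] <= dtb_slice[1])
    stop_bad_arg("dtb_slice must be an increasing length-2 interval")
  if (n_repeats < 1 || n_boot < 1) stop_bad_arg("n_repeats and n_boot must be >= 1")
  structure(list(input = input, dbh_slice = dbh_slice, dtb_slice = dtb_slice,
                 params = params, slice_height = slice_height,
                 n_repeats = as.integer(n_repeats),
                 branch_allowance = branch_allowance, n_boot = as.integer(n_boot),
                 uk_forms = uk_forms, published_models = published_models,
                 cohorts = cohorts, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full TLS-to-carbon pipeline
#'
#' Orchestrates the stages end to end: read (or accept) per-tree point
#' clouds and tree records, compute structural metrics and slice-stack
#' volumes, convert to AGB/carbon and annual rates, summarise sites and
#' cohorts, evaluate the published allometric models against TLS-derived
#' AGB, and fit the UK power-law forms with bootstrap envelopes. Per-tree
#' failures are recorded in the issue ledger and the pipeline continues
#' with the remaining trees. Deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @param clouds Named list of point clouds (names = tree ids); required if
#'   `config$input` is `NULL`.
#' @param records Tree records table; required if `config$input` is `NULL`.
#' @return A list of class `pipeline_result`: `metrics`, `rates`,
#'   `site_summaries`, `published_eval` (per published model),
#'   `published_predictions`, `uk_fits` (named list of `allom_fit`),
#'   `uk_summary`, `bootstraps`, `issues` (per-tree ledger), `manifest`.
#' @export
run_pipeline <- function(config, clouds = NULL, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input)) {
    rec_path <- file.path(config$input, "tree_records.csv")
    records <- read_tree_table(rec_path)
    files <- list.files(config$input, pattern = "\\.(ply|xyz|las)$", full.names = TRUE)
    ids <- tools::file_path_sans_ext(basename(files))
    clouds <- setNames(as.list(files), ids)
  }
  if (is.null(clouds) || is.null(records))
    stop_bad_arg("either config$input or both clouds and records must be supplied")

  issues <- list()
  note <- function(tree_id, stage, msg) {
    issues[[length(issues) + 1]] <<- tibble::tibble(tree_id = tree_id,
                                                    stage = stage, message = msg)
  }

  metrics <- purrr::imap_dfr(clouds, function(cl, id) {
    cl <- tryCatch(if (is.character(cl)) read_cloud(cl) else cl,
                   error = function(e) { note(id, "read", conditionMessage(e)); NULL })
    if (is.null(cl)) return(NULL)
    m <- tryCatch(
      compute_all_metrics(cl, tree_id = id, dbh_slice = config$dbh_slice,
                          dtb_slice = config$dtb_slice,
                          volume_config = list(slice_height = config$slice_height,
                                               n_repeats = config$n_repeats,
                                               branch_allowance = config$branch_allowance,
                                               seed = config$seed)),
      error = function(e) { note(id, "metrics", conditionMessage(e)); NULL })
    if (!is.null(m) && length(m$issues[[1]]) > 0) {
      for (nm in names(m$issues[[1]])) note(id, nm, m$issues[[1]][[nm]])
    }
    m
  })
  if (nrow(metrics) == 0) stop_bad_arg("no tree could be processed")

  rates <- growth_rates(metrics, records, params = config$params)
  summaries <- site_summary(rates, cohorts = config$cohorts)

  complete <- !is.na(rates$agb_mg)
  obs <- rates[complete, , drop = FALSE]

  published_predictions <- NULL
  published_eval <- NULL
  for (mid in config$published_models) {
    pred <- tryCatch(predict_allometry(obs, mid), error = function(e) {
      note("(all)", paste0("allometry_", mid), conditionMessage(e)); NULL
    })
    if (is.null(pred)) next
    published_predictions <- dplyr::bind_rows(
      published_predictions,
      pred[, c("tree_id", "model_id", "pred_volume_m3", "pred_agb_mg")])
    ev <- tryCatch(evaluate_model(pred$pred_agb_mg, obs$agb_mg), error = function(e) {
      note("(all)", paste0("evaluate_", mid), conditionMessage(e)); NULL
    })
    if (!is.null(ev)) published_eval <- dplyr::bind_rows(
      published_eval, dplyr::mutate(ev, model_id = mid, .before = 1))
  }

  uk_fits <- list()
  bootstraps <- list()
  for (form in config$uk_forms) {
    f <- tryCatch(fit_uk_model(obs, form = form), error = function(e) {
      note("(all)", paste0("uk_fit_", form), conditionMessage(e)); NULL
    })
    if (is.null(f)) next
    uk_fits[[form]] <- f
    bootstraps[[form]] <- tryCatch(
      parametric_bootstrap(f, n_boot = config$n_boot, seed = config$seed),
      error = function(e) { note("(all)", paste0("bootstrap_", form), conditionMessage(e)); NULL })
  }
  uk_summary <- purrr::map_dfr(uk_fits, glance)

  issues_tbl <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble::tibble(tree_id = character(0), stage = character(0), message = character(0))

  manifest <- list(
    package_version = as.character(utils::packageVersion("tlscarbon")),
    seed = config$seed,
    n_trees_in = length(clouds), n_trees_out = nrow(metrics),
    params = unclass(config$params),
    dbh_slice = config$dbh_slice, dtb_slice = config$dtb_slice,
    slice_height = config$slice_height, n_repeats = config$n_repeats,
    branch_allowance = config$branch_allowance, n_boot = config$n_boot,
    n_issues = nrow(issues_tbl))

  result <- structure(list(metrics = metrics, rates = rates,
                           site_summaries = summaries,
                           published_predictions = published_predictions,
                           published_eval = published_eval,
                           uk_fits = uk_fits, uk_summary = uk_summary,
                           bootstraps = bootstraps, issues = issues_tbl,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("TLS-to-carbon pipeline: %d/%d trees processed, %d issue(s) logged\n",
              x$manifest$n_trees_out, x$manifest$n_trees_in, x$manifest$n_issues))
  if (nrow(x$site_summaries) > 0) {
    cat("site summaries:\n")
    print(x$site_summaries[, c("site", "cohort", "n_trees", "mean_h_m",
                               "mean_agb_mg", "rate_agb_kg_yr")])
  }
  if (!is.null(x$uk_summary) && nrow(x$uk_summary) > 0) {
    cat("UK allometric refits:\n")
    print(x$uk_summary[, c("form", "a", "b", "r.squared", "rmse", "bias_pct")])
  }
  invisible(x)
}

#' Write pipeline outputs as CSVs plus a JSON manifest
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl) > 0)
      readr::write_csv(tbl, file.path(dir, paste0(name, ".csv")))
  }
  w(dplyr::select(result$metrics, -"issues"), "metrics")
  w(result$rates[, setdiff(names(result$rates), "issues")], "rates")
  w(result$site_summaries, "site_summaries")
  w(result$published_predictions, "published_predictions")
  w(result$published_eval, "published_eval")
  w(result$uk_summary, "uk_models")
  w(result$issues, "issues")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
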