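#' Registry of published allometric models for giant sequoia
#'
#' Five published size-to-volume/biomass models, with their printed
#' coefficients, functional forms and declared units. Forms:
#' \describe{
#'   \item{parks}{`log10(V) = a log10(DBH^2 H) - b` (DBH, H in m; V in m^3)}
#'   \item{chojnacky}{`AGB = a DTB^b + c fDBH^d` (diameters in m; AGB in Mg)}
#'   \item{jenkins}{`ln(AGB) = a + b ln(DBH)` (native calibration: DBH in cm,
#'     AGB in kg; converted to m / Mg on the way in and out)}
#'   \item{sillett2019}{`V = a DTB^b + c CV^d` (m, m^3)}
#'   \item{sillett2015}{`V = a DTB^b + c CV^d` (m, m^3)}
#' }
#' Models that predict volume are converted to AGB with the per-model
#' `density` column (0.34 Mg m^-3, the adopted whole-tree value, where the
#' source study does not print one). Unit declarations for the generalized
#' conifer models (Jenkins, Chojnacky) are documented choices, not
#' statements from the comparison study.
#'
#' @return A tibble with one row per model: `model_id`, `response`
#'   (`"volume"` or `"agb"`), coefficients `a`-`d`, `density` (Mg m^-3,
#'   used for volume-to-AGB conversion), `dbh_unit` (m or cm for the
#'   diameter the form consumes), `mass_unit` (Mg or kg for AGB forms),
#'   `predictors`.
#' @export
allometric_models <- function() {
  tibble::tribble(
    ~model_id, ~response, ~a, ~b, ~c, ~d, ~density, ~dbh_unit, ~mass_unit, ~predictors,
    "parks", "volume", 0.9246, 0.4147, NA, NA, 0.34, "m", "Mg", "DBH,H",
    "chojnacky", "agb", 3.9656e-4, 2.3122, 1.9583e-3, 1.8657, NA, "m", "Mg", "DTB,fDBH",
    "jenkins", "agb", -2.0336, 2.2592, NA, NA, NA, "cm", "kg", "DBH",
    "sillett2019", "volume", 1.1588e-3, 2.1562, 1.0898e-4, 1.4963, 0.34, "m", "Mg", "DTB,CV",
    "sillett2015", "volume", 1.95e-3, 2.1, 1.78e-4, 1.43, 0.34, "m", "Mg", "DTB,CV")
}

need_metric <- function(metrics, col, model_id) {
  if (!col %in% names(metrics) || any(is.na(metrics[[col]])))
    stop_bad_arg("model '%s' requires metric '%s', which is missing", model_id, col)
  v <- metrics[[col]]
  if (any(v <= 0))
    stop_bad_arg("model '%s': metric '%s' must be positive (domain of the form)", model_id, col)
  v
}

#' Predict volume/AGB from a published allometric model
#'
#' Evaluates the printed form of one [allometric_models()] row on a table of
#' structural metrics (columns as produced by [compute_all_metrics()]:
#' `dbh_m`, `dtb_m`, `fdbh_m`, `h_m`, `cv_m3`). Volume predictions are also
#' converted to AGB using the model's density.
#'
#' @param metrics Data frame of per-tree metrics.
#' @param model_id One of `"parks"`, `"chojnacky"`, `"jenkins"`,
#'   `"sillett2019"`, `"sillett2015"`.
#' @return `metrics` with added columns `model_id`, `pred_volume_m3` (NA for
#'   AGB-native models) and `pred_agb_mg`.
#' @export
predict_allometry <- function(metrics, model_id) {
  reg <- allometric_models()
  row <- reg[reg$model_id == model_id, ]
  if (nrow(row) != 1)
    stop_bad_arg("unknown model_id '%s' (known: %s)", model_id,
                 paste(reg$model_id, collapse = ", "))
  metrics <- tibble::as_tibble(metrics)
  vol <- rep(NA_real_, nrow(metrics))
  agb <- switch(model_id,
    parks = {
      dbh <- need_metric(metrics, "dbh_m", model_id)
      h <- need_metric(metrics, "h_m", model_id)
      vol <- 10^(row$a * log10(dbh^2 * h) - row$b)
      vol * row$density
    },
    chojnacky = {
      dtb <- need_metric(metrics, "dtb_m", model_id)
      fdbh <- need_metric(metrics, "fdbh_m", model_id)
      row$a * dtb^row$b + row$c * fdbh^row$d
    },
    jenkins = {
      dbh_cm <- 100 * need_metric(metrics, "dbh_m", model_id)
      exp(row$a + row$b * log(dbh_cm)) / 1000 # native kg -> Mg
    },
    sillett2019 = ,
    sillett2015 = {
      dtb <- need_metric(metrics, "dtb_m", model_id)
      cv <- need_metric(metrics, "cv_m3", model_id)
      vol <- row$a * dtb^row$b + row$c * cv^row$d
      vol * row$density
    })
  dplyr::mutate(metrics, model_id = model_id, pred_volume_m3 = vol, pred_agb_mg = agb)
}

uk_model_forms <- function() {
  tibble::tribble(
    ~form, ~predictor_label, ~make_x,
    "dbh_h", "DBH^2 H (m^3)", function(d) need_metric(d, "dbh_m", "dbh_h")^2 * need_metric(d, "h_m", "dbh_h"),
    "dtb_h", "DTB^2 H (m^3)", function(d) need_metric(d, "dtb_m", "dtb_h")^2 * need_metric(d, "h_m", "dtb_h"),
    "dbh_only", "DBH (m)", function(d) need_metric(d, "dbh_m", "dbh_only"),
    "h_only", "H (m)", function(d) need_metric(d, "h_m", "h_only"))
}

#' Fit a UK-style power-law allometric model
#'
#' Fits `AGB = a x^b` by nonlinear least squares in arithmetic space (no
#' log transform, hence no retransformation bias correction), where `x` is
#' `DBH^2 H`, `DTB^2 H`, `DBH` or `H` depending on `form`. Initialisation
#' is `a = mean(y)/mean(x)`, `b = 1`; Levenberg-Marquardt iterations run to
#' a 1e-12 relative tolerance (200 iteration cap). Diameters and heights
#' are in metres, AGB in Mg.
#'
#' @param data Data frame with metric columns (`dbh_m`, `dtb_m`, `h_m` as
#'   required by the form) and the observed response `agb_mg`.
#' @param form One of `"dbh_h"`, `"dtb_h"`, `"dbh_only"`, `"h_only"`.
#' @return An object of class `allom_fit`: coefficients `a`, `b`, fit
#'   statistics (`r2`, `rmse` in Mg, `bias_pct` = mean of
#'   (predicted - observed)/observed in %), the fitting data and form.
#'   Supports [tidy()], [glance()], [augment()], `predict()` and
#'   [autoplot()].
#' @export
fit_uk_model <- function(data, form = c("dbh_h", "dtb_h", "dbh_only", "h_only")) {
  form <- match.arg(form)
  data <- tibble::as_tibble(data)
  if (!"agb_mg" %in% names(data))
    stop_bad_arg("data must contain observed AGB in column 'agb_mg'")
  if (nrow(data) < 5)
    stop_bad_arg("power-law fit needs >= 5 trees, got %d", nrow(data))
  forms <- uk_model_forms()
  fr <- forms[forms$form == form, ]
  x <- fr$make_x[[1]](data)
  fit_power_law(x, data$agb_mg, form, fr$predictor_label)
}

# arithmetic-space NLS core shared by fit_uk_model() and the bootstrap
fit_power_law <- function(x, y, form, predictor_label) {
  if (any(y <= 0)) stop_bad_arg("observed AGB must be positive")
  if (length(unique(x)) < 2 || sd(x) < 1e-12 * mean(x))
    stop_bad_arg("degenerate predictor: no variance in %s", predictor_label,
                 class = "tlscarbon_degenerate")
  start <- list(a = mean(y) / mean(x), b = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) stop_bad_arg("power-law fit did not converge: %s",
                                     conditionMessage(e),
                                     class = "tlscarbon_fit_failure"))
  ab <- coef(fit)
  pred <- ab[["a"]] * x^ab[["b"]]
  res <- y - pred
  structure(list(a = ab[["a"]], b = ab[["b"]],
                 r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
                 rmse = sqrt(mean(res^2)),
                 bias_pct = mean((pred - y) / y) * 100,
                 sigma = sqrt(sum(res^2) / max(length(y) - 2, 1)),
                 form = form, predictor_label = predictor_label,
                 x = x, y = y, n = length(y)),
            class = "allom_fit")
}

#' @export
print.allom_fit <- function(x, ...) {
  cat(sprintf("power-law allometry AGB = a x^b, x = %s\n", x$predictor_label))
  cat(sprintf("  a = %.4g, b = %.4g (n = %d)\n", x$a, x$b, x$n))
  cat(sprintf("  r2 = %.3f, RMSE = %.3f Mg, bias = %.2f%%\n", x$r2, x$rmse, x$bias_pct))
  invisible(x)
}

#' @export
predict.allom_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
  else if (is.data.frame(newdata)) uk_model_forms()$make_x[[
    match(object$form, uk_model_forms()$form)]](newdata)
  else newdata
  object$a * x^object$b
}

#' @export
tidy.allom_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.allom_fit <- function(x, ...) {
  tibble::tibble(form = x$form, a = x$a, b = x$b, r.squared = x$r2,
                 rmse = x$rmse, bias_pct = x$bias_pct, sigma = x$sigma, n = x$n)
}

#' @export
augment.allom_fit <- function(x, ...) {
  xs <- x$x
  ys <- x$y
  fitted <- x$a * xs^x$b
  tibble::tibble(x = xs, observed = ys, fitted = fitted, residual = ys - fitted)
}

#' Agreement statistics between predicted and observed AGB
#'
#' Ordinary least-squares line of predicted versus observed AGB (gradient,
#' intercept, gradient standard error, r^2 of the regression) plus the
#' root-mean-square difference `RMSE = sqrt(mean((pred - obs)^2))`.
#'
#' @param predicted,observed Equal-length numeric vectors of AGB (Mg),
#'   n >= 3.
#' @return One-row tibble: `gradient`, `intercept`, `rmse`, `r2`,
#'   `std_error`, `n`.
#' @export
evaluate_model <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_bad_arg("predicted (%d) and observed (%d) differ in length",
                 length(predicted), length(observed))
  if (length(predicted) < 3)
    stop_bad_arg("model evaluation needs >= 3 trees, got %d", length(predicted))
  fit <- lm(predicted ~ observed)
  # summary.lm warns on residual-free fits (identity check); harmless here
  s <- suppressWarnings(summary(fit))
  tibble::tibble(gradient = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 rmse = sqrt(mean((predicted - observed)^2)),
                 r2 = s$r.squared,
                 std_error = s$coefficients[2, 2],
                 n = length(predicted))
}

#' Parametric bootstrap envelope for a power-law allometry
#'
#' Draws `n_boot` synthetic datasets from the fitted model plus a Gaussian
#' residual model (s.d. = residual standard deviation of the fit), refits
#' each, and summarises the refit predictions per abscissa as min/max and
#' 2.5/97.5 percentiles. Deterministic for a fixed seed; refit failures are
#' counted, not propagated.
#'
#' @param fit An `allom_fit` from [fit_uk_model()].
#' @param n_boot Number of bootstrap refits.
#' @param seed Integer seed.
#' @param grid Abscissa values for the envelope (defaults to 100 points
#'   spanning the data).
#' @return An object of class `allom_bootstrap`: tibble `envelope`
#'   (`x`, `fitted`, `ymin`, `ymax`, `q025`, `q975`), the refit coefficient
#'   draws, and `n_failed`.
#' @export
parametric_bootstrap <- function(fit, n_boot = 100L, seed = 1L, grid = NULL) {
  if (!inherits(fit, "allom_fit")) stop_bad_arg("fit must be an allom_fit")
  if (is.null(grid)) grid <- seq(min(fit$x), max(fit$x), length.out = 100)
  with_rng(seed, {
    draws <- purrr::map(seq_len(n_boot), function(i) {
      y_star <- pmax(fit$a * fit$x^fit$b + rnorm(fit$n, 0, fit$sigma), 1e-6)
      tryCatch({
        f <- fit_power_law(fit$x, y_star, fit$form, fit$predictor_label)
        c(a = f$a, b = f$b)
      }, error = function(e) NULL)
    })
    draws <- purrr::compact(draws)
    if (length(draws) == 0)
      stop_bad_arg("all %d bootstrap refits failed", n_boot,
                   class = "tlscarbon_fit_failure")
    ab <- do.call(rbind, draws)
    preds <- vapply(seq_len(nrow(ab)),
                    function(i) ab[i, "a"] * grid^ab[i, "b"],
                    numeric(length(grid)))
    preds <- matrix(preds, nrow = length(grid))
    structure(list(
      envelope = tibble::tibble(
        x = grid, fitted = fit$a * grid^fit$b,
        ymin = apply(preds, 1, min), ymax = apply(preds, 1, max),
        q025 = apply(preds, 1, quantile, probs = 0.025),
        q975 = apply(preds, 1, quantile, probs = 0.975)),
      coef_draws = tibble::as_tibble(ab),
      n_boot = n_boot, n_failed = n_boot - nrow(ab), fit = fit),
      class = "allom_bootstrap")
  })
}

#' @export
print.allom_bootstrap <- function(x, ...) {
  w <- mean(x$envelope$ymax - x$envelope$ymin)
  cat(sprintf("parametric bootstrap: %d refits (%d failed), mean min-max band width %.3f Mg\n",
              x$n_boot, x$n_failed, w))
  invisible(x)
}

#' @export
tidy.allom_bootstrap <- function(x, ...) x$envelope
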