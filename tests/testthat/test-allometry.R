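test_that("the registry evaluates its printed forms on unit inputs", {
  m <- tibble::tibble(dbh_m = 1, h_m = 1, dtb_m = 1, fdbh_m = 1, cv_m3 = 1)
  # log10(V) = a log10(DBH^2 H) - b with DBH^2 H = 1 forces V = 10^-b
  expect_equal(predict_allometry(m, "parks")$pred_volume_m3, 10^(-0.4147),
               tolerance = 1e-12)
  # ln(AGB) = a + b ln(DBH): DBH = 1 in native cm units forces AGB = e^a kg
  m_cm <- tibble::tibble(dbh_m = 0.01, h_m = 1)
  expect_equal(predict_allometry(m_cm, "jenkins")$pred_agb_mg,
               exp(-2.0336) / 1000, tolerance = 1e-12)
  # two-term power sums collapse to a + c on unit inputs
  expect_equal(predict_allometry(m, "sillett2015")$pred_volume_m3,
               1.95e-3 + 1.78e-4, tolerance = 1e-12)
  expect_equal(predict_allometry(m, "sillett2019")$pred_volume_m3,
               1.1588e-3 + 1.0898e-4, tolerance = 1e-12)
  expect_equal(predict_allometry(m, "chojnacky")$pred_agb_mg,
               3.9656e-4 + 1.9583e-3, tolerance = 1e-12)
})

test_that("prediction demands its inputs and a valid domain", {
  expect_error(predict_allometry(tibble::tibble(h_m = 10), "parks"), "dbh_m")
  expect_error(predict_allometry(tibble::tibble(dbh_m = -1, h_m = 10), "parks"),
               "positive")
  expect_error(predict_allometry(tibble::tibble(dbh_m = 1, h_m = 1), "nope"),
               "unknown model_id")
})

test_that("predictions increase in every predictor", {
  base <- tibble::tibble(dbh_m = 1.2, h_m = 30, dtb_m = 1.0, fdbh_m = 1.25, cv_m3 = 300)
  for (mid in allometric_models()$model_id) {
    p0 <- predict_allometry(base, mid)$pred_agb_mg
    for (col in c("dbh_m", "h_m", "dtb_m", "fdbh_m", "cv_m3")) {
      up <- base
      up[[col]] <- up[[col]] * 1.2
      expect_gte(predict_allometry(up, mid)$pred_agb_mg, p0)
    }
  }
})

test_that("noiseless power-law data are recovered exactly in all four forms", {
  set.seed(1)
  n <- 40
  d <- tibble::tibble(dbh_m = runif(n, 0.3, 2.3), h_m = runif(n, 10, 55))
  d$dtb_m <- 0.85 * d$dbh_m
  cases <- list(
    list(form = "dbh_h", a = 0.374, b = 0.697, x = d$dbh_m^2 * d$h_m),
    list(form = "dtb_h", a = 0.423, b = 0.750, x = d$dtb_m^2 * d$h_m),
    list(form = "dbh_only", a = 3.542, b = 1.956, x = d$dbh_m),
    list(form = "h_only", a = 0.021, b = 1.663, x = d$h_m))
  for (cs in cases) {
    dd <- dplyr::mutate(d, agb_mg = cs$a * cs$x^cs$b)
    f <- fit_uk_model(dd, form = cs$form)
    expect_equal(f$a, cs$a, tolerance = 1e-6)
    expect_equal(f$b, cs$b, tolerance = 1e-6)
    expect_equal(f$r2, 1, tolerance = 1e-9)
    expect_lt(abs(f$bias_pct), 1e-6)
  }
})

test_that("parameters are recovered within 5% median error at 5% noise, n = 97", {
  errs <- vapply(1:200, function(s) {
    set.seed(s)
    x <- runif(97, 0.3, 2.3)
    mu <- 3.542 * x^1.956
    y <- pmax(mu + rnorm(97, 0, 0.05 * mean(mu)), 1e-3)
    f <- fit_uk_model(tibble::tibble(dbh_m = x, agb_mg = y), form = "dbh_only")
    abs(f$a - 3.542) / 3.542
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("degenerate fitting inputs fail with clear errors", {
  d <- tibble::tibble(dbh_m = rep(1.1, 6), agb_mg = rnorm(6, 4, 0.1))
  expect_error(fit_uk_model(d, "dbh_only"), class = "tlscarbon_degenerate")
  expect_error(fit_uk_model(tibble::tibble(dbh_m = 1:3, agb_mg = 1:3), "dbh_only"),
               ">= 5 trees")
  expect_error(fit_uk_model(tibble::tibble(dbh_m = 1:6, agb_mg = c(-1, 2:6)), "dbh_only"),
               "positive")
})

test_that("model evaluation reproduces closed-form OLS", {
  obs <- c(1, 2, 3, 4, 5)
  ev <- evaluate_model(obs, obs)
  expect_equal(ev$gradient, 1)
  expect_equal(ev$intercept, 0, tolerance = 1e-12)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r2, 1)

  ev2 <- evaluate_model(2 * obs, obs)
  expect_equal(ev2$gradient, 2)
  expect_equal(ev2$intercept, 0, tolerance = 1e-12)
  expect_equal(ev2$r2, 1)
  expect_equal(ev2$rmse, sqrt(mean(obs^2)))

  # 10-point dataset against hand normal equations
  set.seed(3)
  o <- runif(10, 1, 20)
  p <- 1.3 * o - 0.7 + rnorm(10, 0, 0.5)
  ev3 <- evaluate_model(p, o)
  X <- cbind(1, o)
  beta <- solve(t(X) %*% X, t(X) %*% p)
  expect_equal(ev3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(ev3$gradient, beta[2], tolerance = 1e-10)
  resid <- p - X %*% beta
  s2 <- sum(resid^2) / (10 - 2)
  se_grad <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(ev3$std_error, se_grad, tolerance = 1e-10)
  expect_error(evaluate_model(1:3, 1:4), "length")
  expect_error(evaluate_model(1:2, 1:2), ">= 3")
})

test_that("the parametric bootstrap collapses at zero residual sd and is seeded", {
  set.seed(2)
  x <- runif(30, 0.3, 2.3)
  d <- tibble::tibble(dbh_m = x, agb_mg = 3.542 * x^1.956)
  f <- fit_uk_model(d, "dbh_only")
  b <- parametric_bootstrap(f, n_boot = 30, seed = 4L)
  expect_lt(max(b$envelope$ymax - b$envelope$ymin), 1e-6)

  dn <- dplyr::mutate(d, agb_mg = pmax(.data$agb_mg + rnorm(30, 0, 0.4), 0.01))
  fn <- fit_uk_model(dn, "dbh_only")
  b1 <- parametric_bootstrap(fn, n_boot = 40, seed = 4L)
  b2 <- parametric_bootstrap(fn, n_boot = 40, seed = 4L)
  expect_identical(b1$envelope, b2$envelope)
  expect_gt(mean(b1$envelope$ymax - b1$envelope$ymin), 0)
})

test_that("bootstrap envelopes narrow as the sample grows", {
  width_for_n <- function(n) {
    set.seed(10)
    x <- runif(n, 0.3, 2.3)
    y <- pmax(3.542 * x^1.956 + rnorm(n, 0, 0.5), 0.01)
    f <- fit_uk_model(tibble::tibble(dbh_m = x, agb_mg = y), "dbh_only")
    b <- parametric_bootstrap(f, n_boot = 60, seed = 1L,
                              grid = seq(0.5, 2, length.out = 25))
    mean(b$envelope$q975 - b$envelope$q025)
  }
  expect_lt(width_for_n(300), width_for_n(30))
})

test_that("tidy, glance, augment and predict behave like broom methods", {
  set.seed(5)
  x <- runif(20, 0.3, 2.3)
  f <- fit_uk_model(tibble::tibble(dbh_m = x, agb_mg = 3.5 * x^2), "dbh_only")
  expect_equal(tidy(f)$term, c("a", "b"))
  expect_equal(glance(f)$r.squared, 1, tolerance = 1e-9)
  expect_equal(nrow(augment(f)), 20)
  expect_equal(predict(f, tibble::tibble(dbh_m = 1)), f$a, tolerance = 1e-8,
               ignore_attr = TRUE)
})
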