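fit_nomogram_fixture <- function(n = 200, seed = 40) {
  set.seed(seed)
  data <- data.frame(risk = rbinom(n, 1, 0.5), age = rnorm(n, 65, 8),
                     tnm = sample(1:4, n, replace = TRUE))
  lp <- 0.9 * data$risk + 0.03 * (data$age - 65) + 0.3 * data$tnm
  tt <- rexp(n, rate = 0.0004 * exp(lp)) # days
  cens <- rexp(n, rate = 0.0002)
  list(data = data, time = pmin(tt, cens), event = as.integer(tt <= cens))
}

test_that("nomogram point geometry follows its contract", {
  fx <- fit_nomogram_fixture()
  cox <- cox_fit(fx$data, fx$time, fx$event)
  horizons <- unname(quantile(fx$time, c(0.2, 0.4, 0.6)))
  model <- fit_nomogram(cox, fx$data, horizons = horizons)
  pts <- predict(model, fx$data, type = "points")

  # every per-covariate point contribution lies in [0, 100], and the
  # dominant covariate spans the full scale over its observed range
  expect_true(all(as.matrix(pts[, model$covariates]) >= -1e-9))
  spans <- vapply(model$covariates, function(j) {
    r <- range(fx$data[[j]])
    diff(range(100 * model$coefficients[j] * (r - model$reference[j]) /
                 model$maxscale))
  }, 0)
  expect_equal(max(abs(spans)), 100, tolerance = 1e-10)

  # a single-covariate model spans exactly 0-100
  cox1 <- cox_fit(fx$data["age"], fx$time, fx$event)
  m1 <- fit_nomogram(cox1, fx$data, horizons = horizons)
  p1 <- predict(m1, data.frame(age = range(fx$data$age)), type = "points")
  expect_equal(sort(p1$total), c(0, 100), tolerance = 1e-10)

  # the linear predictor reconstructed from total points matches Cox's
  lp_cox <- as.matrix(fx$data[, names(cox$coefficients)]) %*% cox$coefficients
  expect_equal(predict(model, fx$data, type = "lp"), as.vector(lp_cox),
               tolerance = 1e-10)

  # equal total points imply equal predicted survival at every horizon
  s <- predict(model, fx$data)
  same <- which(abs(pts$total - pts$total[1]) < 1e-12)
  if (length(same) > 1) {
    expect_equal(s[same[1], ], s[same[2], ])
  }

  # minimum-risk pattern reproduces the Breslow baseline evaluated directly
  ref_row <- as.data.frame(as.list(model$reference))
  s_ref <- predict(model, ref_row, horizons = horizons)
  h0 <- vapply(horizons, function(h) {
    idx <- findInterval(h, cox$baseline$time)
    if (idx == 0) 0 else cox$baseline$cumhaz[idx]
  }, 0)
  expect_equal(as.vector(s_ref),
               exp(-h0 * exp(sum(cox$coefficients * model$reference))),
               tolerance = 1e-10)

  expect_error(fit_nomogram(cox, fx$data, horizons = max(fx$time) * 2),
               "beyond")
})

test_that("calibration bins compare predictions with the KM observation", {
  fx <- fit_nomogram_fixture(n = 300, seed = 41)
  cox <- cox_fit(fx$data, fx$time, fx$event)
  model <- fit_nomogram(cox, fx$data, horizons = quantile(fx$time, 0.5))
  t_eval <- unname(quantile(fx$time, 0.5))
  calib <- calibration_curve(model, fx$data, fx$time, fx$event, t = t_eval)
  expect_equal(nrow(calib), 3)
  expect_true(all(calib$n > 0))

  # n_bins = 1 collapses to (mean prediction, overall KM at t)
  one <- calibration_curve(model, fx$data, fx$time, fx$event, t = t_eval,
                           n_bins = 1)
  km_all <- km_estimate(fx$time, fx$event)
  expect_equal(one$observed,
               km_all$surv[findInterval(t_eval, km_all$time)],
               tolerance = 1e-12)
  expect_equal(one$predicted,
               mean(predict(model, fx$data, horizons = t_eval)[, 1]))

  # a bin of subjects all censored before t is flagged, not fabricated
  few <- fx$data[1:6, ]
  t_small <- c(10, 20, 30, 1000, 2000, 3000)
  e_small <- c(0, 0, 0, 1, 1, 1)
  cal2 <- calibration_curve(model, few, t_small, e_small, t = 500, n_bins = 1)
  # here some subjects are events, so not flagged; force the degenerate case
  cal3 <- calibration_curve(model, few[1:3, ], t_small[1:3], e_small[1:3],
                            t = 500, n_bins = 1)
  expect_true(cal3$flagged)
  expect_true(is.na(cal3$observed))
  expect_false(any(cal2$flagged))

  expect_error(
    calibration_curve(model, few, t_small, e_small, t = 500, n_bins = 50),
    "distinct")
})

test_that("nomogram-simulated data calibrate against their own fit", {
  fx <- fit_nomogram_fixture(n = 1000, seed = 42)
  cox <- cox_fit(fx$data, fx$time, fx$event)
  t_eval <- unname(quantile(fx$time[fx$event == 1], 0.5))
  model <- fit_nomogram(cox, fx$data, horizons = t_eval)

  # draw survival from the fitted model itself via inverse-transform on the
  # Breslow baseline, then check predicted-vs-KM agreement per bin
  set.seed(43)
  lp <- predict(model, fx$data, type = "lp")
  u <- runif(length(lp))
  target <- -log(u) / exp(lp)
  bl <- model$baseline
  sim_t <- vapply(target, function(tg) {
    idx <- which(bl$cumhaz >= tg)
    if (length(idx) == 0) max(bl$time) * 1.01 else bl$time[idx[1]]
  }, 0)
  sim_e <- as.integer(target <= max(bl$cumhaz))
  calib <- calibration_curve(model, fx$data, sim_t, sim_e, t = t_eval,
                             n_bins = 3)
  expect_false(any(calib$flagged))
  expect_lt(max(abs(calib$predicted - calib$observed)), 0.05)
})

test_that("bootstrap concordance is seeded, calibrated and exact in the perfect case", {
  tt <- c(10, 8, 6, 4, 2) * 30
  boot <- bootstrap_cindex(-tt, tt, rep(1, 5), B = 50, seed = 1)
  expect_equal(boot$estimate, 1)
  expect_equal(c(boot$conf_low, boot$conf_high), c(1, 1))

  sc <- small_survival_cohort(n = 150, seed = 44)
  a <- bootstrap_cindex(sc$scores, sc$time, sc$event, B = 200, seed = 9)
  b <- bootstrap_cindex(sc$scores, sc$time, sc$event, B = 200, seed = 9)
  expect_identical(a, b)
  plain <- concordance_index(sc$scores, sc$time, sc$event)
  expect_lt(abs(a$estimate - plain), 0.02)
  expect_error(bootstrap_cindex(sc$scores, sc$time, sc$event, B = 5), "B")
})
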