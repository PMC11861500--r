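test_that("Cox coefficients match a grid-search maximizer of the Efron partial likelihood", {
  # 8-subject two-group fixtures, including tied event times
  fixtures <- list(
    list(time = c(2, 4, 4, 6, 8, 10, 12, 14),
         event = c(1, 1, 1, 0, 1, 1, 0, 1),
         x = c(1, 1, 0, 1, 0, 0, 1, 0)),
    list(time = c(1, 3, 5, 5, 7, 9, 11, 13),
         event = c(1, 0, 1, 1, 1, 1, 1, 0),
         x = c(0, 1, 1, 0, 1, 0, 0, 1)),
    list(time = c(3, 3, 6, 6, 9, 9, 12, 15),
         event = c(1, 1, 1, 0, 1, 1, 1, 0),
         x = c(1, 0, 1, 1, 0, 1, 0, 0)))
  for (fx in fixtures) {
    fit <- cox_fit(data.frame(x = fx$x), fx$time, fx$event)
    oracle <- optimize(function(b) -oracle_efron_loglik(b, fx$x, fx$time,
                                                        fx$event),
                       interval = c(-8, 8), tol = 1e-10)$minimum
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
    expect_equal(unname(fit$hazard_ratio), exp(unname(fit$coefficients)))
    expect_true(all(diff(fit$baseline$cumhaz) >= 0))
  }
})

test_that("Cox fit rejects degenerate designs", {
  t8 <- c(2, 4, 6, 8, 10, 12, 14, 16)
  expect_error(cox_fit(data.frame(x = rep(1, 8)), t8, rep(1, 8)), "constant")
  expect_error(cox_fit(data.frame(x = rnorm(8)), t8, rep(0, 8)),
               "at least one event")
  # monotone likelihood: the covariate perfectly orders events before censorings
  sep <- data.frame(x = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_error(cox_fit(sep, t8, c(1, 1, 1, 1, 0, 0, 0, 0)), "separation")
})

test_that("Cox estimation is approximately unbiased on simulated PH data", {
  true_beta <- 0.7
  ests <- vapply(1:200, function(r) {
    set.seed(500 + r)
    x <- rbinom(500, 1, 0.5)
    tt <- rexp(500, rate = 0.1 * exp(true_beta * x))
    cens <- rexp(500, rate = 0.04)
    fit <- cox_fit(data.frame(x = x), pmin(tt, cens),
                   as.integer(tt <= cens))
    unname(fit$coefficients)
  }, 0)
  expect_lt(abs(mean(ests) - true_beta), 0.05)
  set.seed(501)
  x <- rbinom(500, 1, 0.5)
  tt <- rexp(500, rate = 0.1 * exp(true_beta * x))
  fit <- cox_fit(data.frame(x = x), tt, rep(1, 500))
  expect_lt(abs(unname(fit$coefficients) - true_beta) / unname(fit$se), 3)
})

test_that("univariate screen keeps nulls at the nominal rate and real effects with power", {
  set.seed(30)
  n <- 150
  tt <- rexp(n, 0.1)
  ev <- rbinom(n, 1, 0.75)
  null_pim <- matrix(rbinom(1000 * n, 1, 0.5), 1000, n,
                     dimnames = list(sprintf("p%04d", 1:1000),
                                     sprintf("s%03d", 1:n)))
  kept <- univariate_screen(null_pim, tt, ev)
  expect_lt(abs(nrow(kept) / 1000 - 0.05), 0.02)

  # a pair indicator that IS the risk factor is nearly always retained
  hits <- vapply(1:100, function(r) {
    set.seed(600 + r)
    x <- rbinom(80, 1, 0.5)
    tt <- rexp(80, rate = 0.1 * exp(1.2 * x))
    pim1 <- matrix(x, 1, 80,
                   dimnames = list("true_pair", sprintf("s%02d", 1:80)))
    nrow(univariate_screen(pim1, tt, rep(1, 80))) == 1
  }, NA)
  expect_gte(mean(hits), 0.95)

  empty <- univariate_screen(null_pim[0, , drop = FALSE], tt, ev)
  expect_equal(nrow(empty), 0)
})

test_that("penalized Cox spans the unpenalized fit and total shrinkage", {
  set.seed(31)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  beta <- c(0.8, -0.6, 0, 0)
  tt <- rexp(n, rate = 0.1 * exp(x %*% beta))
  ev <- rbinom(n, 1, 0.8)

  # penalty -> infinity zeroes everything
  inf_fit <- lasso_cox(x, tt, ev, lambda_fixed = 1e6)
  expect_length(inf_fit$coefficients, 0)

  # penalty 0 agrees with the unpenalized partial-likelihood maximizer
  zero_fit <- lasso_cox(x, tt, ev, lambda_fixed = 0)
  ref <- cox_fit(as.data.frame(x), tt, ev)
  expect_equal(unname(zero_fit$coefficients[names(ref$coefficients)]),
               unname(ref$coefficients), tolerance = 1e-4)

  # repeated CV is seeded and deterministic
  a <- lasso_cox(x, tt, ev, n_folds = 5, n_repeats = 3, seed = 77)
  b <- lasso_cox(x, tt, ev, n_folds = 5, n_repeats = 3, seed = 77)
  expect_identical(a$coefficients, b$coefficients)
  expect_identical(a$lambda, b$lambda)
  expect_error(lasso_cox(x, tt, rep(0:1, c(n - 5, 5)), n_folds = 10),
               "folds")
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  all_censored <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(all_censored$surv == 1))

  km <- km_estimate(1:4, rep(1, 4))
  s_at <- function(t) km$surv[max(findInterval(t, km$time), 1)]
  expect_equal(s_at(2.5), 0.5)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  km2 <- km_estimate(2 * (1:4), rep(1, 4))
  expect_equal(km2$surv, km$surv)
  expect_equal(km2$time, 2 * km$time)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "Negative")
})

test_that("log-rank matches hand tabulation and is null-calibrated", {
  # two identical copies of one group: no difference
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- c(1, 0, 1, 1, 1, 0, 1, 1)
  gg <- rep(c("a", "b"), each = 4)
  expect_equal(logrank_test(gg, tt, ev)$statistic, 0, tolerance = 1e-12)

  # 6-subject worked example against the explicit risk-set tabulation
  t6 <- c(1, 2, 3, 4, 5, 6)
  e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- c("a", "b", "a", "b", "a", "b")
  got <- logrank_test(g6, t6, e6)
  expect_equal(got$statistic, oracle_logrank(g6, t6, e6), tolerance = 1e-10)
  expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))

  expect_error(logrank_test(rep("a", 4), t6[1:4], e6[1:4]), "two non-empty")

  set.seed(32)
  hits <- vapply(1:2000, function(r) {
    tt <- rexp(40, 0.2)
    ev <- rbinom(40, 1, 0.8)
    gg <- rep(0:1, each = 20)
    logrank_test(gg, tt, ev)$p_value < 0.05
  }, NA)
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("time-dependent ROC reduces to the Mann-Whitney AUC without censoring", {
  set.seed(33)
  n <- 80
  scores <- rnorm(n)
  tt <- rexp(n, rate = 0.2 * exp(0.8 * scores))
  horizon <- median(tt)
  roc <- time_dependent_roc(scores, tt, rep(1, n), horizon)
  expect_equal(roc$auc, oracle_mw_auc(scores, as.integer(tt <= horizon)),
               tolerance = 1e-10)
  expect_true(all(roc$curve$sensitivity >= 0 & roc$curve$sensitivity <= 1))
  expect_true(all(roc$curve$specificity >= 0 & roc$curve$specificity <= 1))

  # AUC is invariant under increasing score transforms
  roc2 <- time_dependent_roc(exp(scores), tt, rep(1, n), horizon)
  expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)

  # perfect separation: AUC 1 and the Youden cutoff sits between the groups
  s <- c(rep(0, 5), rep(1, 5))
  tt2 <- c(rep(10, 5), rep(1, 5))
  perfect <- time_dependent_roc(s, tt2, rep(1, 10), 5)
  expect_equal(perfect$auc, 1)
  expect_gte(perfect$best_cutoff, 0)
  expect_lt(perfect$best_cutoff, 1)

  expect_error(time_dependent_roc(s, tt2, rep(1, 10), 0.5), "no cases")
  expect_error(time_dependent_roc(s, tt2, rep(1, 10), 50), "no controls")
})

test_that("concordance matches exhaustive pair enumeration", {
  # 5-subject toy with censoring and a score tie
  tt <- c(2, 4, 6, 8, 10)
  ev <- c(1, 0, 1, 1, 0)
  sc <- c(5, 4, 4, 2, 1)
  expect_equal(concordance_index(sc, tt, ev), oracle_cindex(sc, tt, ev))

  set.seed(34)
  for (r in 1:5) {
    tt <- rexp(12, 0.3)
    ev <- rbinom(12, 1, 0.6)
    sc <- sample(1:6, 12, replace = TRUE)
    if (sum(ev) == 0) next
    expect_equal(concordance_index(sc, tt, ev), oracle_cindex(sc, tt, ev))
  }

  # anti-ranked scores are perfectly concordant; random scores sit near 0.5
  tt <- rexp(500, 0.2)
  expect_equal(concordance_index(-tt, tt, rep(1, 500)), 1)
  set.seed(35)
  expect_lt(abs(concordance_index(rnorm(500), tt, rep(1, 500)) - 0.5), 0.03)
})
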