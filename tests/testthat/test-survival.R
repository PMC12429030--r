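test_that("kaplan_meier matches hand product-limit computation", {
  km <- kaplan_meier(c(5, 10), c(1, 0))
  expect_equal(km_at(km, 4.9), 1)
  expect_equal(km_at(km, 5), 0.5)
  expect_equal(km_at(km, 10), 0.5)

  none <- kaplan_meier(c(3, 8, 12), c(0, 0, 0))
  expect_true(all(none$survival == 1))

  expect_error(kaplan_meier(c(-1, 2), c(1, 0)), "negative")
})

test_that("KM invariants hold on random fixtures", {
  set.seed(401)
  for (i in 1:10) {
    n <- 60
    tm <- rexp(n, 0.1)
    ev <- rbinom(n, 1, 0.7)
    km <- kaplan_meier(tm, ev)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    # no censoring: KM equals the empirical survival function
    km2 <- kaplan_meier(tm, rep(1, n))
    emp <- vapply(km2$time, function(t) mean(tm > t), 0)
    expect_equal(km2$survival, emp, tolerance = 1e-12)
  }
})

test_that("log-rank matches the one-term hypergeometric hand computation", {
  # one event at t=5 with 2 per group at risk: O-E = 0.5, V = 0.25, chi2 = 1
  tm <- c(5, 10, 8, 9)
  ev <- c(1, 0, 0, 0)
  gr <- c("a", "a", "b", "b")
  lr <- log_rank(tm, ev, gr)
  expect_equal(lr$statistic, 1.0, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(1, 1, lower.tail = FALSE))

  # identical groups: statistic 0
  lr0 <- log_rank(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                  rep(c("x", "y"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_true(lr0$p_value >= 0 && lr0$p_value <= 1)

  # invariance under group relabeling
  set.seed(402)
  tm2 <- rexp(80)
  ev2 <- rbinom(80, 1, 0.6)
  g2 <- rep(0:1, 40)
  expect_equal(log_rank(tm2, ev2, g2)$statistic,
               log_rank(tm2, ev2, 1 - g2)$statistic)

  expect_error(log_rank(tm2, ev2, rep(1, 80)), "2 groups")
})

test_that("fit_cox equals brute-force partial-likelihood maximisation", {
  x <- c(1, 1, 1, 0, 0, 0)
  tm <- c(2, 5, 9, 3, 7, 11)
  ev <- c(1, 1, 0, 1, 1, 1)
  fit <- fit_cox(cbind(x = x), tm, ev)
  opt <- optimize(function(b) oracle_cox_plik(b, x, tm, ev),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-4)
})

test_that("fit_cox recovers and rejects as specified", {
  # null covariate at scale
  set.seed(403)
  n <- 5000
  x0 <- rnorm(n)
  tm <- rexp(n, 0.1)
  ev <- rbinom(n, 1, 0.8)
  f0 <- fit_cox(cbind(x = x0), tm, ev)
  expect_lt(abs(f0$hr$coef), 3 * f0$hr$se)

  # two-group exponential with HR 2, robust singleton sandwich
  set.seed(404)
  n <- 10000
  g <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.05 * exp(log(2) * g))
  cens <- rexp(n, 0.02)
  tm2 <- pmin(t_ev, cens)
  ev2 <- as.integer(t_ev <= cens)
  f2 <- fit_cox(cbind(g = g), tm2, ev2, cluster = seq_len(n))
  expect_lt(abs(f2$hr$coef - log(2)), 3 * f2$hr$se)

  # time rescaling leaves the estimate unchanged (no ties)
  f3 <- fit_cox(cbind(g = g), tm2 * 37.5, ev2)
  expect_equal(f3$coefficients, f2$coefficients, tolerance = 1e-8)

  expect_error(fit_cox(cbind(x = x0), tm, rep(0, n)), "zero events")
  # monotone likelihood: the treated all fail first
  xs <- rep(c(1, 0), each = 5)
  ts <- c(1:5, 11:15)
  expect_error(fit_cox(cbind(x = xs), ts, rep(1, 10)), "monotone")
})

test_that("cluster-robust variance matches the survival package's sandwich", {
  set.seed(405)
  n <- 200
  x <- rnorm(n)
  tm <- rexp(n, 0.2 * exp(0.3 * x))
  ev <- rbinom(n, 1, 0.8)
  pair <- rep(seq_len(n / 2), each = 2)
  fit <- fit_cox(cbind(x = x), tm, ev, cluster = pair)
  # independent route: coxph's own cluster() machinery
  ref <- survival::coxph(survival::Surv(tm, ev) ~ x + cluster(pair))
  expect_equal(unname(fit$robust_var[1, 1]), unname(ref$var[1, 1]),
               tolerance = 1e-6)
  # singleton clusters equal the ordinary sandwich
  fit1 <- fit_cox(cbind(x = x), tm, ev, cluster = seq_len(n))
  ref1 <- survival::coxph(survival::Surv(tm, ev) ~ x, robust = TRUE)
  expect_equal(unname(fit1$robust_var[1, 1]), unname(ref1$var[1, 1]),
               tolerance = 1e-6)
  # symmetric PSD on a multivariate fit
  X <- cbind(x = x, z = rnorm(n))
  fitm <- fit_cox(X, tm, ev, cluster = pair)
  V <- fitm$robust_var
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE)$values >= -1e-12))
  expect_error(robust_cluster_variance(fit, pair[-1]), "does not match")
})

test_that("hazard_ratio_ci applies the closed form", {
  mk <- function(b, v) structure(list(coefficients = c(x = b),
                                      var = matrix(v, 1, 1,
                                                   dimnames = list("x", "x")),
                                      robust_var = NULL),
                                 class = "survival_fit")
  z <- qnorm(0.975)
  ci <- hazard_ratio_ci(mk(log(2), 0.01))
  expect_equal(ci$hr, 2)
  expect_equal(ci$lower, exp(log(2) - z * 0.1))
  expect_equal(ci$upper, exp(log(2) + z * 0.1))

  ci0 <- hazard_ratio_ci(mk(0, 0))
  expect_equal(c(ci0$hr, ci0$lower, ci0$upper), c(1, 1, 1))

  set.seed(406)
  for (i in 1:10) {
    ci_i <- hazard_ratio_ci(mk(rnorm(1), runif(1, 0.001, 1)))
    expect_true(ci_i$lower <= ci_i$hr && ci_i$hr <= ci_i$upper)
  }
})

test_that("node_ratio computes and guards", {
  expect_equal(node_ratio(4, 10), 0.4)
  expect_equal(node_ratio(0, 5), 0)
  expect_equal(node_ratio(7, 7), 1)
  expect_error(node_ratio(0, 0), "nodes_removed = 0")
})

test_that("median follow-up has both estimators", {
  tm <- c(10, 20, 30, 40)
  ev <- c(1, 0, 1, 0)
  expect_equal(median_followup(tm, ev), 25)
  expect_true(is.finite(median_followup(tm, ev, "reverse_km")))
})
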