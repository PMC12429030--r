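test_that("generate_cohort handles degenerate sizes and probabilities", {
  expect_equal(nrow(generate_cohort(sim_config(n = 0, seed = 1))), 0L)

  cfg <- sim_config(n = 300, seed = 2,
                    procedure = list(intercept = 50, year = 0, n1 = 0, t2 = 0,
                                     grade3 = 0, er_neg = 0, bcs = 0))
  co <- generate_cohort(cfg)
  expect_true(all(co$latent_procedure == "ALND"))

  bad <- sim_config(n = 10, seed = 1)
  bad$marginals$grade <- c("1" = 0.5, "2" = 0.4, "3" = 0.3)
  expect_error(axsurv:::validate_config(bad), "sum to 1")
})

test_that("node-count calibration matches the registry anchor", {
  co <- generate_cohort(sim_config(n = 10000, seed = 11))
  alnd <- co$latent_procedure == "ALND"
  expect_lt(abs(mean(co$nodes_removed[alnd]) - 13.4), 1.0)
  expect_true(all(co$nodes_removed[!alnd] >= 1 & co$nodes_removed[!alnd] <= 5))
  expect_true(all(co$nodes_removed[alnd] >= 4 & co$nodes_removed[alnd] <= 82))
})

test_that("draw_node_counts respects supports, bands and ordering", {
  cfg <- sim_config(n = 10, seed = 1)
  set.seed(3)
  s0 <- draw_node_counts(rep("SLNB", 2000), rep(0L, 2000), cfg)
  expect_true(all(s0$nodes_removed >= 1 & s0$nodes_removed <= 5))
  expect_true(all(s0$nodes_positive == 0))

  a3 <- draw_node_counts(rep("ALND", 2000), rep(3L, 2000), cfg)
  expect_true(all(a3$nodes_removed >= 10))
  expect_true(all(a3$nodes_positive >= 10))
  expect_true(all(a3$nodes_positive <= a3$nodes_removed))

  # invariant over a large mixed draw
  proc <- sample(c("SLNB", "ALND"), 1e5, TRUE)
  ncat <- ifelse(proc == "SLNB", sample(0:1, 1e5, TRUE), sample(0:3, 1e5, TRUE))
  d <- draw_node_counts(proc, ncat, cfg)
  expect_true(all(d$nodes_positive <= d$nodes_removed))
  expect_true(all(d$nodes_removed[proc == "SLNB"] <= 5))
  expect_true(all(d$nodes_removed[proc == "ALND"] <= 82))
  expect_identical(derive_n_category(d$nodes_positive), ncat)
})

test_that("generated cohorts satisfy record invariants and the pN rule", {
  co <- generate_cohort(sim_config(n = 5000, seed = 21))
  expect_true(all(co$nodes_positive <= co$nodes_removed))
  expect_true(all(co$surv_months >= 0))
  expect_true(all(co$event %in% 0:1))
  expect_identical(derive_n_category(co$nodes_positive), co$n_category)
  expect_true(all(co$latent_procedure[co$n_category >= 2] == "ALND"))
})

test_that("same seed and config give a bitwise-identical cohort", {
  cfg <- sim_config(n = 500, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("survival generator has the stated exponential behaviour", {
  # null treatment effect with unconfounded assignment: equal event fractions
  cfg <- sim_config(n = 20000, seed = 31,
                    procedure = list(intercept = 0, year = 0, n1 = 0, t2 = 0,
                                     grade3 = 0, er_neg = 0, bcs = 0,
                                     force_alnd_n2plus = FALSE))
  cfg$hazard$alnd <- 0
  co <- generate_cohort(cfg)
  f <- tapply(co$event, co$latent_procedure, mean)
  se <- sqrt(sum(f * (1 - f) / table(co$latent_procedure)))
  expect_lt(abs(f[["ALND"]] - f[["SLNB"]]), 4 * se)

  # closed form: no censoring, all covariate effects zero -> mean = 1/baseline
  cfg0 <- sim_config(n = 20000, seed = 32)
  cfg0$hazard <- lapply(cfg0$hazard, function(x) 0)
  cfg0$hazard$baseline <- 0.01
  cfg0$censoring <- list(admin_end_year = 10000L, horizon = Inf, loss_rate = 0)
  co0 <- generate_cohort(cfg0)
  expect_true(all(co0$event == 1))
  expect_lt(abs(mean(co0$surv_months) - 100), 3 * 100 / sqrt(20000))

  # degenerate horizon: everything censored at 0
  cfgh <- sim_config(n = 100, seed = 33)
  cfgh$censoring$horizon <- 0
  coh <- generate_cohort(cfgh)
  expect_true(all(coh$surv_months == 0))
  expect_true(all(coh$event == 0))
})

test_that("planted treatment effect is recovered by adjusted Cox on latent truth", {
  cfg <- sim_config(n = 20000, seed = 41)
  cfg$hazard$alnd <- log(1.5)
  co <- generate_cohort(cfg)
  X <- cbind(alnd = as.numeric(co$latent_procedure == "ALND"),
             axsurv:::encode_mixed(co, c("age_group", "n_category"),
                                   c("year_dx", "t_category", "grade", "er",
                                     "pr", "her2", "bcs", "radiotherapy",
                                     "systemic", "months_dx_to_tx",
                                     "nodes_positive")))
  fit <- fit_cox(X, co$surv_months, co$event)
  row <- fit$hr[fit$hr$term == "alnd", ]
  expect_lt(abs(row$coef - log(1.5)), 3 * row$se)
})

test_that("inject_missingness masks at the requested rates and protects key fields", {
  co <- generate_cohort(sim_config(n = 10000, seed = 51))

  cfg0 <- sim_config(n = 1, seed = 1, missingness = list(
    list(field = "grade", rate = 0)))
  out0 <- inject_missingness(co, cfg0)
  expect_identical(out0$records, co)
  expect_false(any(out0$mask$grade))

  cfg1 <- sim_config(n = 1, seed = 1, missingness = list(
    list(field = "grade", rate = 1)))
  expect_true(all(is.na(inject_missingness(co, cfg1)$records$grade)))

  set.seed(52)
  cfg2 <- sim_config(n = 1, seed = 1, missingness = list(
    list(field = "er", rate = 0.2, mechanism = "MCAR")))
  out2 <- inject_missingness(co, cfg2)
  expect_lt(abs(mean(out2$mask$er) - 0.2), 0.01)

  set.seed(53)
  cfg3 <- sim_config(n = 1, seed = 1, missingness = list(
    list(field = "pr", rate = 0.2, mechanism = "MAR")))
  out3 <- inject_missingness(co, cfg3)
  expect_lt(abs(mean(out3$mask$pr) - 0.2), 0.015)
  # MAR tilt: oldest age group should be missing more often
  m_by_age <- tapply(out3$mask$pr, co$age_group, mean)
  expect_gt(m_by_age[[">=75"]], m_by_age[["<50"]])

  cfgp <- sim_config(n = 1, seed = 1, missingness = list(
    list(field = "nodes_removed", rate = 0.1)))
  expect_error(inject_missingness(co, cfgp), "protected")
})

test_that("cohort CSV and config round-trip", {
  co <- tiny_cohort(25)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back$nodes_removed, co$nodes_removed)
  expect_equal(back$surv_months, co$surv_months, tolerance = 1e-12)

  cfg <- sim_config(n = 123, seed = 9)
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, fy)
  cfg2 <- read_config(fy)
  expect_equal(cfg2$n, 123L)
  expect_equal(cfg2$marginals$n_category, cfg$marginals$n_category)
  expect_equal(config_hash(cfg2), config_hash(cfg))
})
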