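test_that("rule classifier reproduces the stated rules", {
  rec <- data.frame(nodes_removed = c(2, 4, 12, 7, 5),
                    n_category = c(1, 0, 0, 1, 0))
  out <- rule_classify(rec)
  expect_equal(out$label, c("SLNB", "SLNB", "ALND", "ALND", "UNKNOWN"))
  expect_equal(out$rule_fired[5], "none")
  expect_error(rule_classify(data.frame(nodes_removed = 0, n_category = 0)),
               "input error")
})

test_that("rule classifier agrees with the exhaustive brute-force oracle", {
  grid <- expand.grid(nodes_removed = 1:82, n_category = 0:3)
  got <- rule_classify(grid)$label
  want <- mapply(oracle_rule, grid$nodes_removed, grid$n_category)
  expect_identical(got, unname(want))
  # UNKNOWN iff no rule fired
  rf <- rule_classify(grid)$rule_fired
  expect_identical(rf == "none", got == "UNKNOWN")
})

test_that("build_design encodes rows as documented", {
  rec <- data.frame(nodes_removed = c(3, 15), year_dx = c(2010, 2000),
                    n_category = c(0, 2))
  X <- build_design(rec)
  expect_equal(unname(X[1, ]), c(1, 3, 0, 0, 0, 0))
  expect_equal(unname(X[2, ]), c(1, 15, -10, 0, 1, 0))
  empty <- build_design(rec[0, ])
  expect_equal(dim(empty), c(0L, 6L))
  expect_error(build_design(data.frame(nodes_removed = 1, year_dx = 2010,
                                       n_category = 7)), "input error")
})

test_that("Bayesian logistic fit recovers known coefficients under weak priors", {
  set.seed(101)
  n <- 5000
  rec <- data.frame(nodes_removed = rpois(n, 5) + 1,
                    year_dx = sample(2000:2020, n, TRUE),
                    n_category = sample(0:3, n, TRUE))
  X <- build_design(rec)
  beta <- c(-3, 0.55, -0.07, 1.2, 3, 3.5)
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  lab <- ifelse(y == 1, "ALND", "SLNB")
  weak <- prior_spec(sd = c(intercept = 10, nodes_removed = 10, year_c = 10,
                            n1 = 10, n2 = 10, n3 = 10))
  fit <- fit_bayes_logistic(rec, lab, priors = weak, seed = 7)
  pm <- colMeans(fit$draws)
  ps <- apply(fit$draws, 2, sd)
  expect_true(all(abs(pm - beta) < 3 * ps))
  # sampler health after adaptation
  expect_gt(fit$diagnostics$acceptance, 0.1)
  expect_lt(fit$diagnostics$acceptance, 0.6)
  expect_true(all(fit$diagnostics$rhat < 1.05))
})

test_that("a tiny prior sd pins the posterior at the prior mean", {
  set.seed(102)
  rec <- data.frame(nodes_removed = rpois(400, 4) + 1,
                    year_dx = sample(2005:2015, 400, TRUE),
                    n_category = sample(0:1, 400, TRUE))
  lab <- sample(c("SLNB", "ALND"), 400, TRUE)
  pr <- prior_spec(mean = c(nodes_removed = 0.42),
                   sd = c(nodes_removed = 1e-6))
  fit <- fit_bayes_logistic(rec, lab, priors = pr, method = "laplace",
                            seed = 3)
  expect_lt(abs(mean(fit$draws[, "nodes_removed"]) - 0.42), 1e-3)
})

test_that("single-class training sets are rejected", {
  rec <- data.frame(nodes_removed = c(2, 3), year_dx = c(2010, 2011),
                    n_category = c(0, 0))
  expect_error(fit_bayes_logistic(rec, c("SLNB", "SLNB"), seed = 1),
               "both SLNB and ALND")
})

test_that("posterior probability is a mean of inverse-logits with its invariants", {
  fit <- structure(list(draws = matrix(0, 100, 6,
    dimnames = list(NULL, c("intercept", "nodes_removed", "year_c",
                            "n1", "n2", "n3")))), class = "classifier_fit")
  rec <- data.frame(nodes_removed = 5, year_dx = 2012, n_category = 1)
  expect_equal(posterior_prob_alnd(fit, rec), 0.5)

  set.seed(103)
  d <- matrix(rnorm(600), 100, 6)
  d[, 2] <- abs(d[, 2]) + 0.1       # nodes_removed draws all positive
  colnames(d) <- c("intercept", "nodes_removed", "year_c", "n1", "n2", "n3")
  fit2 <- structure(list(draws = d), class = "classifier_fit")
  recAB <- data.frame(nodes_removed = c(9, 3), year_dx = c(2010, 2010),
                      n_category = c(0, 0))
  p <- posterior_prob_alnd(fit2, recAB)
  expect_gt(p[1], p[2])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("finalize_labels resolves UNKNOWNs and never touches rule labels", {
  co <- generate_cohort(sim_config(n = 4000, seed = 104))
  rl <- rule_classify(co)
  fit <- fit_bayes_logistic(co[rl$label != "UNKNOWN", ],
                            rl$label[rl$label != "UNKNOWN"],
                            method = "laplace", seed = 5)
  fin <- finalize_labels(fit, co, rl$label)
  expect_false(any(fin$final_label == "UNKNOWN"))
  keep <- rl$label != "UNKNOWN"
  expect_identical(fin$final_label[keep], rl$label[keep])
  expect_true(all(fin$final_label[co$n_category >= 2] == "ALND"))
  # deterministic given the posterior draws
  fin2 <- finalize_labels(fit, co, rl$label)
  expect_identical(fin, fin2)
  # threshold direction on synthetic probabilities
  unk <- which(rl$label == "UNKNOWN")
  if (length(unk)) {
    hi <- fin$p_alnd[unk] >= 0.5
    expect_true(all(fin$final_label[unk][hi] == "ALND"))
    expect_true(all(fin$final_label[unk][!hi] == "SLNB"))
  }
})

test_that("two-step inference reaches at least 90% accuracy on default cohorts", {
  co <- generate_cohort(sim_config(n = 10000, seed = 105))
  ex <- infer_exposure(co, seed = 105)
  expect_gte(mean(ex$labels$final_label == co$latent_procedure), 0.90)
  # quasi-separation in N2/N3 is flagged, not fatal
  expect_true(ex$fit$diagnostics$quasi_separation)
})
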