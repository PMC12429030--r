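#' Apply registry selection criteria
#'
#' Excludes records in flowchart order, attributing each exclusion to the
#' first violated criterion: (1) in-situ / microinvasive only, (2) metastatic
#' (M1), (3) T3/T4 tumours, (4) non-epithelial histology, (5) neoadjuvant
#' systemic treatment, (6) no axillary surgery (no lymph nodes removed),
#' (7) missing data on survival or on positive/removed node counts.
#'
#' @param records cohort data.frame carrying the selection flags.
#' @return list: `records` (included rows) and `report`, a `selection_report`
#'   with the per-criterion tally (`initial = included + sum(excluded)`).
#' @export
apply_selection <- function(records) {
  n0 <- nrow(records)
  crit <- list(
    tis_tmi = records$tis_flag == 1,
    m1 = records$metastatic_flag == 1,
    t3_t4 = records$t_category >= 3,
    nonepithelial = records$nonepithelial_flag == 1,
    neoadjuvant = records$neoadjuvant_flag == 1,
    no_surgery = is.na(records$nodes_removed) | records$nodes_removed == 0,
    missing_data = is.na(records$surv_months) | is.na(records$event) |
      is.na(records$nodes_positive) | is.na(records$nodes_removed)
  )
  assigned <- rep(FALSE, n0)
  counts <- integer(length(crit))
  names(counts) <- names(crit)
  for (i in seq_along(crit)) {
    hit <- crit[[i]] & !assigned
    hit[is.na(hit)] <- FALSE
    counts[i] <- sum(hit)
    assigned <- assigned | hit
  }
  report <- structure(list(initial = n0, included = n0 - sum(counts),
                           excluded = as.list(counts)),
                      class = "selection_report")
  list(records = records[!assigned, , drop = FALSE], report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection: ", x$initial, " -> ", x$included, " included (",
      x$initial - x$included, " excluded)\n", sep = "")
  for (nm in names(x$excluded))
    cat(sprintf("  %-14s %d\n", nm, x$excluded[[nm]]))
  invisible(x)
}

# covariate roles used across the pipeline
ps_factors <- c("age_group", "histology", "grade", "t_category", "n_category")
ps_numerics <- c("year_dx", "er", "pr", "her2", "systemic", "bcs",
                 "radiotherapy")
# outcome-model adjusters: ordinal T and grade enter linearly (stable when a
# level is nearly empty); age group as indicators
adj_factors <- c("age_group")
adj_numerics <- c("year_dx", "t_category", "grade", "er", "pr", "her2", "bcs",
                  "radiotherapy", "systemic", "months_dx_to_tx",
                  "nodes_positive")

encode_mixed <- function(records, factors, numerics) {
  rec <- records
  for (f in factors) rec[[f]] <- as.character(rec[[f]])
  encode_covariates(rec, c(factors, numerics))
}

#' Infer SLNB/ALND exposure labels for a cohort
#'
#' Two-step procedure: deterministic node-count rules ([rule_classify()]),
#' then a Bayesian logistic model trained on the rule-labelled subgroups to
#' resolve the remaining UNKNOWN records ([fit_bayes_logistic()],
#' [finalize_labels()]).
#'
#' @param records selected cohort.
#' @param method classifier route, "laplace" (fast, deterministic; default
#'   here) or "metropolis".
#' @param seed integer seed for the classifier.
#' @param threshold reclassification threshold on the posterior ALND
#'   probability.
#' @param priors a [prior_spec()].
#' @return list: `labels` (data.frame `rule_label, p_alnd, final_label`) and
#'   `fit` (NULL when no UNKNOWN records needed the model).
#' @export
infer_exposure <- function(records, method = "laplace", seed = 1L,
                           threshold = 0.5, priors = prior_spec()) {
  rl <- rule_classify(records)
  fit <- NULL
  if (any(rl$label == "UNKNOWN")) {
    train <- rl$label != "UNKNOWN"
    fit <- fit_bayes_logistic(records[train, , drop = FALSE],
                              rl$label[train], priors = priors,
                              method = method, seed = seed)
    fin <- finalize_labels(fit, records, rl$label, threshold)
  } else {
    fin <- data.frame(final_label = rl$label, p_alnd = NA_real_,
                      stringsAsFactors = FALSE)
  }
  labels <- data.frame(rule_label = rl$label, rule_fired = rl$rule_fired,
                       p_alnd = fin$p_alnd, final_label = fin$final_label,
                       stringsAsFactors = FALSE)
  list(labels = labels, fit = fit)
}

# propensity-matched, covariate-adjusted, pair-clustered Cox analysis of one
# pN stratum; returns NULL (with a warning) when fewer than 2 pairs form
matched_stratum_analysis <- function(records, final_label, ncat,
                                     caliper_multiplier = 0.2) {
  sub <- records[records$n_category == ncat, , drop = FALSE]
  lab <- final_label[records$n_category == ncat]
  treat <- as.numeric(lab == "ALND")
  if (length(unique(treat)) < 2L) {
    warning("stratum pN", ncat, ": only one exposure group present; skipped")
    return(NULL)
  }
  ps_covs <- c(ps_factor_cols(sub), ps_numerics)
  sub_enc <- sub
  for (f in ps_factor_cols(sub)) sub_enc[[f]] <- as.character(sub_enc[[f]])
  ps <- fit_propensity(sub_enc, treat, ps_covs)
  mc <- match_nearest(ps$scores, treat, caliper_multiplier, ids = sub$id)
  if (nrow(mc$pairs) < 2L) {
    warning("stratum pN", ncat, ": fewer than 2 matched pairs; skipped")
    return(NULL)
  }
  bal <- balance_report(mc, sub_enc, ps_covs, treat,
                        scores = ps$scores, ids = sub$id)
  rows <- match(c(mc$pairs$treated_id, mc$pairs$control_id), sub$id)
  md <- sub[rows, , drop = FALSE]
  md_treat <- rep(c(1, 0), each = nrow(mc$pairs))
  pair_id <- rep(mc$pairs$pair_id, 2)
  X <- cbind(alnd = md_treat,
             encode_mixed(md, adj_factors, adj_numerics))
  fit <- fit_cox(X, md$surv_months, md$event, cluster = pair_id)
  lr <- log_rank(md$surv_months, md$event, md_treat)
  km_a <- kaplan_meier(md$surv_months[md_treat == 1], md$event[md_treat == 1])
  km_s <- kaplan_meier(md$surv_months[md_treat == 0], md$event[md_treat == 0])
  list(stratum = paste0("pN", ncat), n = nrow(sub), pairs = nrow(mc$pairs),
       pair_table = mc$pairs,
       unmatched_treated = mc$unmatched_treated, caliper = mc$caliper,
       balance = bal, alnd_hr = fit$hr[fit$hr$term == "alnd", ],
       fit = fit, log_rank_p = lr$p_value,
       km = list(ALND = km_a, SLNB = km_s))
}

ps_factor_cols <- function(sub) {
  # the stratum variable itself is constant within a stratum and is dropped
  setdiff(ps_factors, "n_category")
}

# adjusted Cox model for the high-nodal-burden (pN2/pN3) population with the
# removed-node count and the positive-to-removed ratio as linear terms
n2n3_analysis <- function(records) {
  sub <- records[records$n_category >= 2, , drop = FALSE]
  if (nrow(sub) < 10L || sum(sub$event) < 2L) {
    warning("pN2/pN3 stratum too small; skipped")
    return(NULL)
  }
  ratio <- node_ratio(sub$nodes_positive, sub$nodes_removed)
  adj <- setdiff(adj_numerics, "nodes_positive")
  X <- cbind(nodes_removed = sub$nodes_removed, node_ratio = ratio,
             encode_mixed(sub, c(adj_factors, "n_category"), adj))
  fit <- fit_cox(X, sub$surv_months, sub$event)
  list(n = nrow(sub), events = sum(sub$event),
       table = fit$hr[fit$hr$term %in% c("nodes_removed", "node_ratio"), ],
       fit = fit)
}

#' Descriptive cohort summary by exposure group
#'
#' A compact baseline-characteristics table: counts/proportions for
#' categorical covariates, mean (sd) for continuous ones, split by label.
#'
#' @param records cohort.
#' @param label grouping vector (e.g. final labels).
#' @return data.frame.
#' @export
summarize_cohort <- function(records, label) {
  groups <- sort(unique(label))
  cat_vars <- c("age_group", "t_category", "n_category", "histology", "grade",
                "er", "pr", "her2", "bcs", "systemic", "radiotherapy")
  num_vars <- c("year_dx", "months_dx_to_tx", "nodes_removed", "nodes_positive")
  out <- list()
  for (v in cat_vars) {
    for (lev in sort(unique(records[[v]]))) {
      row <- data.frame(variable = v, level = as.character(lev),
                        stringsAsFactors = FALSE)
      for (g in groups)
        row[[g]] <- mean(records[[v]][label == g] == lev)
      out[[length(out) + 1L]] <- row
    }
  }
  for (v in num_vars) {
    row <- data.frame(variable = v, level = "mean", stringsAsFactors = FALSE)
    for (g in groups) row[[g]] <- mean(records[[v]][label == g])
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Selection, exposure inference, optional multiple imputation, per-stratum
#' (pN0, pN1) propensity matching with pair-clustered Cox models, and the
#' pN2/pN3 node-count / node-ratio models. pN2/pN3 records never enter the
#' matched strata (no SLNB exists there). Fully reproducible given the
#' configuration seed.
#'
#' @param config an [sim_config()].
#' @param records optional pre-existing cohort (defaults to simulating from
#'   `config`).
#' @param impute logical; when `TRUE` and missing values are present, runs
#'   [mice_pmm()] and pools the stratum treatment coefficients with Rubin's
#'   rules (default `FALSE`: simulated data are complete).
#' @param m,max_iter imputation settings.
#' @param classifier_method "laplace" (default) or "metropolis".
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(config, records = NULL, impute = FALSE, m = 5L,
                         max_iter = 5L, classifier_method = "laplace") {
  t0 <- Sys.time()
  if (is.null(records)) records <- generate_cohort(config)
  sel <- apply_selection(records)
  inc <- sel$records

  exposure <- infer_exposure(inc, method = classifier_method,
                             seed = config$seed)
  lab <- exposure$labels$final_label

  imputation <- NULL
  if (impute && anyNA(inc)) {
    imputation <- mice_pmm(inc, m = m, max_iter = max_iter, seed = config$seed)
  }

  analyze_once <- function(dat) {
    list(pn0 = matched_stratum_analysis(dat, lab, 0L),
         pn1 = matched_stratum_analysis(dat, lab, 1L),
         n2n3 = n2n3_analysis(dat))
  }

  if (is.null(imputation)) {
    res <- analyze_once(inc)
    pooled <- NULL
  } else {
    per_imp <- lapply(imputation$completed, analyze_once)
    res <- per_imp[[1]]
    pooled <- pool_stratum_estimates(per_imp)
  }

  strata <- list()
  for (s in c("pn0", "pn1")) {
    r <- res[[s]]
    if (is.null(r)) next
    strata[[r$stratum]] <- list(
      n = r$n, pairs = r$pairs, unmatched_treated = r$unmatched_treated,
      caliper = r$caliper, balance_pass = r$balance$pass,
      hr = r$alnd_hr$hr, ci = c(r$alnd_hr$lower, r$alnd_hr$upper),
      p_value = r$alnd_hr$p_value, log_rank_p = r$log_rank_p)
  }
  n2n3 <- if (!is.null(res$n2n3)) {
    tab <- res$n2n3$table
    list(n = res$n2n3$n, events = res$n2n3$events,
         terms = stats::setNames(
           lapply(seq_len(nrow(tab)), function(i)
             list(hr = tab$hr[i], ci = c(tab$lower[i], tab$upper[i]),
                  p_value = tab$p_value[i])),
           tab$term))
  } else NULL

  structure(list(
    seed = config$seed, config_hash = config_hash(config),
    selection = sel$report,
    exposure_counts = as.list(table(lab)),
    rule_counts = as.list(table(exposure$labels$rule_label)),
    classifier = if (!is.null(exposure$fit)) exposure$fit$diagnostics else NULL,
    summary_table = summarize_cohort(inc, lab),
    strata = strata, n2n3 = n2n3, pooled = pooled,
    imputation = if (!is.null(imputation))
      list(m = imputation$m, iterations = imputation$iterations) else NULL,
    median_followup = median_followup(inc$surv_months, inc$event),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    details = res),
    class = "pipeline_report")
}

pool_stratum_estimates <- function(per_imp) {
  out <- list()
  for (s in c("pn0", "pn1")) {
    ok <- !vapply(lapply(per_imp, `[[`, s), is.null, TRUE)
    if (!any(ok)) next
    est <- vapply(per_imp[ok], function(r) r[[s]]$alnd_hr$coef, 0)
    vr <- vapply(per_imp[ok], function(r) r[[s]]$alnd_hr$se^2, 0)
    p <- rubin_pool(est, vr)
    out[[s]] <- list(hr = exp(p$estimate),
                     ci = exp(p$estimate + c(-1, 1) * 1.96 * sqrt(p$variance)),
                     m = p$m)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("axsurv pipeline report (seed ", x$seed, ", config ",
      substr(x$config_hash, 1, 8), ")\n", sep = "")
  print(x$selection)
  cat("final labels:", paste(names(x$exposure_counts),
                             unlist(x$exposure_counts), collapse = ", "), "\n")
  cat("median follow-up:", round(x$median_followup, 1), "months\n")
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    cat(sprintf("%s: %d pairs, ALND HR %.3f (95%% CI %.3f-%.3f), balance %s\n",
                s, st$pairs, st$hr, st$ci[1], st$ci[2],
                if (st$balance_pass) "PASS" else "FAIL"))
  }
  if (!is.null(x$n2n3)) {
    for (tm in names(x$n2n3$terms)) {
      t_ <- x$n2n3$terms[[tm]]
      cat(sprintf("pN2/pN3 %s: HR %.3f (95%% CI %.3f-%.3f)\n",
                  tm, t_$hr, t_$ci[1], t_$ci[2]))
    }
  }
  invisible(x)
}

#' Serialise a pipeline report as JSON
#'
#' Deterministic, byte-identical for identical (data, config, seed).
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  x <- report[c("seed", "config_hash", "exposure_counts", "rule_counts",
                "strata", "n2n3", "median_followup")]
  x$selection <- list(initial = report$selection$initial,
                      included = report$selection$included,
                      excluded = report$selection$excluded)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Simulate-and-analyse recovery experiment
#'
#' Repeatedly simulates cohorts with a known planted effect and re-estimates
#' it with the full pipeline machinery, summarising bias and confidence
#' interval coverage. Estimands:
#' \describe{
#'   \item{alnd_pn0}{matched-cohort ALND hazard ratio in the pN0 stratum
#'     (default marginals, pN0-dominated).}
#'   \item{alnd_pn1}{matched-cohort ALND hazard ratio in an all-pN1 cohort.}
#'   \item{per_node}{per-removed-node hazard ratio in a pN2/pN3 cohort.}
#'   \item{ratio}{hazard ratio per unit positive-to-removed node ratio in a
#'     pN2/pN3 cohort.}
#' }
#' For the pN2/pN3 estimands the planted world sets the separate
#' positive-node effect to zero so that the fitted model (which carries the
#' ratio instead of the positive count) is correctly specified.
#'
#' @param effect one of the estimand names above.
#' @param true_loghr planted log hazard ratio for the named estimand.
#' @param n cohort size per seed.
#' @param seeds integer vector of seeds.
#' @param hazard named list of additional log-hazard overrides (e.g. planting
#'   both pN2/pN3 effects at once).
#' @param classifier_method passed to [infer_exposure()].
#' @return list of class `recovery_result`: `per_seed` (data.frame with
#'   seed, hr, loghr, se, lower, upper), `summary` (mean_hr, empirical_se,
#'   coverage, true_hr).
#' @export
recovery_experiment <- function(effect = c("alnd_pn0", "alnd_pn1",
                                           "per_node", "ratio"),
                                true_loghr, n, seeds, hazard = list(),
                                classifier_method = "laplace") {
  effect <- match.arg(effect)
  rows <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- recovery_config(effect, true_loghr, n, seeds[i], hazard)
    est <- recovery_estimate(effect, cfg, classifier_method)
    rows[[i]] <- data.frame(seed = seeds[i], hr = est$hr, loghr = est$coef,
                            se = est$se, lower = est$lower, upper = est$upper)
  }
  per_seed <- do.call(rbind, rows)
  true_hr <- exp(true_loghr)
  summ <- list(
    mean_hr = mean(per_seed$hr),
    empirical_se = stats::sd(per_seed$hr) / sqrt(nrow(per_seed)),
    coverage = mean(per_seed$lower <= true_hr & true_hr <= per_seed$upper),
    true_hr = true_hr, n_seeds = nrow(per_seed))
  structure(list(per_seed = per_seed, summary = summ, effect = effect),
            class = "recovery_result")
}

recovery_config <- function(effect, true_loghr, n, seed, hazard = list()) {
  cfg <- sim_config(n = n, seed = seed)
  if (effect == "alnd_pn0") {
    cfg$hazard$alnd <- true_loghr
  } else if (effect == "alnd_pn1") {
    cfg$hazard$alnd <- true_loghr
    cfg$marginals$n_category <- c("0" = 0, "1" = 1, "2" = 0, "3" = 0)
  } else {
    cfg$marginals$n_category <- c("0" = 0, "1" = 0, "2" = 0.719, "3" = 0.281)
    cfg$hazard$nodes_positive <- 0
    cfg$hazard[[if (effect == "per_node") "nodes_removed" else "node_ratio"]] <-
      true_loghr
  }
  for (nm in names(hazard)) cfg$hazard[[nm]] <- hazard[[nm]]
  cfg
}

recovery_estimate <- function(effect, cfg, classifier_method) {
  co <- generate_cohort(cfg)
  if (effect %in% c("alnd_pn0", "alnd_pn1")) {
    ex <- infer_exposure(co, method = classifier_method, seed = cfg$seed)
    ncat <- if (effect == "alnd_pn0") 0L else 1L
    res <- matched_stratum_analysis(co, ex$labels$final_label, ncat)
    if (is.null(res)) stop("stratum analysis failed in recovery run")
    res$alnd_hr
  } else {
    res <- n2n3_analysis(co)
    term <- if (effect == "per_node") "nodes_removed" else "node_ratio"
    res$table[res$table$term == term, ]
  }
}

#' @export
print.recovery_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("recovery [%s]: true HR %.3f, mean recovered %.4f (emp. SE %.4f), CI coverage %.2f over %d seeds\n",
              x$effect, s$true_hr, s$mean_hr, s$empirical_se, s$coverage,
              s$n_seeds))
  invisible(x)
}
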