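#' Derive the pathological N category from the positive-node count
#'
#' Count-based staging convention: pN0 = 0 positive nodes, pN1 = 1-3,
#' pN2 = 4-9, pN3 = 10 or more.
#'
#' @param nodes_positive integer vector of positive-node counts.
#' @return integer vector in 0:3.
#' @export
derive_n_category <- function(nodes_positive) {
  stopifnot(all(nodes_positive >= 0))
  ifelse(nodes_positive == 0L, 0L,
         ifelse(nodes_positive <= 3L, 1L,
                ifelse(nodes_positive <= 9L, 2L, 3L)))
}

#' Generate a synthetic registry-like breast-cancer cohort
#'
#' Simulates patient-level records with known ground truth: covariates drawn
#' from configured marginals, a latent axillary procedure (SLNB or ALND)
#' assigned by a logistic model in year, N category and tumour covariates,
#' node counts drawn per procedure, exponential cause-specific survival under
#' a proportional-hazards mechanism, and right-censoring by accrual-driven
#' administrative follow-up plus random loss to follow-up.
#'
#' The latent procedure column is the simulation truth that a real registry
#' would not contain; downstream procedure inference is validated against it.
#'
#' @param config an [sim_config()] object.
#' @return a `data.frame` with one row per patient and columns
#'   `id, age_group, year_dx, t_category, n_category, histology, grade,
#'   er, pr, her2, bcs, systemic, radiotherapy, months_dx_to_tx,
#'   nodes_removed, nodes_positive, latent_procedure, surv_months, event,
#'   metastatic_flag, tis_flag, neoadjuvant_flag, nonepithelial_flag`.
#' @export
#' @examples
#' co <- generate_cohort(sim_config(n = 200, seed = 42))
#' table(co$latent_procedure)
generate_cohort <- function(config) {
  validate_config(config)
  n <- config$n
  if (n == 0L) return(empty_cohort())
  set.seed(config$seed)
  m <- config$marginals

  age_group <- sample(names(m$age_group), n, TRUE, m$age_group)
  year_dx <- round(stats::rnorm(n, m$year_mean, m$year_sd))
  year_dx <- as.integer(pmin(pmax(year_dx, m$year_range[1]), m$year_range[2]))
  t_category <- as.integer(sample(names(m$t_category), n, TRUE, m$t_category))
  n_category <- as.integer(sample(names(m$n_category), n, TRUE, m$n_category))
  histology <- sample(names(m$histology), n, TRUE, m$histology)
  grade <- as.integer(sample(names(m$grade), n, TRUE, m$grade))
  er <- stats::rbinom(n, 1, m$er)
  pr <- stats::rbinom(n, 1, m$pr)
  her2 <- stats::rbinom(n, 1, m$her2)
  bcs <- stats::rbinom(n, 1, m$bcs)
  systemic <- stats::rbinom(n, 1, m$systemic)
  radiotherapy <- stats::rbinom(n, 1, m$radiotherapy)
  months_dx_to_tx <- stats::rgamma(n, shape = m$delay_shape, rate = m$delay_rate)

  # latent procedure: logistic in year, N, tumour covariates; pN2+ forced ALND
  pc <- config$procedure
  lp <- pc$intercept + pc$year * (year_dx - 2010) + pc$n1 * (n_category == 1L) +
    pc$t2 * (t_category == 2L) + pc$grade3 * (grade == 3L) +
    pc$er_neg * (er == 0L) + pc$bcs * bcs
  p_alnd <- stats::plogis(lp)
  if (isTRUE(pc$force_alnd_n2plus)) p_alnd[n_category >= 2L] <- 1
  latent_procedure <- ifelse(stats::runif(n) < p_alnd, "ALND", "SLNB")

  nc <- draw_node_counts(latent_procedure, n_category, config)

  rec <- data.frame(
    id = seq_len(n),
    age_group = age_group, year_dx = year_dx, t_category = t_category,
    n_category = n_category, histology = histology, grade = grade,
    er = er, pr = pr, her2 = her2, bcs = bcs, systemic = systemic,
    radiotherapy = radiotherapy, months_dx_to_tx = months_dx_to_tx,
    nodes_removed = nc$nodes_removed, nodes_positive = nc$nodes_positive,
    latent_procedure = latent_procedure,
    stringsAsFactors = FALSE
  )

  surv <- draw_survival_outcome(rec, config)
  rec$surv_months <- surv$surv_months
  rec$event <- surv$event

  sl <- config$selection
  rec$metastatic_flag <- stats::rbinom(n, 1, sl$m1)
  rec$tis_flag <- stats::rbinom(n, 1, sl$tis)
  rec$neoadjuvant_flag <- stats::rbinom(n, 1, sl$neoadjuvant)
  rec$nonepithelial_flag <- stats::rbinom(n, 1, sl$nonepithelial)
  if (sl$t34 > 0) {
    hit <- stats::runif(n) < sl$t34
    rec$t_category[hit] <- sample(3:4, sum(hit), TRUE)
  }
  if (sl$no_surgery > 0) {
    hit <- stats::runif(n) < sl$no_surgery
    rec$nodes_removed[hit] <- 0L
    rec$nodes_positive[hit] <- 0L
  }
  if (sl$missing_data > 0) {
    hit <- stats::runif(n) < sl$missing_data
    rec$surv_months[hit] <- NA_real_
  }
  rec
}

empty_cohort <- function() {
  data.frame(
    id = integer(), age_group = character(), year_dx = integer(),
    t_category = integer(), n_category = integer(), histology = character(),
    grade = integer(), er = integer(), pr = integer(), her2 = integer(),
    bcs = integer(), systemic = integer(), radiotherapy = integer(),
    months_dx_to_tx = numeric(), nodes_removed = integer(),
    nodes_positive = integer(), latent_procedure = character(),
    surv_months = numeric(), event = integer(), metastatic_flag = integer(),
    tis_flag = integer(), neoadjuvant_flag = integer(),
    nonepithelial_flag = integer(), stringsAsFactors = FALSE
  )
}

#' Draw removed and positive node counts for given procedures
#'
#' SLNB removes 1-5 nodes (categorical distribution); ALND removes 4-82
#' (shifted, capped negative binomial). The positive count is drawn inside
#' the band implied by the pN category (0 / 1-3 / 4-9 / 10+) and the removed
#' count is raised to the positive count when needed so that
#' `nodes_positive <= nodes_removed` always holds.
#'
#' @param procedure character vector, "SLNB" or "ALND".
#' @param n_category integer vector in 0:3.
#' @param config an [sim_config()] object.
#' @return list with integer vectors `nodes_removed`, `nodes_positive`.
#' @export
draw_node_counts <- function(procedure, n_category, config) {
  stopifnot(all(procedure %in% c("SLNB", "ALND")),
            all(n_category %in% 0:3),
            length(procedure) == length(n_category))
  n <- length(procedure)
  nd <- config$nodes
  removed <- integer(n)
  positive <- integer(n)
  if (n == 0L) return(list(nodes_removed = removed, nodes_positive = positive))

  is_slnb <- procedure == "SLNB"
  if (any(is_slnb))
    removed[is_slnb] <- sample(1:5, sum(is_slnb), TRUE, nd$slnb_removed_probs)
  if (any(!is_slnb)) {
    draw <- stats::rnbinom(sum(!is_slnb), size = nd$alnd_removed_size,
                           mu = nd$alnd_removed_mu)
    removed[!is_slnb] <- pmin(4L + draw, nd$alnd_removed_max)
  }

  i1 <- n_category == 1L
  i2 <- n_category == 2L
  i3 <- n_category == 3L
  if (any(i1)) positive[i1] <- sample(1:3, sum(i1), TRUE, nd$pn1_positive_probs)
  if (any(i2)) positive[i2] <- sample(4:9, sum(i2), TRUE, nd$pn2_positive_probs)
  if (any(i3)) {
    draw <- stats::rnbinom(sum(i3), size = nd$pn3_positive_size,
                           mu = nd$pn3_positive_mu)
    positive[i3] <- pmin(10L + draw, nd$positive_max)
  }
  removed <- pmax(removed, positive)
  removed <- pmin(removed, ifelse(is_slnb, 5L, nd$alnd_removed_max))
  positive <- pmin(positive, removed)
  list(nodes_removed = as.integer(removed), nodes_positive = as.integer(positive))
}

# log-hazard linear predictor of the outcome model (simulation truth)
survival_linear_predictor <- function(rec, hz) {
  ratio <- ifelse(rec$nodes_removed > 0, rec$nodes_positive / rec$nodes_removed, 0)
  hz$alnd * (rec$latent_procedure == "ALND") +
    hz$age_lt50 * (rec$age_group == "<50") +
    hz$age_ge75 * (rec$age_group == ">=75") +
    hz$t2 * (rec$t_category == 2L) +
    hz$grade2 * (rec$grade == 2L) + hz$grade3 * (rec$grade == 3L) +
    hz$er_pos * rec$er + hz$pr_pos * rec$pr + hz$her2_pos * rec$her2 +
    hz$bcs * rec$bcs + hz$systemic * rec$systemic +
    hz$radiotherapy * rec$radiotherapy +
    hz$year * (rec$year_dx - 2010) + hz$delay * rec$months_dx_to_tx +
    hz$nodes_positive * rec$nodes_positive +
    hz$nodes_removed * rec$nodes_removed +
    hz$node_ratio * ratio
}

#' Draw cause-specific survival outcomes under proportional hazards
#'
#' Event times are exponential with hazard `baseline * exp(linear predictor)`.
#' Censoring is the minimum of (i) administrative follow-up, i.e. months from
#' diagnosis to the configured database cut-off year (capped at the horizon),
#' and (ii) an exponential loss-to-follow-up time. `event = 1` iff the event
#' time does not exceed the censoring time; other-cause death is not modelled
#' separately, matching a cause-specific (breast-cancer death) endpoint where
#' competing deaths are censored.
#'
#' @param records data.frame of patient rows (see [generate_cohort()]).
#' @param config an [sim_config()] object.
#' @return list with `surv_months` (non-negative numeric) and `event` (0/1).
#' @export
draw_survival_outcome <- function(records, config) {
  n <- nrow(records)
  if (n == 0L) return(list(surv_months = numeric(), event = integer()))
  hz <- config$hazard
  cs <- config$censoring
  rate <- hz$baseline * exp(survival_linear_predictor(records, hz))
  t_event <- stats::rexp(n, rate)
  admin <- pmin(cs$horizon,
                pmax(0, (cs$admin_end_year - records$year_dx) * 12 +
                       stats::runif(n, 0, 12)))
  t_cens <- if (cs$loss_rate > 0) pmin(admin, stats::rexp(n, cs$loss_rate)) else admin
  surv <- pmin(t_event, t_cens)
  if (isTRUE(config$round_months)) surv <- round(surv)
  list(surv_months = surv, event = as.integer(t_event <= t_cens))
}

protected_fields <- c("id", "nodes_removed", "nodes_positive", "n_category",
                      "surv_months", "event", "latent_procedure")

#' Inject missingness into a cohort
#'
#' Masks requested fields under MCAR (uniform) or MAR (missingness probability
#' logistic in age group and diagnosis year) mechanisms. Fields that define
#' exposure or outcome (`nodes_removed`, `nodes_positive`, `n_category`,
#' `surv_months`, `event`) can never be masked: in the motivating registry
#' analysis, records missing those fields are excluded, not imputed.
#'
#' @param records cohort data.frame.
#' @param config an [sim_config()] whose `missingness` element is a list of
#'   entries `list(field =, rate =, mechanism = "MCAR"|"MAR")`.
#' @return list: `records` with `NA`s inserted, and `mask` — a logical
#'   data.frame of the same shape, `TRUE` where a value was masked.
#' @export
inject_missingness <- function(records, config) {
  spec <- config$missingness
  mask <- as.data.frame(matrix(FALSE, nrow(records), ncol(records)),
                        stringsAsFactors = FALSE)
  names(mask) <- names(records)
  for (entry in spec) {
    f <- entry$field
    rate <- entry$rate
    mech <- if (is.null(entry$mechanism)) "MCAR" else entry$mechanism
    if (f %in% protected_fields)
      stop("configuration error: field '", f, "' is protected and cannot be masked")
    if (!f %in% names(records)) stop("unknown field: ", f)
    if (rate < 0 || rate > 1) stop("configuration error: rate outside [0,1]")
    if (rate == 0 || nrow(records) == 0L) next
    p <- if (identical(mech, "MAR")) {
      # logistic tilt in age group and year, rescaled to the marginal rate
      s <- 0.5 * (records$age_group == ">=75") + 0.05 * (records$year_dx - 2010)
      pmin(1, rate * exp(s) / mean(exp(s)))
    } else rep(rate, nrow(records))
    hit <- stats::runif(nrow(records)) < p
    records[[f]][hit] <- NA
    mask[[f]] <- hit
  }
  list(records = records, mask = mask)
}

#' Write / read a cohort as CSV
#'
#' Plain CSV with the documented [generate_cohort()] header; the parallel
#' boolean mask from [inject_missingness()] uses the same layout.
#'
#' @param records cohort data.frame (or mask).
#' @param path output path.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
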