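#' Simulation configuration for registry-like breast-cancer cohorts
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' describe an analysis-ready cohort calibrated to the marginal distributions
#' of a large US registry population of non-metastatic, upfront-surgery
#' invasive breast cancer (63.6% sentinel node biopsy, 36.4% axillary
#' dissection; SLNB removes 1-5 nodes with mean 2.368, ALND removes 4-82
#' with mean 13.382). Any component can be overridden via `...` using the
#' element names documented below.
#'
#' @param n number of patients to simulate.
#' @param seed integer seed; every random draw in the generator flows from it.
#' @param ... named overrides for any top-level configuration element:
#'   \describe{
#'     \item{marginals}{list of covariate marginals (category probabilities,
#'       year mean/sd, treatment-delay gamma moments).}
#'     \item{procedure}{logit-scale coefficients of the latent
#'       procedure-assignment model (probability of ALND), plus
#'       `force_alnd_n2plus` which pins all pN2/pN3 patients to ALND.}
#'     \item{nodes}{node-count distribution parameters: categorical removed
#'       counts on 1-5 for SLNB, shifted negative-binomial on 4-82 for ALND,
#'       positive-count distributions per pN category.}
#'     \item{hazard}{`baseline` cause-specific hazard (events/month) and
#'       log-hazard coefficients, including `alnd` (treatment effect),
#'       `nodes_removed` (per removed node) and `node_ratio` (per unit of
#'       positive-to-removed ratio).}
#'     \item{censoring}{administrative end year, horizon in months, and the
#'       exponential loss-to-follow-up rate.}
#'     \item{selection}{rates of the exclusion flags (in-situ only, M1,
#'       T3/T4, non-epithelial, neoadjuvant, no axillary surgery, missing
#'       data); all zero by default, i.e. an already-selected cohort.}
#'     \item{missingness}{list of per-field missingness requests, see
#'       [inject_missingness()].}
#'     \item{round_months}{logical; round survival times to whole months to
#'       stress tie handling (default `FALSE`).}
#'   }
#' @return a list of class `axsurv_config`.
#' @export
#' @examples
#' cfg <- sim_config(n = 500, seed = 1)
#' cfg$hazard$alnd <- log(1.16)   # plant a conditional ALND effect
sim_config <- function(n = 10000L, seed = 1L, ...) {
  cfg <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    marginals = list(
      age_group = c("<50" = 0.203, "50-74" = 0.633, ">=75" = 0.164),
      year_mean = 2010.18, year_sd = 6.014,
      year_range = c(2000L, 2020L),
      t_category = c("0" = 0.001, "1" = 0.697, "2" = 0.302),
      n_category = c("0" = 0.731, "1" = 0.205, "2" = 0.046, "3" = 0.018),
      histology = c(ductal = 0.753, lobular = 0.087, mixed = 0.100,
                    other = 0.060),
      grade = c("1" = 0.251, "2" = 0.453, "3" = 0.296),
      er = 0.844, pr = 0.739, her2 = 0.130,
      bcs = 0.598, systemic = 0.698, radiotherapy = 0.526,
      # treatment delay, months: gamma matched to mean 1.002, sd 1.029
      delay_shape = (1.002 / 1.029)^2, delay_rate = 1.002 / 1.029^2
    ),
    procedure = list(
      intercept = -1.1, year = -0.13, n1 = 1.8,
      t2 = 0.7, grade3 = 0.4, er_neg = 0.3, bcs = -0.8,
      force_alnd_n2plus = TRUE
    ),
    nodes = list(
      slnb_removed_probs = c(0.33, 0.27, 0.19, 0.12, 0.09), # support 1:5
      alnd_removed_mu = 9.382, alnd_removed_size = 2.75,    # on 4 + NB
      alnd_removed_max = 82L,
      pn1_positive_probs = c(0.60, 0.25, 0.15),             # support 1:3
      pn2_positive_probs = c(0.30, 0.22, 0.16, 0.12, 0.11, 0.09), # 4:9
      pn3_positive_mu = 5, pn3_positive_size = 2,           # on 10 + NB
      positive_max = 73L
    ),
    hazard = list(
      baseline = 8e-4,           # events per month for the reference patient
      alnd = 0.15,
      age_lt50 = 0.10, age_ge75 = 0.60,
      t2 = 0.50, grade2 = 0.30, grade3 = 0.70,
      er_pos = -0.40, pr_pos = -0.20, her2_pos = 0.20,
      bcs = -0.10, systemic = -0.20, radiotherapy = -0.10,
      year = 0.0, delay = 0.0,
      nodes_positive = 0.06, nodes_removed = 0.0, node_ratio = 0.0
    ),
    censoring = list(
      admin_end_year = 2022L, horizon = 264, loss_rate = 0.004
    ),
    selection = list(
      tis = 0, m1 = 0, t34 = 0, nonepithelial = 0, neoadjuvant = 0,
      no_surgery = 0, missing_data = 0
    ),
    missingness = list(),
    round_months = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg))
      stop("unknown configuration element: ", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
        !is.null(names(dots[[nm]]))) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "axsurv_config"
  validate_config(cfg)
  cfg
}

#' Registry-style selection-flag rates
#'
#' Convenience preset switching the generator from an analysis-ready cohort to
#' a raw registry extract: roughly 30% of records violate at least one
#' selection criterion, mimicking the attrition of a typical selection
#' flowchart.
#'
#' @return named list suitable for `sim_config(selection = registry_selection_rates())`.
#' @export
registry_selection_rates <- function() {
  list(tis = 0.15, m1 = 0.03, t34 = 0.08, nonepithelial = 0.01,
       neoadjuvant = 0.04, no_surgery = 0.02, missing_data = 0.01)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "axsurv_config"))
  if (cfg$n < 0) stop("n must be non-negative")
  m <- cfg$marginals
  for (nm in c("age_group", "t_category", "n_category", "histology", "grade")) {
    p <- m[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("configuration error: marginal '", nm,
           "' must be non-negative and sum to 1")
  }
  for (nm in c("er", "pr", "her2", "bcs", "systemic", "radiotherapy")) {
    p <- m[[nm]]
    if (p < 0 || p > 1) stop("configuration error: probability '", nm,
                             "' outside [0,1]")
  }
  if (cfg$hazard$baseline <= 0) stop("configuration error: baseline hazard must be > 0")
  if (any(unlist(cfg$selection) < 0) || any(unlist(cfg$selection) > 1))
    stop("configuration error: selection rates outside [0,1]")
  nd <- cfg$nodes
  stopifnot(length(nd$slnb_removed_probs) == 5,
            length(nd$pn1_positive_probs) == 3,
            length(nd$pn2_positive_probs) == 6)
  invisible(cfg)
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip through YAML (or JSON, by file extension).
#'
#' @param cfg an `axsurv_config`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config` returns an `axsurv_config`.
#' @export
write_config <- function(cfg, path) {
  x <- rapply(unclass(cfg), how = "replace", f = function(v) {
    # yaml drops names of atomic vectors; store named vectors as maps
    if (!is.null(names(v))) as.list(v) else v
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- sim_config(n = x$n, seed = x$seed)
  for (nm in setdiff(names(x), c("n", "seed"))) {
    if (is.null(x[[nm]])) next   # e.g. an empty missingness list in YAML
    if (is.list(base[[nm]]) && !is.null(names(x[[nm]]))) {
      for (k in names(x[[nm]])) base[[nm]][[k]] <- restore_numeric(x[[nm]][[k]])
    } else {
      base[[nm]] <- restore_numeric(x[[nm]])
    }
  }
  validate_config(base)
  base
}

restore_numeric <- function(v) {
  if (is.list(v) && length(v) && all(vapply(v, is.numeric, TRUE)))
    unlist(v)
  else v
}

#' Hash a configuration for provenance
#'
#' MD5 digest of the canonical JSON serialisation; embedded in every pipeline
#' report so results can be traced back to their exact settings.
#'
#' @param cfg an `axsurv_config` (or any jsonlite-serialisable list).
#' @return character scalar, 32 hex digits.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
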