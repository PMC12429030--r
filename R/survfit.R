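#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around `survival::survfit` returning the stepwise curve as a
#' plain table. Censorings at an event time are processed after the events at
#' that time (the product-limit convention).
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("negative survival time")
  stopifnot(length(times) == length(events), all(events %in% 0:1))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, survival = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at given times
#'
#' Step-function evaluation of a [kaplan_meier()] curve; S(t) = 1 before the
#' first event.
#'
#' @param curve a `km_curve`.
#' @param at numeric times.
#' @return numeric vector of survival probabilities.
#' @export
km_at <- function(curve, at) {
  idx <- findInterval(at, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed over
#' distinct event times; p-value from a chi-square with `k - 1` degrees of
#' freedom.
#'
#' @param times,events follow-up times and 0/1 indicators.
#' @param group group labels (2 or more levels; a single level is an error).
#' @return list with `statistic`, `p_value`, `df`, `observed`, `expected`.
#' @export
log_rank <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) < 2L) stop("log-rank test requires at least 2 groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       df = df, observed = unname(sd_$obs), expected = unname(sd_$exp))
}

prepare_design <- function(design) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2, function(z) stats::sd(z) > 0)
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation (Newton-Raphson with step-halving, via
#' `survival::coxph`) with the Efron correction for tied event times by
#' default. Constant and linearly redundant design columns are dropped before
#' fitting. If `cluster` is supplied, a cluster-robust sandwich covariance
#' ([robust_cluster_variance()]) is attached and used for confidence
#' intervals. Monotone partial likelihood (an infinite coefficient) is an
#' error naming the covariate.
#'
#' @param design numeric matrix or data.frame of covariates.
#' @param times,events follow-up times and 0/1 indicators.
#' @param ties "efron" or "breslow".
#' @param cluster optional cluster ids (e.g. matched-pair ids), one per row.
#' @return object of class `survival_fit`: `coefficients`, `var`,
#'   `robust_var` (or NULL), `hr` (from [hazard_ratio_ci()]), `n`, `events`,
#'   `ties`, plus the underlying `coxph` fit.
#' @export
fit_cox <- function(design, times, events, ties = c("efron", "breslow"),
                    cluster = NULL) {
  ties <- match.arg(ties)
  if (sum(events) == 0) stop("zero events: Cox model cannot be fitted")
  X <- prepare_design(design)
  if (ncol(X) == 0L) stop("design has no non-constant columns")
  dat <- data.frame(.time = times, .event = events, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converged before", conditionMessage(w))) {
        stop("monotone partial likelihood (coefficient diverging): ",
             conditionMessage(w), call. = FALSE)
      }
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        stop("Cox model failed to converge within 100 iterations",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (any(is.na(cf))) stop("singular design: ",
                           paste(names(cf)[is.na(cf)], collapse = ", "))
  out <- structure(list(coefficients = cf, var = stats::vcov(fit),
                        robust_var = NULL, n = fit$n, events = fit$nevent,
                        ties = ties, cox = fit),
                   class = "survival_fit")
  if (!is.null(cluster)) out$robust_var <- robust_cluster_variance(out, cluster)
  out$hr <- hazard_ratio_ci(out)
  out
}

#' Cluster-robust (sandwich) covariance for a Cox fit
#'
#' Sums the dfbeta (score-times-inverse-information) residuals within each
#' cluster and returns the crossproduct — the grouped jackknife sandwich used
#' for matched-pair survival data. With every cluster a singleton it reduces
#' to the ordinary sandwich estimator.
#'
#' @param fit a [fit_cox()] result.
#' @param cluster vector of cluster ids, one per subject in the fit.
#' @return symmetric positive semidefinite covariance matrix.
#' @export
robust_cluster_variance <- function(fit, cluster) {
  if (length(cluster) != fit$n)
    stop("cluster id length (", length(cluster), ") does not match fit n (",
         fit$n, ")")
  D <- stats::residuals(fit$cox, type = "dfbeta",
                        collapse = as.character(cluster))
  D <- as.matrix(D)
  V <- crossprod(D)
  dimnames(V) <- dimnames(fit$var)
  V
}

#' Hazard ratios with Wald confidence intervals
#'
#' `HR = exp(b)`, `CI = exp(b +/- z * se)` on the log scale; the robust
#' standard error is used when a robust covariance is attached to the fit.
#'
#' @param fit a [fit_cox()] result.
#' @param level confidence level, default 0.95.
#' @return data.frame: `term`, `coef`, `hr`, `lower`, `upper`, `se`,
#'   `p_value`.
#' @export
hazard_ratio_ci <- function(fit, level = 0.95) {
  b <- fit$coefficients
  V <- if (!is.null(fit$robust_var)) fit$robust_var else fit$var
  se <- sqrt(diag(as.matrix(V)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(b), coef = unname(b), hr = unname(exp(b)),
             lower = unname(exp(b - z * se)), upper = unname(exp(b + z * se)),
             se = unname(se),
             p_value = unname(2 * stats::pnorm(-abs(b / ifelse(se > 0, se, NA)))),
             stringsAsFactors = FALSE)
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Cox fit (", x$ties, " ties): n = ", x$n, ", events = ", x$events,
      if (!is.null(x$robust_var)) ", cluster-robust variance" else "",
      "\n", sep = "")
  hr <- x$hr
  hr[, -1] <- round(hr[, -1], 4)
  print(hr)
  invisible(x)
}

#' Positive-to-removed lymph-node ratio
#'
#' A proxy for the adequacy of axillary clearance: the number of positive
#' nodes divided by the number of removed nodes, in `[0, 1]`.
#'
#' @param nodes_positive,nodes_removed integer vectors.
#' @return numeric vector in `[0, 1]`.
#' @export
#' @examples
#' node_ratio(4, 10)  # 0.4
node_ratio <- function(nodes_positive, nodes_removed) {
  if (any(nodes_removed == 0))
    stop("nodes_removed = 0: records without axillary surgery are excluded")
  stopifnot(all(nodes_removed >= 1), all(nodes_positive >= 0),
            all(nodes_positive <= nodes_removed))
  nodes_positive / nodes_removed
}

#' Median follow-up
#'
#' Default: the median of the observed times (to event or censoring).
#' `reverse_km` gives the reverse Kaplan-Meier estimate (censoring treated as
#' the event).
#'
#' @param times,events follow-up data.
#' @param method "observed" or "reverse_km".
#' @return scalar months.
#' @export
median_followup <- function(times, events, method = c("observed", "reverse_km")) {
  method <- match.arg(method)
  if (method == "observed") return(stats::median(times))
  sf <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  unname(stats::quantile(sf, probs = 0.5)$quantile)
}
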