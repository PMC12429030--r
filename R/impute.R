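#' Predictive-mean-matching draw
#'
#' Returns the observed value of one donor chosen uniformly among the `k`
#' donors whose predicted means are closest to the target's predicted mean.
#' Distance ties are broken by donor position for determinism of the candidate
#' set; the final choice among the k candidates is uniform.
#'
#' @param target_pred scalar predicted mean for the missing cell.
#' @param donor_pred numeric vector of donor predicted means.
#' @param donor_values vector of donor observed values (any type).
#' @param k number of candidate donors (>= 1).
#' @return one element of `donor_values`.
#' @export
pmm_draw <- function(target_pred, donor_pred, donor_values, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  stopifnot(length(donor_pred) == length(donor_values), length(donor_pred) >= 1L)
  d <- abs(donor_pred - target_pred)
  cand <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
  donor_values[cand[sample.int(length(cand), 1L)]]
}

# vectorised PMM over many targets: donors sorted once, candidate window of
# 2k around the insertion point, k nearest kept
pmm_match <- function(target_pred, donor_pred, donor_values, k) {
  nd <- length(donor_pred)
  k <- min(k, nd)
  o <- order(donor_pred, seq_len(nd))
  dp <- donor_pred[o]
  dv <- donor_values[o]
  if (length(target_pred) == 0L) return(dv[0])
  pos <- findInterval(target_pred, dp)
  out <- dv[rep(1L, length(target_pred))]  # placeholder of the right type
  for (i in seq_along(target_pred)) {
    lo <- max(1L, pos[i] - k + 1L)
    hi <- min(nd, pos[i] + k)
    idx <- lo:hi
    d <- abs(dp[idx] - target_pred[i])
    keep <- idx[order(d, idx)[seq_len(k)]]
    out[i] <- dv[keep[sample.int(k, 1L)]]
  }
  out
}

code_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(as.integer(factor(x, levels = sort(unique(x[!is.na(x)])))))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' A single PMM engine handles continuous, ordinal and categorical targets:
#' every variable is mapped to a numeric working score, the conditional model
#' for a target is a Bayesian linear regression on all other (currently
#' completed) variables, and each missing cell receives the *observed* value
#' of one of the `k_donors` donors with the closest predicted means
#' (approximate-Bayesian PMM: donor predictions use the least-squares
#' coefficients, target predictions use a posterior draw). Variables are
#' swept in ascending order of missingness fraction, fixed across iterations
#' and imputations.
#'
#' @param records data.frame, possibly containing `NA`s.
#' @param mask optional logical data.frame of the same shape (`TRUE` = treat
#'   as missing); defaults to `is.na(records)`.
#' @param m number of completed datasets.
#' @param max_iter chained-equation sweeps per dataset.
#' @param k_donors donor-pool size for PMM.
#' @param seed integer seed.
#' @return object of class `imputation_set`: list with `completed` (list of m
#'   data.frames), `mask`, `m`, `iterations`, `seed`.
#' @export
mice_pmm <- function(records, mask = NULL, m = 5L, max_iter = 10L,
                     k_donors = 5L, seed = 1L) {
  if (m < 1L) stop("m must be >= 1")
  if (k_donors < 1L) stop("k < 1: k_donors must be >= 1")
  if (is.null(mask)) mask <- as.data.frame(is.na(records))
  if (!identical(dim(mask), dim(records)) ||
      !identical(names(mask), names(records)))
    stop("mask/table shape mismatch")

  frac <- vapply(mask, mean, 0)
  if (any(frac == 1))
    stop("fully missing variable: ", paste(names(frac)[frac == 1], collapse = ", "))
  sweep_vars <- names(frac)[frac > 0]
  sweep_vars <- sweep_vars[order(frac[sweep_vars], sweep_vars)]

  set.seed(seed)
  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    filled <- records
    # initial fill: random observed values
    for (v in sweep_vars) {
      mis <- mask[[v]]
      obs_vals <- records[[v]][!mis]
      filled[[v]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
    }
    for (it in seq_len(max_iter)) {
      for (v in sweep_vars) {
        mis <- mask[[v]]
        others <- setdiff(names(records), v)
        Xall <- cbind(1, vapply(others, function(o) code_numeric(filled[[o]]),
                                numeric(nrow(records))))
        # drop constant predictor columns
        keep <- c(TRUE, apply(Xall[, -1, drop = FALSE], 2,
                              function(z) stats::sd(z) > 0))
        Xall <- Xall[, keep, drop = FALSE]
        yobs <- code_numeric(filled[[v]])[!mis]
        Xo <- Xall[!mis, , drop = FALSE]
        qrX <- qr(Xo)
        piv <- qrX$pivot[seq_len(qrX$rank)]
        Xo <- Xo[, piv, drop = FALSE]
        Xm <- Xall[mis, piv, drop = FALSE]
        fit <- stats::lm.fit(Xo, yobs)
        beta <- fit$coefficients
        rss <- sum(fit$residuals^2)
        df <- max(length(yobs) - length(beta), 1L)
        sigma2 <- rss / stats::rchisq(1, df)
        XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-10, ncol(Xo))))
        beta_dot <- beta + drop(chol(sigma2 * XtXinv) %*% stats::rnorm(length(beta)))
        pred_obs <- drop(Xo %*% beta)
        pred_mis <- drop(Xm %*% beta_dot)
        filled[[v]][mis] <- pmm_match(pred_mis, pred_obs,
                                      records[[v]][!mis], k_donors)
      }
    }
    completed[[imp]] <- filled
  }
  structure(list(completed = completed, mask = mask, m = m,
                 iterations = max_iter, seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("imputation_set: m =", x$m, ", iterations =", x$iterations,
      ", seed =", x$seed, "\n")
  frac <- vapply(x$mask, mean, 0)
  cat("variables imputed:", paste(names(frac)[frac > 0], collapse = ", "), "\n")
  invisible(x)
}

#' Export an imputation set
#'
#' Writes the m completed tables as CSV plus a JSON manifest with the seed,
#' m and iteration count.
#'
#' @param iset an `imputation_set`.
#' @param dir output directory (created if needed).
#' @export
write_imputation_set <- function(iset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(iset$m))
    utils::write.csv(iset$completed[[i]],
                     file.path(dir, sprintf("imputed_%02d.csv", i)),
                     row.names = FALSE)
  jsonlite::write_json(list(m = iset$m, iterations = iset$iterations,
                            seed = iset$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Rubin's rules for combining estimates across imputations
#'
#' Pooled estimate is the mean of the per-imputation estimates; total variance
#' is the mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance.
#'
#' @param estimates numeric vector (length m) or m x p matrix of estimates.
#' @param variances matching vector/matrix of within-imputation variances.
#' @return list with `estimate`, `variance`, `within`, `between`, `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1)
  if (is.vector(variances)) variances <- matrix(variances, ncol = 1)
  if (!identical(dim(estimates), dim(variances)))
    stop("length mismatch between estimates and variances")
  m <- nrow(estimates)
  if (m < 1L) stop("m must be >= 1")
  est <- colMeans(estimates)
  within <- colMeans(variances)
  between <- if (m > 1) apply(estimates, 2, stats::var) else rep(0, ncol(estimates))
  total <- within + (1 + 1 / m) * between
  list(estimate = est, variance = total, within = within, between = between,
       m = m)
}
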