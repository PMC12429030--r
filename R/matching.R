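#' Fit a propensity-score model for ALND vs SLNB
#'
#' Logistic regression of exposure on the configured covariates, fitted by
#' iteratively reweighted least squares (via `stats::glm`). Constant and
#' linearly redundant encoded columns are dropped before fitting so the model
#' is full rank. Perfect separation is an error naming the offending
#' covariate.
#'
#' @param records data.frame.
#' @param exposure 0/1 vector (1 = treated/ALND) or the name of a column.
#' @param covariates character vector of column names; factors/characters are
#'   expanded to indicator columns.
#' @return object of class `propensity_fit`: `coefficients`, `scores`
#'   (fitted probabilities, strictly inside (0,1)), `logit_scores`,
#'   `converged`, `covariates`, `dropped`.
#' @export
fit_propensity <- function(records, exposure, covariates) {
  y <- if (is.character(exposure) && length(exposure) == 1L)
    records[[exposure]] else exposure
  if (is.character(y)) y <- as.numeric(y == "ALND")
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both exposure groups must be present")

  X <- encode_covariates(records, covariates)
  keep <- apply(X, 2, function(z) stats::sd(z) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    red <- qrX$pivot[-seq_len(qrX$rank)] - 1L
    dropped <- c(dropped, colnames(X)[red])
    X <- X[, -red, drop = FALSE]
  }

  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  p <- stats::fitted(fit)
  eps <- 1e-12
  if (any(p < eps | p > 1 - eps) && any(abs(stats::coef(fit)[-1]) > 12)) {
    cf <- stats::coef(fit)[-1]
    worst <- names(cf)[which.max(abs(cf))]
    stop("perfect separation detected in propensity model; separating covariate: ",
         worst)
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  structure(list(coefficients = stats::coef(fit), scores = unname(p),
                 logit_scores = unname(stats::qlogis(p)),
                 converged = fit$converged, covariates = covariates,
                 dropped = dropped, glm = fit),
            class = "propensity_fit")
}

# expand covariates into a numeric matrix: binaries/numerics as-is, factors
# and characters into one indicator column per non-reference level
encode_covariates <- function(records, covariates) {
  cols <- list()
  for (v in covariates) {
    x <- records[[v]]
    if (is.null(x)) stop("unknown covariate: ", v)
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      lev <- sort(unique(x))
      for (l in lev[-1]) cols[[paste0(v, ".", l)]] <- as.numeric(x == l)
      if (length(lev) == 1L) cols[[paste0(v, ".", lev)]] <- as.numeric(x == lev)
    }
  }
  do.call(cbind, cols)
}

#' 1:1 nearest-neighbour caliper matching without replacement
#'
#' The caliper is `caliper_multiplier` times the standard deviation of the
#' logit propensity score (pooled over both groups by default). Treated
#' subjects are processed in ascending propensity-score order by default;
#' each is paired with the still-unmatched control whose logit score is
#' nearest, provided the absolute logit difference is within the caliper;
#' ties between an equally distant left and right control are broken by the
#' lower record id. Treated subjects with no eligible control are dropped and
#' counted.
#'
#' Ascending order processes the common-support region first, so when treated
#' subjects outnumber controls the caliper discards the non-overlapping
#' treated tail rather than forcing it onto the control pool; descending
#' ("hardest-first") order is available but systematically retains the wrong
#' treated subset in that regime and can leave residual imbalance on the
#' strongest covariate.
#'
#' @param scores propensity scores in (0,1) for all records.
#' @param exposure 0/1 vector, 1 = treated.
#' @param caliper_multiplier width multiplier, default 0.2.
#' @param caliper_sd "pooled" (default) or "treated": which scores define the
#'   SD of the logit.
#' @param treated_order "ascending" (default) or "descending" processing
#'   order by propensity score.
#' @param ids optional record ids (default `seq_along(scores)`).
#' @return object of class `matched_cohort`: `pairs` (data.frame
#'   `treated_id, control_id, pair_id, distance`), `caliper`,
#'   `unmatched_treated`, `n_treated`, `n_control`.
#' @export
match_nearest <- function(scores, exposure, caliper_multiplier = 0.2,
                          caliper_sd = c("pooled", "treated"),
                          treated_order = c("closest", "ascending",
                                            "descending"),
                          ids = NULL) {
  caliper_sd <- match.arg(caliper_sd)
  treated_order <- match.arg(treated_order)
  stopifnot(length(scores) == length(exposure))
  if (is.null(ids)) ids <- seq_along(scores)
  y <- as.numeric(exposure)
  if (!any(y == 0)) stop("no controls available for matching")
  if (!any(y == 1)) stop("no treated records to match")
  lg <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  sd_ref <- if (caliper_sd == "pooled") stats::sd(lg) else stats::sd(lg[y == 1])
  if (!is.finite(sd_ref)) sd_ref <- 0
  caliper <- caliper_multiplier * sd_ref

  t_idx <- which(y == 1)
  c_idx <- which(y == 0)
  # deterministic processing order by score, ties by ascending id ("closest"
  # uses this only as its tie-break ordering)
  t_idx <- if (treated_order == "descending")
    t_idx[order(-scores[t_idx], ids[t_idx])]
  else t_idx[order(scores[t_idx], ids[t_idx])]
  # controls sorted by logit score, ties by id
  c_ord <- c_idx[order(lg[c_idx], ids[c_idx])]
  cl <- lg[c_ord]
  cid <- ids[c_ord]
  nc <- length(c_ord)
  # union-find style "next available" pointers with path compression
  nxt <- seq_len(nc + 1L)          # next available at or after i
  prv <- seq_len(nc)               # previous available at or before i

  find_right <- function(i) {
    j <- i
    while (j <= nc && nxt[j] != j) j <- nxt[j]
    # path compression
    while (i <= nc && nxt[i] != i) {
      k <- nxt[i]
      nxt[i] <<- j
      i <- k
    }
    j
  }
  find_left <- function(i) {
    j <- i
    while (j >= 1L && prv[j] != j) j <- prv[j]
    while (i >= 1L && prv[i] != i) {
      k <- prv[i]
      prv[i] <<- j
      i <- k
    }
    j
  }

  nearest <- function(tl) {
    # nearest still-available control to logit value tl; ties -> lower id
    pos <- findInterval(tl, cl)          # last control with logit <= tl
    left <- if (pos >= 1L) find_left(pos) else 0L
    right <- find_right(pos + 1L)
    dl <- if (left >= 1L) tl - cl[left] else Inf
    dr <- if (right <= nc) cl[right] - tl else Inf
    pick <- if (dl < dr) left
    else if (dr < dl) right
    else if (is.finite(dl)) (if (cid[left] <= cid[right]) left else right)
    else 0L
    list(pick = pick, d = min(dl, dr))
  }
  take <- function(pick) {
    nxt[pick] <<- pick + 1L
    prv[pick] <<- pick - 1L
  }

  nt <- length(t_idx)
  pairs_t <- integer(0)
  pairs_c <- integer(0)
  dist <- numeric(0)
  unmatched <- 0L
  if (treated_order == "closest") {
    # closest-pair-first greedy with lazy distance invalidation: distances to
    # a taken control can only grow, so a popped minimum is either current
    # (match it) or stale (refresh and re-queue)
    d <- numeric(nt)
    for (k in seq_len(nt)) d[k] <- nearest(lg[t_idx[k]])$d
    matched_t <- 0L
    while (TRUE) {
      k <- which.min(d)
      if (!is.finite(d[k]) || d[k] > caliper) break
      nb <- nearest(lg[t_idx[k]])
      if (nb$d > d[k] + 1e-15) {
        d[k] <- nb$d           # stale entry; refresh
        next
      }
      pairs_t <- c(pairs_t, ids[t_idx[k]])
      pairs_c <- c(pairs_c, cid[nb$pick])
      dist <- c(dist, nb$d)
      take(nb$pick)
      d[k] <- Inf
      matched_t <- matched_t + 1L
    }
    unmatched <- nt - matched_t
  } else {
    for (ti in t_idx) {
      nb <- nearest(lg[ti])
      if (nb$pick == 0L || nb$d > caliper) {
        unmatched <- unmatched + 1L
        next
      }
      pairs_t <- c(pairs_t, ids[ti])
      pairs_c <- c(pairs_c, cid[nb$pick])
      dist <- c(dist, nb$d)
      take(nb$pick)
    }
  }
  pairs <- data.frame(treated_id = pairs_t, control_id = pairs_c,
                      pair_id = seq_along(pairs_t), distance = dist)
  structure(list(pairs = pairs, caliper = caliper,
                 unmatched_treated = unmatched,
                 n_treated = sum(y == 1), n_control = sum(y == 0)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort:", nrow(x$pairs), "pairs,", x$unmatched_treated,
      "unmatched treated, caliper =", signif(x$caliper, 4), "(logit scale)\n")
  invisible(x)
}

#' Standardized mean difference
#'
#' Continuous: `|mean_t - mean_c| / sqrt((var_t + var_c)/2)`. Binary:
#' `|p_t - p_c| / sqrt((p_t(1-p_t) + p_c(1-p_c))/2)`. Returns 0 when both the
#' numerator and denominator are 0 (e.g. a covariate constant and equal in
#' both groups).
#'
#' @param values_treated,values_control numeric vectors.
#' @param kind "continuous" or "binary".
#' @return non-negative scalar.
#' @export
standardized_mean_difference <- function(values_treated, values_control,
                                         kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (length(values_treated) == 0L || length(values_control) == 0L)
    stop("empty group in SMD computation")
  if (kind == "binary") {
    pt <- mean(values_treated)
    pc <- mean(values_control)
    num <- abs(pt - pc)
    den <- sqrt((pt * (1 - pt) + pc * (1 - pc)) / 2)
  } else {
    num <- abs(mean(values_treated) - mean(values_control))
    den <- sqrt((stats::var(values_treated) + stats::var(values_control)) / 2)
    if (length(values_treated) == 1L || length(values_control) == 1L)
      den <- if (is.na(den)) 0 else den
  }
  if (num == 0 && (den == 0 || is.na(den))) return(0)
  num / den
}

#' Covariate balance before and after matching
#'
#' SMD per encoded covariate column, pre-match (all treated vs all controls)
#' and post-match (matched treated vs matched controls), plus a common-support
#' summary of the propensity-score ranges. The cohort passes iff every
#' post-match SMD is at most 0.1.
#'
#' @param matched a [match_nearest()] result.
#' @param records the full data.frame used for matching (with ids as row ids).
#' @param covariates covariate names to audit.
#' @param exposure 0/1 vector aligned with `records`.
#' @param scores optional propensity scores for the common-support summary.
#' @param ids optional record ids aligned with `records`.
#' @return list of class `balance_report`: `table` (covariate, smd_pre,
#'   smd_post), `pass`, `failing`, `common_support`.
#' @export
balance_report <- function(matched, records, covariates, exposure,
                           scores = NULL, ids = NULL) {
  if (nrow(matched$pairs) == 0L) stop("empty matched set")
  if (is.null(ids)) ids <- seq_len(nrow(records))
  y <- as.numeric(exposure)
  X <- encode_covariates(records, covariates)
  rows_t <- match(matched$pairs$treated_id, ids)
  rows_c <- match(matched$pairs$control_id, ids)

  one <- function(j, rt, rc) {
    x <- X[, j]
    kind <- if (all(x %in% c(0, 1))) "binary" else "continuous"
    standardized_mean_difference(x[rt], x[rc], kind)
  }
  pre <- vapply(seq_len(ncol(X)), one, 0, rt = which(y == 1), rc = which(y == 0))
  post <- vapply(seq_len(ncol(X)), one, 0, rt = rows_t, rc = rows_c)
  tab <- data.frame(covariate = colnames(X), smd_pre = pre, smd_post = post,
                    stringsAsFactors = FALSE)
  pass <- all(tab$smd_post <= 0.1)
  cs <- if (!is.null(scores)) {
    rt <- range(scores[y == 1])
    rc <- range(scores[y == 0])
    list(treated_range = rt, control_range = rc,
         overlap = c(max(rt[1], rc[1]), min(rt[2], rc[2])))
  } else NULL
  structure(list(table = tab, pass = pass,
                 failing = tab$covariate[tab$smd_post > 0.1],
                 common_support = cs),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  print(transform(x$table, smd_pre = round(smd_pre, 3),
                  smd_post = round(smd_post, 3)))
  cat(if (x$pass) "balance PASS (all post-match SMD <= 0.1)\n"
      else paste("balance FAIL:", paste(x$failing, collapse = ", "), "\n"))
  invisible(x)
}

#' Love-plot-ready long-format balance table
#'
#' @param report a [balance_report()].
#' @return data.frame with columns `covariate`, `stage` ("pre"/"post"), `smd`.
#' @export
balance_long <- function(report) {
  tab <- report$table
  data.frame(covariate = rep(tab$covariate, 2),
             stage = rep(c("pre", "post"), each = nrow(tab)),
             smd = c(tab$smd_pre, tab$smd_post),
             stringsAsFactors = FALSE)
}
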