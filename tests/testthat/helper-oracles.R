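# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / direct transcription, separate from the package
# code paths they check.

# direct transcription of the procedure rules, scalar, nested ifs
oracle_rule <- function(removed, ncat) {
  if (removed >= 10) return("ALND")
  if (removed >= 7 && ncat >= 1) return("ALND")
  if (ncat >= 2) return("ALND")
  if (removed >= 1 && removed <= 3) return("SLNB")
  if (removed <= 4 && ncat == 0) return("SLNB")
  "UNKNOWN"
}

# plain Newton-Raphson for unpenalised logistic regression
oracle_logistic_newton <- function(X, y, iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    W <- p * (1 - p)
    b <- b + solve(crossprod(X * W, X), crossprod(X, y - p))
  }
  drop(b)
}

# Cox partial log-likelihood, single covariate, assuming no tied event times
oracle_cox_plik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# tiny deterministic cohort fixture with every analysis column populated
tiny_cohort <- function(n = 40, seed = 99) {
  generate_cohort(sim_config(n = n, seed = seed))
}
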