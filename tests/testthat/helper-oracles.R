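# Independent oracles used across the suite.  These deliberately avoid
# the code paths (and packages) they validate: the Cox oracle maximizes
# the written-out partial likelihood by golden-section search, the
# log-rank oracle tallies hypergeometric moments risk set by risk set,
# and the BH oracle is the literal step-up definition.

# Log partial likelihood for a single binary covariate, Breslow form
# (identical to Efron when event times are untied).
oracle_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid + refinement maximizer of the partial likelihood.
oracle_cox_beta <- function(time, event, x, lower = -10, upper = 10) {
  stats::optimize(function(b) oracle_log_partial_lik(b, time, event, x),
                  interval = c(lower, upper), maximum = TRUE,
                  tol = 1e-9)$maximum
}

# Two-group log-rank by direct tally of observed vs hypergeometric
# expected events in group 1 at each distinct event time.
oracle_logrank_chisq <- function(time, event, x) {
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & x == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & x == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Literal BH step-up: sort ascending, q_i = min_{j>=i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Random small no-tie survival instance with events in both groups.
random_no_tie_instance <- function(n) {
  repeat {
    time <- sort(sample(seq(1, 100), n))  # distinct times
    event <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    if (sum(event) >= 2 && length(unique(x)) == 2 &&
        length(unique(x[event == 1])) == 2)
      return(list(time = as.numeric(time), event = event, x = x))
  }
}

# Tiny expression matrix with given values.
make_expr <- function(values, label = "DS1", scale = "raw_counts") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  expr_matrix(values, dataset_label = label, scale = scale)
}

# Survival table from vectors with auto ids.
make_surv <- function(time, event, endpoint = "OS",
                      ids = sprintf("S%03d", seq_along(time))) {
  survival_table(ids, time, event, endpoint = endpoint)
}
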