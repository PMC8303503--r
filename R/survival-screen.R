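#' Screen configuration
#'
#' Settings shared by the per-feature survival screen and the
#' differential selection step.
#'
#' @param alpha dual p-value threshold: a feature is differential only
#'   when both its log-rank and Wald p-values fall strictly below
#'   `alpha` (default 0.05).
#' @param low_pct,high_pct percentile cut points defining the low and
#'   high expression groups (defaults 33 and 66; the middle tertile is
#'   discarded).
#' @param min_group_size smallest usable group; features splitting into
#'   smaller groups are skipped, not errored (default 2).
#' @param tie_method Cox partial-likelihood tie handling, `"efron"`
#'   (default) or `"breslow"`.
#' @return A `screen_config` list.
#' @export
screen_config <- function(alpha = 0.05, low_pct = 33, high_pct = 66,
                          min_group_size = 2L,
                          tie_method = c("efron", "breslow")) {
  tie_method <- match.arg(tie_method)
  stopifnot(alpha > 0, alpha < 1,
            low_pct >= 0, high_pct <= 100, low_pct < high_pct,
            min_group_size >= 1)
  structure(list(alpha = alpha, low_pct = low_pct, high_pct = high_pct,
                 min_group_size = as.integer(min_group_size),
                 tie_method = tie_method),
            class = "screen_config")
}

#' Tertile split of a feature's per-sample values
#'
#' Samples strictly above the `high_pct` percentile form the high group,
#' samples strictly below the `low_pct` percentile the low group; the
#' middle third is discarded.  Percentiles use linear interpolation of
#' order statistics (index `(n - 1) * q / 100`, R's default type 7).
#' Strict inequalities mean a constant vector yields two empty groups,
#' flagged degenerate.
#'
#' @param values named numeric vector (names = sample ids), >= 3 finite
#'   values.
#' @param config a [screen_config()].
#' @return List with `high`, `low` (character vectors of sample ids),
#'   `p33`, `p66` (the two cut points) and `degenerate` flag.
#' @export
tertile_split <- function(values, config = screen_config()) {
  if (is.null(names(values))) stop("'values' must be named by sample id")
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("tertile split needs >= 3 finite values")
  qs <- quantile(values, c(config$low_pct, config$high_pct) / 100,
                 type = 7, names = FALSE)
  high <- names(values)[values > qs[2L]]
  low <- names(values)[values < qs[1L]]
  list(high = high, low = low, p33 = qs[1L], p66 = qs[2L],
       degenerate = length(high) == 0L && length(low) == 0L)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each distinct
#' event time the observed events in group 1 are compared with their
#' hypergeometric expectation given the risk sets, and the statistic
#' `(sum O - sum E)^2 / sum V` is referred to a chi-square with 1 df.
#' The statistic is invariant to swapping the group labels.
#'
#' @param groups binary (0/1 or logical) group membership, either
#'   aligned with the rows of `surv` or named by sample id.
#' @param surv a [survival_table()].
#' @return List with `chisq`, `p`, and `n_events`; `p` is `NA` with a
#'   `degenerate` flag when no events are present.
#' @export
logrank_test <- function(groups, surv) {
  stopifnot(inherits(surv, "survival_table"))
  g <- align_groups(groups, surv)
  if (length(unique(g)) < 2L) stop("both groups must be non-empty")
  n_events <- sum(surv$event)
  if (n_events == 0L)
    return(list(chisq = NA_real_, p = NA_real_, n_events = 0L,
                degenerate = TRUE))
  sd <- survival::survdiff(Surv(surv$time, surv$event) ~ g, rho = 0)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       n_events = as.integer(n_events), degenerate = FALSE)
}

#' Two-group Cox proportional hazards fit
#'
#' Fits the Cox partial likelihood for a single binary covariate (high
#' group = 1, low group = 0), maximized by Newton-Raphson with Efron
#' handling of tied event times by default.  `beta` is the log hazard
#' ratio of high vs low; the Wald p-value is the two-sided normal test
#' of `beta / se`.  Monotone-likelihood cases (all events in one group,
#' where the maximizer runs to infinity) are flagged `converged = FALSE`
#' with an `NA` beta rather than returning an infinite estimate.
#'
#' @inheritParams logrank_test
#' @param tie_method `"efron"` or `"breslow"`.
#' @return List with `beta`, `hr = exp(beta)`, `se`, `wald_p`,
#'   `n_events`, `converged`.
#' @export
cox_binary_fit <- function(groups, surv, tie_method = c("efron", "breslow")) {
  stopifnot(inherits(surv, "survival_table"))
  tie_method <- match.arg(tie_method)
  g <- align_groups(groups, surv)
  if (length(unique(g)) < 2L) stop("both groups must be non-empty")
  n_events <- sum(surv$event)
  if (n_events == 0L) stop("no events: Cox fit undefined")
  bad <- list(beta = NA_real_, hr = NA_real_, se = NA_real_,
              wald_p = NA_real_, n_events = as.integer(n_events),
              converged = FALSE)
  # all events on one side => the partial likelihood is monotone in beta
  if (length(unique(g[surv$event == 1])) < 2L) return(bad)
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(matrix(as.double(g), ncol = 1L),
                          Surv(surv$time, surv$event),
                          strata = NULL, offset = NULL, init = 0,
                          control = survival::coxph.control(iter.max = 50),
                          weights = NULL, method = tie_method,
                          rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  beta <- unname(fit$coefficients)
  se <- sqrt(fit$var[1L, 1L])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) return(bad)
  list(beta = beta, hr = exp(beta), se = se,
       wald_p = 2 * pnorm(-abs(beta / se)),
       n_events = as.integer(n_events), converged = TRUE)
}

# Coerce group labels to a 0/1 vector aligned with surv rows.
align_groups <- function(groups, surv) {
  if (!is.null(names(groups))) {
    idx <- match(surv$sample_id, names(groups))
    if (anyNA(idx)) stop("group labels missing for some survival samples")
    groups <- groups[idx]
  } else if (length(groups) != nrow(surv)) {
    stop("'groups' must be named or match the survival table length")
  }
  g <- as.integer(as.logical(groups))
  if (anyNA(g)) stop("group labels must be binary")
  g
}

#' Kaplan-Meier product-limit estimate
#'
#' Records censored exactly at an event time are counted at risk for
#' that time (the standard convention).  With no censoring the curve
#' equals the empirical survival function.
#'
#' @param surv a [survival_table()] with >= 1 record.
#' @return A `km_curve`: data frame with columns `time` (distinct
#'   observed times, ascending), `n_risk`, `n_event`, `n_censor`,
#'   `surv`.
#' @export
km_estimate <- function(surv) {
  stopifnot(inherits(surv, "survival_table"))
  if (nrow(surv) == 0L) stop("empty survival table")
  f <- survival::survfit(Surv(surv$time, surv$event) ~ 1)
  out <- data.frame(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
                    n_censor = f$n.censor, surv = f$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Per-feature survival screen
#'
#' For every feature (gene or pathway): tertile-split the samples on the
#' feature's value, then compare the high vs low groups with the
#' log-rank test and the two-group Cox fit.  Samples without a survival
#' record are dropped for this endpoint before splitting.  Features with
#' a degenerate split, an undersized group, no events, or a
#' non-converged Cox fit carry an explicit `skip_reason` instead of
#' aborting the screen.
#'
#' @param x an [expr_matrix()] (log-transformed) or `pal_matrix`.
#' @param surv a [survival_table()]; its samples must be present in `x`.
#' @param config a [screen_config()].
#' @return Data frame of class `screen_result`, one row per feature:
#'   `feature_id`, `beta`, `hr`, `se`, `wald_p`, `logrank_p`, `n_high`,
#'   `n_low`, `n_events`, `skip_reason` (`NA` when screened).
#' @export
screen_features <- function(x, surv, config = screen_config()) {
  stopifnot(inherits(x, "expr_matrix") || inherits(x, "pal_matrix"),
            inherits(surv, "survival_table"))
  v <- x$values
  common <- intersect(colnames(v), surv$sample_id)
  if (length(common) == 0L) stop("no samples shared between matrix and survival table")
  surv <- surv[match(common, surv$sample_id), , drop = FALSE]
  class(surv) <- c("survival_table", "data.frame")
  v <- v[, common, drop = FALSE]
  time <- surv$time
  event <- surv$event
  nfeat <- nrow(v)
  beta <- hr <- se <- wald_p <- logrank_p <- rep(NA_real_, nfeat)
  n_high <- n_low <- n_events <- rep(NA_integer_, nfeat)
  skip <- rep(NA_character_, nfeat)
  ctrl <- survival::coxph.control(iter.max = 50)
  for (i in seq_len(nfeat)) {
    row <- v[i, ]
    sp <- tertile_split(row, config)
    if (sp$degenerate) { skip[i] <- "degenerate split"; next }
    if (length(sp$high) < config$min_group_size ||
        length(sp$low) < config$min_group_size) {
      skip[i] <- "group too small"; next
    }
    hi <- match(sp$high, common)
    lo <- match(sp$low, common)
    idx <- c(hi, lo)
    g <- rep(c(1L, 0L), c(length(hi), length(lo)))
    t_i <- time[idx]; e_i <- event[idx]
    n_high[i] <- length(hi); n_low[i] <- length(lo)
    n_events[i] <- as.integer(sum(e_i))
    if (n_events[i] == 0L) { skip[i] <- "no events"; next }
    sd <- survival::survdiff(Surv(t_i, e_i) ~ g, rho = 0)
    logrank_p[i] <- pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE)
    if (length(unique(g[e_i == 1])) < 2L) { skip[i] <- "cox non-converged"; next }
    fit <- tryCatch(
      suppressWarnings(
        survival::coxph.fit(matrix(as.double(g), ncol = 1L), Surv(t_i, e_i),
                            strata = NULL, offset = NULL, init = 0,
                            control = ctrl, weights = NULL,
                            method = config$tie_method, rownames = NULL)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients) ||
        abs(fit$coefficients) > 15 || !is.finite(fit$var[1L, 1L])) {
      skip[i] <- "cox non-converged"; next
    }
    beta[i] <- unname(fit$coefficients)
    se[i] <- sqrt(fit$var[1L, 1L])
    hr[i] <- exp(beta[i])
    wald_p[i] <- 2 * pnorm(-abs(beta[i] / se[i]))
  }
  out <- data.frame(feature_id = rownames(v), beta = beta, hr = hr, se = se,
                    wald_p = wald_p, logrank_p = logrank_p,
                    n_high = n_high, n_low = n_low, n_events = n_events,
                    skip_reason = skip, stringsAsFactors = FALSE)
  attr(out, "endpoint") <- attr(surv, "endpoint")
  attr(out, "dataset_label") <- x$dataset_label
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Select differential plus/minus feature sets
#'
#' A feature is differential when both the log-rank and Wald p-values
#' fall strictly below `alpha`; differential features are partitioned by
#' the sign of the log hazard ratio into the \emph{plus} set (`beta >
#' 0`: high expression, higher hazard) and the \emph{minus} set (`beta <
#' 0`).  A beta of exactly zero lands in neither set, so the two sets
#' are always disjoint.
#'
#' @param results a `screen_result` from [screen_features()].
#' @param config a [screen_config()] (only `alpha` is used).
#' @return List with character vectors `plus` and `minus`.
#' @export
select_differential <- function(results, config = screen_config()) {
  stopifnot(inherits(results, "data.frame"))
  ok <- is.na(results$skip_reason) &
    !is.na(results$wald_p) & !is.na(results$logrank_p) &
    results$wald_p < config$alpha & results$logrank_p < config$alpha
  list(plus = results$feature_id[ok & results$beta > 0],
       minus = results$feature_id[ok & results$beta < 0])
}

#' Per-group Kaplan-Meier export for a single feature
#'
#' Convenience wrapper: tertile-split one feature and return the KM
#' curves of the high and low groups in long format, suitable for
#' step-function plotting.
#'
#' @inheritParams screen_features
#' @param feature_id feature (row) to split on.
#' @return Data frame: `group` ("high"/"low") plus the [km_estimate()]
#'   columns.
#' @export
km_by_tertile <- function(x, surv, feature_id, config = screen_config()) {
  stopifnot(feature_id %in% rownames(x$values))
  common <- intersect(colnames(x$values), surv$sample_id)
  row <- x$values[feature_id, common]
  sp <- tertile_split(row, config)
  if (sp$degenerate) stop("degenerate split for feature ", feature_id)
  pieces <- lapply(c(high = "high", low = "low"), function(side) {
    ids <- sp[[side]]
    st <- surv[surv$sample_id %in% ids, , drop = FALSE]
    class(st) <- c("survival_table", "data.frame")
    cbind(group = side, as.data.frame(km_estimate(st)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
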