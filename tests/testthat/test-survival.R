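test_that("tertile split uses interpolated percentiles with strict bounds", {
  v <- setNames(1:9, sprintf("s%d", 1:9))
  sp <- tertile_split(v)
  # hand interpolation at index (n-1)*q: p33 = 3.64, p66 = 6.28
  expect_equal(sp$p33, 3.64)
  expect_equal(sp$p66, 6.28)
  expect_setequal(sp$low, c("s1", "s2", "s3"))
  expect_setequal(sp$high, c("s7", "s8", "s9"))

  sp3 <- tertile_split(setNames(1:3, c("a", "b", "c")))
  expect_equal(sp3$p33, 1.66)
  expect_equal(sp3$p66, 2.32)
  expect_identical(sp3$low, "a")
  expect_identical(sp3$high, "c")

  spc <- tertile_split(setNames(rep(2, 5), letters[1:5]))
  expect_true(spc$degenerate)
  expect_length(spc$high, 0)
  expect_length(spc$low, 0)

  expect_error(tertile_split(setNames(1:2, c("a", "b"))), ">= 3")
})

test_that("log-rank test matches hand-tallied hypergeometric examples", {
  # A events at {1,3}, B events at {2,4}: statistic 8/13
  st <- make_surv(c(1, 3, 2, 4), c(1, 1, 1, 1))
  lr <- logrank_test(c(1, 1, 0, 0), st)
  expect_equal(lr$chisq, 8 / 13, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(8 / 13, 1, lower.tail = FALSE), tolerance = 1e-10)

  # one event vs one censored: single risk set, statistic exactly 1
  st2 <- make_surv(c(1, 2), c(1, 0))
  lr2 <- logrank_test(c(1, 0), st2)
  expect_equal(lr2$chisq, 1.0, tolerance = 1e-10)
  expect_equal(lr2$p, 2 * pnorm(-1), tolerance = 1e-3)

  # identical survival in both groups: no signal
  st3 <- make_surv(c(5, 8, 5, 8), c(1, 0, 1, 0))
  expect_equal(logrank_test(c(1, 1, 0, 0), st3)$chisq, 0, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 1, 1, 1), st), "non-empty")
})

test_that("log-rank agrees with the tally oracle and is label-symmetric", {
  set.seed(11)
  for (i in 1:25) {
    inst <- random_no_tie_instance(sample(6:15, 1))
    st <- make_surv(inst$time, inst$event)
    got <- logrank_test(inst$x, st)$chisq
    expect_equal(got, oracle_logrank_chisq(inst$time, inst$event, inst$x),
                 tolerance = 1e-8)
    expect_equal(logrank_test(1 - inst$x, st)$chisq, got, tolerance = 1e-10)
  }
})

test_that("log-rank equals the Cox score test when event times are untied", {
  set.seed(12)
  for (i in 1:20) {
    inst <- random_no_tie_instance(sample(6:14, 1))
    chisq <- logrank_test(inst$x, make_surv(inst$time, inst$event))$chisq
    fit <- survival::coxph.fit(matrix(as.double(inst$x), ncol = 1),
                               survival::Surv(inst$time, inst$event),
                               strata = NULL, offset = NULL, init = 0,
                               control = survival::coxph.control(),
                               weights = NULL, method = "efron",
                               rownames = NULL)
    expect_equal(chisq, unname(fit$score), tolerance = 1e-8)
  }
})

test_that("Cox binary fit maximizes the partial likelihood", {
  # identical groups: beta = 0, hr = 1
  st <- make_surv(c(5, 8, 5, 8), c(1, 0, 1, 0))
  f0 <- cox_binary_fit(c(1, 1, 0, 0), st)
  expect_equal(f0$beta, 0, tolerance = 1e-8)
  expect_equal(f0$hr, 1, tolerance = 1e-8)

  # A events at {1,3}, B at {2,4}: frozen from the grid-search oracle
  st1 <- make_surv(c(1, 3, 2, 4), rep(1, 4))
  f1 <- cox_binary_fit(c(1, 1, 0, 0), st1)
  b_oracle <- oracle_cox_beta(c(1, 3, 2, 4), rep(1, 4), c(1, 1, 0, 0))
  expect_equal(f1$beta, b_oracle, tolerance = 1e-4)
  expect_equal(f1$beta, 0.9406, tolerance = 1e-3)

  # swapping labels negates beta exactly
  f1r <- cox_binary_fit(c(0, 0, 1, 1), st1)
  expect_equal(f1r$beta, -f1$beta, tolerance = 1e-8)

  # monotone likelihood (all events in one group) is flagged, not infinite
  st2 <- make_surv(c(1, 2, 9, 10), c(1, 1, 0, 0))
  f2 <- cox_binary_fit(c(1, 1, 0, 0), st2)
  expect_false(f2$converged)
  expect_true(is.na(f2$beta))

  expect_error(cox_binary_fit(c(1, 0), make_surv(c(1, 2), c(0, 0))),
               "no events")
})

test_that("Cox fit tracks the grid-search oracle on small no-tie instances", {
  set.seed(13)
  for (i in 1:40) {
    inst <- random_no_tie_instance(sample(5:8, 1))
    fit <- cox_binary_fit(inst$x, make_surv(inst$time, inst$event))
    if (!fit$converged) next
    b_oracle <- oracle_cox_beta(inst$time, inst$event, inst$x)
    if (abs(b_oracle) > 9) next  # near-monotone instance, maximum at boundary
    expect_lt(abs(fit$beta - b_oracle), 1e-4)
  }
})

test_that("Kaplan-Meier estimate follows the product-limit construction", {
  # all censored: survival stays at 1
  km0 <- km_estimate(make_surv(c(2, 5, 9), c(0, 0, 0)))
  expect_true(all(km0$surv == 1))

  km1 <- km_estimate(make_surv(c(1, 2), c(1, 1)))
  expect_equal(km1$surv, c(0.5, 0))

  # event, censored, event: S(1) = 2/3, S(3) = 0
  km2 <- km_estimate(make_surv(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  # with no censoring the curve is the empirical survival function
  set.seed(3)
  t <- sample(1:50, 12)
  km3 <- km_estimate(make_surv(t, rep(1, 12)))
  expect_equal(km3$surv, 1 - cumsum(km3$n_event) / 12)
  expect_true(all(diff(km3$surv) <= 0))

  expect_error(km_estimate(make_surv(numeric(), numeric())))
})

test_that("feature screen skips degenerate features and keeps sets disjoint", {
  set.seed(21)
  v <- rbind(const = rep(3, 30),
             good = rnorm(30, 10),
             lowvar = c(rep(1, 28), 2, 3))
  colnames(v) <- sprintf("s%02d", 1:30)
  m <- expr_matrix(v, "DS1", scale = "log_transformed")
  surv <- make_surv(rexp(30, 0.1), rbinom(30, 1, 0.8),
                    ids = colnames(v))
  res <- screen_features(m, surv)
  expect_identical(res$skip_reason[res$feature_id == "const"],
                   "degenerate split")
  expect_true(is.na(res$skip_reason[res$feature_id == "good"]))
  expect_identical(res$skip_reason[res$feature_id == "lowvar"],
                   "group too small")

  d <- select_differential(res)
  expect_length(intersect(d$plus, d$minus), 0)

  # samples without survival records are dropped, not errored
  surv_sub <- make_surv(rexp(20, 0.1), rbinom(20, 1, 0.8),
                        ids = colnames(v)[1:20])
  res_sub <- screen_features(m, surv_sub)
  expect_true(all(res_sub$n_high + res_sub$n_low <= 20, na.rm = TRUE))

  bad <- make_surv(c(1, 2, 3), c(1, 1, 0), ids = c("x1", "x2", "x3"))
  expect_error(screen_features(m, bad), "no samples shared")
})

test_that("differential selection applies the dual threshold and sign split", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    beta = c(0.5, 0.5, 0, -1),
    hr = exp(c(0.5, 0.5, 0, -1)), se = 0.1,
    wald_p = c(0.06, 0.01, 0.01, 0.01),
    logrank_p = c(0.04, 0.01, 0.01, 0.01),
    n_high = 5L, n_low = 5L, n_events = 8L,
    skip_reason = NA_character_, stringsAsFactors = FALSE)
  d <- select_differential(res, screen_config(alpha = 0.05))
  expect_identical(d$plus, "b")   # "a" fails one of the two p-values
  expect_identical(d$minus, "d")  # beta exactly 0 lands in neither set
})

test_that("per-feature KM export returns step functions for both groups", {
  set.seed(5)
  v <- matrix(rnorm(60), 2, 30,
              dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:30)))
  m <- expr_matrix(v, "DS1", scale = "log_transformed")
  surv <- make_surv(rexp(30, 0.1), rbinom(30, 1, 0.7), ids = colnames(v))
  km <- km_by_tertile(m, surv, "g1")
  expect_setequal(unique(km$group), c("high", "low"))
  for (g in c("high", "low"))
    expect_true(all(diff(km$surv[km$group == g]) <= 0))
})
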