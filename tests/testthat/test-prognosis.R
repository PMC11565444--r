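test_that("the product-limit estimator handles events and censoring", {
  km <- km_curve(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km <- km_curve(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)))
  expect_true(all(km$survival == 1))
  # censoring reduces the risk set without a step: 1, 2+, 3
  km <- km_curve(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)  # (2/3) * (1 - 1/1)
  expect_error(km_curve(data.frame(time = c(-1, 2), event = c(1, 1))), "negative")
})

test_that("without censoring the KM curve is one minus the empirical CDF", {
  withr::with_seed(121, {
    times <- stats::rexp(50, 0.1)
    km <- km_curve(data.frame(time = times, event = 1))
    for (k in seq_len(nrow(km))) {
      expect_equal(km$survival[k], mean(times > km$time[k]), tolerance = 1e-12)
    }
  })
})

test_that("the log-rank test separates separated groups and not identical ones", {
  withr::with_seed(131, {
    g <- data.frame(time = stats::rexp(25, 0.1), event = 1)
  })
  same <- logrank_test(g, g)
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  # complete separation: all A events before any B event
  a <- data.frame(time = 1:20, event = 1)
  b <- data.frame(time = 101:120, event = 1)
  sep <- logrank_test(a, b)
  expect_lt(sep$p_value, 0.05)
  expect_error(logrank_test(data.frame(time = 1, event = 0),
                            data.frame(time = 2, event = 0)), "zero events")
})

test_that("the concordance index honours censoring and both tie rules", {
  # perfect reversal: shorter survival always has the higher score
  d <- data.frame(time = c(1, 2, 3, 4), event = 1, risk_score = c(9, 7, 5, 3))
  expect_equal(concordance_index(d), 1)
  # identical scores: all ties, random baseline
  d$risk_score <- 5
  expect_equal(concordance_index(d), 0.5)
  # hand-worked censored example (computed with the pair-enumeration oracle):
  # permissible pairs (1,3), (1,4), (3,4) concordant, (2,4) discordant -> 3/4
  d <- data.frame(time = c(5, 3, 8, 1), event = c(1, 0, 1, 1),
                  risk_score = c(2, 9, 1, 8))
  expect_equal(oracle_cindex(d$time, d$event, d$risk_score), 0.75)
  expect_equal(concordance_index(d), 0.75)
  expect_error(concordance_index(data.frame(time = c(1, 2), event = c(0, 0),
                                            risk_score = c(1, 2))),
               "no permissible pairs")
})

test_that("the concordance index matches the brute-force oracle on random data", {
  withr::with_seed(141, {
    for (i in 1:25) {
      n <- sample(5:100, 1)
      d <- data.frame(time = sample(1:20, n, replace = TRUE),
                      event = stats::rbinom(n, 1, 0.7),
                      risk_score = sample(1:6, n, replace = TRUE))
      if (sum(d$event) == 0) next
      expect_equal(concordance_index(d),
                   oracle_cindex(d$time, d$event, d$risk_score),
                   tolerance = 1e-12)
    }
  })
})

test_that("the concordance index agrees with survival:: on tie-free data", {
  withr::with_seed(151, {
    n <- 80
    d <- data.frame(time = stats::rexp(n), event = stats::rbinom(n, 1, 0.7),
                    risk_score = stats::rnorm(n))
  })
  cc <- survival::concordance(survival::Surv(time, event) ~ risk_score,
                              data = d, reverse = TRUE)
  expect_equal(concordance_index(d), unname(cc$concordance), tolerance = 1e-12)
})

test_that("the ordinal risk score ranks stages and imputes missing values", {
  w <- c(local_invasion = 1)
  v2 <- data.frame(local_invasion = "pT2")
  v3 <- data.frame(local_invasion = "pT3")
  expect_gt(linear_risk_score(v3, w), linear_risk_score(v2, w))
  # sub-stages share their broad stage's code
  expect_equal(linear_risk_score(data.frame(local_invasion = "pT4a"), w),
               linear_risk_score(data.frame(local_invasion = "pT4b"), w))
  # zero weights give zero
  expect_equal(linear_risk_score(v3, c(local_invasion = 0)), 0)
  # NA sentinel takes the cohort median code
  cohort <- data.frame(local_invasion = c("pT2", "pT3", "pT3", "pTX"))
  scores <- linear_risk_score(cohort, w)
  expect_equal(scores[4], stats::median(scores[1:3]))
  expect_error(linear_risk_score(v3, c(bogus_field = 1)), "unknown field")
})

test_that("median-split stratification is conservative about ties", {
  d <- data.frame(risk_score = c(1, 2, 3, 4))
  expect_identical(stratify_by_score(d)$group, c("low", "low", "high", "high"))
  d <- data.frame(risk_score = c(1, 2, 3))
  expect_identical(stratify_by_score(d)$group, c("low", "low", "high"))
  expect_warning(g <- stratify_by_score(data.frame(risk_score = rep(2, 5))),
                 "low-risk")
  expect_true(all(g$group == "low"))
})

test_that("stage-driven cohorts are prognostic for the TNM score", {
  co <- generate_cohort(300, seed = 99)
  truth_wide <- do.call(rbind, lapply(co$cases, function(cs)
    as.data.frame(as.list(cs$true_values), stringsAsFactors = FALSE,
                  check.names = FALSE)))
  d <- co$survival
  d$risk_score <- linear_risk_score(truth_wide, tnm_weights())
  expect_gt(concordance_index(d), 0.65)
  strat <- stratify_by_score(d)
  lr <- logrank_test(strat[strat$group == "high", ], strat[strat$group == "low", ])
  expect_lt(lr$p_value, 0.01)
})
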