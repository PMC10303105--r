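# Product-limit estimation, log-rank testing, stratification, risk indices.

test_that("KM equals empirical survival without censoring", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$steps$survival, c(2 / 3, 1 / 3, 0))
  allc <- km_estimate(c(2, 5, 9), rep(FALSE, 3))
  expect_true(all(allc$steps$survival == 1))
  expect_true(is.na(median_survival(allc)))
})

test_that("KM handles censoring with deaths-first tie convention", {
  km <- km_estimate(c(1, 2, 3), c(FALSE, TRUE, TRUE))
  expect_equal(survival_at(km, 2), 1 / 2)
  expect_equal(survival_at(km, 3), 0)
  # death and censoring tied at t = 2: the censored case stays in the
  # risk set of the event
  tied <- km_estimate(c(1, 2, 2, 4), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(tied$steps$survival[tied$steps$time == 2], 3 / 4 * (1 - 1 / 3))
})

test_that("KM matches oracle and reference on small random datasets", {
  skip_if_not_installed("survival")
  set.seed(83)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    times <- sample(1:5, n, replace = TRUE) # many ties, mixed types
    events <- runif(n) < 0.6
    km <- km_estimate(times, events)
    orc <- oracle_km(times, events)
    expect_equal(km$steps$survival, orc$survival, info = paste(i))
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    expect_equal(survival_at(km, sf$time), sf$surv, tolerance = 1e-12)
    # bookkeeping: risk set drops by events + censored
    st <- km$steps
    expect_equal(st$n_risk[-1],
                 (st$n_risk - st$n_event - st$n_censor)[-nrow(st)])
  }
})

test_that("survival_at is a right-continuous step function", {
  km <- km_estimate(c(2, 4, 6, 8, 10),
                    c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(survival_at(km, 1), 1)
  expect_equal(survival_at(km, 4), 4 / 5 * 3 / 4)
  expect_equal(survival_at(km, 5), 4 / 5 * 3 / 4) # interior of a step
  expect_equal(survival_at(km, 8), 4 / 5 * 3 / 4 * 1 / 2)
  expect_equal(survival_at(km, 100), survival_at(km, 10))
})

test_that("median survival is the first time S drops to one half", {
  km <- km_estimate(c(1, 2, 3, 4, 5, 6),
                    c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # S = 5/6, 4/6, 3/6 at t = 3
  expect_equal(median_survival(km), 3)
  # Monte-Carlo consistency with an exponential of median 5 months
  set.seed(89)
  t <- rexp(5000, log(2) / 5)
  expect_lt(abs(median_survival(km_estimate(t, rep(TRUE, 5000))) - 5), 0.3)
})

test_that("log-rank matches hand computation and the reference", {
  skip_if_not_installed("survival")
  # one event per group: O - E = 1/2, V = 1/4 at the first event time
  lr <- logrank_test(c(1, 2), c(TRUE, TRUE), c("a", "b"))
  expect_equal(lr$statistic, 1)
  expect_equal(lr$p_value, pchisq(1, 1, lower.tail = FALSE))
  # identical groups give statistic 0
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                       rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # no events anywhere: flagged degenerate
  deg <- logrank_test(c(1, 2, 3, 4), rep(FALSE, 4), c("a", "a", "b", "b"))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  set.seed(97)
  for (i in 1:25) {
    n <- sample(6:50, 1); k <- sample(2:3, 1)
    t <- round(rexp(n, 0.2), 1); e <- runif(n) < 0.7
    g <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(g)) < k || !any(e)) next
    mine <- logrank_test(t, e, g)
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    if (!mine$degenerate) {
      expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
    }
    # invariance under group relabeling
    relab <- logrank_test(t, e, factor(g, labels = rev(letters[1:k])))
    expect_equal(mine$statistic, relab$statistic, tolerance = 1e-12)
  }
})

test_that("log-rank rejects under a real hazard difference and holds size", {
  set.seed(101)
  n <- 300
  reject_hr2 <- replicate(60, {
    t1 <- rexp(n, log(2) / 12); t2 <- rexp(n, log(2) / 6)
    cens <- runif(2 * n, 6, 40)
    obs <- pmin(c(t1, t2), cens)
    logrank_test(obs, c(t1, t2) <= cens,
                 rep(c("a", "b"), each = n))$p_value < 0.05
  })
  expect_gt(mean(reject_hr2), 0.95)
})

test_that("TILs-score stratification splits at the cohort median", {
  co <- tibble::tibble(
    case_id = paste0("c", 1:5),
    diagnosis = c(rep("PTCL_NOS", 4), "ALK_POS_ALCL"),
    tils_frac = c(0, 0.2, 0.5, 0.4, 0.3),
    s727_tils_score = c(0, 10, 40, 40, 20),
    os_months = c(3, 10, 20, 30, 40),
    os_event = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  )
  strat <- stratify_by_tils_score(co)
  expect_equal(tils_split_value(strat), 25) # median of 0, 10, 40, 40
  expect_equal(strat$tils_group,
               c("NO_TILS", "LOW", "HIGH", "HIGH", "EXCLUDED"))
  # all cases TILs-free
  allno <- dplyr::mutate(co[1:3, ], tils_frac = 0, s727_tils_score = 0)
  expect_true(all(stratify_by_tils_score(allno)$tils_group == "NO_TILS"))
  # lost to follow-up is excluded and does not enter the median
  lost <- co; lost$os_months[3] <- NA; lost$os_event[3] <- NA
  strat2 <- stratify_by_tils_score(lost)
  expect_equal(strat2$tils_group[3], "EXCLUDED")
  expect_equal(tils_split_value(strat2), 10)
})

test_that("risk indices count adverse factors and map to groups", {
  co <- tibble::tibble(
    case_id = c("x", "y", "z"),
    diagnosis = "PTCL_NOS",
    age = c(50, 70, 65),
    ecog_gt1 = c(FALSE, TRUE, TRUE),
    ldh_elevated = c(FALSE, TRUE, NA),
    bm_involvement = c(FALSE, TRUE, FALSE)
  )
  out <- risk_index_score(co, pit_definition())
  expect_equal(out$pit_score, c(0L, 4L, NA_integer_))
  expect_equal(out$pit_group, c("low", "high", "EXCLUDED"))
  # a 3-factor modified index with the 0-1 / 2-3 grouping
  mpit <- risk_index_definition(
    "MPIT",
    factors = list(a = ~ age > 60, b = ~ ecog_gt1, c = ~ bm_involvement),
    grouping = list(low = 0:1, high = 2:3)
  )
  out2 <- risk_index_score(co[1:2, ], mpit)
  expect_equal(out2$mpit_score, c(0L, 3L))
  expect_equal(out2$mpit_group, c("low", "high"))
  bad <- risk_index_definition("B", list(q = ~ not_a_column > 1),
                               grouping = list(low = 0:1))
  expect_error(risk_index_score(co, bad), class = "ihcdx_config_error")
})

test_that("survival_by_group summarises curves and tests jointly", {
  co <- generate_cohort(default_study_config(), seed = 9)
  res <- survival_by_group(co, "diagnosis")
  expect_setequal(res$summary$group, unique(co$diagnosis))
  expect_s3_class(res$logrank, "tbl_df")
  ptcl <- res$summary[res$summary$group == "PTCL_NOS", ]
  expect_lt(ptcl$median_os, 12) # aggressive course
  expect_true(is.na(res$summary$median_os[res$summary$group == "ALK_POS_ALCL"]))
})
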