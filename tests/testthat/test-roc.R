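# Empirical ROC, Youden cutoffs, marker combination, DeLong comparison.

test_that("AUC equals tie-aware pair counting", {
  roc <- empirical_roc(c(200, 250, 300, 50, 100),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$auc, 1)
  # one tied pair contributes a half
  roc2 <- empirical_roc(c(1, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc2$auc, 3.5 / 4)
  # label inversion flips the AUC
  roc3 <- empirical_roc(c(200, 250, 300, 50, 100),
                        !c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc3$auc, 0)
  expect_error(empirical_roc(1:4, rep(TRUE, 4)),
               class = "ihcdx_degenerate_error")
})

test_that("AUC matches the brute-force oracle and its invariances", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    scores <- round(rnorm(n, 150, 60), sample(c(0, 1), 1)) # force ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    auc <- empirical_roc(scores, labels)$auc
    expect_equal(auc, oracle_auc(scores, labels), info = paste("rep", i))
    # complement and monotone-transform invariances
    expect_equal(empirical_roc(scores, !labels)$auc, 1 - auc)
    expect_equal(empirical_roc(exp(scores / 50), labels)$auc, auc)
  }
})

test_that("ROC curves run from (0,1) to (1,0) with monotone coordinates", {
  set.seed(23)
  scores <- round(rnorm(40, 100, 40)); labels <- runif(40) < 0.5
  pts <- tidy(empirical_roc(scores, labels))
  expect_equal(pts$sensitivity[1], 0)
  expect_equal(pts$specificity[1], 1)
  expect_equal(pts$sensitivity[nrow(pts)], 1)
  expect_equal(pts$specificity[nrow(pts)], 0)
  expect_true(all(diff(pts$sensitivity) >= 0))
  expect_true(all(diff(1 - pts$specificity) >= 0))
})

test_that("the Youden-optimal cutoff equals the exhaustive scan", {
  # perfect separation: J = 1 at the midpoint of the gap
  roc <- empirical_roc(c(200, 250, 300, 50, 100),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE))
  best <- youden_optimal_cutoff(roc)
  expect_equal(best$cutoff, 150)
  expect_equal(best$youden, 1)
  expect_false(best$degenerate)
  # oracle equivalence on the spec-style mixed example and random data
  set.seed(29)
  cases <- c(list(list(s = c(250, 250, 100, 50, 150, 150),
                       l = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))),
             lapply(1:20, function(i) {
               n <- sample(6:80, 1)
               list(s = round(rnorm(n, 100, 50), 1), l = runif(n) < 0.5)
             }))
  for (cs in cases) {
    if (!any(cs$l) || all(cs$l)) next
    best <- youden_optimal_cutoff(empirical_roc(cs$s, cs$l))
    expect_equal(best$youden, oracle_best_youden(cs$s, cs$l))
  }
  # no discrimination: flagged degenerate with J = 0
  flat <- youden_optimal_cutoff(empirical_roc(rep(5, 6),
                                              c(TRUE, TRUE, FALSE,
                                                FALSE, TRUE, FALSE)))
  expect_equal(flat$youden, 0)
  expect_true(flat$degenerate)
})

test_that("evaluate_at_cutoff uses the at-or-above call convention", {
  ev <- evaluate_at_cutoff(c(200, 300, 50, 100),
                           c(TRUE, TRUE, FALSE, FALSE), 145)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$youden, 1)
  flip <- evaluate_at_cutoff(c(100, 200), c(TRUE, FALSE), 145)
  expect_equal(flip$sensitivity, 0)
  expect_equal(flip$specificity, 0)
  # boundary: a score equal to the cutoff is called positive
  bd <- evaluate_at_cutoff(145, TRUE, 145)
  expect_equal(bd$tp, 1)
  bd_gt <- evaluate_at_cutoff(145, TRUE, 145, ge = FALSE)
  expect_equal(bd_gt$tp, 0)
})

test_that("parallel combination boosts sensitivity, serial specificity", {
  a <- c(TRUE, FALSE); b <- c(FALSE, TRUE)
  expect_equal(combine_calls(list(a = a, b = b), "parallel"), c(TRUE, TRUE))
  expect_equal(combine_calls(list(a = a, b = b), "serial"), c(FALSE, FALSE))
  expect_error(combine_calls(list(a, c(TRUE, FALSE, TRUE))),
               class = "ihcdx_validation_error")
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:40, 1)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    calls <- list(m1 = runif(n) < 0.5, m2 = runif(n) < 0.5)
    singles <- lapply(calls, function(cl) {
      tp <- sum(cl & labels); fn <- sum(!cl & labels)
      tn <- sum(!cl & !labels); fp <- sum(cl & !labels)
      c(sens = tp / (tp + fn), spec = tn / (tn + fp))
    })
    par <- combine_markers(calls, labels, "parallel")
    ser <- combine_markers(calls, labels, "serial")
    expect_gte(par$sensitivity, max(singles$m1["sens"], singles$m2["sens"]))
    expect_gte(ser$specificity, max(singles$m1["spec"], singles$m2["spec"]))
  }
})

test_that("DeLong test is symmetric and null for identical classifiers", {
  set.seed(37)
  s <- rnorm(30); l <- runif(30) < 0.5
  same <- delong_paired_test(s, s, l)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  s2 <- rnorm(30)
  ab <- delong_paired_test(s, s2, l)
  ba <- delong_paired_test(s2, s, l)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$z, -ba$z)
  expect_true(ab$p_value > 0 && ab$p_value <= 1)
})

test_that("DeLong agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:10) {
    n <- sample(25:60, 1)
    l <- runif(n) < 0.5
    if (sum(l) < 2 || sum(!l) < 2) next
    sa <- rnorm(n) + l; sb <- rnorm(n) + 0.5 * l
    mine <- delong_paired_test(sa, sb, l)
    ra <- pROC::roc(l, sa, levels = c(FALSE, TRUE), direction = "<",
                    quiet = TRUE)
    rb <- pROC::roc(l, sb, levels = c(FALSE, TRUE), direction = "<",
                    quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(mine$auc_a, as.numeric(ra$auc))
    expect_equal(mine$auc_b, as.numeric(rb$auc))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})
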