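# Exact test implementations against enumeration oracles and base R.

test_that("Fisher exact reproduces hand-checked clinical tables", {
  # bone marrow involvement 0/16 vs 5/17 (printed as 0.045)
  expect_lt(abs(fisher_exact_two_sided(0, 16, 5, 12)$p_value - 0.045), 1e-3)
  # therapy response 8/16 vs 1/10
  expect_equal(round(fisher_exact_two_sided(8, 8, 1, 9)$p_value, 4), 0.0873)
  # identical proportions
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5)$p_value, 1)
})

test_that("Fisher p equals enumeration, base R, and its symmetries", {
  set.seed(53)
  for (i in 1:40) {
    cells <- as.vector(rmultinom(1, sample(8:200, 1), runif(4, 0.05, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact_two_sided(a, b, c, d)$p_value
    expect_equal(p, min(1, oracle_fisher(a, b, c, d)), info = paste(cells, collapse = ","))
    m <- matrix(cells, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
    }
    # transpose and row-swap invariance
    expect_equal(fisher_exact_two_sided(t(m))$p_value, p)
    expect_equal(fisher_exact_two_sided(m[2:1, ])$p_value, p)
  }
  # degenerate margins
  deg <- fisher_exact_two_sided(0, 0, 3, 4)
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("exact Mann-Whitney matches exhaustive assignment enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)
  set.seed(59)
  for (i in 1:15) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:6, nx, replace = TRUE) # ties likely
    y <- sample(1:6, ny, replace = TRUE)
    mine <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(mine$p_value, oracle_mwu(x, y), info = paste(i))
    # U identity
    uy <- mann_whitney_u(y, x, mode = "exact")$statistic
    expect_equal(mine$statistic + uy, nx * ny)
    # untied data: agree with base R's exact test
    if (length(unique(c(x, y))) == nx + ny) {
      expect_equal(mine$p_value,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value)
    }
  }
})

test_that("Mann-Whitney symmetric configurations and degeneracy", {
  sym <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "exact")
  expect_equal(sym$statistic, 9 / 2)
  expect_equal(sym$p_value, 1)
  deg <- mann_whitney_u(rep(2, 4), rep(2, 3))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("normal approximation tracks the exact Mann-Whitney p", {
  set.seed(61)
  # continuous data, moderate n: spec-level closeness of the two modes
  x <- rnorm(20); y <- rnorm(20, 0.4)
  approx_p <- mann_whitney_u(x, y, mode = "normal")$p_value
  ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(approx_p - ref), 0.01)
  # tie-corrected variance agrees with base R's normal approximation
  xt <- sample(1:5, 18, replace = TRUE); yt <- sample(1:5, 15, replace = TRUE)
  expect_equal(mann_whitney_u(xt, yt, mode = "normal")$p_value,
               stats::wilcox.test(xt, yt, exact = FALSE,
                                  correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("Kruskal-Wallis H matches hand computation and base R", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 12 / 42 * 2 * ((1.5 - 3.5)^2 + 0 + (5.5 - 3.5)^2))
  expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE))
  ident <- kruskal_wallis(list(rep(1, 3), rep(1, 4), rep(1, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  set.seed(67)
  for (i in 1:10) {
    gs <- lapply(1:sample(2:4, 1), function(g) sample(1:8, sample(3:9, 1),
                                                      replace = TRUE))
    if (length(unique(unlist(gs))) == 1) next
    mine <- kruskal_wallis(gs)
    ref <- stats::kruskal.test(gs)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("two-group Kruskal-Wallis equals the squared MWU z", {
  set.seed(71)
  x <- sample(1:10, 12, replace = TRUE); y <- sample(1:10, 9, replace = TRUE)
  h <- kruskal_wallis(list(x, y))$statistic
  mwu <- mann_whitney_u(x, y, mode = "normal")
  z <- qnorm(mwu$p_value / 2) # two-sided normal p back to |z|
  expect_equal(h, z^2, tolerance = 1e-9)
})

test_that("Spearman rho matches the rank-then-correlate oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x^3)$statistic, 1)
  expect_equal(spearman_rho(x, -x)$statistic, -1)
  set.seed(73)
  xt <- sample(1:4, 12, replace = TRUE); yt <- xt + sample(0:3, 12, TRUE)
  mine <- spearman_rho(xt, yt)
  expect_equal(mine$statistic,
               stats::cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
  expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "ihcdx_degenerate_error")
})

test_that("p-values live in (0, 1] across random inputs", {
  set.seed(79)
  for (i in 1:20) {
    cells <- as.vector(rmultinom(1, 40, runif(4)))
    p1 <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])$p_value
    x <- rnorm(6); y <- rnorm(5)
    p2 <- mann_whitney_u(x, y)$p_value
    p3 <- kruskal_wallis(list(rnorm(5), rnorm(6)))$p_value
    for (p in c(p1, p2, p3)) {
      expect_gt(p, 0); expect_lte(p, 1)
    }
  }
})

test_that("compare_groups dispatches and returns auditable inputs", {
  co <- score_cohort(classify_cd30_subgroup(
    generate_cohort(default_study_config(), seed = 5)))
  fis <- compare_groups(co, "ldh_elevated", "subgroup",
                        "ALK_NEG_ALCL", "CD30_HIGH")
  expect_match(fis$method, "Fisher")
  audit <- fis$audit[[1]]$table
  expect_equal(fis$p_value,
               fisher_exact_two_sided(audit)$p_value)
  num <- compare_groups(co, "age", "subgroup", "ALK_NEG_ALCL", "CD30_HIGH")
  expect_match(num$method, "Mann-Whitney")
  expect_equal(num$p_value,
               mann_whitney_u(num$audit[[1]]$x, num$audit[[1]]$y)$p_value)
  # covariate missing everywhere
  co$b2m_high <- NA
  expect_error(compare_groups(co, "b2m_high", "subgroup",
                              "ALK_NEG_ALCL", "CD30_HIGH"),
               class = "ihcdx_validation_error")
})
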