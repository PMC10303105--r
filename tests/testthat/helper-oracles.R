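# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the code paths of the implementation.

# AUC by explicit enumeration of all (positive, negative) pairs
oracle_auc <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(x) * length(y))
}

# two-sided Fisher p by direct enumeration of the hypergeometric support,
# computing each table mass from binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  mass <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- mass[ks == a]
  sum(mass[mass <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of which
# pooled observations belong to x, recomputing U by pair counting
oracle_mwu <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(xs, ys) {
    tot <- 0
    for (xi in xs) for (yj in ys) tot <- tot + (xi > yj) + 0.5 * (xi == yj)
    tot
  }
  u_obs <- u_of(x, y)
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# product-limit estimate built observation-by-observation
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- numeric(0)
  for (t in ut) {
    at_risk <- sum(times >= t)
    d <- sum(events & times == t)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  data.frame(time = ut, survival = out)
}

# best Youden index by scanning a dense grid of cutoffs (every observed
# score and every midpoint), independent of the ROC enumeration
oracle_best_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- unique(c(s, (s[-1] + s[-length(s)]) / 2, min(s) - 1, max(s) + 1))
  best <- -Inf
  for (ct in cand) {
    pos <- scores >= ct
    sens <- sum(pos & labels) / sum(labels)
    spec <- sum(!pos & !labels) / sum(!labels)
    best <- max(best, sens + spec - 1)
  }
  best
}

# tiny hand-buildable cohort used across the I/O and scoring tests
make_test_cohort <- function() {
  tibble::tibble(
    case_id = c("A1", "A2", "P1", "P2", "P3"),
    diagnosis = c("ALK_NEG_ALCL", "ALK_NEG_ALCL",
                  "PTCL_NOS", "PTCL_NOS", "PTCL_NOS"),
    cd30_frac = c(0.95, 0.9, 0.85, 0.5, NA),
    tils_frac = c(0.2, 0, 0.3, 0.1, NA),
    s727_tumor_frac0 = c(0.0, 0.1, 0.5, 0.6, 0.3),
    s727_tumor_frac1 = c(0.1, 0.2, 0.3, 0.2, 0.3),
    s727_tumor_frac2 = c(0.3, 0.3, 0.1, 0.1, 0.2),
    s727_tumor_frac3 = c(0.6, 0.4, 0.1, 0.1, 0.2),
    s727_tils_frac0 = c(0.2, NA, 0.4, 0.5, NA),
    s727_tils_frac1 = c(0.4, NA, 0.4, 0.3, NA),
    s727_tils_frac2 = c(0.3, NA, 0.2, 0.2, NA),
    s727_tils_frac3 = c(0.1, NA, 0.0, 0.0, NA),
    age = c(55, 70, 62, 48, 81),
    ecog_gt1 = c(FALSE, TRUE, TRUE, NA, FALSE),
    ldh_elevated = c(TRUE, FALSE, TRUE, TRUE, NA),
    bm_involvement = c(FALSE, FALSE, TRUE, NA, NA),
    os_months = c(40, 55, 3, 12, NA),
    os_event = c(FALSE, FALSE, TRUE, TRUE, NA)
  )
}
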