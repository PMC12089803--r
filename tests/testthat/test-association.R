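test_that("logistic fit matches direct likelihood maximisation on small fixtures", {
  set.seed(101)
  for (rep in 1:3) {
    n <- 20
    x <- rnorm(n)
    c1 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x + 0.4 * c1))
    if (length(unique(y)) < 2) next
    res <- fit_logistic(y, x, cbind(c1))
    beta_oracle <- oracle_logistic(cbind(1, x, c1), y)
    expect_lt(abs(res$beta - beta_oracle[2]), 1e-6)
  }
  expect_error(fit_logistic(rep(0:1, 10), rep(1, 20)), "no variation")
  expect_error(fit_logistic(rep(1, 20), rnorm(20)), "single class")
})

test_that("logistic fit recovers a known effect with nominal CI coverage", {
  set.seed(202)
  beta_true <- 0.3
  hits <- 0L
  reps <- 60
  for (i in seq_len(reps)) {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(-1 + beta_true * x))
    r <- fit_logistic(y, x, metrics = FALSE)
    lo <- r$beta - 1.96 * r$se
    hi <- r$beta + 1.96 * r$se
    hits <- hits + (lo <= beta_true && beta_true <= hi)
  }
  expect_gte(hits / reps, 0.85)   # 95% nominal, 60-rep binomial slack
})

test_that("null predictors give calibrated p-values", {
  set.seed(303)
  reps <- 400
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(600)
    y <- rbinom(600, 1, 0.3)
    p[i] <- fit_logistic(y, x, metrics = FALSE)$p
  }
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("Nagelkerke R2 follows the Cox-Snell rescaling", {
  expect_equal(nagelkerke_r2(-10, -10, 50), 0)
  # saturated fit on balanced outcomes reaches the bound 1
  n <- 40
  ll_null <- n * log(0.5)
  expect_equal(nagelkerke_r2(0, ll_null, n), 1)
  # toy 2x2 data against closed-form Bernoulli likelihoods
  # groups: x=0 with 2/10 cases, x=1 with 7/10 cases
  p0 <- 0.2; p1 <- 0.7; pbar <- 0.45
  ll_full <- 10 * (p0 * log(p0) + (1 - p0) * log(1 - p0)) +
    10 * (p1 * log(p1) + (1 - p1) * log(1 - p1))
  ll_0 <- 20 * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  cs <- 1 - exp(2 * (ll_0 - ll_full) / 20)
  expect_equal(nagelkerke_r2(ll_full, ll_0, 20),
               cs / (1 - exp(2 * ll_0 / 20)))
  expect_error(nagelkerke_r2(-5, -4, 10), "below null")
  expect_error(nagelkerke_r2(-5, -6, 0), "positive")
})

test_that("delta Nagelkerke R2 is non-negative when the predictor is added", {
  set.seed(9)
  x <- rnorm(500); cv <- rnorm(500)
  y <- rbinom(500, 1, plogis(0.5 * x + 0.5 * cv))
  r <- fit_logistic(y, x, cbind(cv))
  expect_gte(r$r2_nagelkerke, 0)
})

test_that("ROC AUC equals all-pairs enumeration, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_equal(roc_auc(c(5, 4, 3), c(1, 1, 0)), 1)
  set.seed(404)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(sc, y), oracle_auc(sc, y))
  }
  # scores independent of labels sit near 1/2
  sc <- rnorm(4000); y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, y) - 0.5), 3 * sqrt(1 / (12 * 1000)))
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- rnorm(300)
  y <- rbinom(300, 1, plogis(sc))
  expect_equal(roc_auc(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))))
})

test_that("tetrachoric correlation matches the quadrature-oracle MLE", {
  # independence: margins multiply
  ind <- matrix(c(20, 80, 30, 120), 2, 2, byrow = TRUE)
  expect_lt(abs(tetrachoric(ind)), 1e-3)
  # perfectly concordant table reported at the boundary
  expect_gte(tetrachoric(matrix(c(50, 0, 0, 50), 2, 2)), 0.999)
  expect_lte(tetrachoric(matrix(c(0, 50, 50, 0), 2, 2)), -0.999)
  expect_warning(est <- tetrachoric(matrix(c(0, 0, 30, 70), 2, 2)),
                 "empty margin")
  expect_true(is.na(est))
  set.seed(505)
  for (i in 1:4) {
    tab <- matrix(sample(5:200, 4), 2, 2)
    expect_lt(abs(tetrachoric(tab) - oracle_tetrachoric(tab)), 1e-3,
              label = paste(tab, collapse = "/"))
  }
})

test_that("tetrachoric recovers the generating correlation from dichotomised normals", {
  set.seed(606)
  rho <- 0.5
  n <- 100000
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  a <- z1 > qnorm(0.7); b <- z2 > qnorm(0.8)
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE)
  expect_lt(abs(tetrachoric(tab) - rho), 0.02)
})

test_that("interaction test reports the product term and flags degeneracy", {
  set.seed(707)
  n <- 20000
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 0.2 * x1 + 0.3 * x2 + 0.5 * x1 * x2))
  r <- interaction_test(y, x1, x2)
  expect_lt(abs(r$beta - 0.5), 4 * r$se)
  expect_lt(r$p, 0.05)
  r0 <- interaction_test(y, x1, rep(0, n))
  expect_true(is.na(r0$beta))
  expect_match(r0$flag, "inestimable")
})

test_that("interaction test keeps nominal type-I error under additivity", {
  set.seed(808)
  reps <- 300
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    x1 <- rnorm(800)
    x2 <- rbinom(800, 1, 0.4)
    y <- rbinom(800, 1, plogis(-0.5 + 0.3 * x1 + 0.3 * x2))
    p[i] <- interaction_test(y, x1, x2)$p
  }
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("conditioning on a mediator attenuates the effect", {
  set.seed(909)
  n <- 30000
  carrier <- rbinom(n, 1, 0.05)
  mood <- rbinom(n, 1, plogis(-1.5 + 1.2 * carrier))
  anx <- rbinom(n, 1, plogis(-1.5 + 1.5 * mood))  # effect only through mood
  marg <- fit_logistic(anx, carrier, metrics = FALSE)
  cond <- conditional_test(anx, carrier, mood)
  expect_lt(abs(cond$beta), abs(marg$beta))
  # conditioning on an irrelevant variable changes little
  noise <- rbinom(n, 1, 0.5)
  cond2 <- conditional_test(anx, carrier, noise)
  expect_lt(abs(cond2$beta - marg$beta), 2 * marg$se)
  # outcome identical to the conditioning variable is flagged
  dg <- conditional_test(mood, carrier, mood)
  expect_match(dg$flag, "degenerate")
})

test_that("Bonferroni thresholds match the analytic correction", {
  expect_equal(bonferroni_threshold(0.05, 16), 3.125e-3)
  expect_equal(bonferroni_threshold(0.05, 24), 2.083e-3, tolerance = 2e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})
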