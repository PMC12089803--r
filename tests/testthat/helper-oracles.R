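# Independent oracles used to cross-check the package implementations.

# Direct logistic likelihood maximisation (BFGS with analytic gradient),
# independent of the IRLS path used by the package.
oracle_logistic <- function(X, y, start = NULL) {
  X <- as.matrix(X)
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(b) {
    p <- plogis(X %*% b)
    as.numeric(crossprod(X, p - y))
  }
  fit <- optim(start %||% rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Bivariate standard-normal CDF by 1-D quadrature (independent of mvtnorm).
oracle_bvn_cdf <- function(a, b, rho) {
  integrate(function(x)
    dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2)),
    -Inf, a, rel.tol = 1e-10)$value
}

# Brute-force tetrachoric MLE on a rho grid refined by optimise, using the
# quadrature CDF.
oracle_tetrachoric <- function(tab) {
  n <- sum(tab)
  q1 <- sum(tab[2, ]) / n
  q2 <- sum(tab[, 2]) / n
  a <- qnorm(q1); b <- qnorm(q2)
  nll <- function(rho) {
    p00 <- oracle_bvn_cdf(a, b, rho)
    p <- pmax(c(1 - q1 - q2 + p00, q2 - p00, q1 - p00, p00), 1e-12)
    -sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(p))
  }
  optimise(nll, c(-0.999, 0.999), tol = 1e-7)$minimum
}

# All-pairs AUC enumeration.
oracle_auc <- function(scores, y) {
  y <- as.logical(y)
  cs <- scores[y]; ct <- scores[!y]
  tot <- 0
  for (s in cs) tot <- tot + sum(s > ct) + 0.5 * sum(s == ct)
  tot / (length(cs) * length(ct))
}

# Exact HWE p-value by direct evaluation of the conditional distribution
# of the heterozygote count (log-multinomial form, no recurrence).
oracle_hwe_exact <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * aa + ab
  nb <- 2 * bb + ab
  rare <- min(na, nb)
  ks <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(ks, function(k) {
    hr <- (rare - k) / 2
    hc <- n - k - hr
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(hc + 1) - lgamma(k + 1) +
      k * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[ks == ab]
  sum(p[p <= obs + 1e-12])
}

# Brute-force greedy LD pruning on one global window (same removal rule:
# worst pair first, remove the higher-missingness member, ties to the
# later position).
oracle_ld_prune <- function(dos, missingness, r2_max) {
  m <- ncol(dos)
  keep <- rep(TRUE, m)
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    cc <- suppressWarnings(cor(dos[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0
    r2 <- cc^2; diag(r2) <- 0
    if (max(r2) <= r2_max) break
    w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    a <- idx[w[1]]; b <- idx[w[2]]
    drop <- if (missingness[a] > missingness[b]) a
    else if (missingness[b] > missingness[a]) b else max(a, b)
    keep[drop] <- FALSE
  }
  keep
}

# Minimal hand-built phenotype_records skeleton: full availability, no
# records, n individuals.  Tests then splice in the rows they need.
make_records <- function(n = 4, ids = sprintf("p%02d", seq_len(n)),
                         mhq = TRUE, primary_care = TRUE) {
  empty_iv <- data.frame(id = character(), code = character(),
                         kind = character(), stringsAsFactors = FALSE)
  gad <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (j in 1:7) gad[[paste0("gad7_", j)]] <- 0L
  cidi <- data.frame(id = ids, mdd_cardinal_mood = 0L,
                     mdd_cardinal_anhedonia = 0L, mdd_symptom_count = 0L,
                     mdd_duration_2wk = 0L, mdd_impairment = 0L,
                     gad_excessive_worry = 0L, gad_duration_6mo = 0L,
                     gad_symptom_count = 0L, stringsAsFactors = FALSE)
  structure(list(
    availability = data.frame(id = ids, touchscreen = TRUE,
                              interview = TRUE, mhq = mhq,
                              primary_care = primary_care, hospital = TRUE,
                              stringsAsFactors = FALSE),
    touchscreen = data.frame(id = ids, gp_help = 0L, psych_help = 0L,
                             low_mood_2wk = 0L, anhedonia_2wk = 0L,
                             stringsAsFactors = FALSE),
    interview = empty_iv,
    gad7 = gad, cidi = cidi,
    mhq_diagnosis = data.frame(id = character(), label = character(),
                               stringsAsFactors = FALSE),
    ehr = data.frame(id = character(), code = character(),
                     source = character(), stringsAsFactors = FALSE)),
    class = "phenotype_records")
}

# Perfect-observation simulation config at modest size.
perfect_config <- function(n = 2000, seed = 11, ...) {
  om <- default_observation_model()
  om$sensitivity <- 1
  om$specificity <- 1
  sim_config(n_individuals = n, n_variants = 100,
             source_availability = list(touchscreen = 1, interview = 1,
                                        mhq = 1, primary_care = 1,
                                        hospital = 1),
             observation_model = om, exclusion_rate = 0,
             seed = seed, ...)
}

status_of <- function(flags, def, dis) {
  sub <- flags[flags$definition == def & flags$disorder == dis, ]
  setNames(sub$status, sub$id)
}

# Simulate two overlapping case-control analyses of the same true effect
# and return the two logistic estimates plus the exact overlap design.
simulate_overlap_pair <- function(n_arm, frac_shared, beta = 0.3) {
  s <- round(frac_shared * n_arm)
  pool <- 2L * n_arm - s
  x <- rnorm(pool)
  y <- rbinom(pool, 1, plogis(-1.5 + beta * x))
  i1 <- seq_len(n_arm)
  i2 <- seq.int(pool - n_arm + 1L, pool)
  shared <- intersect(i1, i2)
  fit <- function(idx) {
    f <- suppressWarnings(glm.fit(cbind(1, x[idx]), y[idx],
                                  family = binomial()))
    v <- chol2inv(chol(crossprod(cbind(1, x[idx]) * sqrt(f$weights))))
    c(beta = f$coefficients[2], se = sqrt(v[2, 2]))
  }
  f1 <- fit(i1); f2 <- fit(i2)
  list(beta1 = f1[1], se1 = f1[2], beta2 = f2[1], se2 = f2[2],
       design = c(n1_case = sum(y[i1]), n1_control = sum(1 - y[i1]),
                  n2_case = sum(y[i2]), n2_control = sum(1 - y[i2]),
                  s_case = sum(y[shared]), s_control = sum(1 - y[shared])))
}

# One calibration pass: rejection rates of the overlap-aware and naive
# difference tests across replicates at one overlap fraction.
overlap_rejection_rates <- function(n_arm, frac_shared, reps,
                                    alpha = 0.05) {
  rej_adj <- rej_naive <- logical(reps)
  for (i in seq_len(reps)) {
    sim <- simulate_overlap_pair(n_arm, frac_shared)
    d <- sim$design
    r <- overlap_correlation(d["n1_case"], d["n1_control"], d["n2_case"],
                             d["n2_control"], d["s_case"], d["s_control"])
    rej_adj[i] <- effect_difference_z(sim$beta1, sim$se1, sim$beta2,
                                      sim$se2, r)$p < alpha
    rej_naive[i] <- effect_difference_z(sim$beta1, sim$se1, sim$beta2,
                                        sim$se2, 0)$p < alpha
  }
  c(adjusted = mean(rej_adj), naive = mean(rej_naive))
}
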