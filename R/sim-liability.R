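# Liability-threshold phenotype simulation ----------------------------------

#' Simulate latent liabilities, CNV carriers and true disorder status
#'
#' Each disorder's liability is `sqrt(h2) * G + shift * carrier + delta_f *
#' female + age_beta * (age - mean age) + sqrt(1 - h2) * E`, with the
#' polygenic scores `G` built from the variant weights (genetic correlation
#' set in the weights) and the environmental components `E` correlated at
#' `env_corr`.  Disorder status is liability above a threshold; thresholds
#' are the empirical liability quantiles matching the target prevalences,
#' and the female liability offset `delta_f` is solved numerically so that
#' the female/male prevalence odds ratio equals `female_or`.
#'
#' @param config a [sim_config()].
#' @param genotypes a `genotype_matrix` (or NULL when `G` is supplied).
#' @param weights weight table from [simulate_weights()].
#' @param G optional n x 2 matrix of pre-standardised polygenic scores
#'   (columns mood, anxiety) for lightweight simulation without genotypes.
#' @param population optional population labels when `G` is supplied.
#' @param seed integer seed.
#' @return object of class `latent_state`: list with `table` (data.frame:
#'   id, female, age, population, G_mood, G_anx, liability_mood,
#'   liability_anx, mood, anx, any_pcnv), `carriers` (logical matrix, one
#'   column per locus), `loci` (config locus table), `thresholds`,
#'   `female_delta`.
#' @export
simulate_liabilities <- function(config, genotypes = NULL, weights = NULL,
                                 G = NULL, population = NULL,
                                 seed = config$seed + 2L) {
  set.seed(seed)
  if (is.null(G)) {
    stopifnot(!is.null(genotypes), !is.null(weights))
    X <- impute_mean(genotypes$dosages)
    w <- weights[match(colnames(X), weights$variant_id), ]
    G <- cbind(X %*% w$weight_mood, X %*% w$weight_anx)
    G <- scale(G)
    population <- genotypes$population
    ids <- genotypes$ids
  } else {
    G <- as.matrix(G)
    stopifnot(ncol(G) == 2L)
    ids <- sprintf("id%06d", seq_len(nrow(G)))
    if (is.null(population)) population <- rep(1L, nrow(G))
  }
  n <- nrow(G)

  loci <- config$pcnv_loci
  carriers <- matrix(FALSE, n, nrow(loci),
                     dimnames = list(ids, loci$locus))
  for (l in seq_len(nrow(loci)))
    carriers[, l] <- stats::runif(n) < loci$frequency[l]
  shift_total <- if (nrow(loci)) as.numeric(carriers %*% loci$shift) else numeric(n)

  female <- stats::runif(n) < 0.5
  age <- sample(40:69, n, replace = TRUE)
  age_term <- config$age_beta * (age - mean(40:69))

  # correlated environmental components
  e1 <- stats::rnorm(n)
  re <- config$env_corr
  e2 <- re * e1 + sqrt(max(0, 1 - re^2)) * stats::rnorm(n)

  base_mood <- sqrt(config$h2_mood) * G[, 1] +
    sqrt(1 - config$h2_mood) * e1 + shift_total + age_term
  base_anx <- sqrt(config$h2_anx) * G[, 2] +
    sqrt(1 - config$h2_anx) * e2 + shift_total + age_term

  sol_mood <- solve_threshold(base_mood, female, config$prevalence_mood,
                              config$female_or)
  sol_anx <- solve_threshold(base_anx, female, config$prevalence_anx,
                             config$female_or)

  tab <- data.frame(
    id = ids, female = female, age = age, population = population,
    G_mood = G[, 1], G_anx = G[, 2],
    liability_mood = sol_mood$liability, liability_anx = sol_anx$liability,
    mood = sol_mood$case, anx = sol_anx$case,
    any_pcnv = rowSums(carriers) > 0,
    stringsAsFactors = FALSE)
  structure(list(table = tab, carriers = carriers, loci = loci,
                 thresholds = c(mood = sol_mood$threshold,
                                anx = sol_anx$threshold),
                 female_delta = c(mood = sol_mood$delta,
                                  anx = sol_anx$delta)),
            class = "latent_state")
}

# Solve the female liability offset and threshold jointly: the threshold is
# the empirical quantile fixing the overall prevalence exactly, and the
# offset is tuned so the female/male prevalence odds ratio hits the target.
solve_threshold <- function(base, female, prevalence, female_or) {
  n <- length(base)
  n_case <- max(1L, round(n * prevalence))
  case_at <- function(delta) {
    liab <- base + delta * female
    thr <- sort(liab, decreasing = TRUE)[n_case]
    list(liab = liab, thr = thr, case = liab >= thr)
  }
  or_gap <- function(delta) {
    cs <- case_at(delta)$case
    pf <- mean(cs[female]); pm <- mean(cs[!female])
    if (pm <= 0 || pm >= 1 || pf <= 0 || pf >= 1) return(sign(delta) * 10)
    log(pf / (1 - pf)) - log(pm / (1 - pm)) - log(female_or)
  }
  delta <- if (abs(log(female_or)) < 1e-12) 0 else
    stats::uniroot(or_gap, lower = -2, upper = 2, extendInt = "upX",
                   tol = 1e-4)$root
  fin <- case_at(delta)
  list(liability = fin$liab, threshold = fin$thr, case = fin$case,
       delta = delta)
}

#' @export
print.latent_state <- function(x, ...) {
  tb <- x$table
  cat(sprintf(
    "Latent state: n=%d, prevalence mood %.3f / anxiety %.3f, P-CNV carriers %.2f%%\n",
    nrow(tb), mean(tb$mood), mean(tb$anx), 100 * mean(tb$any_pcnv)))
  invisible(x)
}
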