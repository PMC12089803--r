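# Balding-Nichols genotype simulation ---------------------------------------

#' Simulate a genotype dosage matrix under population divergence
#'
#' Ancestral allele frequencies are drawn uniformly from `maf_range`;
#' population-specific frequencies follow a Balding-Nichols beta model with
#' divergence parameter `fst` (at `fst = 0` every population shares the
#' ancestral frequency).  Dosages are binomial(2, p).  A small configurable
#' fraction of variants is made to fail each downstream QC filter (low INFO
#' score, high missingness, low MAF, Hardy-Weinberg departure through excess
#' homozygosity) so that quality control has realistic work to do.
#'
#' @param config a [sim_config()].
#' @param n number of individuals (defaults to `config$n_individuals`);
#'   override to draw, e.g., an external reference panel.
#' @param population optional integer vector of population memberships; by
#'   default drawn from `config$pop_weights`.
#' @param freq optional `n_populations x n_variants` matrix of allele
#'   frequencies to reuse (so a reference panel shares the cohort's
#'   frequencies); by default drawn fresh.
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `genotype_matrix`: list with `dosages` (integer
#'   matrix, NA = missing), `variants` (data.frame: variant_id, position,
#'   effect_allele, other_allele, info, ancestral_freq, plus per-population
#'   freq columns), `ids`, `population`.
#' @export
simulate_genotypes <- function(config, n = config$n_individuals,
                               population = NULL, freq = NULL,
                               seed = config$seed) {
  set.seed(seed)
  m <- config$n_variants
  k <- config$n_populations
  if (is.null(population))
    population <- sample.int(k, n, replace = TRUE, prob = config$pop_weights)
  stopifnot(length(population) == n, all(population %in% seq_len(k)))

  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  rare <- stats::runif(m) < config$frac_rare
  p_anc[rare] <- stats::runif(sum(rare), 0.001, 0.009)

  if (is.null(freq)) {
    if (config$fst > 0) {
      a <- p_anc * (1 - config$fst) / config$fst
      b <- (1 - p_anc) * (1 - config$fst) / config$fst
      freq <- matrix(stats::rbeta(k * m, rep(a, each = k), rep(b, each = k)),
                     nrow = k)
      freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
    } else {
      freq <- matrix(rep(p_anc, each = k), nrow = k)
    }
  } else {
    stopifnot(nrow(freq) == k, ncol(freq) == m)
    p_anc <- colMeans(freq)
  }

  hwe_bad <- stats::runif(m) < config$frac_hwe_fail
  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    pj <- freq[population, j]
    if (hwe_bad[j]) {
      # inbreeding-like excess homozygosity (F = 0.6)
      hom <- stats::runif(n) < 0.6
      g <- integer(n)
      g[hom] <- 2L * stats::rbinom(sum(hom), 1L, pj[hom])
      g[!hom] <- stats::rbinom(sum(!hom), 2L, pj[!hom])
      dos[, j] <- g
    } else {
      dos[, j] <- stats::rbinom(n, 2L, pj)
    }
  }

  info <- stats::runif(m, 0.95, 1)
  low_info <- stats::runif(m) < config$frac_low_info
  info[low_info] <- stats::runif(sum(low_info), 0.5, 0.89)

  miss_rate <- stats::runif(m, 0, 0.02)
  high_miss <- stats::runif(m) < config$frac_high_missing
  miss_rate[high_miss] <- stats::runif(sum(high_miss), 0.06, 0.2)
  n_miss <- stats::rbinom(m, n, miss_rate)
  for (j in which(n_miss > 0))
    dos[sample.int(n, n_miss[j]), j] <- NA_integer_

  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, m, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(alleles, x), 1L), character(1))
  variants <- data.frame(
    variant_id = sprintf("var%05d", seq_len(m)),
    position = seq_len(m) * 1000L,
    effect_allele = a1, other_allele = a2,
    info = info, ancestral_freq = p_anc,
    stringsAsFactors = FALSE)
  for (pk in seq_len(k)) variants[[paste0("freq_pop", pk)]] <- freq[pk, ]

  ids <- sprintf("id%06d", seq_len(n))
  dimnames(dos) <- list(ids, variants$variant_id)
  structure(list(dosages = dos, variants = variants, ids = ids,
                 population = population, freq = freq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$ids), "individuals x",
      nrow(x$variants), "variants,", length(unique(x$population)),
      "population(s)\n")
  invisible(x)
}

#' Simulate per-variant effect weights for two genetically correlated traits
#'
#' Per-variant effects for the mood and anxiety liabilities are drawn from a
#' bivariate normal with correlation `config$r_genetic`, standing in for
#' GWAS-derived posterior effect sizes.
#'
#' @param config a [sim_config()].
#' @param variants variant table from [simulate_genotypes()].
#' @param seed integer seed.
#' @return data.frame: variant_id, effect_allele, weight_mood, weight_anx.
#' @export
simulate_weights <- function(config, variants, seed = config$seed + 1L) {
  set.seed(seed)
  m <- nrow(variants)
  r <- config$r_genetic
  b1 <- stats::rnorm(m)
  b2 <- r * b1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(m)
  data.frame(variant_id = variants$variant_id,
             effect_allele = variants$effect_allele,
             weight_mood = b1 / sqrt(m), weight_anx = b2 / sqrt(m),
             stringsAsFactors = FALSE)
}
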