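# Variant and sample quality control ----------------------------------------

#' Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts (full enumeration of the conditional distribution) for sample
#' sizes up to `exact_limit`; above that, the usual 1-df chi-square
#' goodness-of-fit approximation.  Monomorphic variants return p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectors accepted).
#' @param exact_limit largest sample size for the exact test (default
#'   1000).
#' @return vector of p-values.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, exact_limit = 1000L) {
  mapply(function(aa, ab, bb) {
    if (is.na(aa) || is.na(ab) || is.na(bb)) return(NA_real_)
    n <- aa + ab + bb
    if (n == 0L) return(NA_real_)
    na <- 2L * aa + ab
    nb <- 2L * bb + ab
    if (na == 0L || nb == 0L) return(1)  # monomorphic
    if (n <= exact_limit) hwe_exact_p(aa, ab, bb) else hwe_chisq_p(aa, ab, bb)
  }, n_aa, n_ab, n_bb)
}

# Exact test: enumerate P(het = k | allele counts) over all feasible k with
# the standard ratio recurrence, then sum probabilities <= observed.
hwe_exact_p <- function(aa, ab, bb) {
  n <- aa + ab + bb
  rare <- min(2L * aa + ab, 2L * bb + ab)  # rare allele count
  k_vals <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- numeric(length(k_vals))
  for (i in seq_along(k_vals)[-1]) {
    k <- k_vals[i]
    # P(k)/P(k-2) = 4 * n_rare_hom(k-2) * n_common_hom(k-2) / (k * (k-1))
    hr <- (rare - (k - 2L)) / 2L
    hc <- n - (k - 2L) - hr
    logp[i] <- logp[i - 1] + log(4 * hr * hc) - log(k) - log(k - 1)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(k_vals == ab)
  sum(p[p <= p[obs] + 1e-12])
}

hwe_chisq_p <- function(aa, ab, bb) {
  n <- aa + ab + bb
  p <- (2 * aa + ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(aa, ab, bb) - e)^2 / e)
  stats::pchisq(x2, df = 1L, lower.tail = FALSE)
}

#' Variant quality control
#'
#' Retains a variant iff INFO score >= `info_min`, missingness <=
#' `miss_max`, minor allele frequency >= `maf_min` and Hardy-Weinberg
#' p-value >= `hwe_p_min` (computed on hard-called genotypes).  Defaults
#' match the standard imputation-era filters: INFO < 0.9, missingness >
#' 0.05, MAF < 0.01 and HWE p < 1e-6 are removed.
#'
#' @param genotypes a `genotype_matrix`.
#' @param info_min,miss_max,maf_min,hwe_p_min thresholds.
#' @return list with `keep` (variant ids retained), `report` (counts
#'   removed per filter) and `stats` (per-variant maf/missingness/hwe_p).
#' @export
variant_qc <- function(genotypes, info_min = 0.9, miss_max = 0.05,
                       maf_min = 0.01, hwe_p_min = 1e-6) {
  dos <- genotypes$dosages
  miss <- colMeans(is.na(dos))
  p_hat <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  hard <- round(dos)
  n_aa <- colSums(hard == 2, na.rm = TRUE)
  n_ab <- colSums(hard == 1, na.rm = TRUE)
  n_bb <- colSums(hard == 0, na.rm = TRUE)
  hwe_p <- hwe_test(n_aa, n_ab, n_bb)
  info <- genotypes$variants$info

  fail_info <- info < info_min
  fail_miss <- miss > miss_max
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_p_min
  keep <- !(fail_info | fail_miss | fail_maf | fail_hwe)
  list(keep = genotypes$variants$variant_id[keep],
       report = c(n_input = length(keep), n_retained = sum(keep),
                  low_info = sum(fail_info), high_missingness = sum(fail_miss),
                  low_maf = sum(fail_maf), hwe_departure = sum(fail_hwe)),
       stats = data.frame(variant_id = genotypes$variants$variant_id,
                          maf = maf, missingness = miss, hwe_p = hwe_p,
                          info = info, stringsAsFactors = FALSE))
}

#' Remove one individual at random from each related pair
#'
#' Given a pairwise kinship table, repeatedly picks a pair above the
#' threshold and removes one member at random, until no remaining pair
#' exceeds the threshold.  The default threshold 0.0884 flags
#' second-degree or closer relatives on the KING scale.
#'
#' @param kinship data.frame `id1`, `id2`, `kinship`.
#' @param threshold relatedness threshold (pairs strictly above are split).
#' @param seed integer seed for the random choice.
#' @return character vector of removed ids.
#' @export
relatedness_prune <- function(kinship, threshold = 0.0884, seed = 1L) {
  if (!nrow(kinship)) return(character())
  set.seed(seed)
  edges <- kinship[kinship$kinship > threshold, c("id1", "id2")]
  removed <- character()
  while (nrow(edges)) {
    pair <- edges[1L, ]
    drop <- if (stats::runif(1) < 0.5) pair$id1 else pair$id2
    removed <- c(removed, drop)
    edges <- edges[edges$id1 != drop & edges$id2 != drop, , drop = FALSE]
  }
  removed
}

#' Sliding-window LD pruning
#'
#' Greedy pruning in windows of `window` variants advanced by `step`
#' (position order): within a window, while any retained pair has squared
#' correlation above `r2_max`, the member of the worst pair with the
#' greater missingness is removed (ties broken by removing the later
#' position).
#'
#' @param genotypes a `genotype_matrix`.
#' @param window window size in variants (default 500).
#' @param step window step in variants (default 50).
#' @param r2_max squared-correlation threshold (default 0.05).
#' @param variant_ids optional subset of variants to prune within.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, window = 500L, step = 50L, r2_max = 0.05,
                     variant_ids = NULL) {
  vs <- genotypes$variants
  ids <- variant_ids %||% vs$variant_id
  ord <- order(vs$position[match(ids, vs$variant_id)])
  ids <- ids[ord]
  m <- length(ids)
  dos <- impute_mean(genotypes$dosages[, ids, drop = FALSE])
  missingness <- colMeans(is.na(genotypes$dosages[, ids, drop = FALSE]))
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) > 1L) {
      cc <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE]))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      diag(r2) <- 0
      while (max(r2) > r2_max) {
        w <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
        a <- idx[w[1L]]; b <- idx[w[2L]]
        drop <- if (missingness[a] > missingness[b]) a
        else if (missingness[b] > missingness[a]) b
        else max(a, b)  # tie: later position
        keep[drop] <- FALSE
        di <- which(idx == drop)
        r2[di, ] <- 0; r2[, di] <- 0
      }
    }
    if (end >= m) break
    start <- start + step
  }
  ids[keep]
}
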