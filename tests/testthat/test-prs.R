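# Build a small genotype_matrix by hand.
toy_genotypes <- function(dos, info = rep(1, ncol(dos)),
                          effect = rep("A", ncol(dos)),
                          other = rep("G", ncol(dos)),
                          position = seq_len(ncol(dos))) {
  ids <- sprintf("s%03d", seq_len(nrow(dos)))
  vid <- sprintf("v%03d", seq_len(ncol(dos)))
  dimnames(dos) <- list(ids, vid)
  structure(list(
    dosages = dos,
    variants = data.frame(variant_id = vid, position = position,
                          effect_allele = effect, other_allele = other,
                          info = info, ancestral_freq = colMeans(dos) / 2,
                          stringsAsFactors = FALSE),
    ids = ids, population = rep(1L, nrow(dos))), class = "genotype_matrix")
}

test_that("HWE exact test matches full-enumeration oracle and boundaries", {
  cases <- list(c(50, 0, 50), c(25, 50, 25), c(3, 5, 2), c(10, 1, 10),
                c(0, 2, 98), c(40, 20, 40))
  for (cc in cases)
    expect_equal(hwe_test(cc[1], cc[2], cc[3]),
                 oracle_hwe_exact(cc[1], cc[2], cc[3]), tolerance = 1e-10,
                 label = paste(cc, collapse = "/"))
  # extreme homozygote excess fails the usual 1e-6 filter
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  # perfect Hardy-Weinberg proportions at p = 0.5 are retained
  expect_gt(hwe_test(25, 50, 25), 0.5)
  # monomorphic variants get p = 1
  expect_equal(hwe_test(100, 0, 0), 1)
  # large-sample chi-square branch agrees with the exact test direction
  expect_lt(hwe_test(5000, 0, 5000), 1e-6)
})

test_that("variant QC applies the standard imputation-era filters", {
  set.seed(1)
  n <- 400
  dos <- cbind(
    rbinom(n, 2, 0.3),                       # clean
    rbinom(n, 2, 0.3),                       # low info
    rbinom(n, 2, 0.3),                       # high missingness
    rbinom(n, 2, 0.004),                     # rare
    2L * rbinom(n, 1, 0.5))                  # extreme HWE departure
  dos[sample(n, 40), 3] <- NA
  g <- toy_genotypes(dos, info = c(1, 0.89, 1, 1, 1))
  qc <- variant_qc(g)
  expect_identical(qc$keep, "v001")
  expect_equal(unname(qc$report[c("low_info", "high_missingness",
                                  "low_maf", "hwe_departure")]),
               c(1, 1, 1, 1))
  # thresholds at their extremes retain everything
  qc_all <- variant_qc(g, info_min = 0, miss_max = 1, maf_min = 0,
                       hwe_p_min = 0)
  expect_equal(length(qc_all$keep), 5L)
})

test_that("relatedness pruning removes one member per pair until clique-free", {
  expect_identical(relatedness_prune(
    data.frame(id1 = "a", id2 = "b", kinship = 0.05)), character())
  one <- relatedness_prune(
    data.frame(id1 = "a", id2 = "b", kinship = 0.2), seed = 3)
  expect_length(one, 1)
  expect_true(one %in% c("a", "b"))
  tri <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                    kinship = 0.25)
  for (s in 1:10) {
    rm <- relatedness_prune(tri, seed = s)
    expect_gte(length(rm), 2)
    left <- tri[!(tri$id1 %in% rm | tri$id2 %in% rm), ]
    expect_equal(nrow(left), 0)
  }
})

test_that("PRS scoring handles weights, allele flips and variant order", {
  dos <- cbind(c(0, 1, 2), c(2, 2, 0), c(1, 0, 1))
  g <- toy_genotypes(dos)
  w0 <- data.frame(variant_id = c("v001", "v002", "v003"),
                   effect_allele = "A", weight = 0)
  expect_equal(as.numeric(score_prs(g, w0)), c(0, 0, 0))
  w1 <- data.frame(variant_id = "v001", effect_allele = "A", weight = 1)
  expect_equal(as.numeric(score_prs(g, w1)), c(0, 1, 2))
  # recoding a variant to the other allele leaves the PRS unchanged
  w <- data.frame(variant_id = c("v001", "v002", "v003"),
                  effect_allele = "A", weight = c(0.5, -1, 2))
  base <- score_prs(g, w)
  g_flip <- g
  g_flip$dosages[, 2] <- 2L - g_flip$dosages[, 2]
  g_flip$variants$effect_allele[2] <- "G"
  g_flip$variants$other_allele[2] <- "A"
  flipped <- score_prs(g_flip, w)
  expect_equal(as.numeric(flipped), as.numeric(base))
  expect_equal(attr(flipped, "n_flipped"), 1)
  # weight-table row order is irrelevant
  expect_equal(as.numeric(score_prs(g, w[c(3, 1, 2), ])), as.numeric(base))
  # unmatched alleles are dropped, zero overlap errors
  w_bad <- data.frame(variant_id = "v001", effect_allele = "T", weight = 1)
  expect_error(score_prs(g, w_bad), "allele-matched")
  w_none <- data.frame(variant_id = "zzz", effect_allele = "A", weight = 1)
  expect_error(score_prs(g, w_none), "overlapping")
})

test_that("missing dosages are mean-imputed in scoring", {
  dos <- cbind(c(0L, 2L, NA), c(1L, 1L, 1L))
  g <- toy_genotypes(dos)
  w <- data.frame(variant_id = c("v001", "v002"), effect_allele = "A",
                  weight = c(1, 1))
  expect_equal(as.numeric(score_prs(g, w)), c(1, 3, 2))
})

test_that("LD pruning matches the brute-force oracle on toy data", {
  set.seed(14)
  x <- rbinom(60, 2, 0.5)
  dos <- cbind(x, x, rbinom(60, 2, 0.5))
  g <- toy_genotypes(dos)
  kept <- ld_prune(g, window = 10, step = 5, r2_max = 0.05)
  expect_length(intersect(kept, c("v001", "v002")), 1)
  expect_true("v003" %in% kept)

  set.seed(15)
  base <- matrix(rbinom(80 * 4, 2, 0.4), 80, 4)
  dos10 <- cbind(base,
                 base + matrix(rbinom(80 * 4, 1, 0.1), 80, 4),
                 matrix(rbinom(80 * 2, 2, 0.4), 80, 2))
  dos10 <- pmin(dos10, 2)
  g10 <- toy_genotypes(dos10)
  kept <- ld_prune(g10, window = 10, step = 5, r2_max = 0.05)
  ora <- oracle_ld_prune(g10$dosages, rep(0, 10), 0.05)
  expect_identical(kept, g10$variants$variant_id[ora])

  # mutually uncorrelated variants are all retained
  set.seed(16)
  du <- matrix(rbinom(500 * 6, 2, 0.5), 500, 6)
  gu <- toy_genotypes(du)
  if (max((suppressWarnings(cor(du))^2 - diag(6))) < 0.05)
    expect_length(ld_prune(gu, window = 6, step = 3, r2_max = 0.05), 6)
})

test_that("reference PCA is deterministic and projection is consistent", {
  cfg <- sim_config(n_individuals = 600, n_variants = 120, fst = 0.15,
                    pop_weights = c(0.5, 0.5), frac_high_missing = 0,
                    seed = 51)
  g <- simulate_genotypes(cfg)
  expect_error(reference_pca(g, k = 0), "k must be")
  model <- reference_pca(g, k = 5)
  # reprojection of the reference reproduces its own scores
  expect_equal(project_samples(g, model), model$scores, tolerance = 1e-8)
  # PC1 separates the populations
  r <- cor(model$scores[, 1], as.numeric(g$population == 1))
  expect_gt(abs(r), 0.9)
  # a target individual identical to a reference individual scores identically
  sub <- g
  sub$dosages <- g$dosages[7, , drop = FALSE]
  sub$ids <- g$ids[7]
  sub$population <- g$population[7]
  expect_equal(as.numeric(project_samples(sub, model)),
               as.numeric(model$scores[7, ]), tolerance = 1e-8)
  # missing model variants are reported
  g_missing <- g
  g_missing$dosages <- g$dosages[, -(1:5)]
  g_missing$variants <- g$variants[-(1:5), ]
  expect_error(project_samples(g_missing, model), "lack model variants")
})

test_that("ancestry adjustment standardises the reference and removes population shifts", {
  cfg <- sim_config(n_individuals = 4000, n_variants = 400, fst = 0.15,
                    pop_weights = c(0.5, 0.5), seed = 61)
  g <- simulate_genotypes(cfg)
  w <- simulate_weights(cfg, g$variants)
  prs <- score_prs(g, data.frame(variant_id = w$variant_id,
                                 effect_allele = w$effect_allele,
                                 weight = w$weight_mood))
  model <- reference_pca(g, k = 5, variant_ids = ld_prune(g))
  adj <- ancestry_adjust(prs, model$scores, k = 5)
  expect_lt(abs(mean(adj$adjusted)), 1e-10)
  expect_lt(abs(var(adj$adjusted) - 1), 1e-6)
  for (pop in 1:2) {
    expect_lt(abs(mean(adj$adjusted[g$population == pop])), 0.05)
    expect_lt(abs(var(adj$adjusted[g$population == pop]) - 1), 0.1)
  }
  # raw PRS, by contrast, separates populations
  raw_gap <- abs(mean(scale(prs)[g$population == 1]) -
                   mean(scale(prs)[g$population == 2]))
  expect_gt(raw_gap, 4 * abs(mean(adj$adjusted[g$population == 1]) -
                               mean(adj$adjusted[g$population == 2])))
  # PCs exactly uncorrelated with the PRS: adjustment reduces to z-scoring
  set.seed(5)
  prs_r <- rnorm(500)
  pcs_r <- matrix(rnorm(500 * 5), 500, 5)
  pcs_r <- residuals(lm(pcs_r ~ prs_r))  # enforce zero correlation
  adj_r <- ancestry_adjust(prs_r, pcs_r, k = 5)
  expect_equal(adj_r$adjusted, as.numeric(scale(prs_r)), tolerance = 1e-8)
  expect_error(ancestry_adjust(rnorm(4), matrix(rnorm(20), 4, 5), k = 5),
               "too small")
  # literal variance scaling is available
  adj_v <- ancestry_adjust(prs_r, pcs_r, k = 5, scale = "variance")
  expect_equal(adj_v$adjusted * adj_v$residual_sd, adj_r$adjusted)
})
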