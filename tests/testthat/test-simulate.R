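test_that("genotype generator is seed-reproducible and respects divergence", {
  cfg <- sim_config(n_individuals = 300, n_variants = 80, seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosages >= 0 & g1$dosages <= 2, na.rm = TRUE))

  cfg0 <- sim_config(n_individuals = 200, n_variants = 50, fst = 0,
                     seed = 5)
  g0 <- simulate_genotypes(cfg0)
  expect_equal(max(abs(g0$freq[1, ] - g0$freq[2, ])), 0)

  # fst = 0.1: the leading PC separates the two populations
  cfgd <- sim_config(n_individuals = 2000, n_variants = 500, fst = 0.1,
                     pop_weights = c(0.5, 0.5), frac_rare = 0,
                     frac_high_missing = 0, seed = 9)
  gd <- simulate_genotypes(cfgd)
  pca <- reference_pca(gd, k = 2)
  r <- cor(pca$scores[, 1], as.numeric(gd$population == 1L))
  expect_gt(abs(r), 0.9)
})

test_that("generator configuration is validated", {
  expect_error(sim_config(fst = 0.5), "fst")
  expect_error(sim_config(maf_range = c(0.2, 0.1)), "maf_range")
  expect_error(sim_config(prevalence_mood = 0), "prevalence_mood")
  expect_error(sim_config(h2_mood = 1), "h2_mood")
  # h2 + carrier liability variance must stay below 1
  loci <- data.frame(locus = "L", type = "deletion", frequency = 0.5,
                     shift = 2)
  expect_error(sim_config(h2_mood = 0.5, pcnv_loci = loci), "variance")
})

test_that("liability model matches prevalence, female bias and carrier risk", {
  loci <- transform(default_pcnv_loci()[1:3, ], frequency = frequency * 20)
  cfg <- sim_config(n_individuals = 20000, n_variants = 50,
                    pcnv_loci = loci, seed = 3)
  set.seed(31)
  G <- matrix(rnorm(2 * cfg$n_individuals), ncol = 2)
  lat <- simulate_liabilities(cfg, G = G)
  tb <- lat$table
  se_m <- sqrt(0.2 * 0.8 / nrow(tb))
  expect_lt(abs(mean(tb$mood) - 0.20), 3 * se_m)
  expect_lt(abs(mean(tb$anx) - 0.15), 3 * sqrt(0.15 * 0.85 / nrow(tb)))
  # carriers run a higher disorder risk
  expect_gt(mean(tb$mood[tb$any_pcnv]), mean(tb$mood[!tb$any_pcnv]))
  # female-biased prevalence close to the configured odds ratio
  orf <- (mean(tb$mood[tb$female]) / (1 - mean(tb$mood[tb$female]))) /
    (mean(tb$mood[!tb$female]) / (1 - mean(tb$mood[!tb$female])))
  expect_gt(orf, 1.4)
  expect_lt(orf, 2.3)
})

test_that("fully shared liabilities give identical disorder indicators", {
  cfg <- sim_config(n_individuals = 3000, n_variants = 50, r_genetic = 1,
                    h2_mood = 0.3, h2_anx = 0.3, env_corr = 1,
                    pcnv_loci = default_pcnv_loci(0),
                    prevalence_mood = 0.2, prevalence_anx = 0.2, seed = 13)
  set.seed(77)
  g <- rnorm(cfg$n_individuals)
  lat <- simulate_liabilities(cfg, G = cbind(g, g))
  expect_identical(lat$table$mood, lat$table$anx)
})

test_that("record sources honour availability and MHQ carrier uptake", {
  loci <- transform(default_pcnv_loci()[1:2, ], frequency = c(0.15, 0.15))
  cfg <- sim_config(n_individuals = 20000, n_variants = 50,
                    pcnv_loci = loci, seed = 21)
  set.seed(8)
  lat <- simulate_liabilities(cfg, G = matrix(rnorm(2 * 20000), ncol = 2))
  rec <- simulate_records(lat, cfg)
  av <- rec$availability
  # MHQ completion near the configured non-carrier rate
  expect_lt(abs(mean(av$mhq[!lat$table$any_pcnv]) - 0.3161), 0.02)
  # carriers complete the MHQ less often, near the configured ratio
  comp <- mhq_completion(rec, lat$table$any_pcnv)
  expect_lt(comp$pct[comp$group == "carrier"],
            comp$pct[comp$group == "non_carrier"])
  ratio <- comp$pct[comp$group == "carrier"] /
    comp$pct[comp$group == "non_carrier"]
  expect_lt(abs(ratio - cfg$mhq_uptake_pcnv_ratio), 0.08)
  expect_lt(abs(mean(av$primary_care) - 0.40), 0.02)
})

test_that("perfect observation reproduces latent truth on available samples", {
  cfg <- perfect_config(n = 3000, seed = 19)
  co <- simulate_cohort(cfg)
  truth <- co$latent$table
  flags <- derive_definitions(co$records, co$code_lists)
  attainable <- list(
    c("initial_self_report", "mood"), c("initial_self_report", "anxiety"),
    c("medication_self_report", "mood"), c("minimal", "mood"),
    c("minimal", "anxiety"), c("cidi_sf", "mood"), c("cidi_sf", "anxiety"),
    c("mhq_self_report", "mood"), c("mhq_self_report", "anxiety"),
    c("hospital", "mood"), c("hospital", "anxiety"),
    c("primary_care", "mood"), c("primary_care", "anxiety"))
  for (spec_pair in attainable) {
    st <- status_of(flags, spec_pair[1], spec_pair[2])
    tr <- truth[[if (spec_pair[2] == "mood") "mood" else "anx"]][
      match(names(st), truth$id)]
    obs <- st != "missing"
    expect_identical(unname(st[obs] == "case"), tr[obs],
                     label = paste(spec_pair, collapse = "/"))
  }
  # help-seeking equals the internalising truth for every disorder label
  for (dis in c("mood", "anxiety", "internalising")) {
    st <- status_of(flags, "help_seeking", dis)
    tr <- (truth$mood | truth$anx)[match(names(st), truth$id)]
    expect_identical(unname(st == "case"), tr)
  }
})

test_that("tetrachoric correlation of true disorders recovers the liability correlation", {
  rho <- 0.5
  cfg <- sim_config(n_individuals = 50000, n_variants = 50, h2_mood = 0,
                    h2_anx = 0, env_corr = rho, female_or = 1,
                    age_beta = 0, pcnv_loci = default_pcnv_loci(0),
                    seed = 23)
  set.seed(99)
  lat <- simulate_liabilities(cfg, G = matrix(rnorm(2 * 50000), ncol = 2))
  tb <- lat$table
  tab <- table(factor(!tb$mood, levels = c(FALSE, TRUE)),
               factor(!tb$anx, levels = c(FALSE, TRUE)))
  est <- tetrachoric(matrix(as.numeric(tab), 2, 2))
  expect_lt(abs(est - rho), 0.05)
})

test_that("CNV call simulation is deterministic and linked to carriers", {
  loci <- transform(default_pcnv_loci()[1:3, ], frequency = frequency * 30)
  cfg <- sim_config(n_individuals = 2000, n_variants = 50,
                    pcnv_loci = loci, cnv_call_fail_rate = 0,
                    cnv_sample_fail_rate = 0, seed = 37)
  set.seed(4)
  lat <- simulate_liabilities(cfg, G = matrix(rnorm(4000), ncol = 2))
  cnv1 <- simulate_cnv_calls(lat, cfg)
  cnv2 <- simulate_cnv_calls(lat, cfg)
  expect_identical(cnv1$calls, cnv2$calls)
  expect_identical(cnv1$samples, cnv2$samples)
  # with all-pass settings, QC + carrier derivation reproduces the truth
  sqc <- qc_cnv_samples(cnv1$samples)
  expect_true(all(sqc$pass))
  cqc <- qc_cnv_calls(cnv1$calls)
  expect_equal(unname(cqc$report["n_retained"]), nrow(cnv1$calls))
  cs <- carrier_status(cqc$retained, lat$table$id,
                       loci[, c("locus", "type")], min_observations = 1L)
  for (loc in loci$locus)
    expect_identical(cs$table[[loc]], unname(lat$carriers[, loc]))
})
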