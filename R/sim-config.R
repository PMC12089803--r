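#' Default psychiatric-risk CNV locus table
#'
#' A small panel of named recurrent CNV loci with population carrier
#' frequencies and liability-scale effects, emulating the class of rare
#' deletions/duplications previously associated with psychiatric morbidity.
#' Carrier frequencies sum to roughly 1.6% of the cohort, matching the
#' order of magnitude seen in large biobanks.
#'
#' @param n_loci number of loci (default 10; the first `n_loci` rows of the
#'   built-in panel are used).
#' @return data.frame with columns `locus`, `type` ("deletion" or
#'   "duplication"), `frequency` (carrier probability) and `shift`
#'   (liability-scale increment for carriers).
#' @export
default_pcnv_loci <- function(n_loci = 10L) {
  panel <- data.frame(
    locus = c("1q21.1", "2p16.3", "15q11.2", "15q13.3", "16p11.2",
              "16p13.11", "17p12", "17q12", "22q11.2", "3q29"),
    type = c("deletion", "deletion", "deletion", "deletion", "duplication",
             "duplication", "deletion", "deletion", "duplication", "deletion"),
    frequency = c(0.0020, 0.0012, 0.0045, 0.0015, 0.0020,
                  0.0020, 0.0008, 0.0008, 0.0007, 0.0003),
    shift = c(0.40, 0.45, 0.30, 0.40, 0.35, 0.30, 0.30, 0.40, 0.50, 0.50),
    stringsAsFactors = FALSE)
  if (n_loci < 0L || n_loci > nrow(panel))
    stop_config("n_loci must be between 0 and ", nrow(panel))
  panel[seq_len(n_loci), , drop = FALSE]
}

#' Default observation model (sensitivity/specificity per definition)
#'
#' One row per (definition, disorder): the probability that an individual
#' with (sensitivity) / without (specificity complement) the true disorder
#' generates a qualifying record in that source.  Values are chosen to
#' reproduce the broad prevalence spread observed across definition types:
#' help-seeking is common and unspecific, hospital admission records are
#' rare and highly specific, questionnaire instruments sit in between.
#'
#' @return data.frame with columns `definition`, `disorder`, `sensitivity`,
#'   `specificity`.
#' @export
default_observation_model <- function() {
  defs <- definition_names()
  grid <- expand.grid(definition = defs, disorder = c("mood", "anxiety"),
                      stringsAsFactors = FALSE)
  sens <- c(initial_self_report = 0.35, medication_self_report = 0.30,
            help_seeking = 0.75, minimal = 0.55, cidi_sf = 0.70,
            mhq_self_report = 0.65, hospital = 0.08, primary_care = 0.45)
  spec <- c(initial_self_report = 0.995, medication_self_report = 0.985,
            help_seeking = 0.80, minimal = 0.95, cidi_sf = 0.95,
            mhq_self_report = 0.96, hospital = 0.999, primary_care = 0.97)
  grid$sensitivity <- unname(sens[grid$definition])
  grid$specificity <- unname(spec[grid$definition])
  grid
}

#' Names of the eight phenotype definitions
#' @return character vector of length 8.
#' @export
definition_names <- function() {
  c("initial_self_report", "medication_self_report", "help_seeking",
    "minimal", "cidi_sf", "mhq_self_report", "hospital", "primary_care")
}

#' Simulation configuration for the synthetic biobank
#'
#' Collects every knob of the generative model: a Balding-Nichols genotype
#' model over `n_populations` ancestral groups, a liability-threshold model
#' for correlated mood and anxiety disorders with a shared polygenic
#' component and rare CNV carrier effects, per-source availability of the
#' phenotype record sources, and an observation model linking latent
#' disorder to raw records.
#'
#' Defaults describe a European-majority middle-aged volunteer cohort:
#' 94%/6% population split, recruitment ages 40-69, female-biased
#' prevalence (odds ratio 1.8), latent lifetime prevalences 20% (mood) and
#' 15% (anxiety), genetic correlation 0.8 between the disorders, online
#' mental-health questionnaire completed by 31.61% of non-carriers with
#' carrier uptake scaled by 0.2616/0.3161, and primary-care linkage for 40%
#' of the cohort.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of simulated variants.
#' @param n_populations number of ancestral populations.
#' @param pop_weights population mixing proportions (recycled/normalised).
#' @param fst Balding-Nichols divergence parameter in [0, 0.3].
#' @param maf_range ancestral allele-frequency range (pair in (0, 0.5]).
#' @param h2_mood,h2_anx liability variance captured by the polygenic score.
#' @param r_genetic correlation of the per-variant effects for the two
#'   disorders.
#' @param env_corr correlation of the environmental liability components.
#' @param pcnv_loci data.frame as [default_pcnv_loci()].
#' @param prevalence_mood,prevalence_anx target population prevalences.
#' @param female_or female/male prevalence odds ratio.
#' @param age_beta liability increment per year of age (centred).
#' @param source_availability named list of coverage fractions; `mhq` is the
#'   completion rate for non-carriers.
#' @param observation_model data.frame as [default_observation_model()].
#' @param mhq_uptake_pcnv_ratio relative MHQ completion, carriers vs
#'   non-carriers.
#' @param exclusion_rate fraction of the cohort with a schizophrenia or
#'   bipolar disorder record (excluded downstream).
#' @param frac_low_info,frac_high_missing,frac_rare,frac_hwe_fail fractions
#'   of variants simulated to fail each genotype QC filter.
#' @param cnv_call_fail_rate fraction of CNV calls drawn with QC-failing
#'   call metrics; `cnv_sample_fail_rate` likewise for per-sample metrics.
#' @param seed integer seed; fixing it makes every output byte-identical.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 50000L,
                       n_variants = 2000L,
                       n_populations = 2L,
                       pop_weights = c(0.94, 0.06),
                       fst = 0.1,
                       maf_range = c(0.05, 0.5),
                       h2_mood = 0.05,
                       h2_anx = 0.05,
                       r_genetic = 0.8,
                       env_corr = 0.5,
                       pcnv_loci = default_pcnv_loci(),
                       prevalence_mood = 0.20,
                       prevalence_anx = 0.15,
                       female_or = 1.8,
                       age_beta = 0.01,
                       source_availability = list(touchscreen = 1.0,
                                                  interview = 1.0,
                                                  mhq = 0.3161,
                                                  primary_care = 0.40,
                                                  hospital = 1.0),
                       observation_model = default_observation_model(),
                       mhq_uptake_pcnv_ratio = 0.2616 / 0.3161,
                       exclusion_rate = 0.0085,
                       frac_low_info = 0.02,
                       frac_high_missing = 0.02,
                       frac_rare = 0.02,
                       frac_hwe_fail = 0.01,
                       cnv_call_fail_rate = 0.05,
                       cnv_sample_fail_rate = 0.02,
                       seed = 1L) {
  if (n_individuals < 1 || n_variants < 1 || n_populations < 1)
    stop_config("n_individuals, n_variants and n_populations must be positive")
  if (!is.numeric(fst) || fst < 0 || fst > 0.3)
    stop_config("fst must lie in [0, 0.3]")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must be an increasing pair in (0, 0.5]")
  for (nm in c("h2_mood", "h2_anx"))
    if (get(nm) < 0 || get(nm) >= 1) stop_config(nm, " must lie in [0, 1)")
  if (abs(r_genetic) > 1) stop_config("r_genetic must lie in [-1, 1]")
  if (abs(env_corr) > 1) stop_config("env_corr must lie in [-1, 1]")
  check_fraction(prevalence_mood, "prevalence_mood", TRUE, TRUE)
  check_fraction(prevalence_anx, "prevalence_anx", TRUE, TRUE)
  if (female_or <= 0) stop_config("female_or must be positive")
  stopifnot(is.data.frame(pcnv_loci))
  if (nrow(pcnv_loci)) {
    if (any(pcnv_loci$frequency <= 0 | pcnv_loci$frequency >= 1))
      stop_config("pcnv carrier frequencies must lie in (0, 1)")
    cnv_var <- sum(pcnv_loci$shift^2 * pcnv_loci$frequency *
                     (1 - pcnv_loci$frequency))
    if (max(h2_mood, h2_anx) + cnv_var >= 1)
      stop_config("h2 plus carrier liability variance must be < 1")
  }
  for (nm in names(source_availability))
    check_fraction(source_availability[[nm]], paste0("availability[", nm, "]"))
  check_fraction(mhq_uptake_pcnv_ratio, "mhq_uptake_pcnv_ratio")
  if (any(observation_model$sensitivity < 0 | observation_model$sensitivity > 1 |
          observation_model$specificity < 0 | observation_model$specificity > 1))
    stop_config("sensitivity and specificity must lie in [0, 1]")
  check_fraction(exclusion_rate, "exclusion_rate")
  pop_weights <- rep_len(pop_weights, n_populations)
  pop_weights <- pop_weights / sum(pop_weights)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_populations = as.integer(n_populations),
    pop_weights = pop_weights, fst = fst, maf_range = maf_range,
    h2_mood = h2_mood, h2_anx = h2_anx, r_genetic = r_genetic,
    env_corr = env_corr, pcnv_loci = pcnv_loci,
    prevalence_mood = prevalence_mood, prevalence_anx = prevalence_anx,
    female_or = female_or, age_beta = age_beta,
    source_availability = source_availability,
    observation_model = observation_model,
    mhq_uptake_pcnv_ratio = mhq_uptake_pcnv_ratio,
    exclusion_rate = exclusion_rate,
    frac_low_info = frac_low_info, frac_high_missing = frac_high_missing,
    frac_rare = frac_rare, frac_hwe_fail = frac_hwe_fail,
    cnv_call_fail_rate = cnv_call_fail_rate,
    cnv_sample_fail_rate = cnv_sample_fail_rate,
    seed = as.integer(seed)), class = "sim_config")
}

obs_params <- function(config, definition, disorder) {
  om <- config$observation_model
  row <- om[om$definition == definition & om$disorder == disorder, ]
  if (!nrow(row)) stop_config("no observation model entry for ",
                              definition, "/", disorder)
  list(sens = row$sensitivity[1], spec = row$specificity[1])
}
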