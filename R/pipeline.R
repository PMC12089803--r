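# End-to-end orchestration ---------------------------------------------------

#' Simulate a full synthetic cohort
#'
#' Runs every generator stage under one seed: genotypes, variant weights,
#' latent liabilities and true disorders, multi-source phenotype records
#' and the CNV call table.
#'
#' @param config a [sim_config()].
#' @param code_lists clinical code lists used for record generation.
#' @return object of class `synthetic_cohort`: list with `genotypes`,
#'   `weights`, `latent`, `records`, `cnv`, `config`, `code_lists`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            code_lists = default_code_lists()) {
  genotypes <- simulate_genotypes(config)
  weights <- simulate_weights(config, genotypes$variants)
  latent <- simulate_liabilities(config, genotypes, weights)
  records <- simulate_records(latent, config, code_lists)
  cnv <- simulate_cnv_calls(latent, config)
  structure(list(genotypes = genotypes, weights = weights, latent = latent,
                 records = records, cnv = cnv, config = config,
                 code_lists = code_lists),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic biobank cohort (seed", x$config$seed, ")\n")
  print(x$genotypes); print(x$latent); print(x$records); print(x$cnv)
  invisible(x)
}

#' Read a study configuration from YAML
#'
#' Top-level keys are passed to [sim_config()] (unknown keys rejected);
#' `pcnv_loci` and `observation_model` may be given as lists of records.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  for (nm in c("pcnv_loci", "observation_model"))
    if (!is.null(raw[[nm]]) && !is.data.frame(raw[[nm]]))
      raw[[nm]] <- do.call(rbind, lapply(raw[[nm]], as.data.frame))
  bad <- setdiff(names(raw), names(formals(sim_config)))
  if (length(bad)) stop_config("unknown config keys: ",
                               paste(bad, collapse = ", "))
  do.call(sim_config, raw)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes generate -> variant QC -> PRS scoring -> reference-panel
#' ancestry adjustment -> phenotype derivation (with exclusions) -> CNV QC
#' and carrier derivation -> association models -> overlapping-sample
#' effect-size comparisons, and collects every result table.
#'
#' Association models adjust for gender, age and the cohort's first
#' `k_covars` genetic principal components.  PRS and any-P-CNV effects are
#' estimated for the eight definitions of mood, anxiety and internalising
#' disorder; anxiety models are re-fitted conditioning on mood disorder;
#' gender interactions, PRS x P-CNV interactions and per-locus models are
#' included; effect sizes are compared across definitions with the
#' overlap-aware z-test.
#'
#' @param config a [sim_config()].
#' @param code_lists clinical code lists.
#' @param k_adjust reference-projection components for PRS adjustment.
#' @param k_covars cohort principal components used as covariates.
#' @param n_reference reference-panel size.
#' @param definitions definitions to analyse.
#' @param predictors any subset of `c("prs_mood", "prs_anx", "any_pcnv")`.
#' @param alpha family-wise alpha.
#' @param prs_tests,cnv_tests Bonferroni family sizes for the PRS and CNV
#'   test families.
#' @param kinship optional pairwise kinship table for relatedness pruning.
#' @return object of class `biobank_study`; see [summary_report()].
#' @export
run_study <- function(config = sim_config(),
                      code_lists = default_code_lists(),
                      k_adjust = 5L, k_covars = 10L, n_reference = 2500L,
                      definitions = definition_names(),
                      predictors = c("prs_mood", "prs_anx", "any_pcnv"),
                      alpha = 0.05, prs_tests = 16L, cnv_tests = 24L,
                      kinship = NULL) {
  bad <- setdiff(definitions, definition_names())
  if (length(bad)) stop("unknown definition: ", paste(bad, collapse = ", "))
  bad <- setdiff(predictors, c("prs_mood", "prs_anx", "any_pcnv"))
  if (length(bad)) stop("unknown predictor: ", paste(bad, collapse = ", "))

  log_counts <- list()
  cohort <- simulate_cohort(config, code_lists)
  genotypes <- cohort$genotypes

  ## genetic QC
  qc <- variant_qc(genotypes)
  log_counts$variant_qc <- qc$report
  removed_ids <- if (!is.null(kinship))
    relatedness_prune(kinship, seed = config$seed + 10L) else character()
  log_counts$related_removed <- length(removed_ids)
  keep_ind <- !genotypes$ids %in% removed_ids

  ## PRS scoring + ancestry adjustment against a fresh reference panel
  w_mood <- data.frame(variant_id = cohort$weights$variant_id,
                       effect_allele = cohort$weights$effect_allele,
                       weight = cohort$weights$weight_mood)
  w_anx <- transform(w_mood, weight = cohort$weights$weight_anx)
  prs_mood_raw <- score_prs(genotypes, w_mood, qc$keep)
  prs_anx_raw <- score_prs(genotypes, w_anx, qc$keep)

  reference <- simulate_genotypes(config, n = n_reference,
                                  freq = genotypes$freq,
                                  seed = config$seed + 11L)
  pruned <- ld_prune(reference, variant_ids = qc$keep)
  log_counts$ld_pruned_variants <- length(pruned)
  model <- reference_pca(reference, k = k_adjust, variant_ids = pruned)
  pcs_adj <- project_samples(genotypes, model)
  ref_prs_mood <- score_prs(reference, w_mood, qc$keep)
  ref_prs_anx <- score_prs(reference, w_anx, qc$keep)
  prs_mood <- ancestry_adjust(prs_mood_raw, pcs_adj, ref_prs_mood,
                              model$scores, k = k_adjust)$adjusted
  prs_anx <- ancestry_adjust(prs_anx_raw, pcs_adj, ref_prs_anx,
                             model$scores, k = k_adjust)$adjusted

  ## cohort's own PCs for association covariates
  cohort_pca <- reference_pca(genotypes, k = k_covars, variant_ids = pruned)
  covar_pcs <- cohort_pca$scores

  ## phenotype derivation
  flags <- derive_definitions(cohort$records, code_lists,
                              definitions = definitions)
  excluded <- attr(flags, "excluded")
  log_counts$excluded_individuals <- length(excluded)
  tb <- cohort$latent$table
  prevalence <- prevalence_report(flags, gender = tb[, c("id", "female")])

  ## CNV QC + carriers
  sqc <- qc_cnv_samples(cohort$cnv$samples)
  cqc <- qc_cnv_calls(cohort$cnv$calls)
  log_counts$cnv_call_qc <- cqc$report
  log_counts$cnv_samples_failed <- sum(!sqc$pass)
  cnv_pass_ids <- sqc$sample_id[sqc$pass]
  calls_pass <- cqc$retained[cqc$retained$sample_id %in% cnv_pass_ids, ]
  carriers <- carrier_status(calls_pass, cnv_pass_ids,
                             config$pcnv_loci[, c("locus", "type")])
  log_counts$pcnv_loci_retained <- length(carriers$retained_loci)

  ## cohort table
  cohort_table <- data.frame(
    id = genotypes$ids, female = tb$female, age = tb$age,
    population = tb$population,
    prs_mood_raw = as.numeric(prs_mood_raw),
    prs_anx_raw = as.numeric(prs_anx_raw),
    prs_mood = prs_mood, prs_anx = prs_anx, stringsAsFactors = FALSE)
  for (j in seq_len(k_covars))
    cohort_table[[paste0("PC", j)]] <- covar_pcs[, j]
  mcar <- match(cohort_table$id, carriers$table$sample_id)
  cohort_table$any_pcnv <- carriers$table$any_pcnv[mcar]  # NA: no CNV data
  cohort_table <- cohort_table[keep_ind & !cohort_table$id %in% excluded, ]

  covars <- as.matrix(cbind(female = as.numeric(cohort_table$female),
                            age = cohort_table$age,
                            cohort_table[, paste0("PC", seq_len(k_covars))]))

  outcome_of <- function(def, dis) {
    sub <- flags[flags$definition == def & flags$disorder == dis, ]
    st <- sub$status[match(cohort_table$id, sub$id)]
    ifelse(st == "case", 1, ifelse(st == "control", 0, NA))
  }
  thr_prs <- bonferroni_threshold(alpha, prs_tests)
  thr_cnv <- bonferroni_threshold(alpha, cnv_tests)

  prs_results <- list(); cnv_results <- list(); conditional <- list()
  interactions <- list(); per_locus <- list()
  id_sets <- list(prs_mood = list(), prs_anx = list(), any_pcnv = list())
  res_for_pairs <- list(prs_mood = list(), prs_anx = list(),
                        any_pcnv = list())

  for (def in definitions) {
    for (dis in c("mood", "anxiety", "internalising")) {
      y <- outcome_of(def, dis)
      lbl <- paste(def, dis, sep = ".")
      for (pr in intersect(predictors, c("prs_mood", "prs_anx"))) {
        res <- try_fit(fit_logistic, y, cohort_table[[pr]], covars,
                       outcome = lbl, predictor = pr)
        prs_results[[paste(lbl, pr)]] <- res
        if (dis == "internalising" && !is.null(res)) {
          res_for_pairs[[pr]][[def]] <- res
          ok <- !is.na(y)
          id_sets[[pr]][[def]] <-
            list(case = cohort_table$id[ok & y == 1],
                 control = cohort_table$id[ok & y == 0])
        }
      }
      if ("any_pcnv" %in% predictors) {
        res <- try_fit(fit_logistic, y, as.numeric(cohort_table$any_pcnv),
                       covars, outcome = lbl, predictor = "any_pcnv")
        cnv_results[[lbl]] <- res
        if (dis == "internalising" && !is.null(res)) {
          ok <- !is.na(y) & !is.na(cohort_table$any_pcnv)
          res_for_pairs$any_pcnv[[def]] <- res
          id_sets$any_pcnv[[def]] <-
            list(case = cohort_table$id[ok & y == 1],
                 control = cohort_table$id[ok & y == 0])
        }
      }
    }
    ## conditional: anxiety on mood
    if ("any_pcnv" %in% predictors) {
      y <- outcome_of(def, "anxiety")
      mood_flag <- outcome_of(def, "mood")
      conditional[[def]] <- try_fit(
        conditional_test, y, as.numeric(cohort_table$any_pcnv), mood_flag,
        covars, outcome = paste0(def, ".anxiety|mood"),
        predictor = "any_pcnv")
    }
    ## interactions on the internalising outcome
    y <- outcome_of(def, "internalising")
    cv_nosex <- covars[, colnames(covars) != "female"]
    for (pr in intersect(predictors, c("prs_mood", "prs_anx"))) {
      interactions[[paste(def, "femalex", pr)]] <- try_fit(
        interaction_test, y, cohort_table[[pr]],
        as.numeric(cohort_table$female), cv_nosex,
        outcome = paste0(def, ".internalising"),
        predictor = paste0("female:", pr))
      if ("any_pcnv" %in% predictors)
        interactions[[paste(def, pr, "x_pcnv")]] <- try_fit(
          interaction_test, y, cohort_table[[pr]],
          as.numeric(cohort_table$any_pcnv), covars,
          outcome = paste0(def, ".internalising"),
          predictor = paste0(pr, ":any_pcnv"))
    }
    if ("any_pcnv" %in% predictors) {
      interactions[[paste(def, "femalex_pcnv")]] <- try_fit(
        interaction_test, y, as.numeric(cohort_table$any_pcnv),
        as.numeric(cohort_table$female), cv_nosex,
        outcome = paste0(def, ".internalising"),
        predictor = "female:any_pcnv")
      ## per-locus models (retained loci only)
      for (loc in carriers$retained_loci) {
        cl_flag <- carriers$table[[loc]][
          match(cohort_table$id, carriers$table$sample_id)]
        per_locus[[paste(def, loc)]] <- try_fit(
          fit_logistic, y, as.numeric(cl_flag), covars,
          outcome = paste0(def, ".internalising"), predictor = loc)
      }
    }
  }

  pairwise <- list()
  if (length(definitions) >= 2L)
    for (pr in names(res_for_pairs))
      if (length(res_for_pairs[[pr]]) >= 2L)
        pairwise[[pr]] <- pairwise_compare(res_for_pairs[[pr]],
                                           id_sets[[pr]], alpha = alpha)

  ## tetrachoric correlations between internalising definitions
  tetra <- tetrachoric_matrix(flags, definitions)

  results_to_df <- function(lst) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, lapply(lst, as.data.frame))
    rownames(out) <- NULL
    out
  }
  prs_tab <- results_to_df(prs_results)
  if (!is.null(prs_tab)) prs_tab$significant <- prs_tab$p < thr_prs
  cnv_tab <- results_to_df(cnv_results)
  if (!is.null(cnv_tab)) cnv_tab$significant <- cnv_tab$p < thr_cnv

  structure(list(
    cohort = cohort, cohort_table = cohort_table, variant_qc = qc$report,
    prevalence = prevalence, tetrachoric = tetra,
    carriers = carriers, prs_results = prs_tab, cnv_results = cnv_tab,
    conditional = results_to_df(conditional),
    interactions = results_to_df(interactions),
    per_locus = results_to_df(per_locus), pairwise = pairwise,
    thresholds = c(prs = thr_prs, cnv = thr_cnv),
    log_counts = log_counts, flags = flags,
    config = config), class = "biobank_study")
}

# Fit wrapper: single-class outcomes or other degenerate analysis subsets
# yield NULL (reported as gaps) instead of aborting the whole run.
try_fit <- function(fun, y, x, ...) {
  if (all(is.na(y)) || all(is.na(x))) return(NULL)
  tryCatch(fun(y, x, ...), error = function(e) NULL)
}

#' Tetrachoric correlation matrix across definitions
#'
#' @param flags a `definition_flags` table.
#' @param definitions definitions to include.
#' @param disorder disorder to correlate (default internalising).
#' @return symmetric matrix of tetrachoric correlations.
#' @export
tetrachoric_matrix <- function(flags, definitions = definition_names(),
                               disorder = "internalising") {
  get_status <- function(def) {
    sub <- flags[flags$definition == def & flags$disorder == disorder, ]
    stats::setNames(sub$status, sub$id)
  }
  k <- length(definitions)
  out <- diag(1, k)
  dimnames(out) <- list(definitions, definitions)
  st <- lapply(definitions, get_status)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ids <- intersect(names(st[[i]]), names(st[[j]]))
    a <- st[[i]][ids]; b <- st[[j]][ids]
    ok <- a != "missing" & b != "missing"
    tab <- matrix(c(sum(a[ok] == "case" & b[ok] == "case"),
                    sum(a[ok] == "case" & b[ok] == "control"),
                    sum(a[ok] == "control" & b[ok] == "case"),
                    sum(a[ok] == "control" & b[ok] == "control")),
                  2L, 2L, byrow = TRUE)
    out[i, j] <- out[j, i] <- if (all(rowSums(tab) > 0) &&
                                    all(colSums(tab) > 0))
      tetrachoric(tab) else NA_real_
  }
  out
}

#' @export
print.biobank_study <- function(x, ...) {
  cat("Biobank study run (seed", x$config$seed, "):",
      nrow(x$cohort_table), "analysed individuals\n")
  cat("  PRS models:", NROW(x$prs_results),
      "| P-CNV models:", NROW(x$cnv_results),
      "| retained loci:", length(x$carriers$retained_loci), "\n")
  invisible(x)
}

#' @export
summary.biobank_study <- function(object, ...) {
  cat(summary_report(object), sep = "\n")
  invisible(object)
}

#' Human-readable study report
#'
#' Four sections mirroring the analysis: prevalence per definition, PRS
#' association metrics, P-CNV associations (with conditional and
#' per-locus models), and pairwise effect-size comparisons plus
#' interactions.  Absent result sets are marked as gaps rather than
#' omitted silently.
#'
#' @param study a `biobank_study`.
#' @return character vector of report lines.
#' @export
summary_report <- function(study) {
  fmt_df <- function(df) if (is.null(df)) "  (not computed)" else
    paste0("  ", utils::capture.output(print(df, digits = 3,
                                             row.names = FALSE)))
  lines <- c(
    "== 1. Summary statistics: prevalence per definition ==",
    fmt_df(study$prevalence),
    "", "== 2. PRS associations (adjusted PRS; gender, age, PCs) ==",
    sprintf("  Bonferroni threshold (PRS family): %.4g",
            study$thresholds["prs"]),
    fmt_df(study$prs_results),
    "", "== 3. P-CNV associations ==",
    sprintf("  Bonferroni threshold (CNV family): %.4g",
            study$thresholds["cnv"]),
    fmt_df(study$cnv_results),
    "  -- anxiety conditioned on mood --",
    fmt_df(study$conditional),
    "  -- per-locus models --",
    fmt_df(study$per_locus),
    "", "== 4. Effect-size comparisons and interactions ==")
  if (length(study$pairwise)) {
    for (pr in names(study$pairwise))
      lines <- c(lines, paste0("  -- pairwise: ", pr, " --"),
                 fmt_df(study$pairwise[[pr]]))
  } else lines <- c(lines, "  (pairwise comparisons not computed)")
  c(lines, "  -- interactions --", fmt_df(study$interactions))
}

#' Write study result tables and a hashed manifest to a directory
#'
#' @param study a `biobank_study`.
#' @param dir output directory.
#' @return the manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv(study$prevalence, p("prevalence.tsv"))
  if (!is.null(study$prs_results))
    write_tsv(study$prs_results, p("prs_associations.tsv"))
  if (!is.null(study$cnv_results))
    write_tsv(study$cnv_results, p("cnv_associations.tsv"))
  if (!is.null(study$conditional))
    write_tsv(study$conditional, p("conditional_anxiety_on_mood.tsv"))
  if (!is.null(study$interactions))
    write_tsv(study$interactions, p("interactions.tsv"))
  if (!is.null(study$per_locus))
    write_tsv(study$per_locus, p("per_locus.tsv"))
  for (pr in names(study$pairwise))
    write_tsv(study$pairwise[[pr]], p(paste0("pairwise_", pr, ".tsv")))
  write_flags_tsv(study$flags, p("definition_flags.tsv"))
  writeLines(summary_report(study), p("report.txt"))
  files <- list.files(dir, full.names = TRUE)
  manifest <- list(
    seed = study$config$seed,
    n_individuals = study$config$n_individuals,
    log_counts = study$log_counts,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
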