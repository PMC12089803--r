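# Phenotype derivation: eight definitions x three disorders -----------------

#' Score the GAD-7 anxiety questionnaire
#'
#' Seven items, each 0-3; the total defines probable generalised anxiety
#' disorder at a threshold of 10 or above.  Any missing item makes the
#' score (and case flag) missing.
#'
#' @param items numeric vector of 7 items, or a matrix/data.frame with 7
#'   columns (one row per respondent).
#' @param threshold case threshold on the total score (default 10).
#' @return data.frame with columns `score` and `case`.
#' @export
score_gad7 <- function(items, threshold = 10) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1L)
  items <- as.matrix(items)
  if (ncol(items) != 7L) stop("GAD-7 requires exactly 7 items")
  rng <- range(items, na.rm = TRUE)
  if (any(!is.na(items)) && (rng[1] < 0 || rng[2] > 3))
    stop("GAD-7 items must lie in 0..3")
  score <- rowSums(items)  # NA if any item missing
  data.frame(score = score, case = score >= threshold)
}

#' CIDI-SF scoring thresholds
#'
#' Defaults follow the usual short-form criteria: lifetime major depression
#' requires a cardinal symptom (depressed mood or anhedonia), at least
#' `mdd_min_symptoms` of 9 symptoms, two-week duration and impairment;
#' lifetime GAD requires excessive worry, six-month duration and at least
#' `gad_min_symptoms` associated symptoms.
#'
#' @param mdd_min_symptoms minimum MDD symptom count (default 5).
#' @param gad_min_symptoms minimum GAD symptom count (default 3).
#' @return list of class `cidi_config`.
#' @export
cidi_config <- function(mdd_min_symptoms = 5L, gad_min_symptoms = 3L) {
  structure(list(mdd_min_symptoms = as.integer(mdd_min_symptoms),
                 gad_min_symptoms = as.integer(gad_min_symptoms)),
            class = "cidi_config")
}

#' Score CIDI-SF responses into lifetime MDD and GAD flags
#'
#' @param responses data.frame with columns `id`, `mdd_cardinal_mood`,
#'   `mdd_cardinal_anhedonia`, `mdd_symptom_count`, `mdd_duration_2wk`,
#'   `mdd_impairment`, `gad_excessive_worry`, `gad_duration_6mo`,
#'   `gad_symptom_count` (0/1 items, counts for the symptom columns).
#' @param config a [cidi_config()].
#' @return data.frame `id`, `mdd`, `gad`; a missing required item yields a
#'   missing flag, never control.
#' @export
score_cidi_sf <- function(responses, config = cidi_config()) {
  need <- c("mdd_cardinal_mood", "mdd_cardinal_anhedonia",
            "mdd_symptom_count", "mdd_duration_2wk", "mdd_impairment",
            "gad_excessive_worry", "gad_duration_6mo", "gad_symptom_count")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("CIDI-SF responses missing columns: ",
                         paste(miss, collapse = ", "))
  mdd <- (responses$mdd_cardinal_mood > 0 |
            responses$mdd_cardinal_anhedonia > 0) &
    responses$mdd_symptom_count >= config$mdd_min_symptoms &
    responses$mdd_duration_2wk > 0 & responses$mdd_impairment > 0
  gad <- responses$gad_excessive_worry > 0 &
    responses$gad_duration_6mo > 0 &
    responses$gad_symptom_count >= config$gad_min_symptoms
  data.frame(id = responses$id, mdd = mdd, gad = gad,
             stringsAsFactors = FALSE)
}

status_from <- function(case, available) {
  out <- rep("missing", length(available))
  out[available & !is.na(case) & case] <- "case"
  out[available & !is.na(case) & !case] <- "control"
  out
}

ids_with_codes <- function(records_df, id_col, code_col, list_codes,
                           prefix = FALSE) {
  hit <- match_codes(records_df[[code_col]], list_codes, prefix = prefix)
  unique(records_df[[id_col]][hit])
}

#' Derive case/control/missing status for one definition and disorder
#'
#' Implements the eight definition rules: (1) interview diagnosis
#' self-report; (2) interview medication self-report, with any
#' antidepressant counting for mood and any antidepressant or
#' benzodiazepine apart from temazepam counting for anxiety; (3)
#' help-seeking (ever seen a GP or a psychiatrist for depression, tension
#' or nerves), identical for all disorders; (4) minimal phenotyping
#' (Smith-style probable mood disorder; help-seeking plus GAD-7 >= 10 for
#' anxiety); (5) CIDI-SF; (6) MHQ self-reported diagnosis; (7) hospital
#' admission code list; (8) primary-care code list.  Controls are
#' individuals with the defining source available and no qualifying
#' record; individuals without the source are missing.
#'
#' @param records a `phenotype_records` object.
#' @param definition one of [definition_names()].
#' @param disorder "mood", "anxiety" or "internalising".
#' @param code_lists code list data.frame (see [default_code_lists()]).
#' @param cidi a [cidi_config()].
#' @param prefix use prefix code matching for hierarchical codes.
#' @return data.frame `id`, `definition`, `disorder`, `status`.
#' @export
classify_definition <- function(records, definition, disorder,
                                code_lists = default_code_lists(),
                                cidi = cidi_config(), prefix = FALSE) {
  if (!definition %in% definition_names())
    stop("unknown definition: ", definition)
  if (!disorder %in% c("mood", "anxiety", "internalising"))
    stop("unknown disorder: ", disorder)
  if (disorder == "internalising" && definition != "help_seeking") {
    m <- classify_definition(records, definition, "mood", code_lists, cidi,
                             prefix)
    a <- classify_definition(records, definition, "anxiety", code_lists,
                             cidi, prefix)
    return(data.frame(id = m$id, definition = definition,
                      disorder = "internalising",
                      status = combine_internalising(m$status, a$status),
                      stringsAsFactors = FALSE))
  }
  av <- records$availability
  id <- av$id
  dis <- if (disorder == "internalising") "mood" else disorder
  cl <- code_lists

  case <- switch(
    definition,
    initial_self_report = {
      codes <- cl$code[cl$source == "interview" & cl$disorder == dis]
      diag <- records$interview[records$interview$kind == "diagnosis", ]
      id %in% ids_with_codes(diag, "id", "code", codes, prefix)
    },
    medication_self_report = {
      med <- records$interview[records$interview$kind == "medication", ]
      codes <- if (dis == "mood") {
        cl$code[cl$source == "medication" & cl$disorder == "mood"]
      } else {
        # any antidepressant and/or benzodiazepine apart from temazepam
        setdiff(cl$code[cl$source == "medication" &
                          cl$disorder %in% c("mood", "anxiety")],
                temazepam_codes())
      }
      id %in% ids_with_codes(med, "id", "code", codes, prefix)
    },
    help_seeking = {
      ts <- records$touchscreen[match(id, records$touchscreen$id), ]
      ts$gp_help == 1L | ts$psych_help == 1L
    },
    minimal = {
      ts <- records$touchscreen[match(id, records$touchscreen$id), ]
      hs <- ts$gp_help == 1L | ts$psych_help == 1L
      if (dis == "mood") {
        hs & (ts$low_mood_2wk == 1L | ts$anhedonia_2wk == 1L)
      } else {
        g <- score_gad7(records$gad7[, paste0("gad7_", 1:7)])
        gcase <- g$case[match(id, records$gad7$id)]
        hs & gcase
      }
    },
    cidi_sf = {
      sc <- score_cidi_sf(records$cidi, cidi)
      flag <- if (dis == "mood") sc$mdd else sc$gad
      flag[match(id, sc$id)]
    },
    mhq_self_report = {
      labels <- if (dis == "mood") "depression" else mhq_anxiety_labels()
      id %in% unique(records$mhq_diagnosis$id[
        records$mhq_diagnosis$label %in% labels])
    },
    hospital = {
      codes <- cl$code[cl$source == "hospital" & cl$disorder == dis]
      ev <- records$ehr[records$ehr$source == "hospital", ]
      id %in% ids_with_codes(ev, "id", "code", codes, prefix)
    },
    primary_care = {
      codes <- cl$code[cl$source == "primary_care" & cl$disorder == dis]
      ev <- records$ehr[records$ehr$source == "primary_care", ]
      id %in% ids_with_codes(ev, "id", "code", codes, prefix)
    })

  available <- switch(
    definition,
    initial_self_report = , medication_self_report = av$interview,
    help_seeking = av$touchscreen,
    minimal = if (dis == "mood") av$touchscreen else av$touchscreen & av$mhq,
    cidi_sf = , mhq_self_report = av$mhq,
    hospital = av$hospital,
    primary_care = av$primary_care)

  data.frame(id = id, definition = definition, disorder = disorder,
             status = status_from(case, available), stringsAsFactors = FALSE)
}

#' Combine mood and anxiety status into internalising disorder
#'
#' Case if either component is a case; control only when both components
#' are observed controls; missing otherwise (one missing component and one
#' control gives missing, preventing asymmetric misclassification when a
#' source is absent).
#'
#' @param mood,anxiety character vectors of "case"/"control"/"missing".
#' @return character vector of combined status.
#' @export
combine_internalising <- function(mood, anxiety) {
  out <- rep("missing", length(mood))
  out[mood == "case" | anxiety == "case"] <- "case"
  out[mood == "control" & anxiety == "control"] <- "control"
  out
}

#' Identify individuals excluded for schizophrenia or bipolar disorder
#'
#' Union over three routes: an exclusion code in the linked EHRs (hospital
#' or primary care), an exclusion self-report at the nurse-led interview,
#' or an exclusion diagnosis reported in the MHQ.
#'
#' @param records a `phenotype_records` object.
#' @param code_lists code list data.frame.
#' @param mhq_labels MHQ self-report labels treated as exclusions.
#' @param prefix use prefix code matching.
#' @return character vector of excluded ids.
#' @export
apply_exclusions <- function(records, code_lists = default_code_lists(),
                             mhq_labels = c("schizophrenia",
                                            "bipolar disorder"),
                             prefix = FALSE) {
  cl <- code_lists
  ehr_codes <- cl$code[cl$disorder == "exclusion" &
                         cl$source %in% c("hospital", "primary_care")]
  iv_codes <- cl$code[cl$disorder == "exclusion" & cl$source == "interview"]
  diag <- records$interview[records$interview$kind == "diagnosis", ]
  unique(c(
    ids_with_codes(records$ehr, "id", "code", ehr_codes, prefix),
    ids_with_codes(diag, "id", "code", iv_codes, prefix),
    records$mhq_diagnosis$id[records$mhq_diagnosis$label %in% mhq_labels]))
}

#' Derive all definition flags for a cohort
#'
#' Runs [classify_definition()] for the eight definitions and the three
#' disorders, removes excluded individuals, and returns a long-format
#' table.
#'
#' @inheritParams classify_definition
#' @param exclusions if TRUE (default), drop individuals flagged by
#'   [apply_exclusions()].
#' @param definitions subset of definitions to derive.
#' @return data.frame of class `definition_flags`: `id`, `definition`,
#'   `disorder`, `status`; attribute `excluded` holds the removed ids.
#' @export
derive_definitions <- function(records, code_lists = default_code_lists(),
                               cidi = cidi_config(), prefix = FALSE,
                               exclusions = TRUE,
                               definitions = definition_names()) {
  bad <- setdiff(definitions, definition_names())
  if (length(bad)) stop("unknown definition: ", paste(bad, collapse = ", "))
  out <- list()
  for (def in definitions)
    for (dis in c("mood", "anxiety", "internalising"))
      out[[paste(def, dis)]] <-
        classify_definition(records, def, dis, code_lists, cidi, prefix)
  flags <- do.call(rbind, out)
  rownames(flags) <- NULL
  excluded <- character()
  if (exclusions) {
    excluded <- apply_exclusions(records, code_lists, prefix = prefix)
    flags <- flags[!flags$id %in% excluded, ]
  }
  structure(flags, excluded = excluded,
            class = c("definition_flags", "data.frame"))
}

#' Prevalence per definition and disorder
#'
#' Individuals with missing status are removed from each calculation;
#' prevalence = cases / (cases + controls), undefined (NA) when the
#' denominator is zero.
#'
#' @param flags a `definition_flags` table.
#' @param gender optional data.frame `id`, `female` for a by-gender split.
#' @return data.frame with one row per (definition, disorder).
#' @export
prevalence_report <- function(flags, gender = NULL) {
  key <- interaction(flags$definition, flags$disorder, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- flags[key == k, ]
    n_case <- sum(sub$status == "case")
    n_control <- sum(sub$status == "control")
    out <- data.frame(definition = sub$definition[1],
                      disorder = sub$disorder[1],
                      n_case = n_case, n_control = n_control,
                      n_missing = sum(sub$status == "missing"),
                      prevalence = if (n_case + n_control > 0)
                        n_case / (n_case + n_control) else NA_real_)
    if (!is.null(gender)) {
      fem <- gender$female[match(sub$id, gender$id)]
      for (sex in c(TRUE, FALSE)) {
        s <- sub[!is.na(fem) & fem == sex, ]
        nc <- sum(s$status == "case"); nn <- sum(s$status == "control")
        out[[if (sex) "prevalence_female" else "prevalence_male"]] <-
          if (nc + nn > 0) nc / (nc + nn) else NA_real_
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Completion percentage from counts
#'
#' Simple helper for reporting questionnaire completion rates, e.g. MHQ
#' completion among CNV carriers, as a percentage.
#'
#' @param n_completed,n_total counts.
#' @param digits rounding for the percentage (default 2).
#' @return percentage (0-100).
#' @export
completion_pct <- function(n_completed, n_total, digits = 2) {
  if (n_total <= 0 || n_completed < 0 || n_completed > n_total)
    stop("invalid counts")
  round(100 * n_completed / n_total, digits)
}

#' MHQ completion split by carrier status
#'
#' @param records a `phenotype_records` object.
#' @param any_pcnv logical vector aligned with `records$availability$id`.
#' @return data.frame with completion counts and percentages for carriers
#'   and non-carriers.
#' @export
mhq_completion <- function(records, any_pcnv) {
  av <- records$availability
  stopifnot(length(any_pcnv) == nrow(av))
  data.frame(
    group = c("carrier", "non_carrier"),
    n = c(sum(any_pcnv), sum(!any_pcnv)),
    n_completed = c(sum(av$mhq[any_pcnv]), sum(av$mhq[!any_pcnv])),
    pct = c(completion_pct(sum(av$mhq[any_pcnv]), max(1, sum(any_pcnv))),
            completion_pct(sum(av$mhq[!any_pcnv]), max(1, sum(!any_pcnv)))))
}
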