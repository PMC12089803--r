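# Raw multi-source phenotype record simulation ------------------------------

# Draw an observed binary flag with given sensitivity/specificity against
# the true state.
draw_flag <- function(truth, sens, spec) {
  p <- ifelse(truth, sens, 1 - spec)
  stats::runif(length(truth)) < p
}

#' Simulate raw multi-source phenotype records
#'
#' Generates the four record sources a biobank analysis consumes:
#' touchscreen answers (help-seeking questions, low-mood items), nurse-led
#' interview records (diagnosis and medication codes), linked EHR code
#' events (hospital and primary-care), and online mental-health
#' questionnaire (MHQ) responses (GAD-7 items, CIDI-SF items, self-reported
#' diagnoses).  Each source is observed only where its availability mask is
#' drawn; MHQ completion for P-CNV carriers is scaled by
#' `mhq_uptake_pcnv_ratio`.  Conditional on availability, qualifying
#' records are generated so that each definition's observed case status has
#' the configured sensitivity/specificity against the true disorder.
#' Help-seeking is generated once per individual against the internalising
#' (mood-or-anxiety) truth, so it is identical across disorders.
#'
#' A fraction `exclusion_rate` of individuals receives a schizophrenia or
#' bipolar disorder record in one of the sources, to exercise downstream
#' exclusion.
#'
#' @param latent a `latent_state` from [simulate_liabilities()].
#' @param config a [sim_config()].
#' @param code_lists clinical code lists (default [default_code_lists()]).
#' @param seed integer seed.
#' @return object of class `phenotype_records`: list of data.frames
#'   `availability`, `touchscreen`, `interview`, `gad7`, `cidi`,
#'   `mhq_diagnosis`, `ehr`.
#' @export
simulate_records <- function(latent, config,
                             code_lists = default_code_lists(),
                             seed = config$seed + 3L) {
  set.seed(seed)
  tb <- latent$table
  n <- nrow(tb)
  id <- tb$id
  mood <- tb$mood
  anx <- tb$anx
  intern <- mood | anx

  av <- config$source_availability
  mhq_rate <- av$mhq * ifelse(tb$any_pcnv, config$mhq_uptake_pcnv_ratio, 1)
  availability <- data.frame(
    id = id,
    touchscreen = stats::runif(n) < av$touchscreen,
    interview = stats::runif(n) < av$interview,
    mhq = stats::runif(n) < mhq_rate,
    primary_care = stats::runif(n) < av$primary_care,
    hospital = stats::runif(n) < av$hospital,
    stringsAsFactors = FALSE)

  op <- function(def, dis) obs_params(config, def, dis)

  ## --- touchscreen: help-seeking + minimal-phenotyping mood items ---------
  hs <- op("help_seeking", "mood")
  help_flag <- draw_flag(intern, hs$sens, hs$spec)
  gp <- help_flag & stats::runif(n) < 0.9
  psych <- help_flag & stats::runif(n) < 0.35
  gp[help_flag & !gp & !psych] <- TRUE
  mn <- op("minimal", "mood")
  smith_flag <- draw_flag(mood, mn$sens, mn$spec)
  touchscreen <- data.frame(
    id = id, gp_help = as.integer(gp), psych_help = as.integer(psych),
    low_mood_2wk = as.integer(smith_flag),
    anhedonia_2wk = as.integer(smith_flag & stats::runif(n) < 0.6),
    stringsAsFactors = FALSE)
  ts_na <- !availability$touchscreen
  touchscreen[ts_na, -1] <- NA_integer_

  ## --- interview: diagnosis + medication codes ----------------------------
  iv <- availability$interview
  isr_m <- op("initial_self_report", "mood")
  isr_a <- op("initial_self_report", "anxiety")
  d_mood <- iv & draw_flag(mood, isr_m$sens, isr_m$spec)
  d_anx <- iv & draw_flag(anx, isr_a$sens, isr_a$spec)
  med_m <- op("medication_self_report", "mood")
  med_a <- op("medication_self_report", "anxiety")
  m_mood <- iv & draw_flag(mood, med_m$sens, med_m$spec)
  m_anx <- iv & draw_flag(anx, med_a$sens, med_a$spec)

  cl <- code_lists
  ad_codes <- cl$code[cl$source == "medication" & cl$disorder == "mood"]
  bz_codes <- setdiff(cl$code[cl$source == "medication" &
                                cl$disorder == "anxiety"], temazepam_codes())

  rec <- list()
  pick <- function(ids, codes) if (length(ids))
    data.frame(id = ids, code = sample(codes, length(ids), replace = TRUE),
               stringsAsFactors = FALSE)
  dep_code <- ifelse(tb$female[d_mood] & stats::runif(sum(d_mood)) < 0.1,
                     "SR_POSTNATAL_DEPRESSION", "SR_DEPRESSION")
  rec$d1 <- if (any(d_mood)) data.frame(id = id[d_mood], code = dep_code,
                                        stringsAsFactors = FALSE)
  rec$d2 <- pick(id[d_anx], c("SR_ANXIETY", "SR_PANIC_ATTACKS"))
  rec$m1 <- pick(id[m_mood], ad_codes)
  # anxiety-only medication realised as a non-temazepam benzodiazepine;
  # anxiety cases also on an antidepressant are already covered by m_mood
  rec$m2 <- pick(id[m_anx & !m_mood], bz_codes)
  # background temazepam prescriptions (sleep), must not count as anxiety
  temaz <- iv & stats::runif(n) < 0.01
  rec$m3 <- pick(id[temaz], temazepam_codes())
  kind <- rep(c("diagnosis", "medication"),
              c(sum(vapply(rec[c("d1", "d2")], NROW, 1L)),
                sum(vapply(rec[c("m1", "m2", "m3")], NROW, 1L))))
  interview <- do.call(rbind, rec[!vapply(rec, is.null, TRUE)])
  if (is.null(interview))
    interview <- data.frame(id = character(), code = character(),
                            stringsAsFactors = FALSE)
  interview$kind <- if (nrow(interview)) kind else character()

  ## --- MHQ: GAD-7 items, CIDI-SF items, self-reported diagnoses -----------
  mq <- availability$mhq
  mg <- op("minimal", "anxiety")
  gad7_flag <- draw_flag(anx, mg$sens, mg$spec)
  gad7 <- simulate_gad7_items(id[mq], gad7_flag[mq])

  ci_m <- op("cidi_sf", "mood")
  ci_a <- op("cidi_sf", "anxiety")
  cidi_mdd <- draw_flag(mood, ci_m$sens, ci_m$spec)
  cidi_gad <- draw_flag(anx, ci_a$sens, ci_a$spec)
  cidi <- simulate_cidi_items(id[mq], cidi_mdd[mq], cidi_gad[mq])

  sr_m <- op("mhq_self_report", "mood")
  sr_a <- op("mhq_self_report", "anxiety")
  q_mood <- mq & draw_flag(mood, sr_m$sens, sr_m$spec)
  q_anx <- mq & draw_flag(anx, sr_a$sens, sr_a$spec)
  mhq_diag <- rbind(
    if (any(q_mood)) data.frame(id = id[q_mood], label = "depression",
                                stringsAsFactors = FALSE),
    if (any(q_anx)) data.frame(
      id = id[q_anx],
      label = sample(mhq_anxiety_labels(), sum(q_anx), replace = TRUE),
      stringsAsFactors = FALSE))
  if (is.null(mhq_diag))
    mhq_diag <- data.frame(id = character(), label = character(),
                           stringsAsFactors = FALSE)

  ## --- EHR: hospital + primary care code events ---------------------------
  hosp_av <- availability$hospital
  pc_av <- availability$primary_care
  ho_m <- op("hospital", "mood"); ho_a <- op("hospital", "anxiety")
  pc_m <- op("primary_care", "mood"); pc_a <- op("primary_care", "anxiety")
  h_mood <- hosp_av & draw_flag(mood, ho_m$sens, ho_m$spec)
  h_anx <- hosp_av & draw_flag(anx, ho_a$sens, ho_a$spec)
  p_mood <- pc_av & draw_flag(mood, pc_m$sens, pc_m$spec)
  p_anx <- pc_av & draw_flag(anx, pc_a$sens, pc_a$spec)
  code_of <- function(src, dis) cl$code[cl$source == src & cl$disorder == dis]
  ehr <- rbind(
    pick(id[h_mood], code_of("hospital", "mood")),
    pick(id[h_anx], code_of("hospital", "anxiety")),
    pick(id[p_mood], code_of("primary_care", "mood")),
    pick(id[p_anx], code_of("primary_care", "anxiety")))
  if (is.null(ehr))
    ehr <- data.frame(id = character(), code = character(),
                      stringsAsFactors = FALSE)
  ehr$source <- rep(c("hospital", "hospital", "primary_care", "primary_care"),
                    c(sum(h_mood), sum(h_anx), sum(p_mood), sum(p_anx)))

  ## --- exclusion records (schizophrenia / bipolar disorder) ---------------
  excl <- stats::runif(n) < config$exclusion_rate
  if (any(excl)) {
    src <- sample(c("hospital", "primary_care", "interview", "mhq"),
                  sum(excl), replace = TRUE, prob = c(0.3, 0.2, 0.3, 0.2))
    # keep the record observable: fall back to hospital when the drawn
    # source is unavailable for that individual
    src[src == "primary_care" & !pc_av[excl]] <- "hospital"
    src[src == "mhq" & !mq[excl]] <- "hospital"
    src[src == "interview" & !iv[excl]] <- "hospital"
    eid <- id[excl]
    szo <- stats::runif(sum(excl)) < 0.5
    is_ehr <- src %in% c("hospital", "primary_care")
    if (any(is_ehr)) {
      exc_codes <- cl[cl$disorder == "exclusion" & cl$source %in%
                        c("hospital", "primary_care"), ]
      codes <- vapply(which(is_ehr), function(i) {
        pool <- exc_codes$code[exc_codes$source == src[i]]
        pool[1L + (szo[i] == FALSE)]
      }, character(1))
      ehr <- rbind(ehr, data.frame(id = eid[is_ehr], code = codes,
                                   source = src[is_ehr],
                                   stringsAsFactors = FALSE))
    }
    if (any(src == "interview"))
      interview <- rbind(interview, data.frame(
        id = eid[src == "interview"],
        code = ifelse(szo[src == "interview"], "SR_SCHIZOPHRENIA",
                      "SR_BIPOLAR"),
        kind = "diagnosis", stringsAsFactors = FALSE))
    if (any(src == "mhq"))
      mhq_diag <- rbind(mhq_diag, data.frame(
        id = eid[src == "mhq"],
        label = ifelse(szo[src == "mhq"], "schizophrenia",
                       "bipolar disorder"),
        stringsAsFactors = FALSE))
  }

  structure(list(availability = availability, touchscreen = touchscreen,
                 interview = interview, gad7 = gad7, cidi = cidi,
                 mhq_diagnosis = mhq_diag, ehr = ehr),
            class = "phenotype_records")
}

#' @export
print.phenotype_records <- function(x, ...) {
  cat("Phenotype records for", nrow(x$availability), "individuals\n")
  cat(sprintf("  MHQ available: %.1f%%; primary care: %.1f%%\n",
              100 * mean(x$availability$mhq),
              100 * mean(x$availability$primary_care)))
  invisible(x)
}

# GAD-7 items (0..3 each) consistent with a probable-GAD flag (total >= 10).
simulate_gad7_items <- function(ids, flag) {
  n <- length(ids)
  items <- matrix(0L, n, 7L)
  if (any(flag)) {
    m <- sum(flag)
    it <- matrix(sample(1:3, 7L * m, replace = TRUE, prob = c(0.2, 0.4, 0.4)),
                 m, 7L)
    deficit <- pmax(0L, 10L - rowSums(it))
    for (i in which(deficit > 0)) {
      room <- 3L - it[i, ]
      while (deficit[i] > 0L) {
        j <- which.max(room)
        add <- min(room[j], deficit[i])
        it[i, j] <- it[i, j] + add
        room[j] <- room[j] - add
        deficit[i] <- deficit[i] - add
      }
    }
    items[flag, ] <- it
  }
  if (any(!flag)) {
    m <- sum(!flag)
    items[!flag, ] <- matrix(sample(0:1, 7L * m, replace = TRUE,
                                    prob = c(0.7, 0.3)), m, 7L)
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (j in 1:7) out[[paste0("gad7_", j)]] <- items[, j]
  out
}

# CIDI-SF item responses consistent with lifetime MDD / GAD flags.
simulate_cidi_items <- function(ids, mdd, gad) {
  n <- length(ids)
  card_mood <- integer(n); card_anh <- integer(n)
  count <- integer(n); dur <- integer(n); imp <- integer(n)
  if (any(mdd)) {
    m <- sum(mdd)
    card_mood[mdd] <- as.integer(stats::runif(m) < 0.9)
    card_anh[mdd] <- as.integer(stats::runif(m) < 0.7)
    none <- mdd & card_mood == 0L & card_anh == 0L
    card_mood[none] <- 1L
    count[mdd] <- sample(5:9, m, replace = TRUE)
    dur[mdd] <- 1L; imp[mdd] <- 1L
  }
  if (any(!mdd)) {
    m <- sum(!mdd)
    fail <- sample(1:3, m, replace = TRUE)
    w <- which(!mdd)
    card_mood[w] <- as.integer(fail != 1L & stats::runif(m) < 0.4)
    card_anh[w] <- as.integer(fail != 1L & stats::runif(m) < 0.3)
    count[w] <- ifelse(fail == 3L, sample(5:9, m, replace = TRUE),
                       sample(0:4, m, replace = TRUE))
    has_card <- card_mood[w] + card_anh[w] > 0L
    dur[w] <- as.integer(fail != 3L | stats::runif(m) < 0.5)
    imp[w] <- as.integer(!(fail == 3L & dur[w] == 1L))
    # ensure full criteria are never jointly met
    bad <- has_card & count[w] >= 5L & dur[w] == 1L & imp[w] == 1L
    imp[w][bad] <- 0L
  }
  worry <- integer(n); wdur <- integer(n); wcount <- integer(n)
  if (any(gad)) {
    m <- sum(gad)
    worry[gad] <- 1L; wdur[gad] <- 1L
    wcount[gad] <- sample(3:6, m, replace = TRUE)
  }
  if (any(!gad)) {
    m <- sum(!gad)
    fail <- sample(1:3, m, replace = TRUE)
    w <- which(!gad)
    worry[w] <- as.integer(fail != 1L)
    wdur[w] <- as.integer(fail != 2L)
    wcount[w] <- ifelse(fail == 3L, sample(0:2, m, replace = TRUE),
                        sample(0:6, m, replace = TRUE))
    bad <- worry[w] == 1L & wdur[w] == 1L & wcount[w] >= 3L
    wcount[w][bad] <- sample(0:2, sum(bad), replace = TRUE)
  }
  data.frame(id = ids, mdd_cardinal_mood = card_mood,
             mdd_cardinal_anhedonia = card_anh, mdd_symptom_count = count,
             mdd_duration_2wk = dur, mdd_impairment = imp,
             gad_excessive_worry = worry, gad_duration_6mo = wdur,
             gad_symptom_count = wcount, stringsAsFactors = FALSE)
}

#' Self-reported MHQ anxiety diagnosis labels counted as anxiety disorder
#' @return character vector.
#' @export
mhq_anxiety_labels <- function() {
  c("social anxiety or social phobia", "agoraphobia", "panic attacks",
    "anxiety", "nerves", "GAD")
}

#' Medication codes excluded from the anxiety medication definition
#' @return character vector of temazepam codes.
#' @export
temazepam_codes <- function() "BZ_TEMAZEPAM"
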