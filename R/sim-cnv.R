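# CNV call table simulation -------------------------------------------------

#' Simulate a CNV call table with per-call and per-sample QC metrics
#'
#' One call row per true carrier per locus, with probe counts, lengths and
#' confidence scores drawn from distributions that pass the standard
#' filters; a configurable fraction of calls is made QC-failing (too few
#' probes, sparse probe coverage, or low confidence).  Per-sample metrics
#' (number of CNVs, waviness, SNP call rate, log R ratio s.d.) are drawn
#' similarly, with a configurable fraction of samples failing.  Background
#' (non-psychiatric) calls are added so that the per-sample CNV count is
#' realistic.
#'
#' @param latent a `latent_state`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `cnv_call_table`: list with `calls` (sample_id,
#'   locus, type, n_probes, length_bp, confidence) and `samples`
#'   (sample_id, n_cnvs, waviness, call_rate, lrr_sd).
#' @export
simulate_cnv_calls <- function(latent, config, seed = config$seed + 4L) {
  set.seed(seed)
  tb <- latent$table
  n <- nrow(tb)
  carriers <- latent$carriers
  loci <- latent$loci

  calls <- list()
  for (l in seq_len(ncol(carriers))) {
    who <- which(carriers[, l])
    if (!length(who)) next
    m <- length(who)
    n_probes <- 20L + stats::rpois(m, 60)
    length_bp <- round(n_probes * stats::runif(m, 2000, 15000))
    confidence <- 10 + stats::rgamma(m, shape = 2, scale = 15)
    fail <- stats::runif(m) < config$cnv_call_fail_rate
    if (any(fail)) {
      mode <- sample(1:3, sum(fail), replace = TRUE)
      w <- which(fail)
      n_probes[w][mode == 1L] <- sample(3:19, sum(mode == 1L), replace = TRUE)
      length_bp[w][mode == 2L] <-
        round(n_probes[w][mode == 2L] * stats::runif(sum(mode == 2L),
                                                     25000, 60000))
      confidence[w][mode == 3L] <- stats::runif(sum(mode == 3L), 0, 9.9)
    }
    calls[[l]] <- data.frame(
      sample_id = tb$id[who], locus = loci$locus[l], type = loci$type[l],
      n_probes = n_probes, length_bp = length_bp, confidence = confidence,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(), locus = character(),
               type = character(), n_probes = integer(),
               length_bp = integer(), confidence = numeric(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL

  # clean draws are clamped inside the passing region so that QC failures
  # come only from the configured failure fractions
  n_background <- pmin(stats::rpois(n, 5), 25L)
  n_cnvs <- n_background + as.integer(rowSums(carriers))
  waviness <- pmin(pmax(stats::rnorm(n, 0, 0.01), -0.03), 0.03)
  call_rate <- pmax(1 - stats::rbeta(n, 1.2, 80), 0.961)
  lrr_sd <- stats::runif(n, 0.10, 0.30)
  fail <- stats::runif(n) < config$cnv_sample_fail_rate
  if (any(fail)) {
    mode <- sample(1:4, sum(fail), replace = TRUE)
    w <- which(fail)
    n_cnvs[w][mode == 1L] <- 30L + stats::rpois(sum(mode == 1L), 10)
    waviness[w][mode == 2L] <- sample(c(-1, 1), sum(mode == 2L), TRUE) *
      stats::runif(sum(mode == 2L), 0.031, 0.08)
    call_rate[w][mode == 3L] <- stats::runif(sum(mode == 3L), 0.85, 0.959)
    lrr_sd[w][mode == 4L] <- stats::runif(sum(mode == 4L), 0.351, 0.6)
  }
  samples <- data.frame(sample_id = tb$id, n_cnvs = n_cnvs,
                        waviness = waviness, call_rate = call_rate,
                        lrr_sd = lrr_sd, stringsAsFactors = FALSE)
  structure(list(calls = calls, samples = samples),
            class = "cnv_call_table")
}

#' @export
print.cnv_call_table <- function(x, ...) {
  cat("CNV call table:", nrow(x$calls), "calls across",
      nrow(x$samples), "samples\n")
  invisible(x)
}
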