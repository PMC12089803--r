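# CNV quality control and carrier derivation --------------------------------

#' Per-sample CNV quality control
#'
#' A sample passes unless it carries 30 or more CNVs, has absolute waviness
#' factor above 0.03, a SNP call rate below 96%, or a log R ratio standard
#' deviation above 0.35.  Boundary semantics follow the wording exactly:
#' 30 CNVs fails ("30 or more"), waviness of exactly 0.03 passes ("greater
#' than 0.03"), call rate of exactly 0.96 passes, LRR s.d. of exactly 0.35
#' passes.  A missing metric fails the sample with the reason recorded.
#'
#' @param samples data.frame `sample_id`, `n_cnvs`, `waviness`,
#'   `call_rate`, `lrr_sd`.
#' @param max_cnvs,max_waviness,min_call_rate,max_lrr_sd thresholds.
#' @return data.frame `sample_id`, `pass`, `reason` ("" when passing).
#' @export
qc_cnv_samples <- function(samples, max_cnvs = 30L, max_waviness = 0.03,
                           min_call_rate = 0.96, max_lrr_sd = 0.35) {
  reason <- character(nrow(samples))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[bad] <<- ifelse(reason[bad] == "", why,
                           paste(reason[bad], why, sep = ";"))
  }
  flag(samples$n_cnvs >= max_cnvs, "n_cnvs")
  flag(abs(samples$waviness) > max_waviness, "waviness")
  flag(samples$call_rate < min_call_rate, "call_rate")
  flag(samples$lrr_sd > max_lrr_sd, "lrr_sd")
  data.frame(sample_id = samples$sample_id, pass = reason == "",
             reason = reason, stringsAsFactors = FALSE)
}

#' Per-call CNV quality control
#'
#' A call is retained if it is covered by at least 20 probes, has a probe
#' density of at least 1 probe per 20,000 base pairs, and a confidence
#' score of at least 10.  A call of length zero is rejected.
#'
#' @param calls data.frame `sample_id`, `locus`, `type`, `n_probes`,
#'   `length_bp`, `confidence`.
#' @param min_probes,min_density,min_confidence thresholds.
#' @return list with `retained` (the passing subset of `calls`) and
#'   `report` (counts removed per filter).
#' @export
qc_cnv_calls <- function(calls, min_probes = 20L, min_density = 1 / 20000,
                         min_confidence = 10) {
  zero_len <- is.na(calls$length_bp) | calls$length_bp <= 0
  few_probes <- !zero_len & calls$n_probes < min_probes
  sparse <- !zero_len & calls$n_probes / calls$length_bp < min_density
  low_conf <- calls$confidence < min_confidence
  keep <- !(zero_len | few_probes | sparse | low_conf)
  list(retained = calls[keep, , drop = FALSE],
       report = c(n_input = nrow(calls), n_retained = sum(keep),
                  zero_length = sum(zero_len), few_probes = sum(few_probes),
                  sparse_probes = sum(sparse), low_confidence = sum(low_conf)))
}

#' Derive per-individual psychiatric-CNV carrier status
#'
#' Matches QC-passed calls to a named locus list by (locus, type), counts
#' carriers per locus, drops loci observed fewer than `min_observations`
#' times, and sets `any_pcnv` as the union over the retained loci.
#'
#' @param calls QC-passed call data.frame.
#' @param sample_ids ids of all (QC-passed) samples to report on.
#' @param loci data.frame `locus`, `type`.
#' @param min_observations minimum carrier count to retain a locus
#'   (default 5, i.e. loci observed fewer than five times are excluded).
#' @return object of class `carrier_status`: list with `table` (data.frame
#'   `sample_id`, `any_pcnv`, one logical column per retained locus),
#'   `locus_counts` (carrier counts for all requested loci) and
#'   `retained_loci`.
#' @export
carrier_status <- function(calls, sample_ids, loci, min_observations = 5L) {
  unknown <- setdiff(unique(calls$locus), loci$locus)
  if (length(unknown) && nrow(loci))
    warning("calls at loci absent from the locus list were ignored: ",
            paste(unknown, collapse = ", "))
  tab <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  counts <- integer(nrow(loci))
  names(counts) <- loci$locus
  flags <- matrix(FALSE, length(sample_ids), nrow(loci),
                  dimnames = list(NULL, loci$locus))
  for (l in seq_len(nrow(loci))) {
    hit <- calls$locus == loci$locus[l] & calls$type == loci$type[l]
    carriers <- unique(calls$sample_id[hit])
    carriers <- intersect(carriers, sample_ids)
    flags[, l] <- sample_ids %in% carriers
    counts[l] <- length(carriers)
  }
  retained <- names(counts)[counts >= min_observations]
  tab$any_pcnv <- if (length(retained))
    rowSums(flags[, retained, drop = FALSE]) > 0 else
      rep(FALSE, length(sample_ids))
  for (l in retained) tab[[l]] <- flags[, l]
  structure(list(table = tab, locus_counts = counts,
                 retained_loci = retained,
                 min_observations = min_observations),
            class = "carrier_status")
}

#' @export
print.carrier_status <- function(x, ...) {
  cat(sprintf(
    "Carrier status: %d samples, %d/%d loci retained (>= %d carriers), %d any-P-CNV carriers\n",
    nrow(x$table), length(x$retained_loci), length(x$locus_counts),
    x$min_observations, sum(x$table$any_pcnv)))
  invisible(x)
}
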