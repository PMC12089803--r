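# Effect-size comparison on overlapping case-control samples ----------------

#' Correlation between effect estimates from overlapping case-control samples
#'
#' Two logistic effect estimates computed on samples sharing subjects are
#' correlated.  From the influence-function expansion of the logistic MLE,
#' the correlation in terms of the per-study case/control totals and the
#' shared case/control counts is
#'
#'   r = \[ s_case * sqrt(ctrl1 * ctrl2 / (case1 * case2)) +
#'          s_ctrl * sqrt(case1 * case2 / (ctrl1 * ctrl2)) \] /
#'       sqrt(n1 * n2)
#'
#' which is 0 for disjoint samples and 1 for identical, fully shared
#' designs.
#'
#' @param n1_case,n1_control,n2_case,n2_control per-study counts.
#' @param n_shared_case,n_shared_control subjects shared between the
#'   studies as cases / as controls.
#' @return correlation r in [0, 1].
#' @export
overlap_correlation <- function(n1_case, n1_control, n2_case, n2_control,
                                n_shared_case, n_shared_control) {
  counts <- c(n1_case, n1_control, n2_case, n2_control,
              n_shared_case, n_shared_control)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_shared_case > min(n1_case, n2_case) ||
      n_shared_control > min(n1_control, n2_control))
    stop("shared counts exceed study margins")
  if (any(c(n1_case, n1_control, n2_case, n2_control) == 0))
    stop("each study needs both cases and controls")
  n1 <- n1_case + n1_control
  n2 <- n2_case + n2_control
  (n_shared_case * sqrt(n1_control * n2_control / (n1_case * n2_case)) +
      n_shared_control * sqrt(n1_case * n2_case /
                                (n1_control * n2_control))) / sqrt(n1 * n2)
}

#' Z-test for the difference of two correlated effect estimates
#'
#' z = (beta1 - beta2) / sqrt(se1^2 + se2^2 - 2 r se1 se2), with a
#' two-sided normal p-value.  A non-positive difference variance, or a
#' correlation within 1e-9 of 1 (near-identical designs), yields a flagged
#' non-informative result instead of an unstable z.
#'
#' @param beta1,se1,beta2,se2 the two estimates (log-odds scale).
#' @param r correlation of the estimates (e.g. [overlap_correlation()]).
#' @return list `z`, `p`, `var_diff`, `r`, `informative`.
#' @export
effect_difference_z <- function(beta1, se1, beta2, se2, r = 0) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  var_diff <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (r > 1 - 1e-9 || var_diff <= 0) {
    if (var_diff < 0) warning("negative difference variance clipped to 0")
    return(list(z = NA_real_, p = NA_real_, var_diff = max(var_diff, 0),
                r = r, informative = FALSE))
  }
  z <- (beta1 - beta2) / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff, r = r,
       informative = TRUE)
}

#' Pairwise effect-size comparison across phenotype definitions
#'
#' Compares the effect of a shared predictor across all unordered pairs of
#' definitions, computing each pair's sampling correlation from the exact
#' overlap of the analysed case/control id sets and testing the effect
#' difference with [effect_difference_z()].  Significance flags use a
#' Bonferroni threshold over the emitted pairs.
#'
#' @param results named list of `assoc_result`s sharing the predictor.
#' @param id_sets named list (same names) with elements `case` and
#'   `control`: the analysed id sets per definition.
#' @param alpha family-wise alpha for the Bonferroni flag.
#' @return data.frame, one row per pair: `def1`, `def2`, `r`, `z`, `p`,
#'   `significant`.
#' @export
pairwise_compare <- function(results, id_sets, alpha = 0.05) {
  stopifnot(length(results) >= 2L, !is.null(names(results)),
            all(names(results) %in% names(id_sets)))
  preds <- vapply(results, function(r) r$predictor, character(1))
  if (length(unique(preds)) != 1L)
    stop("results compare different predictors: ",
         paste(unique(preds), collapse = ", "))
  nms <- names(results)
  pairs <- utils::combn(nms, 2L)
  n_pairs <- ncol(pairs)
  thr <- bonferroni_threshold(alpha, n_pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ra <- results[[a]]; rb <- results[[b]]
    r <- overlap_correlation(
      length(id_sets[[a]]$case), length(id_sets[[a]]$control),
      length(id_sets[[b]]$case), length(id_sets[[b]]$control),
      length(intersect(id_sets[[a]]$case, id_sets[[b]]$case)),
      length(intersect(id_sets[[a]]$control, id_sets[[b]]$control)))
    dz <- effect_difference_z(ra$beta, ra$se, rb$beta, rb$se, r)
    data.frame(def1 = a, def2 = b, r = r, z = dz$z, p = dz$p,
               significant = !is.na(dz$p) & dz$p < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  out
}
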