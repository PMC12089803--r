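# PRS scoring and reference-panel ancestry adjustment -----------------------

#' Score a polygenic risk score from a weight table
#'
#' PRS_i = sum_v w_v * dosage_iv over the variants shared between the
#' genotype matrix and the weight table.  Missing dosages are imputed to
#' the variant's mean dosage.  When the weight's effect allele equals the
#' variant's *other* allele, the dosage is flipped (2 - dosage); weights
#' whose effect allele matches neither recorded allele are dropped, with
#' the count reported.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights data.frame `variant_id`, `effect_allele`, `weight`.
#' @param variant_ids optional subset (e.g. QC-retained variants).
#' @return numeric vector of raw PRS, named by individual id; attributes
#'   `n_scored`, `n_flipped`, `n_dropped`.
#' @export
score_prs <- function(genotypes, weights, variant_ids = NULL) {
  vs <- genotypes$variants
  use <- intersect(weights$variant_id,
                   variant_ids %||% vs$variant_id)
  if (!length(use)) stop("no overlapping variants between weights and genotypes")
  w <- weights[match(use, weights$variant_id), ]
  v <- vs[match(use, vs$variant_id), ]
  same <- w$effect_allele == v$effect_allele
  flip <- w$effect_allele == v$other_allele
  drop <- !(same | flip)
  if (all(drop)) stop("no allele-matched variants to score")
  use <- use[!drop]; w <- w[!drop, ]; same <- same[!drop]; flip <- flip[!drop]
  dos <- impute_mean(genotypes$dosages[, use, drop = FALSE])
  dos[, flip] <- 2 - dos[, flip]
  prs <- as.numeric(dos %*% w$weight)
  names(prs) <- genotypes$ids
  attr(prs, "n_scored") <- length(use)
  attr(prs, "n_flipped") <- sum(flip)
  attr(prs, "n_dropped") <- sum(drop)
  prs
}

#' Principal components of a reference panel
#'
#' Standardises each variant (reference mean 0, unit variance;
#' zero-variance variants dropped) and extracts the top-k right singular
#' vectors as loadings.  Signs are fixed so the largest-magnitude loading
#' element of each component is positive, making the decomposition
#' deterministic.
#'
#' @param ref_genotypes a `genotype_matrix` for the reference panel.
#' @param k number of components (>= 1).
#' @param variant_ids variants to use (typically LD-pruned).
#' @return object of class `ancestry_model`: list with `variant_ids`,
#'   `center`, `scale`, `loadings` (variants x k), `scores` (reference PC
#'   scores), `k`.
#' @export
reference_pca <- function(ref_genotypes, k = 5L,
                          variant_ids = NULL) {
  if (k < 1L) stop("k must be at least 1")
  ids <- variant_ids %||% ref_genotypes$variants$variant_id
  X <- impute_mean(ref_genotypes$dosages[, ids, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  ok <- scl > 0
  ids <- ids[ok]; X <- X[, ok, drop = FALSE]
  ctr <- ctr[ok]; scl <- scl[ok]
  if (k > min(dim(X)) - 1L) stop("k exceeds the rank of the reference panel")
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  sv <- svd(Z, nu = 0L, nv = k)
  loadings <- sv$v
  for (j in seq_len(k))
    if (loadings[which.max(abs(loadings[, j])), j] < 0)
      loadings[, j] <- -loadings[, j]
  dimnames(loadings) <- list(ids, paste0("PC", seq_len(k)))
  scores <- Z %*% loadings
  rownames(scores) <- ref_genotypes$ids
  structure(list(variant_ids = ids, center = ctr, scale = scl,
                 loadings = loadings, scores = scores, k = k),
            class = "ancestry_model")
}

#' Project samples onto reference principal components
#'
#' Standardises target dosages with the *reference* means and standard
#' deviations and multiplies by the reference loadings, so target scores
#' live in the reference PC space.
#'
#' @param genotypes a `genotype_matrix` for the target samples.
#' @param model an `ancestry_model` from [reference_pca()].
#' @return matrix of PC scores (individuals x k).
#' @export
project_samples <- function(genotypes, model) {
  missing <- setdiff(model$variant_ids, genotypes$variants$variant_id)
  if (length(missing))
    stop("target genotypes lack model variants: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...")
  X <- genotypes$dosages[, model$variant_ids, drop = FALSE]
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  Z[is.na(Z)] <- 0  # missing dosage = reference mean
  scores <- Z %*% model$loadings
  rownames(scores) <- genotypes$ids
  scores
}

#' Post hoc ancestry adjustment of a raw PRS
#'
#' Fits `raw_prs ~ PC1 + ... + PCk` on the reference panel, then for any
#' sample with projected PCs returns `(raw - predicted) / s`, where `s` is
#' the standard deviation of the reference residuals (default) or the
#' residual variance (`scale = "variance"`, the literal reading).  On the
#' reference panel itself the adjusted score has mean 0 and, with the SD
#' scale, variance 1 overall and approximately per population, putting
#' scores from different ancestries on the same scale.
#'
#' @param raw_prs raw PRS for the target samples.
#' @param pcs matrix of projected PCs for the target samples.
#' @param ref_prs,ref_pcs raw PRS and PC scores of the reference panel the
#'   regression is fitted on; default to the target arguments (panel
#'   adjusting itself).
#' @param k number of components used (default 5).
#' @param scale "sd" (default) or "variance".
#' @return list with `adjusted` (numeric vector), `coefficients`,
#'   `residual_sd`.
#' @export
ancestry_adjust <- function(raw_prs, pcs, ref_prs = raw_prs, ref_pcs = pcs,
                            k = 5L, scale = c("sd", "variance")) {
  scale <- match.arg(scale)
  ref_pcs <- as.matrix(ref_pcs)[, seq_len(k), drop = FALSE]
  pcs <- as.matrix(pcs)[, seq_len(k), drop = FALSE]
  if (length(ref_prs) < k + 2L)
    stop("reference panel too small for ", k, " components")
  fit <- stats::lm.fit(cbind(1, ref_pcs), ref_prs)
  beta <- fit$coefficients
  res_sd <- stats::sd(fit$residuals)
  denom <- if (scale == "sd") res_sd else res_sd^2
  predicted <- as.numeric(cbind(1, pcs) %*% beta)
  list(adjusted = (raw_prs - predicted) / denom,
       coefficients = beta, residual_sd = res_sd)
}
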