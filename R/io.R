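# Plain-text readers/writers for the pipeline's tabular formats -------------

#' Write / read a dosage matrix as TSV
#'
#' Layout: one row per variant with columns `variant_id`, `position`,
#' `effect_allele`, `other_allele`, `info`, then one dosage column per
#' individual (NA = missing).
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path.
#' @return `read_dosage_tsv` returns a `genotype_matrix` (population
#'   labels default to 1).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  v <- genotypes$variants[, c("variant_id", "position", "effect_allele",
                              "other_allele", "info")]
  tab <- cbind(v, as.data.frame(t(genotypes$dosages)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta_cols <- c("variant_id", "position", "effect_allele", "other_allele",
                 "info")
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  storage.mode(dos) <- "integer"
  ids <- rownames(dos)
  colnames(dos) <- tab$variant_id
  structure(list(dosages = dos,
                 variants = cbind(tab[, meta_cols],
                                  ancestral_freq = colMeans(dos,
                                                            na.rm = TRUE) / 2),
                 ids = ids, population = rep(1L, length(ids))),
            class = "genotype_matrix")
}

#' Write / read dosages as a minimal VCF 4.2 with a DS FORMAT field
#'
#' One ALT allele per record; the effect allele is written as ALT and the
#' dosage is the ALT-allele dosage.  Missing dosages are written as ".".
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path.
#' @return `read_vcf_dosage` returns a `genotype_matrix`.
#' @export
write_vcf_dosage <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$ids), collapse = "\t")),
             con)
  v <- genotypes$variants
  dos <- t(genotypes$dosages)
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- dos[j, ]
    ds <- ifelse(is.na(ds), ".", format(ds))
    paste(c("1", v$position[j], v$variant_id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "DS", ds),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_vcf_dosage
#' @export
read_vcf_dosage <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: no #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  body <- lines[-seq_len(hdr)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  m <- length(fields)
  ids <- cols[-(1:9)]
  dos <- matrix(NA_integer_, length(ids), m)
  v <- data.frame(variant_id = character(m), position = integer(m),
                  effect_allele = character(m), other_allele = character(m),
                  info = 1, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- fields[[j]]
    v$variant_id[j] <- f[3]; v$position[j] <- as.integer(f[2])
    v$other_allele[j] <- f[4]; v$effect_allele[j] <- f[5]
    ds <- f[-(1:9)]
    dos[, j] <- suppressWarnings(as.integer(ds))
  }
  dimnames(dos) <- list(ids, v$variant_id)
  v$ancestral_freq <- colMeans(dos, na.rm = TRUE) / 2
  structure(list(dosages = dos, variants = v, ids = ids,
                 population = rep(1L, length(ids))),
            class = "genotype_matrix")
}

#' Write definition flags as long-format TSV
#' @param flags a `definition_flags` table.
#' @param path file path.
#' @export
write_flags_tsv <- function(flags, path) {
  utils::write.table(flags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to plain-text files with a JSON manifest
#'
#' Writes the dosage matrix, weight tables, CNV call and sample tables,
#' the per-source phenotype record tables and the latent truth table as
#' TSV, plus a manifest JSON recording paths, the seed and file hashes.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_dosage_tsv(cohort$genotypes, p("dosages.tsv"))
  write_tsv(cohort$weights, p("weights.tsv"))
  write_tsv(cohort$latent$table, p("truth.tsv"))
  write_tsv(cohort$cnv$calls, p("cnv_calls.tsv"))
  write_tsv(cohort$cnv$samples, p("cnv_samples.tsv"))
  r <- cohort$records
  write_tsv(r$availability, p("availability.tsv"))
  write_tsv(r$touchscreen, p("touchscreen.tsv"))
  write_tsv(r$interview, p("interview.tsv"))
  write_tsv(r$gad7, p("mhq_gad7.tsv"))
  write_tsv(r$cidi, p("mhq_cidi.tsv"))
  write_tsv(r$mhq_diagnosis, p("mhq_diagnosis.tsv"))
  write_tsv(r$ehr, p("ehr.tsv"))
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(seed = cohort$config$seed,
                   n_individuals = cohort$config$n_individuals,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
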