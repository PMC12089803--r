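# Clinical code lists -------------------------------------------------------

#' Built-in toy clinical code lists
#'
#' A small, self-contained stand-in for curated clinical code lists: one
#' row per (code, coding system, disorder, source).  Disorders are `mood`,
#' `anxiety` or `exclusion` (schizophrenia / bipolar disorder).  Sources
#' are `hospital` (ICD-10-like), `primary_care` (Read-like), `medication`
#' (drug codes; antidepressants are listed under mood, benzodiazepines
#' under anxiety) and `interview` (self-report codes).  Exclusion codes are
#' ordered schizophrenia-first within each source.
#'
#' These are deliberately synthetic enumerations for testing and the
#' bundled generator, not any licensed code list.
#'
#' @return data.frame with columns `code`, `system`, `disorder`, `source`.
#' @export
default_code_lists <- function() {
  rbind(
    data.frame(code = c("F320", "F321", "F329", "F330", "F331"),
               system = "icd10-like", disorder = "mood", source = "hospital"),
    data.frame(code = c("F400", "F410", "F411", "F419"),
               system = "icd10-like", disorder = "anxiety",
               source = "hospital"),
    data.frame(code = c("F200", "F310"), system = "icd10-like",
               disorder = "exclusion", source = "hospital"),
    data.frame(code = c("E112", "E113", "E130"), system = "read-like",
               disorder = "mood", source = "primary_care"),
    data.frame(code = c("E200", "E202", "E2003"), system = "read-like",
               disorder = "anxiety", source = "primary_care"),
    data.frame(code = c("EU20", "EU31"), system = "read-like",
               disorder = "exclusion", source = "primary_care"),
    data.frame(code = c("AD_CITALOPRAM", "AD_FLUOXETINE", "AD_SERTRALINE",
                        "AD_AMITRIPTYLINE"),
               system = "med-code", disorder = "mood", source = "medication"),
    data.frame(code = c("BZ_DIAZEPAM", "BZ_LORAZEPAM", "BZ_TEMAZEPAM"),
               system = "med-code", disorder = "anxiety",
               source = "medication"),
    data.frame(code = c("SR_DEPRESSION", "SR_POSTNATAL_DEPRESSION"),
               system = "self-report", disorder = "mood",
               source = "interview"),
    data.frame(code = c("SR_ANXIETY", "SR_PANIC_ATTACKS"),
               system = "self-report", disorder = "anxiety",
               source = "interview"),
    data.frame(code = c("SR_SCHIZOPHRENIA", "SR_BIPOLAR"),
               system = "self-report", disorder = "exclusion",
               source = "interview"))
}

#' Normalise a clinical code for matching
#'
#' Strips dots and upper-cases, so `"F32.0"` and `"f320"` match.
#'
#' @param code character vector of codes.
#' @return normalised character vector.
#' @export
normalise_code <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

#' Match observed codes against a code list
#'
#' @param codes character vector of observed codes.
#' @param list_codes character vector of list codes.
#' @param prefix if TRUE, an observed code matches when it starts with a
#'   list code (truncated hierarchical codes); default exact match.
#' @return logical vector, one element per observed code.
#' @export
match_codes <- function(codes, list_codes, prefix = FALSE) {
  codes <- normalise_code(codes)
  list_codes <- normalise_code(list_codes)
  if (!prefix) return(codes %in% list_codes)
  out <- rep(FALSE, length(codes))
  for (lc in unique(list_codes))
    out <- out | startsWith(codes, lc)
  out
}

#' Read / write code lists as CSV
#'
#' CSV columns: `code`, `system`, `disorder`, `source`.
#'
#' @param path file path.
#' @param code_lists data.frame to write.
#' @return `read_code_lists` returns the data.frame.
#' @export
read_code_lists <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "system", "disorder", "source")
  if (!all(need %in% names(df)))
    stop_config("code list CSV must have columns ",
                paste(need, collapse = ", "))
  df
}

#' @rdname read_code_lists
#' @export
write_code_lists <- function(code_lists, path) {
  utils::write.csv(code_lists, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
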