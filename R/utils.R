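#' @keywords internal
"_PACKAGE"

# Internal assertion helpers ------------------------------------------------

stop_config <- function(...) {
  stop(structure(class = c("prscnv_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_fraction <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok)
    stop_config(name, " must be a fraction in ",
                if (open_lower) "(" else "[", "0,1",
                if (open_upper) ")" else "]", ", got ", format(x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean-impute missing dosages, column-wise, returning a double matrix.
impute_mean <- function(dos) {
  dos <- as.matrix(dos)
  storage.mode(dos) <- "double"
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2L]]
  }
  dos
}
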