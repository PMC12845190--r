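# Shared small helpers: rounding, formatting, unit conversion.

ANGSTROM_PER_NM <- 10

ang_to_nm <- function(x) x / ANGSTROM_PER_NM
nm_to_ang <- function(x) x * ANGSTROM_PER_NM

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentage tables in this
#' field round half up, so summaries use this variant.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# mean and sample sd (n-1) of a numeric series; sd is NA for n == 1
series_summary <- function(x, unit) {
  n <- length(x)
  stopifnot(n >= 1)
  list(mean = mean(x), sd = if (n >= 2) stats::sd(x) else NA_real_,
       n = n, unit = unit)
}

# fixed-width numeric formatting used by all table renderers so that repeated
# runs are byte-identical
fmt_num <- function(x, digits) {
  formatC(x, format = "f", digits = digits)
}

write_tsv_file <- function(df, path) {
  cols <- vapply(df, function(col) {
    if (is.numeric(col)) as.character(col) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cols, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
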