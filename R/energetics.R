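#' @name energetics_bookkeeping
#' @title MM/PBSA-style energy component bookkeeping
#'
#' @description
#' Aggregates per-frame binding free-energy components into the usual
#' end-state summary: gas-phase term `GGAS = VDWAALS + EEL`, solvation term
#' `GSOLV = EPB + ENPOLAR`, and `TOTAL = GGAS + GSOLV`, each reported as
#' mean plus-minus sample SD over frames. The derived terms are computed per
#' frame and then summarised, so the additivity identities hold exactly at
#' the mean level. The Poisson-Boltzmann and surface-area terms themselves
#' are inputs, produced upstream by an MM/PBSA engine; entropy corrections
#' are out of scope.
NULL

ENERGY_COMPONENTS <- c("VDWAALS", "EEL", "EPB", "ENPOLAR")

#' Construct an energy component series
#' @param vdwaals,eel,epb,enpolar equal-length numeric per-frame series,
#'   kcal/mol
#' @return an `EnergyComponentSeries` (data.frame)
#' @export
energy_series <- function(vdwaals, eel, epb, enpolar) {
  n <- length(vdwaals)
  stopifnot(n >= 1, length(eel) == n, length(epb) == n,
            length(enpolar) == n)
  df <- data.frame(VDWAALS = vdwaals, EEL = eel, EPB = epb,
                   ENPOLAR = enpolar)
  if (!all(is.finite(as.matrix(df)))) stop("non-finite energy values")
  class(df) <- c("EnergyComponentSeries", "data.frame")
  df
}

#' Read a per-frame energy component table (TSV)
#'
#' The header must name the four components `VDWAALS`, `EEL`, `EPB`,
#' `ENPOLAR`; extra columns (e.g. a frame index) are ignored.
#'
#' @param path TSV path
#' @return an `EnergyComponentSeries`
#' @export
read_component_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(ENERGY_COMPONENTS, names(df))
  if (length(missing) > 0) {
    stop("component table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  energy_series(df$VDWAALS, df$EEL, df$EPB, df$ENPOLAR)
}

#' Write a per-frame energy component table (TSV)
#' @param series an `EnergyComponentSeries`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_component_table <- function(series, path) {
  df <- data.frame(frame = seq_len(nrow(series)),
                   series[, ENERGY_COMPONENTS])
  write_tsv_file(df, path)
}

#' Summarise energy components
#'
#' @param series an `EnergyComponentSeries`
#' @return an `EnergySummary`: data.frame with one row per term (`VDWAALS`,
#'   `EEL`, `EPB`, `ENPOLAR`, `GGAS`, `GSOLV`, `TOTAL`), columns `mean` and
#'   `sd` (sample SD of the per-frame series, NA for a single frame), plus
#'   attribute `n`
#' @export
summarize_energy <- function(series) {
  stopifnot(inherits(series, "EnergyComponentSeries"), nrow(series) >= 1)
  terms <- list(
    VDWAALS = series$VDWAALS, EEL = series$EEL,
    EPB = series$EPB, ENPOLAR = series$ENPOLAR,
    GGAS = series$VDWAALS + series$EEL,
    GSOLV = series$EPB + series$ENPOLAR)
  terms$TOTAL <- terms$GGAS + terms$GSOLV
  n <- nrow(series)
  out <- data.frame(
    term = names(terms),
    mean = vapply(terms, mean, 0),
    sd = vapply(terms, function(x) if (n >= 2) stats::sd(x) else NA_real_, 0),
    row.names = NULL)
  class(out) <- c("EnergySummary", "data.frame")
  attr(out, "n") <- n
  out
}

energy_mean <- function(summary, term) {
  summary$mean[summary$term == term]
}

#' Difference in mean total binding free energy
#'
#' `mean(TOTAL_a) - mean(TOTAL_b)`, kcal/mol; negative when system A binds
#' more favourably.
#'
#' @param a,b `EnergySummary` objects
#' @return kcal/mol
#' @export
delta_binding <- function(a, b) {
  stopifnot(inherits(a, "EnergySummary"), inherits(b, "EnergySummary"))
  energy_mean(a, "TOTAL") - energy_mean(b, "TOTAL")
}
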