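#' @name library_design_adme
#' @title Combinatorial R-group library and drug-likeness filtering
#'
#' @description
#' Enumerates a two-substituent combinatorial library under the `(R2.R1)`
#' naming scheme (head group R2, tail group R1), then filters per-compound
#' descriptor records through the five classical drug-likeness inequality
#' sets (Lipinski, Ghose, Veber, Egan, Muegge), a consensus-logP CNS
#' permeation window, and optional efflux/metabolism flags (P-gp substrate
#' status, CYP isoform inhibition count). Numeric rule thresholds live in
#' `inst/extdata/druglikeness_rules.json`, not in code; descriptors are
#' consumed as data (e.g. from an ADME prediction service export), never
#' recomputed from structure here.
NULL

#' Enumerate the combinatorial library
#'
#' All combinations of tail index `r1 = 1..n_r1` and head index
#' `r2 = 1..n_r2`, ordered r2-major, named `"{r2}.{r1}"` (so R1 = 7 with
#' R2 = 9 is compound `"9.7"`).
#'
#' @param n_r1 number of tail groups
#' @param n_r2 number of head groups
#' @return data.frame with `name`, `r1`, `r2`
#' @export
enumerate_library <- function(n_r1 = 12L, n_r2 = 15L) {
  stopifnot(n_r1 >= 1, n_r2 >= 1)
  grid <- expand.grid(r1 = seq_len(n_r1), r2 = seq_len(n_r2))
  grid <- grid[order(grid$r2, grid$r1), ]
  data.frame(name = paste0(grid$r2, ".", grid$r1),
             r1 = grid$r1, r2 = grid$r2, row.names = NULL)
}

#' Parse a compound name back to its (r1, r2) indices
#' @param name compound name like `"9.7"`
#' @return list with `r1`, `r2`
#' @export
parse_compound_id <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || anyNA(suppressWarnings(as.integer(parts)))) {
    stop("malformed compound name '", name, "'")
  }
  list(r1 = as.integer(parts[2]), r2 = as.integer(parts[1]))
}

#' Consensus logP of a descriptor record
#'
#' If the record carries a precomputed `consensus_logp` it is used
#' verbatim; otherwise the arithmetic mean of the entries in
#' `logp_estimates` is returned.
#'
#' @param record named list / one-row data.frame of descriptors
#' @return consensus logP value
#' @export
consensus_logp <- function(record) {
  cl <- record$consensus_logp
  if (!is.null(cl) && length(cl) == 1 && !is.na(cl)) return(as.numeric(cl))
  est <- unlist(record$logp_estimates)
  est <- est[!is.na(est)]
  if (length(est) == 0) stop("record has no logP estimate")
  mean(as.numeric(est))
}

#' Drug-likeness rule thresholds
#' @param path optional JSON config overriding the bundled thresholds
#' @return nested list of thresholds per rule
#' @export
default_rule_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "druglikeness_rules.json",
                        package = "mdligand")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

rule_field <- function(record, field) {
  v <- record[[field]]
  if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
}

count_violations <- function(conds) {
  # conds: logical vector, TRUE = inequality satisfied; NA = missing input
  if (anyNA(conds)) return(NA_integer_)
  sum(!conds)
}

#' Evaluate the five drug-likeness rules and the CNS logP window
#'
#' Violation counts are per broken inequality. A rule whose required
#' descriptor is missing is marked not-evaluable (count NA, name listed in
#' `not_evaluable`) rather than silently passing with zero violations.
#'
#' Descriptor fields used: `mw`, logP (consensus, see [consensus_logp()]),
#' `hbd`, `hba`, `tpsa`, `rotatable_bonds`, `molar_refractivity`,
#' `atom_count`, `ring_count`, `carbon_count`, `heteroatom_count`.
#'
#' @param record named list / one-row data.frame of descriptors
#' @param thresholds rule thresholds (see [default_rule_thresholds()])
#' @return a `RuleReport`: list with `violations` (named integer vector,
#'   NA = not evaluable), `not_evaluable`, `consensus_logp`, `cns_pass`,
#'   `overall_pass`
#' @export
evaluate_rules <- function(record, thresholds = default_rule_thresholds()) {
  th <- thresholds
  logp <- tryCatch(consensus_logp(record), error = function(e) NA_real_)
  mw <- rule_field(record, "mw")
  hbd <- rule_field(record, "hbd")
  hba <- rule_field(record, "hba")
  tpsa <- rule_field(record, "tpsa")
  rotb <- rule_field(record, "rotatable_bonds")
  mr <- rule_field(record, "molar_refractivity")
  atoms <- rule_field(record, "atom_count")
  rings <- rule_field(record, "ring_count")
  carbons <- rule_field(record, "carbon_count")
  hetero <- rule_field(record, "heteroatom_count")

  violations <- c(
    lipinski = count_violations(c(
      mw <= th$lipinski$mw_max, logp <= th$lipinski$logp_max,
      hbd <= th$lipinski$hbd_max, hba <= th$lipinski$hba_max)),
    ghose = count_violations(c(
      mw >= th$ghose$mw_min, mw <= th$ghose$mw_max,
      logp >= th$ghose$logp_min, logp <= th$ghose$logp_max,
      mr >= th$ghose$mr_min, mr <= th$ghose$mr_max,
      atoms >= th$ghose$atoms_min, atoms <= th$ghose$atoms_max)),
    veber = count_violations(c(
      rotb <= th$veber$rotb_max, tpsa <= th$veber$tpsa_max)),
    egan = count_violations(c(
      logp <= th$egan$logp_max, tpsa <= th$egan$tpsa_max)),
    muegge = count_violations(c(
      mw >= th$muegge$mw_min, mw <= th$muegge$mw_max,
      logp >= th$muegge$logp_min, logp <= th$muegge$logp_max,
      tpsa <= th$muegge$tpsa_max, rings <= th$muegge$rings_max,
      carbons > th$muegge$carbons_min_exclusive,
      hetero > th$muegge$heteroatoms_min_exclusive,
      rotb <= th$muegge$rotb_max, hba <= th$muegge$hba_max,
      hbd <= th$muegge$hbd_max)))
  cns_pass <- !is.na(logp) && logp >= th$cns_logp$min && logp <= th$cns_logp$max
  structure(list(
    violations = violations,
    not_evaluable = names(violations)[is.na(violations)],
    consensus_logp = logp,
    cns_pass = cns_pass,
    overall_pass = all(violations == 0, na.rm = TRUE) && cns_pass),
    class = "RuleReport")
}

record_flag <- function(record, field) {
  v <- record[[field]]
  if (is.null(v) || length(v) == 0 || is.na(v)) return(FALSE)
  if (is.character(v)) return(toupper(v) %in% c("YES", "TRUE", "1"))
  isTRUE(as.logical(v))
}

CYP_ISOFORMS <- c("cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6", "cyp3a4")

#' Filter a compound library by drug-likeness, CNS window and flags
#'
#' A compound passes when every evaluable rule has zero violations, its
#' consensus logP sits in the CNS window, and (optionally) it is not a
#' P-gp substrate and inhibits at most `max_cyp_inhibition` CYP isoforms.
#' The pass list is ordered by compound id (r2-major).
#'
#' @param records data.frame with a `name` column plus descriptor columns
#'   (see [evaluate_rules()]); flag columns `pgp_substrate` and
#'   `cyp1a2`..`cyp3a4` are used when the flag filters are enabled
#' @param thresholds rule thresholds
#' @param exclude_pgp_substrate drop P-gp substrates?
#' @param max_cyp_inhibition maximum number of inhibited CYP isoforms
#'   (default `Inf`, i.e. no CYP filter)
#' @return list with `pass` (data.frame of passing records, id-ordered)
#'   and `reports` (named list of per-compound `RuleReport`s)
#' @export
filter_library <- function(records, thresholds = default_rule_thresholds(),
                           exclude_pgp_substrate = FALSE,
                           max_cyp_inhibition = Inf) {
  stopifnot("name" %in% names(records))
  if (anyDuplicated(records$name)) {
    stop("duplicate compound ids: ",
         paste(unique(records$name[duplicated(records$name)]),
               collapse = ", "))
  }
  if (nrow(records) == 0) {
    return(list(pass = records, reports = list()))
  }
  reports <- list()
  pass <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, ])
    rep_i <- evaluate_rules(rec, thresholds)
    ok <- rep_i$overall_pass
    if (ok && exclude_pgp_substrate && record_flag(rec, "pgp_substrate")) {
      ok <- FALSE
    }
    if (ok && is.finite(max_cyp_inhibition)) {
      n_cyp <- sum(vapply(CYP_ISOFORMS, function(f) record_flag(rec, f), TRUE))
      if (n_cyp > max_cyp_inhibition) ok <- FALSE
    }
    reports[[records$name[i]]] <- rep_i
    pass[i] <- ok
  }
  passed <- records[pass, , drop = FALSE]
  ids <- lapply(passed$name, parse_compound_id)
  ord <- order(vapply(ids, `[[`, 0L, "r2"), vapply(ids, `[[`, 0L, "r1"))
  passed <- passed[ord, , drop = FALSE]
  rownames(passed) <- NULL
  list(pass = passed, reports = reports)
}

#' Read a descriptor table (TSV)
#'
#' Expects a `name` column plus any of the descriptor columns used by
#' [evaluate_rules()] and the flag columns used by [filter_library()].
#'
#' @param path TSV path
#' @return data.frame of descriptor records
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(df)) stop("descriptor table needs a 'name' column")
  df$name <- as.character(df$name)
  df
}
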