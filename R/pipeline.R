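#' @name pipeline_cli
#' @title End-to-end two-system comparison and report rendering
#'
#' @description
#' Orchestrates the full comparison of two protein-ligand systems:
#' trajectory descriptors (RMSD, RMSF, Rg) per system, flexibility
#' classification and differential sliding-window segments, trajectory
#' interaction fingerprints with persistence, final-snapshot interaction
#' detection, and (when component tables are supplied) energy summaries and
#' their delta. `render_tables()` writes every section as fixed-format TSV
#' plus a JSON mirror under one run directory with a provenance manifest,
#' so identical inputs and seed give byte-identical outputs.
NULL

#' Run the two-system comparison
#'
#' @param system_a,system_b annotated `FrameSeries` objects (or multi-model
#'   PDB paths, read with `ligand_codes`)
#' @param energy_a,energy_b optional `EnergyComponentSeries` (or TSV paths);
#'   when absent the energy section is marked absent
#' @param ligand_codes ligand residue names used when reading paths
#' @param templates chemistry role templates used to annotate systems read
#'   from disk; must contain an entry for the ligand residue name
#' @param options analysis options: `window`, `min_abs_diff` (nm),
#'   `fit_selection`, detector thresholds are package defaults
#' @param seed seed recorded in the manifest (analyses are deterministic)
#' @return a `ComparisonReport` list
#' @export
run_compare <- function(system_a, system_b, energy_a = NULL, energy_b = NULL,
                        ligand_codes = "INH",
                        templates = default_residue_roles(),
                        options = list(window = 5L, min_abs_diff = 0.2,
                                       fit_selection = "backbone"),
                        seed = 1L) {
  load_sys <- function(x) {
    if (is.character(x)) x <- read_frame_series(x, ligand_codes = ligand_codes)
    if (!isTRUE(x$annotation$annotated)) x <- annotate_chemistry(x, templates)
    x
  }
  load_energy <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_component_table(x) else x
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sys <- list(A = load_sys(system_a), B = load_sys(system_b))
  en <- list(A = load_energy(energy_a), B = load_energy(energy_b))
  fit_sel <- options$fit_selection %||% "backbone"

  per_system <- lapply(sys, function(s) {
    has_lig <- any(s$ligand_mask)
    final <- n_frames(s)
    list(
      rmsd_protein = stage("rmsd_series", rmsd_series(s, fit_sel)),
      rmsd_ligand = if (has_lig)
        stage("rmsd_ligand", rmsd_series(s, fit_sel, "ligand")) else NULL,
      rg_protein = stage("rg_series", rg_series(s, "protein")),
      rg_ligand = if (has_lig)
        stage("rg_ligand", rg_series(s, "ligand")) else NULL,
      rmsf = stage("rmsf_profile", rmsf_profile(s, fit_sel)),
      fingerprint = if (has_lig)
        stage("fingerprint", fingerprint_trajectory(s)) else NULL,
      snapshot = if (has_lig) stage("snapshot", list(
        hbonds = detect_hbonds_frame(s, final),
        salt_bridges = detect_salt_bridges_frame(s, final),
        pi_stacking = detect_pi_stacking_frame(s, final),
        hydrophobic = detect_hydrophobic_frame(s, final))) else NULL)
  })
  classing <- lapply(per_system, function(p)
    stage("classify", classify_flexibility(p$rmsf)))
  segments <- stage("sliding_window_diff", sliding_window_diff(
    per_system$A$rmsf, per_system$B$rmsf,
    window = options$window %||% 5L,
    min_abs_diff = options$min_abs_diff %||% 0.2))
  energy <- NULL
  if (!is.null(en$A) && !is.null(en$B)) {
    energy <- stage("energetics", list(
      A = summarize_energy(en$A), B = summarize_energy(en$B)))
    energy$delta_total <- delta_binding(energy$A, energy$B)
  }
  structure(list(
    per_system = per_system,
    flexibility = lapply(classing, flexibility_summary),
    classing = classing,
    segments = segments,
    energy = energy,
    metadata = list(seed = seed,
                    options = options,
                    package_version = as.character(
                      utils::packageVersion("mdligand")))),
    class = "ComparisonReport")
}

fmt_summary_row <- function(name, s, digits = 3) {
  data.frame(series = name, mean = fmt_num(s$summary$mean, digits),
             sd = fmt_num(s$summary$sd, digits), n = s$summary$n,
             unit = s$summary$unit)
}

#' Render a comparison report into a run directory
#'
#' Fixed column orders and fixed decimal formatting (RMSF 4 dp nm,
#' distances 2 dp, percentages 2 dp, energies 2 dp) keep repeat runs
#' byte-identical. A `manifest.json` records seed, options hash and
#' package version.
#'
#' @param report a `ComparisonReport`
#' @param outdir output directory (created if missing)
#' @return character vector of files written, invisibly
#' @export
render_tables <- function(report, outdir) {
  stopifnot(inherits(report, "ComparisonReport"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_file(df, path)
    files <<- c(files, path)
  }
  for (sysname in c("A", "B")) {
    p <- report$per_system[[sysname]]
    summaries <- list(protein_rmsd = p$rmsd_protein,
                      ligand_rmsd = p$rmsd_ligand,
                      protein_rg = p$rg_protein, ligand_rg = p$rg_ligand)
    summaries <- Filter(Negate(is.null), summaries)
    emit(do.call(rbind, lapply(names(summaries), function(nm)
      fmt_summary_row(nm, summaries[[nm]]))),
      paste0("descriptors_", sysname, ".tsv"))
    emit(data.frame(resid = p$rmsf$resid,
                    rmsf_nm = fmt_num(p$rmsf$rmsf, 4)),
         paste0("rmsf_", sysname, ".tsv"))
    flex <- report$flexibility[[sysname]]
    emit(data.frame(class = flex$class, count = flex$count,
                    percentage = fmt_num(flex$percentage, 2)),
         paste0("flexibility_", sysname, ".tsv"))
    if (!is.null(p$fingerprint)) {
      k <- p$fingerprint$keys
      emit(data.frame(resid = k$resid, type = k$type,
                      persistence = fmt_num(p$fingerprint$persistence, 4)),
           paste0("persistence_", sysname, ".tsv"))
    }
    if (!is.null(p$snapshot)) {
      counts <- vapply(p$snapshot, nrow, 0L)
      emit(data.frame(interaction = names(counts), count = counts),
           paste0("snapshot_counts_", sysname, ".tsv"))
    }
  }
  seg <- report$segments
  emit(data.frame(start_residue = seg$start_residue,
                  end_residue = seg$end_residue,
                  direction = seg$direction,
                  peak_abs_diff = fmt_num(seg$peak_abs_diff, 4)),
       "segments.tsv")
  if (!is.null(report$energy)) {
    for (sysname in c("A", "B")) {
      es <- report$energy[[sysname]]
      emit(data.frame(term = es$term, mean = fmt_num(es$mean, 2),
                      sd = fmt_num(es$sd, 2)),
           paste0("energy_", sysname, ".tsv"))
    }
    emit(data.frame(quantity = "delta_total",
                    value = fmt_num(report$energy$delta_total, 2)),
         "energy_delta.tsv")
  }
  manifest <- list(
    seed = report$metadata$seed,
    options_hash = unname(tools::md5sum(
      local({
        f <- file.path(outdir, ".options.tmp")
        writeLines(paste(deparse(report$metadata$options), collapse = ""), f)
        f
      }))),
    package_version = report$metadata$package_version)
  file.remove(file.path(outdir, ".options.tmp"))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, manifest_path)
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report_to_json(report), json_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = 6)
  files <- c(files, json_path)
  invisible(files)
}

report_to_json <- function(report) {
  per_sys <- lapply(report$per_system, function(p) {
    out <- list(
      protein_rmsd = p$rmsd_protein$summary,
      protein_rg = p$rg_protein$summary,
      rmsf = list(resid = p$rmsf$resid, rmsf_nm = round(p$rmsf$rmsf, 6)))
    if (!is.null(p$rmsd_ligand)) out$ligand_rmsd <- p$rmsd_ligand$summary
    if (!is.null(p$rg_ligand)) out$ligand_rg <- p$rg_ligand$summary
    if (!is.null(p$snapshot)) {
      out$snapshot_counts <- lapply(p$snapshot, nrow)
    }
    out
  })
  list(systems = per_sys,
       flexibility = report$flexibility,
       segments = report$segments,
       energy = if (is.null(report$energy)) "absent" else list(
         A = report$energy$A, B = report$energy$B,
         delta_total = report$energy$delta_total),
       metadata = report$metadata)
}
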