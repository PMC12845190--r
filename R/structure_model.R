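#' @name structure_model
#' @title Molecular frame series: topology, trajectory frames and chemistry
#'
#' @description
#' The central container of the package is the `FrameSeries`: a fixed atom
#' table (topology) plus `T` coordinate frames in Angstrom, with optional
#' chemical-role annotation (hydrogen-bond donors and acceptors, charged
#' groups, aromatic rings, apolar atoms) used by the interaction-fingerprint
#' detectors. Multi-model PDB is the on-disk trajectory format; fixed columns
#' follow wwPDB v3.3.
NULL

ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.99, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, SE = 78.971
)

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- ATOMIC_MASSES[key]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

empty_annotation <- function() {
  list(donor_pairs = matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("heavy", "hydrogen"))),
       acceptors = integer(0),
       charged_groups = list(),
       rings = list(),
       apolar = integer(0),
       missing_donor_h = character(0),
       annotated = FALSE)
}

#' Construct a molecular frame series
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `resid`,
#'   `resname`, `chain`, `mass` (amu), one row per atom.
#' @param frames numeric array `T x N x 3`, coordinates in Angstrom. A single
#'   `N x 3` matrix is promoted to one frame.
#' @param frame_times numeric vector of frame times in ns, strictly
#'   increasing; defaults to `0:(T-1)`.
#' @param ligand_mask logical vector of length N flagging ligand atoms.
#' @return object of class `FrameSeries`
#' @export
frame_series <- function(atoms, frames, frame_times = NULL, ligand_mask = NULL) {
  req <- c("serial", "name", "element", "resid", "resname", "chain", "mass")
  if (!all(req %in% names(atoms))) {
    stop("atoms table missing columns: ",
         paste(setdiff(req, names(atoms)), collapse = ", "))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(1L, dim(frames)))
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == 3L)
  n <- nrow(atoms)
  if (dim(frames)[2] != n) {
    stop("frame coordinate count (", dim(frames)[2],
         ") does not match atom count (", n, ")")
  }
  if (!all(is.finite(frames))) stop("non-finite coordinates")
  if (any(atoms$mass <= 0)) stop("non-positive atom mass")
  t_n <- dim(frames)[1]
  if (is.null(frame_times)) frame_times <- as.numeric(seq_len(t_n) - 1L)
  stopifnot(length(frame_times) == t_n)
  if (t_n > 1 && any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing")
  }
  if (is.null(ligand_mask)) ligand_mask <- rep(FALSE, n)
  stopifnot(length(ligand_mask) == n)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, frames = frames,
                 frame_times = frame_times,
                 ligand_mask = ligand_mask,
                 annotation = empty_annotation()),
            class = "FrameSeries")
}

#' @export
print.FrameSeries <- function(x, ...) {
  cat(sprintf("FrameSeries: %d atoms, %d residues, %d frame(s)%s%s\n",
              n_atoms(x), length(unique(x$atoms$resid)), n_frames(x),
              if (any(x$ligand_mask))
                sprintf(", ligand %d atoms", sum(x$ligand_mask)) else "",
              if (x$annotation$annotated) ", chemistry annotated" else ""))
  invisible(x)
}

#' Number of atoms / frames in a series
#' @param series a `FrameSeries`
#' @return integer count
#' @export
n_atoms <- function(series) nrow(series$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(series) dim(series$frames)[1]

#' Extract one frame's coordinates
#' @param series a `FrameSeries`
#' @param frame frame index (1-based)
#' @return `N x 3` coordinate matrix, Angstrom
#' @export
frame_coords <- function(series, frame = 1L) {
  t_n <- n_frames(series)
  if (frame < 1L || frame > t_n) stop("frame index out of range")
  matrix(series$frames[frame, , ], ncol = 3L)
}

# ---------------------------------------------------------------------------
# Multi-model PDB I/O (wwPDB v3.3 fixed columns)
# ---------------------------------------------------------------------------

DEFAULT_DROP_CODES <- c("HOH", "NA", "CL")

parse_pdb_atom_line <- function(line, lineno) {
  f <- function(a, b) substr(line, a, b)
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(trimws(f(a, b))))
    if (is.na(v)) {
      stop("malformed PDB ", what, " field at line ", lineno, ": '",
           trimws(f(a, b)), "'")
    }
    v
  }
  icode <- f(27, 27)
  if (icode != " " && icode != "") {
    stop("insertion codes are unsupported (line ", lineno, ")")
  }
  list(record = trimws(f(1, 6)),
       serial = as.integer(num(7, 11, "serial")),
       name = trimws(f(13, 16)),
       altloc = f(17, 17),
       resname = trimws(f(18, 20)),
       chain = f(22, 22),
       resid = as.integer(num(23, 26, "resSeq")),
       x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
       element = trimws(f(77, 78)))
}

element_from_name <- function(name) {
  # strip leading digits (e.g. "1HG1"), then take leading alpha run;
  # two-letter elements in proteins/ligands are rare; CL/BR/NA handled via
  # explicit element column when present
  s <- sub("^[0-9]+", "", name)
  s <- sub("[^A-Za-z].*$", "", s)
  if (nchar(s) == 0) stop("cannot derive element from atom name '", name, "'")
  toupper(substr(s, 1, 1))
}

#' Read a multi-model PDB file into a frame series
#'
#' One frame per `MODEL` block (a single frame if the file has none). All
#' models must contain the same atoms in the same order. `HETATM` records
#' whose residue name is in `drop_codes` (waters/ions) are discarded; atoms
#' whose residue name is in `ligand_codes` are flagged in the ligand mask
#' (this is how the bound small molecule is identified -- HETATM alone is
#' not sufficient).
#'
#' @param path PDB file path
#' @param ligand_codes character vector of ligand residue names
#' @param drop_codes residue names discarded on read (default HOH/NA/CL)
#' @param frame_times optional frame times (ns)
#' @return a `FrameSeries`
#' @export
read_frame_series <- function(path, ligand_codes = character(),
                              drop_codes = DEFAULT_DROP_CODES,
                              frame_times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  models <- list()
  current <- NULL
  in_model <- FALSE
  seen_model_records <- any(trimws(rec) == "MODEL")
  if (!seen_model_records) current <- list()
  for (i in seq_along(lines)) {
    r <- trimws(rec[i])
    if (r == "MODEL") {
      current <- list()
      in_model <- TRUE
    } else if (r == "ENDMDL") {
      if (!in_model) stop("ENDMDL without MODEL at line ", i)
      models[[length(models) + 1L]] <- current
      current <- NULL
      in_model <- FALSE
    } else if (r %in% c("ATOM", "HETATM")) {
      a <- parse_pdb_atom_line(lines[i], i)
      if (a$resname %in% drop_codes && !(a$resname %in% ligand_codes)) next
      if (is.null(current)) stop("ATOM record outside MODEL block at line ", i)
      current[[length(current) + 1L]] <- a
    }
  }
  if (!seen_model_records) models <- list(current)
  if (in_model) stop("unterminated MODEL block")
  models <- Filter(function(m) length(m) > 0, models)
  if (length(models) == 0) stop("no atoms found in ", path)

  n <- length(models[[1]])
  key <- function(m) vapply(m, function(a) paste(a$name, a$resid, a$chain), "")
  k1 <- key(models[[1]])
  for (m in seq_along(models)) {
    if (length(models[[m]]) != n || !identical(key(models[[m]]), k1)) {
      stop("inconsistent atom count or order across MODEL blocks (model ",
           m, ")")
    }
  }
  first <- models[[1]]
  element <- vapply(first, function(a) {
    if (nzchar(a$element)) a$element else element_from_name(a$name)
  }, "")
  atoms <- data.frame(
    serial = vapply(first, `[[`, 0L, "serial"),
    name = vapply(first, `[[`, "", "name"),
    element = element,
    resid = vapply(first, `[[`, 0L, "resid"),
    resname = vapply(first, `[[`, "", "resname"),
    chain = vapply(first, `[[`, "", "chain"),
    mass = element_mass(element),
    stringsAsFactors = FALSE)
  frames <- array(0, dim = c(length(models), n, 3L))
  for (m in seq_along(models)) {
    frames[m, , 1] <- vapply(models[[m]], `[[`, 0, "x")
    frames[m, , 2] <- vapply(models[[m]], `[[`, 0, "y")
    frames[m, , 3] <- vapply(models[[m]], `[[`, 0, "z")
  }
  ligand_mask <- atoms$resname %in% ligand_codes
  frame_series(atoms, frames, frame_times = frame_times,
               ligand_mask = ligand_mask)
}

format_pdb_atom_name <- function(name, element) {
  # element symbol right-justified in cols 13-14 for short names
  if (nchar(name) >= 4L) return(substr(sprintf("%-4s", name), 1, 4))
  if (nchar(element) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write a frame series as a multi-model PDB file
#'
#' Coordinates are written at the format's native 3-decimal precision;
#' ligand atoms are written as `HETATM` records.
#'
#' @param series a `FrameSeries`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frame_series <- function(series, path) {
  a <- series$atoms
  recs <- ifelse(series$ligand_mask, "HETATM", "ATOM")
  names4 <- mapply(format_pdb_atom_name, a$name, a$element)
  con <- file(path, open = "wt")
  on.exit(close(con))
  t_n <- n_frames(series)
  for (m in seq_len(t_n)) {
    if (t_n > 1) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frame_coords(series, m)
    writeLines(sprintf(
      "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      recs, a$serial, names4, a$resname, a$chain, a$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, a$element), con)
    if (t_n > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Chemical-role annotation
# ---------------------------------------------------------------------------

#' Read a residue role template table
#'
#' The template TSV has columns `resname`, `role`, `atoms`. `role` is one of
#' `donor` (atoms = "HEAVY:H"), `acceptor`, `cation`, `anion`, `ring`
#' (comma-separated atom names forming the group/ring), or `apolar`.
#'
#' @param path TSV path
#' @return named list of per-residue role templates
#' @export
read_role_templates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("resname", "role", "atoms") %in% names(df)))
  out <- list()
  for (i in seq_len(nrow(df))) {
    rn <- df$resname[i]
    if (is.null(out[[rn]])) {
      out[[rn]] <- list(donors = list(), acceptors = character(0),
                        cations = list(), anions = list(),
                        rings = list(), apolar = character(0))
    }
    atoms <- trimws(strsplit(df$atoms[i], ",")[[1]])
    out[[rn]] <- switch(df$role[i],
      donor = { t <- out[[rn]]
                t$donors <- c(t$donors, lapply(atoms, function(s)
                  strsplit(s, ":")[[1]])); t },
      acceptor = { t <- out[[rn]]; t$acceptors <- c(t$acceptors, atoms); t },
      cation = { t <- out[[rn]]; t$cations <- c(t$cations, list(atoms)); t },
      anion = { t <- out[[rn]]; t$anions <- c(t$anions, list(atoms)); t },
      ring = { t <- out[[rn]]; t$rings <- c(t$rings, list(atoms)); t },
      apolar = { t <- out[[rn]]; t$apolar <- c(t$apolar, atoms); t },
      stop("unknown role '", df$role[i], "' in template table"))
  }
  out
}

#' Built-in residue role templates for the 20 standard amino acids
#' @return named list of role templates (see [read_role_templates()])
#' @export
default_residue_roles <- function() {
  path <- system.file("extdata", "residue_roles.tsv", package = "mdligand")
  if (!nzchar(path)) stop("bundled residue_roles.tsv not found")
  read_role_templates(path)
}

#' Annotate hydrogen-bond, charge, ring and apolar roles
#'
#' Populates donor pairs (heavy atom + polar hydrogen), acceptor atoms,
#' charged groups (e.g. guanidinium cation, carboxylate anion), aromatic
#' rings and apolar atoms from per-residue templates. Every residue name in
#' the series (including the ligand's) must have a template entry.
#'
#' Template atoms that are absent from a residue are skipped, except donor
#' hydrogens: a donor whose heavy atom is present but whose hydrogen is
#' missing is recorded in `annotation$missing_donor_h`, and the hydrogen-bond
#' detector refuses to run on such a series.
#'
#' @param series a `FrameSeries`
#' @param templates role templates (default: built-in amino-acid table);
#'   supply additional entries for ligand residue names
#' @return the annotated `FrameSeries`
#' @export
annotate_chemistry <- function(series, templates = default_residue_roles()) {
  a <- series$atoms
  unknown <- setdiff(unique(a$resname), names(templates))
  if (length(unknown) > 0) {
    stop("no role template for residue name(s): ",
         paste(unknown, collapse = ", "))
  }
  ann <- empty_annotation()
  donor_rows <- list()
  res_key <- paste(a$chain, a$resid)
  for (rk in unique(res_key)) {
    idx <- which(res_key == rk)
    tmpl <- templates[[a$resname[idx[1]]]]
    find <- function(nm) idx[match(nm, a$name[idx])]
    for (d in tmpl$donors) {
      hv <- find(d[1]); hy <- find(d[2])
      if (is.na(hv)) next
      if (is.na(hy)) {
        ann$missing_donor_h <- c(ann$missing_donor_h,
                                 paste0(a$resname[idx[1]], a$resid[idx[1]],
                                        ":", d[1]))
        next
      }
      donor_rows[[length(donor_rows) + 1L]] <- c(hv, hy)
    }
    acc <- stats::na.omit(vapply(tmpl$acceptors, find, 0L))
    ann$acceptors <- c(ann$acceptors, as.integer(acc))
    for (g in tmpl$cations) {
      gi <- vapply(g, find, 0L)
      if (!anyNA(gi)) {
        ann$charged_groups <- c(ann$charged_groups,
                                list(list(sign = 1L, atoms = as.integer(gi))))
      }
    }
    for (g in tmpl$anions) {
      gi <- vapply(g, find, 0L)
      if (!anyNA(gi)) {
        ann$charged_groups <- c(ann$charged_groups,
                                list(list(sign = -1L, atoms = as.integer(gi))))
      }
    }
    for (g in tmpl$rings) {
      gi <- vapply(g, find, 0L)
      if (!anyNA(gi)) {
        if (length(gi) < 5) stop("ring template with fewer than 5 atoms")
        ann$rings <- c(ann$rings, list(as.integer(gi)))
      }
    }
    ap <- stats::na.omit(vapply(tmpl$apolar, find, 0L))
    ann$apolar <- c(ann$apolar, as.integer(ap))
  }
  if (length(donor_rows) > 0) {
    ann$donor_pairs <- do.call(rbind, donor_rows)
    colnames(ann$donor_pairs) <- c("heavy", "hydrogen")
  }
  ann$annotated <- TRUE
  series$annotation <- ann
  series
}

# ---------------------------------------------------------------------------
# Atom selections
# ---------------------------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Resolve an atom selection
#'
#' `query` is either a named shortcut -- `"protein"`, `"ligand"`,
#' `"backbone"` (N, CA, C, O of protein residues), `"calpha"` -- or a list
#' with any of the fields `chain`, `resid` (vector of residue ids), `names`
#' (atom names), `ligand` (logical). An empty result is always an error,
#' never a silent empty selection.
#'
#' @param series a `FrameSeries`
#' @param query shortcut string or predicate list
#' @return object of class `AtomSelection` with sorted unique `$indices`
#' @export
select_atoms <- function(series, query) {
  a <- series$atoms
  lig <- series$ligand_mask
  if (is.character(query) && length(query) == 1L) {
    idx <- switch(query,
      protein = which(!lig),
      ligand = which(lig),
      backbone = which(!lig & a$name %in% BACKBONE_NAMES),
      calpha = which(!lig & a$name == "CA"),
      stop("unknown selection shortcut '", query, "'"))
    label <- query
  } else if (is.list(query)) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(query$chain)) keep <- keep & a$chain %in% query$chain
    if (!is.null(query$resid)) keep <- keep & a$resid %in% query$resid
    if (!is.null(query$names)) keep <- keep & a$name %in% query$names
    if (!is.null(query$ligand)) keep <- keep & (lig == query$ligand)
    idx <- which(keep)
    label <- "custom"
  } else {
    stop("query must be a shortcut string or a list")
  }
  if (length(idx) == 0) {
    stop("empty atom selection for query '", label, "'")
  }
  structure(list(indices = sort(unique(as.integer(idx))), query = label),
            class = "AtomSelection")
}

resolve_selection <- function(series, sel) {
  if (inherits(sel, "AtomSelection")) return(sel$indices)
  if (is.numeric(sel)) return(sort(unique(as.integer(sel))))
  select_atoms(series, sel)$indices
}
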