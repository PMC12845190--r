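#' @name synthetic_data
#' @title Seeded synthetic fixtures: toy complexes, trajectories, snapshots
#'
#' @description
#' Deterministic generators standing in for the docking and MD engines.
#' They mimic the statistical structure of the real inputs -- a folded
#' protein with a prescribed per-residue fluctuation amplitude profile, a
#' bound ligand, planted interaction geometries at prescribed occupancies,
#' Gaussian energy component series -- with no force field, solvent or
#' thermostat. Per-residue motion is rigid (the whole residue moves
#' together), so the expected C-alpha RMSF of residue r is exactly
#' `sigma_r * sqrt(3)` for per-axis Gaussian noise of SD `sigma_r`.
NULL

rot_z <- function(phi) {
  matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1), 3, 3)
}

regular_polygon <- function(n, radius, center = c(0, 0), phase = pi / 2) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
}

# complete a regular hexagon given two adjacent vertices a, b, on the side of
# the a-b chord away from `away_from`
fused_hexagon <- function(a, b, away_from) {
  side <- sqrt(sum((a - b)^2))
  mid <- (a + b) / 2
  perp <- c(-(b - a)[2], (b - a)[1]) / side
  if (sum(perp * (mid - away_from)) < 0) perp <- -perp
  center <- mid + perp * side * sqrt(3) / 2
  # rotate a about center towards b, then continue four more steps
  ang_a <- atan2(a[2] - center[2], a[1] - center[1])
  ang_b <- atan2(b[2] - center[2], b[1] - center[1])
  step <- ang_b - ang_a
  step <- atan2(sin(step), cos(step))  # fold to (-pi, pi]
  angs <- ang_b + step * seq_len(4)
  radius <- side
  rest <- cbind(center[1] + radius * cos(angs),
                center[2] + radius * sin(angs))
  rest  # vertices after b, in ring order
}

bb <- function(resname) {
  atoms <- list(N = c(-1.2, 0.8, 0), H = c(-1.2, 1.8, 0), CA = c(0, 0, 0),
                C = c(1.2, 0.8, 0), O = c(1.2, 2.0, 0))
  if (resname == "PRO") atoms$H <- NULL
  atoms
}

aromatic_local <- function(resname) {
  if (resname %in% c("PHE", "TYR")) {
    hx <- regular_polygon(6, 1.39, center = c(0, -3.6))
    out <- list(CG = c(hx[5, ], 0.6), CD1 = c(hx[4, ], 0.6),
                CE1 = c(hx[3, ], 0.6), CZ = c(hx[2, ], 0.6),
                CE2 = c(hx[1, ], 0.6), CD2 = c(hx[6, ], 0.6))
    if (resname == "TYR") {
      out$OH <- c(0, -6.4, 0.6)
      out$HH <- c(0.85, -6.9, 0.6)
    }
    return(out)
  }
  if (resname == "HIS") {
    pg <- regular_polygon(5, 1.2, center = c(0, -3.3))
    return(list(CG = c(pg[1, ], 0.6), ND1 = c(pg[2, ], 0.6),
                CE1 = c(pg[3, ], 0.6), NE2 = c(pg[4, ], 0.6),
                CD2 = c(pg[5, ], 0.6),
                HD1 = c(pg[2, 1] - 0.9, pg[2, 2] + 0.4, 0.6),
                HE2 = c(pg[4, 1] + 0.4, pg[4, 2] - 0.9, 0.6)))
  }
  if (resname == "TRP") {
    g <- trp_ring_local(center5 = c(0, -3.2), radius5 = 1.17)
    return(g)
  }
  stop("no aromatic template for ", resname)
}

trp_ring_local <- function(center5 = c(0, -3.2), radius5 = 1.17, z = 0.6) {
  pg <- regular_polygon(5, radius5, center = center5, phase = pi / 2)
  # order: CG, CD1, NE1, CE2, CD2
  cg <- pg[1, ]; cd1 <- pg[2, ]; ne1 <- pg[3, ]; ce2 <- pg[4, ]; cd2 <- pg[5, ]
  rest <- fused_hexagon(ce2, cd2, away_from = center5)
  ne1_out <- ne1 + (ne1 - center5) / sqrt(sum((ne1 - center5)^2))
  list(CG = c(cg, z), CD1 = c(cd1, z), NE1 = c(ne1, z), CE2 = c(ce2, z),
       CD2 = c(cd2, z), CE3 = c(rest[1, ], z), CZ3 = c(rest[2, ], z),
       CH2 = c(rest[3, ], z), CZ2 = c(rest[4, ], z),
       HE1 = c(ne1_out, z))
}

SIDE_CHAINS <- list(
  GLY = list(),
  ALA = list(CB = c(0, -1.5, 0.5)),
  SER = list(CB = c(0, -1.5, 0.5), OG = c(0, -2.8, 0.2),
             HG = c(0.8, -3.3, 0.3)),
  THR = list(CB = c(0, -1.5, 0.5), OG1 = c(-1.1, -2.4, 0.4),
             HG1 = c(-1.0, -3.3, 0.5), CG2 = c(1.2, -2.2, 0.8)),
  CYS = list(CB = c(0, -1.5, 0.5), SG = c(0, -2.9, 0.4)),
  VAL = list(CB = c(0, -1.5, 0.5), CG1 = c(-0.8, -2.6, 0.5),
             CG2 = c(0.9, -2.5, 1.0)),
  LEU = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.7),
             CD1 = c(-1.2, -3.6, 0.7), CD2 = c(1.2, -3.6, 0.9)),
  ILE = list(CB = c(0, -1.5, 0.5), CG1 = c(-1.0, -2.5, 0.5),
             CG2 = c(1.2, -1.9, 0.9), CD1 = c(-1.0, -3.9, 0.6)),
  MET = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.6),
             SD = c(0, -4.2, 0.7), CE = c(0, -5.8, 0.8)),
  PRO = list(CB = c(0, -1.5, 0.5), CG = c(-1.0, -2.3, 0.5),
             CD = c(-2.0, -1.3, 0.3)),
  ASP = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.6),
             OD1 = c(-1.1, -3.6, 0.6), OD2 = c(1.1, -3.6, 0.7)),
  GLU = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.6),
             CD = c(0, -4.3, 0.7), OE1 = c(-1.1, -5.0, 0.7),
             OE2 = c(1.1, -5.0, 0.8)),
  ASN = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.6),
             OD1 = c(-1.1, -3.6, 0.6), ND2 = c(1.1, -3.6, 0.7),
             HD21 = c(1.1, -4.6, 0.7), HD22 = c(2.0, -3.1, 0.7)),
  GLN = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.6),
             CD = c(0, -4.3, 0.7), OE1 = c(-1.1, -5.0, 0.7),
             NE2 = c(1.1, -5.0, 0.8), HE21 = c(1.1, -6.0, 0.8),
             HE22 = c(2.0, -4.5, 0.8)),
  LYS = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.6),
             CD = c(0, -4.3, 0.7), CE = c(0, -5.7, 0.8),
             NZ = c(0, -7.0, 0.9), HZ1 = c(-0.9, -7.5, 0.9),
             HZ2 = c(0.9, -7.5, 0.9), HZ3 = c(0, -7.3, 1.9)),
  ARG = list(CB = c(0, -1.5, 0.5), CG = c(0, -2.9, 0.6),
             CD = c(0, -4.3, 0.7), NE = c(0, -5.6, 0.8),
             HE = c(-0.9, -6.1, 0.8), CZ = c(1.1, -6.3, 0.9),
             NH1 = c(1.1, -7.6, 0.9), HH11 = c(0.3, -8.2, 0.9),
             HH12 = c(1.9, -8.1, 0.9), NH2 = c(2.2, -5.6, 1.0),
             HH21 = c(2.2, -4.6, 1.0), HH22 = c(3.1, -6.1, 1.0)))

residue_local_atoms <- function(resname) {
  atoms <- bb(resname)
  side <- if (resname %in% c("PHE", "TYR", "HIS", "TRP")) {
    c(list(CB = c(0, -1.5, 0.5)), aromatic_local(resname))
  } else {
    sc <- SIDE_CHAINS[[resname]]
    if (is.null(sc)) stop("no local geometry for residue ", resname)
    sc
  }
  c(atoms, side)
}

atom_row <- function(name, resid, resname, chain, serial, coords) {
  element <- element_from_name(name)
  data.frame(serial = serial, name = name, element = element,
             resid = as.integer(resid), resname = resname, chain = chain,
             mass = element_mass(element), stringsAsFactors = FALSE)
}

empty_ligand_template <- function() {
  list(donors = list(), acceptors = character(0), cations = list(),
       anions = list(), rings = list(), apolar = character(0))
}

build_ligand_atoms <- function(spec, center) {
  names_ <- character(0); coords <- NULL
  tmpl <- empty_ligand_template()
  add <- function(nm, xyz) {
    names_ <<- c(names_, nm)
    coords <<- rbind(coords, center + xyz)
  }
  n_rings <- spec$rings %||% 0
  for (i in seq_len(n_rings)) {
    hx <- regular_polygon(6, 1.39, center = c(0, 3 * (i - 1)))
    ring_names <- sprintf("CR%d%d", i, 1:6)
    for (j in 1:6) add(ring_names[j], c(hx[j, ], 0))
    tmpl$rings <- c(tmpl$rings, list(ring_names))
  }
  for (k in seq_len(spec$donors %||% 0)) {
    dn <- sprintf("ND%d", k); hn <- sprintf("HND%d", k)
    add(dn, c(2.5, -2 * k, 0)); add(hn, c(2.5, -2 * k, 1.0))
    tmpl$donors <- c(tmpl$donors, list(c(dn, hn)))
  }
  for (k in seq_len(spec$acceptors %||% 0)) {
    an <- sprintf("OA%d", k)
    add(an, c(-2.5, -2 * k, 0))
    tmpl$acceptors <- c(tmpl$acceptors, an)
  }
  if (isTRUE(spec$cation)) {
    add("CZL", c(0, 4.5, 1.5)); add("NEL", c(-1.1, 5.2, 1.5))
    add("NH1L", c(1.1, 5.2, 1.5)); add("NH2L", c(0, 3.2, 1.5))
    tmpl$cations <- c(tmpl$cations, list(c("NEL", "NH1L", "NH2L", "CZL")))
  }
  if (isTRUE(spec$anion)) {
    add("CGL", c(0, -4.5, 1.5)); add("OD1L", c(-1.1, -5.2, 1.5))
    add("OD2L", c(1.1, -5.2, 1.5))
    tmpl$anions <- c(tmpl$anions, list(c("OD1L", "OD2L")))
  }
  for (k in seq_len(spec$apolar %||% 0)) {
    cn <- sprintf("CM%d", k)
    add(cn, c(0, -4.5 - k, 0))
    tmpl$apolar <- c(tmpl$apolar, cn)
  }
  if (length(names_) == 0) stop("unrealizable ligand_spec: no atoms declared")
  list(names = names_, coords = coords, template = tmpl)
}

#' Generate a toy protein-ligand complex (single frame)
#'
#' The protein backbone runs along a smooth helical curve with simplified
#' per-residue geometry from standard templates (planar aromatic rings,
#' carboxylate/guanidinium groups, amide hydrogens); the ligand is placed
#' in a cleft at `pocket_gap` Angstrom from the protein surface, far enough
#' that the default complex has no protein-ligand contacts (interactions
#' are planted explicitly with [plant_interaction_snapshot()]). The result
#' is chemistry-annotated and deterministic under `seed`.
#'
#' @param n_residues number of protein residues (>= 5)
#' @param ligand_spec list describing ligand chemistry: `rings`, `donors`,
#'   `acceptors` (counts), `cation`, `anion` (logical), `apolar` (count);
#'   `NULL` for a ligand-free protein
#' @param seed RNG seed (small coordinate jitter)
#' @param sequence optional residue-name vector (length `n_residues`)
#' @param pocket_gap protein-ligand clearance, Angstrom
#' @param jitter coordinate jitter SD, Angstrom
#' @return an annotated `FrameSeries` with one frame
#' @export
make_toy_complex <- function(n_residues,
                             ligand_spec = list(rings = 1, donors = 1,
                                                acceptors = 1, apolar = 1),
                             seed = 1L, sequence = NULL, pocket_gap = 6,
                             jitter = 0.02) {
  if (n_residues < 5) stop("need at least 5 residues")
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- rep(c("ALA", "GLY", "VAL", "LEU"), length.out = n_residues)
  }
  stopifnot(length(sequence) == n_residues)
  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  rows <- list(); coords <- NULL
  serial <- 0L
  for (r in seq_len(n_residues)) {
    theta <- twist * r
    ca <- c(radius * cos(theta), radius * sin(theta), rise * r)
    rot <- rot_z(theta + pi / 2)
    local <- residue_local_atoms(sequence[r])
    for (nm in names(local)) {
      serial <- serial + 1L
      rows[[serial]] <- atom_row(nm, r, sequence[r], "A", serial, NULL)
      coords <- rbind(coords, ca + as.numeric(rot %*% local[[nm]]))
    }
  }
  n_prot <- serial
  templates <- default_residue_roles()
  lig_template <- NULL
  if (!is.null(ligand_spec)) {
    lig_center <- c(max(coords[, 1]) + pocket_gap + 2.5, 0,
                    rise * n_residues / 2)
    lig <- build_ligand_atoms(ligand_spec, lig_center)
    for (j in seq_along(lig$names)) {
      serial <- serial + 1L
      rows[[serial]] <- atom_row(lig$names[j], 386L, "INH", "L", serial, NULL)
      coords <- rbind(coords, lig$coords[j, ])
    }
    lig_template <- lig$template
    templates$INH <- lig_template
  }
  atoms <- do.call(rbind, rows)
  coords <- coords + matrix(stats::rnorm(length(coords), 0, jitter),
                            ncol = 3)
  ligand_mask <- c(rep(FALSE, n_prot), rep(TRUE, serial - n_prot))
  series <- frame_series(atoms, coords, ligand_mask = ligand_mask)
  series <- annotate_chemistry(series, templates)
  attr(series, "ligand_template") <- lig_template
  series
}

random_rotation <- function(max_deg) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, -max_deg, max_deg) * pi / 180
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}

#' Generate a fluctuation trajectory around a reference complex
#'
#' Frame `t` places every residue rigidly at its reference position plus an
#' isotropic Gaussian displacement with per-axis SD `sigma_r` (nm), drawn
#' independently per frame and residue, optionally composed with a global
#' rigid motion (removed again by trajectory fitting). Because whole
#' residues move together the expected C-alpha RMSF is `sigma_r * sqrt(3)`.
#'
#' @param complex a single-frame `FrameSeries` (e.g. [make_toy_complex()])
#' @param sigma_nm per-axis displacement SD in nm: a scalar, or a vector
#'   with one value per residue (ordered as `unique(atoms$resid)`), or a
#'   named vector keyed by residue id
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param rigid_motion optional list `list(rot_deg=, trans_ang=)` with
#'   per-frame global rotation/translation magnitudes
#' @param dt frame spacing, ns
#' @return a `FrameSeries` with `n_frames` frames (annotation preserved)
#' @export
make_fluctuation_trajectory <- function(complex, sigma_nm, n_frames,
                                        seed = 1L, rigid_motion = NULL,
                                        dt = 1) {
  stopifnot(n_frames >= 1, all(sigma_nm >= 0))
  set.seed(seed)
  resids <- unique(complex$atoms$resid)
  n_res <- length(resids)
  if (length(sigma_nm) == 1) {
    sigma <- rep(sigma_nm, n_res)
  } else if (!is.null(names(sigma_nm))) {
    sigma <- unname(sigma_nm[as.character(resids)])
    if (anyNA(sigma)) stop("sigma_nm names do not cover all residues")
  } else {
    stopifnot(length(sigma_nm) == n_res)
    sigma <- sigma_nm
  }
  sigma_ang <- nm_to_ang(sigma)
  ref <- frame_coords(complex, 1L)
  res_idx <- lapply(resids, function(r) which(complex$atoms$resid == r))
  frames <- array(0, dim = c(n_frames, nrow(ref), 3L))
  # residue displacements are drawn up front so that the same seed yields
  # the same internal motion whether or not a global rigid motion is added
  disp_all <- array(stats::rnorm(n_frames * n_res * 3),
                    dim = c(n_frames, n_res, 3L)) *
    rep(sigma_ang, each = n_frames)
  for (t in seq_len(n_frames)) {
    xyz <- ref
    disp <- matrix(disp_all[t, , ], ncol = 3L)
    for (k in seq_len(n_res)) {
      xyz[res_idx[[k]], ] <- sweep(xyz[res_idx[[k]], , drop = FALSE], 2,
                                   -disp[k, ])
    }
    if (!is.null(rigid_motion)) {
      rot <- random_rotation(rigid_motion$rot_deg %||% 0)
      trans <- stats::rnorm(3, 0, rigid_motion$trans_ang %||% 0)
      cen <- colMeans(xyz)
      xyz <- sweep(sweep(xyz, 2, cen) %*% rot, 2, -(cen + trans))
    }
    frames[t, , ] <- xyz
  }
  out <- complex
  out$frames <- frames
  out$frame_times <- dt * (seq_len(n_frames) - 1)
  out
}

# --- planted interaction snapshots -----------------------------------------

# H position on the D-A axis triangle: |D-H| = bond, |H-A| = ha, |D-A| = da
solve_h_position <- function(d_pos, a_pos, ha, bond = 1.0) {
  da <- sqrt(sum((a_pos - d_pos)^2))
  if (ha > bond + da || ha < abs(da - bond)) {
    stop("unrealizable H-bond geometry: ha=", ha, " da=", da)
  }
  u <- (a_pos - d_pos) / da
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  w <- ref - sum(ref * u) * u
  w <- w / sqrt(sum(w * w))
  xh <- (bond^2 + da^2 - ha^2) / (2 * da)
  yh <- sqrt(max(0, bond^2 - xh^2))
  d_pos + xh * u + yh * w
}

station_backbone <- function(s, resname, origin_atom, origin_pos) {
  # minimal backbone placed away from the ligand side (+x); origin_atom is
  # the atom the geometry is anchored on
  offs <- list(N = c(-4.0, 2.0, 0), H = c(-4.0, 3.0, 0), CA = c(-2.9, 1.3, 0),
               C = c(-2.5, 0.0, 0), O = c(-2.4, 1.2, 0))
  offs[[origin_atom]] <- NULL
  out <- list(); out[[origin_atom]] <- origin_pos
  for (nm in names(offs)) out[[nm]] <- s + offs[[nm]]
  if (resname == "PRO") out$H <- NULL
  out
}

plant_one <- function(spec, s, k) {
  # returns list(protein = named coords, ligand = named coords,
  #              lig_roles = template fragment, check = function(getpos))
  type <- spec$type
  if (type == "hbond") {
    ha <- spec$ha; da <- spec$da
    donor_side <- spec$donor %||% "protein"
    if (donor_side == "protein") {
      d_pos <- s; a_pos <- s + c(da, 0, 0)
      h_pos <- solve_h_position(d_pos, a_pos, ha)
      prot <- station_backbone(s, spec$resname, "N", d_pos)
      prot$H <- h_pos
      acc <- spec$lig_atom %||% sprintf("NA%d", k)
      lig <- stats::setNames(list(a_pos), acc)
      roles <- list(acceptors = acc)
    } else {
      a_pos <- s; d_pos <- s + c(da, 0, 0)
      h_pos <- solve_h_position(d_pos, a_pos, ha)
      prot <- station_backbone(s, spec$resname, "O", a_pos)
      dn <- spec$lig_atom %||% sprintf("NL%d", k)
      hn <- paste0("H", dn)
      lig <- stats::setNames(list(d_pos, h_pos), c(dn, hn))
      roles <- list(donors = list(c(dn, hn)))
    }
    return(list(protein = prot, ligand = lig, roles = roles))
  }
  if (type == "salt_bridge") {
    d <- spec$dist
    an <- if (spec$resname == "GLU") c("OE1", "OE2", "CD") else
      c("OD1", "OD2", "CG")
    prot <- station_backbone(s, spec$resname, an[1], s)
    prot[[an[2]]] <- s + c(0, 2.2, 0)
    prot[[an[3]]] <- s + c(-0.7, 1.1, 0)
    prot$CB <- s + c(-1.9, 1.3, 0)
    nms <- sprintf(c("NH1%d", "CZ%d", "NE%d", "NH2%d"), k)
    lig <- stats::setNames(list(s + c(d, 0, 0), s + c(d + 1.3, 0, 0),
                                s + c(d + 2.0, 1.05, 0),
                                s + c(d + 2.0, -1.05, 0)), nms)
    roles <- list(cations = list(c(nms[3], nms[1], nms[4], nms[2])))
    return(list(protein = prot, ligand = lig, roles = roles))
  }
  if (type == "pi_stacking") {
    cd <- spec$centroid; off <- spec$offset
    if (off > cd) stop("unrealizable stacking: offset exceeds centroid distance")
    h <- sqrt(cd^2 - off^2)
    g <- trp_ring_local(center5 = c(0, 0), z = 0)
    prot <- lapply(g, function(p) s + p)
    prot$CB <- s + c(0, 1.5, -1.0)
    bbext <- station_backbone(s + c(0, 3.5, -1.5), spec$resname, "CA",
                              s + c(0, 3.5, -1.5))
    prot <- c(prot, bbext[setdiff(names(bbext), names(prot))])
    c6 <- (prot$CE2 + prot$CD2 + prot$CE3 + prot$CZ3 + prot$CH2 +
             prot$CZ2) / 6
    c5 <- (prot$CG + prot$CD1 + prot$NE1 + prot$CE2 + prot$CD2) / 5
    off_dir <- c6 - c5
    off_dir[3] <- 0
    off_dir <- off_dir / sqrt(sum(off_dir^2))
    lig_center <- c6 + off * off_dir + c(0, 0, h)
    hx <- regular_polygon(6, 1.39, center = c(0, 0))
    nms <- sprintf("CP%d%d", k, 1:6)
    lig <- stats::setNames(lapply(1:6, function(j) {
      lig_center + c(hx[j, ], 0)
    }), nms)
    roles <- list(rings = list(nms))
    return(list(protein = prot, ligand = lig, roles = roles))
  }
  if (type == "hydrophobic") {
    d <- spec$dist
    anchor <- switch(spec$resname, ILE = "CD1", LEU = "CD1", VAL = "CG1",
                     ALA = "CB", MET = "CE", "CB")
    prot <- station_backbone(s + c(-2, 2, 0), spec$resname, "CA",
                             s + c(-2, 2, 0))
    prot[[anchor]] <- s
    if (anchor != "CB") prot$CB <- s + c(-1.0, 1.0, 0)
    cn <- sprintf("CHP%d", k)
    lig <- stats::setNames(list(s + c(d, 0, 0)), cn)
    roles <- list(apolar = cn)
    return(list(protein = prot, ligand = lig, roles = roles))
  }
  stop("unknown planted interaction type '", type, "'")
}

merge_roles <- function(tmpl, roles) {
  for (nm in names(roles)) tmpl[[nm]] <- c(tmpl[[nm]], roles[[nm]])
  tmpl
}

#' Plant exact interaction geometries into a complex snapshot
#'
#' Appends, for each requested interaction, a minimal protein residue and
#' the matching ligand atoms positioned so the interaction's geometry
#' matches its targets exactly (verified post-construction to 0.01 A / 1
#' degree). Stations are spaced far apart (and far from the existing
#' complex), so the detectors find exactly the planted events. Planted
#' protein residues carry the residue id and name given in the spec on
#' their own chain; planted ligand atoms join the existing ligand residue.
#'
#' Interaction specs are lists:
#' \itemize{
#'   \item `list(type="hbond", resid=, resname=, donor="protein"|"ligand",
#'     ha=, da=)` -- H-acceptor and donor-acceptor distances in Angstrom
#'   \item `list(type="salt_bridge", resid=, resname="ASP"|"GLU", dist=)` --
#'     minimum cation-anion atom distance
#'   \item `list(type="pi_stacking", resid=, resname="TRP", centroid=,
#'     offset=)` -- ring centroid distance and lateral offset
#'   \item `list(type="hydrophobic", resid=, resname=, dist=)`
#' }
#'
#' @param complex an annotated single-frame `FrameSeries` with a ligand
#' @param interactions list of interaction specs (may be empty)
#' @param spacing distance between stations, Angstrom
#' @return a single-frame annotated `FrameSeries`
#' @export
plant_interaction_snapshot <- function(complex, interactions,
                                       spacing = 25) {
  if (length(interactions) == 0) {
    out <- complex
    out$frames <- out$frames[1, , , drop = FALSE]
    out$frame_times <- out$frame_times[1]
    return(out)
  }
  if (!any(complex$ligand_mask)) stop("complex has no ligand to extend")
  base_x <- max(frame_coords(complex, 1L)[, 1]) + 15
  atoms <- complex$atoms
  coords <- frame_coords(complex, 1L)
  lig_mask <- complex$ligand_mask
  lig_resname <- atoms$resname[lig_mask][1]
  lig_resid <- atoms$resid[lig_mask][1]
  lig_tmpl <- attr(complex, "ligand_template") %||% empty_ligand_template()
  serial <- max(atoms$serial)
  station_chains <- c("B", "C", "D", "E", "F", "G", "I", "J", "K", "M")
  if (length(interactions) > length(station_chains)) {
    stop("too many planted interactions")
  }
  for (k in seq_along(interactions)) {
    spec <- interactions[[k]]
    s <- c(base_x + (k - 1) * spacing, 0, 0)
    st <- plant_one(spec, s, k)
    check_station_geometry(spec, st)
    for (nm in names(st$protein)) {
      serial <- serial + 1L
      atoms <- rbind(atoms, atom_row(nm, spec$resid, spec$resname,
                                     station_chains[k], serial, NULL))
      coords <- rbind(coords, st$protein[[nm]])
      lig_mask <- c(lig_mask, FALSE)
    }
    for (nm in names(st$ligand)) {
      serial <- serial + 1L
      atoms <- rbind(atoms, atom_row(nm, lig_resid, lig_resname, "L",
                                     serial, NULL))
      coords <- rbind(coords, st$ligand[[nm]])
      lig_mask <- c(lig_mask, TRUE)
    }
    lig_tmpl <- merge_roles(lig_tmpl, st$roles)
  }
  templates <- default_residue_roles()
  templates[[lig_resname]] <- lig_tmpl
  out <- frame_series(atoms, coords, ligand_mask = lig_mask)
  out <- annotate_chemistry(out, templates)
  attr(out, "ligand_template") <- lig_tmpl
  verify_planted(out, interactions)
  out
}

measure_station <- function(spec, st) {
  # direct geometric measurement of the constructed station coordinates,
  # independent of the detector code paths and their cutoffs
  if (spec$type == "hbond") {
    if ((spec$donor %||% "protein") == "protein") {
      d <- st$protein$N; h <- st$protein$H
      a <- st$ligand[[1]]
    } else {
      a <- st$protein$O
      d <- st$ligand[[1]]; h <- st$ligand[[2]]
    }
    return(c(ha = dist3(h, a), da = dist3(d, a)))
  }
  if (spec$type == "salt_bridge") {
    an <- if (spec$resname == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
    anion <- do.call(rbind, st$protein[an])
    cation <- do.call(rbind, st$ligand)
    return(c(dist = min(apply(anion, 1, function(p)
      min(sqrt(rowSums(sweep(cation, 2, p)^2)))))))
  }
  if (spec$type == "pi_stacking") {
    c6 <- colMeans(do.call(rbind, st$protein[c("CE2", "CD2", "CE3", "CZ3",
                                               "CH2", "CZ2")]))
    lc <- colMeans(do.call(rbind, st$ligand))
    v <- lc - c6
    # protein ring lies in a z = const plane by construction
    return(c(centroid = sqrt(sum(v^2)), offset = sqrt(sum(v[1:2]^2))))
  }
  if (spec$type == "hydrophobic") {
    prot <- do.call(rbind, st$protein)
    return(c(dist = min(sqrt(rowSums(sweep(prot, 2, st$ligand[[1]])^2)))))
  }
  stop("unknown type")
}

check_station_geometry <- function(spec, st, tol = 0.01) {
  m <- measure_station(spec, st)
  want <- switch(spec$type,
    hbond = c(ha = spec$ha, da = spec$da),
    salt_bridge = c(dist = spec$dist),
    pi_stacking = c(centroid = spec$centroid, offset = spec$offset),
    hydrophobic = c(dist = spec$dist))
  if (any(abs(m[names(want)] - want) > tol)) {
    stop("planted ", spec$type, " at residue ", spec$resid,
         " failed geometry verification (",
         paste(sprintf("%s=%.3f", names(want), m[names(want)]),
               collapse = ", "), ")")
  }
  invisible(TRUE)
}

verify_planted <- function(series, interactions) {
  xyz <- frame_coords(series, 1L)
  a <- series$atoms
  # steric sanity: no cross-interface heavy-atom clash below 1.5 A
  heavy <- a$element != "H"
  p <- which(!series$ligand_mask & heavy)
  l <- which(series$ligand_mask & heavy)
  dmin <- min(vapply(l, function(j) {
    min(sqrt(colSums((t(xyz[p, , drop = FALSE]) - xyz[j, ])^2)))
  }, 0))
  if (dmin < 1.5) stop("planted snapshot has steric clash (", round(dmin, 2),
                       " A)")
  invisible(TRUE)
}

#' Generate a Gaussian per-frame energy component series
#'
#' @param means named list/vector with `VDWAALS`, `EEL`, `EPB`, `ENPOLAR`
#'   means, kcal/mol
#' @param sds matching SDs (>= 0)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return an `EnergyComponentSeries`
#' @export
make_energy_series <- function(means, sds, n_frames, seed = 1L) {
  stopifnot(all(unlist(sds) >= 0), n_frames >= 1)
  set.seed(seed)
  draw <- function(comp) {
    stats::rnorm(n_frames, means[[comp]], sds[[comp]])
  }
  energy_series(draw("VDWAALS"), draw("EEL"), draw("EPB"), draw("ENPOLAR"))
}

#' Generate a pair of RMSF profiles with a planted differential segment
#'
#' Profile A is a smooth baseline; profile B equals A plus `bump_delta` on
#' `bump_range` and differs elsewhere only by seeded jitter bounded below
#' a quarter of the detector's default 0.2 nm threshold.
#'
#' @param length number of residues (ids `1..length`)
#' @param baseline baseline RMSF, nm
#' @param bump_range integer residue range carrying the bump
#' @param bump_delta added RMSF on the bump, nm
#' @param seed RNG seed
#' @param jitter max off-bump |B - A| jitter, nm (default 0.04)
#' @return list with elements `a` and `b`, both `RMSFProfile`s
#' @export
make_rmsf_pair <- function(length, baseline = 0.15, bump_range,
                           bump_delta, seed = 1L, jitter = 0.04) {
  stopifnot(all(bump_range >= 1), all(bump_range <= length))
  set.seed(seed)
  resid <- seq_len(length)
  a_vals <- baseline + 0.03 * sin(resid / 7) +
    abs(stats::rnorm(length, 0, 0.005))
  b_vals <- a_vals + stats::runif(length, -jitter, jitter)
  b_vals[bump_range] <- a_vals[bump_range] + bump_delta
  b_vals <- pmax(b_vals, 0)
  list(a = rmsf_profile_from_values(resid, a_vals),
       b = rmsf_profile_from_values(resid, b_vals))
}
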