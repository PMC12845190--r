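# Shared fixtures: planted-interaction specs mirroring the final-snapshot
# contact geometries of the two reference complexes, and small manual
# series builders for detector edge cases.

inh1_snapshot_specs <- function() {
  list(
    list(type = "hbond", resid = 74, resname = "GLY", donor = "protein",
         ha = 2.96, da = 3.94, lig_atom = "N24"),
    list(type = "hbond", resid = 108, resname = "PHE", donor = "ligand",
         ha = 1.79, da = 2.72, lig_atom = "N8"),
    list(type = "hbond", resid = 108, resname = "PHE", donor = "ligand",
         ha = 2.33, da = 3.22, lig_atom = "N17"),
    list(type = "salt_bridge", resid = 32, resname = "ASP", dist = 4.19),
    list(type = "salt_bridge", resid = 228, resname = "ASP", dist = 5.26),
    list(type = "pi_stacking", resid = 115, resname = "TRP",
         centroid = 5.37, offset = 0.63))
}

ver_snapshot_specs <- function() {
  list(
    list(type = "hbond", resid = 10, resname = "SER", donor = "ligand",
         ha = 2.03, da = 2.97, lig_atom = "N19"),
    list(type = "hbond", resid = 73, resname = "GLN", donor = "protein",
         ha = 2.52, da = 3.49, lig_atom = "O2"))
}

# one protein residue (GLY backbone, donor N-H) plus one ligand acceptor
# atom at prescribed H-A / D-A distances; used to probe detector cutoffs
manual_hbond_series <- function(ha, da) {
  d_pos <- c(0, 0, 0)
  a_pos <- c(da, 0, 0)
  h_pos <- mdligand:::solve_h_position(d_pos, a_pos, ha)
  atoms <- do.call(rbind, list(
    mdligand:::atom_row("N", 1, "GLY", "A", 1L, NULL),
    mdligand:::atom_row("H", 1, "GLY", "A", 2L, NULL),
    mdligand:::atom_row("CA", 1, "GLY", "A", 3L, NULL),
    mdligand:::atom_row("C", 1, "GLY", "A", 4L, NULL),
    mdligand:::atom_row("O", 1, "GLY", "A", 5L, NULL),
    mdligand:::atom_row("OA1", 386, "LIG", "L", 6L, NULL)))
  coords <- rbind(d_pos, h_pos, c(-1.0, -1.1, 0), c(-2.2, -0.5, 0),
                  c(-2.4, -6, 0), a_pos)
  s <- frame_series(atoms, coords,
                    ligand_mask = c(rep(FALSE, 5), TRUE))
  tmpl <- default_residue_roles()
  tmpl$LIG <- list(donors = list(), acceptors = "OA1", cations = list(),
                   anions = list(), rings = list(), apolar = character(0))
  annotate_chemistry(s, tmpl)
}

# two parallel hexagonal rings (one protein PHE-like, one ligand) with
# controlled centroid distance geometry
manual_ring_pair_series <- function(lateral, vertical) {
  hx <- mdligand:::regular_polygon(6, 1.39)
  prot_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  lig_names <- paste0("CR1", 1:6)
  rows <- list()
  coords <- NULL
  for (j in 1:6) {
    rows[[j]] <- mdligand:::atom_row(prot_names[j], 1, "PHE", "A",
                                     as.integer(j), NULL)
    coords <- rbind(coords, c(hx[j, ], 0))
  }
  # minimal backbone so the PHE template is satisfied gracefully
  extra <- c("N", "H", "CA", "C", "O")
  epos <- rbind(c(-6, 2, 0), c(-6, 3, 0), c(-5, 1, 0), c(-4, 0, 0),
                c(-4, 1.2, 0))
  for (j in seq_along(extra)) {
    rows[[6 + j]] <- mdligand:::atom_row(extra[j], 1, "PHE", "A",
                                         as.integer(6 + j), NULL)
    coords <- rbind(coords, epos[j, ])
  }
  for (j in 1:6) {
    rows[[11 + j]] <- mdligand:::atom_row(lig_names[j], 386, "LIG", "L",
                                          as.integer(11 + j), NULL)
    coords <- rbind(coords, c(hx[j, 1] + lateral, hx[j, 2], vertical))
  }
  atoms <- do.call(rbind, rows)
  s <- frame_series(atoms, coords,
                    ligand_mask = c(rep(FALSE, 11), rep(TRUE, 6)))
  tmpl <- default_residue_roles()
  tmpl$LIG <- list(donors = list(), acceptors = character(0),
                   cations = list(), anions = list(),
                   rings = list(lig_names), apolar = character(0))
  annotate_chemistry(s, tmpl)
}

# random rigid transform (for invariance properties)
random_rigid <- function() {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, pi)
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
  list(R = R, t = stats::rnorm(3, 0, 10))
}

apply_rigid_to_series <- function(series, rig) {
  for (t in seq_len(n_frames(series))) {
    xyz <- frame_coords(series, t)
    series$frames[t, , ] <- sweep(xyz %*% rig$R, 2, -rig$t)
  }
  series
}
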