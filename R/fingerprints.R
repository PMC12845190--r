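#' @name interaction_fingerprints
#' @title Geometric protein-ligand interaction detection and fingerprints
#'
#' @description
#' Per-frame geometric detectors for hydrogen bonds, salt bridges,
#' face-to-face pi-stacking and hydrophobic contacts across the
#' protein-ligand interface, the trajectory fingerprint matrix with
#' per-contact persistence (occupancy), donor-acceptor mean-distance tables,
#' and a per-residue contact class map (green < 4 A, yellow 4-6 A) for a
#' single complex frame. All thresholds are inclusive and every emitted
#' event's stored geometry is asserted to satisfy them.
NULL

EVENT_COLS <- c("frame", "type", "resid", "resname", "protein_atoms",
                "ligand_atoms", "ha_dist", "da_dist", "dha_angle", "dist",
                "centroid_dist", "offset", "planar_angle")

empty_events <- function() {
  df <- data.frame(frame = integer(0), type = character(0),
                   resid = integer(0), resname = character(0),
                   protein_atoms = character(0), ligand_atoms = character(0),
                   ha_dist = numeric(0), da_dist = numeric(0),
                   dha_angle = numeric(0), dist = numeric(0),
                   centroid_dist = numeric(0), offset = numeric(0),
                   planar_angle = numeric(0))
  df
}

make_event <- function(frame, type, resid, resname, protein_atoms,
                       ligand_atoms, ...) {
  geo <- list(...)
  base <- list(frame = as.integer(frame), type = type,
               resid = as.integer(resid), resname = resname,
               protein_atoms = protein_atoms, ligand_atoms = ligand_atoms,
               ha_dist = NA_real_, da_dist = NA_real_, dha_angle = NA_real_,
               dist = NA_real_, centroid_dist = NA_real_, offset = NA_real_,
               planar_angle = NA_real_)
  for (nm in names(geo)) base[[nm]] <- geo[[nm]]
  as.data.frame(base, stringsAsFactors = FALSE)
}

check_annotated <- function(series) {
  if (!isTRUE(series$annotation$annotated)) {
    stop("series is not chemistry-annotated; call annotate_chemistry() first")
  }
  if (!any(series$ligand_mask)) stop("series has no ligand atoms")
}

dist3 <- function(p, q) sqrt(sum((p - q)^2))

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' A donor pair (heavy atom D, polar hydrogen H) on one side of the
#' interface and an acceptor A on the other side form a hydrogen bond when
#' `d(H,A) <= h_a_max`, `d(D,A) <= d_a_max` and the D-H-A angle is
#' `>= dha_min`. Both directions (protein donor -> ligand acceptor and
#' ligand donor -> protein acceptor) are scanned.
#'
#' @param series annotated `FrameSeries`
#' @param frame frame index
#' @param h_a_max hydrogen-acceptor cutoff, Angstrom
#' @param d_a_max donor-acceptor cutoff, Angstrom
#' @param dha_min minimum D-H-A angle, degrees
#' @return event data.frame (one row per bond) with `ha_dist`, `da_dist`,
#'   `dha_angle`
#' @export
detect_hbonds_frame <- function(series, frame = 1L, h_a_max = 3.0,
                                d_a_max = 4.0, dha_min = 120) {
  check_annotated(series)
  ann <- series$annotation
  if (length(ann$missing_donor_h) > 0) {
    stop("declared donors missing hydrogens: ",
         paste(ann$missing_donor_h, collapse = ", "))
  }
  xyz <- frame_coords(series, frame)
  a <- series$atoms
  lig <- series$ligand_mask
  dp <- ann$donor_pairs
  events <- list()
  for (i in seq_len(nrow(dp))) {
    d_i <- dp[i, "heavy"]; h_i <- dp[i, "hydrogen"]
    opp <- ann$acceptors[lig[ann$acceptors] != lig[d_i]]
    for (a_i in opp) {
      ha <- dist3(xyz[h_i, ], xyz[a_i, ])
      if (ha > h_a_max) next
      da <- dist3(xyz[d_i, ], xyz[a_i, ])
      if (da > d_a_max) next
      ang <- angle_deg(xyz[d_i, ] - xyz[h_i, ], xyz[a_i, ] - xyz[h_i, ])
      if (ang < dha_min) next
      prot_i <- if (lig[d_i]) a_i else d_i
      lig_atoms <- if (lig[d_i]) paste(a$name[d_i], a$name[h_i]) else a$name[a_i]
      prot_atoms <- if (lig[d_i]) a$name[a_i] else paste(a$name[d_i], a$name[h_i])
      stopifnot(ha <= h_a_max, da <= d_a_max, ang >= dha_min)
      events[[length(events) + 1L]] <- make_event(
        frame, "hbond", a$resid[prot_i], a$resname[prot_i],
        prot_atoms, lig_atoms,
        ha_dist = ha, da_dist = da, dha_angle = ang)
    }
  }
  if (length(events) == 0) return(empty_events())
  do.call(rbind, events)
}

#' Detect salt bridges in one frame
#'
#' A cation group and an anion group on opposite sides of the interface
#' form a salt bridge when the minimum distance over their atom pairs is
#' `<= max_dist`; that minimum is the reported distance.
#'
#' @param series annotated `FrameSeries`
#' @param frame frame index
#' @param max_dist minimum-atom-distance cutoff, Angstrom
#' @return event data.frame with `dist`
#' @export
detect_salt_bridges_frame <- function(series, frame = 1L, max_dist = 5.5) {
  check_annotated(series)
  xyz <- frame_coords(series, frame)
  a <- series$atoms
  lig <- series$ligand_mask
  groups <- series$annotation$charged_groups
  events <- list()
  if (length(groups) >= 2) {
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        gi <- groups[[i]]; gj <- groups[[j]]
        if (gi$sign != 1L || gj$sign != -1L) next       # cation vs anion
        if (lig[gi$atoms[1]] == lig[gj$atoms[1]]) next  # cross-interface only
        dmat <- outer(gi$atoms, gj$atoms,
                      Vectorize(function(p, q) dist3(xyz[p, ], xyz[q, ])))
        dmin <- min(dmat)
        if (dmin > max_dist) next
        prot_g <- if (lig[gi$atoms[1]]) gj else gi
        lig_g <- if (lig[gi$atoms[1]]) gi else gj
        stopifnot(dmin <= max_dist)
        events[[length(events) + 1L]] <- make_event(
          frame, "salt_bridge", a$resid[prot_g$atoms[1]],
          a$resname[prot_g$atoms[1]],
          paste(a$name[prot_g$atoms], collapse = " "),
          paste(a$name[lig_g$atoms], collapse = " "),
          dist = dmin)
      }
    }
  }
  if (length(events) == 0) return(empty_events())
  do.call(rbind, events)
}

ring_geometry <- function(xyz, ring_idx) {
  pts <- xyz[ring_idx, , drop = FALSE]
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  s <- svd(centered)
  if (s$d[2] <= max(s$d[1], 1e-12) * 1e-8) {
    stop("degenerate ring: atoms are collinear")
  }
  list(centroid = centroid, normal = s$v[, 3])
}

#' Detect face-to-face pi-stacking in one frame
#'
#' For each cross-interface pair of aromatic rings: centroid distance
#' `<= centroid_max`, lateral offset (projection of the centroid-centroid
#' vector onto the protein ring plane) `<= offset_max`, and angle between
#' ring normals (folded to <= 90 degrees) `<= planarity_max`.
#'
#' @param series annotated `FrameSeries`
#' @param frame frame index
#' @param centroid_max centroid distance cutoff, Angstrom
#' @param offset_max lateral offset cutoff, Angstrom
#' @param planarity_max maximum angle between ring normals, degrees
#' @return event data.frame with `centroid_dist`, `offset`, `planar_angle`
#' @export
detect_pi_stacking_frame <- function(series, frame = 1L, centroid_max = 5.5,
                                     offset_max = 2.0, planarity_max = 35) {
  check_annotated(series)
  xyz <- frame_coords(series, frame)
  a <- series$atoms
  lig <- series$ligand_mask
  rings <- series$annotation$rings
  on_lig <- vapply(rings, function(r) lig[r[1]], TRUE)
  events <- list()
  for (i in which(!on_lig)) {
    gp <- ring_geometry(xyz, rings[[i]])
    for (j in which(on_lig)) {
      gl <- ring_geometry(xyz, rings[[j]])
      v <- gl$centroid - gp$centroid
      cd <- sqrt(sum(v * v))
      if (cd > centroid_max) next
      off_vec <- v - sum(v * gp$normal) * gp$normal
      off <- sqrt(sum(off_vec * off_vec))
      if (off > offset_max) next
      ang <- angle_deg(gp$normal, gl$normal)
      if (ang > 90) ang <- 180 - ang
      if (ang > planarity_max) next
      stopifnot(cd <= centroid_max, off <= offset_max, ang <= planarity_max)
      ri <- rings[[i]][1]
      events[[length(events) + 1L]] <- make_event(
        frame, "pi_stacking", a$resid[ri], a$resname[ri],
        paste(a$name[rings[[i]]], collapse = " "),
        paste(a$name[rings[[j]]], collapse = " "),
        centroid_dist = cd, offset = off, planar_angle = ang)
    }
  }
  if (length(events) == 0) return(empty_events())
  do.call(rbind, events)
}

#' Detect hydrophobic contacts in one frame
#'
#' One event per protein residue having at least one apolar-apolar
#' cross-interface atom pair within `max_dist`; the reported distance is
#' the residue's minimum such pair distance.
#'
#' @param series annotated `FrameSeries`
#' @param frame frame index
#' @param max_dist contact cutoff, Angstrom
#' @return event data.frame with `dist`
#' @export
detect_hydrophobic_frame <- function(series, frame = 1L, max_dist = 4.5) {
  check_annotated(series)
  xyz <- frame_coords(series, frame)
  a <- series$atoms
  lig <- series$ligand_mask
  ap <- series$annotation$apolar
  p_ap <- ap[!lig[ap]]
  l_ap <- ap[lig[ap]]
  if (length(p_ap) == 0 || length(l_ap) == 0) return(empty_events())
  events <- list()
  for (r in unique(a$resid[p_ap])) {
    ridx <- p_ap[a$resid[p_ap] == r]
    dmat <- outer(ridx, l_ap,
                  Vectorize(function(p, q) dist3(xyz[p, ], xyz[q, ])))
    dmin <- min(dmat)
    if (dmin > max_dist) next
    best <- which(dmat == dmin, arr.ind = TRUE)[1, ]
    stopifnot(dmin <= max_dist)
    events[[length(events) + 1L]] <- make_event(
      frame, "hydrophobic", r, a$resname[ridx[1]],
      a$name[ridx[best[1]]], a$name[l_ap[best[2]]], dist = dmin)
  }
  if (length(events) == 0) return(empty_events())
  do.call(rbind, events)
}

#' Fingerprint a whole trajectory
#'
#' Runs all four detectors on every frame and assembles the boolean
#' frames-by-keys fingerprint matrix, where a key is a
#' `(residue, interaction type)` pair. Persistence of a key is the exact
#' fraction of frames in which it is present.
#'
#' @param series annotated `FrameSeries`
#' @param ... threshold arguments forwarded to the four detectors
#'   (`h_a_max`, `d_a_max`, `dha_min`, `sb_max_dist`, `centroid_max`,
#'   `offset_max`, `planarity_max`, `hp_max_dist`)
#' @return a `FingerprintMatrix`: list with logical `matrix`
#'   (frames x keys, key columns named `"resid:type"`), `keys` data.frame,
#'   `persistence`, and the full `events` table
#' @export
fingerprint_trajectory <- function(series, h_a_max = 3.0, d_a_max = 4.0,
                                   dha_min = 120, sb_max_dist = 5.5,
                                   centroid_max = 5.5, offset_max = 2.0,
                                   planarity_max = 35, hp_max_dist = 4.5) {
  check_annotated(series)
  t_n <- n_frames(series)
  ev_list <- lapply(seq_len(t_n), function(t) {
    rbind(detect_hbonds_frame(series, t, h_a_max, d_a_max, dha_min),
          detect_salt_bridges_frame(series, t, sb_max_dist),
          detect_pi_stacking_frame(series, t, centroid_max, offset_max,
                                   planarity_max),
          detect_hydrophobic_frame(series, t, hp_max_dist))
  })
  events <- do.call(rbind, ev_list)
  keys <- unique(events[, c("resid", "type")])
  keys <- keys[order(keys$resid, keys$type), , drop = FALSE]
  rownames(keys) <- NULL
  key_names <- paste(keys$resid, keys$type, sep = ":")
  mat <- matrix(FALSE, nrow = t_n, ncol = nrow(keys),
                dimnames = list(NULL, key_names))
  if (nrow(events) > 0) {
    ev_key <- paste(events$resid, events$type, sep = ":")
    mat[cbind(events$frame, match(ev_key, key_names))] <- TRUE
  }
  structure(list(matrix = mat, keys = keys,
                 persistence = colSums(mat) / t_n,
                 events = events), class = "FingerprintMatrix")
}

#' @export
print.FingerprintMatrix <- function(x, ...) {
  cat(sprintf("FingerprintMatrix: %d frames x %d keys\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Mean donor-acceptor distance table
#'
#' For each requested donor/acceptor atom pair, the mean donor-acceptor
#' distance over all frames (bonded or not) in nm. Means well above any
#' bonding cutoff simply indicate a pair that is rarely in contact.
#'
#' @param series a `FrameSeries`
#' @param pairs data.frame with columns `donor_resid`, `donor_atom`,
#'   `acceptor_resid`, `acceptor_atom`
#' @return data.frame with `pair_id`, `donor_residue`, `donor_atom`,
#'   `acceptor_residue`, `acceptor_atom`, `avg_distance_nm`
#' @export
hbond_distance_table <- function(series, pairs) {
  req <- c("donor_resid", "donor_atom", "acceptor_resid", "acceptor_atom")
  stopifnot(all(req %in% names(pairs)))
  a <- series$atoms
  find_atom <- function(resid, name) {
    i <- which(a$resid == resid & a$name == name)
    if (length(i) != 1) {
      stop("cannot resolve atom ", name, " of residue ", resid,
           " (", length(i), " matches)")
    }
    i
  }
  res_label <- function(i) paste0(a$resname[i], a$resid[i])
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    d_i <- find_atom(pairs$donor_resid[k], pairs$donor_atom[k])
    a_i <- find_atom(pairs$acceptor_resid[k], pairs$acceptor_atom[k])
    dists <- vapply(seq_len(n_frames(series)), function(t) {
      xyz <- frame_coords(series, t)
      dist3(xyz[d_i, ], xyz[a_i, ])
    }, 0)
    data.frame(pair_id = k,
               donor_residue = res_label(d_i),
               donor_atom = a$name[d_i],
               acceptor_residue = res_label(a_i),
               acceptor_atom = a$name[a_i],
               avg_distance_nm = ang_to_nm(mean(dists)))
  })
  do.call(rbind, out)
}

#' Per-residue ligand contact class for a single frame
#'
#' Classifies each protein residue by its minimum heavy-atom distance to
#' any ligand heavy atom: `green` below `green_max`, `yellow` between
#' `green_max` and `yellow_max`, `none` beyond. The yellow band must be
#' capped to keep the interacting-residue set finite.
#'
#' @param series a `FrameSeries` with a ligand
#' @param frame frame index
#' @param green_max green cutoff, Angstrom (exclusive)
#' @param yellow_max outer yellow cutoff, Angstrom (inclusive)
#' @return data.frame with `resid`, `resname`, `min_dist` (Angstrom),
#'   `class`
#' @export
contact_class_map <- function(series, frame = 1L, green_max = 4.0,
                              yellow_max = 6.0) {
  if (!any(series$ligand_mask)) stop("series has no ligand atoms")
  xyz <- frame_coords(series, frame)
  a <- series$atoms
  heavy <- a$element != "H"
  lidx <- which(series$ligand_mask & heavy)
  pidx <- which(!series$ligand_mask & heavy)
  out <- lapply(unique(a$resid[pidx]), function(r) {
    ridx <- pidx[a$resid[pidx] == r]
    dmin <- min(vapply(ridx, function(p) {
      min(sqrt(colSums((t(xyz[lidx, , drop = FALSE]) - xyz[p, ])^2)))
    }, 0))
    cls <- if (dmin < green_max) "green" else if (dmin <= yellow_max)
      "yellow" else "none"
    data.frame(resid = r, resname = a$resname[ridx[1]], min_dist = dmin,
               class = cls)
  })
  do.call(rbind, out)
}
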