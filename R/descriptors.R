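#' @name trajectory_descriptors
#' @title Per-frame RMSD, per-residue RMSF, and radius of gyration
#'
#' @description
#' Standard MD trajectory descriptors. Internally all geometry is in
#' Angstrom (the PDB's native unit); these reporting-layer functions return
#' values in nm, the unit in which such summaries are conventionally
#' printed. Each frame is least-squares fitted on a fit selection before
#' measuring, which removes global translational and rotational motion.
NULL

#' Per-frame RMSD series relative to a reference frame
#'
#' Each frame is Kabsch-fitted on `fit_selection` to the reference frame
#' (by default the first, i.e. the initial conformation), and RMSD is then
#' measured on `measure_selection`. Measuring the ligand after fitting on
#' the protein backbone reports pocket-relative ligand motion; pass
#' `measure_selection = fit_selection = "ligand"` for internal ligand RMSD.
#'
#' @param series a `FrameSeries`
#' @param fit_selection selection fitted to the reference (default backbone)
#' @param measure_selection selection RMSD is measured on (default: same)
#' @param reference reference frame index (1-based, default first frame)
#' @return list with `time` (ns), `value` (nm per frame) and `summary`
#'   (`mean`, `sd` (sample), `n`, `unit = "nm"`)
#' @export
rmsd_series <- function(series, fit_selection = "backbone",
                        measure_selection = fit_selection, reference = 1L) {
  fit_idx <- resolve_selection(series, fit_selection)
  mea_idx <- resolve_selection(series, measure_selection)
  t_n <- n_frames(series)
  if (reference < 1L || reference > t_n) stop("invalid reference frame")
  ref <- frame_coords(series, reference)
  vals <- vapply(seq_len(t_n), function(t) {
    xyz <- frame_coords(series, t)
    tf <- kabsch_fit(xyz[fit_idx, , drop = FALSE],
                     ref[fit_idx, , drop = FALSE])
    moved <- apply_transform(xyz, tf)
    rmsd(moved[mea_idx, , drop = FALSE], ref[mea_idx, , drop = FALSE])
  }, 0)
  vals_nm <- ang_to_nm(vals)
  list(time = series$frame_times, value = vals_nm,
       summary = series_summary(vals_nm, "nm"))
}

fit_frames_to <- function(series, target, fit_idx) {
  t_n <- n_frames(series)
  out <- series$frames
  for (t in seq_len(t_n)) {
    xyz <- frame_coords(series, t)
    tf <- kabsch_fit(xyz[fit_idx, , drop = FALSE],
                     target[fit_idx, , drop = FALSE])
    out[t, , ] <- apply_transform(xyz, tf)
  }
  out
}

#' Per-residue RMSF profile
#'
#' Frames are fitted to the time-average structure: an initial fit to the
#' first frame gives a provisional mean, then one refinement pass refits all
#' frames to that mean and recomputes it. RMSF of residue `r` is the root
#' mean squared deviation over frames of its basis atom (`calpha`, the
#' convention for residue-level flexibility plots) or the mean over its
#' heavy atoms (`heavy-mean`) from the mean position.
#'
#' @param series a `FrameSeries` with at least 2 frames
#' @param fit_selection selection used for fitting (default backbone)
#' @param atom_basis `"calpha"` or `"heavy-mean"`
#' @return an `RMSFProfile`: data.frame with `resid` and `rmsf` (nm), with
#'   attribute `atom_basis`
#' @export
rmsf_profile <- function(series, fit_selection = "backbone",
                         atom_basis = c("calpha", "heavy-mean")) {
  atom_basis <- match.arg(atom_basis)
  if (n_frames(series) < 2) stop("RMSF requires at least 2 frames")
  fit_idx <- resolve_selection(series, fit_selection)
  # pass 1: fit to first frame, take the mean; pass 2: refit to that mean
  fitted <- fit_frames_to(series, frame_coords(series, 1L), fit_idx)
  mean1 <- apply(fitted, c(2, 3), mean)
  tmp <- series
  tmp$frames <- fitted
  fitted <- fit_frames_to(tmp, mean1, fit_idx)
  mean2 <- apply(fitted, c(2, 3), mean)

  dev2 <- (fitted - rep(mean2, each = dim(fitted)[1]))^2
  atom_msf <- apply(dev2, 2, sum) / dim(fitted)[1]  # per-atom mean sq. dev.

  prot <- !series$ligand_mask
  a <- series$atoms
  if (atom_basis == "calpha") {
    idx <- which(prot & a$name == "CA")
    if (length(idx) == 0) stop("no C-alpha atoms in series")
    resid <- a$resid[idx]
    rmsf <- sqrt(atom_msf[idx])
  } else {
    idx <- which(prot & a$element != "H")
    resid_all <- a$resid[idx]
    resid <- unique(resid_all)
    rmsf <- vapply(resid, function(r) {
      mean(sqrt(atom_msf[idx[resid_all == r]]))
    }, 0)
  }
  out <- data.frame(resid = resid, rmsf = ang_to_nm(rmsf))
  class(out) <- c("RMSFProfile", "data.frame")
  attr(out, "atom_basis") <- atom_basis
  out
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )` per frame, reported
#' in nm. With `mass_weighted = FALSE` all masses are taken equal.
#'
#' @param series a `FrameSeries`
#' @param selection atoms included (default whole protein)
#' @param mass_weighted logical
#' @return list with `time`, `value` (nm) and `summary`
#' @export
rg_series <- function(series, selection = "protein", mass_weighted = TRUE) {
  idx <- resolve_selection(series, selection)
  m <- if (mass_weighted) series$atoms$mass[idx] else rep(1, length(idx))
  if (sum(m) <= 0) stop("zero total mass in selection")
  w <- m / sum(m)
  vals <- vapply(seq_len(n_frames(series)), function(t) {
    xyz <- frame_coords(series, t)[idx, , drop = FALSE]
    com <- colSums(xyz * w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
  }, 0)
  vals_nm <- ang_to_nm(vals)
  list(time = series$frame_times, value = vals_nm,
       summary = series_summary(vals_nm, "nm"))
}
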