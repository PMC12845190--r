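test_that("hydrogen-bond detector: planted geometries and cutoffs", {
  s <- manual_hbond_series(ha = 2.96, da = 3.94)
  ev <- detect_hbonds_frame(s)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ha_dist, 2.96, tolerance = 1e-9)
  expect_equal(ev$da_dist, 3.94, tolerance = 1e-9)
  expect_gte(ev$dha_angle, 120)

  expect_equal(nrow(detect_hbonds_frame(manual_hbond_series(1.79, 2.72))), 1L)
  # H-A beyond 3.0 A: not a bond
  expect_equal(nrow(detect_hbonds_frame(manual_hbond_series(3.5, 4.0))), 0L)
  # wide D-H-A angle violation: H on the far side (bent geometry)
  bent <- manual_hbond_series(2.9, 2.1)  # geometry forces angle < 120
  expect_equal(nrow(detect_hbonds_frame(bent)), 0L)
})

test_that("missing donor hydrogens are an error, not a silent skip", {
  s <- manual_hbond_series(2.5, 3.2)
  s2 <- s
  keep <- s$atoms$name != "H"
  s2$atoms <- s$atoms[keep, ]
  s2$frames <- s$frames[, keep, , drop = FALSE]
  s2$ligand_mask <- s$ligand_mask[keep]
  tmpl <- default_residue_roles()
  tmpl$LIG <- list(donors = list(), acceptors = "OA1", cations = list(),
                   anions = list(), rings = list(), apolar = character(0))
  s2 <- annotate_chemistry(s2, tmpl)
  expect_error(detect_hbonds_frame(s2), "missing hydrogens")
})

test_that("salt-bridge detector thresholds on minimum group distance", {
  cx <- make_toy_complex(10, seed = 51)
  for (d in c(4.19, 5.26)) {
    snap <- plant_interaction_snapshot(cx, list(
      list(type = "salt_bridge", resid = 32, resname = "ASP", dist = d)))
    ev <- detect_salt_bridges_frame(snap)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$dist, d, tolerance = 1e-6)
    expect_identical(ev$resname, "ASP")
  }
  far <- plant_interaction_snapshot(cx, list(
    list(type = "salt_bridge", resid = 32, resname = "ASP", dist = 6.0)))
  expect_equal(nrow(detect_salt_bridges_frame(far)), 0L)
})

test_that("pi-stacking detector: centroid, offset and planarity rules", {
  cx <- make_toy_complex(10, seed = 52)
  snap <- plant_interaction_snapshot(cx, list(
    list(type = "pi_stacking", resid = 115, resname = "TRP",
         centroid = 5.37, offset = 0.63)))
  ev <- detect_pi_stacking_frame(snap)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$centroid_dist, 5.37, tolerance = 1e-6)
  expect_equal(ev$offset, 0.63, tolerance = 1e-6)
  expect_lte(ev$planar_angle, 35)

  # centroid beyond 5.5 A
  expect_equal(nrow(detect_pi_stacking_frame(
    manual_ring_pair_series(lateral = 0.5, vertical = 7.0))), 0L)
  # coplanar rings, 3 A lateral offset: rejected by the offset rule
  expect_equal(nrow(detect_pi_stacking_frame(
    manual_ring_pair_series(lateral = 3.0, vertical = 0))), 0L)
  # parallel slipped stack inside all cutoffs is accepted
  expect_equal(nrow(detect_pi_stacking_frame(
    manual_ring_pair_series(lateral = 1.0, vertical = 4.5))), 1L)
})

test_that("hydrophobic detector: one event per residue within cutoff", {
  cx <- make_toy_complex(10, seed = 53)
  near <- plant_interaction_snapshot(cx, list(
    list(type = "hydrophobic", resid = 110, resname = "ILE", dist = 4.0)))
  ev <- detect_hydrophobic_frame(near)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$resid, 110L)
  expect_equal(ev$dist, 4.0, tolerance = 1e-6)
  far <- plant_interaction_snapshot(cx, list(
    list(type = "hydrophobic", resid = 110, resname = "ILE", dist = 5.0)))
  expect_equal(nrow(detect_hydrophobic_frame(far)), 0L)

  # planted pocket: several residues in the 3.8-4.4 A contact range
  pocket <- plant_interaction_snapshot(cx, list(
    list(type = "hydrophobic", resid = 115, resname = "TRP", dist = 3.8),
    list(type = "hydrophobic", resid = 110, resname = "ILE", dist = 4.4)))
  evp <- detect_hydrophobic_frame(pocket)
  expect_setequal(evp$resid, c(110L, 115L))
})

test_that("final-snapshot fixtures give the exact interaction census", {
  cx <- make_toy_complex(12, seed = 54)
  inh1 <- plant_interaction_snapshot(cx, inh1_snapshot_specs())
  expect_equal(nrow(detect_hbonds_frame(inh1)), 3L)
  expect_equal(nrow(detect_salt_bridges_frame(inh1)), 2L)
  expect_equal(nrow(detect_pi_stacking_frame(inh1)), 1L)

  ver <- plant_interaction_snapshot(cx, ver_snapshot_specs())
  expect_equal(nrow(detect_hbonds_frame(ver)), 2L)
  expect_equal(nrow(detect_salt_bridges_frame(ver)), 0L)
  expect_equal(nrow(detect_pi_stacking_frame(ver)), 0L)
  hb <- detect_hbonds_frame(ver)
  expect_setequal(round(hb$ha_dist, 2), c(2.03, 2.52))
  expect_setequal(round(hb$da_dist, 2), c(2.97, 3.49))
})

test_that("detectors are invariant under rigid transforms of the frame", {
  cx <- make_toy_complex(12, seed = 55)
  snap <- plant_interaction_snapshot(cx, inh1_snapshot_specs())
  set.seed(56)
  rig <- random_rigid()
  moved <- apply_rigid_to_series(snap, rig)
  for (fn in list(detect_hbonds_frame, detect_salt_bridges_frame,
                  detect_pi_stacking_frame, detect_hydrophobic_frame)) {
    a <- fn(snap)
    b <- fn(moved)
    expect_equal(nrow(a), nrow(b))
    geo <- c("ha_dist", "da_dist", "dha_angle", "dist", "centroid_dist",
             "offset")
    expect_equal(a[order(a$resid, a$ligand_atoms), geo],
                 b[order(b$resid, b$ligand_atoms), geo], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("fingerprint matrix and persistence", {
  cx <- make_toy_complex(10, seed = 57)
  snap <- plant_interaction_snapshot(cx, list(
    list(type = "hbond", resid = 74, resname = "GLY", donor = "protein",
         ha = 2.5, da = 3.3, lig_atom = "N24")))
  # 1-frame fingerprint equals the union of the four frame detectors
  fp1 <- fingerprint_trajectory(snap)
  expect_equal(sum(fp1$matrix), nrow(detect_hbonds_frame(snap)))
  expect_equal(unname(fp1$persistence), 1.0)

  # alternating 2-frame presence: second frame pushes the ligand atoms away
  two <- snap
  two$frames <- array(0, dim = c(2, n_atoms(snap), 3))
  two$frames[1, , ] <- frame_coords(snap, 1)
  shifted <- frame_coords(snap, 1)
  shifted[two$ligand_mask, 1] <- shifted[two$ligand_mask, 1] + 50
  two$frames[2, , ] <- shifted
  two$frame_times <- c(0, 1)
  fp2 <- fingerprint_trajectory(two)
  expect_equal(unname(fp2$persistence["74:hbond"]), 0.5)
  expect_equal(colSums(fp2$matrix)["74:hbond"] / 2,
               fp2$persistence["74:hbond"])

  # empty interface -> empty matrix
  fp0 <- fingerprint_trajectory(plant_interaction_snapshot(cx, list()))
  expect_equal(ncol(fp0$matrix), 0L)
})

test_that("donor-acceptor mean distance table", {
  cx <- make_toy_complex(10, seed = 58)
  snap <- plant_interaction_snapshot(cx, list(
    list(type = "hbond", resid = 74, resname = "GLY", donor = "protein",
         ha = 2.2, da = 3.0, lig_atom = "N24")))
  pairs <- data.frame(donor_resid = 74, donor_atom = "N",
                      acceptor_resid = 386, acceptor_atom = "N24")
  tab <- hbond_distance_table(snap, pairs)
  expect_equal(tab$avg_distance_nm, 0.30, tolerance = 1e-9)

  # alternating 3.0 / 5.0 A separation -> 0.40 nm mean
  two <- snap
  two$frames <- array(0, dim = c(2, n_atoms(snap), 3))
  two$frames[1, , ] <- frame_coords(snap, 1)
  sh <- frame_coords(snap, 1)
  i <- which(two$atoms$name == "N24")
  sh[i, 1] <- sh[i, 1] + 2.0
  two$frames[2, , ] <- sh
  two$frame_times <- c(0, 1)
  tab2 <- hbond_distance_table(two, pairs)
  expect_equal(tab2$avg_distance_nm, 0.40, tolerance = 1e-9)

  # drifting pair matches a per-frame brute-force mean
  set.seed(59)
  drift <- make_fluctuation_trajectory(snap, 0.05, 10, seed = 59)
  tab3 <- hbond_distance_table(drift, pairs)
  d_i <- which(drift$atoms$resid == 74 & drift$atoms$name == "N")
  a_i <- which(drift$atoms$name == "N24")
  manual <- mean(vapply(1:10, function(t) {
    sqrt(sum((drift$frames[t, d_i, ] - drift$frames[t, a_i, ])^2))
  }, 0)) / 10
  expect_equal(tab3$avg_distance_nm, manual, tolerance = 1e-12)

  expect_error(hbond_distance_table(snap, data.frame(
    donor_resid = 999, donor_atom = "N", acceptor_resid = 386,
    acceptor_atom = "N24")), "999")
})

test_that("contact class map bands", {
  cx <- make_toy_complex(10, seed = 60)
  snap <- plant_interaction_snapshot(cx, list(
    list(type = "hydrophobic", resid = 201, resname = "ALA", dist = 3.9),
    list(type = "hydrophobic", resid = 202, resname = "ALA", dist = 4.2)))
  cm <- contact_class_map(snap)
  expect_identical(cm$class[cm$resid == 201], "green")
  expect_identical(cm$class[cm$resid == 202], "yellow")
  # backbone residues of the toy helix sit far from everything
  expect_true(all(cm$class[cm$resid <= 10] == "none"))
  noli <- make_toy_complex(8, ligand_spec = NULL, seed = 61)
  expect_error(contact_class_map(noli), "ligand")
})
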