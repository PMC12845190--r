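test_that("rmsd_series: static and rigid-motion-only trajectories are zero", {
  cx <- make_toy_complex(15, seed = 21)
  static <- make_fluctuation_trajectory(cx, 0, 6, seed = 22)
  rs <- rmsd_series(static)
  expect_equal(rs$value, rep(0, 6), tolerance = 1e-9)
  expect_equal(rs$summary$mean, 0, tolerance = 1e-9)
  expect_equal(rs$summary$sd, 0, tolerance = 1e-9)

  rigid <- make_fluctuation_trajectory(
    cx, 0, 6, seed = 23, rigid_motion = list(rot_deg = 40, trans_ang = 5))
  rr <- rmsd_series(rigid)
  expect_equal(rr$value, rep(0, 6), tolerance = 1e-8)
})

test_that("rmsd_series matches a per-frame rotation-oracle recomputation", {
  cx <- make_toy_complex(6, ligand_spec = NULL, seed = 24)
  tr <- make_fluctuation_trajectory(cx, 0.08, 4, seed = 25)
  sel <- select_atoms(tr, "calpha")$indices
  rs <- rmsd_series(tr, fit_selection = "calpha",
                    measure_selection = "calpha")
  ref <- frame_coords(tr, 1)[sel, ]
  for (t in 2:4) {
    xyz <- frame_coords(tr, t)[sel, ]
    expect_equal(rs$value[t], mdligand:::ang_to_nm(oracle_min_rmsd(xyz, ref)),
                 tolerance = 2e-3)
  }
})

test_that("rmsf: static zero; planted two-tier profile classified exactly", {
  cx <- make_toy_complex(30, ligand_spec = NULL, seed = 26)
  static <- make_fluctuation_trajectory(cx, 0, 3, seed = 27)
  expect_equal(rmsf_profile(static)$rmsf, rep(0, 30), tolerance = 1e-9)
  expect_error(rmsf_profile(make_fluctuation_trajectory(cx, 0, 1)),
               "at least 2")

  # rigid core at 0.03 nm, mobile loops at 0.15 nm
  sigma <- rep(0.03, 30)
  loops <- c(1:4, 14:18, 27:30)
  sigma[loops] <- 0.15
  tr <- make_fluctuation_trajectory(cx, sigma, 400, seed = 28)
  cl <- classify_flexibility(rmsf_profile(tr))
  expect_setequal(cl$table$resid[cl$table$label == "medium"], loops)
  expect_setequal(cl$table$resid[cl$table$label == "low"],
                  setdiff(1:30, loops))
})

test_that("rmsf is invariant under global rigid motion", {
  cx <- make_toy_complex(20, ligand_spec = NULL, seed = 29)
  tr <- make_fluctuation_trajectory(cx, 0.06, 60, seed = 30)
  base <- rmsf_profile(tr)
  moved <- make_fluctuation_trajectory(
    cx, 0.06, 60, seed = 30, rigid_motion = list(rot_deg = 30, trans_ang = 4))
  # same seed: residue noise identical, only the global motion differs,
  # and fitting removes it
  expect_equal(rmsf_profile(moved)$rmsf, base$rmsf, tolerance = 1e-6)
})

test_that("rg: closed forms, brute-force oracle, rigid invariance", {
  cx <- make_toy_complex(8, ligand_spec = NULL, seed = 31)
  one <- rg_series(cx, list(resid = 1, names = "CA"))
  expect_equal(one$value, 0, tolerance = 1e-12)

  # two equal masses 2 A apart -> Rg = 1 A = 0.1 nm
  atoms <- do.call(rbind, lapply(1:2, function(i)
    mdligand:::atom_row("CA", i, "GLY", "A", as.integer(i), NULL)))
  two <- frame_series(atoms, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(rg_series(two, "protein")$value, 0.1, tolerance = 1e-12)

  # four equal masses at tetrahedron vertices vs direct formula
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  atoms4 <- do.call(rbind, lapply(1:4, function(i)
    mdligand:::atom_row("CA", i, "GLY", "A", as.integer(i), NULL)))
  four <- frame_series(atoms4, tet)
  com <- colMeans(tet)
  oracle <- sqrt(mean(rowSums(sweep(tet, 2, com)^2))) / 10
  expect_equal(rg_series(four, "protein")$value, oracle, tolerance = 1e-12)

  tr <- make_fluctuation_trajectory(cx, 0.05, 5, seed = 32)
  base <- rg_series(tr, "protein")$value
  rig <- random_rigid()
  expect_equal(rg_series(apply_rigid_to_series(tr, rig), "protein")$value,
               base, tolerance = 1e-9)
})

test_that("series summaries match a two-pass brute-force recomputation", {
  cx <- make_toy_complex(10, seed = 33)
  tr <- make_fluctuation_trajectory(cx, 0.07, 25, seed = 34)
  rs <- rmsd_series(tr)
  m <- sum(rs$value) / length(rs$value)
  s2 <- sum((rs$value - m)^2) / (length(rs$value) - 1)
  expect_equal(rs$summary$mean, m, tolerance = 1e-12)
  expect_equal(rs$summary$sd, sqrt(s2), tolerance = 1e-12)
  expect_identical(rs$summary$unit, "nm")
})
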