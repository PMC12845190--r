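# Independent oracles kept deliberately separate from the implementation
# code paths they check.

# minimum RMSD over rotations by Euler-angle grid search plus Nelder-Mead
# refinement; never touches the SVD-based Kabsch path
oracle_min_rmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(p) {
    moved <- mc %*% rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((moved - rc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- NULL; best_val <- Inf
  for (a in grid) for (b in grid) for (c in grid) {
    v <- f(c(a, b, c))
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# brute-force sliding-window differential detector: enumerate every window,
# flag, and merge runs of overlapping same-sign flagged starts
oracle_window_segments <- function(av, bv, resid, window, min_abs_diff) {
  n_win <- length(resid) - window + 1
  rows <- list()
  d <- numeric(n_win)
  for (s in seq_len(n_win)) {
    d[s] <- max(av[s:(s + window - 1)]) - max(bv[s:(s + window - 1)])
  }
  flagged <- which(abs(d) >= min_abs_diff)
  if (length(flagged) == 0) {
    return(data.frame(start_residue = integer(0), end_residue = integer(0),
                      direction = character(0), peak_abs_diff = numeric(0)))
  }
  groups <- list(); cur <- flagged[1]
  for (k in flagged[-1]) {
    last <- cur[length(cur)]
    if ((k - last) <= (window - 1) && sign(d[k]) == sign(d[cur[1]])) {
      cur <- c(cur, k)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- k
    }
  }
  groups[[length(groups) + 1]] <- cur
  do.call(rbind, lapply(groups, function(g) {
    data.frame(start_residue = resid[g[1]],
               end_residue = resid[g[length(g)]],
               direction = if (d[g[1]] > 0) "A-higher" else "B-higher",
               peak_abs_diff = max(abs(d[g])))
  }))
}

# per-inequality drug-likeness oracle, written condition by condition
oracle_rule_violations <- function(rec) {
  lp <- rec$consensus_logp
  c(lipinski = sum(rec$mw > 500, lp > 4.15, rec$hbd > 5, rec$hba > 10),
    ghose = sum(rec$mw < 160, rec$mw > 480, lp < -0.4, lp > 5.6,
                rec$molar_refractivity < 40, rec$molar_refractivity > 130,
                rec$atom_count < 20, rec$atom_count > 70),
    veber = sum(rec$rotatable_bonds > 10, rec$tpsa > 140),
    egan = sum(lp > 5.88, rec$tpsa > 131.6),
    muegge = sum(rec$mw < 200, rec$mw > 600, lp < -2, lp > 5,
                 rec$tpsa > 150, rec$ring_count > 7,
                 rec$carbon_count <= 4, rec$heteroatom_count <= 1,
                 rec$rotatable_bonds > 15, rec$hba > 10, rec$hbd > 5))
}

random_descriptor_record <- function(name) {
  list(name = name,
       mw = stats::runif(1, 100, 700),
       consensus_logp = stats::runif(1, -3, 7),
       hbd = sample(0:8, 1), hba = sample(0:14, 1),
       tpsa = stats::runif(1, 0, 200),
       rotatable_bonds = sample(0:20, 1),
       molar_refractivity = stats::runif(1, 20, 160),
       atom_count = sample(10:90, 1), ring_count = sample(0:9, 1),
       carbon_count = sample(0:40, 1), heteroatom_count = sample(0:12, 1))
}
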