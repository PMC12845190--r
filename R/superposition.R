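#' @name superposition
#' @title Rigid-body superposition, RMSD, and pruned-pair RMSD
#'
#' @description
#' Optimal least-squares superposition via the Kabsch algorithm (SVD of the
#' pair covariance, reflection corrected so the result is a proper rotation),
#' plain RMSD with no fitting, and Chimera-matchmaker-style iterative pruned
#' superposition: refit on retained pairs, drop pairs beyond a distance
#' cutoff, repeat until stable. Transforms act on row-vector coordinate
#' matrices as `x %*% R + t`.
NULL

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  storage.mode(x) <- "double"
  x
}

#' Optimal rigid-body fit (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (optionally weighted) sum of squared distances between
#' `mobile %*% R + t` and `reference`.
#'
#' @param mobile `n x 3` coordinates to move
#' @param reference `n x 3` target coordinates, paired by row
#' @param weights optional per-pair non-negative weights (default uniform)
#' @return a `RigidTransform`: list with `rotation` (3x3, det +1) and
#'   `translation` (length 3), Angstrom
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  m <- as_coord_matrix(mobile)
  r <- as_coord_matrix(reference)
  n <- nrow(m)
  if (nrow(r) != n) stop("pair count mismatch")
  if (n < 3) stop("kabsch_fit requires at least 3 pairs")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cm <- colSums(m * w)
  cr <- colSums(r * w)
  mc <- sweep(m, 2, cm)
  rc <- sweep(r, 2, cr)
  cov <- t(mc * w) %*% rc
  s <- svd(cov)
  # rank deficiency: all points collinear leaves the rotation underdetermined
  if (s$d[2] <= max(s$d[1], 1) * 1e-10) {
    stop("degenerate (collinear) point set: rotation underdetermined")
  }
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("singular covariance in kabsch_fit")
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cr - as.numeric(cm %*% R)
  structure(list(rotation = R, translation = tr), class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param coords `n x 3` matrix
#' @param transform a `RigidTransform`
#' @return transformed `n x 3` matrix
#' @export
apply_transform <- function(coords, transform) {
  stopifnot(inherits(transform, "RigidTransform"))
  sweep(as_coord_matrix(coords) %*% transform$rotation, 2,
        -transform$translation)
}

#' Root mean square deviation between paired coordinates
#'
#' No fitting is performed; see [kabsch_fit()] to superpose first.
#'
#' @param a,b `n x 3` coordinate matrices, paired by row
#' @return RMSD in the input unit (Angstrom throughout this package)
#' @export
rmsd <- function(a, b) {
  a <- as_coord_matrix(a)
  b <- as_coord_matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate count mismatch")
  if (nrow(a) < 1) stop("empty coordinate sets")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Iteratively pruned superposition
#'
#' Fits `mobile` onto `reference`, then repeatedly discards all retained
#' pairs whose post-fit distance exceeds `cutoff` and refits on the
#' survivors. Stops when no retained pair exceeds the cutoff, when the next
#' pruning step would leave fewer than `max(3, min_fraction * n)` pairs
#' (the last valid retained set is kept), or after `max_iter` iterations.
#' Both the pruned-pair RMSD and the all-pair RMSD are reported under the
#' final transform.
#'
#' @param mobile,reference `n x 3` paired coordinates
#' @param cutoff pruning distance cutoff, Angstrom
#' @param max_iter maximum refit iterations
#' @param min_fraction minimum retained fraction of all pairs
#' @return a `SuperpositionResult`: `transform`, `rmsd_all`, `rmsd_pruned`
#'   (Angstrom), `retained_pairs`, `n_all`, `n_retained`
#' @export
pruned_superpose <- function(mobile, reference, cutoff = 2.0, max_iter = 50L,
                             min_fraction = 0.3) {
  m <- as_coord_matrix(mobile)
  r <- as_coord_matrix(reference)
  n <- nrow(m)
  if (nrow(r) != n) stop("pair count mismatch")
  if (n < 3) stop("pruned_superpose requires at least 3 pairs")
  floor_n <- max(3L, ceiling(min_fraction * n))
  retained <- seq_len(n)
  tf <- NULL
  for (iter in seq_len(max_iter)) {
    tf <- kabsch_fit(m[retained, , drop = FALSE],
                     r[retained, , drop = FALSE])
    moved <- apply_transform(m, tf)
    dist <- sqrt(rowSums((moved - r)^2))
    keep <- retained[dist[retained] <= cutoff]
    if (length(keep) == length(retained)) break
    if (length(keep) < 3L) stop("pruning collapsed below 3 pairs")
    if (length(keep) < floor_n) break  # keep last valid retained set
    retained <- keep
  }
  moved <- apply_transform(m, tf)
  structure(list(
    transform = tf,
    rmsd_all = rmsd(moved, r),
    rmsd_pruned = rmsd(moved[retained, , drop = FALSE],
                       r[retained, , drop = FALSE]),
    retained_pairs = retained,
    n_all = n,
    n_retained = length(retained)), class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf(
    "SuperpositionResult: rmsd_all %.3f A (%d pairs), rmsd_pruned %.3f A (%d retained)\n",
    x$rmsd_all, x$n_all, x$rmsd_pruned, x$n_retained))
  invisible(x)
}

#' Report a superposition result as a one-row data frame
#' @param result a `SuperpositionResult`
#' @return data.frame with `rmsd_all`, `rmsd_pruned`, `n_retained`, `n_all`
#' @export
superposition_report <- function(result) {
  stopifnot(inherits(result, "SuperpositionResult"))
  data.frame(rmsd_all = result$rmsd_all, rmsd_pruned = result$rmsd_pruned,
             n_retained = result$n_retained, n_all = result$n_all)
}
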