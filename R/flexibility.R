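#' @name flexibility_analysis
#' @title Residue flexibility classes and differential-flexibility detection
#'
#' @description
#' Three-class flexibility taxonomy on per-residue RMSF values -- low
#' (< 0.1 nm), medium (0.1-0.3 nm), high (> 0.3 nm); both closed boundaries
#' fall to medium -- with count/percentage summaries, extrema reporting, and
#' a sliding-window detector that flags residue segments whose windowed
#' maximum RMSF differs between two systems by at least a threshold.
NULL

as_rmsf_profile <- function(x) {
  if (inherits(x, "RMSFProfile")) return(x)
  stopifnot(is.data.frame(x), all(c("resid", "rmsf") %in% names(x)))
  class(x) <- c("RMSFProfile", "data.frame")
  x
}

#' Construct an RMSF profile from residue ids and values
#' @param resid integer residue ids
#' @param rmsf non-negative per-residue RMSF values, nm
#' @param atom_basis basis atom label
#' @return an `RMSFProfile`
#' @export
rmsf_profile_from_values <- function(resid, rmsf, atom_basis = "calpha") {
  stopifnot(length(resid) == length(rmsf))
  out <- data.frame(resid = as.integer(resid), rmsf = as.numeric(rmsf))
  class(out) <- c("RMSFProfile", "data.frame")
  attr(out, "atom_basis") <- atom_basis
  out
}

#' Classify per-residue flexibility into low/medium/high
#'
#' @param profile an `RMSFProfile` (nm)
#' @param low_max low/medium boundary, nm (values `>= low_max` are not low)
#' @param high_min medium/high boundary, nm (values `<= high_min` are not
#'   high); thus both boundary values classify as medium
#' @return a `FlexibilityClassing`: list with per-residue `table`
#'   (resid, rmsf, label), `counts`, `percentages` (2 decimals, half-up) and
#'   `n_classified`
#' @export
classify_flexibility <- function(profile, low_max = 0.1, high_min = 0.3) {
  profile <- as_rmsf_profile(profile)
  if (nrow(profile) == 0) stop("empty RMSF profile")
  if (any(profile$rmsf < 0)) stop("invalid profile: negative RMSF")
  label <- ifelse(profile$rmsf < low_max, "low",
                  ifelse(profile$rmsf > high_min, "high", "medium"))
  counts <- c(low = sum(label == "low"), medium = sum(label == "medium"),
              high = sum(label == "high"))
  n <- nrow(profile)
  structure(list(
    table = data.frame(resid = profile$resid, rmsf = profile$rmsf,
                       label = label),
    counts = counts,
    percentages = round_half_up(100 * counts / n, 2),
    n_classified = n,
    thresholds = c(low_max = low_max, high_min = high_min)),
    class = "FlexibilityClassing")
}

#' Flexibility class summary rows
#' @param classing a `FlexibilityClassing`
#' @return data.frame with columns `class`, `count`, `percentage`
#' @export
flexibility_summary <- function(classing) {
  stopifnot(inherits(classing, "FlexibilityClassing"))
  data.frame(class = names(classing$counts),
             count = as.integer(classing$counts),
             percentage = as.numeric(classing$percentages))
}

#' Least- and most-fluctuating residues
#'
#' Ties are broken by the lowest residue id.
#'
#' @param profile an `RMSFProfile`
#' @return list with `min_residue`, `min_value`, `max_residue`, `max_value`
#' @export
extrema_residues <- function(profile) {
  profile <- as_rmsf_profile(profile)
  if (nrow(profile) == 0) stop("empty RMSF profile")
  ord <- order(profile$resid)
  p <- profile[ord, ]
  imin <- which.min(p$rmsf)  # first == lowest resid among ties
  imax <- which.max(p$rmsf)
  list(min_residue = p$resid[imin], min_value = p$rmsf[imin],
       max_residue = p$resid[imax], max_value = p$rmsf[imax])
}

#' Sliding-window differential-flexibility detection
#'
#' Over the residues shared by both profiles, each window of `window`
#' consecutive residues (stride 1) is scored
#' `d = max(rmsf_a) - max(rmsf_b)`; windows with `|d| >= min_abs_diff` are
#' flagged. Overlapping flagged windows of the same sign merge into one
#' segment. A window is indexed by its start residue, and a merged segment
#' spans from the first to the last flagged window start (this is the
#' convention under which a bump at residues 10-14 in a 20-residue profile
#' with window 5 yields the segment 6-14: every window touching the
#' elevated maximum flags).
#'
#' @param profile_a,profile_b `RMSFProfile`s (nm)
#' @param window window width in residues
#' @param min_abs_diff flag threshold on `|d|`, nm
#' @return data.frame of `FlexSegment` rows: `start_residue`,
#'   `end_residue`, `direction` (`"A-higher"`/`"B-higher"`),
#'   `peak_abs_diff` (nm); zero rows when nothing is flagged
#' @export
sliding_window_diff <- function(profile_a, profile_b, window = 5L,
                                min_abs_diff = 0.2) {
  profile_a <- as_rmsf_profile(profile_a)
  profile_b <- as_rmsf_profile(profile_b)
  if (window < 1) stop("window must be >= 1")
  shared <- sort(intersect(profile_a$resid, profile_b$resid))
  if (length(shared) == 0) stop("profiles share no residues")
  if (window > length(shared)) stop("window exceeds shared profile length")
  av <- profile_a$rmsf[match(shared, profile_a$resid)]
  bv <- profile_b$rmsf[match(shared, profile_b$resid)]
  n_win <- length(shared) - window + 1L
  d <- vapply(seq_len(n_win), function(s) {
    idx <- s:(s + window - 1L)
    max(av[idx]) - max(bv[idx])
  }, 0)
  flagged <- which(abs(d) >= min_abs_diff)
  empty <- data.frame(start_residue = integer(0), end_residue = integer(0),
                      direction = character(0), peak_abs_diff = numeric(0))
  if (length(flagged) == 0) return(empty)
  segs <- list()
  run <- flagged[1]
  run_sign <- sign(d[flagged[1]])
  close_run <- function(run, s) {
    data.frame(start_residue = shared[run[1]],
               end_residue = shared[run[length(run)]],
               direction = if (s > 0) "A-higher" else "B-higher",
               peak_abs_diff = max(abs(d[run])))
  }
  if (length(flagged) > 1) {
    for (k in flagged[-1]) {
      overlaps <- (k - run[length(run)]) <= (window - 1L)
      if (overlaps && sign(d[k]) == run_sign) {
        run <- c(run, k)
      } else {
        segs[[length(segs) + 1L]] <- close_run(run, run_sign)
        run <- k
        run_sign <- sign(d[k])
      }
    }
  }
  segs[[length(segs) + 1L]] <- close_run(run, run_sign)
  do.call(rbind, segs)
}
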