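test_that("classification thresholds and boundaries", {
  prof <- rmsf_profile_from_values(1:5, c(0.0497, 0.5143, 0.1, 0.3, 0.2))
  cl <- classify_flexibility(prof)
  expect_identical(cl$table$label, c("low", "high", "medium", "medium",
                                     "medium"))
  expect_equal(sum(cl$counts), cl$n_classified)
  expect_error(classify_flexibility(rmsf_profile_from_values(1, -0.1)),
               "negative")
})

test_that("summary percentages round half-up to two decimals", {
  mk <- function(counts) {
    vals <- c(rep(0.05, counts[1]), rep(0.2, counts[2]), rep(0.4, counts[3]))
    classify_flexibility(rmsf_profile_from_values(seq_along(vals), vals))
  }
  s <- flexibility_summary(mk(c(140, 219, 25)))
  expect_equal(s$percentage, c(36.46, 57.03, 6.51))
  expect_equal(flexibility_summary(mk(c(10, 0, 0)))$percentage,
               c(100, 0, 0))
  expect_equal(flexibility_summary(mk(c(1, 1, 1)))$percentage,
               c(33.33, 33.33, 33.33))
  expect_equal(sum(s$count), 384L)
})

test_that("extrema reporting with lowest-residue tie-breaking", {
  vals <- rep(0.2, 200)
  vals[167] <- 0.7678
  vals[120] <- 0.0488
  ex <- extrema_residues(rmsf_profile_from_values(1:200, vals))
  expect_equal(ex$max_residue, 167)
  expect_equal(ex$max_value, 0.7678)
  expect_equal(ex$min_residue, 120)

  const <- extrema_residues(rmsf_profile_from_values(5:10, rep(0.1, 6)))
  expect_equal(const$min_residue, 5)
  expect_equal(const$max_residue, 5)

  set.seed(41)
  rv <- runif(80, 0, 0.5)
  ex2 <- extrema_residues(rmsf_profile_from_values(1:80, rv))
  expect_equal(ex2$max_residue, which.max(rv))
  expect_equal(ex2$min_residue, which.min(rv))
})

test_that("sliding-window detector: hand-enumerated 20-residue case", {
  a <- rmsf_profile_from_values(1:20, rep(0.15, 20))
  bv <- rep(0.15, 20)
  bv[10:14] <- 0.40  # exceeds a by 0.25 only at residues 10-14
  b <- rmsf_profile_from_values(1:20, bv)
  seg <- sliding_window_diff(a, b, window = 5, min_abs_diff = 0.2)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_residue, 6L)   # every window touching the bump flags
  expect_equal(seg$end_residue, 14L)
  expect_identical(seg$direction, "B-higher")
  expect_equal(seg$peak_abs_diff, 0.25)

  expect_equal(nrow(sliding_window_diff(a, a)), 0L)
  expect_error(sliding_window_diff(a, b, window = 0), "window")
  expect_error(sliding_window_diff(
    a, rmsf_profile_from_values(100:119, bv)), "share")
})

test_that("detector is antisymmetric and matches the brute-force oracle", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(10:50, 1)
    av <- runif(n, 0, 0.4)
    bv <- av + rnorm(n, 0, 0.15)
    bv <- pmax(bv, 0)
    a <- rmsf_profile_from_values(1:n, av)
    b <- rmsf_profile_from_values(1:n, bv)
    w <- sample(2:6, 1)
    got <- sliding_window_diff(a, b, window = w, min_abs_diff = 0.2)
    want <- oracle_window_segments(av, bv, 1:n, w, 0.2)
    expect_equal(got, want, ignore_attr = TRUE)
    flipped <- sliding_window_diff(b, a, window = w, min_abs_diff = 0.2)
    expect_equal(flipped$start_residue, got$start_residue)
    expect_equal(flipped$end_residue, got$end_residue)
    expect_identical(flipped$direction,
                     as.character(ifelse(got$direction == "A-higher",
                                         "B-higher", "A-higher")))
  }
})

test_that("planted bump in a generated profile pair is recovered", {
  pair <- make_rmsf_pair(200, bump_range = 159:168, bump_delta = 0.35,
                         seed = 43)
  seg <- sliding_window_diff(pair$a, pair$b)
  expect_equal(nrow(seg), 1L)
  expect_lte(seg$start_residue, 159)
  expect_gte(seg$end_residue, 168)
  expect_identical(seg$direction, "B-higher")

  # below-threshold bump: nothing flagged
  weak <- make_rmsf_pair(200, bump_range = 159:168, bump_delta = 0.1,
                         seed = 44)
  expect_equal(nrow(sliding_window_diff(weak$a, weak$b)), 0L)
  zero <- make_rmsf_pair(200, bump_range = 159:168, bump_delta = 0,
                         seed = 45)
  expect_equal(nrow(sliding_window_diff(zero$a, zero$b)), 0L)
})
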