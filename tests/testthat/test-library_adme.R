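test_that("library enumeration: 180 unique round-tripping names", {
  lib <- enumerate_library()
  expect_equal(nrow(lib), 180L)
  expect_equal(anyDuplicated(lib$name), 0L)
  expect_identical(lib$name[lib$r1 == 7 & lib$r2 == 9], "9.7")
  expect_identical(enumerate_library(1, 1)$name, "1.1")
  # r2-major ordering: all of head group 1 before head group 2
  expect_identical(lib$name[1:12], paste0("1.", 1:12))
  for (i in sample(180, 20)) {
    p <- parse_compound_id(lib$name[i])
    expect_equal(p$r1, lib$r1[i])
    expect_equal(p$r2, lib$r2[i])
  }
  expect_error(parse_compound_id("abc"), "malformed")
})

test_that("consensus logP: verbatim value or mean of estimates", {
  expect_equal(consensus_logp(list(consensus_logp = 2.51)), 2.51)
  expect_equal(consensus_logp(list(logp_estimates = c(2.0, 3.0))), 2.5)
  set.seed(81)
  est <- runif(5, 0, 5)
  expect_equal(consensus_logp(list(logp_estimates = est)), mean(est))
  expect_error(consensus_logp(list()), "estimate")
})

test_that("rule engine: worked examples", {
  # every Lipinski condition broken
  bad <- list(mw = 600, consensus_logp = 6, hbd = 6, hba = 11, tpsa = 80,
              rotatable_bonds = 4, molar_refractivity = 90, atom_count = 40,
              ring_count = 3, carbon_count = 20, heteroatom_count = 6)
  expect_equal(unname(evaluate_rules(bad)$violations["lipinski"]), 4L)

  clean <- list(mw = 350, consensus_logp = 2.5, hbd = 2, hba = 5, tpsa = 80,
                rotatable_bonds = 4, molar_refractivity = 90,
                atom_count = 40, ring_count = 3, carbon_count = 20,
                heteroatom_count = 6)
  r <- evaluate_rules(clean)
  expect_true(all(r$violations == 0))
  expect_true(r$cns_pass)
  expect_true(r$overall_pass)

  # logP 3.83 is outside the 2.0-3.5 CNS window even with zero violations
  high_lp <- clean
  high_lp$consensus_logp <- 3.83
  r2 <- evaluate_rules(high_lp)
  expect_false(r2$cns_pass)
  expect_false(r2$overall_pass)

  # missing TPSA: veber and egan not evaluable, never silently zero
  noTPSA <- clean
  noTPSA$tpsa <- NA
  r3 <- evaluate_rules(noTPSA)
  expect_setequal(r3$not_evaluable, c("veber", "egan", "muegge"))
  expect_true(is.na(r3$violations["veber"]))
})

test_that("rule engine agrees with the per-inequality oracle", {
  set.seed(82)
  for (k in 1:1000) {
    rec <- random_descriptor_record(sprintf("1.%d", k))
    got <- evaluate_rules(rec)$violations
    expect_identical(unname(got), unname(oracle_rule_violations(rec)))
  }
})

test_that("library filtering: planted failures, ordering, idempotence", {
  set.seed(83)
  base <- list(mw = 350, consensus_logp = 2.5, hbd = 2, hba = 5, tpsa = 80,
               rotatable_bonds = 4, molar_refractivity = 90, atom_count = 40,
               ring_count = 3, carbon_count = 20, heteroatom_count = 6)
  recs <- do.call(rbind, lapply(1:10, function(i) {
    r <- base
    r$name <- paste0("1.", i)
    as.data.frame(r)
  }))
  recs$mw[3] <- 700          # fails lipinski/ghose/muegge
  recs$consensus_logp[6] <- 5.0   # outside CNS window
  recs$tpsa[9] <- 160        # fails veber/muegge
  out <- filter_library(recs)
  expect_equal(nrow(out$pass), 7L)
  expect_identical(out$pass$name, paste0("1.", c(1, 2, 4, 5, 7, 8, 10)))
  # idempotence
  again <- filter_library(out$pass)
  expect_identical(again$pass$name, out$pass$name)
  # empty input, duplicate ids
  expect_equal(nrow(filter_library(recs[0, ])$pass), 0L)
  dup <- rbind(recs, recs[1, ])
  expect_error(filter_library(dup), "duplicate")
})

test_that("flag filters: P-gp and CYP screens", {
  base <- data.frame(name = c("1.1", "1.2", "1.3"), mw = 350,
                     consensus_logp = 2.5, hbd = 2, hba = 5, tpsa = 80,
                     rotatable_bonds = 4, molar_refractivity = 90,
                     atom_count = 40, ring_count = 3, carbon_count = 20,
                     heteroatom_count = 6,
                     pgp_substrate = c("Yes", "No", "No"),
                     cyp1a2 = c("No", "Yes", "Yes"),
                     cyp2c9 = c("No", "Yes", "No"),
                     cyp2c19 = "No", cyp2d6 = "No", cyp3a4 = "No")
  all_pass <- filter_library(base)
  expect_equal(nrow(all_pass$pass), 3L)
  no_pgp <- filter_library(base, exclude_pgp_substrate = TRUE)
  expect_identical(no_pgp$pass$name, c("1.2", "1.3"))
  strict <- filter_library(base, exclude_pgp_substrate = TRUE,
                           max_cyp_inhibition = 1)
  expect_identical(strict$pass$name, "1.3")
})

test_that("descriptor tables read back with names intact", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("name", "mw", "consensus_logp", "hbd", "hba", "tpsa",
                     "rotatable_bonds", "molar_refractivity", "atom_count",
                     "ring_count", "carbon_count", "heteroatom_count",
                     sep = "\t"),
               paste("9.7", 420, 2.51, 2, 6, 95, 5, 110, 45, 4, 22, 8,
                     sep = "\t")), f)
  df <- read_descriptor_table(f)
  expect_identical(df$name, "9.7")
  expect_true(evaluate_rules(as.list(df[1, ]))$overall_pass)
})
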