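cat9 <- example_catalog()

test_that("classification follows the principal/secondary/none rules", {
  recs <- make_records(list(c("466.0", "401.9"),          # catalog code first
                            c("401.9", "250.00", "510.0"), # catalog code later
                            c("401.9", "272.4"),           # no catalog codes
                            c("466.2", "510.9")),          # catalog first AND later
                       los = c(5, 5, 5, 5))
  cls <- classify_infection(recs, cat9, "lrti")
  expect_equal(cls, c("principal", "secondary", "none", "principal"))
})

test_that("ICD-10 secondary classification requires a stay of three or more days", {
  recs <- make_records(list(c("I10", "E11.9", "K21.9", "E78.5", "I50.9",
                              "D64.9", "J20.5"),
                            c("I10", "E11.9", "K21.9", "E78.5", "I50.9",
                              "D64.9", "J20.5")),
                       los = c(5, 2), dialect = "ICD10")
  cls <- classify_infection(recs, cat9, "lrti")
  expect_equal(cls, c("secondary", "none"))
})

test_that("classification partitions every record exactly once per type", {
  d <- generate_discharges(lrti_generator_config("ICD9", n_records = 10000,
                                                 seed = 14))
  cls <- classify_infection(d, cat9, "lrti")
  expect_true(all(cls %in% c("principal", "secondary", "none")))
  expect_equal(length(cls), nrow(d))
  # classify() agrees with generator truth except for short-stay secondaries
  truth <- d$sim_group
  expect_true(all(cls[truth == "principal"] == "principal"))
  sec <- truth == "secondary"
  expect_true(all(cls[sec & d$los >= 3] == "secondary"))
  expect_true(all(cls[sec & d$los < 3] == "none"))
  expect_true(all(cls[truth == "uninfected"] == "none"))
})

test_that("malformed and mismatched inputs are refused", {
  recs <- make_records(list(character(0)))
  expect_error(classify_infection(recs, cat9, "lrti"), "empty diagnosis")
  recs2 <- make_records(list(c("466.0")), los = 5)
  recs2$dialect <- "ICD8"
  expect_error(classify_infection(recs2, cat9, "lrti"), "dialect")
  mixed <- make_records(list("466.0", "401.9"))
  mixed$dialect[2] <- "ICD10"
  expect_error(classify_infection(mixed, cat9, "lrti"), "mix")
})

test_that("device flags are the exact conjunction of diagnosis and procedure", {
  # exhaustive over UTI code x pneumonia code x catheter x ventilator
  combos <- expand.grid(uti = c(FALSE, TRUE), pneu = c(FALSE, TRUE),
                        cath = c(FALSE, TRUE), vent = c(FALSE, TRUE))
  dx <- lapply(seq_len(nrow(combos)), function(i) {
    c("401.9", if (combos$uti[i]) "599.0", if (combos$pneu[i]) "486")
  })
  pr <- lapply(seq_len(nrow(combos)), function(i) {
    c(if (combos$cath[i]) "UC01", if (combos$vent[i]) "MV01")
  })
  flags <- device_flags(make_records(dx, pr), cat9)
  expect_equal(flags$cauti, combos$uti & combos$cath)
  expect_equal(flags$vap, combos$pneu & combos$vent)
})

test_that("matched controls hit the exact stratum counts", {
  secondary <- make_records(list(c("401.9", "x", "466.0"),
                                 c("401.9", "x", "510.0")),
                            los = 5)
  secondary$DX2 <- "250.00"
  pool <- make_records(rep(list(c("401.9", "272.4")), 12))
  pool$record_id <- sprintf("P%03d", 1:12)
  pool$DX1[11:12] <- "250.00"  # different principal code: not in the stratum
  res <- build_matched_controls(secondary, pool, cat9, ratio = 5, seed = 3)
  expect_equal(nrow(res$controls), 10L)
  expect_true(all(res$controls$DX1 == "401.9"))
  expect_equal(res$report$achieved_ratio, 5)
})

test_that("stratum shortfalls are reported, not back-filled", {
  secondary <- make_records(list(c("401.9", "x", "466.0")), los = 5)
  secondary$DX2 <- "250.00"
  pool <- make_records(rep(list(c("401.9", "272.4")), 3))
  pool$record_id <- sprintf("P%03d", 1:3)
  expect_warning(res <- build_matched_controls(secondary, pool, cat9,
                                               ratio = 5, seed = 3),
                 "shortfall")
  expect_equal(nrow(res$controls), 3L)
  expect_equal(res$report$achieved_ratio, 3)
})

test_that("degenerate matching inputs behave as specified", {
  secondary0 <- make_records(list(c("401.9", "466.0")), los = 5)[0, ]
  pool <- make_records(list(c("401.9", "272.4")))
  expect_equal(nrow(build_matched_controls(secondary0, pool, cat9)$controls), 0L)
  secondary <- make_records(list(c("401.9", "x", "466.0")), los = 5)
  secondary$DX2 <- "250.00"
  expect_warning(res <- build_matched_controls(secondary, pool[0, ], cat9),
                 "empty")
  expect_equal(nrow(res$controls), 0L)
  expect_equal(res$report$n_matched, 0L)
})

test_that("seeded matching is reproducible and the screen is sound at scale", {
  d <- generate_discharges(lrti_generator_config("ICD9", n_records = 10000,
                                                 seed = 19))
  tri1 <- suppressWarnings(build_cohorts(d, cat9, "lrti", ratio = 5, seed = 7))
  tri2 <- suppressWarnings(build_cohorts(d, cat9, "lrti", ratio = 5, seed = 7))
  expect_identical(tri1$controls$record_id, tri2$controls$record_id)
  # filter soundness
  expect_true(all(tri1$secondary$los >= 3))
  expect_false(any(tri1$secondary$record_id %in% tri1$principal$record_id))
  all_codes <- all_catalog_codes(cat9, "ICD9")
  ctrl_dx <- as.matrix(tri1$controls[, grep("^DX", names(tri1$controls))])
  expect_false(any(ctrl_dx %in% all_codes))
  expect_lte(nrow(tri1$controls), 5 * nrow(tri1$secondary))
  # control principal codes mirror the secondary-group distribution
  expect_true(all(tri1$controls$DX1 %in% tri1$secondary$DX1))
})
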