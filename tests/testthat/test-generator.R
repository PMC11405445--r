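small_cfg <- function(n = 500, seed = 1, dialect = "ICD9", ...) {
  args <- list(
    dialect = dialect, n_records = n, seed = seed,
    infection_mix = list(lrti = c(principal = 0.3, secondary = 0.3)),
    true_coefficients = c(intercept = -4000, los = 1300, n_diagnoses = 90,
                          n_procedures = 1900, urban_teaching = 270,
                          small_bedsize = -550, age = 2.3,
                          severity_index = 150, mortality_risk_index = 100,
                          wage_index = 4000),
    principal = list(los_mean = 3.8, ndx_mean = 6.3, npr_mean = 0.6,
                     age_mean = 27, age_max = 108,
                     severity_probs = c(.4, .37, .17, .06),
                     risk_probs = c(.7, .22, .06, .02)),
    uninfected = list(los_mean = 5.6, ndx_mean = 11, npr_mean = 1.4,
                      age_mean = 59, age_max = 108,
                      severity_probs = c(.18, .32, .33, .17),
                      risk_probs = c(.32, .34, .24, .10)),
    secondary_shift = list(los = 6.5, n_diagnoses = 6.8, n_procedures = 1.7,
                           age = 27,
                           severity_probs = c(.08, .25, .40, .27),
                           risk_probs = c(.25, .30, .31, .14)))
  do.call(generator_config, modifyList(args, list(...)))
}

test_that("invalid generator configurations are rejected", {
  expect_error(small_cfg(infection_mix = list(lrti = c(principal = 0.7, secondary = 0.5))),
               "sum to")
  expect_error(small_cfg(infection_mix = list(lrti = c(principal = -0.1, secondary = 0.2))),
               "nonnegative")
  expect_error(generator_config(
    dialect = "ICD9", n_records = 10,
    infection_mix = list(lrti = c(principal = .1, secondary = .1)),
    true_coefficients = c(intercept = 0),
    principal = list(), uninfected = list(), secondary_shift = list()),
    "true_coefficients")
  expect_error(small_cfg(ccr_range = c(0, 0.8)), "ccr_range")
  cfg_bad_shift <- function() small_cfg(n = 10)$secondary_shift
  expect_error({
    cfg <- small_cfg(n = 10)
    generator_config(dialect = "ICD9", n_records = 10,
                     infection_mix = cfg$infection_mix,
                     true_coefficients = cfg$true_coefficients,
                     principal = cfg$groups$principal,
                     uninfected = cfg$groups$uninfected,
                     secondary_shift = modifyList(cfg$secondary_shift,
                                                  list(los = -1)))
  }, "strictly positive")
})

test_that("an all-zero infection mix yields no catalog codes anywhere", {
  cfg <- small_cfg(n = 300,
                   infection_mix = list(lrti = c(principal = 0, secondary = 0)))
  d <- generate_discharges(cfg, lrti_catalog())
  codes <- all_catalog_codes(lrti_catalog(), "ICD9")
  dx <- as.matrix(d[, grep("^DX", names(d))])
  expect_false(any(dx %in% codes))
  expect_true(all(d$sim_group == "uninfected"))
})

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cfg <- small_cfg(n = 400, seed = 42)
  d1 <- generate_discharges(cfg)
  set.seed(123); probe1 <- rnorm(1)
  set.seed(123); d2 <- generate_discharges(cfg); probe2 <- rnorm(1)
  expect_identical(d1, d2)
  expect_identical(probe1, probe2)  # generator restored the RNG state
})

test_that("zero records give an empty, well-formed dataset", {
  d <- generate_discharges(small_cfg(n = 0))
  expect_equal(nrow(d), 0L)
  expect_true(all(c("DX1", "los", "total_charges", "ccr", "cost") %in% names(d)))
})

test_that("charges times CCR reproduces cost exactly for every record", {
  d <- generate_discharges(small_cfg(n = 2000, seed = 5))
  expect_identical(d$total_charges * d$ccr, d$cost)
})

test_that("record structure is internally consistent", {
  d <- generate_discharges(small_cfg(n = 2000, seed = 8))
  dxc <- paste0("DX", 1:25)
  n_nonempty <- rowSums(as.matrix(d[, dxc]) != "")
  expect_equal(unname(n_nonempty), d$n_diagnoses)
  prc <- paste0("PR", 1:10)
  expect_equal(unname(rowSums(as.matrix(d[, prc]) != "")), d$n_procedures)
  expect_true(all(d$n_diagnoses <= 25))
  expect_true(all(d$los >= 1 & d$los <= 365))
  expect_true(all(d$severity_index %in% 1:4))
  expect_true(all(d$mortality_risk_index %in% 1:4))
  # principal-infection records carry a catalog code first;
  # secondary-infection records carry one in a later field only
  codes <- all_catalog_codes(lrti_catalog(), "ICD9")
  prin <- d$sim_group == "principal"
  expect_true(all(d$DX1[prin] %in% codes))
  sec <- d$sim_group == "secondary"
  expect_false(any(d$DX1[sec] %in% codes))
  later <- as.matrix(d[, dxc[-1]])
  expect_true(all(rowSums(matrix(later %in% codes, nrow(d))) [sec] >= 1))
})

test_that("the cost disturbance has median one and a right-skewed tail", {
  cfg <- lrti_generator_config("ICD9", n_records = 12000, seed = 21)
  d <- generate_discharges(cfg)
  idx <- linear_index(d, cfg$true_coefficients)
  ratio <- d$cost / idx
  expect_lt(abs(median(ratio) - 1), 0.02)
  expect_gt(mean(ratio), median(ratio))  # right skew
  expect_gt(max(ratio), 5)               # heavy upper tail
})

test_that("secondary records dominate principal and uninfected in mean cost and LOS", {
  cfg <- lrti_generator_config("ICD9", n_records = 12000, seed = 33)
  d <- generate_discharges(cfg)
  m <- function(g, v) mean(d[[v]][d$sim_group == g])
  for (v in c("cost", "los")) {
    expect_gt(m("secondary", v), m("principal", v))
    expect_gt(m("secondary", v), m("uninfected", v))
  }
})

test_that("reference configs hit the published principal-group mean LOS", {
  for (dialect in c("ICD9", "ICD10")) {
    cfg <- lrti_generator_config(dialect, n_records = 8000, seed = 2)
    d <- generate_discharges(cfg)
    target <- lrti_group_stats(if (dialect == "ICD9") 2011 else 2016)
    target <- target$los_mean[target$group == "principal"]
    got <- mean(d$los[d$sim_group == "principal"])
    expect_lt(abs(got - target) / target, 0.10)
  }
})

test_that("discharge CSV and config YAML round-trip", {
  cfg <- small_cfg(n = 50, seed = 4)
  d <- generate_discharges(cfg)
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  on.exit(unlink(c(csv, yml)))
  write_discharges(d, csv)
  d2 <- read_discharges(csv)
  expect_equal(d2$cost, d$cost)
  expect_identical(d2$DX1, d$DX1)
  expect_identical(d2$record_id, d$record_id)
  write_generator_config(cfg, yml)
  cfg2 <- read_generator_config(yml)
  expect_identical(generate_discharges(cfg2), d)
})

test_that("files with too many diagnosis columns for the dialect are refused", {
  d <- generate_discharges(small_cfg(n = 5))
  d$DX26 <- ""  # beyond the 25-field layout
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  write_discharges(d, csv)
  expect_error(read_discharges(csv), "diagnosis columns")
})
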