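#' Configuration for the synthetic discharge-record generator
#'
#' Defines the statistical structure of a synthetic hospital discharge
#' dataset emulating an all-payer inpatient sample: per-record diagnosis and
#' procedure code lists, length of stay (LOS), charges and a facility
#' cost-to-charge ratio (CCR), and the patient/facility covariates used by
#' the stage-1 cost model. Ground-truth cost coefficients are part of the
#' configuration so that downstream median-regression fits can be validated
#' by parameter recovery.
#'
#' @param dialect coding dialect, `"ICD9"` (25 diagnosis fields) or
#'   `"ICD10"` (30 diagnosis fields).
#' @param n_records number of discharges to generate (0 gives an empty
#'   dataset).
#' @param infection_mix named list, one element per infection type, each a
#'   numeric vector with entries `principal` and `secondary`: the
#'   probability that a record carries that type's code first (principal) or
#'   in a later field (secondary). Remaining mass is uninfected. All entries
#'   must be nonnegative and sum to at most 1.
#' @param true_coefficients named numeric vector (`intercept` plus the nine
#'   model covariates, see [stage1_covariates()]): the generating linear
#'   median-cost index, in dollars per covariate unit.
#' @param principal,uninfected covariate distribution parameters for the two
#'   base patient groups: lists with `los_mean`, `ndx_mean`, `npr_mean`,
#'   `age_mean`, `age_max`, `severity_probs` (length 4, sums to 1) and
#'   `risk_probs` (length 4).
#' @param secondary_shift how secondary-infection records differ from
#'   principal ones: additive shifts `los`, `n_diagnoses`, `n_procedures`
#'   (all strictly positive, so expected LOS and code counts strictly
#'   increase), additive `age` shift, and replacement `severity_probs` /
#'   `risk_probs`.
#' @param facility list with `urban_share`, `small_share` (Bernoulli rates
#'   for urban-teaching and small-bedsize flags) and `wage_mean`, `wage_sd`
#'   (area wage index, truncated normal).
#' @param noise multiplicative disturbance on cost: a contaminated
#'   log-symmetric model with median exactly 1 — `exp(sd_log * Z)` for most
#'   records plus, with probability `outlier_prob`, a heavy-tailed component
#'   `exp(outlier_sd_log * Z)` producing the extreme right-tail outliers
#'   typical of charge data (and the reason the stage-1 fit is a median
#'   regression). Because each component is symmetric on the log scale the
#'   conditional median of cost equals the linear index, making the
#'   generating coefficients recoverable.
#' @param ccr_range per-record cost-to-charge ratio bounds (uniform draw),
#'   `0 < low <= high < 1`.
#' @param cost_floor lower clamp on generated cost, in dollars.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(dialect = c("ICD9", "ICD10"),
                             n_records,
                             infection_mix,
                             true_coefficients,
                             principal,
                             uninfected,
                             secondary_shift,
                             facility = list(urban_share = 0.5, small_share = 0.3,
                                             wage_mean = 0.99, wage_sd = 0.156),
                             noise = list(sd_log = 0.005, outlier_prob = 0.1,
                                          outlier_sd_log = 1.5),
                             ccr_range = c(0.2, 0.8),
                             cost_floor = 31,
                             seed = 1L) {
  dialect <- match.arg(dialect)
  if (!is.numeric(n_records) || n_records < 0)
    stop("`n_records` must be a nonnegative count", call. = FALSE)

  if (!is.list(infection_mix) || (length(infection_mix) && is.null(names(infection_mix))))
    stop("`infection_mix` must be a named list", call. = FALSE)
  total_mass <- 0
  for (type in names(infection_mix)) {
    m <- infection_mix[[type]]
    if (!all(c("principal", "secondary") %in% names(m)))
      stop("infection_mix[['", type, "']] needs `principal` and `secondary` entries",
           call. = FALSE)
    if (any(m < 0) || sum(m) > 1)
      stop("infection_mix[['", type,
           "']] probabilities must be nonnegative and sum to <= 1", call. = FALSE)
    total_mass <- total_mass + sum(m)
  }
  if (total_mass > 1)
    stop("infection_mix probabilities across types exceed 1", call. = FALSE)

  need <- c("intercept", stage1_covariates())
  if (!all(need %in% names(true_coefficients)))
    stop("`true_coefficients` must be named: ",
         paste(setdiff(need, names(true_coefficients)), collapse = ", "),
         call. = FALSE)

  check_group <- function(g, label) {
    need_g <- c("los_mean", "ndx_mean", "npr_mean", "age_mean", "age_max",
                "severity_probs", "risk_probs")
    if (!all(need_g %in% names(g)))
      stop("`", label, "` missing: ",
           paste(setdiff(need_g, names(g)), collapse = ", "), call. = FALSE)
    for (pr in c("severity_probs", "risk_probs"))
      if (length(g[[pr]]) != 4L || any(g[[pr]] < 0) ||
          abs(sum(g[[pr]]) - 1) > 1e-8)
        stop("`", label, "$", pr, "` must be 4 nonnegative probabilities summing to 1",
             call. = FALSE)
    g
  }
  principal <- check_group(principal, "principal")
  uninfected <- check_group(uninfected, "uninfected")

  for (fld in c("los", "n_diagnoses", "n_procedures"))
    if (is.null(secondary_shift[[fld]]) || secondary_shift[[fld]] <= 0)
      stop("`secondary_shift$", fld, "` must be strictly positive", call. = FALSE)
  secondary <- check_group(list(
    los_mean = principal$los_mean + secondary_shift$los,
    ndx_mean = principal$ndx_mean + secondary_shift$n_diagnoses,
    npr_mean = principal$npr_mean + secondary_shift$n_procedures,
    age_mean = principal$age_mean + (secondary_shift$age %||% 0),
    age_max = principal$age_max,
    severity_probs = secondary_shift$severity_probs %||% principal$severity_probs,
    risk_probs = secondary_shift$risk_probs %||% principal$risk_probs),
    "secondary_shift (derived secondary group)")

  if (length(ccr_range) != 2L || ccr_range[1] <= 0 ||
      ccr_range[1] > ccr_range[2] || ccr_range[2] >= 1)
    stop("`ccr_range` must satisfy 0 < low <= high < 1", call. = FALSE)
  if (noise$sd_log <= 0 || noise$outlier_sd_log <= 0 ||
      noise$outlier_prob < 0 || noise$outlier_prob > 1)
    stop("invalid `noise` parameters", call. = FALSE)

  structure(list(dialect = dialect, n_records = as.integer(n_records),
                 infection_mix = infection_mix,
                 true_coefficients = true_coefficients[need],
                 groups = list(principal = principal, secondary = secondary,
                               uninfected = uninfected),
                 secondary_shift = secondary_shift,
                 facility = facility, noise = noise,
                 ccr_range = ccr_range, cost_floor = cost_floor,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$n_records, "records,", x$dialect,
      "dialect, seed", x$seed, "\n")
  invisible(x)
}

# number of diagnosis fields per dialect (1 principal + the secondary fields)
dx_capacity <- function(dialect) if (dialect == "ICD9") 25L else 30L
pr_capacity <- function() 10L

# filler pools: plausible chronic-condition codes, disjoint from every
# bundled catalog code (including the toy sets and device placeholders)
filler_dx <- function(dialect) {
  if (dialect == "ICD9")
    c("401.9", "250.00", "272.4", "414.01", "427.31", "428.0", "530.81",
      "285.9", "305.1", "311", "327.23", "496", "584.9", "585.9", "V58.61",
      "276.1", "276.51", "244.9", "278.00", "715.90", "412", "443.9",
      "280.9", "338.29", "493.90", "300.00", "780.79", "786.05", "285.21",
      "403.90", "425.4", "331.0", "357.2", "714.0", "733.00")
  else
    c("I10", "E11.9", "E78.5", "I25.10", "I48.91", "I50.9", "K21.9",
      "D64.9", "F17.210", "F32.9", "G47.33", "J44.9", "N18.3", "Z79.4",
      "E87.1", "E03.9", "E66.9", "M17.9", "I25.2", "I73.9", "D50.9",
      "G89.29", "J45.909", "F41.9", "R53.83", "Z95.1", "M54.5", "H25.9",
      "G30.9", "E11.40", "M06.9", "M81.0", "I12.9", "I42.9", "Z87.891")
}
filler_pr <- function(dialect) {
  if (dialect == "ICD9")
    c("99.04", "38.93", "96.6", "99.15", "88.72", "99.21", "45.13",
      "99.18", "93.90", "38.91")
  else
    c("30233N1", "02HV33Z", "0DJ08ZZ", "B244ZZZ", "3E0G76Z", "4A023N7",
      "0W9G3ZZ", "0JH63XZ", "0BJ08ZZ", "10E0XZZ")
}

#' Generate a synthetic discharge-record dataset
#'
#' Draws `config$n_records` hospitalizations. Each record carries an ordered
#' diagnosis-code list (first entry = principal diagnosis): principal-
#' infection records have a catalog code first; secondary-infection records
#' have a catalog code in a non-first field and a filler principal code;
#' uninfected records contain no catalog code. Cost is the configured linear
#' index times a median-one multiplicative disturbance, clamped below at
#' `cost_floor`; charges are defined so that `total_charges * ccr`
#' reproduces `cost` exactly.
#'
#' @param config a [generator_config()].
#' @param catalog a [code_catalog()] containing every type in
#'   `config$infection_mix` for the configured dialect.
#' @return A data.frame, one row per hospitalization, with diagnosis columns
#'   `DX1..DX25` (ICD-9) or `DX1..DX30` (ICD-10), procedure columns
#'   `PR1..PR10`, `los`, `total_charges`, `ccr`, `cost`, the nine model
#'   covariates, and simulation ground-truth columns `sim_group`
#'   (`principal`/`secondary`/`uninfected`) and `sim_infection`.
#' @export
generate_discharges <- function(config, catalog = lrti_catalog()) {
  stopifnot(inherits(config, "generator_config"))
  dialect <- config$dialect
  cap <- dx_capacity(dialect)
  pcap <- pr_capacity()
  types <- names(config$infection_mix)
  type_codes <- lapply(setNames(types, types), function(t)
    catalog_codes(catalog, t, dialect))

  n <- config$n_records
  with_seed(config$seed, {
    # record-level infection status
    labels <- c(unlist(lapply(types, function(t) paste0(t, "|", c("principal", "secondary")))),
                "|uninfected")
    probs <- c(unlist(lapply(types, function(t)
      config$infection_mix[[t]][c("principal", "secondary")])), 0)
    probs[length(probs)] <- 1 - sum(probs)
    lab <- if (n > 0) sample(labels, n, replace = TRUE, prob = probs) else character(0)
    sim_infection <- sub("\\|.*$", "", lab)
    sim_group <- sub("^.*\\|", "", lab)

    los <- integer(n); ndx <- integer(n); npr <- integer(n); age <- integer(n)
    severity <- integer(n); risk <- integer(n)
    for (g in c("principal", "secondary", "uninfected")) {
      idx <- which(sim_group == g)
      if (!length(idx)) next
      par <- config$groups[[g]]
      k <- length(idx)
      los_base <- if (g == "secondary") 3 else 1   # secondary cohort is LOS >= 3
      los[idx] <- pmin(los_base + rnbinom(k, size = 1.5,
                                          mu = max(par$los_mean - los_base, 0.01)), 365L)
      ndx_base <- if (g == "secondary") 2 else 1   # secondary needs a non-first field
      ndx[idx] <- pmin(ndx_base + rnbinom(k, size = 2,
                                          mu = max(par$ndx_mean - ndx_base, 0.01)), cap)
      npr[idx] <- pmin(rnbinom(k, size = 1, mu = par$npr_mean), pcap)
      age[idx] <- pmin(round(rgamma(k, shape = 2, scale = par$age_mean / 2)),
                       par$age_max)
      severity[idx] <- sample.int(4L, k, replace = TRUE, prob = par$severity_probs)
      risk[idx] <- sample.int(4L, k, replace = TRUE, prob = par$risk_probs)
    }

    urban <- rbinom(n, 1L, config$facility$urban_share)
    small <- rbinom(n, 1L, config$facility$small_share)
    wage <- pmax(0.2, rnorm(n, config$facility$wage_mean, config$facility$wage_sd))

    # ordered code lists
    dxm <- matrix("", nrow = n, ncol = cap)
    prm <- matrix("", nrow = n, ncol = pcap)
    pool_dx <- filler_dx(dialect)
    pool_pr <- filler_pr(dialect)
    for (i in seq_len(n)) {
      k <- ndx[i]
      codes <- sample(pool_dx, k, replace = FALSE)
      if (sim_group[i] == "principal") {
        codes[1] <- sample(type_codes[[sim_infection[i]]], 1L)
      } else if (sim_group[i] == "secondary") {
        pos <- if (k > 2L) sample(2:k, 1L) else 2L
        codes[pos] <- sample(type_codes[[sim_infection[i]]], 1L)
      }
      dxm[i, seq_len(k)] <- codes
      if (npr[i] > 0) prm[i, seq_len(npr[i])] <- sample(pool_pr, npr[i])
    }

    # cost: linear median index times a median-one contaminated disturbance
    beta <- config$true_coefficients
    index <- beta[["intercept"]] + beta[["los"]] * los +
      beta[["n_diagnoses"]] * ndx + beta[["n_procedures"]] * npr +
      beta[["urban_teaching"]] * urban + beta[["small_bedsize"]] * small +
      beta[["age"]] * age + beta[["severity_index"]] * severity +
      beta[["mortality_risk_index"]] * risk + beta[["wage_index"]] * wage
    sdv <- ifelse(rbinom(n, 1L, config$noise$outlier_prob) == 1L,
                  config$noise$outlier_sd_log, config$noise$sd_log)
    eta <- exp(sdv * rnorm(n))
    cost <- pmax(index * eta, config$cost_floor)
    ccr <- runif(n, config$ccr_range[1], config$ccr_range[2])
    charges <- cost / ccr
    cost <- charges * ccr   # exact round-trip under IEEE arithmetic

    out <- data.frame(record_id = if (n > 0) sprintf("R%07d", seq_len(n)) else character(0),
                      dialect = rep(dialect, n), stringsAsFactors = FALSE)
    colnames(dxm) <- paste0("DX", seq_len(cap))
    colnames(prm) <- paste0("PR", seq_len(pcap))
    out <- cbind(out, as.data.frame(dxm, stringsAsFactors = FALSE),
                 as.data.frame(prm, stringsAsFactors = FALSE))
    out$los <- los
    out$total_charges <- charges
    out$ccr <- ccr
    out$cost <- cost
    out$age <- age
    out$n_diagnoses <- ndx
    out$n_procedures <- npr
    out$urban_teaching <- urban
    out$small_bedsize <- small
    out$severity_index <- severity
    out$mortality_risk_index <- risk
    out$wage_index <- wage
    out$sim_group <- sim_group
    out$sim_infection <- sim_infection
    out
  })
}

#' Reference LRTI generator configuration
#'
#' A ready-made [generator_config()] whose ground-truth coefficients are the
#' bundled stage-1 LRTI estimates for the matching year (ICD-9 dialect: 2011;
#' ICD-10: 2016) and whose covariate distributions target the bundled
#' LRTI group statistics (principal-group mean LOS 3.83 in 2011, 4.24 in
#' 2016; secondary group shifted upwards in LOS, code counts, age, severity
#' and mortality risk). The infection mix (30% principal, 25% secondary) is
#' chosen so that moderate `n_records` yield usable cohorts of every kind.
#'
#' @inheritParams generator_config
#' @return A [generator_config()] for the single infection type `"lrti"`.
#' @export
lrti_generator_config <- function(dialect = c("ICD9", "ICD10"),
                                  n_records = 10000, seed = 1L) {
  dialect <- match.arg(dialect)
  year <- if (dialect == "ICD9") 2011 else 2016
  stats <- lrti_group_stats(year)
  cs <- reference_coefficients(year)
  grp <- function(g) stats[stats$group == g, , drop = FALSE]
  p <- grp("principal"); s <- grp("secondary"); u <- grp("none")
  sev_probs <- list(  # category probabilities matching the printed group means
    `2011.principal` = c(0.40, 0.37, 0.17, 0.06),
    `2011.secondary` = c(0.08, 0.25, 0.40, 0.27),
    `2011.none`      = c(0.18, 0.32, 0.33, 0.17),
    `2016.principal` = c(0.30, 0.37, 0.23, 0.10),
    `2016.secondary` = c(0.04, 0.16, 0.42, 0.38),
    `2016.none`      = c(0.17, 0.31, 0.34, 0.18))
  risk_probs <- list(
    `2011.principal` = c(0.70, 0.22, 0.06, 0.02),
    `2011.secondary` = c(0.25, 0.30, 0.31, 0.14),
    `2011.none`      = c(0.32, 0.34, 0.24, 0.10),
    `2016.principal` = c(0.55, 0.27, 0.12, 0.06),
    `2016.secondary` = c(0.10, 0.25, 0.36, 0.29),
    `2016.none`      = c(0.27, 0.33, 0.24, 0.16))
  key <- function(g) paste(year, g, sep = ".")
  generator_config(
    dialect = dialect, n_records = n_records,
    infection_mix = list(lrti = c(principal = 0.30, secondary = 0.25)),
    true_coefficients = setNames(cs$table$estimate, cs$table$parameter),
    principal = list(los_mean = p$los_mean, ndx_mean = p$ndx_mean,
                     npr_mean = p$npr_mean, age_mean = p$age_mean,
                     age_max = p$age_max,
                     severity_probs = sev_probs[[key("principal")]],
                     risk_probs = risk_probs[[key("principal")]]),
    uninfected = list(los_mean = u$los_mean, ndx_mean = u$ndx_mean,
                      npr_mean = u$npr_mean, age_mean = u$age_mean,
                      age_max = u$age_max,
                      severity_probs = sev_probs[[key("none")]],
                      risk_probs = risk_probs[[key("none")]]),
    secondary_shift = list(los = s$los_mean - p$los_mean,
                           n_diagnoses = s$ndx_mean - p$ndx_mean,
                           n_procedures = s$npr_mean - p$npr_mean,
                           age = s$age_mean - p$age_mean,
                           severity_probs = sev_probs[[key("secondary")]],
                           risk_probs = risk_probs[[key("secondary")]]),
    facility = list(urban_share = 0.5, small_share = 0.3,
                    wage_mean = p$wage_mean, wage_sd = p$wage_sd),
    seed = seed)
}

#' Bundled LRTI patient-group statistics
#'
#' Univariate reference statistics (cohort sizes, cost and LOS summaries,
#' covariate means/SDs) for the LRTI principal, secondary and matched
#' no-infection groups, per study year. Used to parameterize the reference
#' generator and as anchors in tests.
#'
#' @param year 2011 or 2016.
#' @return A data.frame with one row per patient group.
#' @export
lrti_group_stats <- function(year = c(2011, 2016)) {
  year <- match.arg(as.character(year[1]), c("2011", "2016"))
  tab <- read.csv(hoicost_extdata("lrti_group_stats.csv"), stringsAsFactors = FALSE)
  tab[tab$year == as.numeric(year), , drop = FALSE]
}

#' Read / write discharge records as delimited text
#'
#' One row per hospitalization, diagnosis codes in ordered columns
#' `DX1..DX25` (ICD-9) or `DX1..DX30` (ICD-10), procedure codes `PR1..PR10`.
#' `read_discharges()` refuses files whose diagnosis-column count exceeds
#' the capacity of the stated dialect.
#'
#' @param records data.frame in the layout of [generate_discharges()].
#' @param path file path.
#' @return `read_discharges()` returns the records data.frame;
#'   `write_discharges()` returns `path` invisibly.
#' @export
write_discharges <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_discharges
#' @export
read_discharges <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  dx_cols <- grep("^DX[0-9]+$", names(tab), value = TRUE)
  if (!length(dx_cols)) stop("no DX columns found in ", path, call. = FALSE)
  if (!"dialect" %in% names(tab)) stop("no `dialect` column in ", path, call. = FALSE)
  dialects <- unique(tab$dialect)
  if (nrow(tab) && length(dialects) != 1L)
    stop("mixed dialects in one discharge file", call. = FALSE)
  cap <- if (nrow(tab)) dx_capacity(match.arg(dialects, c("ICD9", "ICD10"))) else 30L
  if (length(dx_cols) > cap)
    stop("file has ", length(dx_cols), " diagnosis columns; the ",
         dialects[1], " layout allows ", cap, call. = FALSE)
  for (col in c(dx_cols, grep("^PR[0-9]+$", names(tab), value = TRUE)))
    tab[[col]][is.na(tab[[col]])] <- ""
  num_cols <- intersect(c("los", "total_charges", "ccr", "cost", "age",
                          "n_diagnoses", "n_procedures", "urban_teaching",
                          "small_bedsize", "severity_index",
                          "mortality_risk_index", "wage_index"), names(tab))
  for (col in num_cols) tab[[col]] <- as.numeric(tab[[col]])
  tab
}

#' Read / write a generator configuration as structured text (YAML)
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @return `read_generator_config()` returns a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$true_coefficients <- as.list(x$true_coefficients)
  x$infection_mix <- lapply(x$infection_mix, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  generator_config(dialect = x$dialect, n_records = x$n_records,
                   infection_mix = lapply(x$infection_mix, unlist),
                   true_coefficients = unlist(x$true_coefficients),
                   principal = x$groups$principal,
                   uninfected = x$groups$uninfected,
                   secondary_shift = x$secondary_shift,
                   facility = x$facility, noise = x$noise,
                   ccr_range = unlist(x$ccr_range),
                   cost_floor = x$cost_floor, seed = x$seed)
}
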