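#' The nine stage-1 model covariates
#'
#' Resource-use variables (length of stay, diagnosis and procedure counts,
#' age, APR-DRG severity-of-illness and risk-of-mortality indices, both
#' treated as continuous) and facility cost-structure variables
#' (urban-teaching flag, small-bedsize flag, area wage index).
#'
#' @return Character vector of column names, in model order.
#' @export
stage1_covariates <- function()
  c("los", "n_diagnoses", "n_procedures", "urban_teaching", "small_bedsize",
    "age", "severity_index", "mortality_risk_index", "wage_index")

stage1_design <- function(records, covariates) {
  missing_cols <- setdiff(covariates, names(records))
  if (length(missing_cols))
    stop("records lack covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- cbind(intercept = 1, as.matrix(records[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Fit the stage-1 median-regression cost model
#'
#' Fits cost on an intercept plus the model covariates by minimizing the sum
#' of absolute residuals (quantile regression at the median), on the
#' principal-diagnosis cohort. The resulting coefficient set parameterizes
#' the stage-2 attribution model: each slope is the cost analog of one unit
#' of its covariate.
#'
#' @param records cohort data.frame with a `cost` column and the covariate
#'   columns.
#' @param covariates character vector of covariate column names (default
#'   [stage1_covariates()]).
#' @param infection,year optional labels stored with the result.
#' @return An object of class `coefficient_set`: list with `table`
#'   (data.frame `parameter`, `estimate`, `std_error`, `ci_lower`,
#'   `ci_upper`), `coefficients` (named vector), `n_fit`, `objective`,
#'   `nonunique`, `covariates`, `infection`, `year`.
#' @export
fit_median_regression <- function(records, covariates = stage1_covariates(),
                                  infection = NA_character_, year = NA_integer_) {
  if (!nrow(records)) stop("empty cohort", call. = FALSE)
  if (!"cost" %in% names(records))
    stop("records need a `cost` column (see add_cost_column())", call. = FALSE)
  complete <- stats::complete.cases(records[, c("cost", covariates)])
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " record(s) excluded from the fit: missing covariates")
  records <- records[complete, , drop = FALSE]
  X <- stage1_design(records, covariates)
  if (nrow(X) <= ncol(X))
    stop("cohort too small: ", nrow(X), " records for ", ncol(X),
         " parameters", call. = FALSE)
  fit <- l1_fit(X, records$cost)
  est <- fit$coefficients
  structure(list(
    table = data.frame(parameter = names(est), estimate = unname(est),
                       std_error = NA_real_, ci_lower = NA_real_,
                       ci_upper = NA_real_, stringsAsFactors = FALSE),
    coefficients = est, n_fit = nrow(X), objective = fit$objective,
    nonunique = fit$nonunique, covariates = covariates,
    infection = infection, year = year), class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set>",
      if (!is.na(x$infection)) paste0(x$infection, ", "),
      if (!is.na(x$year)) paste0(x$year, ", "),
      "n_fit = ", x$n_fit, "\n", sep = "")
  print(x$table, row.names = FALSE)
  if (isTRUE(x$nonunique))
    cat("note: L1 minimizer is not unique (flat optimum detected)\n")
  invisible(x)
}

#' Bootstrap standard errors and percentile confidence intervals
#'
#' Nonparametric case-resampling bootstrap of [fit_median_regression()]:
#' records are resampled with replacement, the median regression refit, and
#' per-coefficient standard errors plus percentile intervals computed.
#' Seeded and reproducible.
#'
#' @inheritParams fit_median_regression
#' @param B number of bootstrap replicates (at least 2; 100+ recommended).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return The fitted `coefficient_set` with `std_error`, `ci_lower`,
#'   `ci_upper` filled in and a `bootstrap` element (`B`, `seed`, `level`).
#' @export
bootstrap_se <- function(records, covariates = stage1_covariates(), B = 200L,
                         seed = 1L, level = 0.95,
                         infection = NA_character_, year = NA_integer_) {
  if (B < 2) stop("`B` must be at least 2", call. = FALSE)
  fit <- fit_median_regression(records, covariates, infection = infection,
                               year = year)
  p <- length(fit$coefficients)
  n <- nrow(records)
  draws <- matrix(NA_real_, nrow = B, ncol = p,
                  dimnames = list(NULL, names(fit$coefficients)))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(
        suppressMessages(fit_median_regression(records[idx, , drop = FALSE],
                                               covariates)),
        error = function(e) NULL)  # degenerate resample (e.g. collinear)
      if (!is.null(bf)) draws[b, ] <- bf$coefficients
    }
  })
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 2) stop("too few successful bootstrap refits", call. = FALSE)
  draws <- draws[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  fit$table$std_error <- apply(draws, 2, sd)
  fit$table$ci_lower <- apply(draws, 2, quantile, probs = alpha, names = FALSE)
  fit$table$ci_upper <- apply(draws, 2, quantile, probs = 1 - alpha, names = FALSE)
  fit$bootstrap <- list(B = B, B_used = nrow(draws), seed = seed, level = level)
  fit
}

#' Bundled stage-1 LRTI coefficient estimates
#'
#' The reference median-regression coefficient sets for non-pneumonia lower
#' respiratory tract infection (intercept plus nine covariates, with
#' standard errors and 95% confidence limits), per study year. These
#' parameterize reproduction-mode stage-2 runs and serve as the ground
#' truth of the reference generator.
#'
#' @param year 2011 (ICD-9 data) or 2016 (ICD-10 data).
#' @return A `coefficient_set`.
#' @export
reference_coefficients <- function(year = c(2011, 2016)) {
  year <- as.integer(match.arg(as.character(year[1]), c("2011", "2016")))
  tab <- read.csv(hoicost_extdata("lrti_stage1_coefficients.csv"),
                  stringsAsFactors = FALSE)
  tab <- tab[tab$year == year, , drop = FALSE]
  structure(list(
    table = data.frame(parameter = tab$parameter, estimate = tab$estimate,
                       std_error = tab$std_error, ci_lower = tab$ci_lower,
                       ci_upper = tab$ci_upper, stringsAsFactors = FALSE),
    coefficients = setNames(tab$estimate, tab$parameter),
    n_fit = tab$n_fit[1], objective = NA_real_, nonunique = FALSE,
    covariates = stage1_covariates(), infection = "lrti", year = year),
    class = "coefficient_set")
}

#' Read / write coefficient sets as delimited text
#'
#' The on-disk schema (`infection`, `year`, `parameter`, `estimate`,
#' `std_error`, `ci_lower`, `ci_upper`, `n_fit`) is symmetric, so published
#' coefficient tables can be transcribed and injected directly in place of
#' a fit (reproduction mode). `structural_zeros = TRUE` additionally writes
#' one zero-estimate row per 0/1 facility dummy, mirroring the
#' reference-level rows of published regression software output.
#'
#' @param cs a `coefficient_set`.
#' @param path file path.
#' @param structural_zeros write reference-level dummy rows with estimate 0.
#' @return `read_coefficients()` returns a `coefficient_set`.
#' @export
write_coefficients <- function(cs, path, structural_zeros = FALSE) {
  stopifnot(inherits(cs, "coefficient_set"))
  tab <- cs$table
  if (structural_zeros) {
    dummies <- intersect(c("urban_teaching", "small_bedsize"), tab$parameter)
    for (d in dummies) {
      at <- which(tab$parameter == d)
      zero <- tab[at, , drop = FALSE]
      zero$estimate <- 0; zero$std_error <- 0
      zero$ci_lower <- 0; zero$ci_upper <- 0
      tab <- rbind(tab[seq_len(at), ], zero, tab[-seq_len(at), ])
    }
  }
  tab$infection <- cs$infection
  tab$year <- cs$year
  tab$n_fit <- cs$n_fit
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  # drop any structural-zero duplicate rows, keeping the estimated one
  tab <- tab[!duplicated(tab$parameter), , drop = FALSE]
  structure(list(
    table = tab[, c("parameter", "estimate", "std_error", "ci_lower",
                    "ci_upper")],
    coefficients = setNames(tab$estimate, tab$parameter),
    n_fit = tab$n_fit[1], objective = NA_real_, nonunique = FALSE,
    covariates = setdiff(tab$parameter, "intercept"),
    infection = tab$infection[1], year = tab$year[1]),
    class = "coefficient_set")
}
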