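#' Per-record stage-2 attributable cost
#'
#' Evaluates the stage-2 attribution model on secondary-diagnosis records:
#' the full stage-1 linear predictor (intercept included), with the
#' length-of-stay covariate replaced by the attributable LOS — the mean LOS
#' of the principal-diagnosis cohort — and every other covariate taken from
#' the secondary record. The LOS term prices the extra hospital days an
#' infection of this type occasions; the remaining terms price treatment
#' intensity (extra diagnoses and procedures), disease severity and
#' mortality risk, and facility cost structure.
#'
#' @param coeffs a `coefficient_set` (fitted or transcribed).
#' @param records secondary-cohort data.frame.
#' @param attributable_los attributable length of stay, in days (> 0).
#' @return Numeric vector of per-record attributable costs (negative values
#'   are retained: averaging, not flooring, is the estimator).
#' @export
attributable_costs <- function(coeffs, records, attributable_los) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (attributable_los <= 0) stop("attributable LOS must be positive", call. = FALSE)
  covs <- coeffs$covariates
  have <- intersect(setdiff(covs, "los"), names(records))
  complete <- stats::complete.cases(records[, have, drop = FALSE])
  if (any(!complete))
    message(sum(!complete), " record(s) excluded: missing covariates")
  records <- records[complete, , drop = FALSE]
  records$los <- attributable_los
  X <- stage1_design(records, covs)
  unname(drop(X %*% coeffs$coefficients[colnames(X)]))
}

#' Mean attributable cost with LOS decomposition
#'
#' The stage-2 estimate for one infection type and year: the mean of
#' [attributable_costs()] over the secondary cohort, with the attributable
#' LOS fixed at the principal cohort's mean LOS, decomposed into an LOS
#' component (`b_los * attributable_los`) and a non-LOS remainder. The two
#' components sum to the mean exactly (pre-rounding).
#'
#' @inheritParams attributable_costs
#' @param principal principal-diagnosis cohort data.frame (supplies the
#'   attributable LOS), or a single positive number to use directly.
#' @param secondary secondary-diagnosis cohort data.frame.
#' @param keep_per_record retain the per-record attributable costs.
#' @return An object of class `attributable_cost_estimate`: list with
#'   `mean_attributable_cost`, `los_component`, `other_component`,
#'   `attributable_los`, `n_secondary`, `infection`, `year`, `cost_year`,
#'   and optionally `per_record`.
#' @export
mean_attributable_cost <- function(coeffs, principal, secondary,
                                   keep_per_record = FALSE) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  attributable_los <- if (is.data.frame(principal)) {
    if (!nrow(principal)) stop("empty principal cohort", call. = FALSE)
    mean(principal$los)
  } else as.numeric(principal)
  if (!is.data.frame(secondary) || !nrow(secondary))
    stop("empty secondary cohort", call. = FALSE)
  per_record <- attributable_costs(coeffs, secondary, attributable_los)
  m <- mean(per_record)
  los_part <- unname(coeffs$coefficients[["los"]]) * attributable_los
  structure(list(mean_attributable_cost = m,
                 los_component = los_part,
                 other_component = m - los_part,
                 attributable_los = attributable_los,
                 n_secondary = length(per_record),
                 infection = coeffs$infection, year = coeffs$year,
                 cost_year = coeffs$year,
                 per_record = if (keep_per_record) per_record else NULL),
            class = "attributable_cost_estimate")
}

#' @export
print.attributable_cost_estimate <- function(x, ...) {
  cat("<attributable_cost_estimate>",
      if (!is.na(x$infection)) x$infection, if (!is.na(x$year)) x$year, "\n")
  cat(sprintf("  mean attributable cost: $%s (%s$)\n",
              format(round(x$mean_attributable_cost), big.mark = ","),
              ifelse(is.na(x$cost_year), "?", x$cost_year)))
  cat(sprintf("  LOS component: $%s (%.2f days); other: $%s; n = %d\n",
              format(round(x$los_component), big.mark = ","),
              x$attributable_los,
              format(round(x$other_component), big.mark = ","),
              x$n_secondary))
  invisible(x)
}

#' LOS / non-LOS decomposition of a mean attributable cost
#'
#' Splits a mean attributable cost into `b_los * attributable_los` and the
#' remainder. `round_coefficient = TRUE` rounds the LOS coefficient to
#' whole dollars before multiplying, the convention used when quoting the
#' decomposition alongside whole-dollar published coefficients.
#'
#' @param b_los LOS coefficient (dollars per day).
#' @param attributable_los attributable length of stay (days).
#' @param mean_attributable_cost the stage-2 mean (dollars).
#' @param round_coefficient round `b_los` to whole dollars first.
#' @return List with `los_component` and `other_component`.
#' @export
attributable_decomposition <- function(b_los, attributable_los,
                                       mean_attributable_cost,
                                       round_coefficient = FALSE) {
  if (round_coefficient) b_los <- round(b_los)
  los_part <- b_los * attributable_los
  list(los_component = los_part,
       other_component = mean_attributable_cost - los_part)
}

#' Wage-index counterfactual
#'
#' Re-prices an attributable-cost estimate at a counterfactual area wage
#' index: by linearity of the stage-2 model, replacing every record's wage
#' index with `new_wage` shifts the mean by
#' `b_wage * (new_wage - mean_secondary_wage)`.
#'
#' @param estimate an `attributable_cost_estimate`, or a plain mean
#'   attributable cost (dollars).
#' @param coeffs the `coefficient_set` behind the estimate.
#' @param mean_secondary_wage mean wage index of the secondary cohort.
#' @param new_wage counterfactual wage index (> 0).
#' @return Adjusted mean attributable cost (dollars), same currency year.
#' @export
wage_counterfactual <- function(estimate, coeffs, mean_secondary_wage,
                                new_wage) {
  if (new_wage <= 0) stop("`new_wage` must be positive", call. = FALSE)
  m <- if (inherits(estimate, "attributable_cost_estimate"))
    estimate$mean_attributable_cost else as.numeric(estimate)
  m + unname(coeffs$coefficients[["wage_index"]]) *
    (new_wage - mean_secondary_wage)
}
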