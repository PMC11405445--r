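#' Modal value after whole-dollar rounding
#'
#' The mode of a cost vector, computed on values rounded to whole dollars;
#' ties are broken by the smallest value.
#'
#' @param x numeric vector.
#' @return The modal (rounded) value.
#' @export
stat_mode <- function(x) {
  r <- round(x)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])  # which.max takes the first maximum;
                                          # table() sorts keys ascending
}

#' Univariate group comparison for a cohort triple
#'
#' Computes, per patient group (principal / secondary / no-infection) and
#' study variable, the summaries used to assess the analogy hypothesis:
#' n, mean, median, mode (costs rounded to whole dollars), range and SD.
#' The result carries an `ordering_holds` attribute: `TRUE` when the
#' secondary group's mean cost **and** mean LOS strictly exceed both other
#' groups' — the pattern required for principal-diagnosis stays to be a
#' conservative cost analog.
#'
#' @param cohorts a `cohort_triple` from [build_cohorts()], or a list with
#'   `principal`, `secondary`, `controls` data.frames.
#' @param variables variables to summarize (default cost, LOS and the
#'   remaining model covariates).
#' @return data.frame with one row per variable and group;
#'   attribute `ordering_holds`.
#' @export
univariate_summary <- function(cohorts,
                               variables = c("cost", stage1_covariates())) {
  groups <- list(secondary = cohorts$secondary, principal = cohorts$principal,
                 none = cohorts$controls)
  for (g in names(groups))
    if (is.null(groups[[g]]) || !nrow(groups[[g]]))
      stop("empty group: ", g, call. = FALSE)
  rows <- list()
  for (v in variables) {
    for (g in names(groups)) {
      x <- groups[[g]][[v]]
      rows[[paste(v, g)]] <- data.frame(
        variable = v, group = g, n = length(x), mean = mean(x),
        median = median(x), mode = stat_mode(x), min = min(x), max = max(x),
        sd = sd(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  check <- intersect(c("cost", "los"), variables)
  ordering <- if (length(check)) all(vapply(check, function(v) {
    m <- setNames(out$mean[out$variable == v], out$group[out$variable == v])
    m[["secondary"]] > m[["principal"]] && m[["secondary"]] > m[["none"]]
  }, logical(1))) else NA
  attr(out, "ordering_holds") <- ordering
  out
}

#' Professional-fee uplift
#'
#' Facility discharge data exclude physician professional fees; a crude
#' multiplicative uplift `total * (1 + rate)` approximates their inclusion.
#'
#' @param total dollar amount(s).
#' @param rate nonnegative uplift rate (e.g. 0.15 for 15%).
#' @return Uplifted amount(s).
#' @export
professional_fee_uplift <- function(total, rate) {
  if (rate < 0) stop("`rate` must be nonnegative", call. = FALSE)
  total * (1 + rate)
}

#' Dollars in billions at three significant figures
#'
#' @param x dollar amount(s).
#' @return `x / 1e9`, to 3 significant figures.
#' @export
billions <- function(x) signif(x / 1e9, 3)

#' Compare a cost total with another study's
#'
#' @param this_total this framework's total.
#' @param other_total the comparison study's total (> 0), same currency
#'   year.
#' @return List with `percent_of_other` (`this / other * 100`) and
#'   `percent_above_other` (`(this / other - 1) * 100`), both rounded to
#'   the nearest percent.
#' @export
compare_totals <- function(this_total, other_total) {
  if (other_total <= 0) stop("`other_total` must be positive", call. = FALSE)
  ratio <- this_total / other_total
  list(percent_of_other = round(100 * ratio),
       percent_above_other = round(100 * (ratio - 1)))
}

#' Bundled cross-study comparison totals
#'
#' Published total direct-medical-cost estimates (2017 dollars, billions)
#' for the four device/procedure-associated infection types under common
#' 2011 central burden: two meta-analysis-based totals and this
#' framework's.
#'
#' @return data.frame with columns `study`, `total_billions_2017`, `scope`.
#' @export
cross_study_totals <- function()
  read.csv(hoicost_extdata("cross_study_totals.csv"), stringsAsFactors = FALSE)
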