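#' Round to the nearest hundred cases
#'
#' National incidence estimates are reported to the nearest 100 cases;
#' halves round away from zero.
#'
#' @param x numeric.
#' @return `x` rounded to a multiple of 100.
#' @export
round_to_100 <- function(x) sign(x) * floor(abs(x) / 100 + 0.5) * 100

#' Validate a national burden (incidence) table
#'
#' One row per infection type with central, low and high incident-case
#' counts (multiples of 100, `low <= central <= high`) and a grouping label
#' (`device` for infections under traditional device/procedure
#' surveillance, `nondevice` otherwise).
#'
#' @param df data.frame with columns `infection`, `group`, `central`,
#'   `low`, `high` and optionally `burden_year`.
#' @return The validated data.frame with class `burden_table`.
#' @export
burden_table <- function(df) {
  need <- c("infection", "group", "central", "low", "high")
  if (!all(need %in% names(df)))
    stop("burden table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$low < 0) || any(df$low > df$central) || any(df$central > df$high))
    stop("burden rows must satisfy 0 <= low <= central <= high", call. = FALSE)
  counts <- unlist(df[, c("central", "low", "high")])
  if (any(counts %% 100 != 0))
    stop("burden counts must be multiples of 100", call. = FALSE)
  structure(df, class = c("burden_table", "data.frame"))
}

#' Split a burden total into device- and nondevice-associated parts
#'
#' Applies a reported device-associated proportion (e.g. the share of
#' ventilator-associated pneumonias among all pneumonias) to a combined
#' burden count. Both parts are re-derived from the unrounded intermediates
#' and rounded to the nearest 100 independently, so they may differ from
#' `total - other_part` by up to 100.
#'
#' @param total combined incident-case count.
#' @param proportion device-associated share, in `[0, 1]`.
#' @return List with `device` and `nondevice` counts (multiples of 100).
#' @export
split_burden <- function(total, proportion) {
  if (proportion < 0 || proportion > 1)
    stop("`proportion` must lie in [0, 1]", call. = FALSE)
  device_raw <- total * proportion
  list(device = round_to_100(device_raw),
       nondevice = round_to_100(total - device_raw))
}

#' National burden-weighted cost totals
#'
#' Multiplies per-infection mean attributable costs (in a single common
#' currency year) by central/low/high incident-case counts, then sums to
#' device/nondevice subtotals and a grand total.
#'
#' @param attributable data.frame with columns `infection`, `mean_cost`
#'   and `cost_year` (one common year).
#' @param burden a [burden_table()].
#' @return An object of class `national_cost_table`: list with
#'   `by_infection` (per-type totals), `subtotals`, `grand` (named vector
#'   central/low/high), `cost_year`, `burden_year`.
#' @export
national_totals <- function(attributable, burden) {
  burden <- burden_table(as.data.frame(burden))
  if (!all(c("infection", "mean_cost", "cost_year") %in% names(attributable)))
    stop("`attributable` needs columns infection, mean_cost, cost_year",
         call. = FALSE)
  if (length(unique(attributable$cost_year)) != 1L)
    stop("attributable costs mix currency years: ",
         paste(unique(attributable$cost_year), collapse = ", "),
         call. = FALSE)
  gaps <- setdiff(burden$infection, attributable$infection)
  if (length(gaps))
    stop("no attributable cost estimate for: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  m <- as.numeric(attributable$mean_cost[match(burden$infection,
                                               attributable$infection)])
  by_inf <- data.frame(infection = burden$infection, group = burden$group,
                       mean_cost = m,
                       total_central = m * as.numeric(burden$central),
                       total_low = m * as.numeric(burden$low),
                       total_high = m * as.numeric(burden$high),
                       stringsAsFactors = FALSE)
  agg <- function(rows) c(central = sum(rows$total_central),
                          low = sum(rows$total_low),
                          high = sum(rows$total_high))
  subtotals <- do.call(rbind, lapply(split(by_inf, by_inf$group), agg))
  structure(list(by_infection = by_inf,
                 subtotals = as.data.frame(subtotals),
                 grand = agg(by_inf),
                 cost_year = attributable$cost_year[1],
                 burden_year = if ("burden_year" %in% names(burden))
                   burden$burden_year[1] else NA),
            class = "national_cost_table")
}

#' @export
print.national_cost_table <- function(x, ...) {
  cat("<national_cost_table> costs in", x$cost_year, "dollars\n")
  tab <- x$by_infection
  tab$total_central <- round(tab$total_central)
  print(tab, row.names = FALSE)
  cat(sprintf("grand total (central): $%s\n",
              format(round(x$grand[["central"]]), big.mark = ",")))
  invisible(x)
}

#' Cost shares of a national cost table
#'
#' The nondevice subtotal as a percentage of the grand total, and each
#' infection's share of its own group subtotal, at the central burden.
#'
#' @param table a `national_cost_table`.
#' @return List with `nondevice_share_percent` and `within_group`
#'   (data.frame `infection`, `group`, `share_percent`).
#' @export
cost_shares <- function(table) {
  stopifnot(inherits(table, "national_cost_table"))
  grand <- table$grand[["central"]]
  if (grand <= 0) stop("grand total must be positive", call. = FALSE)
  by_inf <- table$by_infection
  sub <- tapply(by_inf$total_central, by_inf$group, sum)
  within <- data.frame(infection = by_inf$infection, group = by_inf$group,
                       share_percent = 100 * by_inf$total_central /
                         as.numeric(sub[by_inf$group]),
                       stringsAsFactors = FALSE)
  nd <- if ("nondevice" %in% names(sub)) 100 * sub[["nondevice"]] / grand else 0
  list(nondevice_share_percent = nd, within_group = within)
}

#' Bundled national reference tables
#'
#' Machine-readable transcriptions of the published per-infection burden
#' (central/low/high), attributable LOS, attributable costs in year dollars
#' and 2017 dollars, and total-cost columns, for the 2011 analysis (2011
#' burden) and the 2016 analysis (2015 burden). Used by reproduction mode
#' and by consistency tests; `row_type` distinguishes per-infection rows
#' from printed subtotal and grand-total rows.
#'
#' @param year 2011 or 2016 (the cost year).
#' @return A data.frame.
#' @export
reference_national_table <- function(year = c(2011, 2016)) {
  year <- match.arg(as.character(year[1]), c("2011", "2016"))
  read.csv(hoicost_extdata(paste0("national_costs_", year, ".csv")),
           stringsAsFactors = FALSE)
}

#' Reference table as a national cost table
#'
#' Converts a [reference_national_table()] into a `national_cost_table`
#' built from the printed per-infection total-cost columns (reproduction
#' mode: rounded published inputs, so recomputed aggregates agree with the
#' printed subtotals to printed-rounding slack, a couple of dollars).
#'
#' @param ref a [reference_national_table()].
#' @param cost_year currency year label of the totals (2017 for the bundled
#'   tables).
#' @return A `national_cost_table`.
#' @export
as_national_cost_table <- function(ref, cost_year = 2017) {
  rows <- ref[ref$row_type == "infection", , drop = FALSE]
  by_inf <- data.frame(infection = rows$infection, group = rows$group,
                       mean_cost = rows$att_cost_2017,
                       total_central = rows$total_central,
                       total_low = rows$total_low,
                       total_high = rows$total_high,
                       stringsAsFactors = FALSE)
  agg <- function(r) c(central = sum(r$total_central), low = sum(r$total_low),
                       high = sum(r$total_high))
  structure(list(by_infection = by_inf,
                 subtotals = as.data.frame(
                   do.call(rbind, lapply(split(by_inf, by_inf$group), agg))),
                 grand = agg(by_inf),
                 cost_year = cost_year, burden_year = NA),
            class = "national_cost_table")
}

#' Implied inflation factors of a reference table
#'
#' Per-infection ratio of the 2017-dollar and year-dollar attributable-cost
#' columns — a regression-free consistency check that a single price-index
#' factor underlies the bundled table.
#'
#' @param ref a [reference_national_table()].
#' @return Numeric vector of implied factors, one per infection row.
#' @export
implied_inflation_factors <- function(ref) {
  rows <- ref[ref$row_type == "infection", , drop = FALSE]
  setNames(rows$att_cost_2017 / rows$att_cost_year, rows$infection)
}
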