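#' Convert billed charges to estimated costs
#'
#' Applies the facility cost-to-charge ratio: `cost = charges * ccr`.
#' Vectorized; every charge must be nonnegative and every ratio strictly
#' positive.
#'
#' @param total_charges numeric vector of billed charges (dollars).
#' @param ccr numeric vector of cost-to-charge ratios (> 0).
#' @return Numeric vector of costs.
#' @export
charges_to_cost <- function(total_charges, ccr) {
  if (any(is.na(total_charges)) || any(total_charges < 0))
    stop("charges must be nonnegative and non-missing", call. = FALSE)
  if (any(is.na(ccr)) || any(ccr <= 0))
    stop("cost-to-charge ratios must be strictly positive", call. = FALSE)
  total_charges * ccr
}

#' Add a cost column to discharge records, excluding bad CCRs
#'
#' Record-level variant of [charges_to_cost()]: records with a missing or
#' nonpositive cost-to-charge ratio are dropped rather than raising an
#' error, and the exclusion count is reported (message + `n_excluded`
#' attribute).
#'
#' @param records discharge data.frame with `total_charges` and `ccr`.
#' @return `records` with a recomputed `cost` column; excluded rows removed.
#' @export
add_cost_column <- function(records) {
  ok <- !is.na(records$ccr) & records$ccr > 0 & !is.na(records$total_charges)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(n_bad, " record(s) excluded: missing or nonpositive cost-to-charge ratio")
  out <- records[ok, , drop = FALSE]
  out$cost <- charges_to_cost(out$total_charges, out$ccr)
  attr(out, "n_excluded") <- n_bad
  out
}

#' Price-index factor table for currency-year conversion
#'
#' Multiplicative factors moving dollar amounts between currency years.
#' The bundled default carries 2011->2017 = 1.0921 and 2016->2017 = 1.0226,
#' the hospital producer-price-index factors implied by the bundled
#' national reference tables (ratio of the 2017$ and year$ attributable-cost
#' columns); users may supply their own table.
#'
#' @param from_year,to_year integer vectors of currency years.
#' @param factor strictly positive multiplicative factors.
#' @return data.frame of class `price_index_table`.
#' @export
price_index_table <- function(from_year, to_year, factor) {
  if (any(factor <= 0)) stop("price factors must be positive", call. = FALSE)
  if (any(from_year == to_year & factor != 1))
    stop("factor for a year onto itself must be 1", call. = FALSE)
  structure(data.frame(from_year = as.integer(from_year),
                       to_year = as.integer(to_year), factor = factor),
            class = c("price_index_table", "data.frame"))
}

#' @rdname price_index_table
#' @export
default_price_index <- function() {
  price_index_table(from_year = c(2011L, 2016L),
                    to_year = c(2017L, 2017L),
                    factor = c(1.0921, 1.0226))
}

#' Move a dollar amount between currency years
#'
#' `amount * factor(from_year, to_year)`. The identity factor is implicit
#' for `from_year == to_year`; any other missing pair is an error naming
#' the pair. Inflation is linear, so adjusting before or after averaging is
#' equivalent up to rounding.
#'
#' @param amount numeric dollar amount(s) in `from_year` dollars.
#' @param from_year,to_year currency years.
#' @param index a [price_index_table()].
#' @return Numeric amount(s) in `to_year` dollars.
#' @export
inflate <- function(amount, from_year, to_year, index = default_price_index()) {
  if (from_year == to_year) return(amount)
  hit <- index$from_year == from_year & index$to_year == to_year
  if (!any(hit))
    stop("no price factor for ", from_year, " -> ", to_year, call. = FALSE)
  amount * index$factor[which(hit)[1]]
}

#' Read / write a price-index table as structured text
#'
#' @param path file path.
#' @param index a [price_index_table()].
#' @return `read_price_index()` returns a [price_index_table()].
#' @export
read_price_index <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  price_index_table(tab$from_year, tab$to_year, tab$factor)
}

#' @rdname read_price_index
#' @export
write_price_index <- function(index, path) {
  write.csv(as.data.frame(index), path, row.names = FALSE)
  invisible(path)
}
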