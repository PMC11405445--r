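dx_columns <- function(records) {
  cols <- grep("^DX[0-9]+$", names(records), value = TRUE)
  if (!length(cols)) stop("records have no DX columns", call. = FALSE)
  cols[order(as.integer(sub("^DX", "", cols)))]
}

pr_columns <- function(records)
  grep("^PR[0-9]+$", names(records), value = TRUE)

record_dialect <- function(records, catalog, infection = NULL) {
  if (!"dialect" %in% names(records))
    stop("records need a `dialect` column", call. = FALSE)
  d <- unique(records$dialect)
  if (length(d) != 1L)
    stop("records mix coding dialects: ", paste(d, collapse = ", "),
         call. = FALSE)
  if (!d %in% c("ICD9", "ICD10"))
    stop("unknown dialect '", d, "'", call. = FALSE)
  d
}

#' Classify discharges against an infection-code catalog
#'
#' Per infection type, a record is **principal** when its first-listed
#' diagnosis code is in the catalog set; **secondary** when the first code
#' is not but some later diagnosis field holds a catalog code *and* the stay
#' lasted three days or more (the hospital-onset screen); **none**
#' otherwise. A record whose first code is in the catalog is principal even
#' if later fields also carry catalog codes. Classification is per type: a
#' record may be secondary for several types at once.
#'
#' @param records discharge data.frame (layout of [generate_discharges()]).
#' @param catalog a [code_catalog()]; its dialect sets must cover the
#'   records' dialect or an error is raised.
#' @param infection infection type to classify against.
#' @param min_secondary_los minimum length of stay for the secondary group
#'   (days; default 3).
#' @return Character vector (`"principal"`, `"secondary"`, `"none"`), one
#'   entry per record.
#' @export
classify_infection <- function(records, catalog, infection,
                               min_secondary_los = 3) {
  dialect <- record_dialect(records, catalog)
  codes <- catalog_codes(catalog, infection, dialect)
  dxc <- dx_columns(records)
  first <- records[[dxc[1]]]
  if (any(is.na(first) | !nzchar(first)))
    stop("malformed record(s): empty diagnosis list", call. = FALSE)
  principal <- first %in% codes
  later <- rep(FALSE, nrow(records))
  for (col in dxc[-1]) {
    v <- records[[col]]
    later <- later | (!is.na(v) & v %in% codes)
  }
  out <- rep("none", nrow(records))
  out[later & !principal & records$los >= min_secondary_los] <- "secondary"
  out[principal] <- "principal"
  out
}

#' Device-association flags (CAUTI / VAP)
#'
#' A urinary tract infection is catheter-associated when the record also
#' carries a urinary-catheter insertion procedure code; a pneumonia is
#' ventilator-associated when it carries a mechanical-ventilation procedure
#' code. Bloodstream infections are never split into line-associated and
#' primary components (a single combined type is used throughout).
#'
#' @param records discharge data.frame.
#' @param catalog a [code_catalog()] with `catheter_codes` /
#'   `ventilation_codes` and diagnosis sets for `uti_type` / `pneumonia_type`.
#' @param uti_type,pneumonia_type catalog labels of the two diagnosis sets.
#' @return data.frame with logical columns `cauti` and `vap`.
#' @export
device_flags <- function(records, catalog, uti_type = "uti",
                         pneumonia_type = "pneumonia") {
  dialect <- record_dialect(records, catalog)
  dxc <- dx_columns(records)
  prc <- pr_columns(records)
  has_any <- function(cols, codes) {
    hit <- rep(FALSE, nrow(records))
    for (col in cols) {
      v <- records[[col]]
      hit <- hit | (!is.na(v) & v %in% codes)
    }
    hit
  }
  uti <- has_any(dxc, catalog_codes(catalog, uti_type, dialect))
  pneu <- has_any(dxc, catalog_codes(catalog, pneumonia_type, dialect))
  cath <- has_any(prc, catalog$catheter_codes)
  vent <- has_any(prc, catalog$ventilation_codes)
  data.frame(cauti = uti & cath, vap = pneu & vent)
}

#' Draw a matched no-infection comparison group
#'
#' For each principal-diagnosis-code stratum of the secondary cohort, draws
#' up to `ratio` times the stratum size from candidate-pool records sharing
#' that principal code and carrying **no** catalog infection code of any
#' type in any diagnosis field. Sampling is without replacement and seeded;
#' strata that cannot be filled are reported as shortfalls, not back-filled.
#'
#' @param secondary secondary-cohort data.frame.
#' @param pool candidate data.frame, disjoint from `secondary`.
#' @param catalog full [code_catalog()] used for the no-infection screen.
#' @param ratio target controls per secondary record (default 5).
#' @param seed RNG seed for the draw.
#' @return List with `controls` (data.frame) and `report` (per-stratum
#'   data.frame: `principal_code`, `n_secondary`, `n_target`, `n_matched`,
#'   `achieved_ratio`).
#' @export
build_matched_controls <- function(secondary, pool, catalog, ratio = 5,
                                   seed = 1L) {
  if (ratio < 1) stop("`ratio` must be >= 1", call. = FALSE)
  empty <- function() list(controls = pool[0, , drop = FALSE],
                           report = data.frame(principal_code = character(),
                                               n_secondary = integer(),
                                               n_target = integer(),
                                               n_matched = integer(),
                                               achieved_ratio = numeric()))
  if (!nrow(secondary)) return(empty())
  if (nrow(secondary) && nrow(pool) &&
      length(intersect(secondary$record_id, pool$record_id)))
    stop("candidate pool overlaps the secondary cohort", call. = FALSE)
  if (!nrow(pool)) {
    warning("empty candidate pool: no controls drawn", call. = FALSE)
    rep0 <- as.data.frame(table(secondary[[dx_columns(secondary)[1]]]),
                          stringsAsFactors = FALSE)
    names(rep0) <- c("principal_code", "n_secondary")
    rep0$n_target <- ratio * rep0$n_secondary
    rep0$n_matched <- 0L
    rep0$achieved_ratio <- 0
    return(list(controls = secondary[0, , drop = FALSE], report = rep0))
  }
  dialect <- record_dialect(pool, catalog)
  all_codes <- all_catalog_codes(catalog, dialect)
  dxc <- dx_columns(pool)
  infected <- rep(FALSE, nrow(pool))
  for (col in dxc) {
    v <- pool[[col]]
    infected <- infected | (!is.na(v) & v %in% all_codes)
  }
  eligible <- pool[!infected, , drop = FALSE]

  strata <- table(secondary[[dx_columns(secondary)[1]]])
  first_pool <- eligible[[dx_columns(eligible)[1]]]
  picks <- list(); rep_rows <- list()
  with_seed(seed, {
    for (code in names(strata)) {
      n_sec <- as.integer(strata[[code]])
      target <- ratio * n_sec
      avail <- which(first_pool == code)
      take <- min(length(avail), target)
      chosen <- if (take > 0) sample(avail, take) else integer(0)
      picks[[code]] <- chosen
      rep_rows[[code]] <- data.frame(principal_code = code,
                                     n_secondary = n_sec, n_target = target,
                                     n_matched = take,
                                     achieved_ratio = take / n_sec,
                                     stringsAsFactors = FALSE)
    }
  })
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  if (any(report$n_matched < report$n_target))
    warning("matching shortfall in ", sum(report$n_matched < report$n_target),
            " stratum/strata (see report)", call. = FALSE)
  list(controls = eligible[unlist(picks), , drop = FALSE], report = report)
}

#' Build the principal / secondary / matched-control cohort triple
#'
#' Runs [classify_infection()] and [build_matched_controls()] for one
#' infection type, returning the three patient groups used by the analogy
#' framework: the principal-diagnosis cost analogs, the secondary-diagnosis
#' (hospital-onset proxy) cohort, and a `ratio`:1 matched no-infection
#' group with a similar principal-diagnosis-code distribution.
#'
#' @inheritParams classify_infection
#' @inheritParams build_matched_controls
#' @return An object of class `cohort_triple`: list with `principal`,
#'   `secondary`, `controls`, `match_report`, `infection`, `dialect`,
#'   `match_ratio`.
#' @export
build_cohorts <- function(records, catalog, infection, ratio = 5, seed = 1L) {
  cls <- classify_infection(records, catalog, infection)
  principal <- records[cls == "principal", , drop = FALSE]
  secondary <- records[cls == "secondary", , drop = FALSE]
  pool <- records[cls == "none", , drop = FALSE]
  matched <- build_matched_controls(secondary, pool, catalog, ratio = ratio,
                                    seed = seed)
  structure(list(principal = principal, secondary = secondary,
                 controls = matched$controls, match_report = matched$report,
                 infection = infection,
                 dialect = record_dialect(records, catalog),
                 match_ratio = ratio),
            class = "cohort_triple")
}

#' @export
print.cohort_triple <- function(x, ...) {
  cat("<cohort_triple>", x$infection, "(", x$dialect, "):",
      nrow(x$principal), "principal /", nrow(x$secondary), "secondary /",
      nrow(x$controls), "matched controls (target ", x$match_ratio, ":1)\n")
  invisible(x)
}
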