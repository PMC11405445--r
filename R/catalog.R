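#' Infection diagnosis-code catalogs
#'
#' A code catalog maps each infection type to its ICD-9-CM and ICD-10-CM
#' diagnosis-code sets, plus the procedure-code sets used for
#' device-association rules (urinary catheter insertion, invasive mechanical
#' ventilation). Catalogs drive cohort classification: a discharge is
#' *principal* for a type when its first-listed code is in the set, and
#' *secondary* when a non-first code is.
#'
#' @param codes named list; one element per infection type, each a list with
#'   character vectors `ICD9` and/or `ICD10`.
#' @param catheter_codes character vector of procedure codes identifying
#'   urinary catheter insertion.
#' @param ventilation_codes character vector of procedure codes identifying
#'   invasive mechanical ventilation.
#'
#' @details Within a dialect, a diagnosis code may belong to at most one
#'   infection type; the constructor enforces this, along with non-empty code
#'   sets for every declared type.
#'
#' @return An object of class `code_catalog`.
#' @export
code_catalog <- function(codes, catheter_codes = character(),
                         ventilation_codes = character()) {
  if (!is.list(codes) || is.null(names(codes)) || any(!nzchar(names(codes))))
    stop("`codes` must be a named list of infection types", call. = FALSE)
  for (type in names(codes)) {
    entry <- codes[[type]]
    if (!is.list(entry) || !any(c("ICD9", "ICD10") %in% names(entry)))
      stop("catalog entry for '", type, "' needs an ICD9 and/or ICD10 code set",
           call. = FALSE)
    lens <- vapply(entry, length, integer(1))
    if (all(lens == 0L))
      stop("catalog entry for '", type, "' has no codes", call. = FALSE)
  }
  for (dialect in c("ICD9", "ICD10")) {
    all_codes <- unlist(lapply(codes, function(e) e[[dialect]]))
    dup <- unique(all_codes[duplicated(all_codes)])
    if (length(dup))
      stop("code(s) assigned to more than one infection type (", dialect,
           "): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(codes = codes,
                 catheter_codes = as.character(catheter_codes),
                 ventilation_codes = as.character(ventilation_codes)),
            class = "code_catalog")
}

#' @export
print.code_catalog <- function(x, ...) {
  cat("<code_catalog>", length(x$codes), "infection type(s):",
      paste(names(x$codes), collapse = ", "), "\n")
  invisible(x)
}

#' Diagnosis codes for one infection type and dialect
#'
#' @param catalog a [code_catalog()].
#' @param infection infection type label present in the catalog.
#' @param dialect `"ICD9"` or `"ICD10"`.
#' @return Character vector of diagnosis codes.
#' @export
catalog_codes <- function(catalog, infection, dialect = c("ICD9", "ICD10")) {
  stopifnot(inherits(catalog, "code_catalog"))
  dialect <- match.arg(dialect)
  if (!infection %in% names(catalog$codes))
    stop("infection type '", infection, "' not in catalog", call. = FALSE)
  codes <- catalog$codes[[infection]][[dialect]]
  if (is.null(codes) || !length(codes))
    stop("catalog has no ", dialect, " codes for '", infection,
         "' (dialect mismatch)", call. = FALSE)
  codes
}

#' All infection codes in a catalog for one dialect
#'
#' Used when screening matched-control candidates, which must carry no
#' infection code of any type in any diagnosis field.
#'
#' @inheritParams catalog_codes
#' @return Character vector (possibly empty) of all codes across types.
#' @export
all_catalog_codes <- function(catalog, dialect = c("ICD9", "ICD10")) {
  stopifnot(inherits(catalog, "code_catalog"))
  dialect <- match.arg(dialect)
  unique(unlist(lapply(catalog$codes, function(e) e[[dialect]])))
}

#' Lower respiratory tract infection (LRTI) code catalog
#'
#' The bundled non-pneumonia LRTI catalog: acute bronchitis and
#' bronchiolitis, empyema, pleurisy with effusion, lung/mediastinal abscess,
#' pulmonary mycobacteriosis, and acute (laryngo)tracheitis, in both coding
#' dialects. This is the reference fixture; catalogs for other infection
#' types are user-supplied input in the same format.
#'
#' @return A [code_catalog()] with the single type `"lrti"`.
#' @export
lrti_catalog <- function() {
  tab <- read.csv(hoicost_extdata("lrti_codes.csv"), stringsAsFactors = FALSE)
  code_catalog(list(lrti = list(ICD9 = tab$code[tab$dialect == "ICD9"],
                                ICD10 = tab$code[tab$dialect == "ICD10"])))
}

#' Example multi-type catalog with device rules
#'
#' The LRTI catalog extended with small synthetic toy code sets for urinary
#' tract infection, pneumonia and bloodstream infection, plus placeholder
#' device procedure codes (`UC01` urinary catheter insertion, `MV01`
#' mechanical ventilation). The toy sets exist so that device-association
#' and multi-type cohort logic is exercisable; real analyses supply full
#' catalogs via [read_catalog()].
#'
#' @return A [code_catalog()].
#' @export
example_catalog <- function() {
  base <- lrti_catalog()
  codes <- base$codes
  codes$uti <- list(ICD9 = c("599.0", "590.80"), ICD10 = c("N39.0", "N10"))
  codes$pneumonia <- list(ICD9 = c("486", "482.9"), ICD10 = c("J18.9", "J15.9"))
  codes$bsi <- list(ICD9 = c("038.9", "790.7"), ICD10 = c("A41.9", "R78.81"))
  code_catalog(codes, catheter_codes = "UC01", ventilation_codes = "MV01")
}

#' Read / write a code catalog as structured text (YAML)
#'
#' @param path file path.
#' @return `read_catalog()` returns a [code_catalog()]; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  spec <- yaml::read_yaml(path)
  code_catalog(lapply(spec$infections, function(e)
                 list(ICD9 = as.character(e$ICD9 %||% character()),
                      ICD10 = as.character(e$ICD10 %||% character()))),
               catheter_codes = as.character(spec$devices$catheter %||% character()),
               ventilation_codes = as.character(spec$devices$ventilation %||% character()))
}

#' @rdname read_catalog
#' @param catalog a [code_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "code_catalog"))
  yaml::write_yaml(list(infections = catalog$codes,
                        devices = list(catheter = catalog$catheter_codes,
                                       ventilation = catalog$ventilation_codes)),
                   path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
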