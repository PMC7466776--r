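#' Drug scheduling parameter catalog
#'
#' A drug catalog holds, per drug, the parameters that drive multiplex
#' scheduling: whether interrupted (multiplexed) administration is permitted,
#' the biological half-life, the maximal interruption time `T_iMax` (the
#' longest pharmacologically tolerable gap between two administrations of the
#' same drug), the maximal administration rate with its unit, the solution
#' concentration with its unit, and a clinical category used by the
#' conventional lumen-assignment procedure.
#'
#' The bundled default catalog (`default_catalog()`) covers 34 frequently
#' used ICU drugs. Clinical categories are not part of the published
#' parameter set; the bundle assigns them from standard clinical
#' classification (all pressors/inotropes/vasodilators as `vasoactive`,
#' analgesics and sedatives as `analgesic_sedative`, insulin as
#' `dedicated_lumen`, the rest `other`) and they can be overridden by editing
#' the catalog file.
#'
#' @section Units:
#' `q_max` is given per minute in `mg/min`, `ug/min`, `IU/min` or
#' `mmol/min`; `concentration` per millilitre in the matching substance base.
#' On load the maximal rate is converted to a volumetric limit
#' `q_max_ml_h = (q_max / concentration) * 60` (with a mg/ug factor where
#' needed), the scale on which multiplexed burst rates are checked.
#'
#' @name drug_catalog
NULL

.mux_rate_units <- c("mg/min", "ug/min", "IU/min", "mmol/min")
.mux_conc_units <- c("mg/ml", "ug/ml", "IU/ml", "mmol/ml")

# substance base and scale factor to that base for each unit tag
.mux_unit_base <- function(unit) {
  switch(unit,
    "mg/min" = list(base = "mg", factor = 1),
    "ug/min" = list(base = "mg", factor = 1e-3),
    "IU/min" = list(base = "IU", factor = 1),
    "mmol/min" = list(base = "mmol", factor = 1),
    "mg/ml" = list(base = "mg", factor = 1),
    "ug/ml" = list(base = "mg", factor = 1e-3),
    "IU/ml" = list(base = "IU", factor = 1),
    "mmol/ml" = list(base = "mmol", factor = 1),
    NULL
  )
}

#' Convert a maximal administration rate to ml/h
#'
#' @param q_max rate in `q_max_unit` (amount per minute).
#' @param q_max_unit one of `"mg/min"`, `"ug/min"`, `"IU/min"`, `"mmol/min"`.
#' @param concentration solution concentration in `conc_unit` (amount per ml).
#' @param conc_unit one of `"mg/ml"`, `"ug/ml"`, `"IU/ml"`, `"mmol/ml"`.
#' @return volumetric rate limit in ml/h.
#' @examples
#' q_max_to_ml_h(200, "mg/min", 20, "mg/ml") # propofol: 600 ml/h
#' @export
q_max_to_ml_h <- function(q_max, q_max_unit, concentration, conc_unit) {
  qu <- .mux_unit_base(q_max_unit)
  cu <- .mux_unit_base(conc_unit)
  if (is.null(qu)) mux_unit_error(sprintf("unknown rate unit tag '%s'", q_max_unit))
  if (is.null(cu)) mux_unit_error(sprintf("unknown concentration unit tag '%s'", conc_unit))
  if (qu$base != cu$base) {
    mux_unit_error(sprintf("rate unit '%s' and concentration unit '%s' have different substance bases",
                           q_max_unit, conc_unit))
  }
  (q_max * qu$factor) / (concentration * cu$factor) * 60
}

.catalog_columns <- c("drug", "multiplex_allowed", "half_life_min", "t_imax_min",
                      "q_max", "q_max_unit", "concentration", "conc_unit", "category")

.mux_categories <- c("vasoactive", "analgesic_sedative", "dedicated_lumen", "other")

.validate_catalog <- function(df) {
  missing <- setdiff(.catalog_columns, names(df))
  if (length(missing) > 0) {
    mux_schema_error(sprintf("catalog is missing required column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  df <- df[, .catalog_columns]
  df$drug <- as.character(df$drug)
  df$multiplex_allowed <- as.character(df$multiplex_allowed)
  allowed_states <- c("yes", "no", "undetermined")
  bad <- !df$multiplex_allowed %in% allowed_states
  if (any(bad)) {
    mux_validation_error(sprintf("drug '%s': multiplex_allowed must be yes/no/undetermined, got '%s'",
                                 df$drug[which(bad)[1]], df$multiplex_allowed[which(bad)[1]]))
  }
  for (col in c("half_life_min", "t_imax_min", "q_max", "concentration")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  # interruption time 0 (or N/A) means interruption is not allowed: store NA
  df$t_imax_min[!is.na(df$t_imax_min) & df$t_imax_min <= 0] <- NA_real_
  df$category <- as.character(df$category)
  df$category[is.na(df$category) | !nzchar(df$category)] <- "other"
  bad_cat <- !df$category %in% .mux_categories
  if (any(bad_cat)) {
    mux_validation_error(sprintf("drug '%s': unknown category '%s'",
                                 df$drug[which(bad_cat)[1]], df$category[which(bad_cat)[1]]))
  }
  if (anyDuplicated(df$drug)) {
    mux_validation_error(sprintf("duplicate drug name '%s' in catalog",
                                 df$drug[duplicated(df$drug)][1]))
  }
  for (i in seq_len(nrow(df))) {
    if (is.na(df$half_life_min[i]) || df$half_life_min[i] <= 0) {
      mux_validation_error(sprintf("drug '%s': half_life_min must be positive", df$drug[i]))
    }
    if (!is.na(df$concentration[i]) && df$concentration[i] <= 0) {
      mux_validation_error(sprintf("drug '%s': concentration must be positive", df$drug[i]))
    }
    if (!is.na(df$q_max[i]) && df$q_max[i] <= 0) {
      mux_validation_error(sprintf("drug '%s': q_max must be positive", df$drug[i]))
    }
    if (df$multiplex_allowed[i] == "yes" &&
        (is.na(df$t_imax_min[i]) || df$t_imax_min[i] <= 0)) {
      mux_validation_error(sprintf("drug '%s': multiplexable drugs need a positive t_imax_min",
                                   df$drug[i]))
    }
  }
  # volumetric maximal rate, where both rate and concentration are known
  df$q_max_ml_h <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$q_max[i]) && !is.na(df$concentration[i])) {
      df$q_max_ml_h[i] <- q_max_to_ml_h(df$q_max[i], df$q_max_unit[i],
                                        df$concentration[i], df$conc_unit[i])
    } else if (df$multiplex_allowed[i] == "yes") {
      mux_validation_error(sprintf("drug '%s': multiplexable drugs need q_max and concentration",
                                   df$drug[i]))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("drug_catalog", "data.frame")
  df
}

#' Load a drug catalog
#'
#' @param path path to a catalog file.
#' @param dialect `"delimited"` for comma-separated text with a header row
#'   (one row per drug), or `"keyvalue"` for a YAML document mapping drug
#'   names to parameter records.
#' @return a `drug_catalog` data frame with one row per drug and a derived
#'   `q_max_ml_h` column.
#' @seealso [default_catalog()], [write_catalog()]
#' @export
load_catalog <- function(path, dialect = c("delimited", "keyvalue")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) mux_validation_error(sprintf("catalog file not found: %s", path))
  if (dialect == "delimited") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  } else {
    recs <- yaml::read_yaml(path)
    if (length(recs) == 0) {
      df <- as.data.frame(matrix(character(), 0, length(.catalog_columns),
                                 dimnames = list(NULL, .catalog_columns)),
                          stringsAsFactors = FALSE)
    } else {
      rows <- lapply(names(recs), function(nm) {
        r <- recs[[nm]]
        data.frame(drug = nm,
                   multiplex_allowed = as.character(r$multiplex_allowed %||% NA),
                   half_life_min = as.character(r$half_life_min %||% NA),
                   t_imax_min = as.character(r$t_imax_min %||% NA),
                   q_max = as.character(r$q_max %||% NA),
                   q_max_unit = as.character(r$q_max_unit %||% NA),
                   concentration = as.character(r$concentration %||% NA),
                   conc_unit = as.character(r$conc_unit %||% NA),
                   category = as.character(r$category %||% "other"),
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
    }
  }
  .validate_catalog(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a drug catalog to delimited text
#'
#' Inverse of [load_catalog()] for the `"delimited"` dialect: loading the
#' written file reproduces the catalog.
#'
#' @param catalog a `drug_catalog`.
#' @param path output file path.
#' @export
write_catalog <- function(catalog, path) {
  out <- as.data.frame(catalog)[, .catalog_columns]
  out$t_imax_min[is.na(out$t_imax_min)] <- 0
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' The bundled default drug catalog
#'
#' Thirty-four frequently used ICU drugs with multiplexing permission,
#' half-life, maximal interruption time, maximal administration rate and
#' concentration. Insulin's multiplexing suitability is `undetermined`
#' (adsorption to tubing walls is unresolved) and the pipeline treats it as
#' non-multiplexable.
#'
#' @return a `drug_catalog`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "drug_catalog.csv", package = "ivmux"))
}

#' Look up one drug in a catalog
#'
#' @param catalog a `drug_catalog`.
#' @param drug drug name.
#' @return a one-row data frame, or `NULL` if the drug is unknown.
#' @export
catalog_drug <- function(catalog, drug) {
  i <- match(drug, catalog$drug)
  if (is.na(i)) return(NULL)
  catalog[i, , drop = FALSE]
}

#' Is a drug eligible for multiplexed administration?
#'
#' Unknown drugs and drugs whose suitability is undetermined are treated as
#' non-multiplexable (conservative default).
#'
#' @inheritParams catalog_drug
#' @return logical scalar.
#' @export
is_multiplexable <- function(catalog, drug) {
  row <- catalog_drug(catalog, drug)
  !is.null(row) && identical(row$multiplex_allowed, "yes")
}

#' Clinical category of a drug
#'
#' Drugs absent from the catalog default to category `"other"`.
#'
#' @inheritParams catalog_drug
#' @return one of `"vasoactive"`, `"analgesic_sedative"`, `"dedicated_lumen"`,
#'   `"other"`.
#' @export
drug_category <- function(catalog, drug) {
  row <- catalog_drug(catalog, drug)
  if (is.null(row)) "other" else row$category
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat(sprintf("<drug_catalog> %d drugs (%d multiplexable)\n",
              nrow(x), sum(x$multiplex_allowed == "yes")))
  print.data.frame(x, ...)
  invisible(x)
}
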