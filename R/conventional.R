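#' Build an infusion order list
#'
#' An order is a drug to be administered continuously together with its
#' conventional rate `Q_CONV` in ml/h. Rates only matter for multiplexing
#' (conventional co-administration is assumed feasible at any rate), but the
#' order structure is shared by both schedulers.
#'
#' @param drug character vector of drug names.
#' @param q_conv_ml_h nonnegative conventional rates in ml/h (recycled).
#' @return a data frame of class `infusion_orders` with columns `drug`,
#'   `q_conv_ml_h`. Duplicate drug names are collapsed to their first entry.
#' @export
infusion_orders <- function(drug, q_conv_ml_h = 0) {
  drug <- as.character(drug)
  q <- rep_len(as.numeric(q_conv_ml_h), length(drug))
  if (any(is.na(q) | q < 0)) mux_validation_error("q_conv_ml_h must be nonnegative")
  keep <- !duplicated(drug)
  out <- data.frame(drug = drug[keep], q_conv_ml_h = q[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("infusion_orders", "data.frame")
  out
}

.as_orders <- function(orders) {
  if (is.character(orders)) return(infusion_orders(orders))
  if (is.data.frame(orders)) {
    if (!"drug" %in% names(orders)) mux_schema_error("orders need a 'drug' column")
    q <- if ("q_conv_ml_h" %in% names(orders)) orders$q_conv_ml_h else 0
    return(infusion_orders(orders$drug, q))
  }
  mux_validation_error("orders must be a character vector or a data frame")
}

#' Conventional (nurse protocol) lumen assignment
#'
#' Models the four-stage procedure ICU nurses follow when distributing
#' continuously administered drugs over catheter lumens:
#' \enumerate{
#'   \item all vasoactive drugs share a designated lumen (or more, if
#'     incompatibilities force it);
#'   \item analgesics and sedatives share one or more lumens depending on
#'     compatibility;
#'   \item drugs that are preferably not co-administered (e.g. insulin) each
#'     get a dedicated lumen;
#'   \item all remaining drugs are packed over one or more lumens by
#'     compatibility.
#' }
#' Stages are strict: a lumen is never shared across stages even when that
#' would save a line. Within a stage, drugs are processed alphabetically and
#' placed first-fit into the lowest-indexed lumen whose current occupants are
#' all compatible with the drug. Drugs of unknown category count as `other`.
#'
#' @param orders an `infusion_orders` data frame (or character vector of
#'   drug names).
#' @param catalog a `drug_catalog` (for categories).
#' @param matrix a `compat_matrix`.
#' @return a `lumen_assignment`: list with `lumens` (list of character
#'   vectors, one per lumen) and `l_conv` (the lumen count).
#' @export
schedule_conventional <- function(orders, catalog, matrix) {
  orders <- .as_orders(orders)
  if (nrow(orders) == 0) mux_validation_error("order list is empty")
  drugs <- orders$drug
  cats <- vapply(drugs, function(d) drug_category(catalog, d), character(1))
  lumens <- list()
  for (stage in c("vasoactive", "analgesic_sedative", "dedicated_lumen", "other")) {
    stage_drugs <- sort(drugs[cats == stage])
    if (length(stage_drugs) == 0) next
    if (stage == "dedicated_lumen") {
      for (d in stage_drugs) lumens[[length(lumens) + 1]] <- d
      next
    }
    stage_lumens <- list()
    for (d in stage_drugs) {
      placed <- FALSE
      for (k in seq_along(stage_lumens)) {
        if (all(vapply(stage_lumens[[k]], function(o) is_compatible(matrix, d, o),
                       logical(1)))) {
          stage_lumens[[k]] <- c(stage_lumens[[k]], d)
          placed <- TRUE
          break
        }
      }
      if (!placed) stage_lumens[[length(stage_lumens) + 1]] <- d
    }
    lumens <- c(lumens, stage_lumens)
  }
  structure(list(lumens = lumens, l_conv = length(lumens)),
            class = "lumen_assignment")
}

#' @export
print.lumen_assignment <- function(x, ...) {
  cat(sprintf("<lumen_assignment> %d lumen(s)\n", x$l_conv))
  for (k in seq_along(x$lumens)) {
    cat(sprintf("  lumen %d: %s\n", k, paste(x$lumens[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Serialize / read a lumen assignment
#'
#' Delimited text with columns `lumen` (1-based index) and `drug`.
#'
#' @param assignment a `lumen_assignment`.
#' @param path file path.
#' @export
write_lumen_assignment <- function(assignment, path) {
  df <- do.call(rbind, lapply(seq_along(assignment$lumens), function(k) {
    data.frame(lumen = k, drug = assignment$lumens[[k]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lumen_assignment
#' @export
read_lumen_assignment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lumens <- unname(split(df$drug, df$lumen))
  structure(list(lumens = lumens, l_conv = length(lumens)),
            class = "lumen_assignment")
}
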