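#' IV tube geometry for separator accounting
#'
#' `shared_infusion_volume_ml` (SIV) is the volume of the tubing segment all
#' multiplexed fluids pass through; `separator_volume_ml` (SFV) is the flush
#' volume needed to keep two consecutive packets from mixing. By the rule of
#' thumb, SFV defaults to twice the SIV. The default SIV of 2 ml matches a
#' standard 2 m IV extension line; the experimentally determined 3.7 ml
#' flush for that line is available via `preset = "measured"`.
#'
#' @param shared_infusion_volume_ml SIV in ml (> 0).
#' @param separator_volume_ml SFV in ml (> 0); default `2 * SIV`.
#' @param preset `"rule_of_thumb"` (default) or `"measured"` (SIV 2 ml,
#'   SFV 3.7 ml).
#' @return a `tube_spec` list.
#' @export
tube_spec <- function(shared_infusion_volume_ml = 2,
                      separator_volume_ml = 2 * shared_infusion_volume_ml,
                      preset = c("rule_of_thumb", "measured")) {
  preset <- match.arg(preset)
  if (preset == "measured") {
    shared_infusion_volume_ml <- 2
    separator_volume_ml <- 3.7
  }
  if (shared_infusion_volume_ml <= 0 || separator_volume_ml <= 0) {
    mux_validation_error("tube volumes must be positive")
  }
  structure(list(shared_infusion_volume_ml = shared_infusion_volume_ml,
                 separator_volume_ml = separator_volume_ml),
            class = "tube_spec")
}

#' Compress a continuous rate into a multiplexed burst rate
#'
#' A drug that conventionally runs at `q_conv` ml/h continuously but is only
#' administered `available_min_per_h` minutes out of every hour must run at
#' `q_conv * 60 / available_min_per_h` during its slots to deliver the same
#' hourly volume.
#'
#' @param q_conv conventional continuous rate in ml/h (>= 0).
#' @param available_min_per_h administration minutes available per hour,
#'   in (0, 60].
#' @return burst rate in ml/h.
#' @examples
#' multiplex_rate(5, 20) # 15 ml/h
#' @export
multiplex_rate <- function(q_conv, available_min_per_h) {
  if (!is.numeric(available_min_per_h) || any(is.na(available_min_per_h)) ||
      any(available_min_per_h <= 0) || any(available_min_per_h > 60)) {
    mux_validation_error("available_min_per_h must be in (0, 60]")
  }
  if (any(q_conv < 0)) mux_validation_error("q_conv must be nonnegative")
  q_conv * 60 / available_min_per_h
}

#' Burst rates and maximal-rate compliance for a packet set
#'
#' For every drug in the packets, the long-run available administration time
#' is `d_drugs * 60 / P` minutes per hour (its packet runs `60 / P` times an
#' hour on average). The burst rate is checked against the drug's maximal
#' administration rate converted to ml/h via its concentration; a drug is
#' within limit when `q_mx <= q_max` (running exactly at the maximum is
#' allowed).
#'
#' @param packets list of `infusion_packet`s.
#' @param orders an `infusion_orders` data frame supplying `q_conv_ml_h`.
#' @param catalog a `drug_catalog`.
#' @return a data frame (class `rate_assignment`) with columns `drug`,
#'   `q_conv_ml_h`, `available_min_per_h`, `q_mx_ml_h`, `limit_ml_h`,
#'   `within_limit`.
#' @export
check_rate_limits <- function(packets, orders, catalog) {
  orders <- .as_orders(orders)
  rows <- list()
  for (p in packets) {
    avail <- p$d_drugs_min * 60 / p$period_min
    for (d in p$members) {
      q_conv <- orders$q_conv_ml_h[match(d, orders$drug)]
      if (length(q_conv) == 0 || is.na(q_conv)) q_conv <- 0
      row <- catalog_drug(catalog, d)
      limit <- if (is.null(row)) NA_real_ else row$q_max_ml_h
      if (is.na(limit)) {
        mux_unit_error(sprintf("drug '%s' lacks a convertible maximal rate", d))
      }
      q_mx <- multiplex_rate(q_conv, avail)
      rows[[length(rows) + 1]] <- data.frame(
        drug = d, q_conv_ml_h = q_conv, available_min_per_h = avail,
        q_mx_ml_h = q_mx, limit_ml_h = limit,
        within_limit = q_mx <= limit + 1e-9,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(drug = character(0), q_conv_ml_h = numeric(0),
               available_min_per_h = numeric(0), q_mx_ml_h = numeric(0),
               limit_ml_h = numeric(0), within_limit = logical(0))
  }
  class(out) <- c("rate_assignment", "data.frame")
  out
}

#' Separator-fluid volume over a horizon
#'
#' Every packet administration ends with one separator flush, so the
#' separator budget is the number of packet runs per hyperperiod, scaled to
#' the horizon, times the flush volume.
#'
#' @param timeline a feasible `edf_timeline`.
#' @param tube a `tube_spec`.
#' @param horizon_h horizon in hours (>= 0).
#' @return separator fluid volume in ml.
#' @examples
#' tl <- edf_schedule(list(packet_dp(6, 60)))
#' separator_budget(tl, tube_spec(), 24) # 24 runs x 4 ml = 96 ml
#' @export
separator_budget <- function(timeline, tube, horizon_h) {
  if (horizon_h < 0) mux_validation_error("horizon must be nonnegative")
  cycle_min <- attr(timeline, "horizon_min")
  runs <- nrow(timeline)
  if (runs == 0 || horizon_h == 0) return(0)
  runs * (horizon_h * 60 / cycle_min) * tube$separator_volume_ml
}

#' Serialize a rate report
#'
#' Delimited text with one row per multiplexed drug: conventional rate,
#' available minutes per hour, burst rate, volumetric limit and compliance.
#'
#' @param rates a `rate_assignment`.
#' @param path file path.
#' @export
write_rate_report <- function(rates, path) {
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
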