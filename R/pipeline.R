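#' Full multiplex scheduling pipeline
#'
#' Orchestrates multiplex scheduling for one set of simultaneous infusion
#' orders:
#' \enumerate{
#'   \item drugs whose catalog entry does not permit multiplexing (including
#'     unknown drugs and drugs with undetermined suitability) are routed to
#'     the conventional scheduler (`not_multiplexable`);
#'   \item the multiplexable drugs are partitioned into compatible infusion
#'     packets;
#'   \item while the utilization `U = sum(D_i / P_i)` exceeds 1, the drug
#'     with the smallest `T_iMax` (ties alphabetical) is demoted
#'     (`utility_exceeded`) and the survivors are re-packetized;
#'   \item the packets are scheduled by non-preemptive earliest-deadline-first;
#'     in the rare case a deadline is still missed, the smallest-`T_iMax`
#'     drug is demoted (`edf_infeasible`) and the loop restarts;
#'   \item burst rates are computed; every drug whose rate would exceed its
#'     maximal administration rate is demoted (`rate_exceeded`) and the loop
#'     restarts;
#'   \item demoted and non-multiplexable drugs are assigned lumens by the
#'     conventional procedure; the multiplex lumen (if used) plus those
#'     lumens give `L_MX`.
#' }
#' Each iteration strictly shrinks the multiplexed set, so the loop
#' terminates. Finally, if the assembled plan would need more lumens than
#' the plain conventional schedule of the same orders (possible when
#' demotion splits drugs that conventionally share a lumen), the scheduler
#' falls back to the conventional assignment for all drugs
#' (`fallback_conventional`): a deployed scheduler always takes the cheaper
#' plan, and consequently `L_MX <= L_CONV` always holds.
#'
#' @param orders an `infusion_orders` data frame (or character vector of
#'   drug names; rates then default to 0 ml/h).
#' @param catalog a `drug_catalog`.
#' @param matrix a `compat_matrix`.
#' @param d_drugs drug administration minutes per packet slot (default 5).
#' @param d_sep separator flush minutes per slot (default 1).
#' @param tube a `tube_spec` for separator accounting.
#' @param quiet suppress demotion log messages.
#' @return a `multiplex_result`: list with `multiplex_lumen_used`, `packets`,
#'   `timeline` (or `NULL`), `demoted` (data frame `drug`, `reason`),
#'   `conventional_part` (`lumen_assignment` or `NULL`), `l_mx`, `rates`,
#'   `separator_ml_per_day`, `utility`.
#' @export
schedule_multiplex <- function(orders, catalog, matrix, d_drugs = 5, d_sep = 1,
                               tube = tube_spec(), quiet = FALSE) {
  orders <- .as_orders(orders)
  if (nrow(orders) == 0) mux_validation_error("order list is empty")
  drugs <- orders$drug
  note <- function(drug, reason) {
    if (!quiet) mux_log("multiplex_pipeline", "INFO",
                        sprintf("demoting '%s' (%s)", drug, reason))
    data.frame(drug = drug, reason = reason, stringsAsFactors = FALSE)
  }
  demoted <- do.call(rbind, c(
    list(data.frame(drug = character(0), reason = character(0))),
    lapply(drugs[!vapply(drugs, function(d) is_multiplexable(catalog, d), logical(1))],
           note, reason = "not_multiplexable")))
  mux_set <- setdiff(drugs, demoted$drug)

  t_of <- function(d) catalog_drug(catalog, d)$t_imax_min
  smallest_t <- function(set) {
    tv <- vapply(set, t_of, numeric(1))
    set[order(tv, set)][1]
  }

  packets <- list(); timeline <- NULL; rates <- NULL
  while (length(mux_set) > 0) {
    packets <- partition_into_packets(mux_set, matrix, d_drugs, d_sep, catalog)
    progressed <- FALSE
    while (utility(packets) > 1 && length(mux_set) > 0) {
      v <- smallest_t(mux_set)
      demoted <- rbind(demoted, note(v, "utility_exceeded"))
      mux_set <- setdiff(mux_set, v)
      packets <- partition_into_packets(mux_set, matrix, d_drugs, d_sep, catalog)
      progressed <- TRUE
    }
    if (length(mux_set) == 0) break
    timeline <- edf_schedule(packets)
    if (!is_feasible(timeline)) {
      v <- smallest_t(mux_set)
      demoted <- rbind(demoted, note(v, "edf_infeasible"))
      mux_set <- setdiff(mux_set, v)
      timeline <- NULL
      next
    }
    rates <- check_rate_limits(packets, orders, catalog)
    if (any(!rates$within_limit)) {
      for (v in rates$drug[!rates$within_limit]) {
        demoted <- rbind(demoted, note(v, "rate_exceeded"))
      }
      mux_set <- setdiff(mux_set, rates$drug[!rates$within_limit])
      timeline <- NULL; rates <- NULL
      next
    }
    break
  }

  mux_used <- length(mux_set) > 0
  conv_part <- NULL
  if (nrow(demoted) > 0) {
    conv_orders <- orders[orders$drug %in% demoted$drug, , drop = FALSE]
    conv_part <- schedule_conventional(conv_orders, catalog, matrix)
  }
  l_mx <- as.integer(mux_used) + if (is.null(conv_part)) 0L else conv_part$l_conv

  # never adopt a multiplex plan that is worse than plain conventional
  full_conv <- schedule_conventional(orders, catalog, matrix)
  if (l_mx > full_conv$l_conv) {
    if (!quiet) mux_log("multiplex_pipeline", "WARN",
                        sprintf("multiplex plan needs %d lumens vs %d conventional; falling back",
                                l_mx, full_conv$l_conv))
    for (v in mux_set) demoted <- rbind(demoted, note(v, "fallback_conventional"))
    return(structure(list(multiplex_lumen_used = FALSE,
                          packets = list(), timeline = NULL,
                          demoted = demoted, conventional_part = full_conv,
                          l_mx = full_conv$l_conv, rates = NULL,
                          separator_ml_per_day = 0, utility = 0,
                          orders = orders),
                     class = "multiplex_result"))
  }

  sep_ml <- if (mux_used) separator_budget(timeline, tube, 24) else 0
  structure(list(multiplex_lumen_used = mux_used,
                 packets = if (mux_used) packets else list(),
                 timeline = timeline,
                 demoted = demoted,
                 conventional_part = conv_part,
                 l_mx = l_mx,
                 rates = rates,
                 separator_ml_per_day = sep_ml,
                 utility = if (mux_used) utility(packets) else 0,
                 orders = orders),
            class = "multiplex_result")
}

#' @export
print.multiplex_result <- function(x, ...) {
  cat(sprintf("<multiplex_result> L_MX = %d (%s multiplex lumen, %d conventional)\n",
              x$l_mx, if (x$multiplex_lumen_used) "1" else "no",
              if (is.null(x$conventional_part)) 0L else x$conventional_part$l_conv))
  if (x$multiplex_lumen_used) {
    cat(sprintf("  %d packet(s), U = %.3f, separator %.0f ml/day\n",
                length(x$packets), x$utility, x$separator_ml_per_day))
    for (p in x$packets) {
      cat(sprintf("  packet {%s}: D %g min, P %g min\n",
                  paste(p$members, collapse = ", "), p$d_total_min, p$period_min))
    }
  }
  if (nrow(x$demoted) > 0) {
    cat("  demoted:", paste(sprintf("%s (%s)", x$demoted$drug, x$demoted$reason),
                            collapse = "; "), "\n")
  }
  invisible(x)
}

#' Compare conventional and multiplex lumen requirements
#'
#' Runs both schedulers on identical orders and reports the lumen counts and
#' their difference `delta_l = l_conv - l_mx` (the number of lumens saved by
#' multiplexing; never negative, see [schedule_multiplex()]).
#'
#' @inheritParams schedule_multiplex
#' @return list with `l_conv`, `l_mx`, `delta_l`.
#' @export
compare_lumens <- function(orders, catalog, matrix, d_drugs = 5, d_sep = 1,
                           tube = tube_spec(), quiet = TRUE) {
  orders <- .as_orders(orders)
  conv <- schedule_conventional(orders, catalog, matrix)
  mx <- schedule_multiplex(orders, catalog, matrix, d_drugs, d_sep, tube,
                           quiet = quiet)
  list(l_conv = conv$l_conv, l_mx = mx$l_mx,
       delta_l = conv$l_conv - mx$l_mx)
}

#' Serialize a multiplex result as a structured key-value document
#'
#' YAML with the packet definitions, utilization, hyperperiod, feasibility,
#' demotions, rates, lumen counts and separator budget. Timelines can
#' additionally be written as delimited text with [write_timeline()].
#'
#' @param result a `multiplex_result`.
#' @param path file path.
#' @export
write_multiplex_result <- function(result, path) {
  doc <- list(
    multiplex_lumen_used = result$multiplex_lumen_used,
    l_mx = result$l_mx,
    utility = result$utility,
    separator_ml_per_day = result$separator_ml_per_day,
    packets = lapply(result$packets, function(p) {
      list(members = as.list(p$members), d_total_min = p$d_total_min,
           t_imax_min = p$t_imax_min, period_min = p$period_min)
    }),
    hyperperiod_min = if (!is.null(result$timeline)) attr(result$timeline, "hyperperiod_min"),
    feasible = if (!is.null(result$timeline)) is_feasible(result$timeline),
    demoted = if (nrow(result$demoted)) {
      lapply(seq_len(nrow(result$demoted)), function(i) {
        list(drug = result$demoted$drug[i], reason = result$demoted$reason[i])
      })
    } else list(),
    conventional_lumens = if (!is.null(result$conventional_part)) {
      lapply(result$conventional_part$lumens, as.list)
    } else list(),
    rates = if (!is.null(result$rates)) {
      lapply(seq_len(nrow(result$rates)), function(i) as.list(result$rates[i, ]))
    } else list())
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
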