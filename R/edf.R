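#' Lumen-time utilization of a packet set
#'
#' `U = sum(D_i / P_i)`: the fraction of lumen time the packets demand.
#' `U <= 1` is necessary for a feasible schedule (the lumen cannot be busy
#' more than all of the time); because scheduling here is non-preemptive it
#' is not by itself sufficient, so [edf_schedule()] additionally reports a
#' feasibility flag.
#'
#' @param packets list of `infusion_packet`s.
#' @return nonnegative numeric; `0` for an empty list.
#' @examples
#' utility(list(packet_dp(2, 3), packet_dp(1, 4))) # 11/12
#' @export
utility <- function(packets) {
  if (length(packets) == 0) return(0)
  sum(vapply(packets, function(p) p$d_total_min / p$period_min, numeric(1)))
}

.gcd2 <- function(a, b) {
  while (b > 0.5) {
    r <- a - floor(a / b) * b
    a <- b
    b <- round(r)
  }
  a
}

#' Hyperperiod of a set of packet periods
#'
#' The least common multiple of the periods, computed exactly after
#' expressing each period as an integer number of resolution ticks
#' (default 1 s; periods of the form `D + T_iMax / 2` with odd integer
#' `T_iMax` are half-minutes, which seconds represent exactly). The schedule
#' repeats after one hyperperiod.
#'
#' @param periods_min nonempty numeric vector of periods in minutes.
#' @param resolution_s tick length in seconds.
#' @return the hyperperiod in minutes.
#' @examples
#' hyperperiod(c(20, 30, 20)) # 60
#' @export
hyperperiod <- function(periods_min, resolution_s = 1) {
  if (length(periods_min) == 0) mux_validation_error("periods must be nonempty")
  ticks <- periods_min * 60 / resolution_s
  if (any(abs(ticks - round(ticks)) > 1e-9) || any(round(ticks) < 1)) {
    mux_error("period not representable at the working resolution", "mux_resolution_error")
  }
  ticks <- round(ticks)
  l <- ticks[1]
  for (t in ticks[-1]) l <- l / .gcd2(l, t) * t
  l * resolution_s / 60
}

#' Non-preemptive earliest-deadline-first timeline
#'
#' Builds the repeating administration timeline for a set of infusion
#' packets. Each packet `i` releases one instance at the start of each of
#' its periods (`k * P_i`) whose deadline is the period's end
#' (`(k + 1) * P_i`). The scheduler is work-conserving and non-preemptive:
#' whenever the lumen is free it runs, to completion, the released
#' not-yet-run instance with the earliest deadline (ties broken by lower
#' packet index).
#'
#' Equal deadlines are resolved in favour of the lower packet index, but a
#' fixed tie-break alone can manufacture deadline misses that another
#' equally valid EDF choice avoids (non-preemptive EDF is optimal among
#' work-conserving schedules only as a class, not per tie-break). Because
#' schedules are computed before execution, the dispatcher therefore
#' backtracks across equal-deadline choices: the returned timeline is the
#' first feasible EDF-consistent schedule in lower-index-first order, and
#' infeasibility is reported only when no tie resolution meets every
#' deadline (the search is capped; instances at the cap are reported
#' infeasible).
#'
#' The timeline covers one hyperperiod when the periods' least common
#' multiple is at most 24 h. Catalog-derived periods are frequently
#' pairwise co-prime in seconds, so the true hyperperiod can exceed any
#' practical horizon; in that case the timeline is built, and feasibility
#' judged, over a 24 h scheduling horizon — the operational horizon after
#' which multiplex schedules are recomputed anyway — and the true
#' hyperperiod is still recorded.
#'
#' @param packets nonempty list of `infusion_packet`s. Callers should
#'   enforce `utility(packets) <= 1` first; if a deadline is still missed
#'   (non-preemptive blocking) the result carries `feasible = FALSE` and the
#'   first violated deadline.
#' @param resolution_s tick length in seconds.
#' @param horizon_cap_min horizon cap in minutes (default 24 h).
#' @param max_nodes search-node cap for tie backtracking.
#' @return an `edf_timeline`: data frame with columns `packet_index`,
#'   `instance` (0-based period repetition), `start_min`, `end_min`, and
#'   attributes `hyperperiod_min`, `horizon_min`, `utility`, `feasible`,
#'   `first_miss`.
#' @export
edf_schedule <- function(packets, resolution_s = 1, horizon_cap_min = 1440,
                         max_nodes = 50000) {
  if (length(packets) == 0) mux_validation_error("packet list is empty")
  u <- utility(packets)
  p_ticks <- vapply(packets, function(p) p$period_min * 60 / resolution_s, numeric(1))
  d_ticks <- vapply(packets, function(p) p$d_total_min * 60 / resolution_s, numeric(1))
  if (any(abs(p_ticks - round(p_ticks)) > 1e-9) ||
      any(abs(d_ticks - round(d_ticks)) > 1e-9)) {
    mux_error("packet timing not representable at the working resolution",
              "mux_resolution_error")
  }
  p_ticks <- round(p_ticks); d_ticks <- round(d_ticks)
  hp_min <- hyperperiod(vapply(packets, `[[`, numeric(1), "period_min"), resolution_s)
  horizon_min <- min(hp_min, horizon_cap_min)
  h_ticks <- round(horizon_min * 60 / resolution_s)
  n <- length(packets)
  n_inst <- pmax(floor(h_ticks / p_ticks), 1)
  total <- sum(n_inst)

  # candidate set at one decision point: released pending instances with the
  # minimal deadline, lower packet index first; idle time is skipped to the
  # next release (work conservation)
  decision <- function(t, done) {
    pending <- which(done < n_inst)
    released <- pending[done[pending] * p_ticks[pending] <= t]
    if (length(released) == 0) {
      t <- min(done[pending] * p_ticks[pending])
      released <- pending[done[pending] * p_ticks[pending] <= t]
    }
    dl <- (done[released] + 1) * p_ticks[released]
    list(t = t, cands = sort(released[dl == min(dl)]))
  }

  # depth-first search over equal-deadline tie choices
  frame_t <- numeric(total + 1)
  frame_cands <- vector("list", total + 1)
  frame_next <- integer(total + 1)
  entry_mat <- matrix(0, total, 4)
  done_stack <- vector("list", total + 1)
  depth <- 1L
  done_stack[[1]] <- integer(n)
  dc <- decision(0, done_stack[[1]])
  frame_t[1] <- dc$t; frame_cands[[1]] <- dc$cands; frame_next[1] <- 1L
  nodes <- 0L
  feasible <- FALSE
  first_miss <- NULL
  while (depth >= 1L) {
    if (depth > total) { feasible <- TRUE; break }
    cands <- frame_cands[[depth]]
    ci <- frame_next[depth]
    if (ci > length(cands) || nodes >= max_nodes) {
      depth <- depth - 1L
      next
    }
    frame_next[depth] <- ci + 1L
    nodes <- nodes + 1L
    j <- cands[ci]
    done <- done_stack[[depth]]
    t <- frame_t[depth]
    deadline <- (done[j] + 1) * p_ticks[j]
    end <- t + d_ticks[j]
    if (end > deadline) {
      if (is.null(first_miss)) {
        first_miss <- list(packet_index = j, instance = done[j],
                           deadline_min = deadline * resolution_s / 60)
      }
      next
    }
    entry_mat[depth, ] <- c(j, done[j], t, end)
    done[j] <- done[j] + 1L
    depth <- depth + 1L
    done_stack[[depth]] <- done
    if (depth <= total) {
      dc <- decision(end, done)
      frame_t[depth] <- dc$t
      frame_cands[[depth]] <- dc$cands
      frame_next[depth] <- 1L
    }
  }
  n_sched <- if (feasible) total else 0L
  tl <- if (n_sched > 0) {
    m <- entry_mat[seq_len(n_sched), , drop = FALSE]
    data.frame(packet_index = as.integer(m[, 1]),
               instance = as.integer(m[, 2]),
               start_min = m[, 3] * resolution_s / 60,
               end_min = m[, 4] * resolution_s / 60)
  } else {
    data.frame(packet_index = integer(0), instance = integer(0),
               start_min = numeric(0), end_min = numeric(0))
  }
  if (feasible) first_miss <- NULL
  structure(tl,
            hyperperiod_min = hp_min,
            horizon_min = horizon_min,
            utility = u,
            feasible = feasible,
            first_miss = first_miss,
            class = c("edf_timeline", "data.frame"))
}

#' Feasibility flag of a timeline
#' @param timeline an `edf_timeline`.
#' @return logical scalar.
#' @export
is_feasible <- function(timeline) isTRUE(attr(timeline, "feasible"))

#' @export
print.edf_timeline <- function(x, ...) {
  cat(sprintf("<edf_timeline> %d run(s), hyperperiod %g min (horizon %g min), U = %.3f, %s\n",
              nrow(x), attr(x, "hyperperiod_min"), attr(x, "horizon_min"),
              attr(x, "utility"),
              if (is_feasible(x)) "feasible" else "INFEASIBLE"))
  print.data.frame(utils::head(as.data.frame(x), 12), ...)
  if (nrow(x) > 12) cat(sprintf("  ... %d more rows\n", nrow(x) - 12))
  invisible(x)
}

#' Serialize / read an EDF timeline
#'
#' Delimited text with columns `packet_index`, `instance`, `start_s`,
#' `end_s` (integer seconds).
#'
#' @param timeline an `edf_timeline`.
#' @param path file path.
#' @export
write_timeline <- function(timeline, path) {
  df <- data.frame(packet_index = timeline$packet_index,
                   instance = timeline$instance,
                   start_s = round(timeline$start_min * 60),
                   end_s = round(timeline$end_min * 60))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(packet_index = df$packet_index, instance = df$instance,
             start_min = df$start_s / 60, end_min = df$end_s / 60)
}
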