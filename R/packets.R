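#' Infusion packets
#'
#' An infusion packet is a set of mutually compatible multiplexable drugs
#' that are administered simultaneously during one multiplex time slot,
#' followed by a separator-fluid flush. Its timing is fully determined by
#' three quantities:
#' \itemize{
#'   \item `d_drugs_min`: the drug administration time per slot (a global run
#'     parameter, default 5 min);
#'   \item `d_sep_min`: the separator flush time (default 1 min);
#'   \item `t_imax_min`: the packet's maximal interruption time, the
#'     smallest `T_iMax` of its member drugs, so every member's constraint
#'     is respected.
#' }
#' The total slot duration is `D = d_drugs + d_sep`, and the repetition
#' period is `P = D + T_iMax / 2`: scheduling each slot anywhere inside its
#' period bounds the gap between consecutive administrations by `2 (P - D) =
#' T_iMax`.
#'
#' @name infusion_packet
NULL

.new_packet <- function(members, d_drugs, d_sep, t_imax) {
  d_total <- d_drugs + d_sep
  p <- structure(list(members = sort(as.character(members)),
                      d_drugs_min = d_drugs,
                      d_sep_min = d_sep,
                      d_total_min = d_total,
                      t_imax_min = t_imax,
                      period_min = d_total + t_imax / 2),
                 class = "infusion_packet")
  p
}

#' Build one infusion packet
#'
#' @param members nonempty character vector of mutually compatible,
#'   multiplexable drug names.
#' @param d_drugs drug administration minutes per slot (> 0).
#' @param d_sep separator flush minutes per slot (> 0).
#' @param catalog a `drug_catalog` supplying each member's `T_iMax`.
#' @param matrix optional `compat_matrix`; when given, member pairwise
#'   compatibility is verified and a violation names the offending pair.
#' @return an `infusion_packet`.
#' @export
make_packet <- function(members, d_drugs, d_sep, catalog, matrix = NULL) {
  members <- unique(as.character(members))
  if (length(members) == 0) mux_validation_error("packet needs at least one drug")
  if (!is.numeric(d_drugs) || d_drugs <= 0) mux_validation_error("d_drugs must be positive")
  if (!is.numeric(d_sep) || d_sep <= 0) mux_validation_error("d_sep must be positive")
  t_vals <- vapply(members, function(d) {
    if (!is_multiplexable(catalog, d)) {
      mux_validation_error(sprintf("drug '%s' is not multiplexable", d))
    }
    catalog_drug(catalog, d)$t_imax_min
  }, numeric(1))
  if (!is.null(matrix)) {
    for (i in seq_along(members)) {
      for (j in seq_len(i - 1)) {
        if (!is_compatible(matrix, members[i], members[j])) {
          mux_validation_error(sprintf("incompatible pair in packet: %s / %s",
                                       members[j], members[i]))
        }
      }
    }
  }
  .new_packet(members, d_drugs, d_sep, min(t_vals))
}

#' Build a packet directly from duration and period
#'
#' Bypasses the catalog: useful for worked examples and for replaying
#' externally supplied packet tables. The implied interruption bound is
#' `2 (P - D)`.
#'
#' @param d_total_min slot duration `D` in minutes (> 0).
#' @param period_min period `P` in minutes (>= `d_total_min`).
#' @param name optional packet label.
#' @return an `infusion_packet`.
#' @export
packet_dp <- function(d_total_min, period_min, name = NULL) {
  if (d_total_min <= 0) mux_validation_error("d_total_min must be positive")
  if (period_min < d_total_min) mux_validation_error("period must be >= duration")
  p <- structure(list(members = as.character(name %||% character(0)),
                      d_drugs_min = NA_real_,
                      d_sep_min = NA_real_,
                      d_total_min = d_total_min,
                      t_imax_min = 2 * (period_min - d_total_min),
                      period_min = period_min),
                 class = "infusion_packet")
  p
}

#' @export
print.infusion_packet <- function(x, ...) {
  cat(sprintf("<infusion_packet> {%s} D = %g min, P = %g min, T_iMax = %g min\n",
              paste(x$members, collapse = ", "),
              x$d_total_min, x$period_min, x$t_imax_min))
  invisible(x)
}

# ---- partitioning -----------------------------------------------------------

# exact minimum clique partition over <= .mux_exact_limit drugs: memoized
# subset recursion over cliques containing the lowest-index vertex; among
# optimal branches prefer the larger, then lexicographically earlier clique.
.mux_exact_limit <- 12L

.cliques_with_min_vertex <- function(adj, set_idx) {
  v <- set_idx[1]
  rest <- set_idx[-1]
  out <- list()
  grow <- function(cur, cand) {
    out[[length(out) + 1]] <<- cur
    for (k in seq_along(cand)) {
      u <- cand[k]
      grow(c(cur, u), cand[cand > u & adj[u, cand]])
    }
  }
  grow(v, rest[adj[v, rest]])
  out
}

.exact_partition <- function(adj) {
  n <- nrow(adj)
  memo <- new.env(parent = emptyenv())
  fcount <- function(set_idx) {
    if (length(set_idx) == 0) return(0L)
    key <- paste(set_idx, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- Inf
    for (q in .cliques_with_min_vertex(adj, set_idx)) {
      best <- min(best, 1L + fcount(setdiff(set_idx, q)))
    }
    memo[[key]] <- best
    best
  }
  reconstruct <- function(set_idx) {
    if (length(set_idx) == 0) return(list())
    target <- fcount(set_idx)
    qs <- .cliques_with_min_vertex(adj, set_idx)
    ord <- order(-vapply(qs, length, integer(1)),
                 vapply(qs, function(q) paste(sprintf("%03d", q), collapse = ""),
                        character(1)))
    for (q in qs[ord]) {
      if (1L + fcount(setdiff(set_idx, q)) == target) {
        return(c(list(q), reconstruct(setdiff(set_idx, q))))
      }
    }
    stop("internal error: partition reconstruction failed") # nocov
  }
  reconstruct(seq_len(n))
}

.greedy_partition <- function(adj, order_idx) {
  groups <- list()
  for (v in order_idx) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (all(adj[v, groups[[k]]])) {
        groups[[k]] <- c(groups[[k]], v)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- v
  }
  groups
}

#' Partition multiplexable drugs into infusion packets
#'
#' Groups the drugs into as few packets as possible subject to pairwise
#' compatibility (fewer packets means fewer separator flushes and lower
#' lumen-time utilization). For up to 12 drugs the minimum clique partition
#' of the compatibility graph is computed exactly (order sets average about
#' three drugs, so this is the usual path); larger sets fall back to a
#' greedy first-fit over drugs sorted by decreasing `T_iMax` (ties
#' alphabetical), which keeps short-`T_iMax` drugs — the ones that dominate a
#' packet's period — in small packets.
#'
#' @param drugs character vector of multiplexable drug names.
#' @param matrix a `compat_matrix`.
#' @param d_drugs,d_sep slot timing parameters in minutes.
#' @param catalog a `drug_catalog`.
#' @return list of `infusion_packet`s partitioning `drugs`.
#' @export
partition_into_packets <- function(drugs, matrix, d_drugs, d_sep, catalog) {
  drugs <- sort(unique(as.character(drugs)))
  if (length(drugs) == 0) return(list())
  for (d in drugs) {
    if (!is_multiplexable(catalog, d)) {
      mux_validation_error(sprintf("drug '%s' is not multiplexable", d))
    }
  }
  n <- length(drugs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- is_compatible(matrix, drugs[i], drugs[j])
    }
  }
  if (n <= .mux_exact_limit) {
    groups <- .exact_partition(adj)
  } else {
    t_vals <- vapply(drugs, function(d) catalog_drug(catalog, d)$t_imax_min, numeric(1))
    ord <- order(-t_vals, drugs)
    groups <- .greedy_partition(adj, ord)
  }
  lapply(groups, function(g) make_packet(drugs[g], d_drugs, d_sep, catalog))
}
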