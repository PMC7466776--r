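# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately brute-force and share no code with the package.

# build a small custom catalog through the public loader
tiny_catalog <- function(drug, t_imax = 30, allowed = "yes", q_max = 100,
                         concentration = 10, category = "other",
                         half_life = 60) {
  df <- data.frame(drug = drug,
                   multiplex_allowed = rep_len(allowed, length(drug)),
                   half_life_min = rep_len(half_life, length(drug)),
                   t_imax_min = rep_len(t_imax, length(drug)),
                   q_max = rep_len(q_max, length(drug)),
                   q_max_unit = "mg/min",
                   concentration = rep_len(concentration, length(drug)),
                   conc_unit = "mg/ml",
                   category = rep_len(category, length(drug)),
                   stringsAsFactors = FALSE)
  df$t_imax_min[df$multiplex_allowed == "no"] <- 0
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  load_catalog(path)
}

# exhaustive minimum clique partition: enumerate partitions by assigning each
# vertex to an existing all-adjacent block or a new block, with pruning
oracle_min_clique_partition <- function(adj) {
  n <- nrow(adj)
  best <- n
  rec <- function(v, blocks) {
    if (length(blocks) >= best) return()
    if (v > n) {
      best <<- min(best, length(blocks))
      return()
    }
    for (k in seq_along(blocks)) {
      if (all(adj[v, blocks[[k]]])) {
        blocks[[k]] <- c(blocks[[k]], v)
        rec(v + 1, blocks)
        blocks[[k]] <- setdiff(blocks[[k]], v)
      }
    }
    rec(v + 1, c(blocks, list(v)))
  }
  rec(1, list())
  best
}

# exhaustive search over work-conserving non-preemptive schedules of periodic
# instances (release k*P, deadline (k+1)*P) over one hyperperiod; TRUE iff any
# ordering meets every deadline
oracle_np_feasible <- function(d, p) {
  lcm2 <- function(a, b) a / pgcd(a, b) * b
  pgcd <- function(a, b) if (b == 0) a else pgcd(b, a %% b)
  H <- Reduce(lcm2, p)
  K <- H / p
  seen <- new.env(parent = emptyenv())
  rec <- function(t, done) {
    if (all(done == K)) return(TRUE)
    key <- paste(t, paste(done, collapse = ","))
    if (!is.null(seen[[key]])) return(seen[[key]])
    pending <- which(done < K)
    released <- pending[done[pending] * p[pending] <= t]
    if (length(released) == 0) {
      res <- rec(min(done[pending] * p[pending]), done)
      seen[[key]] <- res
      return(res)
    }
    res <- FALSE
    for (j in released) {
      end <- t + d[j]
      if (end <= (done[j] + 1) * p[j]) {
        done2 <- done
        done2[j] <- done2[j] + 1
        if (rec(end, done2)) { res <- TRUE; break }
      }
    }
    seen[[key]] <- res
    res
  }
  rec(0, rep(0, length(p)))
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign assignments
# (assumes no zero differences and no ties in |d|)
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  min(p, 1)
}

# first-fit colouring of the incompatibility graph in a given vertex order
oracle_first_fit_lumens <- function(mat, drugs_in_order) {
  lumens <- list()
  for (d in drugs_in_order) {
    placed <- FALSE
    for (k in seq_along(lumens)) {
      if (all(vapply(lumens[[k]], function(o) is_compatible(mat, d, o), logical(1)))) {
        lumens[[k]] <- c(lumens[[k]], d)
        placed <- TRUE
        break
      }
    }
    if (!placed) lumens[[length(lumens) + 1]] <- d
  }
  length(lumens)
}

# maximal gap between consecutive runs of each packet in a timeline; NA when
# a packet ran fewer than twice
timeline_gaps <- function(timeline) {
  vapply(sort(unique(timeline$packet_index)), function(i) {
    runs <- timeline[timeline$packet_index == i, ]
    runs <- runs[order(runs$start_min), ]
    if (nrow(runs) < 2) return(NA_real_)
    max(runs$start_min[-1] - runs$end_min[-nrow(runs)])
  }, numeric(1))
}

# random order sets drawn from a catalog
random_orders <- function(catalog, max_drugs = 6) {
  k <- sample(seq_len(max_drugs), 1)
  infusion_orders(sample(catalog$drug, k), round(stats::runif(k, 0.5, 15), 1))
}
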