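#' Batch-schedule a cohort with both strategies
#'
#' Runs the conventional procedure and the multiplex pipeline on every
#' patient-hour of a cohort and records the lumen counts. Deterministic
#' given its inputs.
#'
#' @param cohort a `mux_cohort` (columns `patient`, `hour`, `drug`,
#'   `q_conv_ml_h`).
#' @param catalog a `drug_catalog`.
#' @param matrix a `compat_matrix`.
#' @param d_drugs,d_sep packet slot timing in minutes.
#' @param tube a `tube_spec`.
#' @return a data frame (class `eval_records`) with one row per
#'   patient-hour: `patient`, `hour`, `n_drugs`, `combo` (sorted drug-name
#'   key), `l_conv`, `l_mx`, `delta_l`, `separator_ml_day`.
#' @export
run_evaluation <- function(cohort, catalog, matrix, d_drugs = 5, d_sep = 1,
                           tube = tube_spec()) {
  if (nrow(cohort) == 0) mux_validation_error("cohort is empty")
  split_key <- interaction(cohort$patient, cohort$hour, drop = TRUE)
  groups <- split(cohort, split_key)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    orders <- infusion_orders(g$drug, g$q_conv_ml_h)
    res <- tryCatch({
      conv <- schedule_conventional(orders, catalog, matrix)
      mx <- schedule_multiplex(orders, catalog, matrix, d_drugs, d_sep, tube,
                               quiet = TRUE)
      list(conv = conv, mx = mx)
    }, mux_error = function(e) {
      mux_error(sprintf("patient %s hour %s: %s", g$patient[1], g$hour[1],
                        conditionMessage(e)), class(e)[1])
    })
    rows[[gi]] <- data.frame(
      patient = g$patient[1], hour = g$hour[1],
      n_drugs = nrow(orders),
      combo = paste(sort(orders$drug), collapse = "|"),
      l_conv = res$conv$l_conv, l_mx = res$mx$l_mx,
      delta_l = res$conv$l_conv - res$mx$l_mx,
      separator_ml_day = res$mx$separator_ml_per_day,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient, out$hour), ]
  rownames(out) <- NULL
  class(out) <- c("eval_records", "data.frame")
  out
}

#' Wilcoxon signed-rank test for paired lumen counts
#'
#' Zero differences are dropped; with 25 or fewer informative pairs and no
#' ties among the absolute differences the exact null distribution
#' ([stats::psignrank]) is used, otherwise the normal approximation with tie
#' correction. Two-sided.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V, the positive-rank sum), `n` informative
#'   pairs, `p_value`, and `method`. Degenerate input (all differences zero)
#'   gives `NA` statistic and p-value.
#' @export
signed_rank_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, n = 0L, p_value = NA_real_,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- any(duplicated(abs(d)))
  if (n <= 25 && !has_ties) {
    p <- 2 * min(stats::psignrank(v, n), 1 - stats::psignrank(v - 1, n))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  list(statistic = v, n = as.integer(n), p_value = p, method = method)
}

#' Summarize a lumen comparison
#'
#' Produces the cohort-level comparison: a per-`l_conv`-level table (count,
#' mean and SD of the number of solutions and of `l_mx`, median and IQR of
#' `l_mx`, frequencies of lumen reductions of 1, 2 and 3 or more, and a
#' per-level signed-rank p-value), the fractions of all and of unique
#' combinations where multiplexing saved at least one lumen, an ordinary
#' least-squares regression of `delta_l` on `l_conv` (with F statistic), and
#' the overall paired signed-rank test.
#'
#' @param records an `eval_records` data frame.
#' @return an `eval_summary` list with elements `per_level`,
#'   `fraction_improved_all`, `fraction_improved_unique`, `regression`,
#'   `paired_test`, `n`.
#' @export
summarize_evaluation <- function(records) {
  if (nrow(records) == 0) mux_validation_error("no evaluation records")
  levels_l <- sort(unique(records$l_conv))
  per_level <- do.call(rbind, lapply(levels_l, function(L) {
    sub <- records[records$l_conv == L, ]
    sr <- signed_rank_test(sub$l_conv, sub$l_mx)
    data.frame(l_conv = L, n = nrow(sub),
               n_drugs_mean = mean(sub$n_drugs), n_drugs_sd = stats::sd(sub$n_drugs),
               l_mx_mean = mean(sub$l_mx), l_mx_sd = stats::sd(sub$l_mx),
               l_mx_median = stats::median(sub$l_mx),
               l_mx_q1 = unname(stats::quantile(sub$l_mx, 0.25)),
               l_mx_q3 = unname(stats::quantile(sub$l_mx, 0.75)),
               dl1 = sum(sub$delta_l == 1), dl2 = sum(sub$delta_l == 2),
               dl3 = sum(sub$delta_l >= 3),
               p_value = sr$p_value)
  }))
  frac_all <- mean(records$delta_l >= 1)
  first_per_combo <- records[!duplicated(records$combo), ]
  frac_unique <- mean(first_per_combo$delta_l >= 1)
  degenerate <- stats::var(records$l_conv) == 0 || stats::var(records$delta_l) == 0
  if (degenerate) {
    regression <- list(intercept = NA_real_, slope = NA_real_,
                       f_statistic = NA_real_, p_value = NA_real_,
                       degenerate = TRUE)
  } else {
    fit <- stats::lm(delta_l ~ l_conv, data = records)
    fs <- summary(fit)$fstatistic
    regression <- list(intercept = unname(stats::coef(fit)[1]),
                       slope = unname(stats::coef(fit)[2]),
                       f_statistic = unname(fs[1]),
                       p_value = unname(stats::pf(fs[1], fs[2], fs[3],
                                                  lower.tail = FALSE)),
                       degenerate = FALSE)
  }
  structure(list(per_level = per_level,
                 fraction_improved_all = frac_all,
                 fraction_improved_unique = frac_unique,
                 regression = regression,
                 paired_test = signed_rank_test(records$l_conv, records$l_mx),
                 n = nrow(records)),
            class = "eval_summary")
}

#' Per-day maxima of hourly lumen counts
#'
#' Aggregates hourly records into 24 h periods per patient, taking the
#' maximum of `l_conv` and of `l_mx` within each period (the number of
#' lumens that must physically be available that day).
#'
#' @param records an `eval_records` data frame.
#' @return data frame with `patient`, `day`, `l_conv_max`, `l_mx_max`.
#' @export
aggregate_daily <- function(records) {
  day <- (records$hour - 1) %/% 24 + 1
  key <- interaction(records$patient, day, drop = TRUE)
  out <- data.frame(
    patient = tapply(records$patient, key, `[`, 1),
    day = tapply(day, key, `[`, 1),
    l_conv_max = tapply(records$l_conv, key, max),
    l_mx_max = tapply(records$l_mx, key, max))
  rownames(out) <- NULL
  out
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> %d patient-hours\n", x$n))
  cat(sprintf("  multiplexing saved >= 1 lumen in %.1f%% of combinations (%.1f%% of unique)\n",
              100 * x$fraction_improved_all, 100 * x$fraction_improved_unique))
  if (!x$regression$degenerate) {
    cat(sprintf("  delta_l = %.3f + %.3f * l_conv (F = %.1f, p = %.3g)\n",
                x$regression$intercept, x$regression$slope,
                x$regression$f_statistic, x$regression$p_value))
  }
  if (!is.na(x$paired_test$p_value)) {
    cat(sprintf("  paired signed-rank: V = %g, n = %d, p = %.3g (%s)\n",
                x$paired_test$statistic, x$paired_test$n, x$paired_test$p_value,
                x$paired_test$method))
  }
  print.data.frame(x$per_level, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize an evaluation summary
#'
#' Writes the per-level table as delimited text (`<path>.csv`) and the whole
#' summary as a structured key-value document (`<path>.yaml`).
#'
#' @param summary an `eval_summary`.
#' @param path base path (extensions are appended).
#' @return invisibly, the two file paths.
#' @export
write_summary <- function(summary, path) {
  csv <- paste0(path, ".csv")
  yml <- paste0(path, ".yaml")
  utils::write.csv(summary$per_level, csv, row.names = FALSE, quote = FALSE)
  doc <- list(n = summary$n,
              fraction_improved_all = summary$fraction_improved_all,
              fraction_improved_unique = summary$fraction_improved_unique,
              regression = summary$regression,
              paired_test = summary$paired_test,
              per_level = lapply(seq_len(nrow(summary$per_level)), function(i) {
                as.list(summary$per_level[i, ])
              }))
  yaml::write_yaml(doc, yml, precision = 15)
  invisible(c(csv, yml))
}
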