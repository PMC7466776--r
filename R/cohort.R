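#' Specification for a synthetic patient-hour cohort
#'
#' Describes a synthetic ICU-like dataset of drug combinations: for every
#' patient-hour, a number of simultaneous continuous IV drugs (targeting the
#' reported ICU mean of 2.8 and SD of 1.6 solutions per patient-hour) drawn
#' from the catalog, with hour-to-hour persistence of running infusions and
#' plausible conventional rates.
#'
#' The per-hour drug count is a rounded normal clamped to
#' `[1, nrow(catalog)]`. Clamping shifts the raw moments, so `mean_drugs`
#' and `sd_drugs` are treated as the *target* moments of the clamped count
#' distribution and the latent normal parameters are solved for numerically
#' (exact discrete moments via the normal CDF); the generator therefore
#' reproduces the requested mean/SD within sampling error.
#'
#' @param n_patients number of synthetic patients.
#' @param hours_per_patient hours recorded per patient.
#' @param mean_drugs target mean simultaneous drugs per patient-hour.
#' @param sd_drugs target SD of that count (0 gives a degenerate constant
#'   count).
#' @param drug_weights named nonnegative sampling weights over catalog
#'   drugs; `NULL` for uniform. See [cohort_weights_preset()] for a skewed
#'   ICU-flavoured preset.
#' @param persistence probability that a running drug continues into the
#'   next hour.
#' @param q_conv_range named list of `c(lo, hi)` ml/h ranges per clinical
#'   category from which conventional rates are drawn (rates are clamped to
#'   the drug's maximal-rate-derived ml/h limit).
#' @param seed integer seed; all randomness flows from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 100, hours_per_patient = 24,
                        mean_drugs = 2.8, sd_drugs = 1.6,
                        drug_weights = NULL, persistence = 0.75,
                        q_conv_range = list(vasoactive = c(0.5, 8),
                                            analgesic_sedative = c(1, 10),
                                            dedicated_lumen = c(0.5, 4),
                                            other = c(1, 6)),
                        seed = 1L) {
  if (n_patients < 1 || hours_per_patient < 1) {
    mux_validation_error("cohort needs at least one patient-hour")
  }
  if (mean_drugs <= 0 || sd_drugs < 0) {
    mux_validation_error("mean_drugs must be positive and sd_drugs nonnegative")
  }
  if (persistence < 0 || persistence > 1) {
    mux_validation_error("persistence must be a probability")
  }
  structure(list(n_patients = as.integer(n_patients),
                 hours_per_patient = as.integer(hours_per_patient),
                 mean_drugs = mean_drugs, sd_drugs = sd_drugs,
                 drug_weights = drug_weights, persistence = persistence,
                 q_conv_range = q_conv_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Skewed drug-sampling weights
#'
#' A synthetic ICU-flavoured preset: vasoactives and analgo-sedation drugs
#' are prescribed more often than the remaining drugs (weight 3 and 2 versus
#' 1). Purely illustrative.
#'
#' @param catalog a `drug_catalog`.
#' @return named numeric weight vector over the catalog's drugs.
#' @export
cohort_weights_preset <- function(catalog) {
  w <- ifelse(catalog$category == "vasoactive", 3,
              ifelse(catalog$category == "analgesic_sedative", 2, 1))
  stats::setNames(w, catalog$drug)
}

# exact pmf of the clamped rounded normal on 1..K
.clamped_count_pmf <- function(mu, sigma, K) {
  k <- seq_len(K)
  upper <- stats::pnorm((k + 0.5 - mu) / sigma)
  lower <- stats::pnorm((k - 0.5 - mu) / sigma)
  p <- upper - lower
  p[1] <- stats::pnorm((1.5 - mu) / sigma)
  p[K] <- 1 - stats::pnorm((K - 0.5 - mu) / sigma)
  p
}

# latent normal parameters whose clamped rounded counts hit the target moments
.calibrate_count <- function(mean_target, sd_target, K) {
  if (sd_target == 0) return(c(mu = mean_target, sigma = 0))
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- .clamped_count_pmf(mu, sigma, K)
    k <- seq_len(K)
    m <- sum(k * p)
    s <- sqrt(max(sum(k^2 * p) - m^2, 0))
    (m - mean_target)^2 + (s - sd_target)^2
  }
  fit <- stats::optim(c(mean_target, log(sd_target)), obj)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate a synthetic patient-hour cohort
#'
#' For every patient-hour the drug count is drawn from the calibrated
#' clamped rounded normal; drugs are sampled without replacement by weight.
#' From one hour to the next, each running drug continues with probability
#' `persistence` (keeping its rate); the set is then reconciled with the
#' hour's drawn count — excess survivors are stopped at random and newly
#' started drugs are added until the count is reached — so the count
#' distribution stays calibrated. With `persistence = 1` and a constant
#' count (`sd_drugs = 0`) a patient's drug set is constant across hours;
#' with `persistence = 0` hours are independent draws. Conventional rates are drawn uniformly from the category's
#' configured range and clamped to the drug's maximal-rate limit.
#'
#' @param spec a `cohort_spec`.
#' @param catalog a `drug_catalog`.
#' @return a data frame (class `mux_cohort`) with columns `patient`, `hour`,
#'   `drug`, `q_conv_ml_h`; one row per drug per patient-hour.
#' @export
generate_cohort <- function(spec, catalog) {
  stopifnot(inherits(spec, "cohort_spec"))
  w <- spec$drug_weights
  if (is.null(w)) {
    w <- stats::setNames(rep(1, nrow(catalog)), catalog$drug)
  }
  unknown <- setdiff(names(w), catalog$drug)
  if (length(unknown) > 0) {
    mux_validation_error(sprintf("weights name drugs absent from the catalog: %s",
                                 paste(unknown, collapse = ", ")))
  }
  if (any(w < 0) || sum(w) <= 0) {
    mux_validation_error("drug weights must be nonnegative with a positive sum")
  }
  pool <- names(w)[w > 0]
  w <- w[pool]
  K <- min(nrow(catalog), length(pool))
  cal <- .calibrate_count(spec$mean_drugs, spec$sd_drugs, K)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  draw_count <- function() {
    if (cal["sigma"] == 0) {
      min(max(round(cal["mu"]), 1), K)
    } else {
      min(max(round(stats::rnorm(1, cal["mu"], cal["sigma"])), 1), K)
    }
  }
  draw_rate <- function(drug) {
    cat_row <- catalog_drug(catalog, drug)
    rng <- spec$q_conv_range[[cat_row$category]] %||% c(1, 10)
    q <- stats::runif(1, rng[1], rng[2])
    if (!is.na(cat_row$q_max_ml_h)) q <- min(q, cat_row$q_max_ml_h)
    round(q, 1)
  }
  top_up <- function(current, target) {
    need <- target - length(current)
    if (need <= 0) return(character(0))
    avail <- setdiff(pool, current)
    if (length(avail) == 0) return(character(0))
    need <- min(need, length(avail))
    sample(avail, need, prob = w[avail])
  }

  rows <- vector("list", spec$n_patients * spec$hours_per_patient)
  ri <- 0
  for (pt in seq_len(spec$n_patients)) {
    running <- character(0)
    rates <- numeric(0)
    for (h in seq_len(spec$hours_per_patient)) {
      if (h == 1) {
        running <- top_up(character(0), draw_count())
        rates <- stats::setNames(vapply(running, draw_rate, numeric(1)), running)
      } else {
        keep <- running[stats::runif(length(running)) < spec$persistence]
        n_h <- draw_count()
        if (length(keep) > n_h) {       # count target forces extra stops
          keep <- keep[sort(sample.int(length(keep), n_h))]
        }
        rates <- rates[keep]
        newcomers <- top_up(keep, n_h)
        running <- c(keep, newcomers)
        if (length(newcomers) > 0) {
          rates <- c(rates, stats::setNames(
            vapply(newcomers, draw_rate, numeric(1)), newcomers))
        }
      }
      ri <- ri + 1
      rows[[ri]] <- data.frame(patient = pt, hour = h, drug = running,
                               q_conv_ml_h = unname(rates[running]),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  class(out) <- c("mux_cohort", "data.frame")
  out
}

#' Per patient-hour drug counts of a cohort
#'
#' @param cohort a `mux_cohort`.
#' @return integer vector, one entry per patient-hour.
#' @export
cohort_counts <- function(cohort) {
  as.integer(tapply(cohort$drug, interaction(cohort$patient, cohort$hour, drop = TRUE),
                    length))
}

#' Number of unique drug combinations in a cohort
#'
#' A combination is the unordered set of drug names in one patient-hour
#' (rates ignored).
#'
#' @param cohort a `mux_cohort`.
#' @return integer count of distinct combinations.
#' @export
count_unique_combinations <- function(cohort) {
  keys <- tapply(cohort$drug, interaction(cohort$patient, cohort$hour, drop = TRUE),
                 function(d) paste(sort(d), collapse = "|"))
  length(unique(keys))
}

#' Serialize / read a cohort
#'
#' Delimited text with columns `patient`, `hour`, `drug`, `q_conv_ml_h`.
#'
#' @param cohort a `mux_cohort`.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("mux_cohort", "data.frame")
  out
}
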