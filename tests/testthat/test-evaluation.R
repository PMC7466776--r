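hand_records <- function(l_conv, l_mx) {
  out <- data.frame(patient = seq_along(l_conv), hour = 1,
                    n_drugs = l_conv + 1,
                    combo = paste0("set", seq_along(l_conv)),
                    l_conv = l_conv, l_mx = l_mx, delta_l = l_conv - l_mx,
                    separator_ml_day = 0)
  class(out) <- c("eval_records", "data.frame")
  out
}

test_that("a single-drug hour yields the trivial record", {
  cat_ <- default_catalog()
  m <- default_compat()
  co <- data.frame(patient = 1, hour = 1, drug = "propofol", q_conv_ml_h = 5)
  class(co) <- c("mux_cohort", "data.frame")
  rec <- run_evaluation(co, cat_, m)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$l_conv, 1)
  expect_equal(rec$l_mx, 1)
  expect_equal(rec$delta_l, 0)
})

test_that("records match manual pipeline traces on a hand-built cohort", {
  # drugA/drugB incompatible multiplexables, norepi-like drug non-multiplexable
  drugs <- c("drugA", "drugB", "presser")
  cat_ <- tiny_catalog(drugs, t_imax = c(30, 30, 0), allowed = c("yes", "yes", "no"),
                       category = c("other", "other", "vasoactive"))
  m <- compat_matrix(drugs, matrix(c(TRUE, FALSE, TRUE,
                                     FALSE, TRUE, TRUE,
                                     TRUE, TRUE, TRUE), 3, byrow = TRUE))
  co <- data.frame(
    patient = c(1, 1, 1, 1, 1, 2),
    hour = c(1, 1, 2, 2, 2, 1),
    drug = c("drugA", "drugB", "drugA", "drugB", "presser", "presser"),
    q_conv_ml_h = 5)
  class(co) <- c("mux_cohort", "data.frame")
  rec <- run_evaluation(co, cat_, m)
  rec <- rec[order(rec$patient, rec$hour), ]
  # hour 1: A,B incompatible -> conv 2 lumens; multiplex packs both on 1
  expect_equal(rec$l_conv, c(2, 3, 1))
  expect_equal(rec$l_mx, c(1, 2, 1))
  expect_equal(rec$delta_l, c(1, 1, 0))
  expect_equal(rec$n_drugs, c(2, 3, 1))
})

test_that("the per-level summary tallies reductions by hand", {
  rec <- hand_records(c(2, 2, 3, 3), c(1, 2, 2, 1))
  s <- summarize_evaluation(rec)
  lvl2 <- s$per_level[s$per_level$l_conv == 2, ]
  lvl3 <- s$per_level[s$per_level$l_conv == 3, ]
  expect_equal(lvl2$n, 2)
  expect_equal(lvl2$dl1, 1)
  expect_equal(lvl2$dl2, 0)
  expect_equal(lvl3$dl1, 1)
  expect_equal(lvl3$dl2, 1)
  expect_equal(s$fraction_improved_all, 3 / 4)
  expect_equal(lvl2$l_mx_mean, 1.5)
  expect_equal(lvl3$l_mx_median, 1.5)
})

test_that("degenerate comparisons summarize without error", {
  rec <- hand_records(rep(1, 6), rep(1, 6))
  s <- summarize_evaluation(rec)
  expect_equal(s$per_level$l_mx_mean, 1)
  expect_equal(s$per_level$dl1 + s$per_level$dl2 + s$per_level$dl3, 0)
  expect_true(s$regression$degenerate)
  expect_true(is.na(s$paired_test$p_value))
  expect_equal(s$fraction_improved_all, 0)
})

test_that("the regression matches the closed-form least-squares solution", {
  rec <- hand_records(c(1, 2, 2, 3, 4, 4), c(1, 1, 2, 2, 2, 3))
  s <- summarize_evaluation(rec)
  x <- rec$l_conv; y <- rec$delta_l
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(s$regression$slope, slope)
  expect_equal(s$regression$intercept, intercept)
  # F = t^2 for simple regression; cross-check against anova
  fit <- stats::lm(y ~ x)
  expect_equal(s$regression$f_statistic, stats::anova(fit)[1, "F value"])
})

test_that("the signed-rank test matches exact enumeration and the normal form", {
  set.seed(101)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    d <- round(stats::runif(n, 0.05, 4), 3) * sample(c(-1, 1), n, TRUE)
    x <- d; y <- rep(0, n)
    got <- signed_rank_test(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_signed_rank_p(d), info = paste(d, collapse = ","))
  }
  # tied integer differences route through the normal approximation and
  # agree with the reference implementation without continuity correction
  x <- c(3, 2, 4, 2, 3, 5, 2, 4, 3, 2, 5, 4, 3, 3, 2, 4, 5, 2, 3, 4, 2, 3, 4, 5, 2, 3)
  y <- c(2, 2, 2, 1, 3, 3, 1, 2, 2, 2, 3, 3, 2, 2, 1, 3, 3, 2, 2, 3, 1, 2, 3, 3, 2, 2)
  got <- signed_rank_test(x, y)
  expect_equal(got$method, "normal_approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                             correct = FALSE))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$statistic, unname(ref$statistic))
  # all-zero differences are degenerate, not an error
  z <- signed_rank_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(z$p_value))
})

test_that("daily aggregation takes per-day maxima", {
  rec <- hand_records(c(1, 3, 2), c(1, 2, 2))
  rec$patient <- c(1, 1, 1)
  rec$hour <- c(1, 13, 30)
  agg <- aggregate_daily(rec)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$l_conv_max, c(3, 2))
  expect_equal(agg$l_mx_max, c(2, 2))
})

test_that("summaries serialize to delimited text and key-value form", {
  rec <- hand_records(c(2, 2, 3, 3), c(1, 2, 2, 1))
  s <- summarize_evaluation(rec)
  base <- tempfile()
  write_summary(s, base)
  csv <- utils::read.csv(paste0(base, ".csv"))
  expect_equal(nrow(csv), nrow(s$per_level))
  doc <- yaml::read_yaml(paste0(base, ".yaml"))
  expect_equal(doc$fraction_improved_all, 0.75)
})
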