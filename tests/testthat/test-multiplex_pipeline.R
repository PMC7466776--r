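two_incompatible <- function() {
  cat_ <- tiny_catalog(c("drugA", "drugB"), t_imax = 30)
  none <- generate_random_matrix(c("drugA", "drugB"), 0, seed = 1)
  list(catalog = cat_, matrix = none,
       orders = infusion_orders(c("drugA", "drugB"), 5))
}

test_that("a single non-multiplexable drug needs one conventional lumen", {
  cat_ <- default_catalog()
  m <- default_compat()
  res <- schedule_multiplex("norepinephrine/noradrenalin", cat_, m, quiet = TRUE)
  expect_false(res$multiplex_lumen_used)
  expect_equal(res$l_mx, 1)
  expect_equal(res$demoted$reason, "not_multiplexable")
  expect_null(res$timeline)
})

test_that("four compatible multiplexable drugs share one multiplex lumen", {
  drugs <- paste0("d", 1:4)
  cat_ <- tiny_catalog(drugs, t_imax = 60)
  full <- generate_random_matrix(drugs, 1, seed = 1)
  res <- schedule_multiplex(infusion_orders(drugs, 5), cat_, full, quiet = TRUE)
  expect_true(res$multiplex_lumen_used)
  expect_length(res$packets, 1)
  expect_equal(res$l_mx, 1)
  expect_lt(res$utility, 1)
  expect_equal(nrow(res$demoted), 0)
})

test_that("two incompatible multiplexables alternate over a single lumen", {
  fix <- two_incompatible()
  res <- schedule_multiplex(fix$orders, fix$catalog, fix$matrix, quiet = TRUE)
  expect_true(res$multiplex_lumen_used)
  expect_length(res$packets, 2)
  for (p in res$packets) {
    expect_equal(p$d_total_min, 6)
    expect_equal(p$period_min, 21)
  }
  expect_equal(res$utility, 12 / 21)
  expect_equal(res$l_mx, 1)
  cmp <- compare_lumens(fix$orders, fix$catalog, fix$matrix)
  expect_equal(cmp, list(l_conv = 2, l_mx = 1, delta_l = 1))
})

test_that("utility overload demotes the smallest-interruption-time drug", {
  # three mutually incompatible drugs with tight interruption times:
  # three singleton packets of U = 6/P each; the smallest T_iMax goes first
  drugs <- c("shorty", "mid", "longy")
  cat_ <- tiny_catalog(drugs, t_imax = c(4, 10, 20))
  none <- generate_random_matrix(drugs, 0, seed = 1)
  # U = 6/8 + 6/11 + 6/16 = 1.67 > 1 -> demote shorty (T 4); then
  # U = 6/11 + 6/16 = 0.92 <= 1
  res <- schedule_multiplex(infusion_orders(drugs, 1), cat_, none, quiet = TRUE)
  expect_true("shorty" %in% res$demoted$drug)
  expect_equal(res$demoted$reason[res$demoted$drug == "shorty"], "utility_exceeded")
  expect_setequal(unlist(lapply(res$packets, `[[`, "members")), c("mid", "longy"))
  expect_lte(res$utility, 1)
})

test_that("rate violations demote the offending drug and reschedule", {
  # greedy limit: 1 mg/min at 1 mg/ml = 60 ml/h; conventional 30 ml/h in a
  # shared packet -> available 14.29 min/h -> q_mx 126 ml/h > limit
  drugs <- c("hungry", "calm")
  cat_ <- tiny_catalog(drugs, t_imax = 30, q_max = c(1, 1000))
  none <- generate_random_matrix(drugs, 0, seed = 1)
  res <- schedule_multiplex(infusion_orders(drugs, c(30, 2)), cat_, none,
                            quiet = TRUE)
  expect_true("hungry" %in% res$demoted$drug)
  reasons <- res$demoted$reason[res$demoted$drug == "hungry"]
  expect_true(any(reasons %in% c("rate_exceeded", "fallback_conventional")))
  if (res$multiplex_lumen_used) {
    expect_true(all(res$rates$within_limit))
  }
  expect_lte(res$l_mx,
             schedule_conventional(infusion_orders(drugs, c(30, 2)), cat_, none)$l_conv)
})

test_that("every input drug lands exactly once in a packet or in demotion", {
  cat_ <- default_catalog()
  m <- default_compat()
  set.seed(83)
  for (rep in 1:40) {
    orders <- random_orders(cat_)
    res <- schedule_multiplex(orders, cat_, m, quiet = TRUE)
    in_packets <- unlist(lapply(res$packets, `[[`, "members"))
    placed <- c(in_packets, unique(res$demoted$drug))
    expect_setequal(placed, orders$drug)
    expect_equal(length(in_packets) + length(unique(res$demoted$drug)),
                 nrow(orders))
    # demoted drugs reappear in the conventional part
    if (nrow(res$demoted) > 0) {
      expect_setequal(unlist(res$conventional_part$lumens), unique(res$demoted$drug))
    }
    expect_equal(res$l_mx, as.integer(res$multiplex_lumen_used) +
                   (if (is.null(res$conventional_part)) 0L
                    else res$conventional_part$l_conv))
  }
})

test_that("interruption gaps in emitted timelines never exceed T_iMax", {
  cat_ <- default_catalog()
  m <- default_compat()
  set.seed(89)
  checked <- 0
  for (rep in 1:60) {
    orders <- random_orders(cat_)
    res <- schedule_multiplex(orders, cat_, m, quiet = TRUE)
    if (is.null(res$timeline) || length(res$packets) == 0) next
    gaps <- timeline_gaps(res$timeline)
    for (i in seq_along(res$packets)) {
      if (is.na(gaps[i])) next
      checked <- checked + 1
      expect_lte(gaps[i], res$packets[[i]]$t_imax_min + 1e-9)
      # and therefore every member drug's own bound
      member_t <- vapply(res$packets[[i]]$members,
                         function(d) catalog_drug(cat_, d)$t_imax_min, numeric(1))
      expect_true(all(gaps[i] <= member_t + 1e-9))
    }
  }
  expect_gt(checked, 10)
})

test_that("identical inputs give identical results", {
  cat_ <- default_catalog()
  m <- default_compat()
  orders <- infusion_orders(c("propofol", "vancomycin", "midazolam", "insulin"),
                            c(10, 8, 3, 2))
  a <- schedule_multiplex(orders, cat_, m, quiet = TRUE)
  b <- schedule_multiplex(orders, cat_, m, quiet = TRUE)
  expect_equal(a, b)
})

test_that("single-drug comparisons never improve", {
  cat_ <- default_catalog()
  m <- default_compat()
  for (d in c("propofol", "insulin", "norepinephrine/noradrenalin")) {
    cmp <- compare_lumens(infusion_orders(d, 5), cat_, m)
    expect_equal(cmp$l_conv, 1)
    expect_equal(cmp$delta_l, 0)
  }
})

test_that("multiplex results serialize to a key-value document", {
  fix <- two_incompatible()
  res <- schedule_multiplex(fix$orders, fix$catalog, fix$matrix, quiet = TRUE)
  f <- tempfile(fileext = ".yaml")
  write_multiplex_result(res, f)
  doc <- yaml::read_yaml(f)
  expect_true(doc$multiplex_lumen_used)
  expect_equal(doc$l_mx, 1)
  expect_length(doc$packets, 2)
  expect_equal(doc$utility, 12 / 21, tolerance = 1e-12)
})
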