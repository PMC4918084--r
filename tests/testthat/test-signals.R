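test_that("hypergeometric upper tail matches enumeration and edge cases", {
  expect_identical(hypergeom_upper_tail(0, 5, 5, 20), 1)
  expect_equal(hypergeom_upper_tail(2, 5, 5, 20), hyper_tail_enum(2, 5, 5, 20),
               tolerance = 1e-12)
  expect_equal(hyper_tail_enum(2, 5, 5, 20), 0.3661, tolerance = 1e-4)
  # m = s = a: only the all-success draw contributes
  expect_equal(hypergeom_upper_tail(4, 4, 4, 12),
               choose(4, 4) / choose(12, 4), tolerance = 1e-15)
  expect_equal(hypergeom_upper_tail(4, 4, 4, 12), hyper_tail_enum(4, 4, 4, 12))
  # validation
  expect_error(hypergeom_upper_tail(6, 5, 5, 20), "min\\(a, s\\)")
  expect_error(hypergeom_upper_tail(1, 5, 25, 20), "exceed n")
  expect_error(hypergeom_upper_tail(-1, 5, 5, 20), "non-negative")
  expect_error(hypergeom_upper_tail(1.5, 5, 5, 20), "integer")
})

test_that("extreme tails keep precision (survival computation)", {
  p <- hypergeom_upper_tail(95, 100, 100, 10000)
  expect_gt(p, 0)
  expect_lt(p, 1e-100)
  expect_equal(log(p), log(hyper_tail_enum(95, 100, 100, 10000)),
               tolerance = 1e-9)
})

test_that("conditional p-value is structurally the same hypergeometric test", {
  expect_identical(conditional_p(0, 5, 5, 20), 1)
  expect_equal(conditional_p(2, 5, 5, 20), hypergeom_upper_tail(2, 5, 5, 20))
  expect_error(conditional_p(1, 5, 5, 0), "a_y")
  expect_error(conditional_p(1, 5, 0, 20), "a_xy")
  expect_error(conditional_p(6, 5, 7, 20), "m_xy")
  # ancestor conditioning: when the reference says x always rides with y,
  # observing them together in every draw is unsurprising
  expect_identical(conditional_p(12, 12, 30, 30), 1)
  expect_equal(conditional_p(12, 12, 30, 30), hyper_tail_enum(12, 12, 30, 30))
})

test_that("adjusted p-values keep raw when no eligible partner exists", {
  fx <- dependency_fixture()
  soi <- build_set_of_interest("DRUGX", fx$pairs, fx$level)
  # single enriched term: nothing to condition on
  single <- adjusted_pvalues(c(X = 0.001), soi, fx$stats)
  expect_identical(single, c(X = 0.001))
  # a partner with zero reference co-frequency is ineligible
  stats2 <- fx$stats
  raw <- c(X = 0.001, Q = 0.002)
  soi2 <- soi
  soi2$event_counts <- c(soi$event_counts, Q = 3L)
  soi2$event_articles$Q <- c("R0001", "R0002", "R0003")
  expect_identical(unname(adjusted_pvalues(raw, soi2, stats2)["Q"]), 0.002)
})

test_that("a redundant parent is suppressed while the child survives", {
  fx <- dependency_fixture()
  res <- detect_signals(fx$pairs, fx$stats, fx$level, method = "gea")
  res_x <- res[res$term == "X", ]
  res_p <- res[res$term == "P", ]
  # both raw p-values are tiny: 20 of 20 articles carry each term
  expect_lt(res_x$raw_p, 1e-10)
  expect_lt(res_p$raw_p, 1e-10)
  # child: conditioning on the parent leaves it surprising
  expect_lt(res_x$adjusted_p, 0.005)
  expect_true(res_x$signal_0.005)
  # parent: the reference says it always accompanies the child (a_xy = a_x),
  # so its joint count is fully explained and its adjusted p saturates
  expect_identical(res_p$adjusted_p, 1)
  expect_false(res_p$signal_0.1)
  # max rule invariant
  expect_true(all(res$adjusted_p >= res$raw_p))
  # oracle for the child's conditional: pop a(P)=200, succ a_xy=50, draws 20
  expect_equal(res_x$adjusted_p,
               max(res_x$raw_p, hyper_tail_enum(20, 20, 50, 200)))
})

test_that("PRR follows the contingency formula with zero-cell correction", {
  flat <- prr(5, 45, 10, 90)
  expect_equal(flat$prr, 1)
  expect_equal(prr(5, 95, 10, 890)$prr, 4.5)
  corrected <- prr(2, 8, 0, 90)
  expect_equal(corrected$cells, c(a = 2.5, b = 8.5, c = 0.5, d = 90.5))
  expect_equal(corrected$prr, (2.5 / 11) / (0.5 / 91), tolerance = 1e-12)
  expect_equal(corrected$prr, 41.36, tolerance = 1e-3)
  # 95% CI: log-scale Wald interval, symmetric around log(PRR)
  est <- prr(5, 95, 10, 890)
  se <- sqrt(1 / 5 - 1 / 100 + 1 / 10 - 1 / 900)
  expect_equal(est$ci_low, exp(log(4.5) - 1.96 * se))
  expect_equal(est$ci_high, exp(log(4.5) + 1.96 * se))
  expect_lt(est$ci_low, est$prr)
  expect_gt(est$ci_high, est$prr)
  expect_error(prr(-1, 2, 3, 4), "non-negative")
})

test_that("PRR is invariant under cell scaling and its CI narrows", {
  set.seed(42)
  for (i in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    p1 <- prr(cells[1], cells[2], cells[3], cells[4])
    p5 <- prr(5 * cells[1], 5 * cells[2], 5 * cells[3], 5 * cells[4])
    expect_equal(p5$prr, p1$prr, tolerance = 1e-12)
    expect_lt(p5$ci_high - p5$ci_low, p1$ci_high - p1$ci_low)
  }
})

test_that("detect_signals orders, flags and nests thresholds monotonely", {
  run <- run_synthetic_pipeline(3, cfg = planted_config(3, n_planted = 3))
  gea <- run$gea
  expect_true(all(diff(order(gea$subject, gea$adjusted_p, gea$term)) > 0))
  expect_true(all(gea$adjusted_p >= gea$raw_p))
  expect_gte(sum(gea$signal_0.1), sum(gea$signal_0.05))
  expect_gte(sum(gea$signal_0.05), sum(gea$signal_0.005))
  prr_res <- run$prr
  expect_gte(sum(prr_res$signal_1), sum(prr_res$signal_1.5))
  expect_gte(sum(prr_res$signal_1.5), sum(prr_res$signal_5))
  # a subject absent from the candidate pairs yields zero rows
  expect_identical(nrow(detect_signals(run$pairs, run$stats, run$level,
                                       subjects = "NOSUCH", method = "gea")), 0L)
})

test_that("planted associations dominate both GEA and PRR rankings", {
  run <- run_synthetic_pipeline(5, cfg = planted_config(5, n_planted = 3))
  mesh_to_ing <- stats::setNames(run$map$ingredient_id, run$map$mesh_drug_id)
  for (i in seq_len(nrow(run$truth))) {
    ing <- mesh_to_ing[[run$truth$drug[i]]]
    reps <- map_outcome_to_level(run$truth$event[i], run$level)
    sub <- run$gea[run$gea$subject == ing, ]
    expect_identical(sub$term[1], reps[1])  # ranked first
    expect_lt(sub$adjusted_p[1], 0.005)
    psub <- run$prr[run$prr$subject == ing & run$prr$term %in% reps, ]
    expect_gt(max(psub$prr), 5)
  }
})

test_that("class-level PRR counts articles of member vs other drugs", {
  run <- run_synthetic_pipeline(9, cfg = planted_config(9, n_planted = 2))
  cls <- drug_to_classes("ING001", run$map)[1]
  res <- detect_signals(run$pairs, run$stats, run$level, subjects = cls,
                        method = "prr", map = run$map, subject_type = "class")
  expect_true(nrow(res) > 0)
  members <- class_members(cls, run$map)
  member_articles <- unique(run$pairs$article_id[run$pairs$drug %in% members])
  other_articles <- setdiff(unique(run$pairs$article_id[!run$pairs$drug %in% members]),
                            member_articles)
  expect_identical(unique(res$a + res$b), length(member_articles))
  expect_identical(unique(res$c + res$d), length(other_articles))
})
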