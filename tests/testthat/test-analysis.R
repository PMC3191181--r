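test_that("ICER division and undefined flag", {
  expect_equal(compute_icer(-2719, 0.095), -2719 / 0.095)  # ~ -28621
  expect_equal(compute_icer(-2719, 0.095), -28621.05, tolerance = 1e-6)
  expect_equal(compute_icer(0, 0.3), 0)
  expect_true(is.na(compute_icer(100, 0)))
})

test_that("strategy evaluation is deterministic with sane magnitudes and
           definitional identities", {
  ps <- base_ps
  r1 <- evaluate_strategy("treat_all", ps, base_dem)
  r2 <- evaluate_strategy("treat_all", ps, base_dem)
  expect_equal(r1, r2)
  expect_gt(r1$discounted_cost, 0)
  expect_gt(r1$discounted_qalys, 0)
  expect_lt(r1$discounted_qalys, 50)
  expect_lte(r1$discounted_qalys, r1$undiscounted_lys)

  # utilities 1 and no effect discounting collapse QALYs onto life years
  ps2 <- ps
  ps2$u_diabetes <- 1; ps2$u_esrd <- 1; ps2$r_effect <- 0
  r3 <- evaluate_strategy("screen_micro", ps2, default_demography(ps2))
  expect_equal(r3$discounted_qalys, r3$undiscounted_lys, tolerance = 1e-9)

  # harsher effect discounting strictly lowers discounted QALYs
  ps4 <- set_parameter(ps, "r_effect", 0.04)
  r4 <- evaluate_strategy("treat_all", ps4, base_dem)
  expect_lt(r4$discounted_qalys, r1$discounted_qalys)
})

test_that("strict dominance labelling on constructed instances", {
  res <- data.frame(strategy = c("A", "B"),
                    cost = c(10, 20), qalys = c(2, 1))
  cmp <- compare_strategies(res, reference = "A")
  tab <- cmp$table
  expect_equal(tab$status[tab$strategy == "B"], "dominated")
  expect_equal(tab$status[tab$strategy == "A"], "dominant")
  expect_equal(tab$label[tab$strategy == "B"], "dominated")

  tie <- data.frame(strategy = c("A", "B"),
                    cost = c(10, 10), qalys = c(2, 2))
  cmpt <- compare_strategies(tie, reference = "A")
  expect_false(any(cmpt$table$status == "dominated"))
  expect_true(is.na(cmpt$table$icer_vs_ref[cmpt$table$strategy == "B"]))

  expect_error(compare_strategies(res[1, , drop = FALSE]), "at least two")
  expect_error(compare_strategies(rbind(res, res)), "duplicate")
  expect_error(compare_strategies(res, reference = "Z"), "reference")
})

test_that("extended dominance removes frontier members with decreasing
           downstream ICERs", {
  # B lies above the A-C segment: ICER(A->B) > ICER(B->C)
  res <- data.frame(strategy = c("A", "B", "C"),
                    cost = c(0, 100, 120), qalys = c(0, 0.5, 2))
  cmp <- compare_strategies(res, reference = "A")
  expect_equal(cmp$table$status[cmp$table$strategy == "B"], "ext_dominated")
  expect_equal(cmp$frontier$strategy, c("A", "C"))
  expect_equal(cmp$frontier$icer_vs_previous[2], 120 / 2)
})

test_that("dominance classification agrees with an exhaustive pairwise
           oracle on random instances", {
  set.seed(77)
  for (rep in 1:1000) {
    res <- data.frame(strategy = c("A", "B", "C"),
                      cost = round(stats::runif(3, 0, 100), 1),
                      qalys = round(stats::runif(3, 0, 10), 2))
    if (anyDuplicated(res$cost)) next
    cmp <- compare_strategies(res, reference = "A")
    tab <- cmp$table[match(res$strategy, cmp$table$strategy), ]
    expect_equal(tab$status == "dominated", dominance_oracle(res))
  }
})

test_that("negative ICERs with QALY gains are presented as dominance, never
           as a bare ratio", {
  res <- data.frame(strategy = c("ref", "new"),
                    cost = c(100, 50), qalys = c(1, 2))
  cmp <- compare_strategies(res, reference = "ref")
  lab <- cmp$table$label[cmp$table$strategy == "new"]
  expect_equal(lab, "dominant")
  # machine output still retains the raw ratio
  expect_equal(cmp$table$icer_vs_ref[cmp$table$strategy == "new"], -50)
})

test_that("with no treatment effect and a perfect test, all strategies give
           identical life years and QALYs", {
  ps <- base_ps
  ps$rr_nm <- 1; ps$rr_mM <- 1; ps$rr_ME <- 1; ps$spec_micro <- 1
  res <- evaluate_strategies(ps, base_dem, strategy_set = strategies())
  expect_lt(diff(range(res$qalys)), 1e-9)
  expect_lt(diff(range(res$lys)), 1e-9)
  # strategies then differ only through drug and screening spending
  expect_gt(diff(range(res$cost)), 0)
})

test_that("weakening treatment never raises treat-all QALYs", {
  ps <- base_ps
  qaly_at <- function(rr_name, v) {
    ps2 <- set_parameter(ps, rr_name, v)
    evaluate_strategy("treat_all", ps2, base_dem)$discounted_qalys
  }
  for (rr_name in c("rr_nm", "rr_mM", "rr_ME")) {
    grid <- c(0.3, 0.5, 0.7, 0.9, 1.0)
    q <- vapply(grid, function(v) qaly_at(rr_name, v), numeric(1))
    expect_true(all(diff(q) <= 1e-12))
  }
})

test_that("one-way sensitivity analysis emits a row per bound and collapses
           to the base case on degenerate ranges", {
  ps <- base_ps
  rng <- data.frame(name = c("u_esrd", "c_esrd_override"),
                    low = c(0.62, 42110), high = c(0.62, 42110))
  sa <- univariate_sa(ps, rng, base_dem)
  expect_equal(nrow(sa), 4)
  a <- evaluate_strategy("treat_all", ps, base_dem)
  b <- evaluate_strategy("screen_micro", ps, base_dem)
  expect_equal(sa$delta_cost,
               rep(a$discounted_cost - b$discounted_cost, 4),
               tolerance = 1e-9)
  expect_error(univariate_sa(ps, data.frame(name = "zz", low = 1, high = 2),
                             base_dem), "unknown parameter")
})

test_that("sensitivity rows move in the analytically expected directions", {
  ps <- base_ps
  rng <- default_ranges()
  sa <- univariate_sa(ps, rng, base_dem)
  row <- function(p, b) sa[sa$parameter == p & sa$bound == b, ]
  # higher cost discounting shrinks the (negative) incremental cost
  expect_gt(row("r_cost", "higher")$delta_cost, row("r_cost", "lower")$delta_cost)
  expect_lt(abs(row("r_cost", "higher")$delta_cost),
            abs(row("r_cost", "lower")$delta_cost))
  # higher effect discounting shrinks the incremental QALYs
  expect_lt(row("r_effect", "higher")$delta_qalys,
            row("r_effect", "lower")$delta_qalys)
  # a costlier ESRD state makes treating everyone save more
  expect_lt(row("c_esrd_override", "higher")$delta_cost,
            row("c_esrd_override", "lower")$delta_cost)
})

test_that("breakeven drug cost exceeds the base case, rises with the ESRD
           cost, and flags impossible savings", {
  ps <- base_ps
  thr <- threshold_drug_cost(ps, base_dem)
  expect_gt(thr, 62.70)
  # at the breakeven, incremental cost vanishes
  ps2 <- ps; ps2$c_drug_mixed <- thr
  a <- evaluate_strategy("treat_all", ps2, base_dem)
  b <- evaluate_strategy("screen_micro", ps2, base_dem)
  expect_lt(abs(a$discounted_cost - b$discounted_cost), 1)

  ps_hi <- set_parameter(ps, "c_esrd_override", 50532)
  expect_gt(threshold_drug_cost(ps_hi, base_dem), thr)

  # savings impossible: no disease progression and free ESRD
  ps0 <- frozen_params(ps)
  ps0$c_esrd_override <- 0
  expect_warning(thr0 <- threshold_drug_cost(ps0, default_demography(ps0)),
                 "no breakeven")
  expect_true(is.na(thr0))
})
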