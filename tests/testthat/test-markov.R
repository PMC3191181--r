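test_that("constant-hazard annualisation matches the closed form", {
  expect_equal(annual_prob_from_cumulative(0.5, 10), 1 - 0.5^0.1,
               tolerance = 1e-12)
  expect_equal(annual_prob_from_cumulative(0.5, 10), 0.06697, tolerance = 1e-4)
  p <- c(0.1, 0.37, 0.9)
  expect_equal(annual_prob_from_cumulative(p, 1), p)
  expect_equal(annual_prob_from_cumulative(0, 25), 0)
  expect_error(annual_prob_from_cumulative(1, 10), "cum_prob")
  expect_error(annual_prob_from_cumulative(0.5, 0), "years")
})

test_that("discounting follows (1+r)^-cycle", {
  expect_equal(discount_factor(0.04, 0), 1)
  expect_equal(discount_factor(0.04, 1), 1 / 1.04)
  expect_equal(discount_factor(0, 0:30), rep(1, 31))
  expect_error(discount_factor(-0.01, 1), "rate")
})

test_that("transition matrices are row-stochastic, keep death absorbing and
           never skip a disease stage", {
  ps <- base_ps
  for (strategy in strategies()) {
    for (age in c(50, 75, 98)) {
      m <- build_transition_matrix(age, strategy, ps, base_lt)
      expect_equal(unname(rowSums(m)), rep(1, 8), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(unname(m["DEAD", ]), c(rep(0, 7), 1))
      # no stage-skipping: normo never reaches macro/ESRD in one cycle,
      # micro never reaches ESRD
      expect_equal(unname(m[c("NORMO_U", "NORMO_T"),
                            c("MACRO_U", "MACRO_T", "ESRD")]),
                   matrix(0, 2, 3))
      expect_equal(unname(m[c("MICRO_U", "MICRO_T"), "ESRD"]), c(0, 0))
      # therapy is one-way: no _T compartment flows back to _U
      expect_equal(sum(m[c("NORMO_T", "MICRO_T", "MACRO_T"),
                         c("NORMO_U", "MICRO_U", "MACRO_U")]), 0)
    }
  }
  expect_error(build_transition_matrix(50, "bogus", ps, base_lt),
               "unknown strategy")
})

test_that("treated progression entries equal q * RR on the survivor mass", {
  ps <- base_ps
  m <- build_transition_matrix(60, "treat_all", ps, base_lt)
  live <- 1 - diabetic_death_prob(60, base_lt, ps$smr)
  # macro -> ESRD on therapy: 0.056 * 0.61 = 0.03416 before survival
  expect_equal(m["MACRO_T", "ESRD"] / live, 0.056 * 0.61, tolerance = 1e-12)
  expect_equal(m["NORMO_T", "MICRO_T"] / live, ps$q_nm * ps$rr_nm,
               tolerance = 1e-12)
  m0 <- build_transition_matrix(60, "no_intervention", ps, base_lt)
  expect_equal(m0["NORMO_U", "MICRO_U"] / live, ps$q_nm, tolerance = 1e-12)
})

test_that("screening strategies route detected and false-positive patients
           onto therapy", {
  ps <- base_ps
  ps$spec_micro <- 0.9
  live <- 1 - diabetic_death_prob(55, base_lt, ps$smr)
  m <- build_transition_matrix(55, "screen_micro", ps, base_lt)
  # detected microalbuminuric patients progress at treated rates into _T
  expect_equal(m["MICRO_U", "MACRO_T"] / live, ps$q_mM * ps$rr_mM,
               tolerance = 1e-12)
  expect_equal(sum(m["MICRO_U", c("MICRO_U", "MACRO_U")]), 0)
  # false positives: 10% of surviving normo start therapy
  expect_equal((m["NORMO_U", "NORMO_T"] + m["NORMO_U", "MICRO_T"]) / live,
               0.1, tolerance = 1e-12)
  # under macro screening, normo and micro stay untreated
  m2 <- build_transition_matrix(55, "screen_macro", ps, base_lt)
  expect_equal(sum(m2[c("NORMO_U", "MICRO_U"),
                      c("NORMO_T", "MICRO_T", "MACRO_T")]), 0)
  expect_equal(m2["MACRO_U", "ESRD"] / live, ps$q_ME * ps$rr_ME,
               tolerance = 1e-12)
})

test_that("cohort trace conserves probability, keeps death monotone and
           matches a step-by-step matrix-product oracle", {
  ps <- base_ps
  for (strategy in c("treat_all", "screen_micro", "no_intervention")) {
    tr <- run_cohort(strategy, ps, base_lt)
    expect_equal(nrow(tr), ps$age_end - ps$age_entry + 1)
    expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-9)
    expect_true(all(diff(tr[, "DEAD"]) >= 0))

    v <- initial_occupancy(strategy, ps)
    for (k in seq_len(nrow(tr) - 1)) {
      v <- as.numeric(v %*% build_transition_matrix(ps$age_entry + k - 1,
                                                    strategy, ps, base_lt))
      expect_equal(unname(tr[k + 1, ]), v, tolerance = 1e-12)
    }
  }
})

test_that("initial occupancy places prevalences untreated, or treated under
           treat-all; _T stays empty without treatment edges", {
  ps <- base_ps
  v <- initial_occupancy("screen_micro", ps)
  expect_equal(unname(v[c("NORMO_U", "MICRO_U", "MACRO_U")]),
               c(0.79, 0.18, 0.03))
  vt <- initial_occupancy("treat_all", ps)
  expect_equal(unname(vt[c("NORMO_T", "MICRO_T", "MACRO_T")]),
               c(0.79, 0.18, 0.03))
  tr <- run_cohort("no_intervention", ps, base_lt)
  expect_equal(sum(tr[, c("NORMO_T", "MICRO_T", "MACRO_T")]), 0)
})

test_that("identity dynamics freeze the occupancy", {
  ps <- frozen_params()
  lt0 <- flat_life_table(0)
  tr <- run_cohort("no_intervention", ps, lt0)
  for (k in seq_len(nrow(tr)))
    expect_equal(unname(tr[k, ]), unname(tr[1, ]), tolerance = 1e-12)
})

test_that("half-cycle-corrected accumulation matches hand results and the
           annuity closed form", {
  # occupancy 1 in one alive compartment over 3 boundaries, utility 1,
  # no discounting -> 0.5 + 1 + 0.5 = 2 life years
  occ <- matrix(0, 3, 8, dimnames = list(NULL, compartments()))
  occ[, "NORMO_U"] <- 1
  attr(occ, "ages") <- 50:52
  class(occ) <- c("nephro_trace", class(occ))
  unit <- function(age) list(cost = rep(0, 8),
                             utility = as.numeric(compartments() == "NORMO_U"))
  res <- accumulate_outcomes(occ, unit, r_cost = 0, r_effect = 0, label = "x")
  expect_equal(res$undiscounted_lys, 2)
  expect_equal(res$discounted_qalys, 2)

  # all mass dead -> zero everything
  occ2 <- matrix(0, 4, 8, dimnames = list(NULL, compartments()))
  occ2[, "DEAD"] <- 1
  attr(occ2, "ages") <- 50:53
  class(occ2) <- c("nephro_trace", class(occ2))
  pay <- function(age) list(cost = rep(100, 8), utility = rep(0.9, 8) *
                              as.numeric(compartments() != "DEAD"))
  res2 <- accumulate_outcomes(occ2, function(a)
    list(cost = rep(100, 8) * as.numeric(compartments() != "DEAD"),
         utility = rep(0.9, 8) * as.numeric(compartments() != "DEAD")),
    0.04, 0.015, label = "x")
  expect_equal(res2$discounted_cost, 0)
  expect_equal(res2$discounted_qalys, 0)
  expect_equal(res2$undiscounted_lys, 0)

  # constant alive payoff pi: discounted total = pi * sum w(c) (1+r)^-c
  n <- 11
  occ3 <- matrix(0, n, 8, dimnames = list(NULL, compartments()))
  occ3[, "ESRD"] <- 1
  attr(occ3, "ages") <- seq(50, length.out = n)
  class(occ3) <- c("nephro_trace", class(occ3))
  pi_c <- 250
  r <- 0.05
  res3 <- accumulate_outcomes(occ3, function(a)
    list(cost = pi_c * as.numeric(compartments() == "ESRD"),
         utility = rep(0, 8)), r_cost = r, r_effect = 0, label = "x")
  w <- rep(1, n); w[c(1, n)] <- 0.5
  expect_equal(res3$discounted_cost,
               pi_c * sum(w * (1 + r)^-(0:(n - 1))), tolerance = 1e-12)
  # rates 0, N+1 boundaries -> N * pi
  res4 <- accumulate_outcomes(occ3, function(a)
    list(cost = pi_c * as.numeric(compartments() == "ESRD"),
         utility = rep(0, 8)), 0, 0, label = "x")
  expect_equal(res4$discounted_cost, (n - 1) * pi_c)
})

test_that("accumulation equals an independent brute-force summation on
           random traces", {
  set.seed(421)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    tr <- random_trace(n)
    pays <- lapply(seq_len(n), function(k) {
      list(cost = stats::runif(8, 0, 5000) *
             as.numeric(compartments() != "DEAD"),
           utility = stats::runif(8) *
             as.numeric(compartments() != "DEAD"))
    })
    r_c <- stats::runif(1, 0, 0.1)
    r_e <- stats::runif(1, 0, 0.1)
    res <- accumulate_outcomes(tr, pays, r_c, r_e, label = "x")
    oracle <- brute_force_outcomes(tr, pays, r_c, r_e)
    expect_equal(res$discounted_cost, oracle$cost, tolerance = 1e-9)
    expect_equal(res$discounted_qalys, oracle$qaly, tolerance = 1e-9)
    expect_equal(res$undiscounted_lys, oracle$ly, tolerance = 1e-9)
  }
})

test_that("trace exports carry cycles, ages and 5-state projections", {
  tr <- run_cohort("screen_micro", base_ps, base_lt)
  df <- as.data.frame(tr)
  expect_equal(df$cycle, 0:(nrow(df) - 1))
  expect_equal(df$age, 50:99)
  expect_equal(df$NORMO, df$NORMO_U + df$NORMO_T)
  expect_equal(rowSums(df[, c("NORMO", "MICRO", "MACRO", "ESRD", "DEAD")]),
               rep(1, nrow(df)), tolerance = 1e-9)
})
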