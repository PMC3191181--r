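# Compartment layout. The model's five health states (normo-, micro-,
# macroalbuminuria, ESRD, death) are split into treated (_T) / untreated
# (_U) compartments for the albuminuria stages so each screening strategy
# can track who is on therapy; _U/_T pairs project back onto the five
# states for reporting.
COMPARTMENTS <- c("NORMO_U", "NORMO_T", "MICRO_U", "MICRO_T",
                  "MACRO_U", "MACRO_T", "ESRD", "DEAD")

# 5-state projection used for reporting and strategy-equivalence checks
STATE_OF <- c(NORMO_U = "NORMO", NORMO_T = "NORMO",
              MICRO_U = "MICRO", MICRO_T = "MICRO",
              MACRO_U = "MACRO", MACRO_T = "MACRO",
              ESRD = "ESRD", DEAD = "DEAD")

#' Model compartments and strategies
#'
#' `compartments()` returns the eight compartment labels (treated/untreated
#' split of the three albuminuria stages, plus ESRD and death);
#' `strategies()` the four strategy identifiers: treat everyone at
#' diagnosis, screen annually for microalbuminuria, screen annually for
#' macroalbuminuria, or neither screen nor treat.
#'
#' @return A character vector.
#' @export
compartments <- function() COMPARTMENTS

#' @rdname compartments
#' @export
strategies <- function() {
  c("treat_all", "screen_micro", "screen_macro", "no_intervention")
}

#' Convert a cumulative event probability to an annual probability
#'
#' Assumes a constant hazard over the observation period, so the
#' complement survival decays exponentially: the annual probability is
#' `1 - (1 - cum_prob)^(1/years)`.
#'
#' @param cum_prob Cumulative probability over the whole period, in `[0, 1)`.
#' @param years Length of the period (> 0).
#' @return Annual transition probability.
#' @export
#' @examples
#' annual_prob_from_cumulative(0.5, 10)
annual_prob_from_cumulative <- function(cum_prob, years) {
  if (any(cum_prob < 0 | cum_prob >= 1))
    stop("cum_prob must lie in [0, 1)", call. = FALSE)
  if (any(years <= 0)) stop("years must be > 0", call. = FALSE)
  1 - (1 - cum_prob)^(1 / years)
}

#' Discount factor for a cycle
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index (0 = entry).
#' @return `(1 + rate)^(-cycle)`.
#' @export
discount_factor <- function(rate, cycle) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  (1 + rate)^(-cycle)
}

# Probability that an untreated occupant of a disease stage is switched to
# therapy at the start of a cycle, per strategy. Detection by screening is
# assumed perfect for the targeted stage (test sensitivity 1); under
# microalbuminuria screening a false-positive normoalbuminuric patient is
# started on therapy with probability 1 - specificity per annual screen,
# and macroalbuminuric patients are detected too (their excretion exceeds
# the micro threshold).
treatment_entry_probs <- function(strategy, ps) {
  switch(strategy,
    treat_all       = c(NORMO = 1, MICRO = 1, MACRO = 1),
    screen_micro    = c(NORMO = 1 - ps$spec_micro, MICRO = 1, MACRO = 1),
    screen_macro    = c(NORMO = 0, MICRO = 0, MACRO = 1),
    no_intervention = c(NORMO = 0, MICRO = 0, MACRO = 0),
    stop("unknown strategy: ", strategy, call. = FALSE)
  )
}

#' Build the one-cycle transition matrix at an age under a strategy
#'
#' Death is applied first as a competing risk: occupants of the albuminuria
#' compartments die with the age-specific diabetic probability
#' `min(1, smr * q(age))`; survivors then progress one stage with the
#' annual probability `q` (untreated) or `q * RR` (on therapy). Strategy
#' determines who enters therapy at cycle start (see Details); once on
#' therapy a patient never returns to an untreated compartment. ESRD
#' occupants die with `max(q_esrd_death, smr * q(age))` -- the
#' registry-derived ESRD rate floored at the age-matched diabetic
#' background mortality, so ESRD never confers a survival advantage at high
#' ages. Disease stages are never skipped within a cycle.
#'
#' @details Therapy-entry edges per strategy: `treat_all` converts every
#' untreated disease compartment; `screen_micro` converts micro- (and
#' macro-)albuminuric patients on detection and normoalbuminuric patients
#' with probability `1 - spec_micro` per annual screen (false positives);
#' `screen_macro` converts macroalbuminuric patients only;
#' `no_intervention` converts no one.
#'
#' @param age Age at the start of the cycle (within the life table).
#' @param strategy One of [strategies()].
#' @param ps A `nephro_params` object.
#' @param lt A `nephro_life_table`.
#' @return An 8x8 row-stochastic matrix over [compartments()].
#' @export
build_transition_matrix <- function(age, strategy, ps, lt) {
  f <- treatment_entry_probs(strategy, ps)
  qd <- diabetic_death_prob(age, lt, ps$smr)
  q_esrd <- max(ps$q_esrd_death, qd)

  m <- matrix(0, 8, 8, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  stages <- list(
    NORMO = list(q = ps$q_nm, rr = ps$rr_nm, nxt = "MICRO"),
    MICRO = list(q = ps$q_mM, rr = ps$rr_mM, nxt = "MACRO"),
    MACRO = list(q = ps$q_ME, rr = ps$rr_ME, nxt = "ESRD")
  )
  dest <- function(stage, treated) {
    if (stage == "ESRD") "ESRD" else paste0(stage, if (treated) "_T" else "_U")
  }
  for (stage in names(stages)) {
    s <- stages[[stage]]
    pt <- s$q * s$rr   # annual progression on therapy
    pu <- s$q          # annual progression untreated

    # untreated compartment: possible therapy entry at cycle start
    u <- paste0(stage, "_U")
    m[u, "DEAD"] <- qd
    live <- 1 - qd
    m[u, dest(s$nxt, TRUE)]  <- m[u, dest(s$nxt, TRUE)]  + live * f[[stage]] * pt
    m[u, dest(stage, TRUE)]  <- m[u, dest(stage, TRUE)]  + live * f[[stage]] * (1 - pt)
    m[u, dest(s$nxt, FALSE)] <- m[u, dest(s$nxt, FALSE)] + live * (1 - f[[stage]]) * pu
    m[u, dest(stage, FALSE)] <- m[u, dest(stage, FALSE)] + live * (1 - f[[stage]]) * (1 - pu)

    # treated compartment: stays treated
    tr <- paste0(stage, "_T")
    m[tr, "DEAD"] <- qd
    m[tr, dest(s$nxt, TRUE)] <- m[tr, dest(s$nxt, TRUE)] + live * pt
    m[tr, dest(stage, TRUE)] <- m[tr, dest(stage, TRUE)] + live * (1 - pt)
  }
  m["ESRD", "DEAD"] <- q_esrd
  m["ESRD", "ESRD"] <- 1 - q_esrd
  m["DEAD", "DEAD"] <- 1
  m
}

#' Initial compartment occupancy for a strategy
#'
#' Initial albuminuria prevalences are placed in the untreated
#' compartments, except under `treat_all` where therapy starts at diagnosis
#' and the cohort enters the treated compartments directly.
#'
#' @param strategy One of [strategies()].
#' @param ps A `nephro_params` object.
#' @return A named occupancy vector over [compartments()] summing to 1.
#' @export
initial_occupancy <- function(strategy, ps) {
  treatment_entry_probs(strategy, ps)  # validates the strategy name
  v <- stats::setNames(numeric(8), COMPARTMENTS)
  suffix <- if (strategy == "treat_all") "_T" else "_U"
  v[paste0("NORMO", suffix)] <- ps$prev_normo
  v[paste0("MICRO", suffix)] <- ps$prev_micro
  v[paste0("MACRO", suffix)] <- ps$prev_macro
  v
}

#' Run the cohort through the model horizon
#'
#' Propagates the initial occupancy through the per-age transition matrices
#' from the entry age to the final modelled age (one-year cycles; age at
#' cycle `c` is `age_entry + c`). The trace has one row per cycle boundary.
#'
#' @param strategy One of [strategies()].
#' @param ps A `nephro_params` object.
#' @param lt A `nephro_life_table` covering `[age_entry, age_end]`.
#' @return A `nephro_trace`: a numeric matrix with one row per cycle
#'   boundary (0 to `age_end - age_entry`) and one column per compartment,
#'   with attributes `ages` and `strategy`.
#' @export
#' @examples
#' tr <- run_cohort("treat_all", default_parameters(), default_life_table())
#' tail(tr[, "DEAD"], 1)  # cohort extinction at the final boundary
run_cohort <- function(strategy, ps, lt) {
  viol <- validate_parameters(ps)
  if (length(viol))
    stop("invalid parameters: ", paste(viol, collapse = "; "), call. = FALSE)
  ages <- seq.int(ps$age_entry, ps$age_end)
  n_cycles <- length(ages) - 1
  trace <- matrix(0, n_cycles + 1, 8,
                  dimnames = list(NULL, COMPARTMENTS))
  trace[1, ] <- initial_occupancy(strategy, ps)
  for (k in seq_len(n_cycles)) {
    m <- build_transition_matrix(ages[k], strategy, ps, lt)
    trace[k + 1, ] <- trace[k, ] %*% m
  }
  attr(trace, "ages") <- ages
  attr(trace, "strategy") <- strategy
  class(trace) <- c("nephro_trace", class(trace))
  trace
}

#' Project a trace onto the five health states
#'
#' Merges the treated/untreated compartment pairs, yielding occupancy over
#' normo-, micro-, macroalbuminuria, ESRD and death.
#'
#' @param trace A `nephro_trace`.
#' @return A matrix with columns `NORMO`, `MICRO`, `MACRO`, `ESRD`, `DEAD`.
#' @export
project_states <- function(trace) {
  states <- c("NORMO", "MICRO", "MACRO", "ESRD", "DEAD")
  out <- sapply(states, function(s)
    rowSums(unclass(trace)[, STATE_OF == s, drop = FALSE]))
  colnames(out) <- states
  out
}

#' Export a trace as a data frame
#'
#' One row per cycle boundary, with the cycle index, age, the eight
#' compartment occupancies and the five-state projections.
#'
#' @param x A `nephro_trace`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.nephro_trace <- function(x, ...) {
  ages <- attr(x, "ages")
  cbind(data.frame(cycle = seq_along(ages) - 1L, age = ages),
        as.data.frame(unclass(x)),
        as.data.frame(project_states(x)))
}

#' Accumulate discounted costs, QALYs and life years over a trace
#'
#' Each cycle boundary contributes occupancy-weighted annual payoffs,
#' discounted to entry and weighted by the half-cycle (trapezoid) rule:
#' weight 0.5 at the first and last boundary, 1 elsewhere, reflecting
#' transitions occurring midway through each 12-month cycle. Costs are
#' discounted at `r_cost`, QALYs at `r_effect`; life years (utility 1 for
#' every alive compartment) are reported undiscounted.
#'
#' @param trace A `nephro_trace`.
#' @param payoffs A function of age returning a list with numeric vectors
#'   `cost` and `utility` over [compartments()] (see
#'   [compartment_payoffs()]), or a list of such payoff lists, one per
#'   cycle boundary.
#' @param r_cost,r_effect Annual discount rates.
#' @param label Strategy label carried into the result.
#' @return A `nephro_ce` list: `label`, `discounted_cost`,
#'   `discounted_qalys`, `undiscounted_lys`.
#' @export
accumulate_outcomes <- function(trace, payoffs, r_cost, r_effect,
                                label = attr(trace, "strategy")) {
  ages <- attr(trace, "ages")
  n <- length(ages)
  if (is.function(payoffs)) {
    payoffs <- lapply(ages, payoffs)
  }
  if (length(payoffs) != n)
    stop("payoffs must cover every cycle boundary (need ", n, ", got ",
         length(payoffs), ")", call. = FALSE)
  w <- rep(1, n)
  w[c(1, n)] <- 0.5
  cycles <- seq_len(n) - 1
  alive <- as.numeric(COMPARTMENTS != "DEAD")
  occ <- unclass(trace)

  per_cycle <- function(values_at, rate) {
    contrib <- vapply(seq_len(n), function(k)
      sum(occ[k, ] * values_at(k)), numeric(1))
    sum(w * discount_factor(rate, cycles) * contrib)
  }
  res <- list(
    label = label,
    discounted_cost = per_cycle(function(k) payoffs[[k]]$cost, r_cost),
    discounted_qalys = per_cycle(function(k) payoffs[[k]]$utility, r_effect),
    undiscounted_lys = per_cycle(function(k) alive, 0)
  )
  class(res) <- "nephro_ce"
  res
}

#' @export
print.nephro_ce <- function(x, ...) {
  cat(sprintf("<nephro_ce> %s: cost %.2f euros, %.4f QALYs (discounted), %.4f LYs\n",
              x$label, x$discounted_cost, x$discounted_qalys,
              x$undiscounted_lys))
  invisible(x)
}
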