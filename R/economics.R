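#' Prevalence-weighted annual cost of dialysis
#'
#' The annual dialysis cost is the convex combination of the three modality
#' costs: `beta1*x1 + beta2*x2 + beta3*x3`.
#'
#' @param inputs An [esrd_cost_inputs()] object.
#' @return Euros/year.
#' @export
#' @examples
#' weighted_dialysis_cost(esrd_cost_inputs())
weighted_dialysis_cost <- function(inputs) {
  inputs$beta1 * inputs$x1 + inputs$beta2 * inputs$x2 + inputs$beta3 * inputs$x3
}

#' Annual cost of the ESRD state
#'
#' Mixes dialysis and transplantation by the proportion `p` of the ESRD
#' population on dialysis: `p * X + (1 - p) * Y`, with `X` the weighted
#' dialysis cost and `Y` the annualised transplant cost.
#'
#' @param inputs An [esrd_cost_inputs()] object.
#' @return Euros/year.
#' @export
#' @examples
#' esrd_annual_cost(esrd_cost_inputs())
esrd_annual_cost <- function(inputs) {
  inputs$p * weighted_dialysis_cost(inputs) + (1 - inputs$p) * inputs$y
}

#' Annual cost of mixed ACE-inhibitor/ARB therapy
#'
#' Average annual drug cost when a fraction of patients (those with
#' ACE-inhibitor-induced cough) receive the more expensive ARB instead.
#'
#' @param ace_annual Annual ACE-inhibitor cost (euros/year).
#' @param arb_annual Annual ARB cost (euros/year).
#' @param arb_rate Proportion treated with an ARB, in `[0, 1]`.
#' @return `(1 - arb_rate) * ace_annual + arb_rate * arb_annual`.
#' @export
mixed_drug_cost <- function(ace_annual, arb_annual, arb_rate) {
  if (any(ace_annual < 0) || any(arb_annual < 0))
    stop("drug costs must be >= 0", call. = FALSE)
  if (any(arb_rate < 0 | arb_rate > 1))
    stop("arb_rate must be in [0, 1]", call. = FALSE)
  (1 - arb_rate) * ace_annual + arb_rate * arb_annual
}

# Untreated compartments screened annually under each strategy (the
# detection stage's own _U compartment is screened too: that screen is the
# one that detects its occupants).
screened_compartments <- function(strategy) {
  switch(strategy,
    screen_micro = c("NORMO_U", "MICRO_U"),
    screen_macro = c("NORMO_U", "MICRO_U", "MACRO_U"),
    treat_all = character(),
    no_intervention = character(),
    stop("unknown strategy: ", strategy, call. = FALSE)
  )
}

#' Per-compartment annual costs and utilities at an age
#'
#' Utilities: untreated and treated albuminuria compartments carry the
#' diabetes baseline utility (times the treatment multiplier when on
#' therapy), ESRD its own utility, death 0. Costs: every alive compartment
#' accrues the age-dependent background health-care expenditure; albuminuria
#' compartments additionally the diabetes excess cost; treated compartments
#' the annual drug cost; compartments still being screened the strategy's
#' per-test cost; ESRD the ESRD state cost (added to background expenditure
#' by default, replacing it when `esrd_cost_replaces_background` is set).
#' Drug, screening and excess-diabetes costs never accrue in ESRD.
#'
#' @param age Age (years) within the expenditure curve's span.
#' @param strategy One of [strategies()].
#' @param ps A `nephro_params` object.
#' @param curve A `nephro_expenditure` object.
#' @return A list with numeric vectors `cost` and `utility` over
#'   [compartments()].
#' @export
#' @examples
#' pv <- compartment_payoffs(50, "treat_all", default_parameters(),
#'                           expenditure_curve(default_parameters()))
#' pv$utility[["ESRD"]]
compartment_payoffs <- function(age, strategy, ps, curve) {
  screened <- screened_compartments(strategy)
  comps <- compartments()
  u <- stats::setNames(numeric(8), comps)
  u[c("NORMO_U", "MICRO_U", "MACRO_U")] <- ps$u_diabetes
  u[c("NORMO_T", "MICRO_T", "MACRO_T")] <- ps$u_diabetes * ps$u_treat_mult
  u["ESRD"] <- ps$u_esrd

  background <- expenditure_at_age(age, curve)
  cost <- stats::setNames(numeric(8), comps)
  alive <- comps != "DEAD"
  cost[alive] <- background
  nonesrd <- setdiff(comps[alive], "ESRD")
  cost[nonesrd] <- cost[nonesrd] + ps$c_diabetes_excess
  cost[c("NORMO_T", "MICRO_T", "MACRO_T")] <-
    cost[c("NORMO_T", "MICRO_T", "MACRO_T")] + ps$c_drug_mixed
  screen_fee <- switch(strategy,
                       screen_micro = ps$c_screen_micro,
                       screen_macro = ps$c_screen_macro, 0)
  cost[screened] <- cost[screened] + screen_fee
  cost["ESRD"] <- if (isTRUE(ps$esrd_cost_replaces_background))
    ps$c_esrd_override else background + ps$c_esrd_override
  list(cost = cost, utility = u)
}

#' Audit table of cost components per age and strategy
#'
#' Expands [compartment_payoffs()] over a span of ages so every cost and
#' utility entering the model can be inspected, alongside the aggregated
#' dialysis and ESRD figures.
#'
#' @param strategy One of [strategies()].
#' @param ps A `nephro_params` object.
#' @param curve A `nephro_expenditure` object.
#' @param ages Ages to tabulate (default: the full model span).
#' @return A data frame with one row per (age, compartment).
#' @export
payoff_audit <- function(strategy, ps, curve,
                         ages = seq.int(ps$age_entry, ps$age_end)) {
  rows <- lapply(ages, function(a) {
    pv <- compartment_payoffs(a, strategy, ps, curve)
    data.frame(age = a, strategy = strategy, compartment = compartments(),
               cost = unname(pv$cost), utility = unname(pv$utility))
  })
  out <- do.call(rbind, rows)
  attr(out, "dialysis_cost_X") <- weighted_dialysis_cost(ps$esrd_costs)
  attr(out, "esrd_cost_formula") <- esrd_annual_cost(ps$esrd_costs)
  attr(out, "esrd_cost_charged") <- ps$c_esrd_override
  out
}
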