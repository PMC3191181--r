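#' Inputs for the annual cost of end-stage renal disease
#'
#' Bundles the components from which the annual per-patient cost of
#' end-stage renal disease (ESRD) is assembled: the prevalence weights and
#' annual costs of the three dialysis modalities, the proportion of the
#' ESRD population on dialysis, and the annualised cost of living with a
#' kidney transplant.
#'
#' @param beta1,beta2,beta3 Prevalence weights of home/in-centre
#'   haemodialysis, continuous ambulatory peritoneal dialysis and continuous
#'   cycling peritoneal dialysis; must sum to 1.
#' @param x1,x2,x3 Annual cost of each dialysis modality (euros/year).
#' @param p Proportion of the ESRD population treated with dialysis (the
#'   remainder live with a functioning transplant).
#' @param y Annual cost of renal transplantation (euros/year), averaged over
#'   an assumed graft survival.
#'
#' @return An object of class `esrd_cost_inputs` (a named list).
#' @seealso [weighted_dialysis_cost()], [esrd_annual_cost()]
#' @export
#' @examples
#' esrd_cost_inputs()
esrd_cost_inputs <- function(beta1 = 0.82, beta2 = 0.106, beta3 = 0.074,
                             x1 = 83217, x2 = 54067, x3 = 69546,
                             p = 0.43, y = 14387) {
  out <- list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
              x1 = x1, x2 = x2, x3 = x3, p = p, y = y)
  class(out) <- "esrd_cost_inputs"
  viol <- validate_esrd_cost_inputs(out)
  if (length(viol)) stop("invalid ESRD cost inputs: ",
                         paste(viol, collapse = "; "), call. = FALSE)
  out
}

validate_esrd_cost_inputs <- function(x) {
  v <- character()
  num <- vapply(x, function(e) is.numeric(e) && length(e) == 1 && is.finite(e),
                logical(1))
  if (!all(num)) {
    return(paste0(names(x)[!num], ": must be a finite number"))
  }
  if (abs(x$beta1 + x$beta2 + x$beta3 - 1) > 1e-9)
    v <- c(v, "beta1+beta2+beta3: must sum to 1")
  for (f in c("beta1", "beta2", "beta3", "x1", "x2", "x3", "y"))
    if (x[[f]] < 0) v <- c(v, paste0(f, ": must be >= 0"))
  if (x$p < 0 || x$p > 1) v <- c(v, "p: must be in [0, 1]")
  v
}

#' Base-case model parameters
#'
#' Returns the full base-case parameter set of the nephropathy
#' cost-effectiveness model: initial albuminuria prevalences at diagnosis,
#' annual untreated transition probabilities, relative risks of progression
#' under ACE-inhibitor/ARB therapy, mortality inputs, utilities, costs,
#' screening characteristics and discount rates. All monetary values are
#' 2010 euros.
#'
#' @details
#' Fields (units in parentheses):
#' \describe{
#'   \item{prev_normo, prev_micro, prev_macro}{initial prevalence of normo-,
#'     micro- and macroalbuminuria at diagnosis; sum to 1.}
#'   \item{q_nm, q_mM, q_ME}{annual untreated transition probabilities
#'     normo->micro, micro->macro, macro->ESRD.}
#'   \item{rr_nm, rr_mM, rr_ME}{relative risks of those transitions under
#'     therapy.}
#'   \item{smr}{standardised mortality ratio of diabetic patients versus the
#'     general population.}
#'   \item{q_esrd_death}{annual death probability in ESRD (registry-derived;
#'     the engine floors it at the age-specific diabetic mortality, see
#'     [build_transition_matrix()]).}
#'   \item{u_diabetes, u_esrd}{annual utilities of diabetes without ESRD and
#'     of ESRD.}
#'   \item{u_treat_mult}{multiplier on `u_diabetes` while on therapy.}
#'   \item{c_drug_mixed}{annual cost of the ACE-inhibitor/ARB mix
#'     (euros/year), taken as printed rather than recomputed from
#'     `c_ace`/`c_arb` (the fee/VAT allocation behind the printed figure is
#'     not reconstructible; the components are kept for scenarios).}
#'   \item{c_ace, c_arb}{annual ex-factory drug costs (euros/year).}
#'   \item{arb_rate}{proportion of treated patients on an ARB.}
#'   \item{c_screen_micro, c_screen_macro}{per-test screening costs (euros).}
#'   \item{esrd_costs}{an [esrd_cost_inputs()] object.}
#'   \item{c_esrd_override}{annual cost charged to the ESRD state
#'     (euros/year); the published headline figure, which
#'     [esrd_annual_cost()] reproduces to within rounding.}
#'   \item{c_diabetes_excess}{annual excess cost of diabetes over the
#'     non-diabetic population (euros/year), applied to all states except
#'     ESRD.}
#'   \item{exp_lo, exp_hi}{age-dependent general health-care expenditure
#'     anchors (euros/year) at cohort entry and at the model horizon.}
#'   \item{esrd_cost_replaces_background}{if `TRUE`, the ESRD state cost
#'     replaces (rather than adds to) background expenditures.}
#'   \item{age_entry, age_end}{cohort entry age and final modelled age.}
#'   \item{r_cost, r_effect}{annual discount rates for costs and effects.}
#'   \item{spec_micro}{specificity of the quantitative microalbuminuria
#'     test (sensitivity is taken as 1).}
#'   \item{cohort_size}{nominal cohort size (results are reported per
#'     patient; the size only scales absolute totals).}
#' }
#'
#' @return An object of class `nephro_params` (a named list).
#' @seealso [default_ranges()], [load_parameters()], [validate_parameters()]
#' @export
#' @examples
#' ps <- default_parameters()
#' ps$q_nm
default_parameters <- function() {
  ps <- list(
    prev_normo = 0.79, prev_micro = 0.18, prev_macro = 0.03,
    q_nm = 0.056, q_mM = 0.094, q_ME = 0.056,
    rr_nm = 0.60, rr_mM = 0.45, rr_ME = 0.61,
    smr = 1.41,
    q_esrd_death = 0.09,
    u_diabetes = 0.88, u_esrd = 0.62, u_treat_mult = 1.00,
    c_drug_mixed = 62.70, c_ace = 6.96, c_arb = 298.68, arb_rate = 0.099,
    c_screen_micro = 7.00, c_screen_macro = 1.12,
    esrd_costs = esrd_cost_inputs(),
    c_esrd_override = 42110, c_diabetes_excess = 547,
    exp_lo = 3310.23, exp_hi = 23626.23,
    esrd_cost_replaces_background = FALSE,
    age_entry = 50, age_end = 99,
    r_cost = 0.04, r_effect = 0.015,
    spec_micro = 1.00,
    cohort_size = 1000
  )
  class(ps) <- "nephro_params"
  ps
}

#' Published uncertainty ranges for the one-way sensitivity analysis
#'
#' One row per parameter with a published range (95% confidence interval
#' where available). The printed lower bound of `q_mM` is negative (-0.02)
#' and is clamped to 0, since a negative transition probability is
#' meaningless; its upper bound is kept as printed.
#'
#' @return A data frame with columns `name`, `low`, `high`.
#' @seealso [univariate_sa()], [psa_distributions()]
#' @export
default_ranges <- function() {
  rng <- rbind(
    data.frame(name = "prev_normo",      low = 0.665,  high = 1.00),
    data.frame(name = "q_nm",            low = 0.03,   high = 0.08),
    data.frame(name = "q_mM",            low = 0.0,    high = 0.20),
    data.frame(name = "q_ME",            low = 0.025,  high = 0.08),
    data.frame(name = "rr_nm",           low = 0.43,   high = 0.84),
    data.frame(name = "rr_mM",           low = 0.29,   high = 0.69),
    data.frame(name = "rr_ME",           low = 0.50,   high = 0.75),
    data.frame(name = "u_diabetes",      low = 0.86,   high = 0.90),
    data.frame(name = "u_esrd",          low = 0.39,   high = 0.84),
    data.frame(name = "u_treat_mult",    low = 0.95,   high = 1.00),
    data.frame(name = "c_drug_mixed",    low = 62.70,  high = 83.78),
    data.frame(name = "c_esrd_override", low = 33688,  high = 50532),
    data.frame(name = "smr",             low = 1.39,   high = 1.43),
    data.frame(name = "arb_rate",        low = 0.096,  high = 0.102),
    data.frame(name = "spec_micro",      low = 0.81,   high = 1.00),
    data.frame(name = "r_cost",          low = 0.00,   high = 0.10),
    data.frame(name = "r_effect",        low = 0.00,   high = 0.10)
  )
  rng
}

#' Validate a parameter set
#'
#' Checks every invariant of a [default_parameters()]-shaped parameter set
#' and returns a description of each violation instead of raising, so
#' callers can report all problems at once.
#'
#' @param ps A `nephro_params` object (or plain named list with the same
#'   fields).
#' @return A character vector of violations, empty when the set is valid.
#'   Each entry names the offending field and the rule broken.
#' @export
#' @examples
#' validate_parameters(default_parameters())  # character(0)
validate_parameters <- function(ps) {
  v <- character()
  scalar_fields <- setdiff(names(default_parameters()),
                           c("esrd_costs", "esrd_cost_replaces_background"))
  for (f in scalar_fields) {
    x <- ps[[f]]
    if (!(is.numeric(x) && length(x) == 1 && is.finite(x))) {
      v <- c(v, paste0(f, ": must be a finite number"))
    }
  }
  if (length(v)) return(v)

  if (abs(ps$prev_normo + ps$prev_micro + ps$prev_macro - 1) > 1e-9)
    v <- c(v, "prev_normo+prev_micro+prev_macro: must sum to 1")
  probs <- c("prev_normo", "prev_micro", "prev_macro",
             "q_nm", "q_mM", "q_ME", "q_esrd_death",
             "u_diabetes", "u_esrd", "u_treat_mult",
             "arb_rate", "spec_micro")
  for (f in probs)
    if (ps[[f]] < 0 || ps[[f]] > 1)
      v <- c(v, paste0(f, ": must be in [0, 1]"))
  for (f in c("rr_nm", "rr_mM", "rr_ME"))
    if (ps[[f]] <= 0 || ps[[f]] > 1)
      v <- c(v, paste0(f, ": must be in (0, 1]"))
  costs <- c("c_drug_mixed", "c_ace", "c_arb", "c_screen_micro",
             "c_screen_macro", "c_esrd_override", "c_diabetes_excess",
             "exp_lo", "exp_hi")
  for (f in costs)
    if (ps[[f]] < 0) v <- c(v, paste0(f, ": must be >= 0"))
  if (ps$smr <= 0) v <- c(v, "smr: must be > 0")
  if (!(ps$age_entry < ps$age_end && ps$age_end <= 99))
    v <- c(v, "age_entry/age_end: require age_entry < age_end <= 99")
  for (f in c("r_cost", "r_effect"))
    if (ps[[f]] < 0) v <- c(v, paste0(f, ": must be >= 0"))
  if (ps$cohort_size <= 0) v <- c(v, "cohort_size: must be > 0")
  if (!is.logical(ps$esrd_cost_replaces_background))
    v <- c(v, "esrd_cost_replaces_background: must be TRUE or FALSE")
  v <- c(v, validate_esrd_cost_inputs(ps$esrd_costs))
  v
}

#' Load a parameter set from a configuration file or list
#'
#' Reads a flat YAML mapping (or takes a named list) whose keys are
#' [default_parameters()] field names, overrides the defaults with the
#' values supplied, and validates the result. The `esrd_costs` key may be a
#' nested mapping with the [esrd_cost_inputs()] fields. Unknown keys are an
#' error, as is any invariant violation (reported with the offending field
#' named).
#'
#' @param config Path to a YAML file, a named list of overrides, or `NULL`
#'   for the packaged base case.
#' @return A validated `nephro_params` object.
#' @export
#' @examples
#' load_parameters(list(c_drug_mixed = 426.70))$c_drug_mixed
load_parameters <- function(config = NULL) {
  ps <- default_parameters()
  if (is.null(config)) return(ps)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list",
                             call. = FALSE)
  if (length(config) == 0) return(ps)
  if (is.null(names(config)) || any(names(config) == ""))
    stop("config entries must all be named", call. = FALSE)
  unknown <- setdiff(names(config), names(ps))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(config)) {
    if (k == "esrd_costs") {
      ec <- ps$esrd_costs
      sub <- config[[k]]
      bad <- setdiff(names(sub), names(ec))
      if (length(bad))
        stop("unknown esrd_costs field(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      ec[names(sub)] <- sub
      ps$esrd_costs <- ec
    } else {
      ps[[k]] <- config[[k]]
    }
  }
  viol <- validate_parameters(ps)
  if (length(viol))
    stop("invalid parameter configuration: ", paste(viol, collapse = "; "),
         call. = FALSE)
  ps
}

#' Write a parameter set to a YAML configuration file
#'
#' Serialises a parameter set so that [load_parameters()] on the file
#' reproduces it exactly (decimal-point notation, full precision).
#'
#' @param ps A `nephro_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  out <- unclass(ps)
  out$esrd_costs <- unclass(out$esrd_costs)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Set one parameter, preserving model-level couplings
#'
#' A setter used by the sensitivity machinery. Most fields are assigned
#' directly, but three receive special handling so a one-at-a-time change
#' keeps the parameter set coherent:
#' \itemize{
#'   \item `prev_normo`: the remaining mass is reallocated to `prev_micro`
#'     and `prev_macro` in their current ratio, keeping the simplex intact.
#'   \item `prev_micro` / `prev_macro`: `prev_normo` absorbs the change.
#'   \item `arb_rate`: the mixed annual drug cost is shifted by
#'     `(new - old) * (c_arb - c_ace)`, anchoring the published mixed cost
#'     at the base-case ARB share.
#' }
#'
#' @param ps A `nephro_params` object.
#' @param name Field name (also accepts `esrd_costs` subfields such as
#'   `p` or `x1`).
#' @param value New value.
#' @return The modified, validated parameter set.
#' @export
set_parameter <- function(ps, name, value) {
  if (name %in% names(ps$esrd_costs)) {
    ps$esrd_costs[[name]] <- value
  } else if (name == "prev_normo") {
    rest <- ps$prev_micro + ps$prev_macro
    share_micro <- if (rest > 0) ps$prev_micro / rest else 6 / 7
    ps$prev_normo <- value
    ps$prev_micro <- (1 - value) * share_micro
    ps$prev_macro <- (1 - value) * (1 - share_micro)
  } else if (name %in% c("prev_micro", "prev_macro")) {
    old <- ps[[name]]
    ps[[name]] <- value
    ps$prev_normo <- ps$prev_normo - (value - old)
  } else if (name == "arb_rate") {
    ps$c_drug_mixed <- ps$c_drug_mixed +
      (value - ps$arb_rate) * (ps$c_arb - ps$c_ace)
    ps$arb_rate <- value
  } else if (name %in% names(ps)) {
    ps[[name]] <- value
  } else {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  viol <- validate_parameters(ps)
  if (length(viol))
    stop("setting ", name, " = ", value, " violates: ",
         paste(viol, collapse = "; "), call. = FALSE)
  ps
}

#' @export
print.nephro_params <- function(x, ...) {
  cat("<nephro_params> base-case model inputs\n")
  cat(sprintf("  prevalences (normo/micro/macro): %.3f / %.3f / %.3f\n",
              x$prev_normo, x$prev_micro, x$prev_macro))
  cat(sprintf("  transitions q_nm/q_mM/q_ME: %.3f / %.3f / %.3f  (RR %.2f / %.2f / %.2f)\n",
              x$q_nm, x$q_mM, x$q_ME, x$rr_nm, x$rr_mM, x$rr_ME))
  cat(sprintf("  utilities: diabetes %.2f, ESRD %.2f; drug cost %.2f euros/yr\n",
              x$u_diabetes, x$u_esrd, x$c_drug_mixed))
  cat(sprintf("  ages %d-%d, discounting %.1f%% costs / %.1f%% effects\n",
              x$age_entry, x$age_end, 100 * x$r_cost, 100 * x$r_effect))
  invisible(x)
}
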