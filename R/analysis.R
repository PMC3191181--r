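#' Evaluate one strategy under a parameter set
#'
#' Runs the cohort and accumulates half-cycle-corrected, discounted costs
#' and QALYs and undiscounted life years. Deterministic.
#'
#' @param strategy One of [strategies()].
#' @param ps A `nephro_params` object.
#' @param demography A list with `life_table` and `expenditure` (see
#'   [default_demography()]).
#' @return A `nephro_ce` result.
#' @export
#' @examples
#' evaluate_strategy("treat_all", default_parameters())
evaluate_strategy <- function(strategy, ps,
                              demography = default_demography(ps)) {
  trace <- run_cohort(strategy, ps, demography$life_table)
  accumulate_outcomes(
    trace,
    function(age) compartment_payoffs(age, strategy, ps,
                                      demography$expenditure),
    r_cost = ps$r_cost, r_effect = ps$r_effect, label = strategy
  )
}

#' Evaluate several strategies into one table
#'
#' @param ps A `nephro_params` object.
#' @param demography See [default_demography()].
#' @param strategy_set Strategies to evaluate; by default the three
#'   published strategies (no-intervention is available on request).
#' @return A data frame with columns `strategy`, `cost`, `lys`, `qalys`.
#' @export
evaluate_strategies <- function(ps, demography = default_demography(ps),
                                strategy_set = c("treat_all", "screen_micro",
                                                 "screen_macro")) {
  rows <- lapply(strategy_set, function(s) {
    r <- evaluate_strategy(s, ps, demography)
    data.frame(strategy = s, cost = r$discounted_cost,
               lys = r$undiscounted_lys, qalys = r$discounted_qalys)
  })
  do.call(rbind, rows)
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (euros).
#' @param delta_qalys Incremental QALYs.
#' @return `delta_cost / delta_qalys`, or `NA` when `delta_qalys` is zero
#'   (the ratio is undefined).
#' @export
compute_icer <- function(delta_cost, delta_qalys) {
  ifelse(delta_qalys == 0, NA_real_, delta_cost / delta_qalys)
}

# Dominance label for a (delta_cost, delta_qalys) pair versus a reference:
# a strategy that costs less and yields more is "dominant"; raw negative
# ratios are never presented as cost-effectiveness.
dominance_label <- function(delta_cost, delta_qalys) {
  if (delta_cost < 0 && delta_qalys > 0) return("dominant")
  if (delta_cost > 0 && delta_qalys < 0) return("dominated")
  if (delta_cost == 0 && delta_qalys == 0) return("equivalent")
  sprintf("%.0f", compute_icer(delta_cost, delta_qalys))
}

#' Incremental comparison with dominance classification
#'
#' Sorts strategies by discounted cost, flags strictly dominated strategies
#' (another strategy costs no more and yields no fewer QALYs, with at least
#' one strict inequality), applies extended dominance along the remaining
#' cost-sorted frontier (a strategy is removed when the ICER to the next
#' frontier member is lower than the ICER from the previous one), reports
#' ICERs between adjacent frontier members, and adds pairwise differences
#' against a designated reference strategy. A strategy that strictly
#' dominates every other is labelled `dominant`.
#'
#' @param results A data frame from [evaluate_strategies()] (columns
#'   `strategy`, `cost`, `qalys`, optionally `lys`).
#' @param reference Strategy used for the pairwise `delta_*` columns
#'   (default: screening for microalbuminuria, the customary comparator).
#' @return A `nephro_comparison`: list with `table` (per-strategy costs,
#'   effects, status label, deltas vs reference, `icer_vs_ref` and the
#'   presentation `label`), `frontier` (cost-ordered frontier with
#'   adjacent ICERs) and `reference`.
#' @export
compare_strategies <- function(results, reference = "screen_micro") {
  if (nrow(results) < 2) stop("need at least two strategies", call. = FALSE)
  if (anyDuplicated(results$strategy))
    stop("duplicate strategy labels", call. = FALSE)
  if (!reference %in% results$strategy)
    stop("reference strategy '", reference, "' not among results",
         call. = FALSE)
  res <- results[order(results$cost, results$qalys), , drop = FALSE]
  n <- nrow(res)

  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && res$cost[j] <= res$cost[i] && res$qalys[j] >= res$qalys[i] &&
        (res$cost[j] < res$cost[i] || res$qalys[j] > res$qalys[i])
    }, logical(1)))
  }, logical(1))
  dominant <- vapply(seq_len(n), function(i) {
    all(vapply(seq_len(n), function(j) {
      j == i || (res$cost[i] <= res$cost[j] && res$qalys[i] >= res$qalys[j] &&
                   (res$cost[i] < res$cost[j] || res$qalys[i] > res$qalys[j]))
    }, logical(1)))
  }, logical(1))

  # extended dominance on the cost-sorted, strictly-undominated set
  frontier_idx <- which(!dominated)
  repeat {
    k <- length(frontier_idx)
    if (k < 3) break
    drop <- NULL
    for (pos in 2:(k - 1)) {
      i_prev <- frontier_idx[pos - 1]
      i <- frontier_idx[pos]
      i_next <- frontier_idx[pos + 1]
      icer_in <- compute_icer(res$cost[i] - res$cost[i_prev],
                              res$qalys[i] - res$qalys[i_prev])
      icer_out <- compute_icer(res$cost[i_next] - res$cost[i],
                               res$qalys[i_next] - res$qalys[i])
      if (!is.na(icer_in) && !is.na(icer_out) && icer_out < icer_in) {
        drop <- pos
        break
      }
    }
    if (is.null(drop)) break
    frontier_idx <- frontier_idx[-drop]
  }

  status <- ifelse(dominated, "dominated",
                   ifelse(dominant, "dominant", "on_frontier"))
  status[!dominated & !seq_len(n) %in% frontier_idx] <- "ext_dominated"

  ref <- res[res$strategy == reference, ]
  res$delta_cost <- res$cost - ref$cost
  res$delta_qalys <- res$qalys - ref$qalys
  res$icer_vs_ref <- compute_icer(res$delta_cost, res$delta_qalys)
  res$status <- status
  res$label <- vapply(seq_len(n), function(i) {
    if (status[i] %in% c("dominated", "ext_dominated")) return("dominated")
    if (res$strategy[i] == reference) return("(reference)")
    dominance_label(res$delta_cost[i], res$delta_qalys[i])
  }, character(1))

  front <- res[frontier_idx, c("strategy", "cost", "qalys")]
  front$icer_vs_previous <- c(NA_real_, compute_icer(diff(front$cost),
                                                     diff(front$qalys)))
  out <- list(table = res, frontier = front, reference = reference)
  class(out) <- "nephro_comparison"
  out
}

#' @export
print.nephro_comparison <- function(x, ...) {
  cat("<nephro_comparison> reference:", x$reference, "\n")
  tab <- x$table
  tab$cost <- sprintf("%.2f", tab$cost)
  tab$qalys <- sprintf("%.4f", tab$qalys)
  print(tab[, c("strategy", "cost", "qalys", "status", "label")],
        row.names = FALSE)
  invisible(x)
}

#' One-way (univariate) sensitivity analysis
#'
#' Re-evaluates the treat-all and reference (microalbuminuria-screening)
#' strategies with one parameter at a time set to each bound of its
#' published range, via [set_parameter()] (so prevalence and ARB-rate
#' couplings are respected), restoring the base case between rows.
#'
#' @param ps A `nephro_params` object.
#' @param ranges A data frame like [default_ranges()].
#' @param demography See [default_demography()].
#' @param strategy,reference The strategy pair compared (defaults:
#'   treat-all vs screen for microalbuminuria).
#' @return A data frame with one row per (parameter, bound): columns
#'   `parameter`, `bound` (`"lower"`/`"higher"`), `value`, `delta_cost`,
#'   `delta_qalys`, `icer`.
#' @export
univariate_sa <- function(ps, ranges = default_ranges(),
                          demography = default_demography(ps),
                          strategy = "treat_all", reference = "screen_micro") {
  one <- function(name, bound_label, value) {
    ps2 <- set_parameter(ps, name, value)
    a <- evaluate_strategy(strategy, ps2, demography)
    b <- evaluate_strategy(reference, ps2, demography)
    dc <- a$discounted_cost - b$discounted_cost
    dq <- a$discounted_qalys - b$discounted_qalys
    data.frame(parameter = name, bound = bound_label, value = value,
               delta_cost = dc, delta_qalys = dq,
               icer = compute_icer(dc, dq))
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    rbind(one(ranges$name[i], "lower", ranges$low[i]),
          one(ranges$name[i], "higher", ranges$high[i]))
  })
  do.call(rbind, rows)
}

#' Breakeven annual drug cost
#'
#' Finds the annual mixed drug cost at which the treat-all strategy stops
#' saving money against microalbuminuria screening (incremental discounted
#' cost zero), by bisection on `c_drug_mixed` within a bracket. Returns
#' `NA` with a warning when the incremental cost does not change sign over
#' the bracket (no breakeven exists there).
#'
#' @param ps A `nephro_params` object; treat-all should be cost-saving at
#'   the base drug cost.
#' @param demography See [default_demography()].
#' @param bracket Search interval for the annual drug cost (euros/year).
#' @param tol Absolute tolerance on the breakeven cost (euros).
#' @return The breakeven annual drug cost (euros/year), or `NA_real_`.
#' @export
threshold_drug_cost <- function(ps, demography = default_demography(ps),
                                bracket = c(ps$c_drug_mixed, 5000),
                                tol = 0.01) {
  delta_cost_at <- function(drug_cost) {
    ps2 <- ps
    ps2$c_drug_mixed <- drug_cost
    a <- evaluate_strategy("treat_all", ps2, demography)
    b <- evaluate_strategy("screen_micro", ps2, demography)
    a$discounted_cost - b$discounted_cost
  }
  f_lo <- delta_cost_at(bracket[1])
  f_hi <- delta_cost_at(bracket[2])
  if (sign(f_lo) == sign(f_hi)) {
    warning("incremental cost does not change sign on [",
            bracket[1], ", ", bracket[2], "]; no breakeven found")
    return(NA_real_)
  }
  stats::uniroot(delta_cost_at, interval = bracket,
                 f.lower = f_lo, f.upper = f_hi, tol = tol / 2)$root
}
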