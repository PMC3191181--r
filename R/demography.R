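# Gompertz-Makeham constants behind the packaged life table. Calibrated so
# that remaining life expectancy at 50 falls in 28-34 years and the modelled
# cohort is >99% extinct by the age-99 boundary under the base-case SMR.
.gompertz_defaults <- c(a = 1.4e-5, b = 0.105, c = 5e-4)

#' Synthesise a Gompertz-Makeham life table
#'
#' Builds a deterministic age-specific annual death-probability table from a
#' Gompertz-Makeham hazard, `h(age) = a * exp(b * age) + c`, converted to an
#' annual probability by `q(age) = 1 - exp(-h(age))`. This is the package's
#' stand-in for a national period life table of a contemporary Western
#' European population; a real table can be substituted via
#' [read_life_table()].
#'
#' @param a Baseline (age-0 extrapolated) Gompertz hazard; must be > 0.
#' @param b Log-hazard slope per year of age; must be > 0.
#' @param c Age-independent (Makeham) hazard component; must be >= 0.
#' @param age_min,age_max Integer age span covered (default 50-99).
#' @return A `nephro_life_table`: a data frame with columns `age` and `qx`.
#' @export
#' @examples
#' lt <- synthesize_life_table()
#' head(lt)
#' life_expectancy(lt)
synthesize_life_table <- function(a = .gompertz_defaults[["a"]],
                                  b = .gompertz_defaults[["b"]],
                                  c = .gompertz_defaults[["c"]],
                                  age_min = 50, age_max = 99) {
  if (!(is.numeric(a) && a > 0)) stop("a must be > 0", call. = FALSE)
  if (!(is.numeric(b) && b > 0)) stop("b must be > 0", call. = FALSE)
  if (!(is.numeric(c) && c >= 0)) stop("c must be >= 0", call. = FALSE)
  ages <- seq.int(age_min, age_max)
  hazard <- a * exp(b * ages) + c
  lt <- data.frame(age = ages, qx = pmin(1, 1 - exp(-hazard)))
  class(lt) <- c("nephro_life_table", "data.frame")
  lt
}

#' Packaged default life table
#'
#' The synthetic life table shipped with the package (Gompertz-Makeham,
#' `a = 1.4e-5`, `b = 0.105`, `c = 5e-4`), also available as a two-column
#' CSV in `inst/extdata/life_table_synthetic.csv`.
#'
#' @param age_min,age_max Age span (default 50-99).
#' @return A `nephro_life_table` data frame.
#' @export
default_life_table <- function(age_min = 50, age_max = 99) {
  synthesize_life_table(age_min = age_min, age_max = age_max)
}

#' Read / write a life table as two-column CSV
#'
#' The on-disk format is a plain CSV with header `age,qx`, so a national
#' statistics table can be dropped in bit-for-bit.
#'
#' @param path CSV file path.
#' @return `read_life_table()` returns a `nephro_life_table`;
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table CSV must have columns 'age' and 'qx'", call. = FALSE)
  lt <- lt[order(lt$age), c("age", "qx")]
  if (any(lt$qx < 0 | lt$qx > 1))
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  if (!identical(lt$age, seq.int(min(lt$age), max(lt$age))))
    stop("life table must cover consecutive integer ages", call. = FALSE)
  rownames(lt) <- NULL
  class(lt) <- c("nephro_life_table", "data.frame")
  lt
}

#' @rdname read_life_table
#' @param lt A `nephro_life_table`.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remaining period life expectancy at the table's first age
#'
#' Computed as the sum of cumulative survival over the table's span plus a
#' half-year continuity correction. Used to document the calibration of the
#' synthetic table (target band: 28-34 years at age 50).
#'
#' @param lt A `nephro_life_table`.
#' @return Years of remaining life expectancy.
#' @export
life_expectancy <- function(lt) {
  sum(cumprod(1 - lt$qx)) + 0.5
}

#' Look up the general-population death probability at an age
#'
#' @param age Integer age(s); must lie within the table.
#' @param lt A `nephro_life_table`.
#' @return Annual death probability `q(age)`.
#' @export
death_prob <- function(age, lt) {
  idx <- match(age, lt$age)
  if (anyNA(idx))
    stop("age ", paste(age[is.na(idx)], collapse = ", "),
         " outside the life table (", min(lt$age), "-", max(lt$age), ")",
         call. = FALSE)
  lt$qx[idx]
}

#' Annual death probability of a diabetic patient
#'
#' General-population mortality scaled by the standardised mortality ratio
#' and capped at 1.
#'
#' @param age Integer age(s) within the life table.
#' @param lt A `nephro_life_table`.
#' @param smr Standardised mortality ratio (> 0).
#' @return `min(1, smr * q(age))`.
#' @export
#' @examples
#' diabetic_death_prob(50, default_life_table(), smr = 1.41)
diabetic_death_prob <- function(age, lt, smr) {
  if (!(is.numeric(smr) && all(smr > 0))) stop("smr must be > 0", call. = FALSE)
  pmin(1, smr * death_prob(age, lt))
}

#' Age-dependent general health-care expenditure curve
#'
#' Two anchor points joined by log-linear (exponential) interpolation:
#' annual background health-care expenditure grows multiplicatively with
#' age. The published endpoints are anchored at cohort entry and at the
#' model horizon; both anchors and the interpolation are overridable.
#'
#' @param ps A `nephro_params` object supplying the anchors, or `NULL`.
#' @param age_lo,cost_lo,age_hi,cost_hi Explicit anchors (override `ps`).
#' @param rule Interpolation rule; `"loglinear"` (default) or `"linear"`.
#' @return A `nephro_expenditure` object.
#' @export
#' @examples
#' curve <- expenditure_curve(default_parameters())
#' expenditure_at_age(50, curve)
expenditure_curve <- function(ps = NULL,
                              age_lo = NULL, cost_lo = NULL,
                              age_hi = NULL, cost_hi = NULL,
                              rule = c("loglinear", "linear")) {
  rule <- match.arg(rule)
  if (!is.null(ps)) {
    if (is.null(age_lo)) age_lo <- ps$age_entry
    if (is.null(cost_lo)) cost_lo <- ps$exp_lo
    if (is.null(age_hi)) age_hi <- ps$age_end
    if (is.null(cost_hi)) cost_hi <- ps$exp_hi
  }
  if (is.null(age_lo) || is.null(cost_lo) || is.null(age_hi) || is.null(cost_hi))
    stop("supply either a parameter set or all four anchors", call. = FALSE)
  if (age_lo >= age_hi) stop("age_lo must be < age_hi", call. = FALSE)
  if (cost_lo < 0 || cost_hi < 0)
    stop("anchor costs must be >= 0", call. = FALSE)
  if (rule == "loglinear" && (cost_lo == 0 || cost_hi == 0))
    stop("log-linear interpolation requires positive anchor costs",
         call. = FALSE)
  out <- list(age_lo = age_lo, cost_lo = cost_lo,
              age_hi = age_hi, cost_hi = cost_hi, rule = rule)
  class(out) <- "nephro_expenditure"
  out
}

#' Evaluate the expenditure curve at an age
#'
#' @param age Age(s) within `[age_lo, age_hi]`.
#' @param curve A `nephro_expenditure` object.
#' @return Annual expenditure (euros/year); exact anchor values at anchor
#'   ages.
#' @export
expenditure_at_age <- function(age, curve) {
  if (any(age < curve$age_lo | age > curve$age_hi))
    stop("age outside the expenditure curve's span (",
         curve$age_lo, "-", curve$age_hi, ")", call. = FALSE)
  t <- (age - curve$age_lo) / (curve$age_hi - curve$age_lo)
  if (curve$rule == "loglinear") {
    exp((1 - t) * log(curve$cost_lo) + t * log(curve$cost_hi))
  } else {
    (1 - t) * curve$cost_lo + t * curve$cost_hi
  }
}

#' Bundle the demographic inputs of a model run
#'
#' @param ps A `nephro_params` object.
#' @param life_table A `nephro_life_table`; packaged default if `NULL`.
#' @param expenditure A `nephro_expenditure`; derived from `ps` if `NULL`.
#' @return A list with elements `life_table` and `expenditure`.
#' @export
default_demography <- function(ps = default_parameters(),
                               life_table = NULL, expenditure = NULL) {
  if (is.null(life_table))
    life_table <- default_life_table(ps$age_entry, ps$age_end)
  if (is.null(expenditure)) expenditure <- expenditure_curve(ps)
  list(life_table = life_table, expenditure = expenditure)
}
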