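# Cost aggregation and scenario comparison.  All sums are exact integer
# euro cents; percentages and per-center budgets round half-up.

#' Annual cost of a participation plan
#'
#' Sums the fees of the assigned schemes per year and averages over the
#' horizon (mean rounded half-up to the cent). Every assigned scheme must
#' have a fee in the inventory.
#'
#' @param plan an `eqa_plan`.
#' @param inventory an `eqa_inventory`.
#' @return list of class `eqa_cost` with `per_year_cents` (named integer
#'   vector) and `mean_cents`.
#' @export
annual_cost <- function(plan, inventory) {
  stopifnot(inherits(plan, "eqa_plan"))
  per_year <- vapply(as.character(plan$horizon), function(y) {
    ids <- plan$assignments[[y]]
    if (!length(ids)) return(0L)
    idx <- match(ids, inventory$scheme_id)
    if (anyNA(idx)) {
      stop("no fee known for scheme(s): ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    fees <- inventory$fee_cents[idx]
    if (anyNA(fees)) {
      stop("missing fee for scheme(s): ",
           paste(ids[is.na(fees)], collapse = ", "), call. = FALSE)
    }
    sum(fees)
  }, 1L)
  structure(list(per_year_cents = per_year,
                 mean_cents = as.integer(round_half_up(mean(per_year)))),
            class = "eqa_cost")
}

#' @export
print.eqa_cost <- function(x, ...) {
  for (y in names(x$per_year_cents)) {
    cat(sprintf("  %s: %s\n", y, format_eur(x$per_year_cents[[y]])))
  }
  cat(sprintf("  mean: %s/year\n", format_eur(x$mean_cents)))
  invisible(x)
}

#' Construct a cost scenario
#'
#' A named annual expenditure, optionally with its per-year composition
#' (year -> data frame of `scheme_id`, `fee_cents`); when a composition is
#' present the stated annual cost must equal the recomputed mean of the
#' yearly sums.
#'
#' @param name scenario label (e.g. `"full_participation"`,
#'   `"historical"`, `"guideline_plan"`).
#' @param annual_cost_cents annual cost in integer euro cents (for a
#'   multi-year plan, the mean over the horizon).
#' @param composition optional named list, year -> data frame with
#'   `scheme_id` and `fee_cents`.
#' @return list of class `eqa_scenario`.
#' @export
cost_scenario <- function(name, annual_cost_cents, composition = NULL) {
  annual_cost_cents <- as.integer(annual_cost_cents)
  stopifnot(length(annual_cost_cents) == 1, annual_cost_cents >= 0)
  if (!is.null(composition)) {
    yearly <- vapply(composition, function(df) sum(df$fee_cents), 1)
    recomputed <- as.integer(round_half_up(mean(yearly)))
    if (recomputed != annual_cost_cents) {
      stop(sprintf(
        "annual_cost (%s) does not match the composition mean (%s)",
        format_eur(annual_cost_cents), format_eur(recomputed)),
        call. = FALSE)
    }
  }
  structure(list(name = name, annual_cost_cents = annual_cost_cents,
                 composition = composition),
            class = "eqa_scenario")
}

as_cost_cents <- function(x) {
  if (inherits(x, "eqa_scenario")) x$annual_cost_cents
  else if (inherits(x, "eqa_cost")) x$mean_cents
  else as.integer(x)
}

#' Relative cost reduction between two scenarios
#'
#' `100 * (a - b) / a`, rounded to the nearest integer percent; `a` is the
#' reference. Comparing an €82,000 historical expenditure with a €70,600
#' guideline plan gives 14.
#'
#' @param a,b `eqa_scenario` objects, [annual_cost()] results, or amounts
#'   in integer cents; `a` must be positive.
#' @return integer percent.
#' @export
#' @examples
#' compare_scenarios(eur_to_cents(82000), eur_to_cents(70600))  # 14
compare_scenarios <- function(a, b) {
  a <- as_cost_cents(a)
  b <- as_cost_cents(b)
  if (a <= 0) stop("reference scenario cost must be positive", call. = FALSE)
  as.integer(round_half_up(100 * (a - b) / a))
}

#' Per-center budget share
#'
#' Divides a total budget equally over centers and rounds to the
#' configured step (default €100).
#'
#' @param total_cents total budget in integer cents.
#' @param n_centers number of centers, at least 1.
#' @param step_cents rounding step in cents (default 10000 = €100).
#' @return integer cents per center.
#' @export
#' @examples
#' per_center_budget(eur_to_cents(70600), 8)  # €8,800
per_center_budget <- function(total_cents, n_centers, step_cents = 10000L) {
  stopifnot(n_centers >= 1, step_cents > 0)
  as.integer(round_half_up(total_cents / (n_centers * step_cents)) *
               step_cents)
}
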