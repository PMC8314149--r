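# Bayesian binomial error-rate model under noninformative Beta priors,
# the minimum-annual-volume solver, and t-based confidence intervals for
# literature error-rate summaries.
#
# With k erroneous analyses out of n and a Beta(a0, b0) prior on the error
# rate p, the posterior is Beta(k + a0, n - k + b0).  The uniform prior is
# Beta(1, 1), Jeffreys is Beta(1/2, 1/2).  For the uniform prior with zero
# errors the one-sided upper credible bound has the closed form
# 1 - (1 - level)^(1/(n + 1)), which the generic quantile path must
# reproduce to 1e-9.

PRIORS <- c(uniform = 1, jeffreys = 0.5)

#' Beta posterior of a binomial error rate
#'
#' @param n number of analyses (non-negative integer).
#' @param k number of erroneous analyses, `0 <= k <= n`.
#' @param prior `"uniform"` (Beta(1,1)) or `"jeffreys"` (Beta(1/2,1/2)).
#' @return object of class `eqa_posterior` with fields `alpha`, `beta`,
#'   `n`, `k`, `prior`.
#' @export
#' @examples
#' eqa_posterior(297, 0)            # zero errors in 297 analyses
#' eqa_posterior(297, 1, "jeffreys")
eqa_posterior <- function(n, k = 0, prior = c("uniform", "jeffreys")) {
  prior <- match.arg(prior)
  stopifnot(length(n) == 1, length(k) == 1, n >= 0, k >= 0)
  if (k > n) stop("k (errors) cannot exceed n (analyses)", call. = FALSE)
  a0 <- PRIORS[[prior]]
  structure(list(alpha = k + a0, beta = n - k + a0, n = n, k = k,
                 prior = prior),
            class = "eqa_posterior")
}

#' @export
print.eqa_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior (%s prior, k=%g of n=%g)\n",
              x$alpha, x$beta, x$prior, x$k, x$n))
  invisible(x)
}

#' Upper credible bound of the posterior error rate
#'
#' One-sided upper bounds are the `level` posterior quantile; two-sided
#' bounds the `1 - (1 - level)/2` quantile. For the uniform prior with
#' `k = 0` this equals the closed form `1 - (1 - level)^(1/(n + 1))`.
#'
#' @param p an `eqa_posterior`.
#' @param level credible level in (0,1), default 0.95.
#' @param sidedness `"one_sided_upper"` or `"two_sided"`.
#' @return error-rate proportion in (0,1).
#' @export
#' @examples
#' upper_credible_bound(eqa_posterior(297, 0))  # ~0.01
upper_credible_bound <- function(p, level = 0.95,
                                 sidedness = c("one_sided_upper",
                                               "two_sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(p, "eqa_posterior"), level > 0, level < 1)
  q <- if (sidedness == "one_sided_upper") level else 1 - (1 - level) / 2
  qbeta(q, p$alpha, p$beta)
}

# bound as a function of a *real-valued* n, used by the continuous solver
bound_at_n <- function(n, k, prior, level, sidedness) {
  a0 <- PRIORS[[prior]]
  q <- if (sidedness == "one_sided_upper") level else 1 - (1 - level) / 2
  qbeta(q, k + a0, n - k + a0)
}

#' Minimum annual test volume for a bounded error rate
#'
#' Finds the smallest annual number of analyses such that the upper
#' credible bound of the binomial error rate is at the stated threshold:
#' solves `bound(n) = max_error_rate` for continuous `n` and rounds. With
#' the defaults (1% threshold, 95% one-sided level, uniform prior, zero
#' assumed errors) the continuous solution is
#' `log(0.05)/log(0.99) - 1 = 297.07`, i.e. 297 analyses per year under
#' nearest-integer rounding (the documented default); `rounding = "ceiling"`
#' gives the strict 298.
#'
#' @param max_error_rate maximal tolerated error rate, proportion in (0,1).
#' @param level credible level in (0,1), default 0.95.
#' @param sidedness `"one_sided_upper"` (default) or `"two_sided"`.
#' @param prior `"uniform"` (default) or `"jeffreys"`.
#' @param k assumed number of erroneous analyses (default 0; `k = 1`
#'   expresses the (n-1)/n-correct scenario).
#' @param rounding `"nearest"` (default) or `"ceiling"`.
#' @return integer number of analyses per year, with the achieved bound at
#'   that volume in attribute `"achieved_bound"` and the continuous solution
#'   in attribute `"n_continuous"`.
#' @export
#' @examples
#' min_volume_for_threshold(0.01)                       # 297
#' min_volume_for_threshold(0.01, rounding = "ceiling") # 298
min_volume_for_threshold <- function(max_error_rate, level = 0.95,
                                     sidedness = c("one_sided_upper",
                                                   "two_sided"),
                                     prior = c("uniform", "jeffreys"),
                                     k = 0,
                                     rounding = c("nearest", "ceiling")) {
  sidedness <- match.arg(sidedness)
  prior <- match.arg(prior)
  rounding <- match.arg(rounding)
  stopifnot(max_error_rate > 0, max_error_rate < 1,
            level > 0, level < 1, k >= 0)
  f <- function(n) bound_at_n(n, k, prior, level, sidedness) - max_error_rate
  if (f(k) <= 0) {
    # the prior (or the k-errors-in-k-analyses posterior) already satisfies
    n_star <- k
  } else {
    n_hi <- max(k + 1, 10)
    while (f(n_hi) > 0 && n_hi < 1e8) n_hi <- n_hi * 10
    if (f(n_hi) > 0) {
      stop("infeasible query: bound does not reach ", max_error_rate,
           " below n = 1e8", call. = FALSE)
    }
    n_star <- uniroot(f, c(k, n_hi), tol = 1e-9)$root
  }
  n_int <- if (rounding == "nearest") as.integer(round_half_up(n_star)) else
    as.integer(ceiling(n_star - 1e-9))
  structure(n_int,
            achieved_bound = bound_at_n(n_int, k, prior, level, sidedness),
            n_continuous = n_star)
}

#' t-based confidence interval of a mean error rate from summary statistics
#'
#' For a literature row reporting a mean error-rate percentage and its SD
#' over `n` investigated scenarios, computes
#' `mean +/- t((1 + level)/2, n - 1) * sd / sqrt(n)`. The lower bound may be
#' negative for small `n` and large SD.
#'
#' @param n number of investigated scenarios, at least 2.
#' @param mean mean error rate in percent.
#' @param sd standard deviation in percent, non-negative.
#' @param level confidence level, default 0.95.
#' @param digits round bounds to this many decimals (default 2, matching
#'   how such tables are printed); `NULL` for unrounded.
#' @return named numeric `c(lower, upper)` in percent.
#' @export
#' @examples
#' t_confidence_interval(7, 0.89, 0.82)  # (0.13, 1.65)
t_confidence_interval <- function(n, mean, sd, level = 0.95, digits = 2) {
  stopifnot(length(n) == 1, length(mean) == 1, length(sd) == 1)
  if (n < 2) stop("at least 2 scenarios are required for a CI", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  stopifnot(level > 0, level < 1)
  half <- qt((1 + level) / 2, df = n - 1) * sd / sqrt(n)
  out <- c(lower = mean - half, upper = mean + half)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}
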