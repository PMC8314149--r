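# Internal helpers: money in integer euro cents, half-up rounding, free-text
# indication keys.

#' Convert euros to integer cents
#'
#' Monetary amounts are stored internally as integer euro cents so that
#' budget sums are exact. Conversion rounds half-up at the cent.
#'
#' @param eur numeric vector of euro amounts.
#' @return integer vector of cents.
#' @export
#' @examples
#' eur_to_cents(1250.5)
eur_to_cents <- function(eur) {
  stopifnot(is.numeric(eur))
  as.integer(round_half_up(eur * 100))
}

#' Convert integer cents to euros
#' @param cents integer vector of euro cents.
#' @return numeric euros.
#' @export
cents_to_eur <- function(cents) cents / 100

#' Format cents as a euro string
#'
#' Whole-euro amounts print without decimals, others with two; thousands are
#' separated by commas. Display-only: stored values are never locale-dependent.
#'
#' @param cents integer vector of euro cents.
#' @return character vector like `"€1,200"`.
#' @export
format_eur <- function(cents) {
  whole <- cents %% 100L == 0L
  out <- character(length(cents))
  out[whole] <- formatC(cents[whole] / 100, format = "d", big.mark = ",")
  out[!whole] <- formatC(cents[!whole] / 100, format = "f", digits = 2,
                         big.mark = ",")
  paste0("€", out)
}

# round half away from zero (base round() is half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# indication names are free-text keys, compared case-insensitively after
# whitespace normalization
normalize_indication <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical fee formatting for CSV round trips: integer euros when whole,
# two decimals otherwise
format_fee_csv <- function(cents) {
  ifelse(cents %% 100L == 0L,
         formatC(cents %/% 100L, format = "d"),
         formatC(cents / 100, format = "f", digits = 2))
}
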