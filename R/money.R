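#' Round half-up
#'
#' Deterministic half-up rounding (0.5 always rounds away from zero),
#' independent of the IEEE round-half-even convention used by [round()].
#' Used for all monetary quantities so that printed tables are reproducible
#' to the cent.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (2 for cents, 0 for whole units).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(421.195, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an epsilon proportional to the magnitude so that values which are
  # exactly representable halves are not lost to binary round-off
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a monetary amount with two decimals
#'
#' @param x numeric vector of amounts (AUD).
#' @return character vector, two decimal places, no currency symbol.
#' @export
fmt_money <- function(x) {
  formatC(round_half_up(x, 2), format = "f", digits = 2)
}

# internal: validate a single non-negative finite number
check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop(what, " must be a single non-negative number, got ",
         deparse(substitute(x)), " = ", paste(x, collapse = ","),
         call. = FALSE)
  }
  invisible(x)
}
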