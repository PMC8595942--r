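#' @importFrom rlang .data abort warn
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# reverse complement of plain character DNA (A/C/G/T/N); vectorized
revcomp_chr <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# round-half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# percentages printed to 1 decimal, integral values without the ".0"
format_pct <- function(x) {
  x <- round_half_up(x, 1)
  ifelse(x == floor(x), sprintf("%d", as.integer(x)), sprintf("%.1f", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
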