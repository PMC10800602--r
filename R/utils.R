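#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pt qt rnorm runif rbinom rgamma rlnorm sd complete.cases setNames
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 36.35 -> 36.4), the convention used for the printed dysfunction
#' ratios, rather than base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# canonical unordered edge key: "i|j" with i < j (labels compared as given)
edge_key <- function(i, j) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  paste(a, b, sep = "|")
}

stop_dc <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop_dc(msg)
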