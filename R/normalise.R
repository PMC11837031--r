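#' Rank-based Gaussian (quantile) normalisation
#'
#' Maps a numeric vector monotonically onto standard-normal scores via
#' `qnorm((r - 0.5) / n)`, where `r` is the within-vector rank (average ranks
#' for ties) and `n` the number of non-missing values. The result depends on
#' the input only through its ranks, so any strictly monotone transform of
#' the input yields identical output; missing values stay missing.
#'
#' All numeric model variables in the association screen (IDPs, age, ACE-III
#' total, head size) pass through this transform, so linear-model slopes are
#' standardised effects and the ordinal-model slope is a log-odds per SD.
#'
#' @param values Numeric vector, possibly with `NA`; at least 3 distinct
#'   non-missing values are required.
#' @return Numeric vector of the same length.
#' @examples
#' quantile_normalise(c(10, 20, 30))
#' @export
quantile_normalise <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(values[ok])) == 1) {
    stop("all non-missing values identical: ranks carry no information",
         call. = FALSE)
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}
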