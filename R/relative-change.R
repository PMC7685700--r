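#' Relative (percentage) change between windows
#'
#' The universal shift measure used throughout the package:
#' `(after - before) / before * 100`. Every feature-level "change" in the
#' package (hourly activity, short-interval counts, lexicon-dimension counts,
#' category volumes) flows through this one function.
#'
#' When `before` is zero the ratio is undefined; the `zero_policy` decides
#' what happens. `"strict"` returns `NA`. `"pseudo"` substitutes one
#' event-equivalent (`pseudo_unit`, defaulting to a single event) for the
#' zero baseline, i.e. `(after - before) / pseudo_unit * 100`, which keeps
#' rare behaviors in the analysis at the cost of a scale assumption. For
#' per-day-normalized profiles, pass `pseudo_unit = 1 / window_days`.
#'
#' @param before,after Nonnegative numeric vectors (recycled).
#' @param zero_policy `"strict"` or `"pseudo"`.
#' @param pseudo_unit The event-equivalent used for a zero baseline under the
#'   `"pseudo"` policy.
#' @return Numeric vector of percentage changes (`NA` where undefined).
#' @examples
#' relative_change(100, 150)           # +50
#' relative_change(0, 7)               # NA under "strict"
#' relative_change(0, 7, "pseudo")     # +700
#' @export
relative_change <- function(before, after, zero_policy = c("strict", "pseudo"),
                            pseudo_unit = 1) {
  zero_policy <- match.arg(zero_policy)
  if (any(before < 0, na.rm = TRUE) || any(after < 0, na.rm = TRUE)) {
    abort("relative_change() requires nonnegative inputs")
  }
  n <- max(length(before), length(after))
  before <- rep_len(as.numeric(before), n)
  after <- rep_len(as.numeric(after), n)
  out <- (after - before) / before * 100
  zero <- !is.na(before) & before == 0
  out[zero] <- if (zero_policy == "strict") {
    NA_real_
  } else {
    (after[zero] - before[zero]) / pseudo_unit * 100
  }
  out
}
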