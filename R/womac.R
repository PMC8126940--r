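# WOMAC change scores and the utility map.

#' WOMAC change score
#'
#' Change is pre-operative total minus post-operative total, so a positive
#' change is an improvement (WOMAC is scored higher = worse). Both totals
#' must be on the same instrument range.
#'
#' @param pre,post Numeric WOMAC totals (vectorized).
#' @param total_max Instrument maximum; 240 for the 24-item 0--10 numeric
#'   rating version (the default), 96 for the Likert 0--4 version.
#' @return Numeric change scores, `pre - post`.
#' @export
womac_change <- function(pre, post, total_max = 240) {
  check_womac_total(pre, total_max, "pre")
  check_womac_total(post, total_max, "post")
  pre - post
}

check_womac_total <- function(total, total_max, what = "total") {
  if (total_max <= 0) stop("total_max must be positive")
  bad <- which(is.na(total) | total < 0 | total > total_max)
  if (length(bad))
    stop("WOMAC ", what, " total outside [0, ", total_max, "] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(total)
}

#' Map a WOMAC total to a health-state utility
#'
#' The utility is the linear complement of the WOMAC total on its range:
#' u = 1 - total / total_max, so a symptom-free patient (total 0) has
#' utility 1 and the worst score maps to 0. Under this map the utility gain
#' from surgery equals the WOMAC change score divided by `total_max`. The
#' map is deliberately isolated in this one function so an alternative
#' (e.g. a published crosswalk to a preference-based index) can be swapped
#' in without touching the QALY engine.
#'
#' @param total Numeric WOMAC totals (vectorized).
#' @inheritParams womac_change
#' @return Utilities in [0, 1].
#' @export
womac_to_utility <- function(total, total_max = 240) {
  check_womac_total(total, total_max)
  1 - total / total_max
}
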