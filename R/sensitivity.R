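#' Sensitivity weight from current and future suitability totals
#'
#' Suitability below the species' TSS threshold is zeroed, both surfaces
#' are summed, and the sensitivity weight is
#' `S = (sum_current - sum_future) / sum_future`: the habitat change as a
#' ratio of what remains. S = 1 means future suitability halved; negative S
#' means expansion. A species whose future total is zero (all suitable
#' habitat lost) is reported with `S = NA`, a `degenerate` flag, and
#' `sensitive = TRUE` rather than an infinite ratio, which keeps reports
#' finite and sortable.
#'
#' @param current,future `suitability_surface`s sharing subcatchment set
#'   and TSS threshold.
#' @return Object of class `sensitivity_result`: list(S, sum_current,
#'   sum_future, percent_change, degenerate, sensitive).
#' @export
sensitivity_weight <- function(current, future) {
  stopifnot(identical(current$subcatchment, future$subcatchment))
  tau_c <- attr(current, "tss_threshold")
  tau_f <- attr(future, "tss_threshold")
  if (is.na(tau_c) || is.na(tau_f) || tau_c != tau_f) {
    abort("Surfaces must share a (set) TSS threshold.")
  }
  zero_below <- function(v) ifelse(v >= tau_c, v, 0)
  sum_c <- sum(zero_below(current$suitability))
  sum_f <- sum(zero_below(future$suitability))
  if (sum_c == 0 && sum_f == 0) {
    abort("Both suitability totals are zero: species was never modelled as present.")
  }
  degenerate <- sum_f == 0
  S <- if (degenerate) NA_real_ else (sum_c - sum_f) / sum_f
  res <- structure(
    list(
      S = S, sum_current = sum_c, sum_future = sum_f,
      percent_change = if (sum_c > 0) 100 * (sum_f - sum_c) / sum_c else NA_real_,
      degenerate = degenerate, sensitive = NA
    ),
    class = "sensitivity_result"
  )
  res$sensitive <- classify_sensitivity(res)
  res
}

#' Classify a sensitivity result
#'
#' Highly vulnerable iff S is strictly above one, or the species loses all
#' suitable future habitat while having some now.
#'
#' @param result A `sensitivity_result`.
#' @param cut Sensitivity cut (default 1).
#' @return Logical flag.
#' @export
classify_sensitivity <- function(result, cut = 1) {
  if (isTRUE(result$degenerate)) {
    return(result$sum_current > 0)
  }
  isTRUE(result$S > cut)
}

#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) {
  tibble(
    sum_current = x$sum_current, sum_future = x$sum_future,
    S = x$S, percent_change = x$percent_change,
    degenerate = x$degenerate, sensitive = x$sensitive
  )
}
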