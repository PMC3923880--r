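#' Exposure of a species' current habitat to one factor
#'
#' Mean, over the species' currently suitable subcatchments, of the
#' absolute projected shift expressed in standard-deviation units:
#' `mean(|future - current|) / SD`. By default the SD basis is the spatial
#' SD of current values across the species' suitable habitat (a stand-in
#' for the inter-annual variation the species is assumed to tolerate);
#' externally supplied per-factor SDs are accepted via `sd_mode =
#' "supplied"`.
#'
#' @param current,future Numeric vectors of per-subcatchment factor values,
#'   aligned.
#' @param suitable Logical mask of the species' current habitat, aligned.
#' @param sd_mode `"habitat"` (default) or `"supplied"`.
#' @param sd_value SD to use when `sd_mode = "supplied"`.
#' @param factor Factor name used in error messages.
#' @return Exposure in SD units (non-negative scalar).
#' @export
factor_exposure <- function(current, future, suitable, sd_mode = c("habitat", "supplied"),
                            sd_value = NULL, factor = "factor") {
  sd_mode <- match.arg(sd_mode)
  stopifnot(length(current) == length(future), length(current) == length(suitable))
  if (!any(suitable)) abort("Habitat mask is empty; exposure undefined.")
  s <- switch(sd_mode,
    habitat = sd(current[suitable]),
    supplied = sd_value
  )
  if (is.null(s) || !is.finite(s) || s <= 0) {
    abort(sprintf("Zero or invalid SD for factor '%s'; exposure undefined.", factor))
  }
  mean(abs(future[suitable] - current[suitable])) / s
}

#' Fraction of current habitat within reach of sea-level rise
#'
#' @param elevation Per-subcatchment mean elevation (m), aligned with
#'   `suitable`.
#' @param suitable Logical habitat mask.
#' @param rise Sea-level rise in m (default 1).
#' @return Proportion of suitable subcatchments with mean elevation <=
#'   `rise`.
#' @export
sea_level_fraction <- function(elevation, suitable, rise = 1) {
  stopifnot(length(elevation) == length(suitable))
  if (!any(suitable)) abort("Habitat mask is empty; sea-level fraction undefined.")
  mean(elevation[suitable] <= rise)
}

#' Apply the exposure flagging rules
#'
#' A species is exposed if any factor shifts by more than `single_cut` SDs,
#' if at least `multi_n` factors shift by more than `multi_cut` SDs, or if
#' at least `sea_cut` of its habitat lies within `rise` m of sea level.
#'
#' @param factor_exposures Named numeric vector of per-factor exposures (SD
#'   units).
#' @param sea_fraction Proportion from [sea_level_fraction()].
#' @param single_cut Single-factor cut in SD (default 2).
#' @param multi_cut Multi-factor cut in SD (default 1).
#' @param multi_n Number of factors for the multi rule (default 2).
#' @param sea_cut Sea-level habitat fraction cut (default 0.10).
#' @return Object of class `exposure_result`: list(factor_exposures,
#'   sea_fraction, exposed, reasons).
#' @export
exposure_flag <- function(factor_exposures, sea_fraction = 0, single_cut = 2,
                          multi_cut = 1, multi_n = 2, sea_cut = 0.10) {
  stopifnot(length(factor_exposures) >= 1)
  reasons <- character(0)
  if (any(factor_exposures > single_cut)) reasons <- c(reasons, "single-factor>2SD")
  if (sum(factor_exposures > multi_cut) >= multi_n) reasons <- c(reasons, "multi-factor>1SD")
  if (sea_fraction >= sea_cut) reasons <- c(reasons, "sea-level")
  structure(
    list(
      factor_exposures = factor_exposures, sea_fraction = sea_fraction,
      exposed = length(reasons) > 0, reasons = reasons
    ),
    class = "exposure_result"
  )
}

#' @method tidy exposure_result
#' @export
tidy.exposure_result <- function(x, ...) {
  tibble(
    factor = names(x$factor_exposures),
    exposure_sd = unname(x$factor_exposures),
    sea_fraction = x$sea_fraction,
    exposed = x$exposed,
    reasons = paste(x$reasons, collapse = ";")
  )
}

#' Default mapping from modelling factors to exposure factors
#'
#' Exposure is assessed on the mean and seasonality of temperature and
#' precipitation plus mean annual flow; the wet/dry-quarter precipitation
#' pair is averaged into a single precipitation-mean measure.
#'
#' @return Named list: exposure factor -> modelling factor(s) averaged.
#' @export
default_exposure_mapping <- function() {
  list(
    tmean = "tmean", tseasonality = "tseasonality",
    precip = c("p_wet", "p_dry"), p_seasonality = "p_seasonality",
    flow = "flow"
  )
}

#' Assess exposure of one species under one future scenario
#'
#' @param current_stack,future_stack `scenario_stack`s sharing a
#'   subcatchment set.
#' @param habitat_subcatchments Character vector of the species' currently
#'   suitable subcatchment ids.
#' @param landscape A `vuln_landscape` (supplies subcatchment elevations).
#' @param mapping Exposure-factor mapping, see
#'   [default_exposure_mapping()].
#' @param rise Sea-level rise in m.
#' @param sd_mode,supplied_sd SD basis; `supplied_sd` is a named vector of
#'   per-exposure-factor SDs when `sd_mode = "supplied"`.
#' @inheritParams exposure_flag
#' @return An `exposure_result`.
#' @export
assess_exposure <- function(current_stack, future_stack, habitat_subcatchments,
                            landscape, mapping = default_exposure_mapping(),
                            rise = 1, single_cut = 2, multi_cut = 1, multi_n = 2,
                            sea_cut = 0.10, sd_mode = "habitat", supplied_sd = NULL) {
  stopifnot(identical(current_stack$subcatchment, future_stack$subcatchment))
  suitable <- current_stack$subcatchment %in% habitat_subcatchments
  exposures <- vapply(names(mapping), function(ef) {
    cols <- mapping[[ef]]
    cur <- rowMeans(as.data.frame(current_stack[cols]))
    fut <- rowMeans(as.data.frame(future_stack[cols]))
    factor_exposure(cur, fut, suitable,
      sd_mode = sd_mode,
      sd_value = supplied_sd[[ef]] %||% NULL, factor = ef
    )
  }, numeric(1))
  elev <- landscape$subcatchments$mean_elev[
    match(current_stack$subcatchment, landscape$subcatchments$subcatchment)
  ]
  sea <- sea_level_fraction(elev, suitable, rise = rise)
  exposure_flag(exposures, sea,
    single_cut = single_cut, multi_cut = multi_cut,
    multi_n = multi_n, sea_cut = sea_cut
  )
}
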