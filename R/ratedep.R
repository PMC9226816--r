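# Rate-dependence statistics: APD prolongation at long vs short cycle length,
# percentage APD shortening, and reverse/positive classification.

#' APD prolongation with respect to control
#'
#' @param intervention_apd,control_apd APD90 values (ms) at the same BCL and
#'   model.
#' @return `intervention_apd - control_apd`, ms.
#' @export
delta_apd <- function(intervention_apd, control_apd) {
  intervention_apd - control_apd
}

#' Percentage APD shortening between slow and fast pacing
#'
#' Defined as `100 * (APD_BCL=3000 - APD_BCL=400) / APD_BCL=3000`.
#'
#' @param apd_3000 steady-state APD90 at the long BCL, ms (> 0).
#' @param apd_400 steady-state APD90 at the short BCL, ms.
#' @return percentage shortening.
#' @export
pct_shortening <- function(apd_3000, apd_400) {
  if (any(!is.finite(apd_3000)) || any(apd_3000 <= 0))
    stop("apd_3000 must be positive")
  100 * (apd_3000 - apd_400) / apd_3000
}

#' Classify the rate dependence of an intervention
#'
#' The rate-dependence index is `delta_short - delta_long`: the APD
#' prolongation (vs control) at the short BCL minus the prolongation at the
#' long BCL. Positive values mean the intervention prolongs more at fast
#' rates (positive rate dependence); negative values mean reverse rate
#' dependence. A small neutral band absorbs integration noise.
#'
#' @param rd_index rate-dependence index, ms.
#' @param neutral_band half-width of the neutral band, ms (default 0.5).
#' @return `"positive"`, `"reverse"` or `"neutral"`.
#' @export
classify_rate_dependence <- function(rd_index, neutral_band = 0.5) {
  stopifnot(is.finite(rd_index), neutral_band >= 0)
  if (rd_index > neutral_band) "positive"
  else if (rd_index < -neutral_band) "reverse"
  else "neutral"
}

#' Rate-dependence result for one intervention/control pair
#'
#' Combines steady-state APD90 values of an intervention and of control at a
#' long and a short BCL into the rate-dependence statistics: the APD
#' prolongations at each rate, the rate-dependence index
#' (`delta_short - delta_long`), the percentage APD shortening of the
#' intervention between the two rates, and the reverse/positive
#' classification.
#'
#' @param apd_long,apd_short intervention APD90 (ms) at `bcl_long`/`bcl_short`.
#' @param control_long,control_short control APD90 (ms) at the same BCLs.
#' @param bcl_long,bcl_short the two reference cycle lengths, ms (defaults
#'   3000 and 400).
#' @param neutral_band classification band, ms.
#' @return an object of class `rate_dependence_result`.
#' @export
rate_dependence <- function(apd_long, apd_short, control_long, control_short,
                            bcl_long = 3000, bcl_short = 400,
                            neutral_band = 0.5) {
  dl <- delta_apd(apd_long, control_long)
  ds <- delta_apd(apd_short, control_short)
  rd <- ds - dl
  structure(list(
    apd_long = apd_long, apd_short = apd_short,
    control_long = control_long, control_short = control_short,
    bcl_long = bcl_long, bcl_short = bcl_short,
    delta_long = dl, delta_short = ds, rd_index = rd,
    pct_shortening = pct_shortening(apd_long, apd_short),
    classification = classify_rate_dependence(rd, neutral_band)),
    class = "rate_dependence_result")
}

#' @export
print.rate_dependence_result <- function(x, ...) {
  cat(sprintf(paste0("<rate_dependence> dAPD(long)=%.1f dAPD(short)=%.1f ms, ",
                     "rd_index=%.1f ms (%s), shortening=%.1f%%\n"),
              x$delta_long, x$delta_short, x$rd_index, x$classification,
              x$pct_shortening))
  invisible(x)
}
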