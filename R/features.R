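# Action potential phase segmentation and shape features.
#
# Phase boundaries follow operational, current-based definitions: phase 1 runs
# from depolarization to the first sign change (negative to positive) of the
# total ionic current; phase 2 ends when IK1 first reaches 10% of its peak
# over the repolarization window; phase 3 ends at 90% repolarization of the
# action potential amplitude. All landmark crossings are linearly interpolated
# between samples.

.check_trace <- function(trace, need = c("time_ms", "Vm_mV")) {
  if (!is.data.frame(trace)) stop("trace must be a data.frame")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(trace) < 3) stop("trace too short")
  if (is.unsorted(trace$time_ms, strictly = TRUE))
    stop("trace time must be strictly increasing")
  invisible(trace)
}

# linear interpolation of the time at which y crosses level `lev` between
# samples k-1 and k
.cross_time <- function(t, y, k, lev) {
  t[k - 1] + (lev - y[k - 1]) * (t[k] - t[k - 1]) / (y[k] - y[k - 1])
}

# index of the sample taken just before the upstroke (takeoff): walk back from
# the maximum-slope segment while the local slope still exceeds 1 mV/ms
.takeoff_index <- function(t, v, i_up) {
  dv <- diff(v) / diff(t)
  i <- i_up
  while (i > 1 && dv[i - 1] > 1) i <- i - 1
  i
}

#' Segment an action potential into phases 1-3
#'
#' Locates the upstroke, the end of phase 1 (first negative-to-positive sign
#' change of the total ionic current after the upstroke), the end of phase 2
#' (IK1 first reaching 10% of its peak over the repolarization window) and
#' APD90 (90% repolarization of the amplitude), with linear interpolation at
#' every crossing.
#'
#' @param trace a data.frame with columns `time_ms`, `Vm_mV`, `Iion`, `IK1`
#'   containing one captured action potential.
#' @return an object of class `phase_segmentation`: list with `t_upstroke`,
#'   `t_phase1_end`, `t_phase2_end`, `t_apd90`, the three phase durations,
#'   `takeoff_vm`, `peak_vm`, `apa` and `vm_phase2_end` (membrane potential at
#'   the phase-2/3 boundary).
#' @export
segment_phases <- function(trace) {
  .check_trace(trace, c("time_ms", "Vm_mV", "Iion", "IK1"))
  t <- trace$time_ms; v <- trace$Vm_mV
  iion <- trace$Iion; ik1 <- trace$IK1

  dv <- diff(v) / diff(t)
  i_up <- which.max(dv)                 # steepest segment = upstroke
  t_up <- t[i_up]
  i_take <- .takeoff_index(t, v, i_up)
  v_take <- v[i_take]

  i_peak <- i_up + which.max(v[i_up:length(v)]) - 1L
  v_peak <- v[i_peak]
  apa <- v_peak - v_take
  if (apa <= 0) stop("segmentation error: no action potential amplitude")

  # phase-1 end: first - to + sign change of Iion after the inward surge
  i_min <- which.min(iion)
  k1 <- NA_integer_
  for (k in seq(i_min + 1L, length(iion))) {
    if (iion[k - 1] <= 0 && iion[k] > 0) { k1 <- k; break }
  }
  if (is.na(k1)) stop("segmentation error: no sign change of Iion (phase-1 end)")
  t1 <- .cross_time(t, iion, k1, 0)

  # APD90: 90% repolarization from peak
  v90 <- v_peak - 0.9 * apa
  k9 <- NA_integer_
  for (k in seq(i_peak + 1L, length(v))) {
    if (v[k - 1] > v90 && v[k] <= v90) { k9 <- k; break }
  }
  if (is.na(k9)) stop("segmentation error: no APD90 crossing within the beat")
  t9 <- .cross_time(t, v, k9, v90)

  # phase-2 end: IK1 reaches 10% of its peak over [t1, end of beat]
  win <- which(t >= t1)
  pk <- max(ik1[win])
  if (pk <= 0) stop("segmentation error: no IK1 rise in repolarization window")
  thr <- 0.10 * pk
  k2 <- NA_integer_
  for (k in win[-1]) {
    if (ik1[k - 1] < thr && ik1[k] >= thr) { k2 <- k; break }
  }
  if (is.na(k2)) stop("segmentation error: no IK1 10%-of-peak crossing (phase-2 end)")
  t2 <- .cross_time(t, ik1, k2, thr)
  vm2 <- approx(t, v, xout = t2)$y

  if (!(t_up < t1 && t1 < t2 && t2 < t9))
    stop(sprintf(paste0("segmentation error: landmarks out of order ",
                        "(up=%.2f, p1=%.2f, p2=%.2f, apd90=%.2f ms)"),
                 t_up, t1, t2, t9))

  structure(list(t_upstroke = t_up, t_phase1_end = t1, t_phase2_end = t2,
                 t_apd90 = t9,
                 phase1 = t1 - t_up, phase2 = t2 - t1, phase3 = t9 - t2,
                 takeoff_vm = v_take, peak_vm = v_peak, apa = apa,
                 vm_phase2_end = vm2),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<phase_segmentation> up %.2f | p1 end %.2f | p2 end %.2f",
                     " | APD90 %.2f ms (Vm at p2 end %.1f mV)\n"),
              x$t_upstroke, x$t_phase1_end, x$t_phase2_end, x$t_apd90,
              x$vm_phase2_end))
  invisible(x)
}

#' Average total ionic current between two points of the action potential
#'
#' For a single cell the membrane current is zero, so the total ionic current
#' equals `-Cm dVm/dt`; integrating between two times shows that the average
#' ionic current (in pA/pF) over `[t1, t2]` is the negative slope of the line
#' joining the two membrane potentials: `-(Vm(t2) - Vm(t1)) / (t2 - t1)`.
#'
#' @param trace a trace data.frame with `time_ms` and `Vm_mV`.
#' @param t1,t2 interval bounds, ms, with `t2 > t1`, both inside the trace.
#' @return average ionic current, pA/pF.
#' @export
avg_ionic_current <- function(trace, t1, t2) {
  .check_trace(trace)
  if (!(is.finite(t1) && is.finite(t2)) || t2 <= t1)
    stop("t2 must be greater than t1")
  tr <- range(trace$time_ms)
  if (t1 < tr[1] || t2 > tr[2]) stop("t1, t2 must lie inside the trace")
  v <- approx(trace$time_ms, trace$Vm_mV, xout = c(t1, t2))$y
  -(v[2] - v[1]) / (t2 - t1)
}

# trapezoidal integral of (Vm - baseline) over [ta, tb], with interpolated
# endpoints
.auc_above <- function(t, v, baseline, ta, tb) {
  va <- approx(t, v, xout = ta)$y
  vb <- approx(t, v, xout = tb)$y
  keep <- t > ta & t < tb
  tt <- c(ta, t[keep], tb)
  vv <- c(va, v[keep], vb) - baseline
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
}

#' Extract the action potential feature set
#'
#' Computes the shape features used to relate action potential morphology to
#' its rate dependence: amplitude (APA), APD90, phase 1-3 durations, the
#' average total ionic current during phases 2 and 3 (via the slope identity,
#' see [avg_ionic_current()]), their ratio (a triangulation index: smaller
#' means more triangular), and the area under the action potential above the
#' takeoff potential from the upstroke to APD90, normalized to APD90 x APA
#' (`auap_norm`; 1 for a rectangle).
#'
#' If the trace lacks `Iion`/`IK1` columns the phase-based features are `NA`
#' and only APA, APD90 and `auap_norm` are computed (useful for idealized
#' fixture shapes without current columns).
#'
#' @param trace a trace data.frame (see [segment_phases()]).
#' @return an object of class `feature_set`.
#' @export
extract_features <- function(trace) {
  .check_trace(trace)
  has_currents <- all(c("Iion", "IK1") %in% names(trace))
  t <- trace$time_ms; v <- trace$Vm_mV

  if (has_currents) {
    seg <- segment_phases(trace)
    apa <- seg$apa
    apd90 <- seg$t_apd90 - seg$t_upstroke
    i2 <- avg_ionic_current(trace, seg$t_phase1_end, seg$t_phase2_end)
    i3 <- avg_ionic_current(trace, seg$t_phase2_end, seg$t_apd90)
    auap <- .auc_above(t, v, seg$takeoff_vm, seg$t_upstroke, seg$t_apd90)
    out <- list(apa = apa, apd90 = apd90,
                phase1 = seg$phase1, phase2 = seg$phase2, phase3 = seg$phase3,
                iion_phase2 = i2, iion_phase3 = i3, ratio = i3 / i2,
                auap_norm = auap / (apd90 * apa),
                takeoff_vm = seg$takeoff_vm, peak_vm = seg$peak_vm,
                vm_phase2_end = seg$vm_phase2_end,
                segmentation = seg)
  } else {
    dv <- diff(v) / diff(t)
    i_up <- which.max(dv)
    t_up <- t[i_up]
    i_take <- .takeoff_index(t, v, i_up)
    v_take <- v[i_take]
    i_peak <- i_up + which.max(v[i_up:length(v)]) - 1L
    v_peak <- v[i_peak]
    apa <- v_peak - v_take
    v90 <- v_peak - 0.9 * apa
    k9 <- NA_integer_
    for (k in seq(i_peak + 1L, length(v))) {
      if (v[k - 1] > v90 && v[k] <= v90) { k9 <- k; break }
    }
    if (is.na(k9)) stop("no APD90 crossing within the trace")
    t9 <- .cross_time(t, v, k9, v90)
    apd90 <- t9 - t_up
    auap <- .auc_above(t, v, v_take, t_up, t9)
    out <- list(apa = apa, apd90 = apd90,
                phase1 = NA_real_, phase2 = NA_real_, phase3 = NA_real_,
                iion_phase2 = NA_real_, iion_phase3 = NA_real_,
                ratio = NA_real_, auap_norm = auap / (apd90 * apa),
                takeoff_vm = v_take, peak_vm = v_peak,
                vm_phase2_end = NA_real_, segmentation = NULL)
  }
  structure(out, class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> APA=%.1f mV APD90=%.1f ms", x$apa, x$apd90))
  if (is.finite(x$phase2))
    cat(sprintf(" | phases %.1f/%.1f/%.1f ms | Iion p2=%.3f p3=%.3f (ratio %.2f)",
                x$phase1, x$phase2, x$phase3,
                x$iion_phase2, x$iion_phase3, x$ratio))
  cat(sprintf(" | AUAP=%.3f\n", x$auap_norm))
  invisible(x)
}
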