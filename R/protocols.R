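# Stimulation protocols: threshold search, steady-state pacing, restitution
# and the repolarization-reserve current-injection protocol.

# session-level caches: simulated APDs (keyed on rounded multipliers, BCL,
# pacing length, dt) and stimulation thresholds (keyed per parameter set)
.sim_cache <- new.env(parent = emptyenv())

#' Clear the simulation cache
#'
#' Pacing results and thresholds are memoised per parameter set to avoid
#' repeating identical multi-minute simulations (the integration is
#' deterministic, so caching is lossless).
#' @return invisibly, the number of entries removed.
#' @export
clear_sim_cache <- function() {
  n <- length(ls(.sim_cache))
  rm(list = ls(.sim_cache), envir = .sim_cache)
  invisible(n)
}

.cache_key <- function(params, ...) {
  extra <- c(...)
  paste(params$model, sprintf("%.3f", params$sKs), sprintf("%.3f", params$sKr),
        sprintf("%.3f", params$sK1), sprintf("%g", params$stim_duration),
        paste(names(extra), as.character(extra), sep = "=", collapse = "|"),
        sep = "|")
}

.cache_get <- function(key) {
  if (exists(key, envir = .sim_cache, inherits = FALSE))
    get(key, envir = .sim_cache, inherits = FALSE)
  else NULL
}

.cache_set <- function(key, value) {
  assign(key, value, envir = .sim_cache)
  value
}

#' Stimulation threshold of a rectangular pulse
#'
#' Finds, by bisection to 1% relative tolerance, the minimal rectangular-pulse
#' amplitude that elicits an action potential from rest, where an action
#' potential is an overshoot of Vm above 0 mV within 10 ms of stimulus onset.
#' Pacing stimuli are applied at `stim_scale` (default 1.5) times this value.
#'
#' @param params a [scaled_params()] object (the threshold depends on the
#'   conductance multipliers, notably sK1).
#' @param stim_duration pulse duration, ms (defaults to the value in
#'   `params`).
#' @param dt integration step, ms.
#' @param upper upper search bound, pA/pF; no capture at this amplitude is an
#'   error.
#' @return threshold amplitude in pA/pF (positive magnitude).
#' @export
find_threshold <- function(params = scaled_params(),
                           stim_duration = params$stim_duration, dt = 0.02,
                           upper = 100) {
  params <- as_scaled_params(params)
  key <- .cache_key(params, thr_dur = stim_duration, dt = dt)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)

  mod <- get_model(params$model)
  init <- mod$initial_state()
  captures <- function(amp) {
    r <- mod$pace_engine(init, params, amp, stim_duration, bcl = 50,
                         n_beats = 1L, dt = dt, sample_ms = 1,
                         inject_amp = 0, record_last = FALSE,
                         record_all = FALSE)
    r$vmax10[1] > 0
  }
  if (!captures(upper))
    stop("no excitation at the upper search bound (", upper, " pA/pF)")
  lo <- 0; hi <- upper
  while ((hi - lo) / hi > 0.01) {
    mid <- (hi + lo) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  .cache_set(key, hi)
}

.stim_amplitude <- function(params, dt) {
  if (!is.null(params$stim_amplitude)) return(params$stim_amplitude)
  params$stim_scale * find_threshold(params, dt = dt)
}

#' Pace the model at a fixed cycle length
#'
#' Paces from the published initial conditions for `minutes` of simulated time
#' (or `n_beats` beats) at basic cycle length `bcl` and returns the final
#' beat: its sampled trace (time, Vm and the IKs/IKr/IK1/total ionic
#' currents), per-beat APD90 diagnostics, a 1:1-capture flag and an alternans
#' flag. Integration is Rush-Larsen for gating variables and forward Euler
#' otherwise, at fixed `dt`; the result is fully deterministic.
#'
#' @param params a [scaled_params()] object.
#' @param bcl basic cycle length, ms.
#' @param minutes pacing duration in simulated minutes (default 16, after
#'   which APD90 is within 1 ms of its steady-state value).
#' @param n_beats number of beats; overrides `minutes` when given. `0` returns
#'   the initial conditions with no trace.
#' @param dt integration step, ms (default 0.02).
#' @param sample_ms trace sampling interval, ms (default 0.1).
#' @param record record the final-beat trace (default TRUE).
#' @param init_state optional starting state (defaults to the published
#'   initial conditions).
#' @param inject extra constant current (pA/pF, signed; depolarizing is
#'   negative) applied during the final beat from stimulus onset until its
#'   APD90 crossing. Used by [repolarization_reserve()].
#' @param cache memoise the headline numbers of this run (default TRUE).
#' @return an object of class `beat_record`: list with `trace` (data.frame),
#'   `apd90` (final beat, ms), `apd90_beats` (all beats), `takeoff_vm`,
#'   `captured`, `alternans`, `repol_fail`, `stim_amplitude`, `threshold`,
#'   `final_state`, `last_beat_state`, and the protocol settings.
#' @examples
#' \donttest{
#' rec <- pace(scaled_params(), bcl = 1000, n_beats = 5)
#' rec$apd90
#' }
#' @export
pace <- function(params = scaled_params(), bcl = 3000, minutes = 16,
                 n_beats = NULL, dt = 0.02, sample_ms = 0.1, record = TRUE,
                 init_state = NULL, inject = 0, cache = TRUE) {
  params <- as_scaled_params(params)
  mod <- get_model(params$model)
  if (is.null(n_beats)) n_beats <- as.integer(floor(minutes * 60000 / bcl))
  if (n_beats == 0) {
    s0 <- if (is.null(init_state)) mod$initial_state() else init_state
    return(structure(list(trace = NULL, apd90 = NA_real_,
                          apd90_beats = numeric(0), takeoff_vm = s0[["Vm"]],
                          captured = NA, alternans = NA, repol_fail = FALSE,
                          stim_amplitude = NA_real_, threshold = NA_real_,
                          final_state = s0, last_beat_state = s0,
                          bcl = bcl, n_beats = 0L, dt = dt, params = params),
                     class = "beat_record"))
  }
  thr <- if (is.null(params$stim_amplitude)) find_threshold(params, dt = dt)
         else NA_real_
  amp <- .stim_amplitude(params, dt)
  init <- if (is.null(init_state)) mod$initial_state() else init_state

  r <- mod$pace_engine(init, params, amp, params$stim_duration, bcl,
                       as.integer(n_beats), dt, sample_ms, inject,
                       record_last = record, record_all = FALSE)
  nb <- length(r$apd90)
  last10 <- r$captured[max(1, nb - 9):nb]
  apds <- r$apd90
  alternans <- nb >= 2 && is.finite(apds[nb]) && is.finite(apds[nb - 1]) &&
    abs(apds[nb] - apds[nb - 1]) > 2
  trace <- if (record) as.data.frame(r$trace) else NULL

  rec <- structure(list(
    trace = trace, apd90 = apds[nb], apd90_beats = apds,
    takeoff_vm = r$takeoff[nb], captured = all(last10),
    alternans = alternans, repol_fail = isTRUE(r$repol_fail),
    stim_amplitude = amp, threshold = thr,
    final_state = r$final_state, last_beat_state = r$last_beat_state,
    bcl = bcl, n_beats = as.integer(n_beats), dt = dt, params = params),
    class = "beat_record")

  if (cache && inject == 0 && is.null(init_state)) {
    key <- .cache_key(params, bcl = bcl, n_beats = n_beats, dt = dt, tag = 0)
    .cache_set(key, list(apd90 = rec$apd90, captured = rec$captured,
                         alternans = rec$alternans,
                         repol_fail = rec$repol_fail))
  }
  rec
}

#' @export
print.beat_record <- function(x, ...) {
  cat(sprintf("<beat_record> bcl=%g ms, %d beats, APD90=%.2f ms, capture=%s%s\n",
              x$bcl, x$n_beats, x$apd90, x$captured,
              if (isTRUE(x$alternans)) " [alternans]" else ""))
  invisible(x)
}

# cached final-beat APD90 (the building block of restitution, the optimizer
# objective and the acceptance runs); `init_state`/`tag` support warm-started
# evaluations (tag keeps warm and cold entries apart in the cache)
.apd_at <- function(params, bcl, minutes = 16, dt = 0.02, init_state = NULL,
                    tag = 0) {
  params <- as_scaled_params(params)
  n_beats <- as.integer(floor(minutes * 60000 / bcl))
  key <- .cache_key(params, bcl = bcl, n_beats = n_beats, dt = dt, tag = tag)
  hit <- .cache_get(key)
  if (is.null(hit)) {
    rec <- pace(params, bcl = bcl, n_beats = n_beats, dt = dt, record = FALSE,
                init_state = init_state, cache = FALSE)
    hit <- .cache_set(key, list(apd90 = rec$apd90, captured = rec$captured,
                                alternans = rec$alternans,
                                repol_fail = rec$repol_fail))
  }
  hit
}

# control steady state at a BCL: full 16-min pacing, memoised with its final
# state so shortened warm-started runs can depart from it
.control_steady <- function(bcl, dt = 0.02, model = "tnnp2004epi") {
  params <- scaled_params(model = model)
  key <- .cache_key(params, bcl = bcl, dt = dt, tag = 16)
  hit <- .cache_get(key)
  if (is.null(hit)) {
    rec <- pace(params, bcl = bcl, minutes = 16, dt = dt, record = FALSE)
    hit <- .cache_set(key, list(apd90 = rec$apd90, captured = rec$captured,
                                alternans = rec$alternans,
                                repol_fail = rec$repol_fail,
                                final_state = rec$final_state))
  }
  hit
}

#' Steady-state APD90 restitution over a set of cycle lengths
#'
#' Each BCL is paced independently from the published initial conditions for
#' `minutes` of simulated time; the final-beat APD90 is reported.
#'
#' @inheritParams pace
#' @param bcls vector of basic cycle lengths, ms.
#' @return a data.frame with columns `bcl`, `apd90`, `captured`, `alternans`.
#' @export
restitution <- function(params = scaled_params(), bcls = c(400, 3000),
                        minutes = 16, dt = 0.02) {
  params <- as_scaled_params(params)
  rows <- lapply(bcls, function(b) {
    r <- .apd_at(params, b, minutes = minutes, dt = dt)
    data.frame(bcl = b, apd90 = r$apd90, captured = r$captured,
               alternans = r$alternans)
  })
  do.call(rbind, rows)
}

#' Repolarization reserve by constant depolarizing current injection
#'
#' Estimates the repolarization reserve of the steady-state beat as the
#' percentage APD90 prolongation when a constant depolarizing current
#' (default -0.1 pA/pF) is injected during the action potential, from the
#' upstroke until repolarization to APD90 completes. A larger prolongation
#' means a smaller reserve. Failure to repolarize within one BCL under the
#' injection is reported as infinite prolongation.
#'
#' @inheritParams pace
#' @param inject injected current, pA/pF (negative = depolarizing).
#' @return list with `pct_prolongation`, `apd_baseline`, `apd_injected`,
#'   `repol_fail`.
#' @export
repolarization_reserve <- function(params = scaled_params(), bcl = 3000,
                                   inject = -0.1, minutes = 16, dt = 0.02,
                                   n_beats = NULL) {
  params <- as_scaled_params(params)
  base <- pace(params, bcl = bcl, minutes = minutes, n_beats = n_beats,
               dt = dt, record = FALSE)
  if (!isTRUE(base$captured) || !is.finite(base$apd90))
    stop("baseline pacing lost 1:1 capture; reserve undefined")
  mod <- get_model(params$model)
  amp <- base$stim_amplitude
  r <- mod$pace_engine(base$last_beat_state, params, amp,
                       params$stim_duration, bcl, 1L, dt, 0.1, inject,
                       record_last = FALSE, record_all = FALSE)
  if (isTRUE(r$repol_fail) || !is.finite(r$apd90[1])) {
    return(list(pct_prolongation = Inf, apd_baseline = base$apd90,
                apd_injected = NA_real_, repol_fail = TRUE))
  }
  list(pct_prolongation = 100 * (r$apd90[1] - base$apd90) / base$apd90,
       apd_baseline = base$apd90, apd_injected = r$apd90[1],
       repol_fail = FALSE)
}
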