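# Ionic model interface and the TNNP 2006 epicardial implementation.

#' The ten Tusscher-Panfilov (2006) epicardial cell model
#'
#' Returns the built-in human ventricular epicardial ionic model (the 2006
#' CellML-distributed parameterization) as an `ionic_model` plugin object.
#' The three repolarizing potassium conductances GKs, GKr and GK1 are scalable
#' through [scaled_params()]; all other parameters are the published values.
#'
#' All currents are normalized to membrane capacitance (pA/pF), outward
#' positive, and the membrane equation is `dVm/dt = -(Iion + i_stim)` so a
#' depolarizing stimulus is negative.
#'
#' @return an object of class `ionic_model`.
#' @examples
#' mod <- tnnp_model()
#' s0 <- mod$initial_state()
#' mod$currents(s0, scaled_params())[["IK1"]]
#' @export
tnnp_model <- function() {
  structure(list(
    name = "tnnp2006epi",
    state_names = names(cpp_tnnp_init()),
    mult_ranges = list(sKs = c(0, 2), sKr = c(0, 2), sK1 = c(0.2, 2)),
    initial_state = function() cpp_tnnp_init(),
    derivatives = function(state, params, i_stim = 0) {
      p <- as_scaled_params(params)
      cpp_tnnp_derivs(state, p$sKs, p$sKr, p$sK1, i_stim)
    },
    currents = function(state, params) {
      p <- as_scaled_params(params)
      cpp_tnnp_currents(state, p$sKs, p$sKr, p$sK1)
    },
    step = function(state, params, i_stim = 0, dt = 0.02) {
      p <- as_scaled_params(params)
      cpp_tnnp_step(state, p$sKs, p$sKr, p$sK1, i_stim, dt)
    },
    pace_engine = function(init_state, params, stim_amp, stim_dur, bcl,
                           n_beats, dt, sample_ms, inject_amp, record_last,
                           record_all) {
      cpp_tnnp_pace(init_state, params$sKs, params$sKr, params$sK1,
                    stim_amp, stim_dur, bcl, n_beats, dt, sample_ms,
                    inject_amp, record_last, record_all)
    }
  ), class = "ionic_model")
}

#' The ten Tusscher-Noble-Noble-Panfilov (2004) epicardial cell model
#'
#' Returns the original TNNP human ventricular epicardial ionic model (2004,
#' CellML-distributed parameterization) as an `ionic_model` plugin object.
#' This is the default model of the package: its smaller maximal IKs and IKr
#' conductances (0.245 and 0.096 nS/pF) reproduce the reference
#' conductance-intervention APD values, whereas the 2006 revision
#' ([tnnp_model()]) carries a much larger IKs. Same conventions as
#' [tnnp_model()].
#'
#' @return an object of class `ionic_model`.
#' @export
tnnp04_model <- function() {
  structure(list(
    name = "tnnp2004epi",
    state_names = names(cpp_tnnp04_init()),
    mult_ranges = list(sKs = c(0, 2), sKr = c(0, 2), sK1 = c(0.2, 2)),
    initial_state = function() cpp_tnnp04_init(),
    derivatives = function(state, params, i_stim = 0) {
      p <- as_scaled_params(params)
      cpp_tnnp04_derivs(state, p$sKs, p$sKr, p$sK1, i_stim)
    },
    currents = function(state, params) {
      p <- as_scaled_params(params)
      cpp_tnnp04_currents(state, p$sKs, p$sKr, p$sK1)
    },
    step = function(state, params, i_stim = 0, dt = 0.02) {
      p <- as_scaled_params(params)
      cpp_tnnp04_step(state, p$sKs, p$sKr, p$sK1, i_stim, dt)
    },
    pace_engine = function(init_state, params, stim_amp, stim_dur, bcl,
                           n_beats, dt, sample_ms, inject_amp, record_last,
                           record_all) {
      cpp_tnnp04_pace(init_state, params$sKs, params$sKr, params$sK1,
                      stim_amp, stim_dur, bcl, n_beats, dt, sample_ms,
                      inject_amp, record_last, record_all)
    }
  ), class = "ionic_model")
}

#' Conductance multipliers and stimulus description
#'
#' Bundles the three potassium conductance multipliers with the stimulus
#' description used by the pacing protocols. Multipliers of exactly 1
#' reproduce the unmodified published model. `stim_amplitude = NULL` means
#' "determine the threshold with a 1-ms pulse and pace at `stim_scale` times
#' threshold", the protocol used throughout.
#'
#' @param sKs,sKr,sK1 multipliers on the maximal IKs, IKr and IK1
#'   conductances (dimensionless). Allowed ranges for the TNNP model:
#'   sKs, sKr in `[0, 2]`, sK1 in `[0.2, 2]`.
#' @param stim_amplitude stimulus amplitude in pA/pF (positive magnitude of
#'   the depolarizing pulse), or `NULL` to derive it from the threshold.
#' @param stim_duration stimulus pulse duration, ms.
#' @param stim_scale multiple of threshold used when `stim_amplitude` is
#'   `NULL` (default 1.5).
#' @param model name of a registered ionic model.
#' @return an object of class `scaled_params`.
#' @examples
#' scaled_params(sKs = 2, sKr = 0.3, sK1 = 0.2)
#' @export
scaled_params <- function(sKs = 1, sKr = 1, sK1 = 1, stim_amplitude = NULL,
                          stim_duration = 1, stim_scale = 1.5,
                          model = "tnnp2004epi") {
  mod <- get_model(model)
  rng <- mod$mult_ranges
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop(nm, " must be a finite scalar")
    if (x < rng[[nm]][1] || x > rng[[nm]][2])
      stop(nm, " = ", x, " outside the allowed range [",
           rng[[nm]][1], ", ", rng[[nm]][2], "] for model '", model, "'")
  }
  chk(sKs, "sKs"); chk(sKr, "sKr"); chk(sK1, "sK1")
  stopifnot(stim_duration > 0, stim_scale > 0)
  structure(list(sKs = sKs, sKr = sKr, sK1 = sK1,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration, stim_scale = stim_scale,
                 model = model),
            class = "scaled_params")
}

as_scaled_params <- function(x) {
  if (inherits(x, "scaled_params")) return(x)
  if (is.numeric(x) && length(x) == 3)
    return(scaled_params(x[[1]], x[[2]], x[[3]]))
  stop("expected a scaled_params object or a numeric triple (sKs, sKr, sK1)")
}

#' @export
print.scaled_params <- function(x, ...) {
  cat(sprintf("<scaled_params> model %s: sKs=%g sKr=%g sK1=%g; stim %s x %g ms\n",
              x$model, x$sKs, x$sKr, x$sK1,
              if (is.null(x$stim_amplitude)) sprintf("%gx threshold", x$stim_scale)
              else sprintf("%g pA/pF", x$stim_amplitude),
              x$stim_duration))
  invisible(x)
}

#' @export
print.ionic_model <- function(x, ...) {
  cat(sprintf("<ionic_model> %s (%d state variables)\n", x$name,
              length(x$state_names)))
  invisible(x)
}
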