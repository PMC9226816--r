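# Workbench: synthetic fixture traces with analytically known features,
# trace/feature file I/O, and the experiment pipeline that turns a
# declarative config into tidy result tables.

# ---- fixtures --------------------------------------------------------------

# integrate a piecewise-linear (t, v) knot polyline above `baseline` over
# [ta, tb] (exact trapezoid between knots)
.knot_auc <- function(kt, kv, baseline, ta, tb) {
  vat <- function(x) approx(kt, kv, xout = x)$y
  xs <- sort(unique(c(ta, tb, kt[kt > ta & kt < tb])))
  vs <- vat(xs) - baseline
  sum(diff(xs) * (vs[-1] + vs[-length(vs)]) / 2)
}

#' Generate an idealized action potential fixture trace
#'
#' Deterministic piecewise-linear test traces whose features (APA, APD90,
#' phase durations, phase-average currents, normalized AUAP) are known
#' analytically, so the feature extractor can be tested without running the
#' ionic model. The synthetic `Iion` column is the exact negative slope of
#' the membrane potential (the single-cell identity), and, for the `"ap"`
#' shape, a synthetic `IK1` column is placed so that its 10%-of-peak crossing
#' falls exactly at the requested phase-2 end.
#'
#' Shapes:
#' \describe{
#'   \item{rectangle}{baseline to `baseline + apa` at `t_up`, back down at
#'     `t_up + duration`; ground-truth `auap_norm` is 1.}
#'   \item{triangle}{instant rise then linear decay back to baseline over
#'     `duration`; the measured APD90 is `0.9 * duration` and the
#'     ground-truth `auap_norm` under the APD90 cutoff is 0.55.}
#'   \item{trapezoid}{plateau of half the duration, then linear decay.}
#'   \item{ap}{a stylized action potential: slight post-upstroke rise to the
#'     peak at `t_phase1_end` (inward total current), shallow plateau decay to
#'     `t_phase2_end`, steep phase-3 decay crossing 90% repolarization at
#'     `t_apd90`; full current columns.}
#' }
#'
#' @param shape one of `"rectangle"`, `"triangle"`, `"trapezoid"`, `"ap"`.
#' @param apa amplitude, mV.
#' @param duration nominal shape duration, ms (rectangle/triangle/trapezoid).
#' @param baseline resting potential, mV.
#' @param t_up upstroke time, ms (placed on the sample grid).
#' @param t_phase1_end,t_phase2_end,t_apd90 landmark times for the `"ap"`
#'   shape, ms.
#' @param plateau_frac for `"ap"`: fraction of the amplitude still
#'   depolarized at the end of phase 2 (must exceed 0.1, the APD90 level).
#' @param sample_ms sampling interval, ms.
#' @param total_ms trace length, ms.
#' @param ik1_peak peak value of the synthetic IK1 bump, pA/pF.
#' @return list with `trace` (data.frame) and `truth` (named list of
#'   analytically computed features).
#' @export
generate_fixture <- function(shape = c("ap", "rectangle", "triangle",
                                       "trapezoid"),
                             apa = 130, duration = 300, baseline = -85,
                             t_up = 10, t_phase1_end = 17, t_phase2_end = 250,
                             t_apd90 = 310, plateau_frac = 0.55,
                             sample_ms = 0.1, total_ms = NULL,
                             ik1_peak = 1) {
  shape <- match.arg(shape)
  stopifnot(apa > 0, duration > 0, sample_ms > 0)
  snap <- function(x) round(x / sample_ms) * sample_ms
  t_up <- snap(t_up)
  peak <- baseline + apa

  if (shape == "ap") {
    t1 <- snap(t_phase1_end); t2 <- snap(t_phase2_end); t9 <- snap(t_apd90)
    if (!(t_up < t1 && t1 < t2 && t2 < t9))
      stop("fixture spec error: need t_up < t_phase1_end < t_phase2_end < t_apd90")
    v1 <- baseline + 0.93 * apa            # end of the instantaneous upstroke
    v2 <- baseline + plateau_frac * apa    # plateau end (phase-2/3 boundary)
    v90 <- peak - 0.9 * apa
    if (!(v2 > v90)) stop("fixture spec error: plateau_frac too low")
    s3 <- (v2 - v90) / (t9 - t2)           # phase-3 downslope, mV/ms
    t_base <- t9 + (v90 - baseline) / s3
    if (is.null(total_ms)) total_ms <- snap(t_base + 20)
    kt <- c(0, t_up, t_up + sample_ms, t1, t2, t9, t_base, total_ms)
    kv <- c(baseline, baseline, v1, peak, v2, v90, baseline, baseline)
  } else {
    t_end <- snap(t_up + duration)
    if (is.null(total_ms)) total_ms <- snap(t_end + 20)
    if (shape == "rectangle") {
      kt <- c(0, t_up, t_up + sample_ms, t_end, t_end + sample_ms, total_ms)
      kv <- c(baseline, baseline, peak, peak, baseline, baseline)
    } else if (shape == "triangle") {
      kt <- c(0, t_up, t_up + sample_ms, t_end, total_ms)
      kv <- c(baseline, baseline, peak, baseline, baseline)
    } else { # trapezoid
      t_mid <- snap(t_up + duration / 2)
      kt <- c(0, t_up, t_up + sample_ms, t_mid, t_end, total_ms)
      kv <- c(baseline, baseline, peak, peak, baseline, baseline)
    }
  }
  if (is.unsorted(kt, strictly = TRUE))
    stop("fixture spec error: inconsistent boundary times")

  tt <- seq(0, total_ms, by = sample_ms)
  vv <- approx(kt, kv, xout = tt)$y
  # exact negative slope of the polyline, sampled at segment values
  slope_at <- function(x) {
    i <- findInterval(x, kt, rightmost.closed = TRUE)
    i[i >= length(kt)] <- length(kt) - 1
    (kv[i + 1] - kv[i]) / (kt[i + 1] - kt[i])
  }
  iion <- -slope_at(tt)

  trace <- data.frame(time_ms = tt, Vm_mV = vv, IKs = 0, IKr = 0,
                      IK1 = 0, Iion = iion)
  # only the "ap" shape carries a meaningful IK1 landmark; the elementary
  # shapes drop the column so feature extraction takes the current-free path
  if (shape != "ap") trace$IK1 <- NULL

  # analytic ground truth under the extractor's operative definitions
  v90 <- peak - 0.9 * apa
  if (shape == "ap") {
    gt_apd90 <- t9 - t_up
    ik1 <- numeric(length(tt))
    # linear IK1 ramp whose 10%-of-peak crossing is exactly at t2,
    # peaking at t9 then decaying
    ta <- (t2 - 0.1 * t9) / 0.9
    if (ta <= t1) stop("fixture spec error: IK1 ramp would start before phase 2")
    up <- tt >= ta & tt <= t9
    ik1[up] <- ik1_peak * (tt[up] - ta) / (t9 - ta)
    dn <- tt > t9 & tt <= t_base
    ik1[dn] <- ik1_peak * pmax(0, 1 - (tt[dn] - t9) / (t_base - t9))
    trace$IK1 <- ik1
    i2 <- (peak - v2) / (t2 - t1)
    i3 <- (v2 - v90) / (t9 - t2)
    truth <- list(apa = apa, apd90 = gt_apd90,
                  phase1 = t1 - t_up, phase2 = t2 - t1, phase3 = t9 - t2,
                  t_upstroke = t_up, t_phase1_end = t1, t_phase2_end = t2,
                  t_apd90 = t9,
                  iion_phase2 = i2, iion_phase3 = i3, ratio = i3 / i2,
                  auap_norm = .knot_auc(kt, kv, baseline, t_up, t9) /
                    (gt_apd90 * apa),
                  vm_phase2_end = v2)
  } else {
    # APD90 crossing time on the polyline
    dec <- which(diff(kv) < 0 & kv[-length(kv)] > v90)
    k <- dec[length(dec)]
    tc <- kt[k] + (v90 - kv[k]) * (kt[k + 1] - kt[k]) / (kv[k + 1] - kv[k])
    gt_apd90 <- tc - t_up
    truth <- list(apa = apa, apd90 = gt_apd90,
                  t_upstroke = t_up, t_apd90 = tc,
                  auap_norm = .knot_auc(kt, kv, baseline, t_up, tc) /
                    (gt_apd90 * apa))
  }
  list(trace = trace, truth = truth)
}

# ---- trace and feature I/O -------------------------------------------------

#' Write / read an action potential trace
#'
#' Columnar text (CSV) with header
#' `time_ms,Vm_mV,IKs,IKr,IK1,Iion`, one row per sample.
#'
#' @param trace a trace data.frame.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   trace data.frame.
#' @export
write_trace <- function(trace, path) {
  .check_trace(trace)
  cols <- c("time_ms", "Vm_mV", "IKs", "IKr", "IK1", "Iion")
  miss <- setdiff(cols, names(trace))
  for (m in miss) trace[[m]] <- NA_real_
  data.table::fwrite(trace[cols], path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- as.data.frame(data.table::fread(path))
  .check_trace(tr)
  tr
}

#' Write a feature set to JSON
#'
#' @param features a `feature_set` from [extract_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_json <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  units <- list(apa = "mV", apd90 = "ms", phase1 = "ms", phase2 = "ms",
                phase3 = "ms", iion_phase2 = "pA/pF", iion_phase3 = "pA/pF",
                ratio = "dimensionless", auap_norm = "dimensionless",
                takeoff_vm = "mV", peak_vm = "mV", vm_phase2_end = "mV")
  out <- lapply(names(units), function(nm)
    list(value = unclass(features)[[nm]], unit = units[[nm]]))
  names(out) <- names(units)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- experiment configs and the reproduction pipeline ----------------------

#' Experiment configuration
#'
#' A declarative description of a batch of interventions: labelled
#' conductance-multiplier triples, the BCLs to pace, and optional
#' repolarization-reserve and optimization stages. Mirrors the JSON config
#' file accepted by [read_experiment_config()].
#'
#' @param interventions named list of numeric triples `(sKs, sKr, sK1)`;
#'   names are the intervention labels (e.g. `"0.41(IKr)"`) and must be
#'   unique.
#' @param bcls cycle lengths to pace, ms; the first is the long and the last
#'   the short reference BCL for the rate-dependence statistics.
#' @param minutes pacing length, simulated minutes.
#' @param dt integration step, ms.
#' @param reserve also run the reserve protocol at the long BCL.
#' @param optimize `NULL`, or a list with `apd_goals`, `k1_mins` and
#'   optionally `swarm` (arguments to [swarm_config()]).
#' @param seed seed for the optimization stage.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(interventions = list(), bcls = c(3000, 400),
                              minutes = 16, dt = 0.02, reserve = FALSE,
                              optimize = NULL, seed = 1L) {
  if (length(interventions)) {
    if (is.null(names(interventions)) || anyDuplicated(names(interventions)))
      stop("interventions must be uniquely labelled")
    lapply(interventions, function(m) stopifnot(length(m) == 3))
  }
  structure(list(interventions = interventions, bcls = bcls,
                 minutes = minutes, dt = dt, reserve = reserve,
                 optimize = optimize, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path JSON file with the same fields.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- raw$interventions
  if (!is.null(iv)) iv <- lapply(iv, as.numeric)
  experiment_config(
    interventions = if (is.null(iv)) list() else iv,
    bcls = if (is.null(raw$bcls)) c(3000, 400) else as.numeric(raw$bcls),
    minutes = if (is.null(raw$minutes)) 16 else raw$minutes,
    dt = if (is.null(raw$dt)) 0.02 else raw$dt,
    reserve = isTRUE(raw$reserve),
    optimize = raw$optimize,
    seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Run the full analysis pipeline for an experiment config
#'
#' For every intervention (plus control): steady-state pacing at each BCL,
#' feature extraction on the long-BCL beat, rate-dependence statistics
#' against control, and optionally the repolarization reserve and the PSO
#' optimization protocols. Per-intervention failures are recorded in the
#' tables and the run continues.
#'
#' @param config an [experiment_config()].
#' @param out_dir if non-`NULL`, tidy CSV tables are written there.
#' @return list of data.frames: `restitution` (one row per intervention x
#'   BCL), `rate_dependence`, `features`, and, when requested, `reserve` and
#'   `optima`.
#' @export
reproduce <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  bcl_long <- config$bcls[1]
  bcl_short <- config$bcls[length(config$bcls)]
  labels <- c("control", names(config$interventions))
  mults <- c(list(control = c(1, 1, 1)), config$interventions)

  resti <- list(); feats <- list(); rd <- list(); resv <- list()
  for (lb in labels) {
    p <- scaled_params(mults[[lb]][1], mults[[lb]][2], mults[[lb]][3])
    for (b in config$bcls) {
      row <- tryCatch({
        r <- .apd_at(p, b, config$minutes, config$dt)
        data.frame(label = lb, sKs = p$sKs, sKr = p$sKr, sK1 = p$sK1,
                   bcl = b, apd90 = r$apd90, captured = r$captured,
                   alternans = r$alternans, error = NA_character_)
      }, error = function(e)
        data.frame(label = lb, sKs = p$sKs, sKr = p$sKr, sK1 = p$sK1,
                   bcl = b, apd90 = NA_real_, captured = FALSE,
                   alternans = NA, error = conditionMessage(e)))
      resti[[length(resti) + 1]] <- row
    }
    ft <- tryCatch({
      rec <- pace(p, bcl = bcl_long, minutes = config$minutes, dt = config$dt)
      f <- extract_features(rec$trace)
      data.frame(label = lb, apa = f$apa, apd90 = f$apd90,
                 phase1 = f$phase1, phase2 = f$phase2, phase3 = f$phase3,
                 iion_phase2 = f$iion_phase2, iion_phase3 = f$iion_phase3,
                 ratio = f$ratio, auap_norm = f$auap_norm,
                 vm_phase2_end = f$vm_phase2_end, error = NA_character_)
    }, error = function(e)
      data.frame(label = lb, apa = NA, apd90 = NA, phase1 = NA, phase2 = NA,
                 phase3 = NA, iion_phase2 = NA, iion_phase3 = NA, ratio = NA,
                 auap_norm = NA, vm_phase2_end = NA,
                 error = conditionMessage(e)))
    feats[[length(feats) + 1]] <- ft
    if (isTRUE(config$reserve)) {
      rv <- tryCatch({
        r <- repolarization_reserve(p, bcl = bcl_long,
                                    minutes = config$minutes, dt = config$dt)
        data.frame(label = lb, pct_prolongation = r$pct_prolongation,
                   apd_baseline = r$apd_baseline,
                   apd_injected = r$apd_injected, error = NA_character_)
      }, error = function(e)
        data.frame(label = lb, pct_prolongation = NA, apd_baseline = NA,
                   apd_injected = NA, error = conditionMessage(e)))
      resv[[length(resv) + 1]] <- rv
    }
  }
  resti <- do.call(rbind, resti)
  feats <- do.call(rbind, feats)

  ctl <- resti[resti$label == "control", ]
  cl <- ctl$apd90[ctl$bcl == bcl_long][1]
  cs <- ctl$apd90[ctl$bcl == bcl_short][1]
  for (lb in labels) {
    il <- resti$apd90[resti$label == lb & resti$bcl == bcl_long][1]
    is_ <- resti$apd90[resti$label == lb & resti$bcl == bcl_short][1]
    rd[[length(rd) + 1]] <- if (is.finite(il) && is.finite(is_)) {
      x <- rate_dependence(il, is_, cl, cs, bcl_long, bcl_short)
      data.frame(label = lb, apd_long = il, apd_short = is_,
                 delta_long = x$delta_long, delta_short = x$delta_short,
                 rd_index = x$rd_index, pct_shortening = x$pct_shortening,
                 classification = x$classification)
    } else {
      data.frame(label = lb, apd_long = il, apd_short = is_,
                 delta_long = NA, delta_short = NA, rd_index = NA,
                 pct_shortening = NA, classification = NA_character_)
    }
  }
  rd <- do.call(rbind, rd)

  out <- list(restitution = resti, rate_dependence = rd, features = feats)
  if (isTRUE(config$reserve)) out$reserve <- do.call(rbind, resv)

  if (!is.null(config$optimize)) {
    op <- config$optimize
    sw <- do.call(swarm_config, c(op$swarm, list(seed = config$seed)))
    rows <- list()
    for (goal in op$apd_goals) for (k1m in op$k1_mins) {
      fit <- optimize_conductances(goal, k1_min = k1m, config = sw,
                                   minutes = config$minutes, dt = config$dt)
      rows[[length(rows) + 1]] <- data.frame(
        apd_goal = goal, k1_min = k1m,
        sKs = fit$par[["sKs"]], sKr = fit$par[["sKr"]], sK1 = fit$par[["sK1"]],
        objective = fit$value, apd_long = fit$details$apd_long,
        apd_short = fit$details$apd_short, rd_index = fit$details$rd_index)
    }
    out$optima <- do.call(rbind, rows)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      data.table::fwrite(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  out
}
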