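# Pacing protocols: threshold search, steady-state pacing, restitution,
# repolarization reserve.

test_that("threshold bisection brackets the true excitation threshold", {
  p <- scaled_params()
  thr <- find_threshold(p)
  mod <- get_model(p$model)
  captures <- function(amp) {
    r <- mod$pace_engine(mod$initial_state(), p, amp, 1, 50, 1L, 0.02, 1, 0,
                         FALSE, FALSE)
    r$vmax10[1] > 0
  }
  expect_true(captures(1.01 * thr))
  expect_false(captures(0.99 * thr))
  # dense-scan oracle on a 0.5% amplitude grid around the returned value:
  # the capture transition lies within the bisection's 1% tolerance
  grid <- thr * seq(0.95, 1.05, by = 0.005)
  cap <- vapply(grid, captures, logical(1))
  expect_true(all(diff(cap) >= 0))  # single transition
  true_thr <- grid[which(cap)[1]]
  expect_lt(abs(true_thr - thr) / thr, 0.011)
  expect_false(captures(0))
  # no capture at the bound -> explicit error (fresh parameter set so the
  # memoised threshold of `p` cannot short-circuit the search)
  expect_error(find_threshold(scaled_params(sK1 = 1.5), upper = 0.5),
               "no excitation")
})

test_that("pacing returns a coherent beat record", {
  rec <- control_beat_1000()
  expect_s3_class(rec, "beat_record")
  expect_true(rec$captured)
  expect_false(rec$alternans)
  expect_equal(rec$stim_amplitude, 1.5 * rec$threshold)
  expect_equal(nrow(rec$trace), 1000 / 0.1 + 0)
  expect_equal(rec$trace$time_ms[1], 0)
  # first trace row is the pre-stimulus sample
  expect_equal(rec$trace$Vm_mV[1], rec$takeoff_vm)
  expect_true(rec$apd90 > 250 && rec$apd90 < 350)
  # per-beat APD envelope settles: late beats within 1 ms of each other
  late <- tail(rec$apd90_beats, 5)
  expect_lt(max(late) - min(late), 1)
})

test_that("zero beats requested returns the initial conditions untouched", {
  rec <- pace(scaled_params(), bcl = 1000, n_beats = 0)
  expect_null(rec$trace)
  expect_identical(rec$final_state, get_model("tnnp2004epi")$initial_state())
})

test_that("sub-threshold pacing is flagged as loss of capture", {
  p <- scaled_params(stim_amplitude = 1)  # far below threshold
  rec <- pace(p, bcl = 500, n_beats = 3, record = FALSE, cache = FALSE)
  expect_false(rec$captured)
  expect_true(is.na(rec$apd90))
})

test_that("restitution is consistent with pace() and monotone for control", {
  p <- scaled_params()
  r <- restitution(p, bcls = c(500, 1000, 2000), minutes = 0.5)
  expect_equal(names(r), c("bcl", "apd90", "captured", "alternans"))
  expect_true(all(diff(r$apd90) > 0))  # APD90 non-decreasing in BCL
  single <- restitution(p, bcls = 1000, minutes = 0.5)
  expect_equal(single$apd90,
               pace(p, bcl = 1000, minutes = 0.5, record = FALSE)$apd90)
  expect_equal(r$apd90[r$bcl == 1000], single$apd90)
})

test_that("repolarization reserve: zero injection is exactly zero, and
           prolongation grows monotonically with depolarizing current", {
  p <- scaled_params()
  r0 <- repolarization_reserve(p, bcl = 1000, inject = 0, minutes = 0.5)
  expect_identical(r0$pct_prolongation, 0)
  amps <- c(-0.05, -0.1, -0.2)
  pct <- vapply(amps, function(a)
    repolarization_reserve(p, bcl = 1000, inject = a,
                           minutes = 0.5)$pct_prolongation, numeric(1))
  expect_true(all(pct > 0))
  expect_true(all(diff(pct) > 0))  # more depolarizing -> more prolongation
})

test_that("protocol determinism: identical specs give identical records", {
  p <- scaled_params(1.2, 0.8, 0.9)
  r1 <- pace(p, bcl = 600, n_beats = 4, cache = FALSE)
  r2 <- pace(p, bcl = 600, n_beats = 4, cache = FALSE)
  expect_identical(r1$apd90_beats, r2$apd90_beats)
  expect_identical(r1$trace, r2$trace)
})
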