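# Workbench: fixture generator contracts, trace/feature I/O round trips,
# experiment configs and the reproduction pipeline.

test_that("fixture specs are validated", {
  expect_error(generate_fixture("ap", t_up = 50, t_phase1_end = 40), "spec error")
  expect_error(generate_fixture("ap", plateau_frac = 0.05), "plateau_frac")
  expect_error(generate_fixture("banana"), "arg")
})

test_that("fixture traces satisfy the slope identity exactly", {
  fx <- generate_fixture("ap")
  tr <- fx$trace
  # Iion is the negative slope of the sampled polyline on every linear piece
  dv <- diff(tr$Vm_mV) / diff(tr$time_ms)
  # compare against the recorded Iion at segment left ends, skipping knots
  mism <- abs(-dv - tr$Iion[-nrow(tr)])
  expect_lt(sort(mism, decreasing = TRUE)[10], 1e-8)
})

test_that("traces round-trip through CSV with identical features", {
  rec <- control_beat_1000()
  path <- tempfile(fileext = ".csv")
  write_trace(rec$trace, path)
  expect_identical(readLines(path, n = 1), "time_ms,Vm_mV,IKs,IKr,IK1,Iion")
  tr2 <- read_trace(path)
  f1 <- extract_features(rec$trace)
  f2 <- extract_features(tr2)
  for (nm in c("apa", "apd90", "phase2", "iion_phase2", "auap_norm"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  unlink(path)
})

test_that("feature sets serialize to JSON with units", {
  f <- extract_features(generate_fixture("ap")$trace)
  path <- tempfile(fileext = ".json")
  write_features_json(f, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$apd90$value, f$apd90, tolerance = 1e-9)
  expect_identical(j$apd90$unit, "ms")
  expect_identical(j$iion_phase2$unit, "pA/pF")
  unlink(path)
})

test_that("experiment configs validate labels and load from JSON", {
  expect_error(experiment_config(list(c(1, 1, 1), c(1, 1, 1))), "label")
  expect_error(experiment_config(list(a = c(1, 1, 1), a = c(2, 1, 1))), "label")
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(interventions = list("0.5(IK1)" = c(1, 1, 0.5)),
                            bcls = c(1000, 500), minutes = 0.25, seed = 3),
                       path, auto_unbox = TRUE)
  cfg <- read_experiment_config(path)
  expect_s3_class(cfg, "experiment_config")
  expect_identical(names(cfg$interventions), "0.5(IK1)")
  expect_equal(cfg$bcls, c(1000, 500))
  unlink(path)
})

test_that("reproduce runs the pipeline and is deterministic", {
  cfg <- experiment_config(
    interventions = list("0.5(IK1)" = c(1, 1, 0.5)),
    bcls = c(1000, 500), minutes = 0.25)
  out <- reproduce(cfg)
  expect_named(out, c("restitution", "rate_dependence", "features"))
  expect_equal(nrow(out$restitution), 4)  # 2 labels x 2 bcls
  expect_true(all(out$restitution$captured))
  rd <- out$rate_dependence
  expect_identical(rd$classification[rd$label == "control"], "neutral")
  expect_identical(rd$rd_index[rd$label == "control"], 0)
  # IK1 block prolongs at both rates
  expect_true(all(rd$delta_long[rd$label != "control"] > 0))
  # deterministic rerun: byte-identical CSV outputs
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  out1 <- reproduce(cfg, out_dir = d1)
  out2 <- reproduce(cfg, out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  unlink(c(d1, d2), recursive = TRUE)
  # empty intervention list -> control-only tables
  out0 <- reproduce(experiment_config(bcls = c(1000, 500), minutes = 0.25))
  expect_equal(nrow(out0$restitution), 2)
})
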