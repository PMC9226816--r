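# Rate-dependence statistics and classification.

test_that("delta_apd and pct_shortening follow their definitions", {
  expect_identical(delta_apd(310, 310), 0)
  expect_identical(delta_apd(330, 310), 20)
  expect_equal(pct_shortening(320, 320), 0)
  expect_equal(pct_shortening(320, 272), 15)
  expect_error(pct_shortening(0, 100), "positive")
  expect_error(pct_shortening(-5, 100), "positive")
})

test_that("classification is sign-based with a neutral band", {
  expect_identical(classify_rate_dependence(0), "neutral")
  expect_identical(classify_rate_dependence(0.4), "neutral")
  expect_identical(classify_rate_dependence(-0.4), "neutral")
  expect_identical(classify_rate_dependence(0.6), "positive")
  expect_identical(classify_rate_dependence(-0.6), "reverse")
  expect_identical(classify_rate_dependence(0.6, neutral_band = 1), "neutral")
})

test_that("control against itself has rd_index exactly 0 at every BCL pair", {
  r <- restitution(scaled_params(), bcls = c(600, 1200), minutes = 0.5)
  x <- rate_dependence(r$apd90[2], r$apd90[1], r$apd90[2], r$apd90[1],
                       bcl_long = 1200, bcl_short = 600)
  expect_identical(x$rd_index, 0)
  expect_identical(x$delta_long, 0)
  expect_identical(x$classification, "neutral")
  # control-vs-control deltas across BCLs reproduce the restitution map
  expect_equal(delta_apd(r$apd90[2], r$apd90[1]), r$apd90[2] - r$apd90[1])
})

test_that("rate_dependence assembles a coherent result", {
  x <- rate_dependence(330, 290, 310, 250)
  expect_equal(x$delta_long, 20)
  expect_equal(x$delta_short, 40)
  expect_equal(x$rd_index, 20)
  expect_identical(x$classification, "positive")
  expect_equal(x$pct_shortening, 100 * 40 / 330)
  y <- rate_dependence(330, 255, 310, 250)
  expect_equal(y$rd_index, -15)
  expect_identical(y$classification, "reverse")
})
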