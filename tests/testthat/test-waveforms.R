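test_that("cardiac waveform is calibrated to the pulse volume", {
  w <- make_cardiac(heart_rate = 60, pulse_volume = 1.0e-6)
  expect_equal(stroke_volume(w), 1.0e-6, tolerance = 1e-6)
  ## zero mean over one period (pure oscillation)
  expect_lt(abs(waveform_mean(w)), 1e-12 * max(abs(waveform_eval(w, seq(0, 1, 0.01)))))
  ## linear calibration: doubling the volume doubles the signal pointwise
  w2 <- make_cardiac(heart_rate = 60, pulse_volume = 2.0e-6)
  ts <- seq(0, 1, length.out = 37)
  expect_equal(waveform_eval(w2, ts), 2 * waveform_eval(w, ts), tolerance = 1e-12)
  expect_error(make_cardiac(pulse_volume = 0), "configuration error")
  expect_error(make_cardiac(heart_rate = -10), "configuration error")
})

test_that("calibration round-trip holds across rates and volumes", {
  for (hr in c(50, 60, 75, 90)) {
    for (V in c(0.5e-6, 1.0e-6, 1.8e-6)) {
      expect_equal(stroke_volume(make_cardiac(hr, V)), V, tolerance = 1e-5)
    }
  }
  for (rr in c(10, 12, 16)) {
    for (V in c(0, 0.3e-6, 0.8e-6)) {
      w <- make_respiratory(rr, V)
      expect_equal(w$period, 60 / rr)
      expect_equal(stroke_volume(w), V, tolerance = 1e-6 * max(V, 1e-9))
    }
  }
})

test_that("waveforms are periodic and deterministic", {
  w <- combine_waveforms(make_cardiac(), make_respiratory(), 0.4e-6 / 60)
  ts <- seq(0, w$period, length.out = 23)
  expect_equal(waveform_eval(w, ts), waveform_eval(w, ts + w$period), tolerance = 1e-12)
  expect_identical(waveform_eval(w, ts), waveform_eval(w, ts))
})

test_that("combined waveform mean equals the production rate", {
  w <- default_waveform()
  ## 60 s is an integer number of cardiac (1 s) and respiratory (5 s) periods
  expect_equal(waveform_mean(w, over = 60) * 60e6, 0.4, tolerance = 1e-6)
  ## daily production ~576 mL
  expect_equal(waveform_mean(w, over = 60) * 86400 * 1e6, 576, tolerance = 1e-4)
  ## identity: zero respiration + zero production reduces to the cardiac wave
  c0 <- make_cardiac()
  w0 <- combine_waveforms(c0, make_respiratory(tidal_csf_volume = 0), 0)
  ts <- seq(0, 5, length.out = 41)
  expect_equal(waveform_eval(w0, ts), waveform_eval(c0, ts), tolerance = 1e-15)
  ## superposition of means for arbitrary production
  w1 <- combine_waveforms(c0, make_respiratory(), 2e-8)
  expect_equal(waveform_mean(w1, over = 60), 2e-8, tolerance = 1e-6)
})

test_that("stroke volume handles degenerate and tabulated inputs", {
  z <- make_respiratory(tidal_csf_volume = 0)
  expect_equal(stroke_volume(z), 0)
  expect_error(stroke_volume(make_production(1e-9)), "finite period")
  ## square wave +q, -q: positive-phase volume q T / 2
  q <- 3e-6; Tp <- 2
  ts <- seq(0, Tp, length.out = 4001)
  Qs <- ifelse(ts %% Tp < Tp / 2, q, -q)
  sq <- waveform_from_table(ts, Qs, period = Tp)
  expect_equal(stroke_volume(sq), q * Tp / 2, tolerance = 1e-3)
})

test_that("sampled waveforms round-trip through delimited text", {
  w <- make_cardiac()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_waveform(w, f, times = seq(0, 1, length.out = 501))
  w2 <- read_waveform(f)
  ts <- seq(0.01, 0.99, length.out = 53)
  expect_equal(waveform_eval(w2, ts), waveform_eval(w, ts), tolerance = 1e-3)
})
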