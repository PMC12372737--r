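test_that("PI and RI match their defining formulas and closed forms", {
  w <- flow_waveform(c(10, rep(5, 30), 2), 1)   # max 10, min 2, mean != 0
  expect_equal(pulsatility_index(w), (10 - 2) / mean(w$flow))
  expect_equal(resistance_index(w), 0.8)
  expect_equal(pulsatility_index(sine_cycle(5, 2)), 0.8)      # 2a/m
  expect_equal(resistance_index(sine_cycle(5, 2)), 4 / 7)     # 2a/(m+a)
  cw <- rep(3, 32)
  expect_equal(pulsatility_index(cw), 0)
  expect_equal(resistance_index(cw), 0)
  expect_error(pulsatility_index(sine_cycle(0, 1)), "mean")
  expect_error(resistance_index(rep(0, 32)), "maximum")
})

test_that("PI/RI are scale-invariant; FVP scales linearly and ignores offsets", {
  y <- sine_cycle(5, 2, phase = 0.4) + 0.6 * sin(4 * pi * frac32 + 1)
  for (k in c(2, 7.5)) {
    expect_equal(pulsatility_index(k * y), pulsatility_index(y))
    expect_equal(resistance_index(k * y), resistance_index(y))
    expect_equal(flow_volume_pulsatility(k * y, 1),
                 k * flow_volume_pulsatility(y, 1), tolerance = 1e-12)
  }
  expect_equal(flow_volume_pulsatility(y + 11, 1),
               flow_volume_pulsatility(y, 1), tolerance = 1e-12)
})

test_that("RI = PI * mean / max as an algebraic identity", {
  set.seed(7)
  for (i in 1:20) {
    y <- abs(stats::rnorm(1, 5, 1)) + 2 * stats::runif(1) * sin(2 * pi * frac32 +
           stats::runif(1, 0, 2 * pi)) + 0.5 * sin(4 * pi * frac32)
    expect_equal(resistance_index(y),
                 pulsatility_index(y) * mean(y) / max(y), tolerance = 1e-12)
  }
})

test_that("FVP matches the sinusoid closed form a*T/pi", {
  expect_equal(flow_volume_pulsatility(sine_cycle(0, 2), 1), 2 / pi,
               tolerance = 1e-9)
  expect_equal(flow_volume_pulsatility(sine_cycle(3, 2), 0.8), 2 * 0.8 / pi,
               tolerance = 1e-9)
  expect_equal(flow_volume_pulsatility(rep(5, 32), 1), 0)
  crv <- flow_volume_curve(sine_cycle(0, 2), 1)
  expect_gte(min(crv$volume), 0)
  expect_equal(max(crv$volume), 2 / pi, tolerance = 1e-6)
})

test_that("combined arterial waveform sums framewise with PI scale invariance", {
  w <- sine_waveform(5, 2, cycle = 0.9)
  comb <- combined_arterial_waveform(list(w, w))
  expect_equal(comb$flow, 2 * w$flow)
  expect_equal(pulsatility_index(comb), pulsatility_index(w))
  # summing a constant lowers PI
  cst <- flow_waveform(rep(3, 32), 0.9)
  expect_lt(pulsatility_index(combined_arterial_waveform(list(w, cst))),
            pulsatility_index(w))
  # antiphase cancellation gives a constant: PI = 0
  w2 <- sine_waveform(5, 2, cycle = 0.9, phase = pi)
  expect_equal(pulsatility_index(combined_arterial_waveform(list(w, w2))), 0,
               tolerance = 1e-12)
  expect_error(combined_arterial_waveform(list(w, sine_waveform(5, 2, 0.8))),
               "cycle")
  expect_false(attr(combined_arterial_waveform(list(w, w)), "complete"))
  expect_true(attr(combined_arterial_waveform(list(w, w, w, w)), "complete"))
})

test_that("mean venous index averages available sinuses symmetrically", {
  m1 <- vessel_metrics(sine_waveform(5, 1, class = "venous", vessel = "sss"))
  m2 <- vessel_metrics(sine_waveform(4, 1.2, class = "venous", vessel = "st"))
  out <- mean_venous_index(list(m1, m2))
  expect_equal(out$pi, mean(c(m1$pi, m2$pi)))
  expect_equal(out$n_vessels, 2L)
  expect_equal(mean_venous_index(list(m2, m1))$pi, out$pi)   # permutation
  expect_equal(mean_venous_index(list(m1))$pi, m1$pi)
  empty <- mean_venous_index(list())
  expect_true(is.na(empty$pi) && empty$n_vessels == 0L)
})

test_that("vessel_metrics refuses CSF waveforms", {
  expect_error(vessel_metrics(sine_waveform(0, 1, class = "csf")), "csf_metrics")
})

test_that("pulse transit time measures peak-to-peak delay on the 1-s cycle", {
  peak_at <- function(fr, class = "arterial", cycle = 1) {
    y <- numeric(32); y[fr + 1] <- 1
    flow_waveform(y + 5, cycle, vessel_class = class)
  }
  expect_equal(pulse_transit_time(peak_at(4), peak_at(8))$ptt, 0.125)
  # wrap: downstream peak earlier in the next cycle
  expect_equal(pulse_transit_time(peak_at(30), peak_at(2))$ptt, 0.125)
  expect_equal(pulse_transit_time(peak_at(30), peak_at(2), wrap = FALSE)$ptt,
               -0.875)
  # CSF: caudal (most negative) peak
  y <- sine_cycle(0, 1)                      # min at frame 24
  csf <- flow_waveform(y, 1, vessel_class = "csf")
  expect_equal(pulse_transit_time(peak_at(8), csf)$ptt, 0.5)
})

test_that("PTT excludes heart-rate mismatch > 15 bpm and degenerate waveforms", {
  w1 <- sine_waveform(5, 2, cycle = 60 / 70)
  w2 <- sine_waveform(5, 2, cycle = 60 / 86)
  r <- pulse_transit_time(w1, w2)            # 16 bpm apart
  expect_true(r$excluded)
  expect_match(r$exclusion_reason, "15 bpm")
  expect_true(is.na(r$ptt))
  # exactly 15 bpm is kept
  w3 <- sine_waveform(5, 2, cycle = 60 / 85)
  expect_false(pulse_transit_time(w1, w3, hr_upstream = 70,
                                  hr_downstream = 85)$excluded)
  flat <- flow_waveform(rep(4, 32), 1)
  rf <- pulse_transit_time(flat, w1, hr_upstream = 70, hr_downstream = 70)
  expect_true(rf$excluded)
  expect_match(rf$exclusion_reason, "degenerate")
  # self transit is zero
  expect_equal(pulse_transit_time(w1, w1)$ptt, 0)
})

test_that("CBF normalises total inflow to brain volume", {
  w <- flow_waveform(rep(2.25, 32), 1)       # 4 vessels x 2.25 = 9 mL/s
  r <- cerebral_blood_flow(list(w, w, w, w), 1350)
  expect_equal(r$cbf, 40)
  expect_true(r$complete)
  expect_equal(cerebral_blood_flow(list(flow_waveform(rep(0, 32), 1)),
                                   1000)$cbf, 0)
  r2 <- cerebral_blood_flow(list(w, w, w, w), 2700)
  expect_equal(r2$cbf, 20)                   # doubling volume halves CBF
  r3 <- cerebral_blood_flow(list(w, w, w), 1350)
  expect_false(r3$complete)
  expect_error(cerebral_blood_flow(list(w), -1), "brain_volume")
})

test_that("CSF metrics: net, peak and stroke volume", {
  expect_equal(csf_metrics(sine_cycle(0, 2), 1)$net_flow, 0, tolerance = 1e-12)
  cm <- csf_metrics(0.5 + sin(2 * pi * frac32), 1)
  expect_equal(cm$net_flow, 30, tolerance = 1e-12)          # mean * 60
  cm2 <- csf_metrics(pi * sin(2 * pi * frac32), 1)
  expect_equal(cm2$stroke_volume, 1, tolerance = 1e-4)      # directed volume
  expect_equal(cm2$peak_flow, pi, tolerance = 1e-12)
  expect_equal(csf_metrics(pi * sin(2 * pi * frac32), 1,
                           convention = "total")$stroke_volume, 2,
               tolerance = 1e-4)
  # antisymmetry: net flow of negation cancels
  y <- 0.3 + 1.4 * sin(2 * pi * frac32 + 0.9)
  expect_equal(csf_metrics(y, 1)$net_flow + csf_metrics(-y, 1)$net_flow, 0,
               tolerance = 1e-12)
  expect_error(csf_metrics(sine_waveform(5, 2, class = "arterial")), "CSF")
})

test_that("pulse pressure is systolic minus diastolic", {
  expect_equal(pulse_pressure(c(140, 160), c(80, 90)), c(60, 70))
})
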