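test_that("waveform_spec places the maximum at the requested peak time", {
  for (pf in c(0, 0.16, 0.5, 0.9)) {
    sp <- waveform_spec("arterial", 4, rbind(c(2, 0.4), c(0.7, 1.3)),
                        peak_time_fraction = pf, cycle_duration = 0.9)
    tt <- seq(0, 0.9, length.out = 8192L)
    expect_equal(tt[which.max(eval_waveform(sp, tt))] / 0.9, pf,
                 tolerance = 1e-3)
    expect_gte(eval_waveform(sp, pf * 0.9),
               max(eval_waveform(sp, tt)) - 1e-9)
  }
})

test_that("constant-velocity vessel encodes phase = pi*v/venc exactly with no noise", {
  acq <- tiny_acquisition(mean_flow = 3.5, amp = 0, n_frames = 8L, venc = 70)
  mask <- acq$rois$labels == 1L
  npix <- sum(mask)
  v_true <- 100 * 3.5 / npix            # cm/s, 1 mm^2 pixels
  for (f in seq_len(8L)) {
    ph <- acq$series$phase[, , f][mask]
    expect_equal(ph, rep(pi * v_true / 70, npix), tolerance = 1e-12)
  }
  # all frames identical
  expect_equal(acq$series$phase[, , 1], acq$series$phase[, , 5])
})

test_that("background phase offset appears uniformly in the static ROI", {
  acq <- tiny_acquisition(offset = 0.3, noise = 0)
  bg <- acq$rois$labels == acq$rois$background_label
  expect_equal(mean(acq$series$phase[, , 3][bg]), 0.3, tolerance = 1e-12)
  acq2 <- tiny_acquisition(offset = 0.3, noise = 0.05, seed = 11L)
  expect_equal(mean(acq2$series$phase[, , 3][bg]), 0.3, tolerance = 0.05)
})

test_that("overlapping vessel geometries raise an error naming both labels", {
  sp <- waveform_spec("arterial", 2, rbind(c(0.5, 0)), cycle_duration = 1)
  vessels <- list(vessel_geom("left", sp, c(20, 16), 3),
                  vessel_geom("right", sp, c(23, 16), 3))
  enc <- encoding_spec(70, n_frames_acquired = 8L)
  expect_error(make_cine_series(vessels, enc, grid_dim = c(40L, 32L)),
               "left.*right|overlap")
})

test_that("velocities reaching venc are refused unless wrap is allowed", {
  expect_error(tiny_acquisition(mean_flow = 40, venc = 10), "venc")
  sp <- waveform_spec("arterial", 40, NULL, cycle_duration = 1)
  enc <- encoding_spec(10, n_frames_acquired = 8L)
  expect_silent(make_cine_series(
    list(vessel_geom("v1", sp, c(22, 16), 2.5)), enc,
    grid_dim = c(40L, 32L), allow_wrap = TRUE))
})

test_that("generation is deterministic given the seed", {
  a <- tiny_acquisition(noise = 0.05, seed = 42L)
  b <- tiny_acquisition(noise = 0.05, seed = 42L)
  cc <- tiny_acquisition(noise = 0.05, seed = 43L)
  expect_identical(a$series$phase, b$series$phase)
  expect_false(identical(a$series$phase, cc$series$phase))
})

test_that("doubling waveform amplitudes doubles extracted flow", {
  a1 <- tiny_acquisition(mean_flow = 2, amp = 1)
  a2 <- tiny_acquisition(mean_flow = 4, amp = 2)
  w1 <- extract_waveforms(a1$series, a1$rois)[["v1"]]
  w2 <- extract_waveforms(a2$series, a2$rois)[["v1"]]
  expect_equal(2 * w1$flow, w2$flow, tolerance = 1e-10)
})

test_that("ground truth equals the spec evaluated on the acquired grid", {
  acq <- tiny_acquisition(mean_flow = 5, amp = 2, n_frames = 12L)
  tr <- acq$truth$v1
  expect_equal(tr$flow, eval_waveform(tr$spec, tr$times))
  expect_length(tr$flow, 12L)
})
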