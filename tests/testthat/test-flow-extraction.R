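test_that("phase maps linearly and sign-preservingly to velocity", {
  mk <- function(phase_val, venc) {
    ph <- array(phase_val, c(4, 4, 4))
    cine_series(ph, array(1, c(4, 4, 4)), venc = venc,
                pixel_spacing = c(1, 1), cycle_duration = 1)
  }
  expect_equal(as.vector(phase_to_velocity(mk(pi / 2, 70)))[1], 35)
  expect_equal(as.vector(phase_to_velocity(mk(0, 70)))[1], 0)
  expect_equal(as.vector(phase_to_velocity(mk(-pi / 4, 6)))[1], -1.5)
})

test_that("phase at the wrap boundary triggers an aliasing warning", {
  ph <- array(0, c(4, 4, 4)); ph[1, 1, 1] <- -pi
  s <- cine_series(ph, array(1, c(4, 4, 4)), venc = 70,
                   pixel_spacing = c(1, 1), cycle_duration = 1)
  expect_warning(v <- phase_to_velocity(s), "aliasing")
  expect_equal(attr(v, "aliasing_suspect"), 1L)
})

test_that("background correction removes a uniform offset and is idempotent", {
  acq <- tiny_acquisition(mean_flow = 4, amp = 1)
  vel <- phase_to_velocity(acq$series)
  off <- vel + 2                       # uniform +2 cm/s everywhere
  rois <- acq$rois
  bg <- rois$labels == rois$background_label
  cor1 <- background_correct(off, rois)
  for (f in c(1L, 8L)) expect_equal(mean(cor1[, , f][bg]), 0, tolerance = 1e-12)
  expect_equal(array(cor1, dim(vel)), array(background_correct(vel, rois),
                                            dim(vel)), tolerance = 1e-12)
  cor2 <- background_correct(cor1, rois)
  expect_equal(array(cor2, dim(vel)), array(cor1, dim(vel)), tolerance = 1e-14)
})

test_that("empty background ROI is an error", {
  acq <- tiny_acquisition()
  labs <- acq$rois$labels
  labs[labs == acq$rois$background_label] <- 0L
  expect_error(roi_set(labs, acq$rois$vessel_map,
                       acq$rois$background_label), "background")
})

test_that("roi_flow does the unit arithmetic, sign flip and spatial invariance", {
  # 10 one-mm^2 pixels at a uniform 35 cm/s -> 3.5 mL/s
  labs <- matrix(0L, 10, 10)
  labs[1:5, 1:2] <- 1L
  labs[1:5, 5:6] <- 2L
  labs[10, 10] <- 3L
  vm <- data.frame(label = 1:3, name = c("a", "b", "bg"),
                   vessel_class = c("arterial", "arterial", "static"),
                   sign = c(1L, -1L, 1L))
  rois <- roi_set(labs, vm, background_label = 3L)
  vel <- array(0, c(10, 10, 4))
  vel[rep(labs %in% c(1L, 2L), 4)] <- 35
  expect_equal(roi_flow(vel, rois, "a", c(1, 1)), rep(3.5, 4))
  expect_equal(roi_flow(vel, rois, "b", c(1, 1)), rep(-3.5, 4))
  # same geometry and waveform, disjoint labels -> identical series (mod sign)
  expect_equal(roi_flow(vel, rois, "a", c(1, 1)),
               -roi_flow(vel, rois, "b", c(1, 1)))
  expect_error(roi_flow(vel, rois, "missing", c(1, 1)), "unknown vessel")
})

test_that("splitting a vessel ROI conserves total flow exactly", {
  acq <- tiny_acquisition(mean_flow = 5, amp = 2)
  vel <- background_correct(phase_to_velocity(acq$series), acq$rois)
  labs <- acq$rois$labels
  mask <- labs == 1L
  xs <- which(mask, arr.ind = TRUE)
  half <- xs[, 1] >= stats::median(xs[, 1])
  labs[xs[half, , drop = FALSE]] <- 5L
  vm <- rbind(acq$rois$vessel_map,
              data.frame(label = 5L, name = "v1b", vessel_class = "arterial",
                         sign = 1L))
  rois2 <- roi_set(labs, vm, acq$rois$background_label)
  whole <- roi_flow(vel, acq$rois, "v1", c(1, 1))
  parts <- roi_flow(vel, rois2, "v1", c(1, 1)) +
    roi_flow(vel, rois2, "v1b", c(1, 1))
  expect_equal(parts, whole, tolerance = 1e-14)
})

test_that("resample_to_cycle is the identity on 32 frames and preserves constants", {
  y <- sine_cycle(5, 2, 32L)
  w <- resample_to_cycle(y, 1, vessel = "v")
  expect_identical(w$flow, y)
  expect_equal(resample_to_cycle(rep(4, 20L), 1)$flow, rep(4, 32L))
  expect_error(resample_to_cycle(c(1, 2, 3), 1), "at least 4")
})

test_that("scaling all phases scales every extracted waveform linearly", {
  acq <- tiny_acquisition(mean_flow = 4, amp = 1.5, two_vessels = TRUE)
  s <- acq$series
  s2 <- cine_series(s$phase * 0.5, s$magnitude, s$venc, s$pixel_spacing,
                    cycle_duration = s$cycle_duration)
  w <- extract_waveforms(s, acq$rois)
  w2 <- extract_waveforms(s2, acq$rois)
  for (v in names(w))
    expect_equal(w2[[v]]$flow, 0.5 * w[[v]]$flow, tolerance = 1e-12)
})
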