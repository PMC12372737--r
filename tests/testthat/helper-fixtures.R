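# Shared fixture builders; everything is generated in code.

frac32 <- (0:31) / 32

# One cycle of m + a*sin(2*pi*t/T + phase) sampled at n uniform points.
sine_cycle <- function(m, a, n = 32L, phase = 0) {
  m + a * sin(2 * pi * (0:(n - 1)) / n + phase)
}

sine_waveform <- function(m, a, cycle = 1, phase = 0, vessel = "v",
                          class = "arterial") {
  flow_waveform(sine_cycle(m, a, 32L, phase), cycle, vessel = vessel,
                vessel_class = class)
}

# A minimal one- or two-vessel synthetic acquisition on a small grid.
tiny_acquisition <- function(mean_flow = 5, amp = 2, cycle = 1,
                             n_frames = 16L, venc = 70, noise = 0,
                             offset = 0, seed = 1L, two_vessels = FALSE,
                             peak = 0.25) {
  sp <- waveform_spec("arterial", mean_flow,
                      if (amp > 0) rbind(c(amp, 0)) else NULL,
                      peak_time_fraction = peak, cycle_duration = cycle)
  vessels <- list(vessel_geom("v1", sp, centre = c(22, 16), radius = 2.5))
  if (two_vessels)
    vessels <- c(vessels, list(vessel_geom("v2", sp, centre = c(30, 16),
                                           radius = 2.5)))
  enc <- encoding_spec(venc = venc, pixel_spacing = c(1, 1),
                       n_frames_acquired = n_frames, noise_sd_phase = noise,
                       background_phase_offset = offset, seed = seed)
  make_cine_series(vessels, enc, grid_dim = c(40L, 32L),
                   background_geom = c(2L, 9L, 2L, 9L))
}

# Cohort spec with a single planted linear/logistic/ordinal effect of x.
planted_spec <- function(n, family, beta, seed, noise_sd = 0.3) {
  out <- switch(family,
    linear = list(family = "linear", transform = "log10", intercept = -1,
                  coef = c(x = beta), noise_sd = noise_sd),
    logistic = list(family = "logistic", intercept = -0.5,
                    coef = c(x = beta)),
    ordinal = list(family = "ordinal", coef = c(x = beta),
                   thresholds = c(-0.8, 0.4, 1.6)))
  cohort_spec(n,
    covariates = list(x = list("normal", mean = 1, sd = 0.5),
                      age = list("normal", mean = 66, sd = 11),
                      sex = list("binary", p = 0.5),
                      systolic_bp = list("normal", mean = 145, sd = 18)),
    outcomes = stats::setNames(list(out), "y"), seed = seed)
}
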