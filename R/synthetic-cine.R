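# Synthetic cine PC-MRI generator: pulsatile waveform specs, phase encoding
# with noise and a constant background phase offset, circular vessel ROIs and
# a static-tissue background region — everything downstream needs, with known
# ground truth.

#' Specify a periodic flow waveform
#'
#' A waveform is `mean_flow` plus a sum of sinusoidal harmonics of the cardiac
#' frequency, time-shifted so that its maximum falls at
#' `peak_time_fraction * cycle_duration`. The shift is applied by
#' construction, so the requested peak time is exact (up to the numerical
#' peak search on the base shape).
#'
#' @param vessel_class `"arterial"`, `"venous"` or `"csf"`.
#' @param mean_flow Mean flow in mL/s, signed (CSF may be near 0).
#' @param harmonics Two-column matrix (or list of length-2 vectors) of
#'   `(amplitude mL/s, phase radians)` for harmonics 1, 2, ... of the cardiac
#'   frequency.
#' @param peak_time_fraction Where in the cycle the waveform maximum occurs,
#'   in `[0, 1)`.
#' @param cycle_duration Cardiac cycle duration in seconds.
#' @return An object of class `waveform_spec`.
#' @export
#' @examples
#' sp <- waveform_spec("arterial", 4.5, rbind(c(2, 0.3), c(0.8, 1.2)),
#'                     peak_time_fraction = 0.15, cycle_duration = 0.9)
#' tmax <- 0.15 * 0.9
#' all.equal(eval_waveform(sp, tmax), max(eval_waveform(sp, seq(0, 0.9, length.out = 2048))))
waveform_spec <- function(vessel_class = c("arterial", "venous", "csf"),
                          mean_flow, harmonics = NULL,
                          peak_time_fraction = 0, cycle_duration = 1) {
  vessel_class <- match.arg(vessel_class)
  if (is.list(harmonics)) harmonics <- do.call(rbind, harmonics)
  if (is.null(harmonics)) harmonics <- matrix(numeric(0), ncol = 2L)
  harmonics <- matrix(as.numeric(harmonics), ncol = 2L)
  stopifnot(is.finite(mean_flow), all(is.finite(harmonics)))
  if (!is.finite(cycle_duration) || cycle_duration <= 0)
    stop("cycle_duration must be > 0", call. = FALSE)
  if (peak_time_fraction < 0 || peak_time_fraction >= 1)
    stop("peak_time_fraction must lie in [0, 1)", call. = FALSE)
  if (any(harmonics[, 1L] < 0))
    stop("harmonic amplitudes must be >= 0", call. = FALSE)
  sp <- structure(
    list(vessel_class = vessel_class, mean_flow = as.numeric(mean_flow),
         harmonics = harmonics,
         peak_time_fraction = as.numeric(peak_time_fraction),
         cycle_duration = as.numeric(cycle_duration), time_shift = 0),
    class = "waveform_spec")
  sp$time_shift <- .peak_shift(sp)
  sp
}

# Base shape before shifting: mean + sum_j a_j sin(2 pi j t / T + phi_j)
.eval_base <- function(sp, t) {
  out <- rep(sp$mean_flow, length(t))
  if (nrow(sp$harmonics)) {
    for (j in seq_len(nrow(sp$harmonics))) {
      out <- out + sp$harmonics[j, 1L] *
        sin(2 * pi * j * t / sp$cycle_duration + sp$harmonics[j, 2L])
    }
  }
  out
}

# Time shift that moves the base-shape maximum to the requested fraction.
.peak_shift <- function(sp) {
  if (!nrow(sp$harmonics) || all(sp$harmonics[, 1L] == 0)) return(0)
  tt <- seq(0, sp$cycle_duration, length.out = 4097L)[-4097L]
  t0 <- tt[which.max(.eval_base(sp, tt))]
  h <- sp$cycle_duration / 4096
  opt <- stats::optimize(function(t) .eval_base(sp, t),
                         interval = c(t0 - h, t0 + h), maximum = TRUE,
                         tol = .Machine$double.eps^0.5 * sp$cycle_duration)
  (sp$peak_time_fraction * sp$cycle_duration - opt$maximum) %% sp$cycle_duration
}

#' Evaluate a waveform specification at arbitrary times
#'
#' @param spec A [waveform_spec()].
#' @param t Numeric vector of times in seconds (interpreted periodically).
#' @return Flow in mL/s at each time.
#' @export
eval_waveform <- function(spec, t) {
  stopifnot(inherits(spec, "waveform_spec"))
  .eval_base(spec, as.numeric(t) - spec$time_shift)
}

#' Specify the phase-contrast encoding of an acquisition
#'
#' @param venc Velocity encoding in cm/s (> 0): velocity `v` maps to phase
#'   `pi * v / venc`, so phase of +/- pi corresponds to +/- venc.
#' @param pixel_spacing Length-2 numeric, in-plane pixel spacing in mm.
#' @param n_frames_acquired Number of reconstructed timeframes (>= 4).
#' @param noise_sd_phase SD of additive Gaussian phase noise, radians,
#'   independent per pixel and frame.
#' @param background_phase_offset Constant phase offset (radians) added to
#'   every pixel, emulating residual background phase error.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(venc, pixel_spacing = c(1, 1),
                          n_frames_acquired = 24L, noise_sd_phase = 0,
                          background_phase_offset = 0, seed = 1L) {
  stopifnot(length(pixel_spacing) == 2L, all(pixel_spacing > 0))
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0", call. = FALSE)
  if (n_frames_acquired < 4L) stop("need at least 4 acquired frames", call. = FALSE)
  if (noise_sd_phase < 0) stop("noise_sd_phase must be >= 0", call. = FALSE)
  structure(
    list(venc = as.numeric(venc), pixel_spacing = as.numeric(pixel_spacing),
         n_frames_acquired = as.integer(n_frames_acquired),
         noise_sd_phase = as.numeric(noise_sd_phase),
         background_phase_offset = as.numeric(background_phase_offset),
         seed = as.integer(seed)),
    class = "encoding_spec")
}

#' Describe a circular vessel cross-section on the image grid
#'
#' @param name Vessel name (unique within a series).
#' @param spec The vessel's [waveform_spec()].
#' @param centre Length-2 numeric, centre in pixel coordinates (1-based).
#' @param radius Radius in pixels; a pixel belongs to the vessel if its centre
#'   lies within `radius` of `centre`.
#' @param sign Direction sign of through-plane velocity for physiologically
#'   forward flow (+1 or -1); recorded in the ROI sidecar so extraction can
#'   restore the forward-positive convention.
#' @return A `vessel_geom` list.
#' @export
vessel_geom <- function(name, spec, centre, radius, sign = 1L) {
  stopifnot(inherits(spec, "waveform_spec"), length(centre) == 2L,
            radius > 0, sign %in% c(-1L, 1L))
  structure(list(name = as.character(name), spec = spec,
                 centre = as.numeric(centre), radius = as.numeric(radius),
                 sign = as.integer(sign)),
            class = "vessel_geom")
}

.disc_mask <- function(dim, centre, radius) {
  dx <- outer(seq_len(dim[1L]) - centre[1L], rep(1, dim[2L]))
  dy <- outer(rep(1, dim[1L]), seq_len(dim[2L]) - centre[2L])
  dx * dx + dy * dy <= radius * radius
}

#' Generate a synthetic cine phase-contrast series with ground truth
#'
#' Builds a 2D+time phase/magnitude series in which each vessel is a filled
#' circle of spatially uniform through-plane velocity carrying its specified
#' flow waveform. Phase at a vessel pixel is
#' `pi * v / venc + background_phase_offset + noise`, wrapped to `[-pi, pi)`;
#' magnitude is high inside vessels and static tissue and low elsewhere. A
#' static-tissue background region (true velocity zero) is always included and
#' labelled in the returned ROI set.
#'
#' @param vessels List of [vessel_geom()] objects; geometries must fit the
#'   grid and must not overlap.
#' @param enc An [encoding_spec()].
#' @param grid_dim Length-2 integer image dimensions in pixels.
#' @param background_geom Length-4 numeric `c(x0, x1, y0, y1)` pixel-index
#'   bounds of the rectangular static-tissue ROI.
#' @param acquisition_id Identifier stored with the series.
#' @param allow_wrap If `FALSE` (default), generation refuses waveforms whose
#'   instantaneous velocity reaches `venc` rather than silently aliasing.
#' @return A list with components `series` (a [cine_series()]), `rois` (a
#'   [roi_set()]; background label is `length(vessels) + 1`), and `truth`
#'   (per-vessel list with the `spec`, the flow evaluated on the acquired time
#'   grid, and the acquired times).
#' @export
make_cine_series <- function(vessels, enc, grid_dim = c(64L, 64L),
                             background_geom = c(3L, 12L, 3L, 12L),
                             acquisition_id = "synthetic",
                             allow_wrap = FALSE) {
  stopifnot(inherits(enc, "encoding_spec"), length(grid_dim) == 2L)
  if (!length(vessels)) stop("need at least one vessel", call. = FALSE)
  grid_dim <- as.integer(grid_dim)
  cycles <- vapply(vessels, function(v) v$spec$cycle_duration, numeric(1))
  if (max(cycles) - min(cycles) > 1e-12)
    stop("all vessels in one acquisition must share cycle_duration", call. = FALSE)
  cycle <- cycles[[1L]]
  nf <- enc$n_frames_acquired
  t_acq <- (seq_len(nf) - 1L) * cycle / nf
  area_mm2 <- prod(enc$pixel_spacing)

  masks <- lapply(vessels, function(v) .disc_mask(grid_dim, v$centre, v$radius))
  names(masks) <- vapply(vessels, `[[`, character(1), "name")
  for (i in seq_along(masks)) {
    if (!any(masks[[i]]))
      stop("vessel '", names(masks)[i], "' has no pixels on the grid", call. = FALSE)
    if (i > 1L) for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]]))
        stop("vessel geometries overlap: '", names(masks)[j], "' and '",
             names(masks)[i], "'", call. = FALSE)
    }
  }
  bg <- matrix(FALSE, grid_dim[1L], grid_dim[2L])
  bg[background_geom[1L]:background_geom[2L],
     background_geom[3L]:background_geom[4L]] <- TRUE
  for (i in seq_along(masks)) if (any(bg & masks[[i]]))
    stop("vessel geometries overlap: '", names(masks)[i],
         "' and 'background'", call. = FALSE)

  # velocity per vessel: uniform across the lumen, v [cm/s] = 100 Q / (n A)
  npix <- vapply(masks, sum, integer(1))
  tt_dense <- seq(0, cycle, length.out = 2049L)[-2049L]
  for (i in seq_along(vessels)) {
    vmax <- max(abs(eval_waveform(vessels[[i]]$spec, tt_dense))) * 100 /
      (npix[i] * area_mm2)
    if (vmax >= enc$venc && !allow_wrap)
      stop("vessel '", names(masks)[i], "' reaches |v| = ",
           sprintf("%.2f", vmax), " cm/s >= venc = ", enc$venc,
           " cm/s; increase venc/radius or set allow_wrap = TRUE",
           call. = FALSE)
  }

  phase <- array(0, c(grid_dim, nf))
  magnitude <- array(8, c(grid_dim, nf))   # low signal outside tissue
  truth <- vector("list", length(vessels))
  names(truth) <- names(masks)
  for (f in seq_len(nf)) {
    ph <- matrix(0, grid_dim[1L], grid_dim[2L])
    mg <- matrix(8, grid_dim[1L], grid_dim[2L])
    mg[bg] <- 80                            # static tissue
    for (i in seq_along(vessels)) {
      q <- eval_waveform(vessels[[i]]$spec, t_acq[f])
      v <- vessels[[i]]$sign * 100 * q / (npix[i] * area_mm2)
      ph[masks[[i]]] <- pi * v / enc$venc
      mg[masks[[i]]] <- 100
    }
    phase[, , f] <- ph
    magnitude[, , f] <- mg
  }
  phase <- phase + enc$background_phase_offset
  if (enc$noise_sd_phase > 0) {
    phase <- phase + with_seed(enc$seed,
      array(stats::rnorm(length(phase), sd = enc$noise_sd_phase), dim(phase)))
  }
  phase <- ((phase + pi) %% (2 * pi)) - pi   # wrapped storage convention

  for (i in seq_along(vessels)) {
    truth[[i]] <- list(spec = vessels[[i]]$spec,
                       flow = eval_waveform(vessels[[i]]$spec, t_acq),
                       times = t_acq)
  }

  labels <- matrix(0L, grid_dim[1L], grid_dim[2L])
  for (i in seq_along(masks)) labels[masks[[i]]] <- i
  bg_label <- length(masks) + 1L
  labels[bg] <- bg_label
  vmap <- data.frame(
    label = c(seq_along(vessels), bg_label),
    name = c(names(masks), "background"),
    vessel_class = c(vapply(vessels, function(v) v$spec$vessel_class,
                            character(1)), "static"),
    sign = c(vapply(vessels, `[[`, integer(1), "sign"), 1L),
    stringsAsFactors = FALSE)

  list(series = cine_series(phase, magnitude, venc = enc$venc,
                            pixel_spacing = enc$pixel_spacing,
                            cycle_duration = cycle,
                            acquisition_id = acquisition_id),
       rois = roi_set(labels, vmap, background_label = bg_label),
       truth = truth)
}

#' Default vessel layouts for the three acquisition planes
#'
#' Returns waveform specs and geometries emulating the three standard planes:
#' an axial arterial/jugular plane (venc 70 cm/s), a coronal venous-sinus
#' plane (venc 50 cm/s), and an axial cervical CSF plane (venc 6 cm/s).
#' Mean flows sum to a total arterial inflow of about 11.7 mL/s (~700 mL/min);
#' venous outflow peaks later in the cycle than arterial inflow and CSF
#' oscillates around a small cranial mean, with its caudal peak following the
#' arterial systolic peak.
#'
#' @param cycle_duration Cardiac cycle duration in seconds (default 60/66 s,
#'   i.e. 66 bpm).
#' @param flow_scale Multiplies every mean flow and harmonic amplitude; used
#'   to vary subjects.
#' @param pulsatility_scale Multiplies harmonic amplitudes only, so it moves
#'   PI/RI/FVP without changing mean flow.
#' @return Named list of plane descriptions, each with `vessels` (list of
#'   [vessel_geom()]), `venc`, `pixel_spacing`, `temporal_resolution` (s) and
#'   `plane` name.
#' @export
default_planes <- function(cycle_duration = 60 / 66, flow_scale = 1,
                           pulsatility_scale = 1) {
  h <- function(...) {
    m <- rbind(...)
    m[, 1L] <- m[, 1L] * flow_scale * pulsatility_scale
    m
  }
  art <- function(name, mf, amp, centre, peak = 0.16) {
    vessel_geom(name,
      waveform_spec("arterial", mf * flow_scale,
                    h(c(amp, 0), c(0.38 * amp, 1.1), c(0.14 * amp, 2.1)),
                    peak_time_fraction = peak, cycle_duration = cycle_duration),
      centre = centre, radius = 2.6, sign = 1L)
  }
  ven <- function(name, mf, amp, centre, peak = 0.34, sgn = -1L, r = 2.6) {
    vessel_geom(name,
      waveform_spec("venous", mf * flow_scale, h(c(amp, 0), c(0.25 * amp, 0.9)),
                    peak_time_fraction = peak, cycle_duration = cycle_duration),
      centre = centre, radius = r, sign = sgn)
  }
  csf <- vessel_geom("csf_foramen_magnum",
    waveform_spec("csf", 0.03 * flow_scale,
                  h(c(1.8, 0), c(0.5, 0.8)),
                  # cranial peak late in the cycle; caudal peak (what PTT uses)
                  # follows the arterial peak at ~0.30 of the cycle
                  peak_time_fraction = 0.72, cycle_duration = cycle_duration),
    centre = c(32, 32), radius = 7.0, sign = 1L)
  list(
    arterial = list(
      plane = "arterial", venc = 70, pixel_spacing = c(1.0, 1.0),
      temporal_resolution = 0.0392,
      vessels = list(
        art("ICA_left", 4.3, 1.9, c(22, 24)),
        art("ICA_right", 4.5, 2.0, c(42, 24), peak = 0.165),
        art("vertebral_left", 1.4, 0.55, c(26, 42), peak = 0.17),
        art("vertebral_right", 1.5, 0.6, c(38, 42), peak = 0.175),
        ven("jugular_left", 4.8, 1.1, c(16, 34), peak = 0.32, r = 3.2),
        ven("jugular_right", 5.6, 1.3, c(48, 34), peak = 0.33, r = 3.2))),
    venous = list(
      plane = "venous", venc = 50, pixel_spacing = c(0.71, 0.71),
      temporal_resolution = 0.0434,
      vessels = list(
        ven("superior_sagittal_sinus", 4.6, 1.0, c(32, 14), peak = 0.33,
            sgn = -1L, r = 4.2),
        ven("straight_sinus", 1.6, 0.4, c(32, 34), peak = 0.35, sgn = -1L,
            r = 2.8),
        ven("transverse_sinus_left", 2.6, 0.6, c(16, 46), peak = 0.36,
            sgn = -1L, r = 3.4),
        ven("transverse_sinus_right", 3.2, 0.7, c(48, 46), peak = 0.37,
            sgn = -1L, r = 3.4))),
    csf = list(
      plane = "csf", venc = 6, pixel_spacing = c(0.83, 0.83),
      temporal_resolution = 0.0504,
      vessels = list(csf)))
}

#' Simulate the three acquisitions for one subject
#'
#' Frame counts follow from the cycle duration and each plane's temporal
#' resolution, as in retrospectively gated cine reconstruction.
#'
#' @param planes As returned by [default_planes()].
#' @param noise_sd_phase,background_phase_offset,seed Encoding parameters
#'   shared across planes (the seed is varied per plane).
#' @param subject Subject identifier used in acquisition ids.
#' @return Named list (one element per plane) of [make_cine_series()] results.
#' @export
simulate_subject <- function(planes = default_planes(), noise_sd_phase = 0,
                             background_phase_offset = 0, seed = 1L,
                             subject = "s01") {
  out <- vector("list", length(planes))
  names(out) <- names(planes)
  for (i in seq_along(planes)) {
    pl <- planes[[i]]
    cyc <- pl$vessels[[1L]]$spec$cycle_duration
    nf <- max(4L, as.integer(floor(cyc / pl$temporal_resolution)))
    enc <- encoding_spec(venc = pl$venc, pixel_spacing = pl$pixel_spacing,
                         n_frames_acquired = nf,
                         noise_sd_phase = noise_sd_phase,
                         background_phase_offset = background_phase_offset,
                         seed = seed + i * 101L)
    out[[i]] <- make_cine_series(pl$vessels, enc,
                                 acquisition_id = paste(subject, pl$plane,
                                                        sep = "_"))
  }
  out
}
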