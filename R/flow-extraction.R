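# From cine phase images + ROI masks to background-corrected flow waveforms
# on the 32-timeframe normalised cardiac cycle.

#' Construct a cine phase-contrast series
#'
#' @param phase 2D+time array of phase values in radians, wrapped to
#'   `[-pi, pi)`.
#' @param magnitude 2D+time array of signal magnitude, same shape as `phase`.
#' @param venc Velocity encoding in cm/s (> 0).
#' @param pixel_spacing Length-2 numeric, pixel spacing in mm.
#' @param cycle_duration Cardiac cycle duration in seconds. Supply either this
#'   or `heart_rate`.
#' @param heart_rate Heart rate in bpm (alternative to `cycle_duration`).
#' @param acquisition_id Free-text identifier.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(phase, magnitude, venc, pixel_spacing,
                        cycle_duration = NULL, heart_rate = NULL,
                        acquisition_id = "") {
  if (is.null(cycle_duration)) {
    if (is.null(heart_rate)) stop("supply cycle_duration or heart_rate",
                                  call. = FALSE)
    cycle_duration <- 60 / heart_rate
  }
  phase <- as.array(phase); magnitude <- as.array(magnitude)
  if (length(dim(phase)) != 3L)
    stop("phase must be a 2D+time array (x, y, t)", call. = FALSE)
  if (!identical(dim(phase), dim(magnitude)))
    stop("phase and magnitude must share shape", call. = FALSE)
  if (any(phase < -pi - 1e-9) || any(phase >= pi + 1e-9))
    stop("phase values must lie in [-pi, pi)", call. = FALSE)
  if (!is.finite(venc) || venc <= 0) stop("venc must be > 0", call. = FALSE)
  if (!is.finite(cycle_duration) || cycle_duration <= 0)
    stop("cycle_duration must be > 0", call. = FALSE)
  stopifnot(length(pixel_spacing) == 2L, all(pixel_spacing > 0))
  structure(list(phase = phase, magnitude = magnitude,
                 venc = as.numeric(venc),
                 pixel_spacing = as.numeric(pixel_spacing),
                 cycle_duration = as.numeric(cycle_duration),
                 acquisition_id = as.character(acquisition_id)),
            class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(
    "<cine_series> %s: %d x %d pixels, %d frames, venc %g cm/s, cycle %.3f s\n",
    if (nzchar(x$acquisition_id)) x$acquisition_id else "<unnamed>",
    d[1L], d[2L], d[3L], x$venc, x$cycle_duration))
  invisible(x)
}

#' Construct a labelled ROI set
#'
#' @param labels 2D integer matrix of ROI labels (0 = unlabelled).
#' @param vessel_map Data frame with columns `label`, `name`, `vessel_class`
#'   (`"arterial"`, `"venous"`, `"csf"` or `"static"`) and `sign` (+1/-1,
#'   the direction multiplier restoring the forward-positive convention).
#' @param background_label Label of the stationary-tissue background ROI.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, vessel_map, background_label) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  vessel_map <- as.data.frame(vessel_map, stringsAsFactors = FALSE)
  needed <- c("label", "name", "vessel_class", "sign")
  if (!all(needed %in% names(vessel_map)))
    stop("vessel_map needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  background_label <- as.integer(background_label)
  if (!any(labels == background_label))
    stop("background label ", background_label, " absent from mask",
         call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, vessel_map$label)
  if (length(missing))
    stop("labels without vessel_map entry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(vessel_map$sign %in% c(-1L, 1L)))
    stop("vessel_map$sign must be +1 or -1", call. = FALSE)
  structure(list(labels = labels, vessel_map = vessel_map,
                 background_label = background_label),
            class = "roi_set")
}

.roi_lookup <- function(rois, vessel) {
  vm <- rois$vessel_map
  row <- if (is.numeric(vessel)) vm[vm$label == vessel, , drop = FALSE]
         else vm[vm$name == vessel, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown vessel '", vessel, "'; known: ",
         paste(vm$name, collapse = ", "), call. = FALSE)
  row
}

#' Convert phase images to a velocity field
#'
#' Applies the linear phase-to-velocity mapping `v = venc * phase / pi`
#' (cm/s) per pixel and frame. Pixels whose phase sits at the wrap boundary
#' are counted and reported in the `aliasing_suspect` attribute, since a
#' measurement at +/- venc is indistinguishable from a wrapped one.
#'
#' @param series A [cine_series()].
#' @return 2D+time numeric array of velocities (cm/s), same shape as the
#'   phase array, with attribute `aliasing_suspect` (pixel-frame count).
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "cine_series"))
  v <- series$venc * series$phase / pi
  n_alias <- sum(abs(series$phase) >= pi * (1 - 1e-6))
  if (n_alias > 0)
    warning(n_alias, " pixel-frame(s) at the phase wrap boundary; ",
            "possible velocity aliasing", call. = FALSE)
  attr(v, "aliasing_suspect") <- n_alias
  v
}

#' Background-correct a velocity field
#'
#' Subtracts, per timeframe, the spatial mean velocity over the
#' stationary-tissue background ROI from every pixel of that frame, removing
#' constant and slowly varying background phase error. After correction the
#' background-ROI mean is zero at each frame.
#'
#' @param velocity 2D+time velocity array (cm/s), as from
#'   [phase_to_velocity()].
#' @param rois A [roi_set()] with a nonempty background ROI.
#' @return Corrected velocity array with attribute `background_offset`
#'   (the per-frame offsets that were removed).
#' @export
background_correct <- function(velocity, rois) {
  stopifnot(inherits(rois, "roi_set"))
  bg <- rois$labels == rois$background_label
  if (!any(bg)) stop("background ROI is empty", call. = FALSE)
  nf <- dim(velocity)[3L]
  offsets <- numeric(nf)
  out <- velocity
  for (f in seq_len(nf)) {
    offsets[f] <- mean(velocity[, , f][bg])
    out[, , f] <- velocity[, , f] - offsets[f]
  }
  attr(out, "aliasing_suspect") <- attr(velocity, "aliasing_suspect")
  attr(out, "background_offset") <- offsets
  out
}

#' Integrate velocity over a vessel ROI into a flow series
#'
#' Multiplies pixel velocities by pixel area and sums over the vessel lumen,
#' giving flow in mL/s per acquired frame
#' (`cm/s * mm^2 = 10 mm^3/s = 1/100 mL/s`), then applies the vessel's
#' direction sign so positive is physiologically forward.
#'
#' @param velocity 2D+time velocity array (cm/s), background-corrected.
#' @param rois A [roi_set()].
#' @param vessel Vessel name or integer label.
#' @param pixel_spacing Length-2 pixel spacing in mm.
#' @return Numeric vector of flow (mL/s), one value per acquired frame.
#' @export
roi_flow <- function(velocity, rois, vessel, pixel_spacing) {
  row <- .roi_lookup(rois, vessel)
  mask <- rois$labels == row$label
  if (!any(mask)) stop("vessel ROI '", row$name, "' is empty", call. = FALSE)
  area_ml_per_cm <- prod(pixel_spacing) / 100   # cm/s * mm^2 -> mL/s
  nf <- dim(velocity)[3L]
  vapply(seq_len(nf),
         function(f) row$sign * sum(velocity[, , f][mask]) * area_ml_per_cm,
         numeric(1))
}

#' Resample an acquired flow series onto the 32-frame cardiac cycle
#'
#' Treats the acquired frames as one full period (frame after the last wraps
#' to the first) and resamples to 32 uniformly spaced timeframes. The default
#' band-limited (Fourier) scheme is exact for the harmonic content a gated
#' reconstruction can represent; `"linear"` gives periodic linear
#' interpolation.
#'
#' @param flow Numeric vector of flow samples (mL/s), one full cycle, >= 4
#'   frames.
#' @param cycle_duration Cycle duration in seconds.
#' @param vessel,vessel_class,acquisition_id Passed to [flow_waveform()].
#' @param method `"fourier"` (default) or `"linear"`.
#' @return A [flow_waveform()].
#' @export
resample_to_cycle <- function(flow, cycle_duration, vessel = "",
                              vessel_class = "arterial", acquisition_id = "",
                              method = c("fourier", "linear")) {
  flow <- as.numeric(flow)
  if (length(flow) < 4L)
    stop("need at least 4 acquired frames, got ", length(flow), call. = FALSE)
  out <- resample_periodic(flow, CINE_FRAMES, method = match.arg(method))
  flow_waveform(out, cycle_duration, vessel = vessel,
                vessel_class = vessel_class, acquisition_id = acquisition_id)
}

#' Extract all vessel waveforms from a cine series
#'
#' Runs the full chain phase-to-velocity, background correction, ROI flow
#' integration and 32-frame resampling for every non-background label.
#'
#' @param series A [cine_series()].
#' @param rois A [roi_set()].
#' @param method Resampling scheme, see [resample_to_cycle()].
#' @return Named list of [flow_waveform()] objects (one per vessel), with
#'   attribute `provenance` (aliasing count and background offsets).
#' @export
extract_waveforms <- function(series, rois, method = c("fourier", "linear")) {
  method <- match.arg(method)
  vel <- withCallingHandlers(phase_to_velocity(series),
                             warning = function(w) invokeRestart("muffleWarning"))
  vel <- background_correct(vel, rois)
  vm <- rois$vessel_map
  vm <- vm[vm$label != rois$background_label, , drop = FALSE]
  out <- vector("list", nrow(vm))
  names(out) <- vm$name
  for (i in seq_len(nrow(vm))) {
    fl <- roi_flow(vel, rois, vm$label[i], series$pixel_spacing)
    out[[i]] <- resample_to_cycle(fl, series$cycle_duration,
                                  vessel = vm$name[i],
                                  vessel_class = vm$vessel_class[i],
                                  acquisition_id = series$acquisition_id,
                                  method = method)
  }
  attr(out, "provenance") <- list(
    aliasing_suspect = attr(vel, "aliasing_suspect"),
    background_offset = attr(vel, "background_offset"))
  out
}
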