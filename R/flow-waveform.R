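# The central intermediate of the pipeline: a flow waveform on the
# 32-timeframe normalised cardiac cycle.

#' Number of timeframes on the normalised cardiac cycle
#' @export
CINE_FRAMES <- 32L

#' Construct a flow waveform
#'
#' A flow waveform is one cardiac cycle of flow rate (mL/s) sampled at 32
#' uniform timeframes, signed so that positive is the physiological forward
#' direction (arteries: inflow; veins: outflow; CSF: cranial).
#'
#' @param flow Numeric vector of exactly 32 finite flow values (mL/s).
#' @param cycle_duration Cardiac cycle duration in seconds (> 0).
#' @param vessel Vessel name (e.g. `"ICA_left"`).
#' @param vessel_class One of `"arterial"`, `"venous"`, `"csf"`.
#' @param acquisition_id Identifier of the source acquisition.
#' @return An object of class `flow_waveform`.
#' @export
#' @examples
#' w <- flow_waveform(5 + 2 * sin(2 * pi * (0:31) / 32), cycle_duration = 0.9,
#'                    vessel = "ICA_left", vessel_class = "arterial")
#' pulsatility_index(w)
flow_waveform <- function(flow, cycle_duration, vessel = "",
                          vessel_class = c("arterial", "venous", "csf"),
                          acquisition_id = "") {
  vessel_class <- match.arg(vessel_class)
  flow <- as.numeric(flow)
  if (length(flow) != CINE_FRAMES)
    stop("a flow_waveform has exactly ", CINE_FRAMES, " timeframes, got ",
         length(flow), call. = FALSE)
  if (!all(is.finite(flow)))
    stop("flow values must be finite", call. = FALSE)
  if (!is.numeric(cycle_duration) || length(cycle_duration) != 1L ||
      !is.finite(cycle_duration) || cycle_duration <= 0)
    stop("cycle_duration must be a single positive number (seconds)",
         call. = FALSE)
  structure(
    list(vessel = as.character(vessel), vessel_class = vessel_class,
         flow = flow, cycle_duration = as.numeric(cycle_duration),
         acquisition_id = as.character(acquisition_id)),
    class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> %s (%s), cycle %.3f s\n  mean %.3f mL/s, range [%.3f, %.3f] mL/s\n",
    if (nzchar(x$vessel)) x$vessel else "<unnamed>", x$vessel_class,
    x$cycle_duration, mean(x$flow), min(x$flow), max(x$flow)))
  invisible(x)
}

#' @export
as.data.frame.flow_waveform <- function(x, ...) {
  data.frame(vessel = x$vessel, vessel_class = x$vessel_class,
             frame = seq_along(x$flow) - 1L, flow_ml_s = x$flow,
             cycle_s = x$cycle_duration, acquisition = x$acquisition_id,
             stringsAsFactors = FALSE)
}

is_flow_waveform <- function(x) inherits(x, "flow_waveform")

# Accept a flow_waveform or a bare numeric cycle; returns list(flow, cycle).
# Bare vectors (any length >= 4) let the metric functions run on densely
# sampled analytic waveforms.
.as_cycle <- function(w, cycle_duration = NULL) {
  if (is_flow_waveform(w)) {
    list(flow = w$flow, cycle = w$cycle_duration)
  } else {
    flow <- as.numeric(w)
    if (length(flow) < 4L || !all(is.finite(flow)))
      stop("waveform must be a flow_waveform or a finite numeric vector of length >= 4",
           call. = FALSE)
    list(flow = flow, cycle = cycle_duration)
  }
}
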