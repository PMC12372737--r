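# Waveform-derived statistics: Gosling PI, Pourcelot RI, flow volume
# pulsatility, combined/mean multi-vessel indices, pulse transit time,
# volume-normalised CBF, pulse pressure and the CSF flow statistics.

.MEAN_TOL <- 1e-12  # mL/s below which a mean flow is treated as zero

#' Gosling pulsatility index
#'
#' `PI = (flow_max - flow_min) / flow_mean` over the cardiac cycle. Not
#' defined for waveforms whose mean flow is (numerically) zero, which is why
#' it is not computed for CSF.
#'
#' @param w A [flow_waveform()] or a numeric vector sampling one cycle.
#' @return The pulsatility index (dimensionless).
#' @export
#' @examples
#' pulsatility_index(5 + 2 * sin(2 * pi * (0:31) / 32))  # 2a/m = 0.8
pulsatility_index <- function(w) {
  x <- .as_cycle(w)$flow
  m <- mean(x)
  if (abs(m) <= .MEAN_TOL)
    stop("pulsatility index undefined: mean flow is zero (within ",
         .MEAN_TOL, " mL/s); for CSF use csf_metrics()", call. = FALSE)
  (max(x) - min(x)) / m
}

#' Pourcelot resistance index
#'
#' `RI = (flow_max - flow_min) / flow_max`.
#'
#' @inheritParams pulsatility_index
#' @return The resistance index (dimensionless).
#' @export
resistance_index <- function(w) {
  x <- .as_cycle(w)$flow
  mx <- max(x)
  if (abs(mx) <= .MEAN_TOL)
    stop("resistance index undefined: maximum flow is zero", call. = FALSE)
  (mx - min(x)) / mx
}

#' Flow volume pulsatility
#'
#' Subtracts the mean flow, integrates cumulatively over real time across the
#' cycle, shifts the volume curve so its minimum is zero, and returns the
#' maximum — the pulsatile volume excursion. Dimensionally this is a volume
#' and is reported in mL.
#'
#' @inheritParams pulsatility_index
#' @param cycle_duration Cycle duration in seconds; taken from `w` when it is
#'   a [flow_waveform()].
#' @return FVP in mL.
#' @export
#' @examples
#' # sinusoid amplitude a over cycle T: FVP = a * T / pi
#' flow_volume_pulsatility(2 * sin(2 * pi * (0:31) / 32), cycle_duration = 1)
flow_volume_pulsatility <- function(w, cycle_duration = NULL) {
  cy <- .as_cycle(w, cycle_duration)
  if (is.null(cy$cycle)) stop("cycle_duration required", call. = FALSE)
  v <- .cycle_antiderivative(cy$flow, cy$cycle)
  max(v) - min(v)
}

#' Cumulative volume curve over the cycle
#'
#' The mean-subtracted cumulative flow integral, shifted to set the minimum
#' volume to zero; `flow_volume_pulsatility()` is its maximum.
#'
#' @inheritParams flow_volume_pulsatility
#' @param n_points Number of uniform cycle points to evaluate on.
#' @return Data frame with `time` (s) and `volume` (mL).
#' @export
flow_volume_curve <- function(w, cycle_duration = NULL, n_points = 256L) {
  cy <- .as_cycle(w, cycle_duration)
  if (is.null(cy$cycle)) stop("cycle_duration required", call. = FALSE)
  v <- .cycle_antiderivative(cy$flow, cy$cycle, min_points = n_points)
  data.frame(time = (seq_along(v) - 1L) * cy$cycle / length(v),
             volume = v - min(v))
}

#' Per-vessel waveform metrics
#'
#' @param w A [flow_waveform()] of class `"arterial"` or `"venous"`. CSF
#'   waveforms (mean flow near zero) are rejected; use [csf_metrics()].
#' @return A `vessel_metrics` list: `vessel`, `mean_flow` (mL/s), `pi`, `ri`,
#'   `fvp` (mL) and `peak_time` (s within the cycle).
#' @export
vessel_metrics <- function(w) {
  stopifnot(is_flow_waveform(w))
  if (w$vessel_class == "csf")
    stop("PI/RI are not computed for CSF waveforms; use csf_metrics()",
         call. = FALSE)
  structure(
    list(vessel = w$vessel, mean_flow = mean(w$flow),
         pi = pulsatility_index(w), ri = resistance_index(w),
         fvp = flow_volume_pulsatility(w),
         peak_time = (which.max(w$flow) - 1L) * w$cycle_duration /
           length(w$flow)),
    class = "vessel_metrics")
}

#' Sum the four arterial inflow waveforms
#'
#' Frame-wise sum of the two internal carotid and two vertebral artery
#' waveforms; combined arterial PI/RI/FVP are computed on the sum.
#'
#' @param waveforms List of [flow_waveform()] objects from the same
#'   acquisition (identical cycle duration).
#' @return A [flow_waveform()] named `"combined_arterial"`, with attribute
#'   `n_vessels` and `complete` (`TRUE` when `length(waveforms) ==
#'   n_expected`).
#' @param n_expected Number of vessels expected (4: 2 ICAs + 2 vertebrals).
#' @export
combined_arterial_waveform <- function(waveforms, n_expected = 4L) {
  stopifnot(length(waveforms) >= 1L, all(vapply(waveforms, is_flow_waveform,
                                                logical(1))))
  cyc <- vapply(waveforms, `[[`, numeric(1), "cycle_duration")
  if (max(cyc) - min(cyc) > 1e-9)
    stop("mismatched cycle durations: ",
         paste(sprintf("%.4f", range(cyc)), collapse = " vs "), " s",
         call. = FALSE)
  total <- Reduce(`+`, lapply(waveforms, `[[`, "flow"))
  out <- flow_waveform(total, cyc[1L], vessel = "combined_arterial",
                       vessel_class = "arterial",
                       acquisition_id = waveforms[[1L]]$acquisition_id)
  attr(out, "n_vessels") <- length(waveforms)
  attr(out, "complete") <- length(waveforms) == n_expected
  out
}

#' Mean venous-sinus index
#'
#' Venous sinuses are either downstream of each other or drain separate
#' territories, so their waveforms are not summed; the combined venous index
#' is the arithmetic mean of the per-vessel values.
#'
#' @param metrics List of [vessel_metrics()] for the available sinuses
#'   (superior sagittal, straight, transverse); may be empty.
#' @return List with `pi`, `ri`, `fvp` (each `NA` when no vessel is
#'   available) and `n_vessels`.
#' @export
mean_venous_index <- function(metrics) {
  stopifnot(is.list(metrics))
  if (!length(metrics))
    return(list(pi = NA_real_, ri = NA_real_, fvp = NA_real_, n_vessels = 0L))
  stopifnot(all(vapply(metrics, inherits, logical(1), "vessel_metrics")))
  list(pi = mean(vapply(metrics, `[[`, numeric(1), "pi")),
       ri = mean(vapply(metrics, `[[`, numeric(1), "ri")),
       fvp = mean(vapply(metrics, `[[`, numeric(1), "fvp")),
       n_vessels = length(metrics))
}

#' Pulse transit time between an upstream and a downstream waveform
#'
#' Both cycles are normalised to 1 second; the transit time is the difference
#' between the downstream and upstream peak times, wrapped into `[0, 1)`
#' (arterial-to-downstream propagation happens within a cycle, so a negative
#' raw difference is a wrap artefact). Peaks are located by argmax over the
#' 32 timeframes, earliest frame on ties; for a CSF target the peak *caudal*
#' (most negative) flow is used, as that is what arterial inflow drives.
#' Measurements are excluded when the heart rates of the two source scans
#' differ by more than 15 bpm, or when a waveform is flat.
#'
#' @param upstream,downstream [flow_waveform()] objects.
#' @param hr_upstream,hr_downstream Heart rates (bpm) of the two source
#'   scans; defaults derived from each waveform's cycle duration.
#' @param downstream_is_csf Use the caudal-peak rule for the downstream
#'   waveform. Defaults to `TRUE` when its vessel class is `"csf"`.
#' @param wrap Wrap negative raw differences by +1 s (default). With
#'   `wrap = FALSE` the signed difference in `(-1, 1)` is returned.
#' @return A `ptt_result` list: `upstream`, `downstream`, `ptt` (s on the
#'   1-second cycle; `NA` when excluded), `excluded`, `exclusion_reason`.
#' @export
pulse_transit_time <- function(upstream, downstream,
                               hr_upstream = 60 / upstream$cycle_duration,
                               hr_downstream = 60 / downstream$cycle_duration,
                               downstream_is_csf =
                                 downstream$vessel_class == "csf",
                               wrap = TRUE) {
  stopifnot(is_flow_waveform(upstream), is_flow_waveform(downstream),
            hr_upstream > 0, hr_downstream > 0)
  res <- function(ptt, excluded = FALSE, reason = "")
    structure(list(upstream = upstream$vessel, downstream = downstream$vessel,
                   ptt = ptt, excluded = excluded, exclusion_reason = reason),
              class = "ptt_result")
  if (abs(hr_upstream - hr_downstream) > 15)
    return(res(NA_real_, TRUE,
               sprintf("heart-rate difference %.1f bpm exceeds 15 bpm",
                       abs(hr_upstream - hr_downstream))))
  flat <- function(x) diff(range(x)) <= 1e-9 * max(1, max(abs(x)))
  if (flat(upstream$flow) || flat(downstream$flow))
    return(res(NA_real_, TRUE, "degenerate waveform"))
  n <- length(upstream$flow)
  t_up <- (which.max(upstream$flow) - 1L) / n
  t_dn <- if (downstream_is_csf) (which.min(downstream$flow) - 1L) / n
          else (which.max(downstream$flow) - 1L) / n
  d <- t_dn - t_up
  if (wrap) d <- d %% 1
  res(d)
}

#' Volume-normalised cerebral blood flow
#'
#' Total mean arterial inflow (ICAs + vertebral arteries) per minute,
#' normalised to brain volume: `CBF = sum(mean flow) * 60 / brain_volume *
#' 100`, in mL/min per 100 mL brain. When fewer than the expected four
#' vessels are available the sum runs over the available ones and the result
#' carries `complete = FALSE`.
#'
#' @param waveforms List of arterial [flow_waveform()] objects.
#' @param brain_volume Brain volume in mL (> 0).
#' @param n_expected Expected number of inflow vessels (default 4).
#' @return List with `cbf` (mL/min per 100 mL), `total_inflow` (mL/s),
#'   `n_vessels`, `complete`.
#' @export
cerebral_blood_flow <- function(waveforms, brain_volume, n_expected = 4L) {
  stopifnot(length(waveforms) >= 1L, all(vapply(waveforms, is_flow_waveform,
                                                logical(1))))
  if (!is.finite(brain_volume) || brain_volume <= 0)
    stop("brain_volume must be > 0 (mL)", call. = FALSE)
  total <- sum(vapply(waveforms, function(w) mean(w$flow), numeric(1)))
  list(cbf = total * 60 / brain_volume * 100, total_inflow = total,
       n_vessels = length(waveforms),
       complete = length(waveforms) == n_expected)
}

#' CSF flow statistics
#'
#' With the cranial-positive sign convention: net flow is the cycle integral
#' of flow expressed per minute (mL/min); peak flow is the absolute maximum
#' flow rate (mL/s); stroke volume is the average absolute flow volume, i.e.
#' the mean of the cranially and caudally directed volumes per cycle,
#' `integral(|Q|) / 2` (mL) — equal to either directed volume when net flow
#' is zero. `convention = "total"` instead returns the total absolute volume
#' `integral(|Q|)`.
#'
#' The absolute-value integral is evaluated on a trigonometric upsampling of
#' the waveform, since the kinks that `|.|` introduces alias at the raw frame
#' count.
#'
#' @param w A CSF-class [flow_waveform()] or numeric cycle (then supply
#'   `cycle_duration`).
#' @param cycle_duration Cycle duration (s) for numeric input.
#' @param convention `"directed_mean"` (default) or `"total"` for the stroke
#'   volume.
#' @return A `csf_metrics` list: `net_flow` (mL/min, cranial positive),
#'   `peak_flow` (mL/s), `stroke_volume` (mL).
#' @export
#' @examples
#' t32 <- (0:31) / 32
#' csf_metrics(pi * sin(2 * pi * t32), cycle_duration = 1)  # SV 1 mL, peak pi
csf_metrics <- function(w, cycle_duration = NULL,
                        convention = c("directed_mean", "total")) {
  convention <- match.arg(convention)
  if (is_flow_waveform(w) && w$vessel_class != "csf")
    stop("csf_metrics expects a CSF-class waveform", call. = FALSE)
  cy <- .as_cycle(w, cycle_duration)
  if (is.null(cy$cycle)) stop("cycle_duration required", call. = FALSE)
  abs_volume <- .cycle_mean_abs(cy$flow) * cy$cycle
  structure(
    list(net_flow = mean(cy$flow) * 60,
         peak_flow = max(abs(cy$flow)),
         stroke_volume = if (convention == "directed_mean") abs_volume / 2
                         else abs_volume),
    class = "csf_metrics")
}

#' Pulse pressure
#'
#' @param systolic,diastolic Blood pressures in mm Hg (vectorised).
#' @return `systolic - diastolic` in mm Hg.
#' @export
pulse_pressure <- function(systolic, diastolic) systolic - diastolic
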