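# Format readers/writers: NIfTI phase/magnitude series and label masks with
# JSON sidecars, tidy waveform CSVs. The same schema serves synthetic and
# real data.

#' Write a cine series as NIfTI phase/magnitude plus JSON metadata
#'
#' Produces `<prefix>_phase.nii.gz`, `<prefix>_mag.nii.gz` (dimensions
#' x, y, t; pixel spacing and frame duration in the header `pixdim`) and
#' `<prefix>_meta.json` carrying `venc`, `pixel_spacing`, `cycle_duration`
#' and `acquisition_id`.
#'
#' @param series A [cine_series()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the three paths written.
#' @export
write_cine_series <- function(series, dir, prefix = series$acquisition_id) {
  stopifnot(inherits(series, "cine_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- dim(series$phase)[3L]
  dt <- series$cycle_duration / nf
  paths <- file.path(dir, paste0(prefix, c("_phase.nii.gz", "_mag.nii.gz",
                                           "_meta.json")))
  ph <- RNifti::asNifti(series$phase)
  RNifti::pixdim(ph) <- c(series$pixel_spacing, dt)
  RNifti::writeNifti(ph, paths[1L])
  mg <- RNifti::asNifti(series$magnitude)
  RNifti::pixdim(mg) <- c(series$pixel_spacing, dt)
  RNifti::writeNifti(mg, paths[2L])
  jsonlite::write_json(
    list(venc = series$venc, pixel_spacing = series$pixel_spacing,
         cycle_duration = series$cycle_duration,
         acquisition_id = series$acquisition_id,
         phase_convention = "phase = pi * v / venc, wrapped to [-pi, pi)"),
    paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cine series written by [write_cine_series()]
#'
#' @param phase_path,mag_path NIfTI file paths.
#' @param meta_path JSON sidecar path; alternatively supply `venc` and
#'   `cycle_duration` directly.
#' @param venc,cycle_duration,acquisition_id Overrides / replacements for
#'   sidecar fields.
#' @return A [cine_series()].
#' @export
read_cine_series <- function(phase_path, mag_path, meta_path = NULL,
                             venc = NULL, cycle_duration = NULL,
                             acquisition_id = NULL) {
  meta <- list()
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path))
      stop("metadata sidecar not found: ", meta_path, call. = FALSE)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  venc <- venc %||% meta$venc
  cycle_duration <- cycle_duration %||% meta$cycle_duration
  acquisition_id <- acquisition_id %||% meta$acquisition_id %||% ""
  if (is.null(venc) || is.null(cycle_duration))
    stop("venc and cycle_duration must come from the sidecar or arguments",
         call. = FALSE)
  ph <- RNifti::readNifti(phase_path)
  mg <- RNifti::readNifti(mag_path)
  spacing <- meta$pixel_spacing %||% RNifti::pixdim(ph)[1:2]
  cine_series(array(as.numeric(ph), dim(ph)), array(as.numeric(mg), dim(mg)),
              venc = venc, pixel_spacing = spacing,
              cycle_duration = cycle_duration,
              acquisition_id = acquisition_id)
}

#' Write an ROI set as integer-label NIfTI plus JSON sidecar
#'
#' The sidecar maps each label to vessel name, class and flow-direction
#' sign, and names the background label.
#'
#' @param rois A [roi_set()].
#' @param nii_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_roi_set <- function(rois, nii_path, json_path) {
  stopifnot(inherits(rois, "roi_set"))
  dir.create(dirname(nii_path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(rois$labels), nii_path)
  jsonlite::write_json(
    list(background_label = rois$background_label,
         vessels = rois$vessel_map),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(nii_path, json_path))
}

#' Read an ROI set written by [write_roi_set()]
#'
#' @param nii_path Label NIfTI path.
#' @param json_path Sidecar path.
#' @return A [roi_set()].
#' @export
read_roi_set <- function(nii_path, json_path) {
  if (!file.exists(json_path))
    stop("ROI sidecar not found: ", json_path, call. = FALSE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  lab <- RNifti::readNifti(nii_path)
  labm <- matrix(as.integer(lab), dim(lab)[1L], dim(lab)[2L])
  roi_set(labm, side$vessels, background_label = side$background_label)
}

#' Write per-vessel waveforms as tidy CSV
#'
#' One row per (subject, vessel, frame): columns `subject`, `acquisition`,
#' `vessel`, `vessel_class`, `frame` (0-31), `flow_ml_s`, `cycle_s`.
#'
#' @param waveforms Either a named list of [flow_waveform()] (one subject) or
#'   a named list of such lists (names = subject ids).
#' @param path Output CSV path.
#' @param subject Subject id used when `waveforms` is a single subject's
#'   list.
#' @return Invisibly, `path`.
#' @export
write_waveforms_csv <- function(waveforms, path, subject = "s01") {
  if (length(waveforms) && is_flow_waveform(waveforms[[1L]]))
    waveforms <- stats::setNames(list(waveforms), subject)
  rows <- list()
  for (sub in names(waveforms)) {
    for (w in waveforms[[sub]]) {
      d <- as.data.frame(w)
      d$subject <- sub
      rows[[length(rows) + 1L]] <- d
    }
  }
  out <- do.call(rbind, rows)
  out <- out[c("subject", "acquisition", "vessel", "vessel_class", "frame",
               "flow_ml_s", "cycle_s")]
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read waveforms from the tidy CSV format
#'
#' @param path CSV written by [write_waveforms_csv()].
#' @return Named list (by subject) of named lists of [flow_waveform()].
#' @export
read_waveforms_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (sub in unique(d$subject)) {
    ds <- d[d$subject == sub, ]
    ws <- list()
    for (v in unique(ds$vessel)) {
      dv <- ds[ds$vessel == v, ]
      dv <- dv[order(dv$frame), ]
      ws[[v]] <- flow_waveform(dv$flow_ml_s, dv$cycle_s[1L], vessel = v,
                               vessel_class = dv$vessel_class[1L],
                               acquisition_id = dv$acquisition[1L])
    }
    out[[as.character(sub)]] <- ws
  }
  out
}
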