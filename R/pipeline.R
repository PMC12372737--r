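# End-to-end pipeline: simulate -> quantify -> metrics -> analyze, with a
# provenance record, plus the per-subject metrics assembly.

#' Compute one subject's metrics row from their vessel waveforms
#'
#' Assembles the full per-subject statistics set: combined arterial PI/RI/FVP
#' (on the summed ICA + vertebral waveform), mean venous-sinus indices,
#' jugular metrics, pulse transit times from the summed ICA waveform to the
#' superior sagittal sinus and to the CSF space (with the >15 bpm heart-rate
#' exclusion), volume-normalised CBF, the CSF statistics and pulse pressure.
#'
#' Vessels are recognised by name: `ICA_*`, `vertebral_*`, `jugular_*`,
#' `superior_sagittal_sinus`, `straight_sinus`, `transverse_sinus_*`,
#' `csf_*`. Missing vessels reduce the combined/mean indices to the available
#' ones (flagged via `arterial_complete` / `n_venous_sinuses`).
#'
#' @param waveforms Named list of [flow_waveform()] covering the subject's
#'   acquisitions.
#' @param brain_volume Brain volume in mL (for CBF; `NA` skips CBF).
#' @param systolic_bp,diastolic_bp Blood pressures in mm Hg (for pulse
#'   pressure).
#' @param subject Subject id for the output row.
#' @return One-row data frame of metrics.
#' @export
compute_subject_metrics <- function(waveforms, brain_volume = NA,
                                    systolic_bp = NA, diastolic_bp = NA,
                                    subject = "s01") {
  nm <- names(waveforms)
  pick <- function(pat) waveforms[grepl(pat, nm)]
  arterial <- pick("^(ICA|vertebral)")
  icas <- pick("^ICA")
  sinuses <- pick("^(superior_sagittal|straight|transverse)")
  jugulars <- pick("^jugular")
  csf <- pick("^csf")

  row <- data.frame(subject = subject, stringsAsFactors = FALSE)

  if (length(arterial)) {
    comb <- combined_arterial_waveform(arterial)
    am <- vessel_metrics(comb)
    row$arterial_mean_flow <- am$mean_flow
    row$arterial_pi <- am$pi
    row$arterial_ri <- am$ri
    row$arterial_fvp <- am$fvp
    row$arterial_complete <- attr(comb, "complete")
  } else {
    row[c("arterial_mean_flow", "arterial_pi", "arterial_ri",
          "arterial_fvp")] <- NA_real_
    row$arterial_complete <- FALSE
  }

  vm <- lapply(sinuses, vessel_metrics)
  vi <- mean_venous_index(unname(vm))
  row$venous_pi <- vi$pi
  row$venous_ri <- vi$ri
  row$venous_fvp <- vi$fvp
  row$n_venous_sinuses <- vi$n_vessels

  if (length(jugulars)) {
    jm <- lapply(jugulars, vessel_metrics)
    row$jugular_pi <- mean(vapply(jm, `[[`, numeric(1), "pi"))
    row$jugular_mean_flow <- sum(vapply(jm, `[[`, numeric(1), "mean_flow"))
  } else {
    row$jugular_pi <- NA_real_
    row$jugular_mean_flow <- NA_real_
  }

  row$cbf <- if (length(arterial) && is.finite(brain_volume))
    cerebral_blood_flow(arterial, brain_volume)$cbf else NA_real_
  row$brain_volume <- brain_volume

  if (length(csf)) {
    cm <- csf_metrics(csf[[1L]])
    row$csf_net_flow <- cm$net_flow
    row$csf_peak_flow <- cm$peak_flow
    row$csf_stroke_volume <- cm$stroke_volume
  } else {
    row[c("csf_net_flow", "csf_peak_flow", "csf_stroke_volume")] <- NA_real_
  }

  ptt_to <- function(target) {
    if (!length(icas) || !length(target))
      return(list(ptt = NA_real_, excluded = NA))
    up <- combined_arterial_waveform(icas)
    up$vessel <- "ICA_combined"
    r <- pulse_transit_time(up, target[[1L]])
    list(ptt = r$ptt, excluded = r$excluded)
  }
  pv <- ptt_to(pick("^superior_sagittal"))
  pc <- ptt_to(csf)
  row$ptt_arterial_venous <- pv$ptt
  row$ptt_arterial_venous_excluded <- pv$excluded
  row$ptt_arterial_csf <- pc$ptt
  row$ptt_arterial_csf_excluded <- pc$excluded

  row$pulse_pressure <- pulse_pressure(systolic_bp, diastolic_bp)
  row
}

#' Pipeline configuration with defaults
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every random draw.
#' @param n_subjects Number of synthetic subjects.
#' @param noise_sd_phase Phase noise SD (radians).
#' @param background_phase_offset Constant background phase error (radians).
#' @param resample_method `"fourier"` or `"linear"`.
#' @param write_nifti Also write the per-subject NIfTI series and masks
#'   (slower; CSV intermediates are always written).
#' @param stages Stages to run, in order, from
#'   `c("simulate", "quantify", "metrics", "analyze")`. A stage may be
#'   skipped when its inputs already exist in `out_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_subjects = 60L,
                            noise_sd_phase = 0.02,
                            background_phase_offset = 0.1,
                            resample_method = "fourier",
                            write_nifti = FALSE,
                            stages = c("simulate", "quantify", "metrics",
                                       "analyze")) {
  stopifnot(all(stages %in% c("simulate", "quantify", "metrics", "analyze")))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 noise_sd_phase = noise_sd_phase,
                 background_phase_offset = background_phase_offset,
                 resample_method = resample_method,
                 write_nifti = isTRUE(write_nifti), stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Simulate a study: per-subject acquisitions with varied physiology
#'
#' Subjects vary in heart rate, overall flow and pulsatility; each gets the
#' three acquisition planes from [default_planes()]. Per-acquisition heart
#' rates drift slightly around the subject's mean, as happens between scans.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param noise_sd_phase,background_phase_offset Encoding imperfections.
#' @return List with `subjects` (per subject: `acquisitions` from
#'   [simulate_subject()], `heart_rate`, `brain_volume`, `systolic_bp`,
#'   `diastolic_bp`) and `params` (data frame of the drawn physiology).
#' @export
simulate_study <- function(n_subjects = 8L, seed = 1L, noise_sd_phase = 0.02,
                           background_phase_offset = 0.1) {
  clamp2 <- function(x, sd) pmin(pmax(x, -2 * sd), 2 * sd)  # keep velocities
                                                            # inside venc
  draws <- with_seed(seed, data.frame(
    subject = sprintf("sub%04d", seq_len(n_subjects)),
    heart_rate = stats::rnorm(n_subjects, 66, 7),
    flow_scale = exp(clamp2(stats::rnorm(n_subjects, 0, 0.12), 0.12)),
    pulsatility_scale = exp(clamp2(stats::rnorm(n_subjects, 0, 0.18), 0.18)),
    brain_volume = stats::rnorm(n_subjects, 1400, 120),
    systolic_bp = stats::rnorm(n_subjects, 145, 18),
    diastolic_bp = stats::rnorm(n_subjects, 82, 10),
    hr_drift = stats::rnorm(n_subjects, 0, 1.5),
    stringsAsFactors = FALSE))
  subjects <- vector("list", n_subjects)
  names(subjects) <- draws$subject
  for (i in seq_len(n_subjects)) {
    hr <- draws$heart_rate[i]
    planes <- default_planes(cycle_duration = 60 / hr,
                             flow_scale = draws$flow_scale[i],
                             pulsatility_scale = draws$pulsatility_scale[i])
    acq <- simulate_subject(planes, noise_sd_phase = noise_sd_phase,
                            background_phase_offset = background_phase_offset,
                            seed = seed + i * 1009L,
                            subject = draws$subject[i])
    subjects[[i]] <- list(acquisitions = acq, heart_rate = hr,
                          brain_volume = draws$brain_volume[i],
                          systolic_bp = draws$systolic_bp[i],
                          diastolic_bp = draws$diastolic_bp[i])
  }
  list(subjects = subjects, params = draws)
}

#' Run the full pipeline
#'
#' Executes `simulate -> quantify -> metrics -> analyze` on synthetic data,
#' writing tidy CSV intermediates (`waveforms.csv`, `metrics.csv`,
#' `cohort.csv`, `results.csv`) and a `provenance.json` record (tool version,
#' config hash, per-stage warnings and exclusion counts) to
#' `config$out_dir`. Outputs are deterministic given the seed; rerunning with
#' an unchanged config rewrites identical data files.
#'
#' @param config A [pipeline_config()], a YAML path, or a list of fields.
#' @return Invisibly, a list with `waveforms`, `metrics`, `cohort`,
#'   `results`, `provenance` and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(waveforms = file.path(config$out_dir, "waveforms.csv"),
                metrics = file.path(config$out_dir, "metrics.csv"),
                cohort = file.path(config$out_dir, "cohort.csv"),
                results = file.path(config$out_dir, "results.csv"),
                provenance = file.path(config$out_dir, "provenance.json"))
  warnings <- list()
  stage <- function(s) s %in% config$stages

  study <- NULL
  if (stage("simulate")) {
    study <- simulate_study(config$n_subjects, seed = config$seed,
                            noise_sd_phase = config$noise_sd_phase,
                            background_phase_offset =
                              config$background_phase_offset)
    if (config$write_nifti) {
      for (sub in names(study$subjects)) {
        for (pl in names(study$subjects[[sub]]$acquisitions)) {
          a <- study$subjects[[sub]]$acquisitions[[pl]]
          d <- file.path(config$out_dir, "nifti", sub)
          write_cine_series(a$series, d)
          write_roi_set(a$rois,
                        file.path(d, paste0(pl, "_roi.nii.gz")),
                        file.path(d, paste0(pl, "_roi.json")))
        }
      }
    }
  }

  waveforms <- NULL
  if (stage("quantify")) {
    if (is.null(study)) stop("quantify stage needs simulated data in-memory; ",
                             "run the simulate stage or use extract_waveforms()",
                             call. = FALSE)
    waveforms <- list()
    alias_total <- 0L
    for (sub in names(study$subjects)) {
      ws <- list()
      for (pl in names(study$subjects[[sub]]$acquisitions)) {
        a <- study$subjects[[sub]]$acquisitions[[pl]]
        ex <- extract_waveforms(a$series, a$rois,
                                method = config$resample_method)
        alias_total <- alias_total +
          attr(ex, "provenance")$aliasing_suspect
        ws <- c(ws, ex)
      }
      waveforms[[sub]] <- ws
    }
    warnings$aliasing_suspect_pixels <- alias_total
    write_waveforms_csv(waveforms, paths$waveforms)
  } else if (file.exists(paths$waveforms)) {
    waveforms <- read_waveforms_csv(paths$waveforms)
  }

  metrics <- NULL
  if (stage("metrics")) {
    if (is.null(waveforms))
      stop("metrics stage needs ", paths$waveforms, call. = FALSE)
    rows <- lapply(names(waveforms), function(sub) {
      info <- if (!is.null(study)) study$subjects[[sub]] else
        list(brain_volume = NA, systolic_bp = NA, diastolic_bp = NA)
      compute_subject_metrics(waveforms[[sub]],
                              brain_volume = info$brain_volume,
                              systolic_bp = info$systolic_bp,
                              diastolic_bp = info$diastolic_bp,
                              subject = sub)
    })
    metrics <- do.call(rbind, rows)
    warnings$ptt_exclusions <-
      sum(metrics$ptt_arterial_venous_excluded, na.rm = TRUE) +
      sum(metrics$ptt_arterial_csf_excluded, na.rm = TRUE)
    utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  } else if (file.exists(paths$metrics)) {
    metrics <- utils::read.csv(paths$metrics, stringsAsFactors = FALSE)
  }

  cohort <- NULL
  results <- NULL
  if (stage("analyze")) {
    if (is.null(metrics))
      stop("analyze stage needs ", paths$metrics, call. = FALSE)
    csp <- default_cohort_spec(nrow(metrics), seed = config$seed + 7L,
                               with_flow_covariates = FALSE)
    flow_cols <- metrics[c("arterial_pi", "arterial_ri", "arterial_fvp",
                           "venous_pi", "cbf", "csf_stroke_volume",
                           "csf_net_flow", "csf_peak_flow")]
    cohort <- make_cohort(csp, flow_metrics = flow_cols)
    # measured brain volume replaces the drawn one where available
    cohort$brain_volume <- ifelse(is.na(metrics$brain_volume),
                                  cohort$brain_volume, metrics$brain_volume)
    utils::write.csv(cohort, paths$cohort, row.names = FALSE)
    grid <- default_analysis_grid()
    results <- run_analysis_suite(cohort, grid)
    warnings$model_errors <- sum(!is.na(results$error))
    warnings$rows_dropped <- attr(results, "dropped")
    utils::write.csv(results, paths$results, row.names = FALSE)
  }

  cfg_for_hash <- unclass(config)
  tf <- tempfile()
  writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE), tf)
  provenance <- list(
    tool = "cineflow",
    version = as.character(utils::packageVersion("cineflow")),
    config = cfg_for_hash,
    config_hash = unname(tools::md5sum(tf)),
    warnings = warnings,
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tf)
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(waveforms = waveforms, metrics = metrics, cohort = cohort,
                 results = results, provenance = provenance, paths = paths))
}

#' One-command synthetic demo
#'
#' Runs the entire synthetic pipeline (a small cohort) in well under a
#' minute.
#'
#' @param out_dir Output directory (default: a fresh temporary directory).
#' @param seed Integer seed.
#' @param n_subjects Number of subjects.
#' @return The [run_pipeline()] result (invisibly).
#' @export
demo_pipeline <- function(out_dir = tempfile("cineflow_demo"), seed = 1L,
                          n_subjects = 60L) {
  run_pipeline(pipeline_config(out_dir, seed = seed,
                               n_subjects = n_subjects))
}
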