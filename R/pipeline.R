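# Pipeline orchestration: phantom -> preprocess -> segment -> quantify -> fit.
#
# A run is driven by a single JSON config. Volumes come either from a
# phantom time-series specification (one per wall shear stress) or from a
# manifest CSV listing TIFF stacks on disk. Every stage is logged to stderr
# with its parameters and timing; outputs are a scan-summary CSV, per-scan
# JSON reports, and a power-law fit report when at least two shear
# conditions are present.

pipe_log <- function(logfile, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Default pipeline configuration
#'
#' Returns the full set of recognised options with their defaults; a user
#' config (JSON) is merged over these. Stage toggles: `rotate` (with
#' `angle_a`, `angle_b`), `flatten`, `denoise`, `trim`.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    rotate = FALSE, angle_a = 0, angle_b = 0,
    flatten = TRUE, substratum_layers = 1,
    denoise = TRUE, filter_radius = 2,
    trim = TRUE, trim_margin = 3,
    smooth = 3, threshold_offset = 3,
    streamer_threshold = 2 / 3,
    voxel_lateral = 12, voxel_axial = 2.1,
    phantom = NULL,   # list(tau_w=..., times=..., shape=..., noise_mean=..., ...)
    manifest = NULL,  # CSV path with columns path, time, tau_w
    outdir = NULL
  )
}

merge_config <- function(config) {
  cfg <- default_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

#' Process one scan through the preprocessing and segmentation stages
#'
#' Stage order follows the acquisition pipeline: rotate, detect + flatten
#' the substratum (dropping the substratum layer itself), binarise at the
#' histogram-inflexion threshold, denoise (removal-only), trim.
#'
#' @param vol an [intensity_volume()].
#' @param cfg configuration list (see [default_config()]).
#' @param logfile optional log file path.
#' @return list with `binary` ([binary_volume()]) and `report`.
#' @export
process_scan <- function(vol, cfg = default_config(), logfile = NULL) {
  cfg <- merge_config(cfg)
  t0 <- proc.time()[3]
  stages <- character()
  if (isTRUE(cfg$rotate) && (cfg$angle_a != 0 || cfg$angle_b != 0)) {
    vol <- rotate_volume(vol, cfg$angle_a, cfg$angle_b)
    stages <- c(stages, sprintf("rotate(%g,%g)", cfg$angle_a, cfg$angle_b))
  }
  if (isTRUE(cfg$flatten)) {
    sub <- detect_substratum(vol)
    vol <- flatten(vol, sub)
    if (cfg$substratum_layers > 0)
      vol <- strip_bottom(vol, cfg$substratum_layers)
    stages <- c(stages, sprintf("flatten(strip=%d)", cfg$substratum_layers))
  }
  seg <- segment_volume(vol,
                        filter_radius = if (isTRUE(cfg$denoise)) cfg$filter_radius else 0,
                        trim_margin = if (isTRUE(cfg$trim)) cfg$trim_margin else -1,
                        smooth = cfg$smooth, offset = cfg$threshold_offset)
  stages <- c(stages, sprintf("segment(thr=%d)", seg$report$threshold))
  pipe_log(logfile, "scan processed [%s] in %.2fs", paste(stages, collapse = ", "),
           proc.time()[3] - t0)
  seg$report$stages <- stages
  seg
}

phantom_entries <- function(cfg, logfile) {
  ph <- cfg$phantom
  p <- do.call(growth_params,
               ph[intersect(names(ph), c("g", "C", "mu_b", "beta", "A_fp", "A"))])
  taus <- ph$tau_w
  seeds <- split_seed(cfg$seed, length(taus))
  noise <- noise_spec(ph$noise_mean %||% 30, ph$noise_sigma %||% 5)
  entries <- list()
  for (i in seq_along(taus)) {
    spec <- time_series_spec(
      p, taus[i], ph$times,
      shape = ph$shape %||% c(64, 64, 64),
      noise = noise, seed = seeds[i],
      tilt_deg = ph$tilt_deg %||% 0,
      voxel_lateral = cfg$voxel_lateral, voxel_axial = cfg$voxel_axial)
    pipe_log(logfile, "phantom series: tau_w=%.3g Pa, %d times, seed %d",
             taus[i], length(ph$times), seeds[i])
    entries <- c(entries, generate_time_series(spec))
  }
  entries
}

manifest_entries <- function(cfg, logfile) {
  man <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "time", "tau_w") %in% names(man)))
    stop("manifest needs columns path, time, tau_w")
  base <- dirname(normalizePath(cfg$manifest))
  lapply(seq_len(nrow(man)), function(i) {
    path <- man$path[i]
    if (!file.exists(path)) path <- file.path(base, man$path[i])
    if (!file.exists(path)) stop("manifest volume not found: ", man$path[i])
    pipe_log(logfile, "reading %s", path)
    list(time = man$time[i], tau_w = man$tau_w[i],
         volume = read_tiff_volume(path, cfg$voxel_lateral, cfg$voxel_axial),
         truth = NULL)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Generates or loads volumes, processes each scan, quantifies it, and fits
#' the growth power law when at least two shear conditions are available.
#' With `outdir` set, writes `summaries.csv`, `scan_<i>_report.json`,
#' `fit.json`, `config.json` (with the seed recorded) and `run.log`.
#'
#' @param config configuration list or path to a JSON config file; see
#'   [default_config()]. Must contain either `phantom` or `manifest`.
#' @return list with `summaries` (data frame), `fit` (power-law fit or NULL)
#'   and `reports` (per-scan segmentation reports).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(config)
  logfile <- NULL
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(cfg$outdir, "run.log")
    jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                         file.path(cfg$outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  t0 <- proc.time()[3]
  entries <- if (!is.null(cfg$phantom)) phantom_entries(cfg, logfile)
             else if (!is.null(cfg$manifest)) manifest_entries(cfg, logfile)
             else stop("config must provide either 'phantom' or 'manifest'")
  summaries <- NULL
  reports <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    seg <- process_scan(e$volume, cfg, logfile)
    s <- scan_summary(seg$binary, time = e$time, tau_w = e$tau_w)
    summaries <- rbind(summaries, s)
    reports[[i]] <- seg$report
    if (!is.null(cfg$outdir))
      jsonlite::write_json(seg$report,
                           file.path(cfg$outdir, sprintf("scan_%03d_report.json", i)),
                           auto_unbox = TRUE, digits = NA)
  }
  fit <- NULL
  if (length(unique(summaries$tau_w)) >= 2 && any(summaries$T_bar > 0)) {
    fit <- tryCatch(recover_from_pipeline(summaries), error = function(e) {
      pipe_log(logfile, "fit skipped: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(fit))
      pipe_log(logfile, "power-law fit: a=%.4g (sd %.2g), k=%.4g (sd %.2g)",
               fit$a, fit$a_sd, fit$k, fit$k_sd)
  }
  if (!is.null(cfg$outdir)) {
    utils::write.csv(summaries, file.path(cfg$outdir, "summaries.csv"),
                     row.names = FALSE)
    if (!is.null(fit))
      jsonlite::write_json(fit, file.path(cfg$outdir, "fit.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  pipe_log(logfile, "pipeline complete: %d scans in %.1fs",
           length(entries), proc.time()[3] - t0)
  list(summaries = summaries, fit = fit, reports = reports)
}
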