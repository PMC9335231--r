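#' Run the full analysis pipeline on a synthetic recording
#'
#' Orchestrates every stage end to end: simulation, physiological nuisance
#' regression, sliding-window spectrogram, 1/f fit and dual-band peak
#' detection on the sleep-stage spectrum, band-power traces, EEG event
#' detection and activity traces, BOLD-EEG correlations, wake-sleep
#' percent power change, and onset/offset lag maps. All stage outputs are
#' written as TSV/JSON under `out_dir` and listed with MD5 checksums in a
#' run manifest; reruns with the same config produce identical files.
#'
#' @param config a [sim_config()] (or path to its YAML).
#' @param out_dir output directory (created if needed).
#' @param regress_physio regress nuisance regressors out of BOLD first.
#' @return the manifest (invisibly), a list with stage outputs, paths and
#'   checksums; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, regress_physio = TRUE) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  stages <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    val
  }

  rec <- tick("simulate", simulate_recording(config))
  write_bold_tsv(rec$bold, file.path(out_dir, "bold.tsv"))
  write_hypnogram(rec$hypnogram, file.path(out_dir, "hypnogram.txt"))
  write_signal_tsv(rec$eeg, rec$eeg_fs, file.path(out_dir, "eeg.tsv"), "EEG1")
  write_signal_tsv(cbind(rec$physio$resp, rec$physio$cardiac),
                   rec$physio$fs, file.path(out_dir, "physio.tsv"),
                   c("resp", "cardiac"))
  write_events_tsv(rec$events_truth, file.path(out_dir, "events_truth.tsv"))
  write_sim_config(config, file.path(out_dir, "config.yaml"))

  bold <- rec$bold
  if (regress_physio) {
    reg <- tick("physio_regressors",
                build_regressors(rec$physio$resp, rec$physio$cardiac,
                                 rec$physio$fs, config$tr_s,
                                 nrow(bold$values)))
    .write_tsv(as.data.frame(reg$matrix),
               file.path(out_dir, "physio_regressors.tsv"))
    bold <- tick("regress_out", regress_out(bold, reg))
  }

  spec <- tick("spectrogram", sliding_spectrogram(bold))
  hyp <- rec$hypnogram

  peaks <- tick("peaks", {
    sleep_sp <- stage_average_spectrum(spec, hyp, "N2")
    if (!sleep_sp$available) stop(sleep_sp$reason)
    lapply(seq_len(config$n_regions), function(r) {
      fit <- fit_one_over_f(spec$freqs_hz, sleep_sp$spectrum[, r])
      detect_band_peaks(spec$freqs_hz, fit)
    })
  })
  peak_df <- data.frame(
    region = bold$region_labels,
    lf_peak_hz = vapply(peaks, function(p) p$LF$peak_freq_hz, numeric(1)),
    hf_peak_hz = vapply(peaks, function(p) p$HF$peak_freq_hz, numeric(1)))
  .write_tsv(peak_df, file.path(out_dir, "peaks.tsv"))

  lf_band <- c(stats::median(peak_df$lf_peak_hz, na.rm = TRUE) - 0.015,
               stats::median(peak_df$lf_peak_hz, na.rm = TRUE) + 0.015)
  hf_band <- c(stats::median(peak_df$hf_peak_hz, na.rm = TRUE) - 0.03,
               stats::median(peak_df$hf_peak_hz, na.rm = TRUE) + 0.03)
  lf_trace <- tick("powertrace", band_power_trace(spec, lf_band))
  hf_trace <- band_power_trace(spec, hf_band)

  pc <- tick("stagechange", list(
    lf = percent_power_change(lf_trace, hyp),
    hf = percent_power_change(hf_trace, hyp)))
  .write_tsv(data.frame(region = bold$region_labels,
                        lf_pct = pc$lf, hf_pct = pc$hf),
             file.path(out_dir, "percent_change.tsv"))

  events <- tick("detect_events", rbind(
    detect_spindles(rec$eeg, rec$eeg_fs),
    detect_slow_waves(rec$eeg, rec$eeg_fs)))
  write_events_tsv(events, file.path(out_dir, "events_detected.tsv"))

  act <- tick("activity_trace", {
    span <- c(0, nrow(bold$values) * config$tr_s)
    lapply(split(events, events$type), function(ev) {
      hamming_aggregate(bin_activity(ev, bin_s = config$tr_s, span = span))
    })
  })

  corr <- tick("correlate", {
    mean_trace <- function(tr) list(values = rowMeans(tr$values),
                                    window_centers_s = tr$window_centers_s)
    pairings <- list()
    for (band in c("lf", "hf")) for (ev in names(act)) {
      bt <- mean_trace(if (band == "lf") lf_trace else hf_trace)
      ce <- correlate_traces(bt, act[[ev]], hyp = hyp)
      pairings[[paste(band, ev, sep = "_x_")]] <-
        if (ce$available) ce$r else NA_real_
    }
    pairings
  })
  jsonlite::write_json(corr, file.path(out_dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA)

  lag <- tick("lagmap", {
    seg <- extract_transition(hyp, "falling_asleep",
                              duration_s = config$duration_s)
    build_lagmap(lf_trace, seg, hyp)
  })
  if (isTRUE(lag$available))
    .write_tsv(lag$lags, file.path(out_dir, "lagmap_lf_onset.tsv"))

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    tool = paste0("sleepbold ", as.character(utils::packageVersion("sleepbold"))),
    seed = config$seed,
    config_hash = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    stage_seconds = stages,
    elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 2),
    physio_regression = regress_physio,
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, peaks = peak_df, percent_change = pc,
                 correlations = corr, lagmap = lag))
}
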