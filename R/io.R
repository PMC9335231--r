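# TSV dialect used throughout: tab-separated, header row, '.' decimal,
# UTF-8, no quoting.
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}
.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Write / read regional BOLD as TSV
#'
#' Columns are regions (header row holds the labels), rows are volumes.
#' The TR is stored in a JSON sidecar `<path>.json` and can be overridden
#' on read.
#'
#' @param ts a [region_ts()].
#' @param path output TSV path.
#' @export
write_bold_tsv <- function(ts, path) {
  df <- as.data.frame(ts$values)
  names(df) <- ts$region_labels
  .write_tsv(df, path)
  jsonlite::write_json(list(tr_s = ts$tr_s, t0_s = ts$t0_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bold_tsv
#' @param tr_s repetition time; overrides the sidecar when given.
#' @return `read_bold_tsv`: a [region_ts()].
#' @export
read_bold_tsv <- function(path, tr_s = NULL) {
  df <- .read_tsv(path)
  side <- paste0(path, ".json")
  t0 <- 0
  if (is.null(tr_s)) {
    if (!file.exists(side))
      stop("no TR available: provide tr_s or a ", basename(side), " sidecar")
    meta <- jsonlite::read_json(side)
    tr_s <- meta$tr_s
    t0 <- meta$t0_s %||% 0
  } else if (file.exists(side)) {
    t0 <- jsonlite::read_json(side)$t0_s %||% 0
  }
  m <- as.matrix(df)
  if (any(!is.finite(m))) stop("non-finite values in BOLD TSV: ", path)
  region_ts(m, tr_s = tr_s, region_labels = names(df), t0_s = t0)
}

#' Read 4D NIfTI BOLD with an integer-label atlas
#'
#' Averages voxel time series within each atlas label to produce regional
#' series. Requires the RNifti package. Label 0 is background; labels
#' missing from `region_table` (when given) are an error.
#'
#' @param bold_path path to a 4D NIfTI file.
#' @param atlas_path path to a 3D integer-label NIfTI on the same grid.
#' @param region_table optional data.frame with columns id, name.
#' @param tr_s override for the TR (else read from the NIfTI header).
#' @return a [region_ts()].
#' @export
read_bold_nifti <- function(bold_path, atlas_path, region_table = NULL,
                            tr_s = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  img <- RNifti::readNifti(bold_path)
  atl <- RNifti::readNifti(atlas_path)
  d <- dim(img)
  if (length(d) != 4) stop("BOLD NIfTI must be 4D")
  if (!all(dim(atl) == d[1:3])) stop("atlas grid does not match BOLD grid")
  if (is.null(tr_s)) {
    tr_s <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_s) || tr_s <= 0)
      stop("TR missing from NIfTI header; pass tr_s explicitly")
  }
  labs <- sort(unique(as.integer(atl)))
  labs <- labs[labs != 0L]
  if (!is.null(region_table)) {
    missing <- setdiff(labs, region_table$id)
    if (length(missing))
      stop("atlas label(s) absent from region table: ",
           paste(missing, collapse = ", "))
  }
  vox <- matrix(img, prod(d[1:3]), d[4])
  av <- as.integer(atl)
  vals <- vapply(labs, function(l) colMeans(vox[av == l, , drop = FALSE]),
                 numeric(d[4]))
  nm <- if (!is.null(region_table))
    region_table$name[match(labs, region_table$id)] else paste0("region", labs)
  region_ts(vals, tr_s = tr_s, region_labels = nm)
}

#' Read a hypnogram from plain text
#'
#' One stage token per line (30-s epochs by default). Tokens are
#' case-insensitive; common aliases are normalised: Wake/W0 -> W,
#' S1/S2/S3 -> N1/N2/N3, S4 -> N3, REM -> R.
#'
#' @param path text file path.
#' @param epoch_s epoch length (seconds).
#' @return a `hypnogram`.
#' @export
read_hypnogram <- function(path, epoch_s = 30) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("empty hypnogram file: ", path)
  alias <- c(W = "W", WAKE = "W", W0 = "W",
             N1 = "N1", S1 = "N1", N2 = "N2", S2 = "N2",
             N3 = "N3", S3 = "N3", S4 = "N3",
             R = "R", REM = "R")
  up <- toupper(ln)
  bad <- which(!(up %in% names(alias)))
  if (length(bad))
    stop(sprintf("unknown stage token '%s' at line %d", ln[bad[1]], bad[1]))
  hypnogram(unname(alias[up]), epoch_s = epoch_s)
}

#' Write a hypnogram as plain text
#' @param hyp a `hypnogram`.
#' @param path output path.
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(hyp$stages, path)
  invisible(path)
}

#' Write / read an event list as TSV
#' @param events event data.frame (onset_s, duration_s, type, channel,
#'   amplitude).
#' @param path TSV path.
#' @export
write_events_tsv <- function(events, path) {
  .write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- .read_tsv(path)
  need <- c("onset_s", "duration_s", "type")
  if (!all(need %in% names(ev)))
    stop("event TSV must have columns ", paste(need, collapse = ", "))
  ev[order(ev$onset_s), , drop = FALSE]
}

#' Write a channel time-series TSV with a time column
#' @param x numeric vector or matrix (samples x channels).
#' @param fs sampling rate (Hz).
#' @param path TSV path.
#' @param labels channel labels.
#' @export
write_signal_tsv <- function(x, fs, path, labels = NULL) {
  x <- as.matrix(x)
  labels <- labels %||% paste0("ch", seq_len(ncol(x)))
  df <- data.frame(time_s = (seq_len(nrow(x)) - 1) / fs, x)
  names(df) <- c("time_s", labels)
  .write_tsv(df, path)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @return `read_signal_tsv`: list with `values` (matrix), `fs`, `labels`.
#' @export
read_signal_tsv <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "time_s") stop("first column must be time_s: ", path)
  dt <- diff(df$time_s[1:2])
  list(values = as.matrix(df[, -1, drop = FALSE]), fs = 1 / dt,
       labels = names(df)[-1])
}

#' Load a simulation configuration from YAML
#'
#' Top-level keys mirror [sim_config()] arguments; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$stage_gain))
    y$stage_gain <- lapply(y$stage_gain, unlist)
  do.call(sim_config, y)
}

#' Write a simulation configuration as YAML
#' @param config a `sim_config`.
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12L)
  invisible(path)
}
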