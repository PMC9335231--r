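#' Correlate two windowed time courses
#'
#' Pearson (or Spearman) correlation between two traces that share the
#' sliding-window grid, either across sleep stages (all clean windows) or
#' within one stage. Misaligned window centers are an error, never a
#' silent truncation. Because consecutive 104-s windows overlap almost
#' completely, the per-entry p-value is also reported with a Bartlett
#' effective-sample-size correction (a diagnostic; group inference should
#' use [group_distribution()] over independent entries).
#'
#' @param a,b numeric vectors (one value per window) or lists with
#'   `values` and `window_centers_s`.
#' @param centers window centers (seconds); required when `a`/`b` are bare
#'   vectors.
#' @param scope "across_stage" or "within_stage".
#' @param hyp a `hypnogram`; needed to select windows by stage.
#' @param stage stage label for `scope = "within_stage"`.
#' @param window_len_volumes,tr_s windowing metadata used for stage
#'   labelling (defaults match the BOLD contract).
#' @param min_windows minimum windows for a usable entry.
#' @param method "pearson" or "spearman".
#' @return list with `available`; when available: `r`, `n_windows`,
#'   `fisher_z`, `p_naive`, `p_eff` (Bartlett-corrected), `scope`; else
#'   `reason`.
#' @export
correlate_traces <- function(a, b, centers = NULL, scope = "across_stage",
                             hyp = NULL, stage = NULL,
                             window_len_volumes = 50L, tr_s = 2.08,
                             min_windows = 30L, method = "pearson") {
  ga <- .trace_values(a, centers)
  gb <- .trace_values(b, centers)
  if (length(ga$values) != length(gb$values) ||
      max(abs(ga$centers - gb$centers)) > 1e-6)
    stop("window centers of the two traces are not aligned")
  sel <- seq_along(ga$values)
  if (!is.null(hyp)) {
    meta <- list(window_centers_s = ga$centers,
                 window_len_volumes = window_len_volumes, tr_s = tr_s)
    ws <- window_stages(meta, hyp)
    sel <- if (scope == "within_stage") {
      if (is.null(stage)) stop("within_stage scope needs a stage")
      which(ws == stage)
    } else which(ws != "transition")
  }
  if (length(sel) < min_windows)
    return(list(available = FALSE,
                reason = sprintf("only %d usable windows (need >= %d)",
                                 length(sel), min_windows)))
  x <- ga$values[sel]; y <- gb$values[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(available = FALSE, reason = "zero-variance trace"))
  r <- stats::cor(x, y, method = method)
  n <- length(sel)
  # Bartlett correction: n_eff = n (1 - r1a r1b) / (1 + r1a r1b)
  r1 <- function(v) {
    v <- v - mean(v)
    sum(v[-1] * v[-length(v)]) / sum(v^2)
  }
  phi <- max(min(r1(x) * r1(y), 0.999), -0.999)
  n_eff <- max(n * (1 - phi) / (1 + phi), 3)
  tt <- function(nn) {
    tv <- r * sqrt((nn - 2) / max(1 - r^2, 1e-12))
    2 * stats::pt(-abs(tv), nn - 2)
  }
  list(available = TRUE, r = r, n_windows = n, fisher_z = atanh(min(max(r, -1 + 1e-12), 1 - 1e-12)),
       p_naive = tt(n), p_eff = tt(n_eff), n_eff = n_eff, scope = scope)
}

.trace_values <- function(x, centers) {
  if (is.list(x)) list(values = as.numeric(x$values),
                       centers = x$window_centers_s)
  else {
    if (is.null(centers)) stop("bare trace vectors need explicit centers")
    list(values = as.numeric(x), centers = centers)
  }
}

#' Group-level summary of correlation coefficients
#'
#' Fisher z-transforms the per-(region, run) coefficients and tests the
#' mean z against zero with a two-sided one-sample t-test, mirroring the
#' histogram-across-entries approach for group inference. An optional
#' paired contrast (e.g. r with spindle activity minus r with slow-wave
#' activity per entry) is tested with a paired t-test.
#'
#' @param r numeric vector of correlation coefficients (one per entry).
#' @param r_contrast optional second vector, matched entry-by-entry.
#' @return list with `mean_r`, `mean_z`, `ci_r` (95% on the mean, back-
#'   transformed), `t`, `df`, `p`; for contrasts additionally
#'   `contrast` (paired test on z differences).
#' @export
group_distribution <- function(r, r_contrast = NULL) {
  stopifnot(length(r) >= 2)
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  if (stats::sd(z) < 1e-14) {
    # degenerate (constant) distribution: report the limit of the t-test
    out <- list(mean_r = mean(r), mean_z = mean(z),
                ci_r = rep(tanh(mean(z)), 2),
                t = if (mean(z) == 0) 0 else Inf * sign(mean(z)),
                df = length(r) - 1,
                p = if (mean(z) == 0) 1 else 0, n = length(r))
  } else {
    tt <- stats::t.test(z)
    out <- list(mean_r = mean(r), mean_z = mean(z),
                ci_r = tanh(as.numeric(tt$conf.int)),
                t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, n = length(r))
  }
  if (!is.null(r_contrast)) {
    stopifnot(length(r_contrast) == length(r))
    zc <- atanh(pmin(pmax(r_contrast, -1 + 1e-12), 1 - 1e-12))
    if (stats::sd(z - zc) < 1e-14) {
      d <- mean(z - zc)
      out$contrast <- list(mean_dz = d, t = if (d == 0) 0 else Inf * sign(d),
                           df = length(r) - 1, p = if (d == 0) 1 else 0)
    } else {
      pt <- stats::t.test(z, zc, paired = TRUE)
      out$contrast <- list(mean_dz = mean(z - zc), t = unname(pt$statistic),
                           df = unname(pt$parameter), p = pt$p.value)
    }
  }
  out
}

#' Broadband BOLD amplitude time course (control pairing)
#'
#' Per sliding window, the standard deviation of the demeaned,
#' Hamming-tapered signal, normalised by the taper's RMS so white noise of
#' SD sigma yields a trace at level sigma. The control quantity used to
#' show that event activity tracks the BOLD frequency content rather than
#' its overall amplitude.
#'
#' @param ts a [region_ts()].
#' @param window_volumes,step_volumes windowing (BOLD contract).
#' @return object of class `power_trace` (values are amplitudes, not
#'   powers; `band_hz` is the full analysis band).
#' @export
amplitude_trace <- function(ts, window_volumes = 50L, step_volumes = 1L) {
  n <- nrow(ts$values)
  N <- as.integer(window_volumes)
  starts <- .window_starts(n, N, step_volumes)
  w <- .hamming(N)
  wrms <- sqrt(mean(w^2))
  vals <- matrix(0, length(starts), ncol(ts$values))
  for (r in seq_len(ncol(ts$values))) {
    xr <- ts$values[, r]
    vals[, r] <- vapply(starts, function(s) {
      seg <- xr[(s + 1):(s + N)]
      stats::sd((seg - mean(seg)) * w) / wrms
    }, numeric(1))
  }
  structure(list(values = vals, band_hz = c(0, 1 / (2 * ts$tr_s)),
                 window_centers_s = ts$t0_s + (starts + (N - 1) / 2) * ts$tr_s,
                 window_len_volumes = N, step_volumes = as.integer(step_volumes),
                 tr_s = ts$tr_s, region_labels = ts$region_labels),
            class = "power_trace")
}
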