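#' Extract a wake-sleep transition segment from a hypnogram
#'
#' The falling-asleep segment runs from the end of the last sustained wake
#' run before the first sustained NREM run to the first sustained N2/N3
#' epoch, padded by a margin on both sides; the waking segment is defined
#' symmetrically (last sustained N2/N3 before the first sustained wake run
#' that follows sleep, to that wake run's first epoch).
#'
#' @param hyp a `hypnogram`.
#' @param kind "falling_asleep" or "waking".
#' @param margin_s padding added on both sides (seconds).
#' @param sustain_epochs minimum run length (epochs) for "sustained".
#' @param duration_s recording length used to clamp the segment.
#' @return list with `available`; when available: `kind`, `t_start_s`,
#'   `t_end_s`; else `reason`.
#' @export
extract_transition <- function(hyp, kind = c("falling_asleep", "waking"),
                               margin_s = 120, sustain_epochs = 2L,
                               duration_s = length(hyp$stages) * hyp$epoch_s) {
  kind <- match.arg(kind)
  st <- hyp$stages
  ep <- hyp$epoch_s
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sust <- r$lengths >= sustain_epochs
  is_nrem <- r$values %in% c("N1", "N2", "N3")
  is_deep <- r$values %in% c("N2", "N3")
  is_w <- r$values == "W"

  absent <- function(reason) list(available = FALSE, kind = kind,
                                  reason = reason)
  if (kind == "falling_asleep") {
    i <- which(sust & is_nrem)[1]
    if (is.na(i)) return(absent("no sustained NREM run"))
    jw <- which(sust & is_w & seq_along(r$values) < i)
    if (!length(jw)) return(absent("no sustained wake before sleep onset"))
    k <- which(sust & is_deep & seq_along(r$values) >= i)[1]
    if (is.na(k)) return(absent("no sustained N2/N3 after sleep onset"))
    t0 <- (ends[jw[length(jw)]] - 1) * ep - margin_s
    t1 <- starts[k] * ep + margin_s
  } else {
    iw <- which(sust & is_w)
    slept <- which(sust & is_deep)
    if (!length(slept)) return(absent("no sustained N2/N3 sleep"))
    iw <- iw[iw > slept[1]]
    if (!length(iw)) return(absent("no sustained wake after sleep"))
    i <- iw[1]
    k <- slept[slept < i]
    k <- k[length(k)]
    t0 <- (ends[k] - 1) * ep - margin_s
    t1 <- starts[i] * ep + margin_s
  }
  list(available = TRUE, kind = kind,
       t_start_s = max(t0, 0), t_end_s = min(t1, duration_s))
}

#' Time-lagged cross-correlation between two windowed traces
#'
#' Normalised cross-correlation over integer window shifts in
#' [-max_lag, +max_lag], refined by parabolic interpolation through the
#' peak and its two neighbours. A positive lag means `a` leads `b`
#' (`b` looks like a delayed copy of `a`). A peak at the search boundary
#' is flagged unreliable.
#'
#' @param a,b numeric traces on the same window grid.
#' @param step_s time between consecutive windows (seconds).
#' @param max_lag_s largest lag searched (seconds).
#' @return list with `lag_s`, `r_peak`, `reliable`.
#' @export
pairwise_lag <- function(a, b, step_s = 2.08, max_lag_s = 60) {
  n <- length(a)
  stopifnot(length(b) == n)
  L <- min(floor(max_lag_s / step_s), n - 3)
  if (L < 1) stop("segment too short for the requested max lag")
  a <- a - mean(a); b <- b - mean(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) stop("zero-variance trace in lag estimation")
  shifts <- (-L):L
  # biased normalisation (divide by n, not the overlap length): shrinks
  # large-shift values and so suppresses spurious boundary peaks that the
  # per-overlap correlation produces on step-like onset traces
  cc <- vapply(shifts, function(s) {
    if (s >= 0) x <- sum(a[1:(n - s)] * b[(1 + s):n])
    else        x <- sum(a[(1 - s):n] * b[1:(n + s)])
    x / ((n - 1) * sa * sb)
  }, numeric(1))
  pk <- which.max(cc)
  reliable <- !(pk == 1L || pk == length(cc) || is.na(cc[pk]))
  lag <- shifts[pk] * step_s
  if (reliable && pk > 1 && pk < length(cc)) {
    y1 <- cc[pk - 1]; y2 <- cc[pk]; y3 <- cc[pk + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > 1e-12)
      lag <- lag + 0.5 * (y1 - y3) / den * step_s
  }
  list(lag_s = lag, r_peak = cc[pk], reliable = reliable)
}

#' Per-region lead/lag map for oscillation onset or offset
#'
#' Restricts the band-power traces to a transition segment, subtracts a
#' baseline (mean wake-window power per region, so the rising or falling
#' edge dominates), computes the full pairwise lag matrix, and summarises
#' each region as the mean of its row over reliable pairs (lag
#' projection). Lags are zero-centred across regions; positive values
#' mean the region leads (earlier onset/offset).
#'
#' @param trace a `power_trace` (all regions).
#' @param segment result of [extract_transition()].
#' @param hyp a `hypnogram` (for the wake baseline); NULL skips baseline
#'   subtraction.
#' @param max_lag_s lag search bound (seconds).
#' @param min_regions minimum regions with reliable pairs.
#' @return list with `available`; when available: data.frame `lags`
#'   (region, lag_s, n_reliable_pairs), `pair_lags` matrix, `kind`; else
#'   `reason`.
#' @export
build_lagmap <- function(trace, segment, hyp = NULL, max_lag_s = 60,
                         min_regions = 3L) {
  if (!isTRUE(segment$available))
    return(list(available = FALSE, reason = segment$reason))
  step_s <- trace$step_volumes * trace$tr_s
  sel <- which(trace$window_centers_s >= segment$t_start_s &
               trace$window_centers_s <= segment$t_end_s)
  if (length(sel) < 3 * floor(max_lag_s / step_s))
    return(list(available = FALSE,
                reason = "transition segment shorter than 3x the lag range"))
  v <- trace$values[sel, , drop = FALSE]
  if (!is.null(hyp)) {
    ws <- window_stages(trace, hyp)
    wk <- which(ws == "W")
    if (length(wk) >= 5)
      v <- sweep(v, 2, colMeans(trace$values[wk, , drop = FALSE]))
  }
  nr <- ncol(v)
  lm <- matrix(NA_real_, nr, nr)
  ok <- matrix(FALSE, nr, nr)
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    pl <- pairwise_lag(v[, i], v[, j], step_s, max_lag_s)
    lm[i, j] <- pl$lag_s
    lm[j, i] <- -pl$lag_s
    ok[i, j] <- ok[j, i] <- pl$reliable
  }
  n_rel <- rowSums(ok)
  usable <- n_rel >= 1
  if (sum(usable) < min_regions)
    return(list(available = FALSE,
                reason = "fewer than min_regions regions with reliable pairs"))
  lag_r <- vapply(seq_len(nr), function(i) {
    if (!usable[i]) return(NA_real_)
    mean(lm[i, ok[i, ]])
  }, numeric(1))
  lag_r <- lag_r - mean(lag_r, na.rm = TRUE)   # zero-centred
  labels <- trace$region_labels %||% paste0("R", seq_len(nr))
  list(available = TRUE, kind = segment$kind,
       lags = data.frame(region = labels, lag_s = lag_r,
                         n_reliable_pairs = n_rel),
       pair_lags = lm)
}
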