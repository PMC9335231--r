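# Small, fast configurations shared across tests. 20 min is the shortest
# duration that fits the full stage trajectory.
quick_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, duration_s = 1200, n_regions = 3L, ...)
}

# Hypnogram with long clean wake and N2 blocks, for stage-contrast tests.
two_block_hyp <- function(n_wake = 40L, n_sleep = 40L) {
  hypnogram(c(rep("W", n_wake), rep("N2", n_sleep)))
}

# Hand-built power_trace on the standard windowing grid.
make_trace <- function(values, tr_s = 2.08, window_volumes = 50L, t0 = 0) {
  values <- as.matrix(values)
  starts <- seq_len(nrow(values)) - 1L
  structure(list(
    values = values, band_hz = c(0.04, 0.07),
    window_centers_s = t0 + (starts + (window_volumes - 1) / 2) * tr_s,
    window_len_volumes = window_volumes, step_volumes = 1L, tr_s = tr_s,
    region_labels = paste0("R", seq_len(ncol(values)))),
    class = "power_trace")
}
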