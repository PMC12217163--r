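# Shared fixtures, built once per test run. All fixtures are generated in
# code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# Small noiseless static experiment: no motion, no bleaching, no noise.
clean_sim <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- simulation_config(n_frames = 60, n_cells = 2,
                             n_vesicles_per_cell = 3,
                             n_reference_per_cell = 1,
                             height = 128, width = 64,
                             bleach_rate_per_s = c(0, 0, 0),
                             motion_sd_px_per_frame = 0,
                             onset_margin_frames = 20,
                             noise = FALSE, rng_seed = 101)
    .fixtures$clean <- simulate_release_experiment(cfg)
  }
  .fixtures$clean
}

# Small realistic experiment: motion, bleaching and camera noise on.
noisy_sim <- function() {
  if (is.null(.fixtures$noisy)) {
    cfg <- simulation_config(n_frames = 60, n_cells = 2,
                             n_vesicles_per_cell = 3,
                             n_reference_per_cell = 4,
                             height = 128, width = 64,
                             onset_margin_frames = 20, rng_seed = 202)
    .fixtures$noisy <- simulate_release_experiment(cfg)
  }
  .fixtures$noisy
}

noisy_analysis <- function() {
  if (is.null(.fixtures$noisy_res))
    .fixtures$noisy_res <- suppressWarnings(  # tiny cohort: CI warnings
      analyze_release_experiment(noisy_sim()))
  .fixtures$noisy_res
}

# Minimal TraceSeries for classifier unit tests: a normalized RNA trace
# (and optional damage trace) on a regular time grid.
fake_trace <- function(rna_normalized, t0_frame, frame_interval_s = 2.2,
                       corrected = rna_normalized * 100,
                       bg_noise_sd = 1, damage = NULL) {
  n <- length(rna_normalized)
  frames <- seq_len(n)
  channels <- if (is.null(damage)) c(rna = 1) else c(rna = 1, damage = 2)
  nm <- cbind(rna = rna_normalized)
  co <- cbind(rna = corrected)
  if (!is.null(damage)) {
    nm <- cbind(nm, damage = damage)
    co <- cbind(co, damage = damage * 100)
  }
  structure(list(frames = frames,
                 times_s = (frames - t0_frame) * frame_interval_s,
                 t0_frame = t0_frame, frame_interval_s = frame_interval_s,
                 channels = channels,
                 positions = data.frame(frame = frames, x = 1, y = 1, z = 1),
                 raw_mean = co, local_background = co * 0,
                 corrected = co, bleach_corrected = co, normalized = nm,
                 bg_noise_sd = stats::setNames(rep(bg_noise_sd,
                                                   length(channels)),
                                               names(channels))),
            class = "TraceSeries")
}

# Single Gaussian spot image on a flat background.
gaussian_image <- function(h, w, y0, x0, sigma, amplitude, background = 0) {
  img <- matrix(background, h, w)
  for (x in seq_len(w))
    img[, x] <- img[, x] + amplitude *
      exp(-((seq_len(h) - y0)^2 + (x - x0)^2) / (2 * sigma^2))
  img
}
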