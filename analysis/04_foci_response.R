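#!/usr/bin/env Rscript
# Galectin foci counting and response normalization, LNP uptake intensity,
# and object-based colocalization.
#
# Counts galectin foci per cell over the simulated acquisition (foci appear
# at each vesicle's damage onset), baseline-subtracts, normalizes a
# "treated" response to the control maximum, and demonstrates both
# colocalization measures (5-px resized discs; >25% area overlap).

library(lnptrace)
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(n_frames = 80, n_cells = 4,
                         n_vesicles_per_cell = 6,
                         n_reference_per_cell = 0,
                         onset_margin_frames = 10, rng_seed = 5L)
sim <- simulate_release_experiment(cfg)
n_cells <- attr(read_labels(sim$cells), "n")

frames <- seq_len(dim(sim$stack)[2])
foci <- do.call(rbind, lapply(frames, function(t) {
  img <- enhance_foci(sim$stack$data[2, t, 1, , ], 9)
  detect_foci(img, intensity_threshold = 60, size_range = c(2, 100),
              cells = sim$cells, frame = t, channel = 2L)
}))
pc <- foci_per_cell(foci, n_cells, frames = frames)
pc$time_s <- (pc$frame - 1) * sim$stack$frame_interval_s
write.csv(pc, "results/galectin_foci_per_cell.csv", row.names = FALSE)

# uptake: total LNP (RNA-channel) foci intensity per cell
rna_foci <- do.call(rbind, lapply(frames, function(t) {
  img <- enhance_foci(sim$stack$data[1, t, 1, , ], 9)
  detect_foci(img, intensity_threshold = 60, size_range = c(2, 100),
              frame = t, channel = 1L)
}))
up <- uptake_intensity(rna_foci, n_cells)
write.csv(up, "results/uptake_intensity.csv", row.names = FALSE)

# response normalization: treat this run as the control of itself and a
# scaled series as a knockdown condition
ctrl <- pc$baseline_subtracted
norm <- normalize_response(list(control = ctrl, knockdown = 0.4 * ctrl),
                           ctrl)
write.csv(data.frame(frame = pc$frame, control = norm$control,
                     knockdown = norm$knockdown),
          "results/normalized_response.csv", row.names = FALSE)

cat(sprintf("Counted galectin foci over %d frames (%d cells):\n",
            length(frames), n_cells))
cat(sprintf("  baseline-subtracted count rises from %.2f to %.2f per cell\n",
            pc$baseline_subtracted[1],
            pc$baseline_subtracted[length(frames)]))
cat(sprintf("  %d/%d programmed damage events detected in the final frame\n",
            pc$n_foci[length(frames)],
            sum(!sim$truth$vesicles$is_reference)))

# colocalization on a two-channel scene with known geometry
sc <- simulate_endosome_scene(n_endosomes = 16, angle_offset_deg = 0,
                              rng_seed = 6L)
fA <- detect_foci(enhance_foci(sc$stack$data[2, 1, 1, , ], 9), 100,
                  size_range = c(2, 300))
fB <- detect_foci(enhance_foci(sc$stack$data[3, 1, 1, , ], 9), 100,
                  size_range = c(2, 300))
rc <- colocalize_resized(fA, fB, dims = dim(sc$masks))
labA <- segment_structures(sc$stack$data[2, 1, 1, , ])
labB <- segment_structures(sc$stack$data[3, 1, 1, , ])
ov <- colocalize_overlap(labA, labB)
write.csv(data.frame(measure = c("resized_disc_5px", "overlap_gt25pct"),
                     fraction = c(rc$fraction, ov$fraction),
                     n = c(nrow(fA), ov$n_A)),
          "results/colocalization.csv", row.names = FALSE)
cat(sprintf(
  "Colocalization at coincident angles: %.2f (discs), %.2f (>25%% overlap).\n",
  rc$fraction, ov$fraction))
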