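#!/usr/bin/env Rscript
# Bead-based channel registration and chromatic-aberration correction.
#
# Fits the alignment model (integer shift + linear chromatic line per
# channel) on a simulated TetraSpeck-style bead field with a programmed
# misalignment, applies it, and reports the residual bead distances.

library(lnptrace)
dir.create("results", showWarnings = FALSE)

truth_shift <- c(4, -3, 1)
bf <- simulate_bead_field(
  n_beads = 16, shifts = list(truth_shift),
  chromatic_slope = list(c(0.008, -0.004)),
  chromatic_intercept = list(c(0.4, 0.2)),
  n_z = 31, z_range = c(12, 20), rng_seed = 2L)

model <- fit_alignment_model(bf$stack)
write_alignment_model(model, "results/alignment_model.yaml")

pre <- bead_residual_distance(bf$stack)
post <- bead_residual_distance(apply_alignment(bf$stack, model))

mc <- model$channels[[2]]
summary <- data.frame(
  channel = 2,
  dx = mc$shift[["dx"]], dy = mc$shift[["dy"]], dz = mc$shift[["dz"]],
  true_dx = truth_shift[1], true_dy = truth_shift[2],
  true_dz = truth_shift[3],
  chromatic_slope_x = mc$chromatic$x$slope,
  chromatic_slope_y = mc$chromatic$y$slope,
  residual_px_before = pre, residual_px_after = post)
write.csv(summary, "results/registration_summary.csv", row.names = FALSE)

cat(sprintf("Fitted shift (%d, %d, %d) for programmed (%d, %d, %d) plus a\n",
            mc$shift[["dx"]], mc$shift[["dy"]], mc$shift[["dz"]],
            truth_shift[1], truth_shift[2], truth_shift[3]))
cat(sprintf("chromatic line (slope_x %.4f, slope_y %.4f); the integer part\n",
            mc$chromatic$x$slope, mc$chromatic$y$slope))
cat("absorbs whole pixels of the position-dependent offset, so the composite\n")
cat("model is what matters:\n")
cat(sprintf("  mean bead residual %.2f px before, %.2f px after alignment\n",
            pre, post))
cat("  (sub-pixel remainder reflects the 1-px accuracy of the correction).\n")
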