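#!/usr/bin/env Rscript
# Sub-endosomal localization of membrane damage relative to the LNP, spot
# sizing, and the random-localization null.
#
# Measures angular and magnitude differences between damage-marker and LNP
# vectors on simulated endosomes with a programmed 20-degree offset
# (single and dual-maxima geometries), sizes simulated LNP spots by 2D
# Gaussian FWHM, and contrasts the measurements with the Monte-Carlo null.

library(lnptrace)
dir.create("results", showWarnings = FALSE)

sc1 <- simulate_endosome_scene(n_endosomes = 60, angle_offset_deg = 20,
                               noise = TRUE, rng_seed = 7L)
g1 <- analyze_endosome_scene(sc1$stack, sc1$masks)
g1$geometry <- "single"
sc2 <- simulate_endosome_scene(n_endosomes = 40, angle_offset_deg = 20,
                               antipodal = TRUE, noise = TRUE, rng_seed = 8L)
g2 <- analyze_endosome_scene(sc2$stack, sc2$masks)
g2$geometry <- "dual"
pairs <- rbind(g1, g2)
write.csv(pairs, "results/geometry_pairs.csv", row.names = FALSE)

null1 <- angular_null(1e5, "single", rng_seed = 9L)
null2 <- angular_null(1e5, "dual_antipodal", rng_seed = 10L)
write.csv(data.frame(mode = c("single", "dual_antipodal"),
                     mean_deg = c(null1$mean, null2$mean),
                     n_pairs = c(null1$n_pairs, null2$n_pairs)),
          "results/angular_null.csv", row.names = FALSE)

cat("Sub-endosomal geometry on scenes with a programmed 20-degree offset:\n")
cat(sprintf("  single geometry: median angular difference %.1f deg (n = %d)\n",
            median(g1$angular_difference_deg), nrow(g1)))
cat(sprintf("  dual geometry:   median angular difference %.1f deg (n = %d)\n",
            median(g2$angular_difference_deg), nrow(g2)))
cat(sprintf("  random null means: %.2f deg (single), %.2f deg (dual)\n",
            null1$mean, null2$mean))
cat("  measured offsets sit far below the null, as for a localized damage\n")
cat("  site adjacent to the LNP.\n")

# FWHM spot sizing of isolated LNPs (Poisson noise, 9 nm pixels)
set.seed(11)
fits <- lapply(1:40, function(i) {
  sigma_nm <- runif(1, 45, 90)
  amp <- runif(1, 300, 800)
  clean <- matrix(10, 61, 61)
  clean <- lnptrace:::add_spot(clean, 31 + runif(1, -2, 2),
                               31 + runif(1, -2, 2), sigma_nm / 9, amp)
  roi <- matrix(rpois(length(clean), clean), 61, 61)
  f <- fit_gaussian2d(roi, pixel_size_nm = 9)
  data.frame(true_fwhm_nm = 2 * sqrt(2 * log(2)) * sigma_nm,
             fwhm_nm = f$fwhm_nm, converged = f$converged)
})
fwhm <- do.call(rbind, fits)
write.csv(fwhm, "results/spot_fwhm.csv", row.names = FALSE)
ok <- fwhm[fwhm$converged, ]
cat(sprintf(
  "FWHM sizing: %d/%d fits converged, median |error| %.1f nm (%.1f%%).\n",
  nrow(ok), nrow(fwhm), median(abs(ok$fwhm_nm - ok$true_fwhm_nm)),
  100 * median(abs(ok$fwhm_nm - ok$true_fwhm_nm) / ok$true_fwhm_nm)))
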