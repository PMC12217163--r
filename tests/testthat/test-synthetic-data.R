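# The generator is first-class code: its contracts (determinism, truth
# consistency, rendered amplitudes) are what make every downstream test
# meaningful.

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(hit_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(pixel_size_nm = -1), "> 0")
  expect_error(simulation_config(bleach_rate_per_s = -0.1), "non-negative")
  expect_error(simulation_config(n_channels = 5), "2 or 3")
  # spot amplitude at the noise floor makes classifier tests meaningless
  expect_error(simulation_config(rna_amplitude_mean = 5,
                                 background_level = 400, noise = TRUE),
               "noise floor")
  expect_silent(simulation_config(rna_amplitude_mean = 5,
                                  background_level = 400, noise = FALSE))
})

test_that("identical config and seed give byte-identical stacks and truth", {
  cfg <- simulation_config(n_frames = 10, n_cells = 1,
                           n_vesicles_per_cell = 2, n_reference_per_cell = 0,
                           height = 64, width = 64, onset_margin_frames = 3,
                           rng_seed = 42)
  a <- simulate_release_experiment(cfg)
  b <- simulate_release_experiment(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  fa <- tempfile(fileext = ".tif"); fb <- tempfile(fileext = ".tif")
  write_stack(a$stack, fa); write_stack(b$stack, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("with no dynamics configured every mask-mean trace is constant", {
  cfg <- simulation_config(n_frames = 20, n_cells = 1,
                           n_vesicles_per_cell = 3, n_reference_per_cell = 0,
                           height = 64, width = 64,
                           bleach_rate_per_s = 0, motion_sd_px_per_frame = 0,
                           fast_release_fraction = 0, hit_fraction = 1,
                           onset_margin_frames = 5,
                           noise = FALSE, rng_seed = 7)
  sim <- simulate_release_experiment(cfg)
  off <- lnptrace:::disc_offsets(6)
  for (v in sim$truth$vesicles$vesicle_id) {
    tr <- sim$seeds[sim$seeds$vesicle_id == v, ]
    means <- vapply(tr$frame, function(t) {
      img <- sim$stack$data[1, t, 1, , ]
      mean(lnptrace:::pixels_at(img, tr$y[tr$frame == t],
                                tr$x[tr$frame == t], off))
    }, numeric(1))
    expect_lt(diff(range(means)), 1e-9)
  }
})

test_that("fast release renders a post-onset amplitude of (1 - fraction) x pre", {
  cfg <- simulation_config(n_frames = 30, n_cells = 1,
                           n_vesicles_per_cell = 4, n_reference_per_cell = 0,
                           height = 96, width = 96,
                           bleach_rate_per_s = 0, motion_sd_px_per_frame = 0,
                           hit_fraction = 1, fast_release_fraction = 1,
                           release_magnitude_fraction = 0.5,
                           onset_margin_frames = 8,
                           noise = FALSE, rng_seed = 11)
  sim <- simulate_release_experiment(cfg)
  off <- lnptrace:::disc_offsets(6)
  for (i in seq_len(nrow(sim$truth$vesicles))) {
    v <- sim$truth$vesicles[i, ]
    tr <- sim$seeds[sim$seeds$vesicle_id == v$vesicle_id, ]
    readout <- function(t) {
      img <- sim$stack$data[1, t, 1, , ]
      mean(lnptrace:::pixels_at(img, tr$y[1], tr$x[1], off)) -
        cfg$background_level
    }
    pre <- readout(v$t0_frame - 2)
    post <- readout(v$t0_frame + 2)
    expect_equal(post / pre, 0.5, tolerance = 1e-9)
  }
})

test_that("noiseless mask-mean readout matches the truth amplitude within 1%", {
  sim <- clean_sim()
  off <- lnptrace:::disc_offsets(6)
  ves <- sim$truth$vesicles
  for (i in which(ves$hit)) {
    v <- ves[i, ]
    tr <- sim$seeds[sim$seeds$vesicle_id == v$vesicle_id, ]
    t <- if (is.na(v$t0_frame)) 1 else v$t0_frame - 5
    img <- sim$stack$data[1, t, 1, , ]
    m <- mean(lnptrace:::pixels_at(img, tr$y[1], tr$x[1], off)) -
      sim$config$background_level
    expect_equal(m, v$mask_mean_amplitude, tolerance = 0.01)
  }
})

test_that("every rendered object has exactly one truth record per frame", {
  sim <- clean_sim()
  pos <- sim$truth$positions
  nv <- nrow(sim$truth$vesicles)
  expect_equal(nrow(pos), nv * dim(sim$stack)[2])
  expect_false(any(duplicated(pos[, c("vesicle_id", "frame")])))
  # rendered RNA objects in frame 1 equal the number of RNA-carrying vesicles
  img <- sim$stack$data[1, 1, 1, , ] - sim$config$background_level
  lab <- label_components(img > 50)
  expect_equal(max(lab), sum(sim$truth$vesicles$hit))
  # onsets lie strictly inside the acquisition
  t0 <- sim$truth$vesicles$t0_frame
  expect_true(all(is.na(t0) | (t0 > 1 & t0 < dim(sim$stack)[2])))
})

test_that("bead fields render programmed shifts and chromatic offsets", {
  # zero shift, zero aberration: channels identical
  bf0 <- simulate_bead_field(n_beads = 9, shifts = list(c(0, 0, 0)),
                             width = 96, height = 96, n_z = 7, rng_seed = 1)
  expect_identical(bf0$stack$data[1, 1, , , ], bf0$stack$data[2, 1, , , ])
  # programmed lateral shift appears in the truth and in exhaustive
  # cross-correlation of the rendered planes
  bf <- simulate_bead_field(n_beads = 9, shifts = list(c(3, -2, 0)),
                            width = 96, height = 96, n_z = 7, rng_seed = 1)
  expect_equal(unname(unlist(bf$truth$channels[2, c("dx", "dy", "dz")])),
               c(3, -2, 0))
  z <- 4
  a <- bf$stack$data[1, 1, z, , ]; b <- bf$stack$data[2, 1, z, , ]
  best <- c(NA, NA); bestv <- -Inf
  for (dx in -5:5) for (dy in -5:5) {
    ys <- 10:86; xs <- 10:86
    v <- sum(a[ys, xs] * b[ys + dy, xs + dx])
    if (v > bestv) { bestv <- v; best <- c(dx, dy) }
  }
  expect_equal(best, c(3, -2))
  # overlapping beads are rejected
  expect_error(simulate_bead_field(n_beads = 400, width = 96, height = 96),
               "6 PSF sigmas")
  # linear chromatic model: offset grows to slope * x at the far edge
  bfc <- simulate_bead_field(n_beads = 9, shifts = list(c(0, 0, 0)),
                             chromatic_slope = list(c(0.01, 0)),
                             width = 2048, height = 64, n_z = 5,
                             z_range = c(2.5, 2.5), rng_seed = 2)
  expect_equal(max(bfc$truth$beads$x) * 0.01, 20.3, tolerance = 0.02)
})

test_that("endosome scenes store and render the programmed angles", {
  sc <- simulate_endosome_scene(n_endosomes = 4, lnp_angles = rep(0, 4),
                                marker_angles = rep(0, 4), rng_seed = 1)
  f <- sc$truth$foci
  for (e in 1:4) {
    a <- f$angle_deg[f$endosome_id == e & f$channel == 2]
    b <- f$angle_deg[f$endosome_id == e & f$channel == 3]
    expect_equal(angular_difference(a, b), 0)
  }
  # antipodal mode renders two foci per channel, 180 degrees apart
  sc2 <- simulate_endosome_scene(n_endosomes = 3, antipodal = TRUE,
                                 rng_seed = 2)
  f2 <- sc2$truth$foci
  expect_equal(nrow(f2), 3 * 2 * 2)
  for (e in 1:3) for (ch in 2:3) {
    a <- f2$angle_deg[f2$endosome_id == e & f2$channel == ch]
    expect_equal(angular_difference(a[1], a[2]), 180)
  }
})
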