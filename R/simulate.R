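# Synthetic time-lapse generator with ground truth.
#
# Emulates the widefield single-vesicle release assay: diffraction-limited
# Gaussian spots on a noisy background (Poisson shot noise + Gaussian read
# noise), per-vesicle Brownian motion, a galectin-recruitment onset per
# event, a step-wise partial RNA release at onset for fast-releasing
# vesicles, exponential photobleaching, per-cell endosomal-marker intensity
# with a linear time trend, and (for bead fields) programmed inter-channel
# shifts plus position-dependent linear chromatic offsets.
#
# Channel semantics for the release experiment:
#   1 "rna"      labelled RNA cargo
#   2 "galectin" membrane-damage reporter (appears at onset)
#   3 "marker"   endosomal compartment marker (optional)

#' Simulation configuration for the release experiment
#'
#' Defaults follow the acquisition conditions of the widefield release
#' assay: 2.2 s frame interval, 103 nm pixels (so the 6-pixel object mask
#' spans 620 nm), and event statistics in the range reported for siRNA-LNPs
#' (hit fraction 0.7, fast-release fraction 0.5, fractional release
#' magnitude 0.25). Field, cohort and z sizes are desk-scale.
#'
#' @param n_channels 2 (rna, galectin) or 3 (plus compartment marker).
#' @param n_frames,n_z,height,width Stack dimensions.
#' @param pixel_size_nm,z_step_nm,frame_interval_s Physical metadata.
#' @param psf_sigma_nm Lateral PSF sigma per channel (recycled).
#' @param psf_sigma_z_nm Axial PSF sigma (amplitude weight across planes).
#' @param background_level Constant background offset (counts).
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param photon_scaling Counts per photon for the Poisson shot noise.
#' @param bleach_rate_per_s Photobleaching rate per channel (1/s, recycled).
#' @param n_cells,n_vesicles_per_cell Cohort layout. Each cell additionally
#'   carries `n_reference_per_cell` event-free vesicles used for bleach
#'   calibration.
#' @param n_reference_per_cell Event-free reference vesicles per cell.
#' @param hit_fraction Probability that a damaged vesicle carries detectable
#'   RNA payload.
#' @param fast_release_fraction Probability that a hit releases fast.
#' @param release_magnitude_fraction Fractional RNA intensity drop at onset
#'   for fast-release vesicles.
#' @param marker_positive_fraction Probability a vesicle resides in a
#'   marker-positive compartment.
#' @param marker_p90_start Typical per-cell 90th-percentile marker intensity
#'   at acquisition start (counts).
#' @param marker_p90_drift Fractional change of the per-cell p90 over the
#'   acquisition (e.g. 0.5 means p90 rises by 50%).
#' @param marker_positive_level,marker_negative_level Target marker
#'   intensity of positive/negative vesicles, as a fraction of the
#'   per-cell p90.
#' @param rna_amplitude_mean,rna_amplitude_cv Peak RNA spot amplitude
#'   (counts) and its per-vesicle coefficient of variation (log-normal).
#' @param galectin_amplitude Peak galectin spot amplitude (counts).
#' @param onset_margin_frames Onset frames are drawn uniformly at least this
#'   many frames away from both ends of the acquisition.
#' @param motion_sd_px_per_frame Per-frame Gaussian random-walk step sd.
#' @param noise Logical; apply shot and read noise.
#' @param rng_seed Top-level seed; all draws derive from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_channels = 3L, n_frames = 100L, n_z = 1L,
                              height = 128L, width = 128L,
                              pixel_size_nm = 103, z_step_nm = 500,
                              frame_interval_s = 2.2,
                              psf_sigma_nm = 130,
                              psf_sigma_z_nm = 400,
                              background_level = 100,
                              read_noise_sd = 2,
                              photon_scaling = 1,
                              bleach_rate_per_s = c(0.002, 0.001, 0),
                              n_cells = 4L, n_vesicles_per_cell = 5L,
                              n_reference_per_cell = 2L,
                              hit_fraction = 0.7,
                              fast_release_fraction = 0.5,
                              release_magnitude_fraction = 0.25,
                              marker_positive_fraction = 0.6,
                              marker_p90_start = 400,
                              marker_p90_drift = 0.3,
                              marker_positive_level = 0.8,
                              marker_negative_level = 0.2,
                              rna_amplitude_mean = 600,
                              rna_amplitude_cv = 0.3,
                              galectin_amplitude = 400,
                              onset_margin_frames = 20L,
                              motion_sd_px_per_frame = 0.3,
                              noise = TRUE,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$psf_sigma_nm <- rep(psf_sigma_nm, length.out = n_channels)
  cfg$bleach_rate_per_s <- rep(bleach_rate_per_s, length.out = n_channels)
  validate_simulation_config(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validate_simulation_config <- function(cfg) {
  fr <- c("hit_fraction", "fast_release_fraction",
          "release_magnitude_fraction", "marker_positive_fraction")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("simulation_config: ", f, " must lie in [0, 1]")
  pos <- c("pixel_size_nm", "z_step_nm", "frame_interval_s",
           "psf_sigma_z_nm", "photon_scaling")
  for (f in pos)
    if (any(cfg[[f]] <= 0)) stop("simulation_config: ", f, " must be > 0")
  if (any(cfg$psf_sigma_nm <= 0))
    stop("simulation_config: psf_sigma_nm must be > 0")
  if (any(cfg$bleach_rate_per_s < 0) || cfg$read_noise_sd < 0 ||
      cfg$background_level < 0)
    stop("simulation_config: rates and noise levels must be non-negative")
  if (!(cfg$n_channels %in% 2:3))
    stop("simulation_config: n_channels must be 2 or 3")
  if (cfg$n_frames < 2 * cfg$onset_margin_frames)
    stop("simulation_config: n_frames too small for onset_margin_frames")
  # a spot that classifier tests could not see is a configuration error
  if (cfg$noise) {
    noise_floor <- sqrt(cfg$background_level * cfg$photon_scaling +
                        cfg$read_noise_sd^2)
    if (cfg$rna_amplitude_mean <= noise_floor)
      stop("simulation_config: RNA spot amplitude (", cfg$rna_amplitude_mean,
           ") is at or below the noise floor (", round(noise_floor, 1),
           "); classifier tests on such data would be meaningless")
  }
  invisible(cfg)
}

# Add an isotropic Gaussian spot to a [y,x] matrix (in place value return).
# Sub-pixel centre (y0, x0); evaluation window is +/- 4 sigma.
add_spot <- function(img, y0, x0, sigma_px, amplitude) {
  if (amplitude <= 0) return(img)
  r <- ceiling(4 * sigma_px)
  ys <- max(1, floor(y0) - r):min(nrow(img), ceiling(y0) + r)
  xs <- max(1, floor(x0) - r):min(ncol(img), ceiling(x0) + r)
  if (!length(ys) || !length(xs)) return(img)
  g <- outer(exp(-(ys - y0)^2 / (2 * sigma_px^2)),
             exp(-(xs - x0)^2 / (2 * sigma_px^2)))
  img[ys, xs] <- img[ys, xs] + amplitude * g
  img
}

# Analytic in-mask mean of a unit-amplitude spot centred at the given
# sub-pixel position, read out with the discrete disc at the rounded centre.
mask_gain <- function(y0, x0, sigma_px, diameter = 6) {
  off <- disc_offsets(diameter)
  yy <- round(y0) + off[, "dy"]
  xx <- round(x0) + off[, "dx"]
  mean(exp(-((yy - y0)^2 + (xx - x0)^2) / (2 * sigma_px^2)))
}

# z amplitude weight of a spot at plane z (1-based) for a spot centred at
# z0 (may be fractional), axial sigma in plane units.
z_weight <- function(z, z0, sigma_z_planes) {
  exp(-(z - z0)^2 / (2 * sigma_z_planes^2))
}

apply_camera_noise <- function(img, cfg) {
  photons <- stats::rpois(length(img), pmax(img, 0) / cfg$photon_scaling)
  out <- photons * cfg$photon_scaling +
    stats::rnorm(length(img), 0, cfg$read_noise_sd)
  matrix(pmin(pmax(out, 0), 65535), nrow(img), ncol(img))
}

# Rectangular cell tiling of the field; returns list(cells, nuclei, tiles)
# where tiles is a per-cell data.frame of inclusive pixel bounds.
layout_cells <- function(cfg) {
  nx <- ceiling(sqrt(cfg$n_cells))
  ny <- ceiling(cfg$n_cells / nx)
  tw <- floor(cfg$width / nx)
  th <- floor(cfg$height / ny)
  cells <- matrix(0L, cfg$height, cfg$width)
  nuclei <- matrix(0L, cfg$height, cfg$width)
  tiles <- data.frame(cell_id = integer(0), y0 = integer(0), y1 = integer(0),
                      x0 = integer(0), x1 = integer(0))
  id <- 0L
  for (gy in seq_len(ny)) for (gx in seq_len(nx)) {
    if (id >= cfg$n_cells) break
    id <- id + 1L
    y0 <- (gy - 1L) * th + 1L; y1 <- gy * th
    x0 <- (gx - 1L) * tw + 1L; x1 <- gx * tw
    cells[(y0 + 1):(y1 - 1), (x0 + 1):(x1 - 1)] <- id  # 1-px gutter
    cy <- (y0 + y1) / 2; cx <- (x0 + x1) / 2
    rn <- max(3, floor(min(tw, th) / 8))
    off <- disc_offsets(2 * rn)
    nuclei[cbind(round(cy) + off[, "dy"], round(cx) + off[, "dx"])] <- id
    tiles <- rbind(tiles, data.frame(cell_id = id, y0 = y0, y1 = y1,
                                     x0 = x0, x1 = x1))
  }
  list(cells = cells, nuclei = nuclei, tiles = tiles)
}

# Draw vesicle start positions inside one cell tile with a minimum mutual
# separation, keeping the full background annulus inside the field.
place_vesicles <- function(n, tile, cfg, margin = 16, min_sep = 14) {
  ylo <- max(tile$y0 + 2, margin); yhi <- min(tile$y1 - 2, cfg$height - margin + 1)
  xlo <- max(tile$x0 + 2, margin); xhi <- min(tile$x1 - 2, cfg$width - margin + 1)
  if (yhi - ylo < 2 || xhi - xlo < 2)
    stop("place_vesicles: cell tile too small for the measurement geometry")
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:500) {
      p <- c(stats::runif(1, ylo, yhi), stats::runif(1, xlo, xhi))
      if (i == 1 || all(sqrt(rowSums((pts[seq_len(i - 1), , drop = FALSE] -
             matrix(p, i - 1, 2, byrow = TRUE))^2)) >= min_sep)) {
        pts[i, ] <- p
        break
      }
    }
    if (anyNA(pts[i, ]))
      stop("place_vesicles: cannot place ", n,
           " vesicles with separation ", min_sep, " in this cell")
  }
  colnames(pts) <- c("y", "x")
  pts
}

# Reflected Gaussian random walk inside [lo, hi].
random_walk <- function(start, n, sd, lo, hi) {
  out <- numeric(n)
  out[1] <- start
  for (t in 2:n) {
    p <- out[t - 1] + stats::rnorm(1, 0, sd)
    while (p < lo || p > hi) p <- ifelse(p < lo, 2 * lo - p, 2 * hi - p)
    out[t] <- p
  }
  out
}

#' Simulate a single-vesicle endosomal-release experiment
#'
#' Renders a multi-channel, multi-z time-lapse stack of moving vesicles with
#' known event parameters, plus cell and nucleus label images, a seed
#' coordinate table for tracking, and the full ground truth.
#'
#' Per vesicle, the RNA channel carries a Gaussian spot whose amplitude is
#' constant until the onset frame, drops by `release_magnitude_fraction` at
#' onset for fast-release vesicles, and decays with the configured bleach
#' rate throughout. A galectin spot appears at onset. Marker-channel spots
#' track the per-cell 90th-percentile reference with its linear time trend.
#' Noise is applied last.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `stack` ([image_stack()]), `cells`, `nuclei`
#'   (label matrices), `seeds` (data frame `vesicle_id, frame, x, y, z` of
#'   rounded true positions, the tracking input), and `truth` (list of data
#'   frames `vesicles`, `positions`, `cells`).
#' @export
simulate_release_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$rng_seed)
  lay <- layout_cells(cfg)
  dt <- cfg$frame_interval_s
  sigma_px <- cfg$psf_sigma_nm / cfg$pixel_size_nm
  sigma_z <- cfg$psf_sigma_z_nm / cfg$z_step_nm
  n_per_cell <- cfg$n_vesicles_per_cell + cfg$n_reference_per_cell

  # per-cell marker reference (p90 at start/end, linear in between)
  cells_truth <- data.frame(
    cell_id = seq_len(cfg$n_cells),
    p90_start = cfg$marker_p90_start *
      exp(stats::rnorm(cfg$n_cells, 0, 0.15)),
    t_start_s = 0,
    t_end_s = (cfg$n_frames - 1) * dt)
  cells_truth$p90_end <- cells_truth$p90_start * (1 + cfg$marker_p90_drift)
  p90_at <- function(cell, t_s) {
    r <- cells_truth[cells_truth$cell_id == cell, ]
    r$p90_start + (r$p90_end - r$p90_start) * t_s / max(r$t_end_s, dt)
  }

  # vesicle-level truth
  vlist <- list()
  plist <- list()
  vid <- 0L
  for (ci in seq_len(cfg$n_cells)) {
    tile <- lay$tiles[ci, ]
    pts <- place_vesicles(n_per_cell, tile, cfg)
    for (k in seq_len(n_per_cell)) {
      vid <- vid + 1L
      is_ref <- k > cfg$n_vesicles_per_cell
      hit <- if (is_ref) TRUE else stats::runif(1) < cfg$hit_fraction
      fast <- !is_ref && hit && stats::runif(1) < cfg$fast_release_fraction
      t0 <- if (is_ref) NA_integer_ else
        sample(seq(cfg$onset_margin_frames + 1L,
                   cfg$n_frames - cfg$onset_margin_frames), 1)
      amp <- if (hit) cfg$rna_amplitude_mean *
        exp(stats::rnorm(1, -0.5 * log(1 + cfg$rna_amplitude_cv^2),
                         sqrt(log(1 + cfg$rna_amplitude_cv^2)))) else 0
      gal <- if (is_ref) 0 else cfg$galectin_amplitude *
        exp(stats::rnorm(1, 0, 0.3))
      mpos <- stats::runif(1) < cfg$marker_positive_fraction
      z0 <- if (cfg$n_z == 1) 1 else stats::runif(1, 1.5, cfg$n_z - 0.5)
      # motion track
      ymin <- max(tile$y0 + 2, 16); ymax <- min(tile$y1 - 2, cfg$height - 15)
      xmin <- max(tile$x0 + 2, 16); xmax <- min(tile$x1 - 2, cfg$width - 15)
      yy <- random_walk(pts[k, "y"], cfg$n_frames,
                        cfg$motion_sd_px_per_frame, ymin, ymax)
      xx <- random_walk(pts[k, "x"], cfg$n_frames,
                        cfg$motion_sd_px_per_frame, xmin, xmax)
      vlist[[vid]] <- data.frame(
        vesicle_id = vid, cell_id = ci, is_reference = is_ref,
        hit = hit, fast_release = fast, marker_positive = mpos,
        t0_frame = t0, amplitude = amp,
        mask_mean_amplitude = amp * mask_gain(yy[1], xx[1], sigma_px[1]) *
          z_weight(round(z0), z0, sigma_z),
        release_magnitude = ifelse(fast, cfg$release_magnitude_fraction, 0),
        galectin_amplitude = gal, z_plane = z0)
      plist[[vid]] <- data.frame(vesicle_id = vid,
                                 frame = seq_len(cfg$n_frames),
                                 y = yy, x = xx)
    }
  }
  vesicles <- do.call(rbind, vlist)
  positions <- do.call(rbind, plist)

  # render (positions as [vesicle, frame] matrices for speed)
  nv <- nrow(vesicles)
  Y <- matrix(positions$y, nrow = cfg$n_frames)   # [frame, vesicle]
  X <- matrix(positions$x, nrow = cfg$n_frames)
  p90s <- cells_truth$p90_start[vesicles$cell_id]
  p90e <- cells_truth$p90_end[vesicles$cell_id]
  t_end <- max((cfg$n_frames - 1) * dt, dt)
  data <- array(0, c(cfg$n_channels, cfg$n_frames, cfg$n_z,
                     cfg$height, cfg$width))
  for (t in seq_len(cfg$n_frames)) {
    t_s <- (t - 1) * dt
    for (z in seq_len(cfg$n_z)) {
      for (ch in seq_len(cfg$n_channels)) {
        img <- matrix(cfg$background_level, cfg$height, cfg$width)
        for (i in seq_len(nv)) {
          zw <- z_weight(z, vesicles$z_plane[i], sigma_z)
          if (zw < 1e-4) next
          a <- 0
          if (ch == 1 && vesicles$hit[i]) {
            a <- vesicles$amplitude[i] * exp(-cfg$bleach_rate_per_s[1] * t_s)
            if (vesicles$fast_release[i] && t >= vesicles$t0_frame[i])
              a <- a * (1 - cfg$release_magnitude_fraction)
          } else if (ch == 2 && !vesicles$is_reference[i] &&
                     t >= vesicles$t0_frame[i]) {
            a <- vesicles$galectin_amplitude[i] *
              exp(-cfg$bleach_rate_per_s[2] *
                  (t_s - (vesicles$t0_frame[i] - 1) * dt))
          } else if (ch == 3) {
            lvl <- if (vesicles$marker_positive[i]) cfg$marker_positive_level
                   else cfg$marker_negative_level
            a <- lvl * (p90s[i] + (p90e[i] - p90s[i]) * t_s / t_end) /
              mask_gain(Y[t, i], X[t, i], sigma_px[3])
          }
          if (a > 0) img <- add_spot(img, Y[t, i], X[t, i],
                                     sigma_px[ch], a * zw)
        }
        if (cfg$noise) img <- apply_camera_noise(img, cfg)
        data[ch, t, z, , ] <- img
      }
    }
  }

  seeds <- data.frame(vesicle_id = positions$vesicle_id,
                      frame = positions$frame,
                      x = round(positions$x), y = round(positions$y),
                      z = if (cfg$n_z == 1) 1L else
                        pmin(pmax(round(vesicles$z_plane[
                          positions$vesicle_id]), 1L), cfg$n_z))
  ch_names <- c("rna", "galectin", "marker")[seq_len(cfg$n_channels)]
  list(stack = image_stack(data, cfg$pixel_size_nm, cfg$z_step_nm,
                           cfg$frame_interval_s, ch_names),
       cells = lay$cells, nuclei = lay$nuclei, seeds = seeds,
       truth = list(vesicles = vesicles, positions = positions,
                    cells = cells_truth),
       config = cfg)
}

#' Simulate a bead reference field for channel registration
#'
#' Beads (sub-diffraction microspheres) rendered in every channel; each
#' non-reference channel is displaced by a programmed integer shift plus a
#' position-dependent linear chromatic offset
#' (`slope_x * x + intercept_x` laterally in x, and analogously in y).
#' Channel 1 is the reference.
#'
#' @param n_beads Number of beads, placed on a jittered grid.
#' @param shifts List of per-channel integer shifts `c(dx, dy, dz)` for
#'   channels 2..K (one list element per extra channel).
#' @param chromatic_slope,chromatic_intercept Lists of `c(x, y)` linear
#'   chromatic coefficients for channels 2..K (default zero).
#' @param width,height,n_z Field size.
#' @param z_range Range of bead z-centres (planes); default
#'   `c(3, n_z - 2)`. Narrow it when programming large z shifts so that
#'   shifted beads stay inside the acquired planes.
#' @param psf_sigma_px,psf_sigma_z_planes PSF width laterally/axially.
#' @param amplitude,background Peak bead amplitude and background (counts).
#' @param noise Logical; camera noise as in the release simulator.
#' @param read_noise_sd,photon_scaling Noise parameters.
#' @param pixel_size_nm,z_step_nm Metadata.
#' @param rng_seed Seed.
#' @return List with `stack` and `truth` (`beads` data frame of reference
#'   positions; `channels` data frame of programmed shift and chromatic
#'   coefficients per channel).
#' @export
simulate_bead_field <- function(n_beads = 20,
                                shifts = list(c(0, 0, 0)),
                                chromatic_slope = NULL,
                                chromatic_intercept = NULL,
                                width = 160, height = 160, n_z = 9,
                                z_range = NULL,
                                psf_sigma_px = 1.3, psf_sigma_z_planes = 1.2,
                                amplitude = 2000, background = 100,
                                noise = FALSE, read_noise_sd = 2,
                                photon_scaling = 1,
                                pixel_size_nm = 103, z_step_nm = 260,
                                rng_seed = 1L) {
  set.seed(rng_seed)
  nch <- 1L + length(shifts)
  if (is.null(chromatic_slope))
    chromatic_slope <- rep(list(c(0, 0)), nch - 1)
  if (is.null(chromatic_intercept))
    chromatic_intercept <- rep(list(c(0, 0)), nch - 1)
  # jittered grid placement; margin leaves room for +/-12 px shifts
  margin <- 20
  ng <- ceiling(sqrt(n_beads))
  gy <- seq(margin, height - margin, length.out = ng)
  gx <- seq(margin, width - margin, length.out = ng)
  grid <- expand.grid(y = gy, x = gx)[seq_len(n_beads), ]
  jit <- min(diff(gy)[1], diff(gx)[1]) * 0.2
  grid$y <- grid$y + stats::runif(n_beads, -jit, jit)
  grid$x <- grid$x + stats::runif(n_beads, -jit, jit)
  if (is.null(z_range)) z_range <- c(3, n_z - 2)
  grid$z <- stats::runif(n_beads, z_range[1], z_range[2])
  dmin <- min(stats::dist(grid[, c("y", "x")]))
  if (dmin < 6 * psf_sigma_px)
    stop("simulate_bead_field: beads closer than 6 PSF sigmas (",
         round(dmin, 1), " px); reduce n_beads or enlarge the field")
  beads <- data.frame(bead_id = seq_len(n_beads),
                      y = grid$y, x = grid$x, z = grid$z)
  chan <- data.frame(channel = seq_len(nch), dx = 0, dy = 0, dz = 0,
                     slope_x = 0, intercept_x = 0,
                     slope_y = 0, intercept_y = 0)
  for (k in seq_len(nch - 1)) {
    chan[k + 1, c("dx", "dy", "dz")] <- shifts[[k]]
    chan[k + 1, c("slope_x", "slope_y")] <- chromatic_slope[[k]]
    chan[k + 1, c("intercept_x", "intercept_y")] <- chromatic_intercept[[k]]
  }
  data <- array(0, c(nch, 1, n_z, height, width))
  for (ch in seq_len(nch)) {
    co <- chan[ch, ]
    px <- beads$x + co$dx + co$slope_x * beads$x + co$intercept_x
    py <- beads$y + co$dy + co$slope_y * beads$y + co$intercept_y
    pz <- beads$z + co$dz
    for (z in seq_len(n_z)) {
      img <- matrix(background, height, width)
      for (b in seq_len(n_beads)) {
        zw <- z_weight(z, pz[b], psf_sigma_z_planes)
        if (zw > 1e-4)
          img <- add_spot(img, py[b], px[b], psf_sigma_px, amplitude * zw)
      }
      if (noise) {
        cfgn <- list(photon_scaling = photon_scaling,
                     read_noise_sd = read_noise_sd)
        img <- apply_camera_noise(img, cfgn)
      }
      data[ch, 1, z, , ] <- img
    }
  }
  list(stack = image_stack(data, pixel_size_nm, z_step_nm, 1,
                           paste0("ch", seq_len(nch))),
       truth = list(beads = beads, channels = chan))
}

#' Simulate endosome ROIs with membrane-adjacent foci
#'
#' Each endosome is an annular membrane signal (channel 1) plus one or two
#' Gaussian foci per analysis channel (2 = LNP, 3 = damage marker), placed
#' on the ring at specified or uniformly random angles. With
#' `antipodal = TRUE` each channel carries two foci 180 degrees apart at an
#' independent random rotation. Endosomes are laid out on a tile grid in a
#' single frame; a label image marks each endosome's mask.
#'
#' @param n_endosomes Number of endosomes.
#' @param ring_radius_px Membrane ring radius.
#' @param lnp_angles,marker_angles Optional numeric vectors (degrees, one
#'   per endosome) fixing the focus angles; default uniform random.
#' @param angle_offset_deg If given (and `marker_angles` is NULL), marker
#'   foci are placed at the LNP angle plus this offset.
#' @param antipodal Two antipodal foci per channel instead of one.
#' @param foci_radius_px Radial position of the foci (default on the ring).
#' @param tile_px Tile edge length per endosome.
#' @param psf_sigma_px,ring_sigma_px Widths of foci and membrane ring.
#' @param focus_amplitude,membrane_amplitude,background Intensities (counts).
#' @param noise,read_noise_sd,photon_scaling Camera noise as elsewhere.
#' @param pixel_size_nm Metadata.
#' @param rng_seed Seed.
#' @return List with `stack` (3-channel single-frame [image_stack()]),
#'   `masks` (endosome label matrix), and `truth` (`endosomes` with centres,
#'   `foci` with per-channel angles, radii and positions).
#' @export
simulate_endosome_scene <- function(n_endosomes = 16,
                                    ring_radius_px = 10,
                                    lnp_angles = NULL,
                                    marker_angles = NULL,
                                    angle_offset_deg = NULL,
                                    antipodal = FALSE,
                                    foci_radius_px = ring_radius_px,
                                    tile_px = 40,
                                    psf_sigma_px = 1.6,
                                    ring_sigma_px = 1.5,
                                    focus_amplitude = 800,
                                    membrane_amplitude = 300,
                                    background = 50,
                                    noise = FALSE, read_noise_sd = 2,
                                    photon_scaling = 1,
                                    pixel_size_nm = 46,
                                    rng_seed = 1L) {
  set.seed(rng_seed)
  if (foci_radius_px + 4 * psf_sigma_px > tile_px / 2 - 2)
    stop("simulate_endosome_scene: tile too small for the ring geometry")
  if (is.null(lnp_angles)) lnp_angles <- stats::runif(n_endosomes, 0, 360)
  if (is.null(marker_angles)) {
    marker_angles <- if (is.null(angle_offset_deg))
      stats::runif(n_endosomes, 0, 360)
    else lnp_angles + angle_offset_deg
  }
  stopifnot(length(lnp_angles) == n_endosomes,
            length(marker_angles) == n_endosomes)
  ng <- ceiling(sqrt(n_endosomes))
  H <- ng * tile_px; W <- ng * tile_px
  data <- array(0, c(3, 1, 1, H, W))
  for (ch in 1:3) data[ch, 1, 1, , ] <- background
  masks <- matrix(0L, H, W)
  endo <- data.frame(endosome_id = seq_len(n_endosomes), cy = NA_real_,
                     cx = NA_real_)
  flist <- list()
  mask_off <- disc_offsets(2 * (ring_radius_px + 4))
  for (e in seq_len(n_endosomes)) {
    gy <- (e - 1) %/% ng; gx <- (e - 1) %% ng
    cy <- gy * tile_px + tile_px / 2 + 0.5
    cx <- gx * tile_px + tile_px / 2 + 0.5
    endo$cy[e] <- cy; endo$cx[e] <- cx
    masks[cbind(round(cy) + mask_off[, "dy"],
                round(cx) + mask_off[, "dx"])] <- e
    # membrane annulus in channel 1
    ys <- (round(cy) - ring_radius_px - 6):(round(cy) + ring_radius_px + 6)
    xs <- (round(cx) - ring_radius_px - 6):(round(cx) + ring_radius_px + 6)
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    data[1, 1, 1, ys, xs] <- data[1, 1, 1, ys, xs] +
      membrane_amplitude * exp(-(d - ring_radius_px)^2 / (2 * ring_sigma_px^2))
    for (ch in 2:3) {
      base <- if (ch == 2) lnp_angles[e] else marker_angles[e]
      angs <- if (antipodal) c(base, base + 180) else base
      for (a in angs) {
        fy <- cy + foci_radius_px * sin(a * pi / 180)
        fx <- cx + foci_radius_px * cos(a * pi / 180)
        data[ch, 1, 1, , ] <- add_spot(data[ch, 1, 1, , ], fy, fx,
                                       psf_sigma_px, focus_amplitude)
        flist[[length(flist) + 1]] <- data.frame(
          endosome_id = e, channel = ch, angle_deg = a %% 360,
          radius_px = foci_radius_px, y = fy, x = fx)
      }
    }
  }
  if (noise) {
    cfgn <- list(photon_scaling = photon_scaling,
                 read_noise_sd = read_noise_sd)
    for (ch in 1:3)
      data[ch, 1, 1, , ] <- apply_camera_noise(data[ch, 1, 1, , ], cfgn)
  }
  list(stack = image_stack(data, pixel_size_nm, pixel_size_nm, 1,
                           c("membrane", "lnp", "damage")),
       masks = masks,
       truth = list(endosomes = endo, foci = do.call(rbind, flist)))
}

#' Simulate per-cell foci with channel-dependent radial placement
#'
#' A positions-only generator for nuclear-distance statistics: each cell has
#' a nucleus centroid and two channels of foci, one placed in an inner
#' radial band ("disintegrated") and one in an outer band ("intact").
#'
#' @param n_cells Number of cells.
#' @param n_foci_per_channel Foci per channel per cell.
#' @param cell_radius_px Cell radius.
#' @param inner_band,outer_band Radial bands (fractions of the cell radius)
#'   for channels 1 and 2.
#' @param rng_seed Seed.
#' @return List with `foci` (cell_id, channel, x, y) and `nuclei`
#'   (cell_id, x, y).
#' @export
simulate_radial_foci <- function(n_cells = 20, n_foci_per_channel = 6,
                                 cell_radius_px = 60,
                                 inner_band = c(0.1, 0.5),
                                 outer_band = c(0.5, 1.0),
                                 rng_seed = 1L) {
  set.seed(rng_seed)
  flist <- list()
  nuc <- data.frame(cell_id = seq_len(n_cells),
                    x = stats::runif(n_cells, 0, 1000),
                    y = stats::runif(n_cells, 0, 1000))
  for (c_ in seq_len(n_cells)) {
    for (ch in 1:2) {
      band <- if (ch == 1) inner_band else outer_band
      r <- stats::runif(n_foci_per_channel, band[1], band[2]) * cell_radius_px
      a <- stats::runif(n_foci_per_channel, 0, 2 * pi)
      flist[[length(flist) + 1]] <- data.frame(
        cell_id = c_, channel = ch,
        x = nuc$x[c_] + r * cos(a), y = nuc$y[c_] + r * sin(a))
    }
  }
  list(foci = do.call(rbind, flist), nuclei = nuc)
}
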