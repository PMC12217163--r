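# Single-vesicle intensity trace quantification: object-mask fitting, local
# background estimation, rolling-background subtraction, photobleaching
# correction and event-aligned normalization.

#' Object-mask specification
#'
#' The measurement geometry of the single-vesicle assay: a discrete disc of
#' `diameter_px` (default 6 px = 620 nm at 103 nm pixels) and one z-plane
#' depth, a background annulus starting `background_offset_px` (default
#' 8 px, ~825 nm) outside the mask with width `background_ring_width_px`,
#' and an 11-frame rolling window for the background series.
#'
#' @param diameter_px Mask diameter in pixels (>= 3).
#' @param z_depth_planes Mask depth in z-planes (only 1 supported; the mask
#'   is fitted in z but measured in a single plane).
#' @param background_offset_px Gap between mask edge and annulus (px).
#' @param background_ring_width_px Annulus width (px).
#' @param rolling_window_frames Rolling-average window (odd).
#' @param search_radius_px,search_radius_z Mask-fitting search range around
#'   the seed.
#' @return List of class `MaskSpec`.
#' @export
mask_spec <- function(diameter_px = 6, z_depth_planes = 1,
                      background_offset_px = 8,
                      background_ring_width_px = 2,
                      rolling_window_frames = 11,
                      search_radius_px = 3, search_radius_z = 1) {
  if (diameter_px < 3) stop("mask_spec: diameter must be >= 3 px")
  if (background_offset_px <= diameter_px / 2)
    stop("mask_spec: background offset must exceed the mask radius")
  if (rolling_window_frames %% 2 != 1)
    stop("mask_spec: rolling window must be odd")
  spec <- list(diameter_px = diameter_px, z_depth_planes = z_depth_planes,
               background_offset_px = background_offset_px,
               background_ring_width_px = background_ring_width_px,
               rolling_window_frames = rolling_window_frames,
               search_radius_px = search_radius_px,
               search_radius_z = search_radius_z,
               mask_offsets = disc_offsets(diameter_px),
               ring_offsets = annulus_offsets(
                 diameter_px / 2 + background_offset_px,
                 background_ring_width_px))
  class(spec) <- "MaskSpec"
  spec
}

#' Fit the object mask around a seed position
#'
#' Evaluates the total in-mask intensity on an integer grid of candidate
#' positions (`+/- search_radius_px` laterally, `+/- search_radius_z`
#' axially) around the seed and returns the position maximizing it. Ties are
#' broken toward the smallest displacement from the seed, then
#' lexicographically by (dx, dy, dz).
#'
#' @param stack An [image_stack()].
#' @param channel Channel used for fitting (the tracked RNA channel).
#' @param frame Frame index (1-based).
#' @param seed Named vector or list with `x`, `y`, `z` (1-based).
#' @param spec A [mask_spec()].
#' @return List `x, y, z` (refined integer position) and `mean` (mask mean).
#' @export
fit_mask <- function(stack, channel, frame, seed, spec = mask_spec()) {
  d <- dim(stack$data)
  sr <- spec$search_radius_px
  hw <- sr + ceiling(spec$diameter_px / 2)
  x0 <- round(seed[["x"]]); y0 <- round(seed[["y"]])
  z0 <- if (!is.null(seed[["z"]])) round(seed[["z"]]) else 1L
  if (x0 - hw < 1 || x0 + hw > d[5] || y0 - hw < 1 || y0 + hw > d[4])
    stop("fit_mask: seed at (", x0, ",", y0,
         ") is nearer the border than the mask search radius")
  zs <- max(1, z0 - spec$search_radius_z):min(d[3], z0 + spec$search_radius_z)
  cache <- mask_search_cache(spec)
  best <- NULL
  for (z in zs) {
    patch <- stack$data[channel, frame, z, (y0 - hw):(y0 + hw),
                        (x0 - hw):(x0 + hw)]
    totals <- colSums(matrix(patch[cache$idx], nrow(cache$idx)))
    sel <- which(totals == max(totals))
    g <- sel[which.min(cache$tie_rank[sel])]   # min displacement, then lex
    cand <- list(x = x0 + cache$grid$dx[g], y = y0 + cache$grid$dy[g],
                 z = z, total = totals[g],
                 disp = cache$grid$dx[g]^2 + cache$grid$dy[g]^2 +
                   (z - z0)^2,
                 key = c(cache$grid$dx[g], cache$grid$dy[g], z - z0))
    if (is.null(best) || cand$total > best$total ||
        (cand$total == best$total &&
         (cand$disp < best$disp ||
          (cand$disp == best$disp && is_lex_less(cand$key, best$key)))))
      best <- cand
  }
  list(x = best$x, y = best$y, z = best$z,
       mean = best$total / nrow(spec$mask_offsets))
}

# Precomputed linear indices into the search patch for every candidate
# displacement (memoized per geometry).
.mask_cache <- new.env(parent = emptyenv())
mask_search_cache <- function(spec) {
  key <- paste(spec$diameter_px, spec$search_radius_px, sep = "_")
  if (!is.null(.mask_cache[[key]])) return(.mask_cache[[key]])
  sr <- spec$search_radius_px
  hw <- sr + ceiling(spec$diameter_px / 2)
  P <- 2L * hw + 1L
  grid <- expand.grid(dx = -sr:sr, dy = -sr:sr)
  off <- spec$mask_offsets
  idx <- matrix(0L, nrow(off), nrow(grid))
  for (g in seq_len(nrow(grid))) {
    yy <- hw + 1L + grid$dy[g] + off[, "dy"]
    xx <- hw + 1L + grid$dx[g] + off[, "dx"]
    idx[, g] <- (xx - 1L) * P + yy
  }
  tie_rank <- integer(nrow(grid))
  tie_rank[order(grid$dx^2 + grid$dy^2, grid$dx, grid$dy)] <-
    seq_len(nrow(grid))
  .mask_cache[[key]] <- list(grid = grid, idx = idx, tie_rank = tie_rank)
  .mask_cache[[key]]
}

is_lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Local background around a fitted mask
#'
#' Median pixel intensity in the annulus `background_offset_px` outside the
#' object mask. Annulus pixels falling outside the image are excluded.
#'
#' @param img A `[y, x]` matrix (one plane of one frame).
#' @param position List/vector with `x`, `y` (integer, 1-based).
#' @param spec A [mask_spec()].
#' @return Scalar median background.
#' @export
local_background <- function(img, position, spec = mask_spec()) {
  px <- pixels_at(img, round(position[["y"]]), round(position[["x"]]),
                  spec$ring_offsets)
  if (length(px) == 0)
    stop("local_background: background annulus is entirely outside the image")
  stats::median(px)
}

#' Rolling average of a background series
#'
#' Centred moving mean over `window` frames; at the series edges the window
#' is truncated to the available frames.
#'
#' @param x Numeric series.
#' @param window Odd window length (default 11).
#' @return Smoothed series, same length.
#' @export
rolling_background <- function(x, window = 11) rolling_mean(x, window)

#' Robust background noise sigma at a vesicle position
#'
#' Median over frames of the MAD-based sd of the annulus pixels; used by the
#' payload-detectability rule.
#' @param stack,channel,track,frames,spec As in [build_trace()].
#' @export
estimate_background_noise <- function(stack, channel, track, frames,
                                      spec = mask_spec()) {
  s <- vapply(frames, function(t) {
    p <- track[track$frame == t, ]
    img <- stack$data[channel, t, p$z[1], , ]
    stats::mad(pixels_at(img, round(p$y[1]), round(p$x[1]),
                         spec$ring_offsets))
  }, numeric(1))
  stats::median(s)
}

#' Fit the photobleaching reference model
#'
#' Reference traces (vesicles without damage events) are each normalized to
#' their first measurement, pooled, and fitted with a single exponential
#' `exp(-k t)` by least squares. The correction multiplies measurements by
#' `exp(+k t)`. A negative fitted rate is clamped to 0 with a warning
#' (no "unbleaching").
#'
#' @param times_s List of numeric time vectors (seconds), one per trace.
#' @param values List of numeric intensity vectors, matching `times_s`.
#' @return List with `k` (1/s) and `correct(values, times_s)` function.
#' @export
fit_bleach_model <- function(times_s, values) {
  if (!is.list(times_s)) { times_s <- list(times_s); values <- list(values) }
  if (length(values) < 3)
    stop("fit_bleach_model: need >= 3 reference traces")
  if (max(vapply(times_s, max, numeric(1))) -
      min(vapply(times_s, min, numeric(1))) < 120)
    warning("fit_bleach_model: reference traces span less than 2 minutes")
  t <- unlist(times_s)
  y <- unlist(lapply(values, function(v) v / v[1]))
  ok <- is.finite(y) & y > 0
  k0 <- -unname(stats::coef(stats::lm(log(y[ok]) ~ t[ok]))[2])
  fit <- try(minpack.lm::nlsLM(y ~ exp(-k * t),
                               start = list(k = max(k0, 1e-6)),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 100)),
             silent = TRUE)
  k <- if (inherits(fit, "try-error")) k0 else unname(stats::coef(fit)["k"])
  if (k < 0) {
    warning("fit_bleach_model: fitted rate ", signif(k, 3),
            " < 0; clamped to 0")
    k <- 0
  }
  list(k = k,
       correct = function(v, t_s) v * exp(k * t_s))
}

# Convert a window given in seconds before/after t0 to 1-based frame
# indices, rounding toward including more frames and intersecting with the
# available range. side = "pre" or "post".
window_frames <- function(t0_frame, dt, lo_s, hi_s, n_frames, side) {
  n_near <- floor(lo_s / dt)       # nearest bound, include more frames
  n_far <- ceiling(hi_s / dt)
  if (side == "pre") fr <- (t0_frame - n_far):(t0_frame - max(n_near, 1))
  else fr <- (t0_frame + max(n_near, 1)):(t0_frame + n_far)
  fr[fr >= 1 & fr <= n_frames]
}

#' Build a background-, bleach-corrected and normalized trace
#'
#' The full measurement pipeline for one vesicle: per frame, the object mask
#' is fitted around the seed in the tracked channel and the mask mean is
#' read out in every channel at that position; the 11-frame rolling average
#' of the local background is subtracted; the bleach model multiplies by
#' `exp(+k t)`; times are aligned so the onset frame maps to 0 s; the RNA
#' trace is normalized to mean 1 over the pre-onset window (default 3-60 s
#' before onset) and damage-marker channels to their maximum.
#'
#' @param stack An [image_stack()].
#' @param track Data frame `frame, x, y, z` (1-based) of seed positions.
#' @param t0_frame Onset frame (1-based), or NA for reference vesicles
#'   (times then run from the first frame and no normalization window is
#'   applied; `normalized` equals `bleach_corrected`).
#' @param spec A [mask_spec()].
#' @param channels Named integer vector mapping roles to channel indices,
#'   e.g. `c(rna = 1, damage = 2)`; extra channels are measured and left
#'   unnormalized.
#' @param bleach_k Per-channel bleach rates (1/s), recycled; default 0.
#' @param norm_window_s Pre-onset normalization window (seconds before t0).
#' @param fit_channel Channel used for mask fitting (default the rna role).
#' @return Object of class `TraceSeries`: list with `frames`, `times_s`
#'   (onset-aligned), `t0_frame`, per-channel matrices `raw_mean`,
#'   `local_background`, `corrected`, `bleach_corrected`, `normalized`
#'   (frames x channels), positions, and `bg_noise_sd` per channel.
#' @export
build_trace <- function(stack, track, t0_frame, spec = mask_spec(),
                        channels = c(rna = 1, damage = 2),
                        bleach_k = 0,
                        norm_window_s = c(3, 60),
                        fit_channel = NULL) {
  d <- dim(stack$data)
  dt <- stack$frame_interval_s
  frames <- sort(track$frame)
  n <- length(frames)
  if (!is.na(t0_frame) && !(t0_frame > min(frames) && t0_frame < max(frames)))
    stop("build_trace: t0 must lie strictly inside the track")
  if (is.null(fit_channel))
    fit_channel <- if ("rna" %in% names(channels)) channels[["rna"]]
                   else channels[[1]]
  nch <- length(channels)
  raw <- bg <- ringmad <- matrix(NA_real_, n, nch,
                                 dimnames = list(NULL, names(channels)))
  px <- py <- numeric(n); pz <- integer(n)
  ord <- match(frames, track$frame)
  sx <- track$x[ord]; sy <- track$y[ord]
  sz <- if (is.null(track$z)) rep(1L, n) else track$z[ord]
  for (i in seq_len(n)) {
    t <- frames[i]
    f <- fit_mask(stack, fit_channel, t,
                  c(x = sx[i], y = sy[i], z = sz[i]), spec)
    px[i] <- f$x; py[i] <- f$y; pz[i] <- f$z
    for (j in seq_len(nch)) {
      ch <- channels[[j]]
      img <- stack$data[ch, t, f$z, , ]
      raw[i, j] <- mean(pixels_at(img, f$y, f$x, spec$mask_offsets))
      ring <- pixels_at(img, f$y, f$x, spec$ring_offsets)
      if (length(ring) == 0)
        stop("build_trace: background annulus entirely outside the image")
      bg[i, j] <- stats::median(ring)
      ringmad[i, j] <- stats::mad(ring)
    }
  }
  pos <- data.frame(frame = frames, x = px, y = py, z = pz)
  corrected <- raw - apply(bg, 2, rolling_background,
                           window = spec$rolling_window_frames)
  bleach_k <- rep(bleach_k, length.out = nch)
  t_abs <- (frames - 1) * dt
  bleach_corrected <- corrected *
    outer(t_abs, bleach_k, function(t, k) exp(k * t))
  times <- if (is.na(t0_frame)) t_abs else (frames - t0_frame) * dt
  normalized <- bleach_corrected
  if (!is.na(t0_frame)) {
    pre <- window_frames(t0_frame, dt, norm_window_s[1], norm_window_s[2],
                         d[2], "pre")
    pre <- intersect(pre, frames)
    if (length(pre) == 0)
      stop("build_trace: empty normalization window before onset")
    ii <- match(pre, frames)
    for (j in seq_len(nch)) {
      role <- names(channels)[j]
      if (identical(role, "rna")) {
        normalized[, j] <- bleach_corrected[, j] /
          mean(bleach_corrected[ii, j])
      } else if (identical(role, "damage")) {
        normalized[, j] <- bleach_corrected[, j] /
          max(bleach_corrected[, j])
      }
    }
  }
  noise <- apply(ringmad, 2, stats::median)
  names(noise) <- names(channels)
  structure(list(frames = frames, times_s = times, t0_frame = t0_frame,
                 frame_interval_s = dt, channels = channels,
                 positions = pos, raw_mean = raw, local_background = bg,
                 corrected = corrected,
                 bleach_corrected = bleach_corrected,
                 normalized = normalized, bg_noise_sd = noise),
            class = "TraceSeries")
}

#' @export
print.TraceSeries <- function(x, ...) {
  cat(sprintf("TraceSeries: %d frames, channels: %s, t0 = %s\n",
              length(x$frames), paste(names(x$channels), collapse = ", "),
              ifelse(is.na(x$t0_frame), "none (reference)", x$t0_frame)))
  invisible(x)
}

#' Flatten TraceSeries objects into a TraceTable data frame
#'
#' @param traces Named list of `TraceSeries` (names = vesicle ids) or a
#'   single trace.
#' @param cell_ids Optional vector of cell ids per trace.
#' @return Data frame in the TraceTable schema (1-based; see
#'   [write_trace_table()] for the 0-based file form).
#' @export
traces_to_table <- function(traces, cell_ids = NULL) {
  if (inherits(traces, "TraceSeries")) traces <- list(`1` = traces)
  rows <- list()
  for (vi in seq_along(traces)) {
    tr <- traces[[vi]]
    vid <- names(traces)[vi]
    for (j in seq_along(tr$channels)) {
      rows[[length(rows) + 1]] <- data.frame(
        vesicle_id = vid,
        cell_id = if (is.null(cell_ids)) NA else cell_ids[vi],
        frame = tr$frames,
        time_s = NA_real_,  # filled on write from the 0-based frame
        channel = names(tr$channels)[j],
        x_px = tr$positions$x, y_px = tr$positions$y,
        z_index = tr$positions$z,
        raw_mean = tr$raw_mean[, j],
        local_background = tr$local_background[, j],
        corrected = tr$corrected[, j],
        bleach_corrected = tr$bleach_corrected[, j],
        normalized = tr$normalized[, j],
        t0_frame = tr$t0_frame)
    }
  }
  do.call(rbind, rows)
}
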