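# Spot sizing (2D Gaussian FWHM), nuclear-distance statistics, and the
# sub-endosomal vector analysis of damage-marker versus LNP localization
# with its random null model.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))   # 2.3548...

#' Fit a 2D Gaussian to a single-spot ROI
#'
#' Nonlinear least squares of
#' `offset + A * exp(-((x-x0)^2 / (2 sx^2) + (y-y0)^2 / (2 sy^2)))`,
#' initialized from image moments. The FWHM is reported in nanometres from
#' the mean sigma: `fwhm_nm = 2 sqrt(2 ln 2) * mean(sx, sy) * pixel_size`.
#'
#' @param roi `[y, x]` matrix containing one dominant spot.
#' @param pixel_size_nm Pixel size for the nm conversion.
#' @return Object of class `SpotFit`: `x0, y0, sigma_x_px, sigma_y_px,
#'   sigma_x_nm, sigma_y_nm, amplitude, offset, fwhm_nm, converged`.
#'   Non-convergence is flagged, not an error.
#' @export
fit_gaussian2d <- function(roi, pixel_size_nm = 1) {
  h <- nrow(roi); w <- ncol(roi)
  off0 <- stats::median(roi)
  amp0 <- max(roi) - off0
  fail <- function() structure(list(x0 = NA, y0 = NA, sigma_x_px = NA,
                                    sigma_y_px = NA, sigma_x_nm = NA,
                                    sigma_y_nm = NA, amplitude = NA,
                                    offset = NA, fwhm_nm = NA,
                                    converged = FALSE), class = "SpotFit")
  if (amp0 <= 0 || stats::sd(roi) == 0) return(fail())
  wgt <- pmax(roi - off0, 0)
  ctr <- weighted_centroid(wgt)
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  v <- as.vector(roi)
  s0 <- sqrt(max(sum(wgt * ((ys - ctr["y"])^2 + (xs - ctr["x"])^2) / 2) /
                 sum(wgt), 0.25))
  df <- data.frame(v = v, x = xs, y = ys)
  fit <- try(minpack.lm::nlsLM(
    v ~ b + a * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))),
    data = df,
    start = list(b = off0, a = amp0, x0 = unname(ctr["x"]),
                 y0 = unname(ctr["y"]), sx = s0, sy = s0),
    lower = c(-Inf, 0, 1, 1, 0.1, 0.1),
    upper = c(Inf, Inf, w, h, w, h),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(fail())
  cf <- stats::coef(fit)
  if (cf["a"] <= 0 || cf["sx"] <= 0 || cf["sy"] <= 0) return(fail())
  ms <- mean(c(cf["sx"], cf["sy"]))
  structure(list(x0 = unname(cf["x0"]), y0 = unname(cf["y0"]),
                 sigma_x_px = unname(cf["sx"]), sigma_y_px = unname(cf["sy"]),
                 sigma_x_nm = unname(cf["sx"]) * pixel_size_nm,
                 sigma_y_nm = unname(cf["sy"]) * pixel_size_nm,
                 amplitude = unname(cf["a"]), offset = unname(cf["b"]),
                 fwhm_nm = FWHM_FACTOR * ms * pixel_size_nm,
                 converged = TRUE),
            class = "SpotFit")
}

#' Normalized distance of foci from the nucleus
#'
#' Per cell, the distance d of every focus (pooled across the compared
#' channels) from the nucleus centroid is normalized to the innermost and
#' outermost focus: `(d - d_min) / (d_max - d_min)`. Cells with fewer than
#' two foci, or with `d_max == d_min`, are excluded with a warning.
#'
#' @param foci Data frame `cell_id, channel, x, y`.
#' @param nuclei Data frame `cell_id, x, y` of nucleus centroids.
#' @return List `foci` (input plus `d`, `d_norm`) and `per_cell` (mean
#'   `d_norm` per cell and channel).
#' @export
nuclear_distance_normalized <- function(foci, nuclei) {
  out <- list(); skipped <- 0L
  for (cid in unique(foci$cell_id)) {
    f <- foci[foci$cell_id == cid, ]
    nu <- nuclei[nuclei$cell_id == cid, ]
    if (nrow(f) < 2 || nrow(nu) != 1) { skipped <- skipped + 1L; next }
    d <- sqrt((f$x - nu$x)^2 + (f$y - nu$y)^2)
    if (max(d) == min(d)) { skipped <- skipped + 1L; next }
    f$d <- d
    f$d_norm <- (d - min(d)) / (max(d) - min(d))
    out[[length(out) + 1]] <- f
  }
  if (skipped > 0)
    warning("nuclear_distance_normalized: ", skipped,
            " cell(s) excluded (fewer than 2 foci or degenerate range)")
  if (length(out) == 0)
    stop("nuclear_distance_normalized: no usable cells")
  all <- do.call(rbind, out)
  per_cell <- stats::aggregate(d_norm ~ cell_id + channel, all, mean)
  list(foci = all, per_cell = per_cell)
}

#' Centre of mass of an endosome
#'
#' Intensity-weighted centroid of the endosome-marker channel within the
#' mask; falls back to the binary mask centroid (with a warning) when the
#' total intensity is zero, or when weighting is disabled.
#'
#' @param mask Logical/0-1 matrix.
#' @param intensity `[y, x]` matrix (same shape), ignored if
#'   `weighted = FALSE`.
#' @param weighted Use intensity weighting (default TRUE).
#' @return `c(y, x)` centre.
#' @export
endosome_center <- function(mask, intensity = NULL, weighted = TRUE) {
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("endosome_center: empty mask")
  if (!weighted || is.null(intensity))
    return(weighted_centroid(matrix(1, nrow(mask), ncol(mask)), idx))
  if (sum(intensity[idx]) <= 0) {
    warning("endosome_center: zero total intensity; using binary centroid")
    return(weighted_centroid(matrix(1, nrow(mask), ncol(mask)), idx))
  }
  weighted_centroid(intensity, idx)
}

#' Local intensity maxima within an endosome mask
#'
#' Pixels that are 8-neighbourhood maxima inside the mask and above the
#' noise floor (default: mask median + 3 MAD), with equal-valued plateaus
#' resolved to their centroid, ranked by intensity, suppressed within
#' `min_separation_px`, and capped at `max_n`. Positions are refined to
#' sub-pixel precision by a 3x3 intensity-weighted centroid around the
#' peak.
#'
#' @param roi `[y, x]` intensity matrix.
#' @param mask Logical/0-1 matrix (same shape).
#' @param max_n Maximum number of maxima (default 3).
#' @param min_separation_px Non-maximum suppression radius.
#' @param floor Noise floor; default `median + 3 * mad` of the in-mask
#'   pixels.
#' @return Data frame `x, y, intensity` (possibly 0 rows), strongest first.
#' @export
find_local_maxima <- function(roi, mask, max_n = 3, min_separation_px = 4,
                              floor = NULL) {
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("find_local_maxima: empty mask")
  vals <- roi[idx]
  if (is.null(floor)) floor <- stats::median(vals) + 3 * stats::mad(vals)
  h <- nrow(roi); w <- ncol(roi)
  cand <- idx[vals > floor]
  if (length(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0)))
  # 8-neighbourhood non-strict maxima among candidates
  is_max <- vapply(cand, function(ii) {
    y <- (ii - 1L) %% h + 1L; x <- (ii - 1L) %/% h + 1L
    nb <- expand.grid(dy = -1:1, dx = -1:1)
    nb <- nb[!(nb$dy == 0 & nb$dx == 0), ]
    yy <- y + nb$dy; xx <- x + nb$dx
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    all(roi[ii] >= roi[cbind(yy[ok], xx[ok])])
  }, logical(1))
  peaks <- cand[is_max]
  if (length(peaks) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0)))
  # merge plateaus: group peak pixels of equal value closer than 1.9 px
  rc <- arrayInd(peaks, dim(roi))
  pv <- roi[peaks]
  groups <- label_point_clusters(rc, pv, link_dist = 1.9)
  plist <- lapply(unique(groups), function(g) {
    sel <- groups == g
    c(y = mean(rc[sel, 1]), x = mean(rc[sel, 2]), v = pv[sel][1])
  })
  pk <- do.call(rbind, plist)
  pk <- pk[order(-pk[, "v"]), , drop = FALSE]
  # non-maximum suppression
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      d <- sqrt((pk[(i + 1):nrow(pk), "y"] - pk[i, "y"])^2 +
                (pk[(i + 1):nrow(pk), "x"] - pk[i, "x"])^2)
      keep[(i + 1):nrow(pk)][d < min_separation_px] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE][seq_len(min(max_n, sum(keep))), ,
                                 drop = FALSE]
  # sub-pixel refinement: 3x3 background-subtracted weighted centroid
  # around the peak pixel (the in-mask median as baseline)
  baseline <- stats::median(vals)
  ref <- t(apply(pk, 1, function(p) {
    y <- round(p["y"]); x <- round(p["x"])
    ys <- max(1, y - 1):min(h, y + 1)
    xs <- max(1, x - 1):min(w, x + 1)
    wts <- pmax(roi[ys, xs, drop = FALSE] - baseline, 0)
    if (sum(wts) == 0) return(c(p["x"], p["y"], p["v"]))
    c(sum(outer(rep(1, length(ys)), xs) * wts) / sum(wts),
      sum(outer(ys, rep(1, length(xs))) * wts) / sum(wts),
      p["v"])
  }))
  data.frame(x = ref[, 1], y = ref[, 2], intensity = ref[, 3])
}

# Single-linkage clustering of peak pixels (used for plateau merging).
label_point_clusters <- function(rc, values, link_dist) {
  n <- nrow(rc)
  g <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (values[i] == values[j] &&
        sqrt(sum((rc[i, ] - rc[j, ])^2)) <= link_dist)
      g[g == g[j]] <- g[i]
  }
  g
}

#' Pair damage-marker and LNP maxima and measure their separation
#'
#' Vectors run from the endosome centre of mass to each local maximum. The
#' marker maxima are assigned to LNP maxima by exhaustive search over all
#' injective assignments (at most 3x3), minimizing the total angular
#' difference; the best one or two pairs (smallest angular difference) are
#' kept. The angular difference is folded to [0, 180] degrees; the
#' magnitude difference is `(|marker vector| - |LNP vector|) *
#' pixel_size_nm` (positive when the damage marker sits further from the
#' centre than the LNP).
#'
#' @param center `c(y, x)` endosome centre of mass.
#' @param marker_maxima,lnp_maxima Data frames `x, y` from
#'   [find_local_maxima()].
#' @param pixel_size_nm Pixel size.
#' @param max_pairs Pairs retained (default 2).
#' @return Data frame `marker_angle_deg, lnp_angle_deg,
#'   angular_difference_deg, magnitude_difference_nm`, best pairs first.
#' @export
pair_and_measure <- function(center, marker_maxima, lnp_maxima,
                             pixel_size_nm = 1, max_pairs = 2) {
  nm <- nrow(marker_maxima); nl <- nrow(lnp_maxima)
  if (nm == 0 || nl == 0)
    stop("pair_and_measure: need at least one maximum in each channel")
  ang <- function(df) atan2(df$y - center[["y"]],
                            df$x - center[["x"]]) * 180 / pi
  len <- function(df) sqrt((df$y - center[["y"]])^2 +
                           (df$x - center[["x"]])^2)
  ma <- ang(marker_maxima); la <- ang(lnp_maxima)
  mr <- len(marker_maxima); lr <- len(lnp_maxima)
  k <- min(nm, nl)
  small_is_marker <- nm <= nl
  ns <- min(nm, nl); nb <- max(nm, nl)
  perms <- all_injections(ns, nb)
  best <- NULL
  for (p in perms) {
    mi <- if (small_is_marker) seq_len(ns) else p
    li <- if (small_is_marker) p else seq_len(ns)
    tot <- sum(angular_difference(ma[mi], la[li]))
    if (is.null(best) || tot < best$tot)
      best <- list(tot = tot, mi = mi, li = li)
  }
  dd <- angular_difference(ma[best$mi], la[best$li])
  ord <- order(dd)[seq_len(min(max_pairs, k))]
  data.frame(marker_angle_deg = ma[best$mi][ord] %% 360,
             lnp_angle_deg = la[best$li][ord] %% 360,
             angular_difference_deg = dd[ord],
             magnitude_difference_nm =
               (mr[best$mi][ord] - lr[best$li][ord]) * pixel_size_nm)
}

# All injective maps of 1..ns into 1..nb as a list of index vectors.
all_injections <- function(ns, nb) {
  if (ns == 1) return(as.list(seq_len(nb)))
  out <- list()
  rec <- function(chosen) {
    if (length(chosen) == ns) {
      out[[length(out) + 1]] <<- chosen
      return()
    }
    for (j in setdiff(seq_len(nb), chosen)) rec(c(chosen, j))
  }
  rec(integer(0))
  out
}

#' Random-localization null for the angular difference
#'
#' Monte-Carlo model of angular differences expected if damage-marker and
#' LNP maxima were placed independently at random on the endosome:
#' `mode = "single"` draws one uniform angle per channel and folds the
#' difference to [0, 180] (mean 90 degrees); `mode = "dual_antipodal"`
#' places two antipodal maxima per channel at independent uniform
#' rotations and pairs each marker maximum with the nearest LNP maximum by
#' angular distance, giving matched differences in [0, 90] (mean 45
#' degrees).
#'
#' @param n_endosomes Number of simulated endosomes.
#' @param mode `"single"` or `"dual_antipodal"`.
#' @param rng_seed Seed.
#' @return List `mean`, `differences` (per pair), `n_pairs`.
#' @export
angular_null <- function(n_endosomes, mode = c("single", "dual_antipodal"),
                         rng_seed = 1L) {
  mode <- match.arg(mode)
  set.seed(rng_seed)
  a <- stats::runif(n_endosomes, 0, 360)
  b <- stats::runif(n_endosomes, 0, 360)
  if (mode == "single") {
    d <- angular_difference(a, b)
  } else {
    # two antipodal maxima per channel; nearest-angle pairing matches each
    # marker maximum to the closer of the two LNP maxima, so each pair
    # realizes min(delta, 180 - delta) for the rotation difference delta
    delta <- angular_difference(a, b)
    d <- rep(pmin(delta, 180 - delta), each = 2)
  }
  list(mean = mean(d), differences = d, n_pairs = length(d))
}

#' Analyze a simulated or measured endosome scene end to end
#'
#' For every endosome in the label mask: centre of mass from the membrane
#' channel, local maxima in the LNP and damage channels, minimal-angle
#' pairing and angular/magnitude measurement.
#'
#' @param stack 3-channel [image_stack()] (membrane, lnp, damage).
#' @param masks Endosome label matrix.
#' @param channels Named vector `c(membrane=, lnp=, damage=)`.
#' @param ... Passed to [find_local_maxima()].
#' @return Data frame of pairs with `endosome_id` column.
#' @export
analyze_endosome_scene <- function(stack, masks,
                                   channels = c(membrane = 1, lnp = 2,
                                                damage = 3), ...) {
  mem <- stack$data[channels[["membrane"]], 1, 1, , ]
  lnp <- stack$data[channels[["lnp"]], 1, 1, , ]
  dmg <- stack$data[channels[["damage"]], 1, 1, , ]
  out <- list()
  for (e in setdiff(sort(unique(as.vector(masks))), 0L)) {
    m <- masks == e
    ctr <- endosome_center(m, mem)
    mm <- find_local_maxima(dmg, m, ...)
    lm <- find_local_maxima(lnp, m, ...)
    if (nrow(mm) == 0 || nrow(lm) == 0) next
    pr <- pair_and_measure(ctr, mm, lm, stack$pixel_size_nm)
    pr$endosome_id <- e
    out[[length(out) + 1]] <- pr
  }
  if (length(out) == 0)
    stop("analyze_endosome_scene: no endosome yielded maxima in both channels")
  do.call(rbind, out)
}
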