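# Bead-based channel alignment and lateral chromatic-aberration correction.
# Channel alignment is an integer translation (1-pixel lateral, 1-z-interval
# axial accuracy) maximizing bead overlap; residual misalignment is modelled
# as a straight line in x and in y (fitted separately) and applied with
# 1-pixel accuracy.

#' Detect beads and measure weighted centroids
#'
#' Beads are segmented as pixels above `background + k_sigma * sd` on the
#' maximum z-projection, labelled with 8-connectivity, and localized as the
#' intensity-weighted centroid (background-subtracted) within a local
#' window, laterally and in z. Beads whose window clips the image border
#' are excluded (logged to stderr).
#'
#' @param stack An [image_stack()] of a bead field.
#' @param channel Channel to detect in.
#' @param k_sigma Detection threshold in robust background sigmas.
#' @param window_px Half-width of the centroid window.
#' @return Data frame `bead_id, x, y, z, intensity` (sub-pixel, 1-based).
#' @export
detect_beads <- function(stack, channel, k_sigma = 8, window_px = 5) {
  d <- dim(stack$data)
  nz <- d[3]
  proj <- apply(stack$data[channel, 1, , , , drop = FALSE], 4:5, max)
  bg <- stats::median(proj)
  sdev <- stats::mad(proj)
  if (sdev == 0) sdev <- max(stats::sd(proj), 1e-9)
  bw <- proj > bg + k_sigma * sdev
  lab <- label_components(bw)
  n <- max(lab)
  if (n == 0) stop("detect_beads: no beads detected in channel ", channel)
  out <- list()
  id <- 0L
  for (i in seq_len(n)) {
    idx <- which(lab == i)
    ctr <- round(weighted_centroid(proj - bg, idx))
    ys <- (ctr["y"] - window_px):(ctr["y"] + window_px)
    xs <- (ctr["x"] - window_px):(ctr["x"] + window_px)
    if (min(ys) < 1 || max(ys) > d[4] || min(xs) < 1 || max(xs) > d[5]) {
      message("detect_beads: bead near border at (",
              ctr["x"], ",", ctr["y"], ") excluded")
      next
    }
    w <- pmax(proj[ys, xs] - bg, 0)
    if (sum(w) <= 0) next
    cy <- sum(outer(ys, rep(1, length(xs))) * w) / sum(w)
    cx <- sum(outer(rep(1, length(ys)), xs) * w) / sum(w)
    # axial centroid from the in-window z intensity profile
    zprof <- vapply(seq_len(nz), function(z)
      sum(pmax(stack$data[channel, 1, z, ys, xs] - bg, 0)), numeric(1))
    cz <- if (sum(zprof) > 0) sum(seq_len(nz) * zprof) / sum(zprof) else NA
    id <- id + 1L
    out[[id]] <- data.frame(bead_id = id, x = cx, y = cy, z = cz,
                            intensity = sum(w))
  }
  if (id == 0) stop("detect_beads: all beads clipped at the border")
  do.call(rbind, out)
}

#' Integer translation maximizing bead overlap
#'
#' Finds the integer shift `(dx, dy, dz)` such that target beads minus the
#' shift best coincide with reference beads: the shift maximizing the number
#' of target beads within `match_radius` of some reference bead. Candidate
#' shifts are the rounded pairwise position differences. Ties are broken
#' toward the smallest squared shift magnitude, then lexicographically by
#' (dx, dy, dz). The returned shift is the displacement of the target
#' channel relative to the reference (target = reference + shift).
#'
#' @param ref,target Bead tables from [detect_beads()] (need `x, y, z`).
#' @param match_radius Lateral match radius in pixels.
#' @param max_shift Candidate shifts are clipped to this magnitude per axis.
#' @return Named integer vector `c(dx, dy, dz)`.
#' @export
fit_integer_shift <- function(ref, target, match_radius = 2.5,
                              max_shift = 15) {
  if (nrow(ref) < 3 || nrow(target) < 3)
    stop("fit_integer_shift: need at least 3 beads per channel")
  rz <- ifelse(is.na(ref$z), 0, ref$z)
  tz <- ifelse(is.na(target$z), 0, target$z)
  dx <- outer(target$x, ref$x, "-")
  dy <- outer(target$y, ref$y, "-")
  dz <- outer(tz, rz, "-")
  cand <- unique(data.frame(dx = round(as.vector(dx)),
                            dy = round(as.vector(dy)),
                            dz = round(as.vector(dz))))
  cand <- cand[abs(cand$dx) <= max_shift & abs(cand$dy) <= max_shift &
               abs(cand$dz) <= max_shift, , drop = FALSE]
  if (nrow(cand) == 0) stop("fit_integer_shift: no candidate shift matches")
  score <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    # target bead j matched if min over ref of shifted distance <= radius
    d2 <- (dx - cand$dx[i])^2 + (dy - cand$dy[i])^2 + (dz - cand$dz[i])^2
    score[i] <- sum(apply(d2, 1, min) <= match_radius^2)
  }
  best <- max(score)
  if (best == 0) stop("fit_integer_shift: no shift matches any bead")
  k <- which(score == best)
  mag <- cand$dx[k]^2 + cand$dy[k]^2 + cand$dz[k]^2
  k <- k[mag == min(mag)]
  k <- k[order(cand$dx[k], cand$dy[k], cand$dz[k])][1]
  c(dx = as.integer(cand$dx[k]), dy = as.integer(cand$dy[k]),
    dz = as.integer(cand$dz[k]))
}

# Mutual-nearest-neighbour bead matching (after removing the integer
# shift from the target). Returns index pairs.
match_beads <- function(ref, target, shift = c(dx = 0, dy = 0, dz = 0),
                        radius = 5) {
  tx <- target$x - shift[["dx"]]
  ty <- target$y - shift[["dy"]]
  d2 <- outer(ty, ref$y, "-")^2 + outer(tx, ref$x, "-")^2
  ti <- apply(d2, 1, which.min)           # nearest ref for each target
  ri <- apply(d2, 2, which.min)           # nearest target for each ref
  keep <- which(ri[ti] == seq_len(nrow(target)) &
                d2[cbind(seq_len(nrow(target)), ti)] <= radius^2)
  data.frame(target = keep, ref = ti[keep])
}

#' Fit the linear chromatic-aberration model
#'
#' After integer alignment, the residual displacement of each bead between
#' a channel and the reference is regressed on field position: a
#' least-squares line of residual dx versus x, and of residual dy versus y,
#' fitted separately. A degenerate position range fixes the slope at 0 with
#' the intercept at the mean residual (with a warning).
#'
#' @param positions Positions (x or y) of matched beads in the reference.
#' @param residuals Residual displacement along the same axis (target -
#'   reference, after integer-shift removal).
#' @return List `slope`, `intercept`.
#' @export
fit_chromatic_model <- function(positions, residuals) {
  if (length(positions) < 5)
    stop("fit_chromatic_model: need >= 5 beads spanning the field")
  if (stats::sd(positions) < 1e-8) {
    warning("fit_chromatic_model: degenerate position range; slope fixed at 0")
    return(list(slope = 0, intercept = mean(residuals)))
  }
  fit <- stats::lm(residuals ~ positions)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Fit the full alignment model from a bead field
#'
#' Per non-reference channel: integer shift by [fit_integer_shift()], then
#' the lateral chromatic line on the residuals of mutual-nearest-neighbour
#' matched beads.
#'
#' @param stack Bead-field [image_stack()].
#' @param reference_channel Reference channel index (default 1).
#' @param ... Passed to [detect_beads()].
#' @return An object of class `AlignmentModel`: per channel a list with
#'   `shift` (dx, dy, dz) and `chromatic` (x/y slope and intercept).
#' @export
fit_alignment_model <- function(stack, reference_channel = 1, ...) {
  nch <- dim(stack$data)[1]
  ref <- detect_beads(stack, reference_channel, ...)
  per_channel <- vector("list", nch)
  for (ch in seq_len(nch)) {
    if (ch == reference_channel) {
      per_channel[[ch]] <- list(shift = c(dx = 0L, dy = 0L, dz = 0L),
                                chromatic = list(
                                  x = list(slope = 0, intercept = 0),
                                  y = list(slope = 0, intercept = 0)))
      next
    }
    tgt <- detect_beads(stack, ch, ...)
    shift <- fit_integer_shift(ref, tgt)
    m <- match_beads(ref, tgt, shift)
    rx <- tgt$x[m$target] - shift[["dx"]] - ref$x[m$ref]
    ry <- tgt$y[m$target] - shift[["dy"]] - ref$y[m$ref]
    per_channel[[ch]] <- list(
      shift = shift,
      chromatic = list(x = fit_chromatic_model(ref$x[m$ref], rx),
                       y = fit_chromatic_model(ref$y[m$ref], ry)))
  }
  structure(list(reference_channel = reference_channel,
                 channels = per_channel),
            class = "AlignmentModel")
}

#' Apply an alignment model to a stack
#'
#' Each non-reference channel is resampled so that its content lands on the
#' reference grid: output pixel (y, x) takes the input pixel at
#' `(y + dy + round(slope_y * y + intercept_y),
#'   x + dx + round(slope_x * x + intercept_x))` in the same channel
#' (1-pixel accuracy; no interpolation), and z-planes are shifted by dz.
#' Out-of-field pixels are filled with 0. The reference channel is
#' unchanged.
#'
#' @param stack An [image_stack()].
#' @param model An `AlignmentModel` from [fit_alignment_model()].
#' @return Aligned [image_stack()].
#' @export
apply_alignment <- function(stack, model) {
  stopifnot(inherits(model, "AlignmentModel"))
  d <- dim(stack$data)
  if (length(model$channels) != d[1])
    stop("apply_alignment: model has ", length(model$channels),
         " channels, stack has ", d[1])
  out <- stack
  for (ch in seq_len(d[1])) {
    if (ch == model$reference_channel) next
    mc <- model$channels[[ch]]
    sx <- seq_len(d[5])
    sy <- seq_len(d[4])
    src_x <- sx + mc$shift[["dx"]] +
      round(mc$chromatic$x$slope * sx + mc$chromatic$x$intercept)
    src_y <- sy + mc$shift[["dy"]] +
      round(mc$chromatic$y$slope * sy + mc$chromatic$y$intercept)
    okx <- src_x >= 1 & src_x <= d[5]
    oky <- src_y >= 1 & src_y <= d[4]
    for (t in seq_len(d[2])) for (z in seq_len(d[3])) {
      src_z <- z + mc$shift[["dz"]]
      img <- matrix(0, d[4], d[5])
      if (src_z >= 1 && src_z <= d[3])
        img[oky, okx] <- stack$data[ch, t, src_z, src_y[oky], src_x[okx]]
      out$data[ch, t, z, , ] <- img
    }
  }
  out
}

#' Mean inter-channel bead centroid distance
#'
#' Summary used to verify that applying an alignment model reduces the mean
#' residual distance between matched bead centroids.
#' @param stack Bead-field stack.
#' @param reference_channel Reference channel.
#' @param ... Passed to [detect_beads()].
#' @return Mean lateral distance (px) over non-reference channels.
#' @export
bead_residual_distance <- function(stack, reference_channel = 1, ...) {
  nch <- dim(stack$data)[1]
  ref <- detect_beads(stack, reference_channel, ...)
  dists <- c()
  for (ch in setdiff(seq_len(nch), reference_channel)) {
    tgt <- detect_beads(stack, ch, ...)
    m <- match_beads(ref, tgt, radius = 20)
    dists <- c(dists, sqrt((tgt$x[m$target] - ref$x[m$ref])^2 +
                           (tgt$y[m$target] - ref$y[m$ref])^2))
  }
  mean(dists)
}

#' Serialize / restore an alignment model as structured text (YAML)
#' @param model AlignmentModel.
#' @param path File path.
#' @export
write_alignment_model <- function(model, path) {
  ser <- list(reference_channel = model$reference_channel,
              channels = lapply(model$channels, function(mc)
                list(shift = as.list(mc$shift), chromatic = mc$chromatic)))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_alignment_model
#' @export
read_alignment_model <- function(path) {
  ser <- yaml::read_yaml(path)
  chans <- lapply(ser$channels, function(mc)
    list(shift = c(dx = mc$shift$dx, dy = mc$shift$dy, dz = mc$shift$dz),
         chromatic = mc$chromatic))
  structure(list(reference_channel = ser$reference_channel,
                 channels = chans),
            class = "AlignmentModel")
}
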