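# Foci detection, per-cell counting, response normalization and
# object-based colocalization.

#' Enhance small bright foci
#'
#' Subtracts a median-filtered copy of the image from the raw image and
#' clamps at zero, removing smooth background (including gradients wider
#' than the kernel) while preserving foci smaller than the kernel.
#'
#' @param img `[y, x]` matrix.
#' @param median_kernel_px Odd kernel edge length (>= 3; default 9).
#' @return Enhanced matrix, same shape.
#' @export
enhance_foci <- function(img, median_kernel_px = 9) {
  if (median_kernel_px < 3 || median_kernel_px %% 2 != 1)
    stop("enhance_foci: kernel must be odd and >= 3")
  hi <- max(img, 1)
  med <- EBImage::medianFilter(img / hi, (median_kernel_px - 1) / 2) * hi
  pmax(img - med, 0)
}

#' Detect foci by intensity threshold and size gate
#'
#' Connected components (8-connectivity) of pixels strictly above
#' `intensity_threshold`, kept if their pixel area lies within
#' `size_range` (inclusive).
#'
#' @param img Enhanced `[y, x]` matrix (see [enhance_foci()]).
#' @param intensity_threshold Per-channel manual threshold.
#' @param size_range Length-2 vector, inclusive area gate in pixels.
#' @param cells Optional cell label matrix; each focus gets the label at
#'   its centroid pixel (0 outside any cell).
#' @param frame,channel Bookkeeping columns for the output.
#' @return FociTable data frame: `frame, channel, focus_id, x, y, area_px,
#'   total_intensity, cell_id`.
#' @export
detect_foci <- function(img, intensity_threshold, size_range = c(1, Inf),
                        cells = NULL, frame = 1L, channel = 1L) {
  lab <- label_components(img > intensity_threshold)
  n <- max(lab)
  rows <- list()
  fid <- 0L
  for (i in seq_len(n)) {
    idx <- which(lab == i)
    if (length(idx) < size_range[1] || length(idx) > size_range[2]) next
    ctr <- weighted_centroid(img, idx)
    fid <- fid + 1L
    cell <- if (is.null(cells)) 0L
            else cells[round(ctr["y"]), round(ctr["x"])]
    rows[[fid]] <- data.frame(frame = frame, channel = channel,
                              focus_id = fid,
                              x = unname(ctr["x"]), y = unname(ctr["y"]),
                              area_px = length(idx),
                              total_intensity = sum(img[idx]),
                              cell_id = cell)
  }
  if (fid == 0)
    return(data.frame(frame = integer(0), channel = integer(0),
                      focus_id = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0), total_intensity = numeric(0),
                      cell_id = integer(0)))
  do.call(rbind, rows)
}

#' Baseline-subtracted foci count per cell over time
#'
#' Foci counts per frame are divided by the number of cells identified in
#' the first frame; the mean per-cell count over the baseline frames is
#' subtracted from all later time points. Values are reported as computed
#' (slightly negative values are not clamped).
#'
#' @param foci FociTable rows across frames (one channel).
#' @param n_cells Number of cells in the first frame (> 0).
#' @param frames Frame indices to report (default all frames in `foci`).
#' @param baseline_frames Frames defining the baseline (default the first).
#' @return Data frame `frame, n_foci, per_cell, baseline_subtracted`.
#' @export
foci_per_cell <- function(foci, n_cells, frames = NULL,
                          baseline_frames = NULL) {
  if (n_cells <= 0) stop("foci_per_cell: no cells in the first frame")
  if (is.null(frames)) frames <- sort(unique(foci$frame))
  if (is.null(baseline_frames)) baseline_frames <- frames[1]
  counts <- vapply(frames, function(f) sum(foci$frame == f), numeric(1))
  per_cell <- counts / n_cells
  baseline <- mean(per_cell[frames %in% baseline_frames])
  data.frame(frame = frames, n_foci = counts, per_cell = per_cell,
             baseline_subtracted = per_cell - baseline)
}

#' Total foci intensity per cell per frame (LNP uptake)
#'
#' Sum of `total_intensity` over all foci in a frame divided by the number
#' of cells identified in the first frame.
#'
#' @inheritParams foci_per_cell
#' @return Data frame `frame, total_intensity, per_cell`.
#' @export
uptake_intensity <- function(foci, n_cells, frames = NULL) {
  if (n_cells <= 0) stop("uptake_intensity: no cells in the first frame")
  if (is.null(frames)) frames <- sort(unique(foci$frame))
  tot <- vapply(frames, function(f)
    sum(foci$total_intensity[foci$frame == f]), numeric(1))
  data.frame(frame = frames, total_intensity = tot,
             per_cell = tot / n_cells)
}

#' Normalize response series to the control maximum
#'
#' Every condition is divided by the maximum of the control series over the
#' experiment (so the control peaks at exactly 1).
#'
#' @param series Named list of numeric vectors (conditions).
#' @param control Numeric vector, the negative-control series.
#' @return Named list of normalized vectors.
#' @export
normalize_response <- function(series, control) {
  m <- max(control)
  if (!is.finite(m) || m <= 0)
    stop("normalize_response: control maximum must be positive")
  lapply(series, function(x) x / m)
}

#' Object colocalization after resizing foci to 5-px discs
#'
#' Each focus is replaced by a disc of `disc_diameter_px` centred at its
#' centroid (rounded to the pixel grid); a focus in A colocalizes if its
#' disc shares at least one pixel with the disc of any focus in B.
#'
#' @param fociA,fociB FociTable rows for one frame (need `x`, `y`).
#' @param disc_diameter_px Disc diameter (default 5).
#' @param dims Image dimensions `c(height, width)` used for rasterization;
#'   defaults to the bounding box of all centroids plus the disc radius.
#' @return List `n_colocalized`, `fraction`, `flags` (per A focus).
#' @export
colocalize_resized <- function(fociA, fociB, disc_diameter_px = 5,
                               dims = NULL) {
  if (nrow(fociA) == 0)
    return(list(n_colocalized = 0L, fraction = NaN, flags = logical(0)))
  off <- disc_offsets(disc_diameter_px)
  if (is.null(dims)) {
    r <- ceiling(disc_diameter_px / 2) + 1
    dims <- c(max(round(c(fociA$y, fociB$y))) + r,
              max(round(c(fociA$x, fociB$x))) + r)
  }
  bmask <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(fociB))) {
    yy <- round(fociB$y[i]) + off[, "dy"]
    xx <- round(fociB$x[i]) + off[, "dx"]
    ok <- yy >= 1 & yy <= dims[1] & xx >= 1 & xx <= dims[2]
    bmask[cbind(yy[ok], xx[ok])] <- TRUE
  }
  flags <- vapply(seq_len(nrow(fociA)), function(i) {
    px <- pixels_at(bmask, round(fociA$y[i]), round(fociA$x[i]), off)
    any(px)
  }, logical(1))
  list(n_colocalized = sum(flags), fraction = mean(flags), flags = flags)
}

#' Object colocalization by area-overlap fraction
#'
#' An object in label image A colocalizes if the pixels it shares with some
#' single object of label image B exceed `min_fraction` of the A-object's
#' area (strict inequality). The measure is asymmetric in A and B.
#'
#' @param labelsA,labelsB Integer label matrices of identical shape.
#' @param min_fraction Overlap threshold on the A-object area (default
#'   0.25, strict).
#' @return List `flags` (per A label), `fraction` (of A objects
#'   colocalizing), `n_A`.
#' @export
colocalize_overlap <- function(labelsA, labelsB, min_fraction = 0.25) {
  stopifnot(all(dim(labelsA) == dim(labelsB)))
  idsA <- setdiff(sort(unique(as.vector(labelsA))), 0L)
  if (length(idsA) == 0)
    return(list(flags = logical(0), fraction = NaN, n_A = 0L))
  flags <- vapply(idsA, function(a) {
    pix <- labelsA == a
    area <- sum(pix)
    partners <- labelsB[pix]
    partners <- partners[partners != 0]
    if (length(partners) == 0) return(FALSE)
    max(tabulate(partners)) / area > min_fraction
  }, logical(1))
  list(flags = stats::setNames(flags, idsA), fraction = mean(flags),
       n_A = length(idsA))
}

#' Global threshold segmentation of structures (Otsu)
#'
#' Configurable global threshold used where a manual structure threshold is
#' not available; Otsu's method on the image histogram by default.
#'
#' @param img `[y, x]` matrix.
#' @param method `"otsu"` or a numeric threshold.
#' @return Integer label matrix (8-connectivity).
#' @export
segment_structures <- function(img, method = "otsu") {
  thr <- if (is.numeric(method)) method
         else EBImage::otsu(EBImage::Image(img / max(img)),
                            range = c(0, 1)) * max(img)
  label_components(img > thr)
}
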