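# Image and table I/O. Image stacks travel as multi-page 16-bit TIFF with a
# YAML sidecar carrying the metadata (the sidecar, not TIFF tags, is
# authoritative: TIFF dialects disagree on where resolution metadata lives).

#' Construct an ImageStack
#'
#' The container for all pixel data in the package: a 5-dimensional array
#' ordered (channel, time, z, y, x) together with the physical metadata
#' needed to convert pixels to nanometres and frames to seconds. Singleton
#' axes are allowed; lower-dimensional input arrays are promoted by
#' prepending singleton axes (a plain `[y, x]` matrix becomes
#' `(1, 1, 1, y, x)`).
#'
#' @param data Numeric array with 2 to 5 dimensions; values must be
#'   non-negative. Axis order of a 5-D array is (c, t, z, y, x).
#' @param pixel_size_nm Lateral pixel size in nanometres (> 0).
#' @param z_step_nm Axial plane spacing in nanometres (> 0).
#' @param frame_interval_s Time between frames in seconds (> 0).
#' @param channel_names Character vector, one name per channel.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size_nm, z_step_nm = pixel_size_nm,
                        frame_interval_s = 1, channel_names = NULL) {
  if (is.null(dim(data))) dim(data) <- c(1L, length(data))
  nd <- length(dim(data))
  if (nd < 2 || nd > 5)
    stop("image_stack: data must have 2 to 5 dimensions, got ", nd)
  if (nd < 5) dim(data) <- c(rep(1L, 5 - nd), dim(data))
  if (any(data < 0)) stop("image_stack: intensities must be non-negative")
  for (v in c(pixel_size_nm, z_step_nm, frame_interval_s))
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stop("image_stack: metadata fields must be positive scalars")
  nc <- dim(data)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("image_stack: need ", nc, " channel names, got ", length(channel_names))
  structure(list(data = data,
                 pixel_size_nm = pixel_size_nm,
                 z_step_nm = z_step_nm,
                 frame_interval_s = frame_interval_s,
                 channel_names = channel_names),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d channel(s) x %d frame(s) x %d z x %d x %d px\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel %.1f nm, z-step %.1f nm, frame interval %.2f s\n",
              x$pixel_size_nm, x$z_step_nm, x$frame_interval_s))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

# Extract one 2-D [y, x] plane.
plane <- function(stack, channel, frame = 1, z = 1) {
  stack$data[channel, frame, z, , ]
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write an ImageStack to multi-page TIFF with a YAML sidecar
#'
#' Pages are written in (c, t, z) nesting order with z fastest. Pixel values
#' are rounded and clamped to the 16-bit range. The sidecar
#' (`<path>.yaml`) records array dimensions, axis order and physical
#' metadata and is required to read the stack back.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (ch in seq_len(d[1])) for (t in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    img <- pmin(pmax(round(stack$data[ch, t, z, , ]), 0), 65535)
    pages[[i]] <- img / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(axes = "ctzyx",
               shape = as.integer(d),
               pixel_size_nm = stack$pixel_size_nm,
               z_step_nm = stack$z_step_nm,
               frame_interval_s = stack$frame_interval_s,
               channel_names = as.list(stack$channel_names))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read an ImageStack written by [write_stack()]
#'
#' A bare multi-page TIFF without a sidecar is read as a single-channel,
#' single-z time series only if it has one page (promoted to shape
#' (1,1,1,H,W)); otherwise the sidecar is required because page order is
#' ambiguous.
#'
#' @param path TIFF path.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("read_stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("read_stack: cannot parse TIFF: ",
                                             conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    if (length(pages) == 1)
      return(image_stack(array(as.numeric(pages[[1]]),
                               c(1, 1, 1, dim(pages[[1]]))),
                         pixel_size_nm = 1))
    stop("read_stack: missing sidecar metadata file: ", sc)
  }
  meta <- yaml::read_yaml(sc)
  for (f in c("shape", "pixel_size_nm", "z_step_nm", "frame_interval_s"))
    if (is.null(meta[[f]]))
      stop("read_stack: sidecar is missing required field '", f, "'")
  d <- as.integer(meta$shape)
  if (length(pages) != prod(d[1:3]))
    stop("read_stack: TIFF has ", length(pages), " pages but sidecar declares ",
         prod(d[1:3]))
  data <- array(0, d)
  i <- 0L
  for (ch in seq_len(d[1])) for (t in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    data[ch, t, z, , ] <- pages[[i]]
  }
  image_stack(data, meta$pixel_size_nm, meta$z_step_nm, meta$frame_interval_s,
              unlist(meta$channel_names))
}

#' Read a label image (cell or nucleus masks)
#'
#' Accepts a 16-bit TIFF or an in-memory matrix of non-negative integers,
#' 0 denoting background. Labels are relabelled to contiguous integers in
#' raster order; the object count is attached as attribute `n`.
#'
#' @param x TIFF path or integer matrix.
#' @return Integer matrix with attribute `n` (number of labels).
#' @export
read_labels <- function(x) {
  if (is.character(x)) {
    img <- tiff::readTIFF(x, as.is = TRUE)
    if (is.list(img)) img <- img[[1]]
  } else img <- x
  if (any(img != round(img)) || any(img < 0))
    stop("read_labels: label image must contain non-negative integers")
  img <- matrix(as.integer(img), nrow(img), ncol(img))
  ids <- sort(setdiff(unique(as.vector(img)), 0L))
  out <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_along(ids)) out[img == ids[i]] <- i
  attr(out, "n") <- length(ids)
  out
}

#' Write a label image as 16-bit TIFF
#' @param labels Integer matrix (0 = background).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

# ---- tabular schemas ------------------------------------------------------
# All CSVs: comma-separated, '.' decimal, UTF-8, header required.
# Frames and pixel coordinates are 0-based in files (so that
# time_s = frame * frame_interval_s), 1-based in R objects.

trace_table_cols <- c("vesicle_id", "cell_id", "frame", "time_s", "channel",
                      "x_px", "y_px", "z_index", "raw_mean",
                      "local_background", "corrected", "bleach_corrected",
                      "normalized", "t0_frame")

#' Write per-vesicle trace measurements to CSV (TraceTable schema)
#'
#' Converts the package's 1-based frames and pixel coordinates to the
#' 0-based file convention and adds `time_s = frame * frame_interval_s`.
#'
#' @param traces Data frame with 1-based `frame`, `t0_frame`, `x_px`, `y_px`,
#'   `z_index` columns plus the measurement columns.
#' @param path Output CSV path.
#' @param frame_interval_s Frame interval used to compute `time_s`.
#' @export
write_trace_table <- function(traces, path, frame_interval_s) {
  out <- traces
  out$frame <- out$frame - 1L
  out$t0_frame <- out$t0_frame - 1L
  out$x_px <- out$x_px - 1
  out$y_px <- out$y_px - 1
  out$z_index <- out$z_index - 1L
  out$time_s <- out$frame * frame_interval_s
  out <- out[, trace_table_cols]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TraceTable CSV back into the 1-based R convention
#' @param path CSV path.
#' @export
read_trace_table <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  miss <- setdiff(trace_table_cols, names(x))
  if (length(miss))
    stop("read_trace_table: missing columns: ", paste(miss, collapse = ", "))
  x$frame <- x$frame + 1L
  x$t0_frame <- x$t0_frame + 1L
  x$x_px <- x$x_px + 1
  x$y_px <- x$y_px + 1
  x$z_index <- x$z_index + 1L
  x
}

#' Read/write a run configuration as YAML
#' @param config Named list.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
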