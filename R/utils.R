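# Shared low-level helpers: pixel masks, connected components, centroids.
# Convention used throughout the package: arrays are indexed [y, x] (row = y),
# positions are 1-based pixel centers, frames are 1-based. Exported CSV tables
# are 0-based (see write_trace_table()).

#' Integer pixel offsets of a discrete disc
#'
#' A pixel belongs to the disc if its centre lies strictly within `diameter/2`
#' of the disc centre (`<=` radius). Returned as a two-column matrix of
#' (dy, dx) offsets around the centre pixel.
#'
#' @param diameter Disc diameter in pixels.
#' @return Integer matrix with columns `dy`, `dx`.
#' @keywords internal
disc_offsets <- function(diameter) {
  r <- diameter / 2
  ri <- ceiling(r)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' Integer pixel offsets of an annulus
#'
#' Pixels whose centre distance d from the annulus centre satisfies
#' `r_inner <= d < r_inner + width`.
#' @keywords internal
annulus_offsets <- function(r_inner, width) {
  ro <- ceiling(r_inner + width)
  g <- expand.grid(dy = -ro:ro, dx = -ro:ro)
  d2 <- g$dy^2 + g$dx^2
  g <- g[d2 >= r_inner^2 & d2 < (r_inner + width)^2, , drop = FALSE]
  as.matrix(g)
}

# Values of img (a [y,x] matrix) at centre + offsets; offsets falling outside
# the image are dropped. Returns numeric vector (possibly length 0).
pixels_at <- function(img, y, x, offsets) {
  yy <- y + offsets[, "dy"]
  xx <- x + offsets[, "dx"]
  ok <- yy >= 1 & yy <= nrow(img) & xx >= 1 & xx <= ncol(img)
  img[cbind(yy[ok], xx[ok])]
}

#' Label connected components with 8-connectivity
#'
#' Two-pass union-find labelling of the foreground (non-zero pixels) of a
#' binary matrix. Labels are contiguous integers starting at 1, assigned in
#' raster order of first appearance.
#'
#' @param bw Logical or 0/1 numeric matrix.
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(bw) {
  bw <- bw != 0
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (ii in which(bw)) {          # foreground only, column-major order
    {
      y <- (ii - 1L) %% h + 1L
      x <- (ii - 1L) %/% h + 1L
      # already-labelled 8-neighbours (previous column fully, previous row in this column)
      nb <- integer(0)
      if (y > 1 && lab[y - 1, x] > 0) nb <- c(nb, lab[y - 1, x])
      if (x > 1) {
        if (lab[y, x - 1] > 0) nb <- c(nb, lab[y, x - 1])
        if (y > 1 && lab[y - 1, x - 1] > 0) nb <- c(nb, lab[y - 1, x - 1])
        if (y < h && lab[y + 1, x - 1] > 0) nb <- c(nb, lab[y + 1, x - 1])
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[y, x] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r0 <- min(roots)
        lab[y, x] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt == 0L) return(lab)
  # resolve and compact labels in raster order of first appearance
  roots <- vapply(seq_len(nxt), find, integer(1))
  pos <- which(lab > 0)            # increasing linear (column-major) order
  resolved <- roots[lab[pos]]
  ids <- unique(resolved)
  remap <- integer(nxt)
  remap[ids] <- seq_along(ids)
  lab[pos] <- remap[resolved]
  lab
}

# Intensity-weighted centroid of a [y,x] matrix over given linear indices
# (or the whole matrix). Returns c(y, x) in 1-based pixel-centre coordinates.
weighted_centroid <- function(img, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(img)
  w <- img[idx]
  rc <- arrayInd(idx, dim(img))
  if (sum(w) <= 0) stop("weighted_centroid: total intensity is not positive")
  c(y = sum(rc[, 1] * w) / sum(w), x = sum(rc[, 2] * w) / sum(w))
}

#' Fold an angular difference to [0, 180] degrees
#'
#' Symmetric circular difference between two directions given in degrees.
#' @param a,b Angles in degrees (any real values).
#' @return Difference in degrees within \[0, 180\].
#' @export
angular_difference <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Centred moving average with the window truncated to available samples at
# the edges (a length-5 series with an 11-frame window degenerates to the
# plain mean).
rolling_mean <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(x)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Distribution-free confidence interval of the median
#'
#' Order-statistic (binomial) interval: the interval runs from the
#' `qbinom(alpha/2, n, 1/2)`-th to the `qbinom(1 - alpha/2, n, 1/2) + 1`-th
#' order statistic. Coverage is at least the nominal level.
#'
#' @param x Numeric vector.
#' @param conf Confidence level (default 0.95).
#' @return List with `median`, `lower`, `upper`, `n`.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("median_ci: no finite values")
  alpha <- 1 - conf
  lo <- stats::qbinom(alpha / 2, n, 0.5)
  hi <- stats::qbinom(1 - alpha / 2, n, 0.5) + 1
  lo <- max(lo, 1); hi <- min(hi, n)
  list(median = stats::median(x), lower = x[lo], upper = x[hi], n = n)
}

# Derive a child seed below 2^31 from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 11 * as.numeric(stream)) %% 2147483629
}
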