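# Damage-event classification and cohort summaries: hit/no-hit (detectable
# RNA payload), fast release, release magnitude at ~10 s, endosomal-marker
# positivity against the per-cell 90th-percentile reference, and load/
# response subgrouping.

#' Classify fast initial RNA release
#'
#' A vesicle releases fast if its mean normalized RNA intensity ~2.2-30 s
#' after onset falls below the pre-onset mean (computed over ~2.2-30 s
#' before onset) minus one pre-onset standard deviation.
#'
#' @param trace A `TraceSeries` from [build_trace()] with an `rna` channel
#'   and a finite `t0_frame`.
#' @param window_s The assessment window in seconds (before and after t0).
#' @return List `flag, pre_mean, pre_sd, post_mean`.
#' @export
classify_fast_release <- function(trace, window_s = c(2.2, 30)) {
  stopifnot(inherits(trace, "TraceSeries"), !is.na(trace$t0_frame))
  dt <- trace$frame_interval_s
  j <- match("rna", names(trace$channels))
  pre <- intersect(window_frames(trace$t0_frame, dt, window_s[1],
                                 window_s[2], max(trace$frames), "pre"),
                   trace$frames)
  post <- intersect(window_frames(trace$t0_frame, dt, window_s[1],
                                  window_s[2], max(trace$frames), "post"),
                    trace$frames)
  if (length(pre) < 2 || length(post) < 2)
    stop("classify_fast_release: assessment window has fewer than 2 frames")
  y <- trace$normalized[, j]
  pre_v <- y[match(pre, trace$frames)]
  post_v <- y[match(post, trace$frames)]
  pre_mean <- mean(pre_v)
  pre_sd <- stats::sd(pre_v)      # sample sd (n - 1)
  post_mean <- mean(post_v)
  list(flag = post_mean < pre_mean - pre_sd,
       pre_mean = pre_mean, pre_sd = pre_sd, post_mean = post_mean)
}

#' Classify detectable RNA payload ("hit")
#'
#' A damaged vesicle is a hit if its pre-onset background-corrected mean RNA
#' intensity exceeds `detection_k` times the background noise sd at the
#' vesicle position (a k-sigma surrogate for visual detectability).
#'
#' @param trace A `TraceSeries` with an `rna` channel.
#' @param detection_k Detection threshold in noise sigmas (default 3).
#' @param window_s Pre-onset window in seconds.
#' @return Logical flag.
#' @export
classify_hit <- function(trace, detection_k = 3, window_s = c(3, 60)) {
  stopifnot(inherits(trace, "TraceSeries"))
  j <- match("rna", names(trace$channels))
  dt <- trace$frame_interval_s
  if (is.na(trace$t0_frame)) {
    pre <- trace$frames
  } else {
    pre <- intersect(window_frames(trace$t0_frame, dt, window_s[1],
                                   window_s[2], max(trace$frames), "pre"),
                     trace$frames)
  }
  if (length(pre) == 0) stop("classify_hit: empty pre-onset window")
  pre_mean <- mean(trace$corrected[match(pre, trace$frames), j])
  unname(pre_mean > detection_k * trace$bg_noise_sd[[j]])
}

#' Median release magnitude with order-statistic confidence interval
#'
#' The per-event drop is `1 - normalized RNA level` in the frame nearest
#' `at_time_s` after onset. The summary is the median drop with a
#' distribution-free 95% CI of the median; with fewer than 5 events only
#' the point estimate is returned (with a warning).
#'
#' @param drops Numeric vector of per-event drops (see
#'   [release_magnitude()]).
#' @param conf Confidence level.
#' @return List `median, lower, upper, n` (`lower`/`upper` NA if n < 5).
#' @export
release_magnitude_summary <- function(drops, conf = 0.95) {
  drops <- drops[is.finite(drops)]
  n <- length(drops)
  if (n == 0) stop("release_magnitude_summary: no events")
  if (n < 5) {
    warning("release_magnitude_summary: fewer than 5 events; CI omitted")
    return(list(median = stats::median(drops), lower = NA, upper = NA, n = n))
  }
  ci <- median_ci(drops, conf)
  list(median = ci$median, lower = ci$lower, upper = ci$upper, n = n)
}

#' Per-event release magnitude at ~10 s after onset
#' @param trace A `TraceSeries` with an `rna` channel and finite t0.
#' @param at_time_s Read-out time after onset (default 10 s).
#' @return `1 -` normalized level at the frame nearest `at_time_s`.
#' @export
release_magnitude <- function(trace, at_time_s = 10) {
  stopifnot(!is.na(trace$t0_frame))
  j <- match("rna", names(trace$channels))
  post <- trace$times_s > 0
  if (!any(post)) return(NA_real_)
  i <- which(post)[which.min(abs(trace$times_s[post] - at_time_s))]
  1 - trace$normalized[i, j]
}

#' Per-cell marker normalizer
#'
#' Linear model of the per-cell 90th-percentile compartment-marker
#' intensity over the acquisition, measured at its start and end, used for
#' time-dependent normalization of marker intensities.
#'
#' @param p90_start,p90_end The per-cell p90 at `t_start_s` / `t_end_s`.
#' @param t_start_s,t_end_s Acquisition start and end times (seconds).
#' @return Object of class `MarkerNormalizer` with `p90(t_s)`; construction
#'   fails if the interpolated p90 is not positive over the acquisition.
#' @export
marker_normalizer <- function(p90_start, p90_end, t_start_s, t_end_s) {
  slope <- (p90_end - p90_start) / (t_end_s - t_start_s)
  p90 <- function(t_s) p90_start + slope * (t_s - t_start_s)
  if (min(p90(t_start_s), p90(t_end_s)) <= 0)
    stop("marker_normalizer: p90 model is not positive over the acquisition")
  structure(list(p90 = p90, p90_start = p90_start, p90_end = p90_end,
                 t_start_s = t_start_s, t_end_s = t_end_s),
            class = "MarkerNormalizer")
}

#' Classify endosomal-marker positivity at damage onset
#'
#' The background-corrected marker intensity of the vesicle is divided by
#' the per-cell p90 reference at the measurement time; the vesicle is
#' marker positive if the mean of the five measurements centred on the
#' onset frame (an 11 s interval at 2.2 s frames) exceeds 0.5
#' (strict inequality).
#'
#' @param marker_values Background-corrected marker intensities, one per
#'   frame of the trace.
#' @param times_abs_s Absolute acquisition times of those frames (seconds).
#' @param t0_index Index (into `marker_values`) of the onset frame.
#' @param normalizer A [marker_normalizer()].
#' @param threshold Positivity threshold (default 0.5, strict).
#' @param half_width Measurements on each side of onset (default 2).
#' @return List `flag, normalized_mean, n_used`.
#' @export
classify_marker_positive <- function(marker_values, times_abs_s, t0_index,
                                     normalizer, threshold = 0.5,
                                     half_width = 2) {
  stopifnot(inherits(normalizer, "MarkerNormalizer"))
  idx <- (t0_index - half_width):(t0_index + half_width)
  if (min(idx) < 1 || max(idx) > length(marker_values))
    stop("classify_marker_positive: need ", 2 * half_width + 1,
         " measurements centred on onset")
  nv <- marker_values[idx] / normalizer$p90(times_abs_s[idx])
  m <- mean(nv)
  list(flag = m > threshold, normalized_mean = m,
       n_used = length(idx))
}

#' Tercile subgrouping by pre-damage RNA load
#'
#' Splits events into `n_groups` groups (default low/medium/high terciles)
#' on their pre-damage corrected intensity. Group boundaries are the
#' type-1 empirical quantiles; ties are assigned to the lower group. If all
#' loads are equal every event lands in the lowest group (with a warning).
#'
#' @param loads Numeric vector of pre-damage corrected intensities.
#' @param n_groups Number of groups.
#' @return Ordered factor with levels `low < medium < high` (or `g1..gk`).
#' @export
subgroup_by_load <- function(loads, n_groups = 3) {
  if (length(loads) < n_groups)
    stop("subgroup_by_load: need at least ", n_groups, " events")
  qs <- stats::quantile(loads, seq_len(n_groups - 1) / n_groups,
                        type = 1, names = FALSE)
  labels <- if (n_groups == 3) c("low", "medium", "high")
            else paste0("g", seq_len(n_groups))
  g <- rep(labels[n_groups], length(loads))
  for (i in rev(seq_len(n_groups - 1))) g[loads <= qs[i]] <- labels[i]
  if (length(unique(g)) == 1 && length(unique(loads)) == 1)
    warning("subgroup_by_load: all loads equal; all events in lowest group")
  factor(g, levels = labels, ordered = TRUE)
}

#' Median split of galectin response magnitude
#'
#' Weak/strong subgrouping of events by peak corrected damage-marker
#' intensity (median split; values at the median go to "weak").
#' @param magnitudes Peak corrected galectin/CHMP2A intensities.
#' @return Ordered factor `weak < strong`.
#' @export
subgroup_by_galectin <- function(magnitudes) {
  m <- stats::median(magnitudes)
  factor(ifelse(magnitudes <= m, "weak", "strong"),
         levels = c("weak", "strong"), ordered = TRUE)
}

#' Classify a set of traces into vesicle events
#'
#' Applies [classify_hit()], [classify_fast_release()] and
#' [release_magnitude()] to each trace; fast release and release magnitude
#' are only evaluated (and reported) for hits.
#'
#' @param traces Named list of `TraceSeries` objects (events, finite t0).
#' @param detection_k Payload detection threshold in noise sigmas.
#' @param at_time_s Release-magnitude readout time.
#' @return Data frame with one row per vesicle: `vesicle_id, hit,
#'   fast_release, pre_mean, pre_sd, post_mean, release_magnitude,
#'   galectin_magnitude`.
#' @export
classify_events <- function(traces, detection_k = 3, at_time_s = 10) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    hit <- classify_hit(tr, detection_k)
    fr <- list(flag = NA, pre_mean = NA_real_, pre_sd = NA_real_,
               post_mean = NA_real_)
    mag <- NA_real_
    if (hit) {
      fr <- classify_fast_release(tr)
      mag <- release_magnitude(tr, at_time_s)
    }
    gj <- match("damage", names(tr$channels))
    gmag <- if (is.na(gj)) NA_real_ else max(tr$corrected[, gj])
    data.frame(vesicle_id = names(traces)[i] %||% i,
               hit = hit, fast_release = isTRUE(fr$flag),
               pre_mean = fr$pre_mean, pre_sd = fr$pre_sd,
               post_mean = fr$post_mean, release_magnitude = mag,
               galectin_magnitude = gmag)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort summary of classified events
#'
#' @param events Data frame from [classify_events()].
#' @return List with `n`, `hit_rate` (fraction of damaged vesicles with
#'   detectable payload), `fast_release_fraction` (among hits),
#'   `release_magnitude` (median + 95% CI over fast-release events).
#' @export
summarize_events <- function(events) {
  hits <- events[events$hit, ]
  fast <- hits[hits$fast_release, ]
  mag <- if (nrow(fast) > 0)
    release_magnitude_summary(fast$release_magnitude)
  else list(median = NA, lower = NA, upper = NA, n = 0)
  list(n = nrow(events),
       hit_rate = mean(events$hit),
       fast_release_fraction = if (nrow(hits)) mean(hits$fast_release)
                               else NA_real_,
       release_magnitude = mag)
}
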