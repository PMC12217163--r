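# End-to-end drivers: quantify a (simulated or real) release experiment and
# assemble cohort-level event statistics.

#' Quantify and classify one release experiment
#'
#' Runs the measurement pipeline on every vesicle of an experiment: builds
#' reference traces (event-free vesicles) to fit the photobleaching model,
#' then background-corrects, bleach-corrects and normalizes each event
#' trace aligned to its onset, and classifies events (hit, fast release,
#' release magnitude).
#'
#' @param sim Result of [simulate_release_experiment()], or a list with the
#'   same structure (`stack`, `seeds`, and a `truth$vesicles` table with
#'   `vesicle_id`, `is_reference`, `t0_frame`).
#' @param spec A [mask_spec()].
#' @param detection_k Payload detection threshold in noise sigmas.
#' @param at_time_s Release-magnitude readout time (s after onset).
#' @param summarize Compute the cohort summary (disable when pooling
#'   events across experiments).
#' @return List with `traces` (events), `events` (classified table merged
#'   with cell ids), `summary` ([summarize_events()]), `bleach_k` (fitted
#'   rate, 1/s), `reference_traces`.
#' @export
analyze_release_experiment <- function(sim, spec = mask_spec(),
                                       detection_k = 3, at_time_s = 10,
                                       summarize = TRUE) {
  ves <- sim$truth$vesicles
  track_of <- function(v) sim$seeds[sim$seeds$vesicle_id == v, ]
  refs <- ves$vesicle_id[ves$is_reference]
  if (length(refs) >= 3) {
    ref_traces <- lapply(refs, function(v)
      build_trace(sim$stack, track_of(v), NA_integer_, spec,
                  channels = c(rna = 1)))
    bl <- fit_bleach_model(lapply(ref_traces, `[[`, "times_s"),
                           lapply(ref_traces, function(tr)
                             tr$corrected[, "rna"]))
  } else {
    ref_traces <- list()
    bl <- list(k = 0)
  }
  ev_ids <- ves$vesicle_id[!ves$is_reference]
  traces <- lapply(ev_ids, function(v)
    build_trace(sim$stack, track_of(v),
                ves$t0_frame[ves$vesicle_id == v], spec,
                channels = c(rna = 1, damage = 2),
                bleach_k = c(bl$k, 0)))
  names(traces) <- ev_ids
  events <- classify_events(traces, detection_k, at_time_s)
  events$cell_id <- ves$cell_id[match(as.integer(events$vesicle_id),
                                      ves$vesicle_id)]
  list(traces = traces, events = events,
       summary = if (summarize) summarize_events(events),
       bleach_k = bl$k, reference_traces = ref_traces)
}

#' Simulate and analyze a cohort of damage events
#'
#' Renders the cohort as independent fields (batches) so that arbitrarily
#' large cohorts fit in memory, analyzes each with
#' [analyze_release_experiment()], and pools the classified events.
#'
#' @param n_events Total number of damage events.
#' @param rng_seed Top-level seed; batch seeds derive from it.
#' @param config_args Named list of overrides passed to
#'   [simulation_config()].
#' @param spec A [mask_spec()].
#' @param detection_k,at_time_s Classification parameters.
#' @return List `events` (pooled table), `summary`, `truth` (pooled vesicle
#'   truth for the events), `n_batches`.
#' @export
run_release_cohort <- function(n_events, rng_seed = 1L,
                               config_args = list(), spec = mask_spec(),
                               detection_k = 3, at_time_s = 10) {
  base <- list(n_cells = 4L, n_vesicles_per_cell = 5L)
  base[names(config_args)] <- config_args
  per_batch <- base$n_cells * base$n_vesicles_per_cell
  n_batches <- ceiling(n_events / per_batch)
  ev <- list(); tr <- list()
  for (b in seq_len(n_batches)) {
    args <- base
    args$rng_seed <- derive_seed(rng_seed, b)
    cfg <- do.call(simulation_config, args)
    sim <- simulate_release_experiment(cfg)
    res <- analyze_release_experiment(sim, spec, detection_k, at_time_s,
                                      summarize = FALSE)
    res$events$vesicle_id <- paste0("b", b, "_", res$events$vesicle_id)
    t <- sim$truth$vesicles[!sim$truth$vesicles$is_reference, ]
    t$vesicle_id <- paste0("b", b, "_", t$vesicle_id)
    ev[[b]] <- res$events
    tr[[b]] <- t
  }
  events <- do.call(rbind, ev)[seq_len(n_events), ]
  truth <- do.call(rbind, tr)[seq_len(n_events), ]
  list(events = events, summary = summarize_events(events),
       truth = truth, n_batches = n_batches)
}
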