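test_that("fast release flags post-window means below pre mean minus one sd", {
  # pre values with mean 1.00, sd 0.05; post mean 0.70 -> flagged
  pre <- c(0.95, 1.05, 1.00, 0.95, 1.05, 1.00,
           0.95, 1.05, 1.00, 0.95, 1.05, 1.00, 1.00, 1.00)
  pre <- pre * (1 / mean(pre))
  pre <- 1 + (pre - 1) * (0.05 / sd(pre))
  mk <- function(post_level) fake_trace(c(rep(1, 6), pre, 1,
                                          rep(post_level, 20)),
                                        t0_frame = 21)
  r <- classify_fast_release(mk(0.70))
  expect_true(r$flag)
  expect_equal(r$pre_mean, 1, tolerance = 1e-9)
  expect_equal(r$pre_sd, 0.05, tolerance = 1e-9)
  expect_equal(r$post_mean, 0.70, tolerance = 1e-9)
  expect_false(classify_fast_release(mk(0.97))$flag)
  # boundary: post mean exactly at pre_mean - pre_sd is not flagged
  expect_false(classify_fast_release(mk(0.95))$flag)
  expect_error(classify_fast_release(fake_trace(rep(1, 4), t0_frame = 2)),
               "fewer than 2 frames")
})

test_that("fast-release classification is invariant to positive rescaling", {
  sim <- noisy_sim()
  v <- sim$truth$vesicles
  id <- v$vesicle_id[!v$is_reference & v$hit][1]
  track <- sim$seeds[sim$seeds$vesicle_id == id, ]
  t0 <- v$t0_frame[v$vesicle_id == id]
  scaled <- sim$stack
  # scale signal (not the additive offset) by 3: subtract background,
  # scale, add back
  scaled$data <- (scaled$data - 0) * 3
  tr1 <- build_trace(sim$stack, track, t0, channels = c(rna = 1))
  tr2 <- build_trace(scaled, track, t0, channels = c(rna = 1))
  expect_equal(classify_fast_release(tr2)$flag,
               classify_fast_release(tr1)$flag)
  expect_equal(tr2$normalized, tr1$normalized, tolerance = 1e-9)
})

test_that("payload detection separates RNA-free from RNA-loaded vesicles", {
  res <- noisy_analysis()
  sim <- noisy_sim()
  truth <- sim$truth$vesicles
  for (id in names(res$traces)) {
    expected <- truth$hit[truth$vesicle_id == as.integer(id)]
    expect_equal(classify_hit(res$traces[[id]]), expected,
                 info = paste("vesicle", id))
  }
  # raising the detection threshold can only lower the hit count
  hits_k3 <- sum(vapply(res$traces, classify_hit, logical(1),
                        detection_k = 3))
  hits_k10 <- sum(vapply(res$traces, classify_hit, logical(1),
                         detection_k = 10))
  hits_k100 <- sum(vapply(res$traces, classify_hit, logical(1),
                          detection_k = 100))
  expect_lte(hits_k10, hits_k3)
  expect_lte(hits_k100, hits_k10)
})

test_that("release-magnitude summaries use the order-statistic median CI", {
  s <- release_magnitude_summary(rep(0.24, 20))
  expect_equal(s$median, 0.24)
  expect_equal(s$lower, 0.24)
  expect_equal(s$upper, 0.24)
  expect_warning(s1 <- release_magnitude_summary(0.3), "CI omitted")
  expect_equal(s1$median, 0.3)
  expect_true(is.na(s1$lower))
  # the interval is the binomial order-statistic interval
  set.seed(4)
  x <- rnorm(41, 0.25, 0.05)
  s2 <- release_magnitude_summary(x)
  xs <- sort(x)
  lo <- qbinom(0.025, 41, 0.5); hi <- qbinom(0.975, 41, 0.5) + 1
  expect_equal(s2$lower, xs[lo])
  expect_equal(s2$upper, xs[hi])
})

test_that("marker positivity uses the per-cell p90 line with a strict 0.5 cut", {
  nm <- marker_normalizer(200, 400, 0, 3600)
  # p90(1800) = 300; raw 165 -> normalized 0.55 -> positive
  r <- classify_marker_positive(rep(165, 9), rep(1800, 9), 5, nm)
  expect_true(r$flag)
  expect_equal(r$normalized_mean, 0.55)
  expect_equal(r$n_used, 5)
  # all values exactly at threshold: strict inequality, not positive
  r2 <- classify_marker_positive(rep(150, 9), rep(1800, 9), 5, nm)
  expect_equal(r2$normalized_mean, 0.5)
  expect_false(r2$flag)
  r3 <- classify_marker_positive(rep(300, 9), rep(1800, 9), 5, nm)
  expect_true(r3$flag)
  expect_error(classify_marker_positive(rep(1, 3), rep(0, 3), 2, nm),
               "centred on onset")
  expect_error(marker_normalizer(100, -50, 0, 3600), "positive")
})

test_that("marker scoring recovers simulated compartment identity", {
  sim <- noisy_sim()
  truth <- sim$truth$vesicles
  cells <- sim$truth$cells
  # marker scoring applies to tracked RNA-positive vesicles (tracking and
  # mask fitting follow the RNA signal)
  ids <- truth$vesicle_id[!truth$is_reference & truth$hit]
  dt <- sim$stack$frame_interval_s
  correct <- 0
  for (id in ids) {
    v <- truth[truth$vesicle_id == id, ]
    track <- sim$seeds[sim$seeds$vesicle_id == id, ]
    tr <- build_trace(sim$stack, track, v$t0_frame,
                      channels = c(rna = 1, marker = 3))
    cc <- cells[cells$cell_id == v$cell_id, ]
    nm <- marker_normalizer(cc$p90_start, cc$p90_end, cc$t_start_s,
                            cc$t_end_s)
    r <- classify_marker_positive(tr$corrected[, "marker"],
                                  (tr$frames - 1) * dt,
                                  match(v$t0_frame, tr$frames), nm)
    correct <- correct + (r$flag == v$marker_positive)
  }
  expect_equal(correct, length(ids))
})

test_that("load subgrouping splits terciles with ties going low", {
  g <- subgroup_by_load(c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  expect_equal(as.character(g[1:3]), rep("low", 3))
  expect_warning(g2 <- subgroup_by_load(rep(5, 9)), "all events in lowest")
  expect_true(all(g2 == "low"))
  expect_error(subgroup_by_load(c(1, 2), 3), "at least 3")
  # galectin magnitude median split
  gal <- subgroup_by_galectin(c(1, 2, 3, 4))
  expect_equal(as.character(gal), c("weak", "weak", "strong", "strong"))
})

test_that("cohort estimates track configured truth on a small cohort", {
  coh <- run_release_cohort(60, rng_seed = 31,
                            config_args = list(n_frames = 60,
                                               height = 128, width = 64,
                                               n_cells = 2,
                                               n_vesicles_per_cell = 3,
                                               n_reference_per_cell = 2,
                                               onset_margin_frames = 20))
  expect_equal(nrow(coh$events), 60)
  # the classifier should reproduce the realized truth almost exactly;
  # compare against the truth draw rather than the configured rates
  expect_equal(coh$summary$hit_rate, mean(coh$truth$hit), tolerance = 0.05)
  truth_fast <- mean(coh$truth$fast_release[coh$truth$hit])
  expect_equal(coh$summary$fast_release_fraction, truth_fast,
               tolerance = 0.1)
  expect_equal(coh$summary$release_magnitude$median, 0.25, tolerance = 0.2)
})
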