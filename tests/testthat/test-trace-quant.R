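test_that("mask fitting finds the intensity maximum with deterministic ties", {
  spec <- mask_spec()
  # uniform image: mean is the constant, position stays at the seed
  st <- image_stack(array(42, c(1, 1, 1, 40, 40)), 100)
  f <- fit_mask(st, 1, 1, c(x = 20, y = 20, z = 1), spec)
  expect_equal(f$mean, 42)
  expect_equal(c(f$x, f$y), c(20, 20))
  # noiseless spot 2 px from the seed: refined position equals the result
  # of an independent exhaustive evaluation of all candidate positions
  img <- gaussian_image(40, 40, y0 = 22, x0 = 18, sigma = 1.3,
                        amplitude = 500, background = 10)
  st2 <- image_stack(array(img, c(1, 1, 1, 40, 40)), 100)
  f2 <- fit_mask(st2, 1, 1, c(x = 20, y = 20, z = 1), spec)
  off <- lnptrace:::disc_offsets(6)
  best <- c(NA, NA); bestv <- -Inf
  for (dx in -3:3) for (dy in -3:3) {
    v <- sum(lnptrace:::pixels_at(img, 20 + dy, 20 + dx, off))
    if (v > bestv) { bestv <- v; best <- c(20 + dx, 20 + dy) }
  }
  expect_equal(c(f2$x, f2$y), best)
  expect_equal(c(f2$x, f2$y), c(18, 22))
  # two equal maxima equidistant from the seed: deterministic winner with
  # the lexicographically smallest displacement
  img3 <- matrix(0, 40, 40)
  img3[20, 16] <- 100; img3[20, 24] <- 100
  st3 <- image_stack(array(img3, c(1, 1, 1, 40, 40)), 100)
  f3 <- fit_mask(st3, 1, 1, c(x = 20, y = 20, z = 1), spec)
  # either bright pixel sits exactly on the rim of a disc displaced by 1;
  # the lexicographically smaller dx = -1 wins deterministically
  expect_equal(c(f3$x, f3$y), c(19, 20))
  # border seeds are refused by name
  expect_error(fit_mask(st, 1, 1, c(x = 2, y = 20, z = 1), spec), "border")
})

test_that("mask fitting searches across z-planes", {
  arr <- array(0, c(1, 1, 3, 40, 40))
  for (z in 1:3)
    arr[1, 1, z, , ] <- gaussian_image(40, 40, 20, 20, 1.3,
                                       amplitude = c(100, 300, 200)[z])
  st <- image_stack(arr, 100)
  f <- fit_mask(st, 1, 1, c(x = 20, y = 20, z = 1), mask_spec())
  expect_equal(f$z, 2)
})

test_that("local background is the annulus median and resists bright spots", {
  spec <- mask_spec()
  img <- matrix(100, 60, 60)
  expect_equal(local_background(img, list(x = 30, y = 30), spec), 100)
  # a neighbouring spot covering < 50% of the ring does not move the median
  img2 <- lnptrace:::add_spot(img, 30, 42, 2, 5000)
  expect_equal(local_background(img2, list(x = 30, y = 30), spec), 100,
               tolerance = 1e-6)
  # ring pixels outside the image are excluded rather than fatal
  expect_equal(local_background(img, list(x = 5, y = 30), spec), 100)
  expect_error(local_background(matrix(1, 4, 4), list(x = 100, y = 100),
                                spec), "outside the image")
})

test_that("rolling background is a truncated centred mean", {
  expect_equal(rolling_background(rep(3, 20), 11), rep(3, 20))
  ramp <- 2 + 0.5 * (1:30)
  expect_equal(rolling_background(ramp, 11)[6:25], ramp[6:25])
  expect_equal(rolling_background(1:5, 11), rep(mean(1:5), 5))
})

test_that("bleach model recovers the decay constant and never unbleaches", {
  t <- lapply(1:3, function(i) seq(0, 150, by = 2.2))
  v <- lapply(t, function(tt) 800 * exp(-0.01 * tt))
  fit <- fit_bleach_model(t, v)
  expect_equal(fit$k, 0.01, tolerance = 1e-6)
  expect_equal(fit$correct(exp(-0.01 * 100), 100), 1, tolerance = 1e-6)
  # constant traces: k = 0, correction is the identity
  fit0 <- fit_bleach_model(t, lapply(t, function(tt) rep(5, length(tt))))
  expect_equal(fit0$k, 0, tolerance = 1e-9)
  expect_equal(fit0$correct(c(1, 2, 3), c(0, 50, 100)), c(1, 2, 3))
  # growing traces would need k < 0: clamped with a warning
  expect_warning(
    fitg <- fit_bleach_model(t, lapply(t, function(tt) exp(0.005 * tt))),
    "clamped")
  expect_equal(fitg$k, 0)
  # 2% multiplicative noise, 20 traces: k within 10%
  set.seed(12)
  tn <- lapply(1:20, function(i) seq(0, 150, by = 2.2))
  vn <- lapply(tn, function(tt)
    700 * exp(-0.005 * tt) * (1 + rnorm(length(tt), 0, 0.02)))
  fitn <- fit_bleach_model(tn, vn)
  expect_lt(abs(fitn$k - 0.005) / 0.005, 0.1)
  expect_error(fit_bleach_model(t[1:2], v[1:2]), ">= 3")
})

test_that("built traces are flat at 1 for non-releasing vesicles and step
           to the release level for fast ones", {
  sim <- clean_sim()
  ves <- sim$truth$vesicles
  spec <- mask_spec()
  for (i in which(!ves$is_reference & ves$hit)) {
    v <- ves[i, ]
    tr <- build_trace(sim$stack, sim$seeds[sim$seeds$vesicle_id ==
                                             v$vesicle_id, ],
                      v$t0_frame, spec, channels = c(rna = 1, damage = 2))
    pre <- tr$normalized[tr$times_s < 0, "rna"]
    expect_equal(mean(pre), 1, tolerance = 0.01)
    post <- tr$normalized[tr$times_s > 5, "rna"]
    level <- if (v$fast_release) 1 - v$release_magnitude else 1
    expect_equal(stats::median(post), level, tolerance = 0.01)
    # damage channel normalized to its maximum
    expect_equal(max(tr$normalized[, "damage"]), 1)
  }
})

test_that("trace times are aligned so the onset frame maps to zero", {
  sim <- clean_sim()
  v <- sim$truth$vesicles[!sim$truth$vesicles$is_reference, ][1, ]
  tr <- build_trace(sim$stack,
                    sim$seeds[sim$seeds$vesicle_id == v$vesicle_id, ],
                    v$t0_frame, channels = c(rna = 1))
  dt <- sim$stack$frame_interval_s
  expect_equal(tr$times_s, (tr$frames - v$t0_frame) * dt)
  expect_equal(tr$times_s[tr$frames == v$t0_frame], 0)
  expect_error(build_trace(sim$stack,
                           sim$seeds[sim$seeds$vesicle_id ==
                                       v$vesicle_id, ], 1),
               "strictly inside")
})

test_that("corrected traces are exactly invariant to a constant offset", {
  sim <- clean_sim()
  v <- sim$truth$vesicles[!sim$truth$vesicles$is_reference, ][2, ]
  track <- sim$seeds[sim$seeds$vesicle_id == v$vesicle_id, ]
  tr1 <- build_trace(sim$stack, track, v$t0_frame, channels = c(rna = 1))
  shifted <- sim$stack
  shifted$data <- shifted$data + 250
  tr2 <- build_trace(shifted, track, v$t0_frame, channels = c(rna = 1))
  expect_equal(tr2$corrected, tr1$corrected, tolerance = 1e-12)
})

test_that("window conversion rounds toward including more frames", {
  # 3-60 s at 2.2 s frames: nearest included frame is 1 back (2.2 s),
  # farthest is 28 back (61.6 s)
  fr <- lnptrace:::window_frames(50, 2.2, 3, 60, 100, "pre")
  expect_equal(range(50 - fr), c(1, 28))
  fr2 <- lnptrace:::window_frames(50, 2.2, 2.2, 30, 100, "post")
  expect_equal(range(fr2 - 50), c(1, 14))
  # clipped at the acquisition bounds
  fr3 <- lnptrace:::window_frames(10, 2.2, 3, 60, 100, "pre")
  expect_gte(min(fr3), 1)
})

test_that("known bleaching is undone by the fitted correction", {
  sim <- noisy_sim()
  res <- noisy_analysis()
  k_true <- sim$config$bleach_rate_per_s[1]
  expect_lt(abs(res$bleach_k - k_true) / k_true, 0.25)
  # a non-releasing hit, bleach-corrected, ends within 5% of its start
  ves <- sim$truth$vesicles
  ids <- ves$vesicle_id[!ves$is_reference & ves$hit & !ves$fast_release]
  for (v in ids) {
    tr <- res$traces[[as.character(v)]]
    y <- tr$normalized[, "rna"]
    n <- length(y)
    expect_equal(mean(y[(n - 4):n]), 1, tolerance = 0.05)
  }
})
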