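test_that("2D Gaussian fits report the exact FWHM-sigma relation", {
  roi <- gaussian_image(31, 31, 16, 16.4, sigma = 2.5, amplitude = 300,
                        background = 20)
  f <- fit_gaussian2d(roi, pixel_size_nm = 40)
  expect_true(f$converged)
  # sigma = 100 nm -> FWHM = 2 sqrt(2 ln 2) * 100 = 235.48 nm
  expect_equal(f$fwhm_nm, 2 * sqrt(2 * log(2)) * 100, tolerance = 1e-6)
  expect_equal(f$x0, 16.4, tolerance = 1e-6)
  expect_equal(f$offset, 20, tolerance = 1e-4)
  # the relation holds for every converged fit, whatever the shape
  set.seed(21)
  for (i in 1:5) {
    r2 <- gaussian_image(25, 25, runif(1, 10, 15), runif(1, 10, 15),
                         sigma = runif(1, 1.5, 4), amplitude = 200,
                         background = 10)
    g <- fit_gaussian2d(r2, pixel_size_nm = 9)
    expect_equal(g$fwhm_nm,
                 2 * sqrt(2 * log(2)) * 9 *
                   mean(c(g$sigma_x_px, g$sigma_y_px)),
                 tolerance = 1e-12)
  }
  expect_false(fit_gaussian2d(matrix(7, 21, 21))$converged)
})

test_that("FWHM is stable under Poisson noise at high amplitude", {
  set.seed(33)
  errs <- replicate(25, {
    clean <- gaussian_image(31, 31, 16, 16, sigma = 2.2, amplitude = 500,
                            background = 10)
    noisy <- matrix(rpois(length(clean), clean), 31, 31)
    fit_gaussian2d(noisy, pixel_size_nm = 9)$fwhm_nm
  })
  expect_lt(max(abs(errs - 2 * sqrt(2 * log(2)) * 2.2 * 9)) /
              (2 * sqrt(2 * log(2)) * 2.2 * 9), 0.05)
})

test_that("nuclear distances normalize to the innermost and outermost foci", {
  foci <- data.frame(cell_id = 1, channel = c(1, 1, 2),
                     x = c(2, 5, 8), y = 0)
  nuclei <- data.frame(cell_id = 1, x = 0, y = 0)
  r <- nuclear_distance_normalized(foci, nuclei)
  expect_equal(r$foci$d_norm, c(0, 0.5, 1))
  # single-focus cells are excluded with a warning
  f2 <- rbind(foci, data.frame(cell_id = 2, channel = 1, x = 3, y = 0))
  nu2 <- rbind(nuclei, data.frame(cell_id = 2, x = 0, y = 0))
  expect_warning(r2 <- nuclear_distance_normalized(f2, nu2), "excluded")
  expect_false(2 %in% r2$foci$cell_id)
  # a channel placed nearer the nucleus has the lower mean normalized
  # distance, recovered from the generator
  sim <- simulate_radial_foci(n_cells = 15, rng_seed = 9)
  rr <- nuclear_distance_normalized(sim$foci, sim$nuclei)
  m <- tapply(rr$per_cell$d_norm, rr$per_cell$channel, mean)
  expect_lt(m[["1"]], m[["2"]])
})

test_that("endosome centres follow intensity weighting", {
  # symmetric annulus: geometric centre
  sc <- simulate_endosome_scene(n_endosomes = 1, rng_seed = 2)
  m <- sc$masks == 1
  mem <- sc$stack$data[1, 1, 1, , ]
  ctr <- endosome_center(m, mem)
  expect_equal(unname(ctr["y"]), sc$truth$endosomes$cy[1], tolerance = 0.02)
  expect_equal(unname(ctr["x"]), sc$truth$endosomes$cx[1], tolerance = 0.02)
  # off-centre bright arc on a 9x9 mask pulls the weighted centroid
  mask <- matrix(1, 9, 9)
  inten <- matrix(1, 9, 9); inten[, 8:9] <- 50
  w <- endosome_center(mask, inten)
  expect_gt(w[["x"]], 6)
  unw <- endosome_center(mask, inten, weighted = FALSE)
  expect_equal(unname(unw), c(5, 5))
  expect_warning(z <- endosome_center(mask, inten * 0), "binary centroid")
  expect_equal(unname(z), c(5, 5))
  expect_error(endosome_center(matrix(0, 3, 3)), "empty mask")
})

test_that("local maxima are found at programmed angles and suppressed on
           uniform rings", {
  sc <- simulate_endosome_scene(n_endosomes = 1, lnp_angles = 0,
                                marker_angles = 160, antipodal = FALSE,
                                rng_seed = 4)
  m <- sc$masks == 1
  ctr <- c(y = sc$truth$endosomes$cy[1], x = sc$truth$endosomes$cx[1])
  mx <- find_local_maxima(sc$stack$data[2, 1, 1, , ], m)
  expect_equal(nrow(mx), 1)
  tr <- sc$truth$foci[sc$truth$foci$channel == 2, ]
  expect_lt(sqrt((mx$y - tr$y)^2 + (mx$x - tr$x)^2), 1)
  # uniform ring: no peak above the floor
  ring <- sc$stack$data[1, 1, 1, , ]
  expect_equal(nrow(find_local_maxima(ring, m, floor = max(ring) + 1)), 0)
  # two antipodal spots give two maxima ~180 degrees apart
  sc2 <- simulate_endosome_scene(n_endosomes = 1, lnp_angles = 30,
                                 antipodal = TRUE, rng_seed = 5)
  mx2 <- find_local_maxima(sc2$stack$data[2, 1, 1, , ], sc2$masks == 1)
  expect_equal(nrow(mx2), 2)
  a <- atan2(mx2$y - ctr[["y"]], mx2$x - ctr[["x"]]) * 180 / pi
  expect_equal(angular_difference(a[1], a[2]), 180, tolerance = 0.05)
})

test_that("pairing minimizes total angular difference like brute force", {
  ctr <- c(y = 0, x = 0)
  at <- function(deg, r = 10)
    data.frame(x = r * cos(deg * pi / 180), y = r * sin(deg * pi / 180))
  # circular fold: 350 vs 10 degrees differ by 20
  p <- pair_and_measure(ctr, at(350), at(10))
  expect_equal(p$angular_difference_deg, 20)
  # magnitude difference in nm: marker at 10 px, LNP at 8 px, 46 nm pixels
  p2 <- pair_and_measure(ctr, at(0, 10), at(0, 8), pixel_size_nm = 46)
  expect_equal(p2$magnitude_difference_nm, 92)
  expect_equal(p2$angular_difference_deg, 0)
  # {0, 180} vs {10, 170}: correct assignment totals 20, not 340
  p3 <- pair_and_measure(ctr, rbind(at(0), at(180)),
                         rbind(at(10), at(170)))
  expect_equal(sort(p3$angular_difference_deg), c(10, 10))
  # random <= 3x3 instances match an independent brute-force enumeration
  set.seed(77)
  for (rep in 1:20) {
    nm <- sample(1:3, 1); nl <- sample(1:3, 1)
    am <- runif(nm, 0, 360); al <- runif(nl, 0, 360)
    mm <- do.call(rbind, lapply(am, at))
    ll <- do.call(rbind, lapply(al, at))
    got <- pair_and_measure(ctr, mm, ll, max_pairs = min(nm, nl))
    # brute force: enumerate index tuples directly
    ns <- min(nm, nl); nb <- max(nm, nl)
    tuples <- expand.grid(rep(list(seq_len(nb)), ns))
    tuples <- tuples[apply(tuples, 1, function(r)
      length(unique(r)) == ns), , drop = FALSE]
    best <- Inf
    for (i in seq_len(nrow(tuples))) {
      idx <- as.integer(tuples[i, ])
      tot <- if (nm <= nl)
        sum(angular_difference(am, al[idx]))
      else sum(angular_difference(am[idx], al))
      best <- min(best, tot)
    }
    expect_equal(sum(got$angular_difference_deg), best, tolerance = 1e-9)
  }
  expect_error(pair_and_measure(ctr, at(0)[0, ], at(10)), "at least one")
})

test_that("angular differences are symmetric, folded, and triangle-bounded", {
  expect_equal(angular_difference(350, 10), 20)
  expect_equal(angular_difference(10, 350), 20)
  expect_equal(angular_difference(180, 180), 0)
  expect_equal(angular_difference(0, 90), 90)
  # enumerated example: {(0,90),(10,350),(180,180)} -> {90,20,0}
  d <- angular_difference(c(0, 10, 180), c(90, 350, 180))
  expect_equal(d, c(90, 20, 0))
  expect_equal(mean(d), 36.6667, tolerance = 1e-4)
  set.seed(13)
  for (i in 1:200) {
    u <- runif(3, 0, 720) - 360
    expect_gte(min(angular_difference(u[1], u[2])), 0)
    expect_lte(angular_difference(u[1], u[2]), 180)
    expect_lte(angular_difference(u[1], u[3]),
               angular_difference(u[1], u[2]) +
                 angular_difference(u[2], u[3]) + 1e-9)
  }
})

test_that("the random null gives 90 degrees for single and 45 for dual pairs", {
  n1 <- angular_null(20000, "single", rng_seed = 3)
  se1 <- stats::sd(n1$differences) / sqrt(length(n1$differences))
  expect_lt(abs(n1$mean - 90), 3 * se1)
  # uniformity of the folded difference on [0, 180]
  ks <- suppressWarnings(stats::ks.test(n1$differences,
                                        "punif", 0, 180)$statistic)
  expect_lt(ks, 0.02)
  n2 <- angular_null(20000, "dual_antipodal", rng_seed = 3)
  expect_true(all(n2$differences >= 0 & n2$differences <= 90))
  expect_equal(n2$n_pairs, 40000)
  se2 <- stats::sd(n2$differences) / sqrt(20000)   # pairs share a draw
  expect_lt(abs(n2$mean - 45), 3 * se2)
})

test_that("20-degree offset scenes are recovered end to end", {
  sc <- simulate_endosome_scene(n_endosomes = 36, angle_offset_deg = 20,
                                noise = TRUE, rng_seed = 6)
  g <- analyze_endosome_scene(sc$stack, sc$masks)
  expect_lt(abs(stats::median(g$angular_difference_deg) - 20), 3)
  expect_lte(max(table(g$endosome_id)), 2)
})
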