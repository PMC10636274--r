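# EIC extraction, smoothing, noise/baseline estimation, RT warping, peak
# matching and bound finding.

test_that("EIC extraction recovers the generated intensity trace", {
  run <- make_gaussian_run(apex_rt = 300, sigma = 4, apex = 1e6, mzs = 152.0)
  eic <- extract_eic(run, 152.0, tol = 0.01)
  rt <- seq(240, 360, by = 0.5)
  expect_equal(eic$rt, rt)
  expect_equal(eic$intensity, 1e6 * exp(-(rt - 300)^2 / 32), tolerance = 1e-12)
  # m/z far from any signal: all-zero EIC over the full scan count
  far <- extract_eic(run, 500.0, tol = 0.01)
  expect_length(far$intensity, length(rt))
  expect_true(all(far$intensity == 0))
  expect_error(extract_eic(run, 152.0, tol = 0.01, ms_level = 2,
                           precursor = 152.0), "no scans at MS level 2")
})

test_that("MS2 EICs select scans by precursor isolation window", {
  scans <- c(
    lapply(seq(0, 10, 0.5), function(t)
      ms_scan(t, c(84.04), c(100 + t), ms_level = 2, precursor_mz = 147.08,
              precursor_window = 0.7)),
    lapply(seq(0, 10, 0.5), function(t)
      ms_scan(t, c(84.04), c(9999), ms_level = 2, precursor_mz = 200.0,
              precursor_window = 0.7)))
  run <- ms_run(scans[order(vapply(scans, `[[`, 0, "rt"))])
  eic <- extract_eic(run, 84.04, tol = 0.01, ms_level = 2, precursor = 147.2)
  expect_length(eic$intensity, 21L)
  expect_true(all(eic$intensity < 1000))   # the 200-precursor scans excluded
})

test_that("Savitzky-Golay smoothing is exact on polynomials and matches the 7/3 kernel", {
  x <- seq_len(41)
  for (deg in 0:3) {
    y <- (x / 10)^deg * 5 + deg
    eic <- structure(list(rt = x, intensity = y, target_mz = 1, tol = 1),
                     class = "eic")
    sm <- smooth_eic(eic, window = 7L, order = 3L)
    expect_lt(max(abs(sm$intensity - y)), 1e-9)   # ends included
  }
  # interior points equal convolution with the published 7/3 coefficients
  set.seed(3)
  y <- dnorm(x, 20, 5) * 1e5 + rnorm(41, 0, 50)
  eic <- structure(list(rt = x, intensity = pmax(y, 0), target_mz = 1, tol = 1),
                   class = "eic")
  sm <- smooth_eic(eic, 7L, 3L)
  coefs <- c(-2, 3, 6, 7, 6, 3, -2) / 21
  manual <- vapply(4:38, function(i) sum(coefs * pmax(y, 0)[(i - 3):(i + 3)]), 0)
  expect_equal(sm$intensity[4:38], pmax(manual, 0), tolerance = 1e-9)
  # too-short EICs pass through with a warning
  short <- structure(list(rt = 1:5, intensity = rep(1, 5), target_mz = 1,
                          tol = 1), class = "eic")
  expect_warning(out <- smooth_eic(short, 7L, 3L), "shorter")
  expect_equal(out$intensity, rep(1, 5))
})

test_that("noise estimator is calibrated on Gaussian noise and ignores smooth peaks", {
  set.seed(1)
  y <- rnorm(1e4, 1000, 100)
  expect_equal(estimate_noise(y), 100, tolerance = 0.05)
  # pure smooth peak: noise estimate well under 1% of apex
  rt <- seq(0, 100, 0.5)
  peak <- 1e6 * exp(-(rt - 50)^2 / 50)
  expect_lt(estimate_noise(peak), 0.01 * 1e6)
  expect_equal(estimate_noise(rep(0, 100)), 0)
})

test_that("baseline recovers constant and drifting backgrounds", {
  expect_equal(estimate_baseline(rep(50, 100)), rep(50, 100))
  rt <- seq(0, 100, 0.5)
  n <- length(rt)
  peak <- 1e5 * exp(-(rt - 50)^2 / 18)
  expect_lt(max(estimate_baseline(peak)), 1e-3 * 1e5)
  drift <- 200 + 3 * rt
  est <- estimate_baseline(drift + peak)
  expect_equal(est[1], drift[1], tolerance = 0.1 * drift[1])
  expect_equal(est[n], drift[n], tolerance = 0.1 * drift[n])
  expect_true(all(est >= 0))
})

test_that("RT warp interpolates between anchors and extrapolates flat", {
  # anchors at the expected RTs: identity
  w0 <- warp_rt(c(100, 200), c(100, 200))
  expect_equal(w0(c(50, 150, 250)), c(50, 150, 250))
  # one anchor shifted +5 s: constant offset
  w1 <- warp_rt(100, 105)
  expect_equal(w1(c(50, 100, 300)), c(55, 105, 305))
  # two anchors (+2 s, +6 s): linear interpolation, flat beyond
  w2 <- warp_rt(c(100, 300), c(102, 306))
  expect_equal(w2(200), 204)      # halfway: offset (2+6)/2 = 4
  expect_equal(w2(150), 153)      # quarter: offset 3
  expect_equal(w2(50), 52)        # flat extrapolation on the left
  expect_equal(w2(400), 406)      # and on the right
  expect_warning(wid <- warp_rt(numeric(0), numeric(0)), "identity")
  expect_equal(wid(123), 123)
})

test_that("peak matching scores RT proximity against relative height", {
  m <- gln_c13_method(expected_rt = 300, rt_window = 30)
  t <- m$targets[[1]]
  rt <- seq(240, 360, 0.5)
  # two candidates: full height at delta-rt 5 s, half height at delta-rt 0
  two <- 1e6 * exp(-(rt - 305)^2 / 18) + 5e5 * exp(-(rt - 300)^2 / 18)
  run <- ms_run(lapply(seq_along(rt), function(i)
    ms_scan(rt[i], 147.07642, two[i])))
  cl <- build_cluster(run, target_ion("glutamine", formula = "C5H11N2O3",
                                      charge = 1, base_mz = 147.07642,
                                      tracers = tracer_spec("C", 13, 5),
                                      expected_rt = 300,
                                      isotopologues = 0L), m)
  apex <- match_peak(cl, expected_rt = 300, rt_window = 30, k = 3)
  # S(305) = exp(-25/450) * 1 = 0.946 beats S(300) = 0.5
  expect_equal(cl$composite$rt[apex], 305, tolerance = 0.75)
  # equal heights at 2 s and 20 s: the closer one wins
  two2 <- 1e6 * exp(-(rt - 302)^2 / 18) + 1e6 * exp(-(rt - 320)^2 / 18)
  run2 <- ms_run(lapply(seq_along(rt), function(i)
    ms_scan(rt[i], 147.07642, two2[i])))
  cl2 <- build_cluster(run2, cl$target, m)
  apex2 <- match_peak(cl2, expected_rt = 300, rt_window = 30, k = 3)
  expect_equal(cl2$composite$rt[apex2], 302, tolerance = 0.75)
  # no candidate above threshold: peak not found
  flat <- ms_run(lapply(seq_along(rt), function(i) ms_scan(rt[i], 147.07642, 0)))
  cl3 <- build_cluster(flat, cl$target, m)
  expect_true(is.na(match_peak(cl3, 300, 30, k = 3)))
})

test_that("matching is invariant to uniform intensity scaling", {
  m <- gln_c13_method()
  gs_x <- dbinom(0:5, 5, 0.2)
  sim1 <- simulate_run(truth_spec("glutamine", gs_x, apex_rt = 300,
                                  apex_intensity = 1e6), m, seed = 5)
  sim2 <- simulate_run(truth_spec("glutamine", gs_x, apex_rt = 300,
                                  apex_intensity = 137), m, seed = 5)
  cl1 <- build_cluster(sim1$run, m$targets[[1]], m)
  cl2 <- build_cluster(sim2$run, m$targets[[1]], m)
  expect_equal(match_peak(cl1), match_peak(cl2))
})

test_that("bounds are symmetric on symmetric peaks and capped on tailed ones", {
  m <- gln_c13_method()
  t <- target_ion("glutamine", formula = "C5H11N2O3", charge = 1,
                  base_mz = 147.07642, tracers = tracer_spec("C", 13, 5),
                  expected_rt = 300, isotopologues = 0L)
  run <- make_gaussian_run(apex_rt = 300, sigma = 4, apex = 1e6, mzs = 147.07642)
  cl <- build_cluster(run, t, m)
  apex <- match_peak(cl, 300, 30, k = 3)
  # noiseless: force a small positive threshold so the walk terminates
  cl$noise_level <- 1e-3 * 1e6
  b <- find_bounds(cl, apex, k = 3, asymmetry_cap = 10)
  expect_lte(abs((b$apex_index - b$left_index) - (b$right_index - b$apex_index)), 1L)
  # EMG with tau = 2 sigma: right tail much longer, capped at exactly 2x
  sim <- simulate_run(truth_spec("glutamine", c(1, rep(0, 5)), apex_rt = 300,
                                 sigma = 4, tau = 8, apex_intensity = 1e6),
                      gln_c13_method(), seed = 3)
  cl2 <- build_cluster(sim$run, gln_c13_method()$targets[[1]], gln_c13_method())
  apex2 <- match_peak(cl2)
  cl2$noise_level <- 1e-3 * 1e6
  raw <- find_bounds(cl2, apex2, k = 3, asymmetry_cap = 1e6)
  expect_gt((raw$right_index - raw$apex_index) /
            (raw$apex_index - raw$left_index), 2)
  capped <- find_bounds(cl2, apex2, k = 3, asymmetry_cap = 2)
  expect_equal(capped$right_index - capped$apex_index,
               2L * (capped$apex_index - capped$left_index))
})

test_that("bounds are monotone in k and capture a noiseless Gaussian's area", {
  m <- gln_c13_method()
  t <- target_ion("glutamine", formula = "C5H11N2O3", charge = 1,
                  base_mz = 147.07642, tracers = tracer_spec("C", 13, 5),
                  expected_rt = 300, isotopologues = 0L)
  run <- make_gaussian_run(apex_rt = 300, sigma = 4, apex = 1e6,
                           mzs = 147.07642, rt_range = c(200, 400))
  cl <- build_cluster(run, t, m)
  apex <- match_peak(cl, 300, 30, k = 3)
  cl$noise_level <- 1e-3 * 1e6     # declared noise floor: 0.1% of apex
  widths <- vapply(c(0.5, 1, 2, 3, 5, 8), function(k) {
    b <- find_bounds(cl, apex, k = k, asymmetry_cap = 10)
    b$right_index - b$left_index
  }, 0)
  expect_true(all(diff(widths) <= 0))
  b3 <- find_bounds(cl, apex, k = 3, asymmetry_cap = 10)
  area <- integrate_channel(cl$channel_eics[[1]], b3, subtract_baseline = FALSE)
  analytic <- 1e6 * 4 * sqrt(2 * pi) / 0.5    # full discrete sum, step 0.5 s
  expect_gt(area, 0.99 * analytic)
})
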