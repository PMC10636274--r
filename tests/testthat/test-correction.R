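# Natural-abundance distributions and correction matrices, checked against
# brute-force enumeration oracles.

test_that("single-atom and empty formulas reproduce the isotope table", {
  nd <- natural_distribution("C1")
  expect_equal(as.numeric(nd), c(0.9893, 0.0107))
  expect_equal(as.numeric(natural_distribution(integer(0))), 1)
  expect_error(natural_distribution(c(Zz = 2L)), "unknown element")
})

test_that("convolution equals brute-force enumeration for small formulas", {
  cases <- list(c(C = 6L, H = 12L, O = 6L),           # glucose
                c(C = 3L, N = 2L, S = 1L),
                c(H = 5L, O = 3L, S = 2L),
                c(C = 2L, H = 2L, N = 2L, O = 2L, S = 2L),
                c(S = 4L), c(O = 6L), c(C = 12L))
  for (f in cases) {
    oracle <- oracle_natural_distribution(f)
    got <- natural_distribution(f, max_shift = length(oracle) - 1L)
    expect_lt(max(abs(as.numeric(got) - oracle)), 1e-12)
  }
})

test_that("distribution sums to one and reports truncated tail mass", {
  f <- c(C = 40L, H = 60L, N = 10L, O = 20L, S = 2L)
  full <- natural_distribution(f)
  expect_equal(sum(full), 1, tolerance = 1e-9)
  expect_equal(attr(full, "tail_mass"), 0)
  trunc5 <- natural_distribution(f, max_shift = 5)
  expect_equal(sum(trunc5) + attr(trunc5, "tail_mass"), 1, tolerance = 1e-12)
  expect_gt(attr(trunc5, "tail_mass"), 0)
})

test_that("high-res single-tracer matrix on C2 matches the binomial expansion", {
  cm <- build_correction_matrix("C2", tracer_spec("C", 13, 2), "high_res_ms1")
  p <- 0.0107; q <- 0.9893
  expect_equal(unname(cm$matrix),
               matrix(c(q^2, 2 * q * p, p^2,
                        0,   q,         p,
                        0,   0,         1), 3, 3),
               tolerance = 1e-12)
})

test_that("zeroed heavy abundances give the identity matrix in every mode", {
  iso <- default_isotope_table()
  for (el in names(iso)) {
    iso[[el]]$abundance <- c(1, rep(0, nrow(iso[[el]]) - 1L))
  }
  tr <- tracer_spec("C", 13, 3)
  for (mode in c("low_res_ms1", "high_res_ms1")) {
    cm <- build_correction_matrix("C3H6O3", tr, mode, isotopes = iso)
    expect_equal(unname(cm$matrix), diag(4), tolerance = 1e-12)
  }
  dm <- build_dual_matrix("C3H6N2O3", tr, tracer_spec("N", 15, 2),
                          "high_res_ms1", isotopes = iso)
  expect_equal(unname(dm$matrix), diag(12), tolerance = 1e-12)
})

test_that("low-res matrices include non-tracer elements, high-res do not", {
  f <- "C5H11N2O3"   # glutamine [M+H]+
  tr <- tracer_spec("C", 13, 5)
  lo <- build_correction_matrix(f, tr, "low_res_ms1")
  hi <- build_correction_matrix(f, tr, "high_res_ms1")
  expect_gt(max(abs(lo$matrix - hi$matrix)), 1e-4)
  # column 0 of the low-res matrix is the full-formula natural distribution
  nd <- natural_distribution(f, max_shift = 5)
  expect_equal(unname(lo$matrix[, 1]), as.numeric(nd), tolerance = 1e-12)
  # column 0 of the high-res matrix is the carbon-only distribution
  ndC <- natural_distribution(c(C = 5L), max_shift = 5)
  expect_equal(unname(hi$matrix[, 1]), as.numeric(ndC), tolerance = 1e-12)
})

test_that("single-tracer matrices are lower-triangular in the channel order", {
  cases <- list(
    list(f = "C5H11N2O3", tr = tracer_spec("C", 13, 5)),
    list(f = "C6H13O9P",  tr = tracer_spec("H", 2, 4)),
    list(f = "C3H7NO2S",  tr = tracer_spec("S", 34, 1)),
    list(f = "C2H5O4",    tr = tracer_spec("O", 18, 3)))
  for (cs in cases) for (mode in c("low_res_ms1", "high_res_ms1")) {
    M <- build_correction_matrix(cs$f, cs$tr, mode)$matrix
    expect_true(all(M[upper.tri(M)] == 0))
    expect_true(all(M >= 0))
    expect_true(all(colSums(M) <= 1 + 1e-12))
  }
})

test_that("dual high-res matrix equals per-atom enumeration on C2N1", {
  dm <- build_dual_matrix(c(C = 2L, N = 1L), tracer_spec("C", 13, 2),
                          tracer_spec("N", 15, 1), "high_res_ms1")
  expect_equal(dim(dm$matrix), c(6L, 6L))
  expect_lt(max(abs(unname(dm$matrix) - oracle_dual_highres_c2n1())), 1e-12)
})

test_that("dual matrix with a zero-position tracer reduces to the single-tracer matrix", {
  f <- "C5H11N2O3"
  trC <- tracer_spec("C", 13, 5)
  trN0 <- tracer_spec("N", 15, 0)
  for (mode in c("high_res_ms1", "low_res_ms1")) {
    dm <- build_dual_matrix(f, trC, trN0, mode)
    sm <- build_correction_matrix(f, trC, mode)
    expect_equal(unname(dm$matrix), unname(sm$matrix), tolerance = 1e-12)
  }
})

test_that("unit-resolution isobaric dual channels error unless summing is declared", {
  f <- c(C = 2L, N = 1L)
  trC <- tracer_spec("C", 13, 2); trN <- tracer_spec("N", 15, 1)
  expect_error(build_dual_matrix(f, trC, trN, "low_res_ms1"), "isobaric")
  dm <- build_dual_matrix(f, trC, trN, "low_res_ms1", sum_isobaric = TRUE)
  expect_equal(nrow(dm$matrix), 4L)            # shifts 0,1,2,3
  expect_equal(dm$channel_shifts, 0:3)
  expect_true(all(colSums(dm$matrix) <= 1 + 1e-12))
})

test_that("tandem matrices are built from the product-ion formula", {
  tr <- tracer_spec("C", 13, 5)
  # product == precursor: identical to the MS1 matrix
  tm <- build_tandem_matrix("C5H11N2O3", "C5H11N2O3", tr, 5, "high_res_ms1")
  ms1 <- build_correction_matrix("C5H11N2O3", tr, "high_res_ms1")
  expect_equal(unname(tm$matrix), unname(ms1$matrix), tolerance = 1e-15)
  # high-res product C2 of precursor C5 equals the single-tracer matrix on C2
  tm2 <- build_tandem_matrix(c(C = 5L, H = 11L), c(C = 2L, H = 4L), tr, 2,
                             "high_res_ms1")
  sm2 <- build_correction_matrix(c(C = 2L, H = 4L), tracer_spec("C", 13, 2),
                                 "high_res_ms1")
  expect_equal(unname(tm2$matrix), unname(sm2$matrix), tolerance = 1e-15)
  # product retaining zero tracer atoms: 1x1 matrix of the natural M+0
  tm0 <- build_tandem_matrix("C5H11N2O3", "C2H4O1", tr, 0, "low_res_ms1")
  expect_equal(dim(tm0$matrix), c(1L, 1L))
  expect_equal(tm0$matrix[1, 1],
               as.numeric(natural_distribution("C2H4O1", max_shift = 0)),
               tolerance = 1e-15)
  expect_error(build_tandem_matrix("C5H11N2O3", "C6H4", tr, 2), "subformula")
})

test_that("correction inverts the forward model exactly on noiseless input", {
  gs <- glutamine_standards()
  cm <- correction_matrix_for(gs$method$targets[[1]], gs$method)
  # 30% U-labeled + 70% unlabeled glutamine, forward-simulated then inverted
  x <- 0.7 * gs$standards$unlabeled + 0.3 * gs$standards$u_c13_5
  raw <- as.numeric(cm$matrix %*% x)
  got <- correct_mid(raw / sum(raw), cm)
  expect_equal(got$flag, "ok")
  expect_lt(max(abs(got$fractions - x)), 1e-9)
  expect_lt(got$residual_norm, 1e-9)
  # exact column recovery and identity matrix behaviour
  got2 <- correct_mid(cm$matrix[, 4] / sum(cm$matrix[, 4]), cm)
  expect_lt(max(abs(got2$fractions - replace(numeric(18), 4, 1))), 1e-9)
  id <- build_correction_matrix("C2", tracer_spec("C", 13, 2), "high_res_ms1",
                                isotopes = local({
                                  iso <- default_isotope_table()
                                  iso$C$abundance <- c(1, 0)
                                  iso
                                }))
  expect_equal(correct_mid(c(0.2, 0.3, 0.5), id)$fractions, c(0.2, 0.3, 0.5))
})

test_that("round-trip recovery holds across random simplex vectors", {
  set.seed(42)
  m <- gln_c13_method()
  cm <- correction_matrix_for(m$targets[[1]], m)
  for (i in 1:25) {
    x <- stats::rexp(6); x <- x / sum(x)
    raw <- as.numeric(cm$matrix %*% x)
    got <- correct_mid(raw, cm)
    expect_lt(max(abs(got$fractions - x)), 1e-8)
    # invariance to scaling of the raw areas
    got_scaled <- correct_mid(raw * 1e7, cm)
    expect_equal(got$fractions, got_scaled$fractions, tolerance = 1e-10)
  }
})

test_that("correction is approximately unbiased under multiplicative noise", {
  set.seed(7)
  m <- gln_c13_method()
  cm <- correction_matrix_for(m$targets[[1]], m)
  x <- c(0.45, 0.2, 0.1, 0.05, 0.05, 0.15)
  raw <- as.numeric(cm$matrix %*% x)
  n <- 1000
  est <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    noisy <- raw * (1 + stats::rnorm(6, 0, 0.01))
    est[i, ] <- correct_mid(noisy, cm)$fractions
  }
  se <- apply(est, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(colMeans(est) - x) <= 3 * se + 1e-6))
})

test_that("ill-conditioned or invalid systems flag correction_failed", {
  M <- matrix(c(1, 1, 1, 1 + 1e-15), 2, 2)
  cm <- structure(list(matrix = M, mode = "high_res_ms1",
                       formula = c(C = 1L), tracers = list(),
                       channels = 0:1, channel_shifts = 0:1),
                  class = "correction_matrix")
  expect_equal(correct_mid(c(0.5, 0.5), cm)$flag, "correction_failed")
  good <- build_correction_matrix("C2", tracer_spec("C", 13, 2), "high_res_ms1")
  expect_error(correct_mid(c(1, 0), good), "matrix rows")
  expect_equal(correct_mid(c(NA, 0.5, 0.5), good)$flag, "correction_failed")
})
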