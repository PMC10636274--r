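# Group statistics, RMSE diagnostics, Welch comparisons and the CSV
# workbook export.

# Build a set of records by processing simulated replicate runs.
make_records <- function(xs, method, seeds = seq_along(xs), sigma_mult = 0,
                         ids = paste0("s", seq_along(xs))) {
  out <- list()
  for (i in seq_along(xs)) {
    sim <- simulate_run(truth_spec("glutamine", xs[[i]], apex_rt = 300,
                                   sigma_mult = sigma_mult),
                        method, seed = seeds[i])
    recs <- process_run(sim$run, method, sample_id = ids[i])
    out <- c(out, recs)
  }
  out
}

test_that("RMSE against the theoretical MID matches hand arithmetic", {
  # raw [1, 0] against theoretical [0.9893, 0.0107] on a single-carbon ion
  t <- target_ion("x", formula = c(C = 1L, H = 2L), charge = 1, base_mz = 15,
                  tracers = tracer_spec("C", 13, 1), expected_rt = 10)
  m <- ms_method(list(t))
  rec <- structure(list(target = t, sample_id = "s", raw_mid = c(1, 0),
                        flag = "ok"), class = "mid_record")
  expect_equal(rmse_vs_theoretical(rec, m),
               sqrt((0.0107^2 + 0.0107^2) / 2), tolerance = 1e-12)
  rec$raw_mid <- theoretical_mid(t, m)
  expect_equal(rmse_vs_theoretical(rec, m), 0)
  rec$raw_mid <- c(NA_real_, NA_real_)
  expect_true(is.na(rmse_vs_theoretical(rec, m)))
})

test_that("group summaries compute replicate means and SDs", {
  m <- gln_c13_method()
  x <- dbinom(0:5, 5, 0.25)
  recs <- make_records(list(x, x, x), m, sigma_mult = 0,
                       ids = c("a1", "a2", "b1"))
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     group = c("ctrl", "ctrl", "treat"),
                     time_point = c(0, 0, 0))
  gs <- summarize_groups(recs, meta)
  ctrl <- gs$mids[gs$mids$group == "ctrl", ]
  expect_equal(unique(ctrl$n), 2L)
  expect_equal(ctrl$sd, rep(0, 6), tolerance = 1e-12)   # identical replicates
  treat <- gs$mids[gs$mids$group == "treat", ]
  expect_equal(unique(treat$n), 1L)
  expect_true(all(is.na(treat$sd)))                      # single replicate
  # the mean MID is itself a valid MID
  expect_equal(sum(ctrl$mean), 1, tolerance = 1e-9)
  # hand-checked mean/sd on two diverging replicates
  r2 <- make_records(list(c(0.8, 0.2, 0, 0, 0, 0),
                          c(0.6, 0.4, 0, 0, 0, 0)), m, ids = c("a1", "a2"))
  gs2 <- summarize_groups(r2, data.frame(sample_id = c("a1", "a2"),
                                         group = "g", time_point = 0))
  m1 <- gs2$mids[gs2$mids$channel == "M+1", ]
  expect_equal(m1$mean, 0.3, tolerance = 1e-6)
  expect_equal(m1$sd, stats::sd(c(0.2, 0.4)), tolerance = 1e-6)
  expect_error(summarize_groups(recs, data.frame(sample_id = "zz", group = "g")),
               "without metadata")
})

test_that("Welch comparison matches stats::t.test and handles degenerate groups", {
  # random-data cross-check against the reference implementation
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
    w <- midquant:::.welch(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
  # frozen hand case: means 0.2 vs 0.4, sd 0.01, n = 3 each
  a <- c(0.19, 0.20, 0.21); b <- c(0.39, 0.40, 0.41)
  w <- midquant:::.welch(a, b)
  expect_equal(abs(w$t), 0.2 / (0.01 * sqrt(2 / 3)), tolerance = 1e-9)
  # identical groups: t = 0, p = 1 even at zero variance
  w0 <- midquant:::.welch(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(w0$t, 0); expect_equal(w0$p, 1)
})

test_that("group comparisons report adjusted per-channel statistics", {
  m <- gln_c13_method()
  xa <- dbinom(0:5, 5, 0.2); xb <- dbinom(0:5, 5, 0.4)
  recs <- make_records(list(xa, xa, xa, xb, xb, xb), m, sigma_mult = 0.02,
                       seeds = 1:6, ids = paste0("s", 1:6))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     group = rep(c("lo", "hi"), each = 3), time_point = 0)
  cmp <- compare_groups(recs, meta, list(c("lo", "hi")))
  chan <- cmp[!startsWith(cmp$quantity, "APE"), ]
  expect_equal(nrow(chan), 6L)
  expect_true(all(chan$n1 == 3 & chan$n2 == 3))
  expect_true(all(is.finite(chan$t)))
  # BH never decreases p-values and preserves their order top-to-bottom
  expect_true(all(chan$p_adj >= chan$p - 1e-15))
  expect_equal(chan$p_adj, stats::p.adjust(chan$p, "BH"))
  ape <- cmp[startsWith(cmp$quantity, "APE"), ]
  expect_equal(nrow(ape), 1L)
  expect_lt(ape$p, 0.01)       # enrichment clearly differs between groups
  # insufficient replicates are skipped with a note
  cmp2 <- compare_groups(recs[1:2], meta[1:2, ], list(c("lo", "hi")))
  expect_true(all(grepl("skipped", cmp2$note)))
})

test_that("workbook export mirrors records to CSV sheets and round-trips", {
  m <- gln_c13_method()
  x <- dbinom(0:5, 5, 0.3)
  recs <- make_records(list(c(1, 0, 0, 0, 0, 0), x), m, ids = c("ctrl", "lab"))
  meta <- data.frame(sample_id = c("ctrl", "lab"), group = c("c", "l"),
                     time_point = 0, is_unlabeled_control = c(TRUE, FALSE))
  dir <- file.path(tempdir(), "wb_test")
  export_workbook(recs, dir, m, meta = meta)
  wb <- read_workbook(dir)
  expect_setequal(names(wb),
                  c("MIDs", "APEs", "Abundances", "GroupStats",
                    "GroupStatsAPE", "QC"))
  # 2 samples x 1 target x 6 channels = 12 MID rows
  expect_equal(nrow(wb$MIDs), 12L)
  tab <- records_to_table(recs)
  expect_equal(wb$MIDs$corrected_mid, tab$corrected_mid, tolerance = 1e-12)
  expect_equal(wb$MIDs$area, tab$area, tolerance = 1e-12)
  # QC sheet covers the unlabeled control only, with near-zero RMSE
  expect_equal(wb$QC$sample_id, "ctrl")
  expect_lt(wb$QC$rmse_vs_theoretical, 1e-6)
  # no metadata: no group sheets
  dir2 <- file.path(tempdir(), "wb_test2")
  export_workbook(recs, dir2, m)
  expect_setequal(names(read_workbook(dir2)), c("MIDs", "APEs", "Abundances"))
})
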