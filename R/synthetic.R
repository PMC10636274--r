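# Ground-truth synthetic runs: chromatographic peaks with Gaussian or
# exponentially-modified-Gaussian shapes, isotopologue ratios generated by
# the same forward model the corrector inverts, baseline drift and
# multiplicative + additive noise, written as valid mzML with a truth table.

#' Ground-truth specification for one synthetic target
#'
#' @param compound compound name; must match a target in the method.
#' @param label_distribution true fractional label distribution over the
#'   target's quantified label states (simplex; length = number of
#'   channels in method order).
#' @param apex_rt apex retention time, seconds (defaults to the target's
#'   expected RT at simulation time).
#' @param sigma Gaussian width, seconds.
#' @param tau exponential tail constant, seconds; 0 gives a pure Gaussian,
#'   \code{2 * sigma} a markedly tailed peak.
#' @param apex_intensity composite apex intensity, counts.
#' @param baseline constant baseline, counts.
#' @param drift linear baseline drift, counts/second.
#' @param sigma_add additive noise SD, counts.
#' @param sigma_mult multiplicative noise SD, fraction of signal.
#' @return Object of class \code{truth_spec}.
#' @export
truth_spec <- function(compound, label_distribution, apex_rt = NULL,
                       sigma = 4, tau = 0, apex_intensity = 1e6,
                       baseline = 0, drift = 0, sigma_add = 0,
                       sigma_mult = 0) {
  label_distribution <- as.numeric(label_distribution)
  if (any(label_distribution < 0) || abs(sum(label_distribution) - 1) > 1e-9)
    stop("label_distribution must be a simplex vector (non-negative, sum 1)")
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau < 0 || apex_intensity < 0 || baseline < 0 ||
      sigma_add < 0 || sigma_mult < 0)
    stop("tau, intensities and noise parameters must be non-negative")
  structure(list(compound = compound, label_distribution = label_distribution,
                 apex_rt = apex_rt, sigma = sigma, tau = tau,
                 apex_intensity = apex_intensity, baseline = baseline,
                 drift = drift, sigma_add = sigma_add,
                 sigma_mult = sigma_mult),
            class = "truth_spec")
}

# Unit-apex peak shape on an RT grid: Gaussian, or EMG when tau > 0.
.peak_shape <- function(rt, apex_rt, sigma, tau) {
  if (tau <= 0) return(exp(-(rt - apex_rt)^2 / (2 * sigma^2)))
  z <- (sigma / tau - (rt - apex_rt) / sigma) / sqrt(2)
  h <- exp(0.5 * (sigma / tau)^2 - (rt - apex_rt) / tau) * pracma::erfc(z)
  h[!is.finite(h)] <- 0
  h / max(h)
}

#' Forward model: observable MID of a label distribution
#'
#' \code{M x} with the correction module's matrix for the target, normalized
#' over the tracked channels. The generator and the corrector share this one
#' forward model.
#'
#' @param x true fractional label distribution (simplex over label states).
#' @param target a [target_ion()].
#' @param method an [ms_method()].
#' @return Observable MID over the target's quantified channels (sums to 1).
#' @export
forward_mid <- function(x, target, method) {
  cm <- correction_matrix_for(target, method)
  if (length(x) != ncol(cm$matrix))
    stop("label distribution length ", length(x), " != ", ncol(cm$matrix),
         " label states")
  obs <- as.numeric(cm$matrix %*% x)
  obs / sum(obs)
}

#' Simulate a labeled-run mzML file with ground truth
#'
#' Builds a scan grid at fixed RT spacing; each isotopologue channel's
#' chromatographic trace is \code{shape * apex * observable-MID fraction +
#' baseline + drift + noise} (noise: \code{y * (1 + N(0, sigma_mult)) +
#' N(0, sigma_add)}, clamped at zero), with peaks placed at the
#' isotopologue m/z values from the method. Deterministic under a fixed
#' seed. A truth table records every generated label distribution,
#' observable MID and noiseless area.
#'
#' @param truths list of [truth_spec()] (or a single one).
#' @param method an [ms_method()] containing the named compounds.
#' @param path output mzML path, or \code{NULL} to return the run in memory
#'   only.
#' @param seed RNG seed (integer).
#' @param rt_step scan spacing, seconds.
#' @param rt_range optional \code{c(min, max)} RT coverage, seconds.
#' @param compression mzML binary compression ("zlib" or "none").
#' @return List: \code{run} ([ms_run()]), \code{truth} (data frame),
#'   \code{path}, \code{truth_path} (CSV next to the mzML, when written).
#' @export
simulate_run <- function(truths, method, path = NULL, seed = 1L,
                         rt_step = 0.5, rt_range = NULL,
                         compression = "zlib") {
  if (inherits(truths, "truth_spec")) truths <- list(truths)
  stopifnot(inherits(method, "ms_method"), length(truths) >= 1)
  set.seed(as.integer(seed))
  comp_names <- vapply(method$targets, `[[`, "", "compound")
  plan <- lapply(truths, function(tr) {
    idx <- which(comp_names == tr$compound)
    if (!length(idx)) stop("truth compound '", tr$compound, "' not in method")
    lapply(idx, function(i) {
      target <- method$targets[[i]]
      if (is.null(tr$apex_rt)) tr$apex_rt <- target$expected_rt
      list(truth = tr, target = target,
           obs_mid = forward_mid(tr$label_distribution, target, method),
           mzs = channel_mzs(target))
    })
  })
  plan <- unlist(plan, recursive = FALSE)

  if (is.null(rt_range)) {
    lo <- min(vapply(plan, function(p) p$truth$apex_rt - 6 * p$truth$sigma -
                       4 * p$truth$tau - 15, 0))
    hi <- max(vapply(plan, function(p) p$truth$apex_rt + 6 * p$truth$sigma +
                       8 * p$truth$tau + 15, 0))
    rt_range <- c(max(0, lo), hi)
  }
  rt <- seq(rt_range[1], rt_range[2], by = rt_step)

  # warn on targets whose channels collide in both RT and m/z
  for (i in seq_along(plan)) for (j in seq_len(i - 1L)) {
    pi <- plan[[i]]; pj <- plan[[j]]
    if (abs(pi$truth$apex_rt - pj$truth$apex_rt) <
        2 * (pi$truth$sigma + pj$truth$sigma)) {
      tol <- 2 * max(mz_halfwindow(method, max(pi$mzs)),
                     mz_halfwindow(method, max(pj$mzs)))
      if (min(abs(outer(pi$mzs, pj$mzs, `-`))) < tol)
        warning("targets '", pi$target$compound, "' and '", pj$target$compound,
                "' overlap in both RT and m/z")
    }
  }

  traces <- lapply(plan, function(p) {
    shape <- .peak_shape(rt, p$truth$apex_rt, p$truth$sigma, p$truth$tau)
    clean <- outer(shape, p$truth$apex_intensity * p$obs_mid)
    base <- p$truth$baseline + p$truth$drift * (rt - rt[1])
    noisy <- clean + base
    if (p$truth$sigma_mult > 0)
      noisy <- noisy * (1 + matrix(stats::rnorm(length(noisy), 0, p$truth$sigma_mult),
                                   nrow(noisy)))
    if (p$truth$sigma_add > 0)
      noisy <- noisy + matrix(stats::rnorm(length(noisy), 0, p$truth$sigma_add),
                              nrow(noisy))
    list(clean = clean, noisy = pmax(noisy, 0))
  })

  groups <- vapply(plan, function(p)
    paste0("ms", p$target$ms_level, "@", p$target$precursor_mz %||% ""), "")
  scans <- list()
  for (g in unique(groups)) {
    members <- which(groups == g)
    lev <- plan[[members[1]]]$target$ms_level
    prec <- plan[[members[1]]]$target$precursor_mz
    for (si in seq_along(rt)) {
      mzv <- unlist(lapply(members, function(m) plan[[m]]$mzs))
      iv <- unlist(lapply(members, function(m) traces[[m]]$noisy[si, ]))
      iv <- as.numeric(rowsum(iv, mzv))          # merge coincident channels
      mzv <- sort(unique(mzv))
      scans[[length(scans) + 1L]] <- ms_scan(
        rt = rt[si], mz = mzv, intensity = iv, ms_level = lev,
        precursor_mz = prec,
        precursor_window = if (lev >= 2L) 0.7 else NULL,
        polarity = "positive", centroided = TRUE)
    }
  }
  ord <- order(vapply(scans, `[[`, 0, "rt"),
               vapply(scans, `[[`, 1L, "ms_level"))
  run <- ms_run(scans[ord], source_path = path %||% "<synthetic>")

  truth <- do.call(rbind, lapply(seq_along(plan), function(i) {
    p <- plan[[i]]
    labs <- channel_labels(p$target)
    x_by_channel <- p$truth$label_distribution
    data.frame(compound = p$target$compound, ion = p$target$ion,
               channel = labs, mz = p$mzs,
               true_label_fraction = x_by_channel,
               observable_mid = p$obs_mid,
               apex_rt = p$truth$apex_rt,
               apex_intensity = p$truth$apex_intensity * p$obs_mid,
               true_area = colSums(traces[[i]]$clean),
               stringsAsFactors = FALSE)
  }))

  truth_path <- NULL
  if (!is.null(path)) {
    write_run(run, path, compression = compression)
    truth_path <- paste0(path, ".truth.csv")
    utils::write.csv(truth, truth_path, row.names = FALSE)
  }
  list(run = run, truth = truth, path = path, truth_path = truth_path)
}

#' Glutamine standards method and truth set
#'
#' A ready-made validation suite emulating a dilution series of glutamine
#' standards measured as [M+H]+ on a high-resolution instrument with a
#' dual-tracer (13C5 + 15N2) channel layout: unlabeled, [1-13C],
#' [1,2-13C2], [15N2] and [U-13C5] species.
#'
#' @param expected_rt apex RT of the glutamine peak, seconds.
#' @param rt_window RT search half-window, seconds.
#' @return List: \code{method} ([ms_method()] with the single glutamine
#'   target) and \code{standards} (named list of true label distributions
#'   over the 18 (c, n) channels).
#' @export
glutamine_standards <- function(expected_rt = 300, rt_window = 30) {
  target <- target_ion(
    compound = "glutamine", ion = "[M+H]+", formula = "C5H11N2O3",
    charge = 1, base_mz = 147.07642,
    tracers = list(tracer_spec("C", 13, 5), tracer_spec("N", 15, 2)),
    expected_rt = expected_rt, rt_window = rt_window)
  method <- ms_method(list(target), resolution_mode = "high_res")
  ch <- target$isotopologues   # (c, n) pairs, row-major, carbon outer
  unit <- function(c13, n15) {
    x <- numeric(nrow(ch))
    x[ch[, 1] == c13 & ch[, 2] == n15] <- 1
    x
  }
  standards <- list(
    unlabeled    = unit(0, 0),
    c13_1        = unit(1, 0),   # [1-13C]
    c13_12       = unit(2, 0),   # [1,2-13C2]
    n15_2        = unit(0, 2),   # [15N2]
    u_c13_5      = unit(5, 0))   # [U-13C5]
  list(method = method, standards = standards)
}
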