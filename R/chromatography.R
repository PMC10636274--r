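# EIC extraction, RT warping, smoothing, noise/baseline estimation,
# composite-peak matching and shared integration bounds.

#' Extract an ion chromatogram
#'
#' One intensity point per scan of the requested MS level: the sum of
#' centroided peak intensities within \code{mz +/- tol}. Scans with no
#' in-window signal contribute 0. Profile scans are centroided on the fly.
#' For MS2, only scans whose precursor lies within its isolation window of
#' the requested precursor are used.
#'
#' @param run an [ms_run()].
#' @param mz target m/z.
#' @param tol absolute half-window, Th (resolve ppm upstream).
#' @param ms_level scan level to extract from.
#' @param precursor required precursor m/z for \code{ms_level = 2}.
#' @return Object of class \code{eic}: \code{rt}, \code{intensity},
#'   \code{target_mz}, \code{tol}.
#' @export
extract_eic <- function(run, mz, tol, ms_level = 1L, precursor = NULL) {
  stopifnot(inherits(run, "ms_run"), tol > 0)
  sel <- vapply(run$scans, function(s) {
    if (s$ms_level != ms_level) return(FALSE)
    if (ms_level >= 2L) {
      if (is.null(precursor)) stop("MS2 extraction requires a precursor m/z")
      w <- s$precursor_window %||% 0.7
      return(abs(s$precursor_mz - precursor) <= w)
    }
    TRUE
  }, TRUE)
  if (!any(sel)) stop("no scans at MS level ", ms_level,
                      if (ms_level >= 2L) paste0(" with precursor ", precursor) else "")
  scans <- run$scans[sel]
  inten <- vapply(scans, function(s) {
    if (!s$centroided) s <- centroid_profile_scan(s)
    lo <- findInterval(mz - tol, s$mz) + 1L
    hi <- findInterval(mz + tol, s$mz)
    if (hi < lo) 0 else sum(s$intensity[lo:hi])
  }, 0)
  structure(list(rt = vapply(scans, `[[`, 0, "rt"), intensity = inten,
                 target_mz = mz, tol = tol),
            class = "eic")
}

#' @export
print.eic <- function(x, ...) {
  cat(sprintf("<eic> m/z %.4f ± %.4g, %d points, RT %.1f-%.1f s, max %.3g\n",
              x$target_mz, x$tol, length(x$rt), min(x$rt), max(x$rt),
              max(x$intensity)))
  invisible(x)
}

#' Savitzky-Golay smoothing of an EIC
#'
#' Least-squares polynomial smoothing; reproduces polynomial signals of
#' degree <= \code{order} exactly (including the window ends, which are
#' handled by polynomial fits on the truncated windows). Negative outputs are
#' clamped to zero. An EIC shorter than the window is returned unchanged with
#' a warning.
#'
#' @param eic an [extract_eic()] result.
#' @param window odd window length in scans, greater than \code{order}.
#' @param order polynomial order.
#' @return Smoothed \code{eic}.
#' @export
smooth_eic <- function(eic, window = 7L, order = 3L) {
  window <- as.integer(window); order <- as.integer(order)
  stopifnot(window %% 2L == 1L, window > order)
  if (length(eic$intensity) < window) {
    warning("EIC shorter than the smoothing window; returned unsmoothed")
    return(eic)
  }
  eic$intensity <- pmax(signal::sgolayfilt(eic$intensity, p = order, n = window), 0)
  eic
}

#' Robust chromatographic noise estimate
#'
#' Noise scale from the median absolute successive difference of the raw
#' (unsmoothed) intensities: \code{1.4826 * median(|diff(y)|) / sqrt(2)}.
#' The successive difference cancels the (slow) peak and baseline signal, so
#' no peak-free region needs to be identified; the 1.4826/sqrt(2) factor
#' makes the estimate consistent for the standard deviation of i.i.d.
#' Gaussian noise.
#'
#' @param eic an EIC (raw, not smoothed).
#' @return Non-negative noise level in intensity units.
#' @export
estimate_noise <- function(eic) {
  y <- if (inherits(eic, "eic")) eic$intensity else as.numeric(eic)
  if (length(y) < 2L) return(0)
  1.4826 * stats::median(abs(diff(y))) / sqrt(2)
}

#' Linear baseline estimate
#'
#' Straight line through the minimum smoothed intensity in the leading 10%
#' and in the trailing 10% of the EIC window (at the positions of those
#' minima), extended linearly to the ends and clamped at zero.
#'
#' @param eic an EIC (conventionally the smoothed composite).
#' @return Numeric baseline, same length as the EIC.
#' @export
estimate_baseline <- function(eic) {
  y <- if (inherits(eic, "eic")) eic$intensity else as.numeric(eic)
  n <- length(y)
  if (n < 3L) return(rep(min(y), n))
  m <- max(2L, ceiling(0.1 * n))
  i1 <- which.min(y[1:m])
  i2 <- n - m + which.min(y[(n - m + 1L):n])
  if (i2 == i1) return(rep(y[i1], n))
  slope <- (y[i2] - y[i1]) / (i2 - i1)
  pmax(y[i1] + slope * (seq_len(n) - i1), 0)
}

#' Retention-time warp from characteristic-ion anchors
#'
#' Piecewise-linear correction mapping expected to observed RT, anchored at
#' the matched apexes of characteristic ions and extrapolated flat (constant
#' offset) beyond the outermost anchors. With a single anchor the warp is a
#' constant offset; with none it is the identity (with a warning).
#'
#' @param expected_rts,observed_rts anchor RT pairs, seconds.
#' @return A function: expected RT -> warped (observed-frame) RT.
#' @export
warp_rt <- function(expected_rts, observed_rts) {
  ok <- is.finite(expected_rts) & is.finite(observed_rts)
  expected_rts <- expected_rts[ok]; observed_rts <- observed_rts[ok]
  if (length(expected_rts) == 0L) {
    warning("no RT anchors matched; using identity warp")
    return(function(rt) rt)
  }
  ord <- order(expected_rts)
  e <- expected_rts[ord]; offs <- (observed_rts - expected_rts)[ord]
  if (anyDuplicated(e)) {
    offs <- as.numeric(tapply(offs, e, mean))
    e <- sort(unique(e))
  }
  if (length(e) == 1L) return(function(rt) rt + offs)
  function(rt) rt + stats::approx(e, offs, xout = rt, rule = 2)$y
}

#' Build the isotopic cluster for a target ion
#'
#' Extracts one EIC per quantified isotopologue (all channels come from the
#' same scan set, so they share the RT grid by construction), sums them into
#' the composite trace, smooths the composite, and estimates its noise level
#' and baseline.
#'
#' @param run an [ms_run()].
#' @param target a [target_ion()].
#' @param method an [ms_method()].
#' @return Object of class \code{isotopic_cluster}: \code{target},
#'   \code{channel_eics}, \code{composite}, \code{smoothed_composite},
#'   \code{noise_level}, \code{baseline}.
#' @export
build_cluster <- function(run, target, method) {
  mzs <- channel_mzs(target)
  eics <- lapply(mzs, function(m)
    extract_eic(run, m, mz_halfwindow(method, m), ms_level = target$ms_level,
                precursor = target$precursor_mz))
  comp <- eics[[1]]
  comp$target_mz <- NA_real_
  comp$intensity <- Reduce(`+`, lapply(eics, `[[`, "intensity"))
  sm <- suppressWarnings(smooth_eic(comp, method$smoothing_window,
                                    method$smoothing_order))
  structure(list(target = target, channel_eics = eics, composite = comp,
                 smoothed_composite = sm,
                 noise_level = estimate_noise(comp),
                 baseline = estimate_baseline(sm)),
            class = "isotopic_cluster")
}

#' @export
print.isotopic_cluster <- function(x, ...) {
  cat(sprintf("<isotopic_cluster> %s/%s: %d channels x %d points, noise %.3g\n",
              x$target$compound, x$target$ion, length(x$channel_eics),
              length(x$composite$rt), x$noise_level))
  invisible(x)
}

# Interior local maxima of a numeric vector (plateaus report their last
# point).
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y > c(y[-1L], Inf) & y >= c(-Inf, y[-n]))
}

#' Match the chromatographic peak of an isotopic cluster
#'
#' Probabilistic peak assignment on the smoothed composite trace. Candidate
#' apexes are the local maxima within \code{expected_rt +/- rt_window} that
#' rise above \code{baseline + k * noise}. Each candidate is scored
#' \deqn{S = \exp(-\Delta rt^2 / (2\sigma^2)) \times
#'       (apex - baseline)/(\max_c apex_c - baseline)}
#' with \eqn{\sigma = rt\_window / 2}; when apex RTs of the compound's
#' characteristic ions are supplied, the score is further multiplied by the
#' RT-proximity (Gaussian) term of the nearest characteristic apex. The
#' highest-scoring candidate wins; ties break toward smaller \eqn{|\Delta rt|}.
#'
#' @param cluster an [build_cluster()] result.
#' @param expected_rt expected apex RT (after any warp), seconds.
#' @param rt_window half-width of the search window, seconds.
#' @param k noise multiplier for the detection threshold.
#' @param characteristic_rts optional apex RTs of matched characteristic
#'   sibling ions.
#' @return Apex index into the cluster's RT grid, or \code{NA_integer_} when
#'   no candidate clears the threshold (peak not found).
#' @export
match_peak <- function(cluster, expected_rt = cluster$target$expected_rt,
                       rt_window = cluster$target$rt_window, k = 3,
                       characteristic_rts = NULL) {
  sm <- cluster$smoothed_composite$intensity
  rt <- cluster$smoothed_composite$rt
  base <- cluster$baseline
  thr <- base + k * cluster$noise_level
  cand <- .local_maxima(sm)
  cand <- cand[abs(rt[cand] - expected_rt) <= rt_window & sm[cand] >= thr[cand]]
  if (!length(cand)) return(NA_integer_)
  sigma <- rt_window / 2
  height <- sm[cand] - base[cand]
  drt <- rt[cand] - expected_rt
  score <- exp(-drt^2 / (2 * sigma^2)) * height / max(height)
  if (!is.null(characteristic_rts) && length(characteristic_rts)) {
    dchar <- vapply(rt[cand], function(r) min(abs(r - characteristic_rts)), 0)
    score <- score * exp(-dchar^2 / (2 * sigma^2))
  }
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[which.min(abs(drt[best]))]
  cand[best]
}

#' Shared integration bounds for an isotopic cluster
#'
#' Walks away from the matched apex of the smoothed composite in both
#' directions until the intensity drops below \code{baseline + k * noise},
#' a local minimum below 5% of the (baseline-subtracted) peak height is
#' reached, or the window edge is hit. Asymmetric peaks are then corrected:
#' if the longer apex-to-edge width exceeds \code{asymmetry_cap} times the
#' shorter one, the longer side is clipped to exactly that multiple. The
#' returned bounds are stored once per cluster and apply to every
#' isotopologue channel.
#'
#' @param cluster an [build_cluster()] result.
#' @param apex apex index from [match_peak()].
#' @param k noise multiplier.
#' @param asymmetry_cap maximum longer/shorter width ratio (>= 1).
#' @return Object of class \code{peak_bounds}: \code{apex_index},
#'   \code{left_index}, \code{right_index}.
#' @export
find_bounds <- function(cluster, apex, k = 3, asymmetry_cap = 2) {
  sm <- cluster$smoothed_composite$intensity
  base <- cluster$baseline
  n <- length(sm)
  stopifnot(apex >= 1L, apex <= n)
  thr <- base + k * cluster$noise_level
  min_floor <- (sm[apex] - base[apex]) * 0.05 + base
  walk <- function(dir) {
    i <- apex
    repeat {
      nxt <- i + dir
      if (nxt < 1L || nxt > n) break
      if (sm[nxt] < thr[nxt]) { i <- nxt; break }
      is_local_min <- sm[nxt] < min_floor[nxt] &&
        ((nxt + dir >= 1L && nxt + dir <= n && sm[nxt + dir] >= sm[nxt]) ||
         nxt + dir < 1L || nxt + dir > n)
      if (is_local_min) { i <- nxt; break }
      i <- nxt
    }
    i
  }
  left <- walk(-1L); right <- walk(1L)
  lw <- apex - left; rw <- right - apex
  if (lw > 0L && rw > 0L) {
    if (lw > asymmetry_cap * rw) left <- apex - as.integer(floor(asymmetry_cap * rw))
    if (rw > asymmetry_cap * lw) right <- apex + as.integer(floor(asymmetry_cap * lw))
  }
  structure(list(apex_index = as.integer(apex), left_index = as.integer(left),
                 right_index = as.integer(right)),
            class = "peak_bounds")
}

#' @export
print.peak_bounds <- function(x, ...) {
  cat(sprintf("<peak_bounds> apex %d, [%d, %d]\n", x$apex_index, x$left_index,
              x$right_index))
  invisible(x)
}
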