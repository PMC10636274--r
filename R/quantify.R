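# Integration of isotopologue channels within the cluster's shared bounds;
# raw MIDs, abundances and average percent enrichments.

#' Integrate one isotopologue channel
#'
#' Sum of baseline-subtracted raw intensities between the shared peak edges:
#' \code{sum(max(y_i - b_i, 0))} for \code{i} in \code{left..right}. The
#' channel's own linear edge-to-edge baseline (straight line between the raw
#' intensities at the two bound indices) is subtracted; raw, unsmoothed
#' intensities are integrated — smoothing is used only to locate the peak.
#'
#' @param eic the channel EIC (raw intensities).
#' @param bounds [find_bounds()] result on the cluster's shared grid.
#' @param subtract_baseline set \code{FALSE} to integrate raw sums only.
#' @return Non-negative area (intensity-sum units).
#' @export
integrate_channel <- function(eic, bounds, subtract_baseline = TRUE) {
  y <- if (inherits(eic, "eic")) eic$intensity else as.numeric(eic)
  l <- bounds$left_index; r <- bounds$right_index
  stopifnot(l >= 1L, r <= length(y), l <= r)
  seg <- y[l:r]
  if (!subtract_baseline || r == l) return(sum(seg))
  base <- y[l] + (y[r] - y[l]) * (seq_along(seg) - 1L) / (r - l)
  sum(pmax(seg - base, 0))
}

#' Mass isotopomer distribution from channel areas
#'
#' \code{mid_i = area_i / sum(areas)}; scale-invariant by construction.
#'
#' @param areas non-negative areas, one per quantified isotopologue.
#' @return Fractional vector summing to 1, or all-\code{NA} with attribute
#'   \code{flag = "low_signal"} when the total area is zero.
#' @export
compute_mid <- function(areas) {
  if (any(areas < 0)) stop("areas must be non-negative")
  s <- sum(areas)
  if (s <= 0)
    return(structure(rep(NA_real_, length(areas)), flag = "low_signal"))
  areas / s
}

#' Average percent enrichment
#'
#' \code{APE = 100 * sum_i(labels_i * mid_i) / n_positions}: the mean
#' fraction of potentially labeled positions that carry label. For dual
#' tracers, pass the per-channel label counts of one tracer to marginalize
#' the two-dimensional MID.
#'
#' @param mid fractional MID over the quantified channels.
#' @param labels label count of each channel (defaults to
#'   \code{0:(length(mid)-1)}).
#' @param n_positions number of labelable positions (> 0).
#' @return Percent in [0, 100] (\code{NA} if the MID is missing).
#' @export
#' @examples
#' compute_ape(c(0.5, 0, 0, 0, 0, 0.5), n_positions = 5)  # 50
compute_ape <- function(mid, labels = seq_along(mid) - 1L, n_positions) {
  if (n_positions <= 0) stop("n_positions must be positive")
  if (length(labels) != length(mid)) stop("labels and mid lengths differ")
  if (anyNA(mid)) return(NA_real_)
  100 * sum(labels * mid) / n_positions
}

# Per-tracer label counts of each quantified channel of a target.
.channel_label_counts <- function(target, tracer_index = 1L) {
  ch <- target$isotopologues
  if (is.matrix(ch)) ch[, tracer_index] else ch
}

#' Quantify an isotopic cluster
#'
#' Integrates every channel within the cluster's shared bounds and assembles
#' the per-sample record: areas, total abundance, raw MID, APE per tracer and
#' quality flags. Natural-abundance correction is applied separately (see
#' [correct_record()]).
#'
#' @param cluster a [build_cluster()] result.
#' @param bounds [find_bounds()] result, or \code{NULL} when no peak was
#'   matched (emits a \code{peak_not_found} record with zero areas).
#' @param sample_id sample identifier.
#' @param low_signal_factor record is flagged \code{low_signal} when the
#'   total area is below \code{low_signal_factor * noise * width}.
#' @return Object of class \code{mid_record}.
#' @export
quantify_cluster <- function(cluster, bounds, sample_id = "sample",
                             low_signal_factor = 10) {
  target <- cluster$target
  nch <- n_channels(target)
  if (is.null(bounds) || is.na(bounds$apex_index %||% NA)) {
    return(structure(list(target = target, sample_id = sample_id,
                          areas = numeric(nch), total_abundance = 0,
                          raw_mid = rep(NA_real_, nch),
                          corrected_mid = rep(NA_real_, nch),
                          ape_percent = rep(NA_real_, length(target$tracers)),
                          bounds = NULL, residual_norm = NA_real_,
                          flag = "peak_not_found"),
                     class = "mid_record"))
  }
  areas <- vapply(cluster$channel_eics, integrate_channel, 0, bounds = bounds)
  total <- sum(areas)
  width <- bounds$right_index - bounds$left_index + 1L
  flag <- "ok"
  if (total <= 0 || total < low_signal_factor * cluster$noise_level * width)
    flag <- "low_signal"
  raw_mid <- compute_mid(areas)
  apes <- vapply(seq_along(target$tracers), function(k)
    compute_ape(raw_mid, .channel_label_counts(target, k),
                target$tracers[[k]]$n_positions), 0)
  structure(list(target = target, sample_id = sample_id, areas = areas,
                 total_abundance = total, raw_mid = as.numeric(raw_mid),
                 corrected_mid = rep(NA_real_, nch), ape_percent = apes,
                 bounds = bounds, residual_norm = NA_real_, flag = flag),
            class = "mid_record")
}

#' Apply natural-abundance correction to a record
#'
#' Builds the correction matrix implied by the target (single/dual tracer,
#' resolution mode, MS level with tandem product formulas out of scope here)
#' and replaces the record's corrected MID and APEs. APEs are recomputed from
#' the corrected MID, which reflects tracer incorporation only.
#'
#' @param record a [quantify_cluster()] result.
#' @param method the [ms_method()] (for resolution mode and isotope table).
#' @return The record with \code{corrected_mid}, \code{ape_percent},
#'   \code{residual_norm} and possibly \code{flag} updated.
#' @export
correct_record <- function(record, method) {
  target <- record$target
  if (record$flag %in% c("peak_not_found") || anyNA(record$raw_mid))
    return(record)
  cm <- correction_matrix_for(target, method)
  cr <- correct_mid(record$raw_mid, cm)
  if (cr$flag != "ok") {
    record$flag <- "correction_failed"
    return(record)
  }
  record$corrected_mid <- cr$fractions
  record$residual_norm <- cr$residual_norm
  record$ape_percent <- vapply(seq_along(target$tracers), function(k)
    compute_ape(cr$fractions, .channel_label_counts(target, k),
                target$tracers[[k]]$n_positions), 0)
  record
}

#' Correction matrix implied by a target and method
#'
#' @param target a [target_ion()].
#' @param method an [ms_method()].
#' @return A \code{correction_matrix} over the target's quantified channels.
#' @export
correction_matrix_for <- function(target, method) {
  mode <- paste0(method$resolution_mode, "_ms1")
  if (length(target$tracers) == 2L)
    build_dual_matrix(target$formula, target$tracers[[1]], target$tracers[[2]],
                      mode, channels = target$isotopologues,
                      isotopes = method$isotopes)
  else
    build_correction_matrix(target$formula, target$tracers[[1]], mode,
                            channels = target$isotopologues,
                            isotopes = method$isotopes)
}

#' @export
print.mid_record <- function(x, ...) {
  cat(sprintf("<mid_record> %s/%s sample %s [%s] total %.4g\n",
              x$target$compound, x$target$ion, x$sample_id, x$flag,
              x$total_abundance))
  tab <- data.frame(channel = channel_labels(x$target), area = x$areas,
                    raw_mid = round(x$raw_mid, 5),
                    corrected_mid = round(x$corrected_mid, 5))
  print(tab, row.names = FALSE)
  if (!anyNA(x$ape_percent))
    cat("APE (%):", paste(sprintf("%.2f", x$ape_percent), collapse = ", "), "\n")
  invisible(x)
}
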