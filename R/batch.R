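# Batch driver: read -> warp -> extract clusters -> match/bounds ->
# integrate -> MID -> correct -> record, across files, then summarize and
# export.

#' Process one raw run against a method
#'
#' Runs the full per-file pipeline. Characteristic ions are matched first
#' (unwarped) to anchor the retention-time warp; every target is then matched
#' at its warped expected RT, with the characteristic apexes informing the
#' probabilistic score. Missing peaks yield records flagged
#' \code{peak_not_found} rather than errors.
#'
#' @param run an [ms_run()] or a file path.
#' @param method an [ms_method()].
#' @param sample_id sample identifier (defaults to the file base name).
#' @param correction apply natural-abundance correction (on top of the
#'   method's \code{correction_enabled}).
#' @return List of \code{mid_record} objects, one per target.
#' @export
process_run <- function(run, method, sample_id = NULL, correction = TRUE) {
  if (is.character(run)) run <- read_run(run)
  stopifnot(inherits(run, "ms_run"), inherits(method, "ms_method"))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(run$source_path))
  k <- method$noise_multiplier_k

  # pass 1: anchor characteristic ions at their unwarped expected RTs
  anchors_exp <- numeric(0); anchors_obs <- numeric(0)
  char_rts <- list()   # per compound: observed characteristic apex RTs
  clusters <- vector("list", length(method$targets))
  for (i in seq_along(method$targets)) {
    t <- method$targets[[i]]
    clusters[[i]] <- tryCatch(build_cluster(run, t, method), error = function(e) e)
    if (inherits(clusters[[i]], "error") || !t$is_characteristic) next
    apex <- match_peak(clusters[[i]], t$expected_rt, t$rt_window, k = k)
    if (!is.na(apex)) {
      obs_rt <- clusters[[i]]$smoothed_composite$rt[apex]
      anchors_exp <- c(anchors_exp, t$expected_rt)
      anchors_obs <- c(anchors_obs, obs_rt)
      char_rts[[t$compound]] <- c(char_rts[[t$compound]], obs_rt)
    }
  }
  warp <- if (length(anchors_exp)) warp_rt(anchors_exp, anchors_obs)
          else suppressWarnings(warp_rt(numeric(0), numeric(0)))

  # pass 2: match and quantify every target at its warped RT
  records <- vector("list", length(method$targets))
  for (i in seq_along(method$targets)) {
    t <- method$targets[[i]]
    cl <- clusters[[i]]
    if (inherits(cl, "error")) {
      records[[i]] <- quantify_cluster(
        structure(list(target = t, channel_eics = list(),
                       noise_level = 0), class = "isotopic_cluster"),
        bounds = NULL, sample_id = sample_id)
      next
    }
    sibling_rts <- setdiff(char_rts[[t$compound]], numeric(0))
    apex <- match_peak(cl, warp(t$expected_rt), t$rt_window, k = k,
                       characteristic_rts = if (t$is_characteristic) NULL
                                            else sibling_rts)
    bounds <- if (is.na(apex)) NULL
              else find_bounds(cl, apex, k = k,
                               asymmetry_cap = method$asymmetry_cap)
    rec <- quantify_cluster(cl, bounds, sample_id = sample_id)
    if (correction && method$correction_enabled)
      rec <- correct_record(rec, method)
    records[[i]] <- rec
  }
  records
}

#' Process a batch of raw files
#'
#' Applies [process_run()] to every file; per-file failures are logged and
#' skipped while the batch continues. Optionally summarizes by group,
#' compares groups, and exports the CSV workbook.
#'
#' @param files character vector of raw-file paths.
#' @param method an [ms_method()] or method-config path.
#' @param meta optional metadata data frame (\code{sample_id}, \code{file},
#'   \code{group}, \code{time_point}, \code{is_unlabeled_control}).
#' @param out_dir optional output directory for the workbook and run log.
#' @param correction apply natural-abundance correction.
#' @param group_pairs optional list of group pairs for [compare_groups()].
#' @param seed recorded in the run log (processing itself is deterministic).
#' @return Object of class \code{mid_batch}: \code{records},
#'   \code{summaries}, \code{comparisons}, \code{failures}, \code{files},
#'   \code{method}, \code{log}.
#' @export
process_batch <- function(files, method, meta = NULL, out_dir = NULL,
                          correction = TRUE, group_pairs = NULL, seed = NULL) {
  if (is.character(method)) method <- load_method(method)
  log <- list()
  push_log <- function(...) {
    entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
    log[[length(log) + 1L]] <<- entry
    entry
  }
  push_log(event = "batch_start", n_files = length(files),
           seed = seed %||% NA,
           package_version = as.character(utils::packageVersion("midquant")),
           k = method$noise_multiplier_k,
           asymmetry_cap = method$asymmetry_cap,
           resolution_mode = method$resolution_mode)
  records <- list(); failures <- character(0)
  for (f in files) {
    sid <- if (!is.null(meta) && "file" %in% names(meta) &&
               basename(f) %in% basename(meta$file))
      meta$sample_id[match(basename(f), basename(meta$file))]
    else sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch(process_run(f, method, sample_id = sid,
                                correction = correction),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping '", f, "': ", conditionMessage(res))
      failures <- c(failures, f)
      push_log(event = "file_failed", file = f, error = conditionMessage(res))
    } else {
      records <- c(records, res)
      push_log(event = "file_done", file = f, sample_id = sid,
               n_records = length(res))
    }
  }
  if (!length(records)) stop("no files processed successfully")
  summaries <- if (!is.null(meta) && "group" %in% names(meta))
    summarize_groups(records, meta) else NULL
  comparisons <- if (!is.null(meta) && !is.null(group_pairs))
    compare_groups(records, meta, group_pairs) else NULL
  if (!is.null(out_dir)) {
    export_workbook(records, out_dir, method, meta = meta,
                    comparisons = comparisons)
    logf <- file.path(out_dir, "run_log.jsonl")
    writeLines(vapply(log, function(e)
      jsonlite::toJSON(e, auto_unbox = TRUE), ""), logf)
  }
  structure(list(records = records, summaries = summaries,
                 comparisons = comparisons, failures = failures,
                 files = files, method = method, meta = meta, log = log),
            class = "mid_batch")
}

#' @export
print.mid_batch <- function(x, ...) {
  flags <- table(vapply(x$records, `[[`, "", "flag"))
  cat(sprintf("<mid_batch> %d records from %d files (%d failed)\n",
              length(x$records), length(x$files), length(x$failures)))
  cat("flags:", paste(names(flags), flags, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mid_batch <- function(object, ...) {
  tab <- records_to_table(object$records)
  cat(sprintf("MID batch: %d samples, %d targets, %d channels\n",
              length(unique(tab$sample_id)),
              length(unique(paste(tab$compound, tab$ion))),
              nrow(tab)))
  if (!is.null(object$summaries)) print(object$summaries)
  else print(utils::head(tab, 20))
  invisible(tab)
}

#' Diagnostic plot of an isotopic cluster
#'
#' Overlays the channel EICs, the composite and smoothed composite traces,
#' the baseline, and (optionally) the shared integration bounds.
#'
#' @param x an \code{isotopic_cluster}.
#' @param bounds optional [find_bounds()] result to mark.
#' @param ... passed to [graphics::matplot()].
#' @return Invisible \code{NULL}.
#' @export
plot.isotopic_cluster <- function(x, bounds = NULL, ...) {
  rt <- x$composite$rt
  chans <- do.call(cbind, lapply(x$channel_eics, `[[`, "intensity"))
  graphics::matplot(rt, chans, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(chans), "viridis"),
                    xlab = "retention time (s)", ylab = "intensity",
                    main = paste(x$target$compound, x$target$ion), ...)
  graphics::lines(rt, x$smoothed_composite$intensity, lwd = 2)
  graphics::lines(rt, x$baseline, lty = 3)
  if (!is.null(bounds)) {
    graphics::abline(v = rt[c(bounds$left_index, bounds$right_index)], lty = 2)
    graphics::points(rt[bounds$apex_index],
                     x$smoothed_composite$intensity[bounds$apex_index], pch = 19)
  }
  invisible(NULL)
}

#' Run a batch from a config (CLI entry point)
#'
#' Drives [process_batch()] from a JSON batch config with fields
#' \code{method} (path), \code{data} (file list or glob), optional
#' \code{meta} (CSV path), \code{out} (directory), \code{correction},
#' \code{group_pairs} and \code{seed}.
#'
#' @param config path to a JSON config, or an equivalent named list.
#' @return The [process_batch()] result, invisibly.
#' @export
run_batch <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$method) || is.null(config$data))
    stop("batch config requires 'method' and 'data'")
  files <- unlist(lapply(config$data, function(p)
    if (grepl("[*?]", p)) Sys.glob(p) else p))
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("missing data files: ", paste(missing, collapse = ", "))
  if (!file.exists(config$method)) stop("missing method file: ", config$method)
  meta <- if (!is.null(config$meta)) utils::read.csv(config$meta,
                                                     stringsAsFactors = FALSE)
  gp <- if (!is.null(config$group_pairs))
    lapply(seq_len(nrow(as.matrix(config$group_pairs))), function(i)
      as.character(as.matrix(config$group_pairs)[i, ]))
  invisible(process_batch(files, load_method(config$method), meta = meta,
                          out_dir = config$out %||% NULL,
                          correction = !isFALSE(config$correction),
                          group_pairs = gp, seed = config$seed %||% NULL))
}
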