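# Batch outputs: long tables, group statistics, RMSE diagnostics, Welch
# comparisons and a plain-text (CSV) workbook export.

#' Flatten MID records to a long table
#'
#' @param records list of [quantify_cluster()] records.
#' @return Data frame, one row per record x channel.
#' @export
records_to_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(sample_id = r$sample_id, compound = r$target$compound,
               ion = r$target$ion, channel = channel_labels(r$target),
               mz = channel_mzs(r$target), area = r$areas,
               raw_mid = r$raw_mid, corrected_mid = r$corrected_mid,
               total_abundance = r$total_abundance, flag = r$flag,
               stringsAsFactors = FALSE)
  }))
}

# Per-record APE table (one row per tracer).
.ape_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(sample_id = r$sample_id, compound = r$target$compound,
               ion = r$target$ion,
               tracer = vapply(r$target$tracers, function(t)
                 paste0(t$isotope, t$element), ""),
               ape_percent = r$ape_percent, flag = r$flag,
               stringsAsFactors = FALSE)
  }))
}

#' Theoretical (natural-abundance) MID of a target
#'
#' The observable MID of the fully unlabeled compound: the correction
#' matrix's zero-label column, renormalized over the tracked channels.
#'
#' @param target a [target_ion()].
#' @param method an [ms_method()].
#' @return Fractional vector over the quantified channels.
#' @export
theoretical_mid <- function(target, method) {
  cm <- correction_matrix_for(target, method)
  col0 <- unname(cm$matrix[, 1L])
  col0 / sum(col0)
}

#' RMSE of an unlabeled control against its theoretical MID
#'
#' \code{sqrt(mean((raw_mid - theoretical)^2))} using the *uncorrected* MID
#' (the corrected MID of an unlabeled sample is the unit vector by
#' construction, so it carries no diagnostic information).
#'
#' @param record a record from an unlabeled control sample.
#' @param method an [ms_method()].
#' @return RMSE, or \code{NA} when the record has no MID.
#' @export
rmse_vs_theoretical <- function(record, method) {
  if (anyNA(record$raw_mid)) return(NA_real_)
  th <- theoretical_mid(record$target, method)
  sqrt(mean((record$raw_mid - th)^2))
}

#' Group means and standard deviations
#'
#' Per (target, group, time point): arithmetic mean and sample SD of the
#' corrected MIDs (raw MIDs when correction is disabled) and APEs over
#' replicates; records flagged \code{peak_not_found} are excluded and the
#' replicate count reports only the records used.
#'
#' @param records list of records.
#' @param meta data frame with columns \code{sample_id}, \code{group},
#'   \code{time_point} (and optionally \code{is_unlabeled_control}).
#' @return List of data frames \code{mids} and \code{apes} (class
#'   \code{group_summary}).
#' @export
summarize_groups <- function(records, meta) {
  stopifnot(all(c("sample_id", "group") %in% names(meta)))
  if (!"time_point" %in% names(meta)) meta$time_point <- 0
  if (anyDuplicated(meta$sample_id)) stop("sample_id must be unique in meta")
  tab <- records_to_table(records)
  missing_meta <- setdiff(unique(tab$sample_id), meta$sample_id)
  if (length(missing_meta))
    stop("records without metadata: ", paste(missing_meta, collapse = ", "))
  tab <- merge(tab, meta[c("sample_id", "group", "time_point")], by = "sample_id")
  tab$mid <- ifelse(is.na(tab$corrected_mid), tab$raw_mid, tab$corrected_mid)
  tab <- tab[tab$flag != "peak_not_found" & !is.na(tab$mid), ]
  agg <- function(df, value_col) {
    key <- interaction(df$compound, df$ion, df$channel, df$group,
                       df$time_point, drop = TRUE)
    out <- do.call(rbind, lapply(split(df, key), function(d) {
      data.frame(compound = d$compound[1], ion = d$ion[1],
                 channel = d$channel[1], group = d$group[1],
                 time_point = d$time_point[1],
                 mean = mean(d[[value_col]]),
                 sd = if (nrow(d) >= 2L) stats::sd(d[[value_col]]) else NA_real_,
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out[order(out$compound, out$ion, out$group, out$time_point, out$channel), ]
  }
  apes <- .ape_table(records)
  apes <- merge(apes, meta[c("sample_id", "group", "time_point")], by = "sample_id")
  apes <- apes[apes$flag != "peak_not_found" & !is.na(apes$ape_percent), ]
  apes$channel <- apes$tracer
  structure(list(mids = agg(tab, "mid"), apes = agg(apes, "ape_percent")),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary>\nMIDs:\n"); print(utils::head(x$mids, 20))
  cat("APEs:\n"); print(utils::head(x$apes, 10))
  invisible(x)
}

# Welch two-sample t on raw vectors; handles degenerate zero-variance cases
# that stats::t.test rejects. Cross-checked against stats::t.test in the
# unit tests.
.welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0)
    return(list(t = if (m1 == m2) 0 else sign(m1 - m2) * Inf,
                df = n1 + n2 - 2, p = if (m1 == m2) 1 else 0))
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch comparisons between experimental groups
#'
#' For each requested pair of groups and each target: a Welch two-sample
#' t-statistic and p-value per mass-isotopomer channel and per tracer APE,
#' with Benjamini-Hochberg adjustment across the channels within each
#' target. Comparisons with fewer than two replicates on either side are
#' skipped with a note.
#'
#' @param records list of records.
#' @param meta sample metadata (as in [summarize_groups()]).
#' @param group_pairs list of length-2 character vectors of group labels.
#' @return Data frame with columns compound, ion, quantity, group1, group2,
#'   n1, n2, t, df, p, p_adj, note.
#' @export
compare_groups <- function(records, meta, group_pairs) {
  if (is.character(group_pairs)) group_pairs <- list(group_pairs)
  tab <- records_to_table(records)
  tab <- merge(tab, meta[c("sample_id", "group")], by = "sample_id")
  tab$mid <- ifelse(is.na(tab$corrected_mid), tab$raw_mid, tab$corrected_mid)
  apes <- merge(.ape_table(records), meta[c("sample_id", "group")], by = "sample_id")
  out <- list()
  for (pair in group_pairs) {
    g1 <- pair[1]; g2 <- pair[2]
    for (key in unique(paste(tab$compound, tab$ion, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- tab[tab$compound == parts[1] & tab$ion == parts[2], ]
      rows <- list()
      for (ch in unique(sub$channel)) {
        a <- sub$mid[sub$channel == ch & sub$group == g1]
        b <- sub$mid[sub$channel == ch & sub$group == g2]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) {
          rows[[ch]] <- data.frame(quantity = ch, n1 = length(a), n2 = length(b),
                                   t = NA_real_, df = NA_real_, p = NA_real_,
                                   note = "skipped: <2 replicates")
        } else {
          w <- .welch(a, b)
          rows[[ch]] <- data.frame(quantity = ch, n1 = length(a), n2 = length(b),
                                   t = w$t, df = w$df, p = w$p, note = "")
        }
      }
      res <- do.call(rbind, rows)
      res$p_adj <- stats::p.adjust(res$p, method = "BH")
      asub <- apes[apes$compound == parts[1] & apes$ion == parts[2], ]
      arows <- do.call(rbind, lapply(unique(asub$tracer), function(trc) {
        a <- asub$ape_percent[asub$tracer == trc & asub$group == g1]
        b <- asub$ape_percent[asub$tracer == trc & asub$group == g2]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L)
          data.frame(quantity = paste0("APE:", trc), n1 = length(a),
                     n2 = length(b), t = NA_real_, df = NA_real_, p = NA_real_,
                     note = "skipped: <2 replicates", p_adj = NA_real_)
        else {
          w <- .welch(a, b)
          data.frame(quantity = paste0("APE:", trc), n1 = length(a),
                     n2 = length(b), t = w$t, df = w$df, p = w$p, note = "",
                     p_adj = w$p)
        }
      }))
      res <- rbind(res, arows)
      res$compound <- parts[1]; res$ion <- parts[2]
      res$group1 <- g1; res$group2 <- g2
      out[[length(out) + 1L]] <- res
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("compound", "ion", "quantity", "group1", "group2", "n1", "n2",
        "t", "df", "p", "p_adj", "note")]
}

#' Export the results workbook
#'
#' Writes a plain-text workbook: a directory of CSV sheets (MIDs, APEs,
#' Abundances, and, when metadata is given, GroupStats and QC) plus a JSON
#' manifest with the schema version and sheet list. Every numeric cell is
#' written at full (15 significant digit) precision so a re-read reproduces
#' the values.
#'
#' @param records list of records.
#' @param path output directory (created if needed).
#' @param method the [ms_method()] (for QC theoretical MIDs).
#' @param meta optional sample metadata; enables GroupStats and the
#'   unlabeled-control RMSE QC sheet.
#' @param comparisons optional [compare_groups()] result to include.
#' @return Invisible character vector of written file paths.
#' @export
export_workbook <- function(records, path, method, meta = NULL,
                            comparisons = NULL) {
  if (!length(records)) stop("no records to export")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (file.access(path, 2L) != 0L) stop("cannot write to '", path, "'")
  wr <- function(df, name) {
    f <- file.path(path, paste0(name, ".csv"))
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
    utils::write.csv(df, f, row.names = FALSE)
    f
  }
  files <- c(wr(records_to_table(records), "MIDs"),
             wr(.ape_table(records), "APEs"),
             wr(unique(records_to_table(records)[c("sample_id", "compound",
                                                   "ion", "total_abundance",
                                                   "flag")]), "Abundances"))
  sheets <- c("MIDs", "APEs", "Abundances")
  if (!is.null(meta)) {
    gs <- summarize_groups(records, meta)
    files <- c(files, wr(gs$mids, "GroupStats"), wr(gs$apes, "GroupStatsAPE"))
    sheets <- c(sheets, "GroupStats", "GroupStatsAPE")
    if ("is_unlabeled_control" %in% names(meta)) {
      ctrl <- meta$sample_id[as.logical(meta$is_unlabeled_control)]
      qc <- do.call(rbind, lapply(records, function(r) {
        if (!r$sample_id %in% ctrl) return(NULL)
        data.frame(sample_id = r$sample_id, compound = r$target$compound,
                   ion = r$target$ion,
                   rmse_vs_theoretical = rmse_vs_theoretical(r, method),
                   flag = r$flag, stringsAsFactors = FALSE)
      }))
      if (!is.null(qc)) {
        files <- c(files, wr(qc, "QC")); sheets <- c(sheets, "QC")
      }
    }
  }
  if (!is.null(comparisons)) {
    files <- c(files, wr(comparisons, "Comparisons"))
    sheets <- c(sheets, "Comparisons")
  }
  manifest <- list(workbook_schema = 1L, sheets = as.list(sheets))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, file.path(path, "manifest.json")))
}

#' Read back an exported workbook
#'
#' @param path workbook directory written by [export_workbook()].
#' @return Named list of data frames, one per sheet.
#' @export
read_workbook <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  sheets <- manifest$sheets
  out <- lapply(sheets, function(s)
    utils::read.csv(file.path(path, paste0(s, ".csv")), stringsAsFactors = FALSE))
  names(out) <- sheets
  out
}
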