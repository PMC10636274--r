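# Raw-run I/O: parse mzML / mzXML / ANDI-MS netCDF into a uniform scan model
# (reading goes through mzR), plus plain fixture writers used by the
# synthetic-data generator so round trips can be tested against mzR as an
# independent reader.

#' Construct a scan
#'
#' @param rt retention time, seconds.
#' @param mz sorted m/z values.
#' @param intensity non-negative intensities, same length as \code{mz}.
#' @param ms_level 1 or 2.
#' @param precursor_mz precursor m/z (required for MS2 scans).
#' @param precursor_window isolation-window half-width, m/z.
#' @param polarity "positive", "negative" or "unknown".
#' @param centroided logical.
#' @return Object of class \code{ms_scan}.
#' @export
ms_scan <- function(rt, mz, intensity, ms_level = 1L, precursor_mz = NULL,
                    precursor_window = NULL, polarity = "unknown",
                    centroided = TRUE) {
  ms_level <- as.integer(ms_level)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (is.unsorted(mz, strictly = TRUE)) stop("mz values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (ms_level == 2L && is.null(precursor_mz))
    stop("MS2 scan requires precursor_mz")
  structure(list(rt = as.numeric(rt), ms_level = ms_level,
                 precursor_mz = precursor_mz,
                 precursor_window = precursor_window,
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 polarity = polarity, centroided = isTRUE(centroided)),
            class = "ms_scan")
}

#' Construct a raw run from scans
#'
#' @param scans non-empty list of [ms_scan()] objects with non-decreasing RT.
#' @param source_path provenance string.
#' @param instrument_hint "low_res", "high_res" or "unknown".
#' @return Object of class \code{ms_run}.
#' @export
ms_run <- function(scans, source_path = "<memory>", instrument_hint = "unknown") {
  if (!length(scans)) stop("no scans")
  rts <- vapply(scans, `[[`, 0, "rt")
  if (is.unsorted(rts)) stop("scan retention times must be non-decreasing")
  structure(list(scans = scans, source_path = source_path,
                 instrument_hint = instrument_hint),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  rts <- vapply(x$scans, `[[`, 0, "rt")
  lv <- vapply(x$scans, `[[`, 1L, "ms_level")
  cat(sprintf("<ms_run> %d scans (%d MS1, %d MS2), RT %.1f-%.1f s, source: %s\n",
              length(x$scans), sum(lv == 1L), sum(lv == 2L),
              min(rts), max(rts), x$source_path))
  invisible(x)
}

#' @export
print.ms_scan <- function(x, ...) {
  cat(sprintf("<ms_scan> RT %.2f s, MS%d, %d peaks, %s, %s\n", x$rt, x$ms_level,
              length(x$mz), x$polarity,
              if (x$centroided) "centroid" else "profile"))
  invisible(x)
}

# Detect mzML / mzXML / netCDF from extension, falling back to magic bytes.
.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mzml")) return("mzml")
  if (ext %in% c("mzxml")) return("mzxml")
  if (ext %in% c("cdf", "nc")) return("netcdf")
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 4096L)
  if (length(head) >= 3L && rawToChar(head[1:3]) == "CDF") return("netcdf")
  txt <- suppressWarnings(rawToChar(head))
  if (grepl("<mzML|<indexedmzML", txt)) return("mzml")
  if (grepl("<mzXML", txt)) return("mzxml")
  stop("unsupported format: cannot identify '", path,
       "' as mzML, mzXML or ANDI-MS netCDF")
}

# Heuristic centroid/profile call when the file metadata does not say: a scan
# looks like profile data if most consecutive m/z spacings are tight
# (< 0.01 Th) and it has contiguous nonzero runs of >= 5 points.
.infer_centroided <- function(mz, intensity) {
  if (length(mz) < 10L) return(TRUE)
  d <- diff(mz)
  if (mean(d < 0.01) <= 0.5) return(TRUE)
  r <- rle(intensity > 0)
  !any(r$lengths >= 5L & r$values)
}

#' Read a raw MS run
#'
#' Parses an mzML 1.1, mzXML 3.x or ANDI-MS netCDF file into an [ms_run()].
#' Retention times are converted to seconds regardless of source units; the
#' centroided flag is taken from file metadata when present and inferred from
#' the m/z spacing otherwise.
#'
#' @param path file path.
#' @param format_hint optional "mzml", "mzxml" or "netcdf"; detected from the
#'   extension or magic bytes when absent.
#' @return An [ms_run()].
#' @export
read_run <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (!is.null(format_hint)) match.arg(tolower(format_hint),
                                              c("mzml", "mzxml", "netcdf"))
         else .detect_format(path)
  backend <- if (fmt == "netcdf") "netCDF" else "pwiz"
  handle <- tryCatch(mzR::openMSfile(path, backend = backend),
                     error = function(e) stop("failed to parse '", path, "': ",
                                              conditionMessage(e)))
  on.exit(try(mzR::close(handle), silent = TRUE))
  hdr <- tryCatch(mzR::header(handle),
                  error = function(e) stop("failed to parse header of '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(hdr) || nrow(hdr) == 0L) stop("no scans in '", path, "'")
  pk <- tryCatch(mzR::peaks(handle),
                 error = function(e) stop("failed to parse spectra of '", path,
                                          "': ", conditionMessage(e)))
  if (is.matrix(pk)) pk <- list(pk)
  scans <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    p <- pk[[i]]
    mz <- as.numeric(p[, 1L]); inten <- as.numeric(p[, 2L])
    ord <- order(mz)
    mz <- mz[ord]; inten <- pmax(inten[ord], 0)
    dup <- duplicated(mz)
    if (any(dup)) {   # collapse duplicate m/z rows so the grid is strict
      inten <- as.numeric(rowsum(inten, mz))
      mz <- sort(unique(mz))
    }
    lev <- as.integer(hdr$msLevel[i])
    cent <- hdr$centroided[i]
    if (is.na(cent)) cent <- .infer_centroided(mz, inten)
    prec <- NULL; pwin <- NULL
    if (!is.na(lev) && lev >= 2L) {
      prec <- hdr$precursorMZ[i]
      if (is.na(prec) || prec <= 0)
        stop("parse error in '", path, "' at scan ", i,
             ": MS2 scan without precursor m/z")
      lo <- hdr$isolationWindowLowerOffset[i]
      hi <- hdr$isolationWindowUpperOffset[i]
      if (!is.na(lo) && !is.na(hi)) pwin <- max(lo, hi)
    }
    pol <- if (is.null(hdr$polarity)) -1L else hdr$polarity[i]
    scans[[i]] <- tryCatch(
      ms_scan(rt = hdr$retentionTime[i], mz = mz, intensity = inten,
              ms_level = max(1L, lev, na.rm = TRUE), precursor_mz = prec,
              precursor_window = pwin,
              polarity = c("negative", "unknown", "positive")[match(pol, c(0L, -1L, 1L), nomatch = 2L)],
              centroided = cent),
      error = function(e) stop("parse error in '", path, "' at scan ", i, ": ",
                               conditionMessage(e)))
  }
  ord <- order(vapply(scans, `[[`, 0, "rt"))
  ms_run(scans[ord], source_path = path)
}

#' Centroid a profile scan
#'
#' Reduces a profile-mode scan to centroids: each local intensity maximum
#' above zero becomes one peak whose m/z is the intensity-weighted centroid
#' over its contiguous profile points (down to the surrounding local minima
#' or zeros) and whose intensity is the apex intensity.
#'
#' @param scan an [ms_scan()] with \code{centroided = FALSE}.
#' @return A centroided [ms_scan()].
#' @export
centroid_profile_scan <- function(scan) {
  y <- scan$intensity; mz <- scan$mz
  n <- length(y)
  if (n == 0L || all(y == 0)) {
    out <- scan; out$mz <- numeric(0); out$intensity <- numeric(0)
    out$centroided <- TRUE
    return(out)
  }
  yl <- c(0, y[-n]); yr <- c(y[-1L], 0)
  apex <- which(y > 0 & y >= yl & y > yr)
  cm <- numeric(length(apex)); ci <- numeric(length(apex))
  for (k in seq_along(apex)) {
    a <- apex[k]
    l <- a
    while (l > 1L && y[l - 1L] > 0 && y[l - 1L] <= y[l]) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] > 0 && y[r + 1L] <= y[r]) r <- r + 1L
    seg <- l:r
    cm[k] <- sum(mz[seg] * y[seg]) / sum(y[seg])
    ci[k] <- y[a]
  }
  keep <- !duplicated(cm)
  out <- scan
  ord <- order(cm[keep])
  out$mz <- cm[keep][ord]; out$intensity <- ci[keep][ord]
  out$centroided <- TRUE
  out
}

# ---------------------------------------------------------------------------
# Fixture writers. The package writes its own minimal mzML 1.1 (and ANDI-MS
# netCDF) so synthetic runs are deterministic byte-for-byte under a fixed
# seed; mzR serves as the independent reader in round-trip tests.

# zlib stream (RFC 1950) for mzML binary arrays. R's memCompress(type =
# "gzip") emits a zlib-wrapped deflate stream (0x78 0x9c header + Adler-32),
# which is exactly what the mzML "zlib compression" CV term requires.
.zlib_compress <- function(r) {
  z <- memCompress(r, type = "gzip")
  if (length(z) < 2L || z[1L] != as.raw(0x78))
    stop("compressor did not produce a zlib stream")
  z
}

.b64_binary <- function(x, compression) {
  r <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
  if (compression == "zlib") r <- .zlib_compress(r)
  gsub("[\r\n]", "", jsonlite::base64_enc(r))
}

.num <- function(x) sprintf("%.12g", x)

.spectrum_xml <- function(scan, index, compression) {
  n <- length(scan$mz)
  pol <- switch(scan$polarity,
                positive = '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>\n',
                negative = '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>\n',
                "")
  mode <- if (scan$centroided)
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  comp_cv <- if (compression == "zlib")
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>'
  b64mz <- .b64_binary(scan$mz, compression)
  b64int <- .b64_binary(scan$intensity, compression)
  prec <- ""
  if (scan$ms_level >= 2L) {
    w <- scan$precursor_window %||% 0.5
    prec <- paste0(
      '<precursorList count="1"><precursor><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="', .num(scan$precursor_mz), '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="', .num(w), '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="', .num(w), '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</isolationWindow><selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="', .num(scan$precursor_mz), '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</selectedIon></selectedIonList><activation>',
      '<cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>',
      '</activation></precursor></precursorList>\n')
  }
  paste0(
    '<spectrum index="', index - 1L, '" id="scan=', index, '" defaultArrayLength="', n, '">\n',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="', scan$ms_level, '"/>\n',
    mode, '\n', pol,
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="', .num(scan$rt),
    '" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>\n',
    prec,
    '<binaryDataArrayList count="2">\n',
    '<binaryDataArray encodedLength="', nchar(b64mz), '">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>', comp_cv,
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<binary>', b64mz, '</binary></binaryDataArray>\n',
    '<binaryDataArray encodedLength="', nchar(b64int), '">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>', comp_cv,
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<binary>', b64int, '</binary></binaryDataArray>\n',
    '</binaryDataArrayList>\n</spectrum>\n')
}

#' Write a run as mzML 1.1
#'
#' Minimal, deterministic mzML writer (64-bit little-endian arrays, zlib or
#' uncompressed) used for fixtures and synthetic data. The same input always
#' produces byte-identical output.
#'
#' @param run an [ms_run()].
#' @param path output path.
#' @param compression "zlib" or "none".
#' @return \code{path}, invisibly.
#' @export
write_run <- function(run, path, compression = c("zlib", "none")) {
  stopifnot(inherits(run, "ms_run"))
  compression <- match.arg(compression)
  spectra <- vapply(seq_along(run$scans), function(i)
    .spectrum_xml(run$scans[[i]], i, compression), "")
  has_ms2 <- any(vapply(run$scans, `[[`, 1L, "ms_level") >= 2L)
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    if (has_ms2) '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>' else '',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="midquant" version="0.1.0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="midquant"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="DP1"><processingMethod order="1" softwareRef="midquant">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="', length(run$scans), '" defaultDataProcessingRef="DP1">\n',
    paste0(spectra, collapse = ""),
    '</spectrumList>\n</run>\n</mzML>\n')
  con <- file(path, "wb")
  writeBin(charToRaw(xml), con)
  close(con)
  invisible(path)
}

#' Write a run as mzXML (via mzR)
#'
#' Convenience export used by the format-invariance tests; content matches
#' [write_run()] up to container format.
#'
#' @param run an [ms_run()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_mzxml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  n <- length(run$scans)
  lv <- vapply(run$scans, `[[`, 1L, "ms_level")
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = vapply(run$scans, function(s)
      c(0L, -1L, 1L)[match(s$polarity, c("negative", "unknown", "positive"), nomatch = 2L)], 0L),
    peaksCount = vapply(run$scans, function(s) length(s$mz), 0L),
    totIonCurrent = vapply(run$scans, function(s) sum(s$intensity), 0),
    retentionTime = vapply(run$scans, `[[`, 0, "rt"),
    basePeakMZ = vapply(run$scans, function(s) if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0),
    basePeakIntensity = vapply(run$scans, function(s) if (length(s$intensity)) max(s$intensity) else 0, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s) if (length(s$mz)) min(s$mz) else 0, 0),
    highMZ = vapply(run$scans, function(s) if (length(s$mz)) max(s$mz) else 0, 0),
    precursorScanNum = 0L,
    precursorMZ = vapply(run$scans, function(s) s$precursor_mz %||% 0, 0),
    precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = vapply(run$scans, `[[`, TRUE, "centroided"),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(run$scans, function(s) s$precursor_mz %||% NA_real_, 0),
    isolationWindowLowerOffset = vapply(run$scans, function(s)
      if (s$ms_level >= 2L) s$precursor_window %||% 0.5 else NA_real_, 0),
    isolationWindowUpperOffset = vapply(run$scans, function(s)
      if (s$ms_level >= 2L) s$precursor_window %||% 0.5 else NA_real_, 0),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  pks <- lapply(run$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  suppressWarnings(mzR::writeMSData(pks, path, header = hdr, backend = "pwiz",
                                    outformat = "mzxml"))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal NetCDF-3 (classic) writer restricted to the ANDI-MS layout
# (scan_acquisition_time, scan_index, point_count, total_intensity,
# mass_values, intensity_values). Big-endian per the NetCDF spec.

.nc_pad4 <- function(n) (4L - n %% 4L) %% 4L

.nc_name <- function(con, name) {
  b <- charToRaw(name)
  writeBin(length(b), con, size = 4L, endian = "big")
  writeBin(b, con)
  pad <- .nc_pad4(length(b))
  if (pad) writeBin(raw(pad), con)
}

#' Write a run as ANDI-MS netCDF
#'
#' Minimal NetCDF-3 classic writer emitting exactly the ANDI-MS (ASTM E2077)
#' variables. MS1 scans only (the ANDI-MS layout has no precursor
#' information). Fixture/testing use.
#'
#' @param run an [ms_run()] containing only MS1 scans.
#' @param path output path (conventionally .cdf).
#' @return \code{path}, invisibly.
#' @export
write_andi_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  if (any(vapply(run$scans, `[[`, 1L, "ms_level") != 1L))
    stop("ANDI-MS netCDF supports MS1 scans only")
  nscan <- length(run$scans)
  counts <- vapply(run$scans, function(s) length(s$mz), 0L)
  npoint <- sum(counts)
  if (npoint == 0L) stop("cannot write a run with no data points")
  sat <- vapply(run$scans, `[[`, 0, "rt")
  idx <- c(0L, cumsum(counts)[-nscan])
  tic <- vapply(run$scans, function(s) sum(s$intensity), 0)
  allmz <- unlist(lapply(run$scans, `[[`, "mz"))
  allint <- unlist(lapply(run$scans, `[[`, "intensity"))

  NC_INT <- 4L; NC_DOUBLE <- 6L
  vars <- list(
    list(name = "scan_acquisition_time", dim = 0L, type = NC_DOUBLE, data = sat),
    list(name = "scan_index",            dim = 0L, type = NC_INT,    data = idx),
    list(name = "point_count",           dim = 0L, type = NC_INT,    data = counts),
    list(name = "total_intensity",       dim = 0L, type = NC_DOUBLE, data = tic),
    list(name = "mass_values",           dim = 1L, type = NC_DOUBLE, data = allmz),
    list(name = "intensity_values",      dim = 1L, type = NC_DOUBLE, data = allint))
  dims <- list(list(name = "scan_number", len = nscan),
               list(name = "point_number", len = npoint))

  vsize <- function(v) {
    bytes <- length(v$data) * if (v$type == NC_INT) 4L else 8L
    bytes + .nc_pad4(bytes)
  }
  # header size: magic(4) + numrecs(4) + dim tag/count(8) + dims +
  # gatt ABSENT(8) + var tag/count(8) + per-var entries
  name_bytes <- function(nm) 4L + nchar(nm) + .nc_pad4(nchar(nm))
  hdr_len <- 4L + 4L + 8L +
    sum(vapply(dims, function(d) name_bytes(d$name) + 4L, 0L)) + 8L + 8L +
    sum(vapply(vars, function(v)
      name_bytes(v$name) + 4L + 4L + 8L + 4L + 4L + 4L, 0L))
  begins <- cumsum(c(hdr_len, vapply(vars[-length(vars)], vsize, 0L)))

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("CDF"), as.raw(1L)), con)
  writeBin(0L, con, size = 4L, endian = "big")                 # numrecs
  writeBin(c(10L, length(dims)), con, size = 4L, endian = "big")
  for (d in dims) { .nc_name(con, d$name); writeBin(d$len, con, size = 4L, endian = "big") }
  writeBin(c(0L, 0L), con, size = 4L, endian = "big")          # gatt ABSENT
  writeBin(c(11L, length(vars)), con, size = 4L, endian = "big")
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    .nc_name(con, v$name)
    writeBin(1L, con, size = 4L, endian = "big")               # ndims
    writeBin(v$dim, con, size = 4L, endian = "big")            # dimid
    writeBin(c(0L, 0L), con, size = 4L, endian = "big")        # vatt ABSENT
    writeBin(v$type, con, size = 4L, endian = "big")
    writeBin(vsize(v), con, size = 4L, endian = "big")
    writeBin(begins[k], con, size = 4L, endian = "big")
  }
  for (v in vars) {
    if (v$type == NC_INT) writeBin(as.integer(v$data), con, size = 4L, endian = "big")
    else writeBin(as.numeric(v$data), con, size = 8L, endian = "big")
    bytes <- length(v$data) * if (v$type == NC_INT) 4L else 8L
    if (.nc_pad4(bytes)) writeBin(raw(.nc_pad4(bytes)), con)
  }
  invisible(path)
}
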