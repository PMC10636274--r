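# Method definition: target ions, tracers, isotopologue channels and
# processing parameters, loadable from a declarative JSON config.

.method_defaults <- list(
  resolution_mode = "high_res",
  mz_tolerance_ppm = 10,     # used when resolution_mode == "high_res"
  mz_tolerance_da = 0.3,     # used when resolution_mode == "low_res"
  smoothing_window = 7L,
  smoothing_order = 3L,
  noise_multiplier_k = 3,
  asymmetry_cap = 2.0,
  rt_window = 30,
  correction_enabled = TRUE
)

#' Define a target ion
#'
#' One quantifiable ion of a target compound: its elemental formula (all
#' atoms of the detected species, including adduct/derivatization groups),
#' charge, tracer(s), expected retention time and the isotopologue channels
#' to extract.
#'
#' @param compound compound name.
#' @param ion ion name (defaults to the compound name).
#' @param formula formula string or named count vector for the detected ion.
#' @param charge signed integer charge, non-zero.
#' @param base_mz m/z of the lightest (unlabeled, all-light-isotope)
#'   isotopologue.
#' @param tracers a [tracer_spec()] or list of one or two tracer_specs.
#' @param expected_rt expected apex retention time, seconds.
#' @param rt_window half-width of the retention-time search window, seconds.
#' @param ms_level 1 or 2.
#' @param precursor_mz precursor m/z; required iff \code{ms_level = 2}.
#' @param is_characteristic whether this ion anchors peak matching and RT
#'   warping for its compound.
#' @param isotopologues label counts to quantify: integer vector for a single
#'   tracer (default \code{0:n_positions}), or a two-column matrix of
#'   (tracer1, tracer2) pairs for dual tracers (default all pairs,
#'   row-major, first tracer outer).
#' @return Object of class \code{target_ion}.
#' @export
#' @examples
#' target_ion("glutamine", formula = "C5H11N2O3", charge = 1,
#'            base_mz = 147.0764, tracers = tracer_spec("C", 13, 5),
#'            expected_rt = 300)
target_ion <- function(compound, ion = compound, formula, charge, base_mz,
                       tracers, expected_rt, rt_window = .method_defaults$rt_window,
                       ms_level = 1L, precursor_mz = NULL,
                       is_characteristic = TRUE, isotopologues = NULL) {
  if (inherits(tracers, "tracer_spec")) tracers <- list(tracers)
  if (is.character(formula)) formula <- parse_formula(formula)
  errs <- character(0)
  add <- function(e) errs <<- c(errs, e)
  if (!length(tracers) %in% 1:2 || !all(vapply(tracers, inherits, TRUE, "tracer_spec")))
    add("tracers must be one or two tracer_spec objects")
  charge <- as.integer(charge)
  if (is.na(charge) || charge == 0L) add("charge must be a non-zero integer")
  if (!is.numeric(base_mz) || base_mz <= 0) add("base_mz must be > 0")
  if (!is.numeric(rt_window) || rt_window <= 0) add("rt_window must be > 0")
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% 1:2) add("ms_level must be 1 or 2")
  if (ms_level == 2L && is.null(precursor_mz)) add("ms_level 2 requires precursor_mz")
  for (tr in tracers) {
    if (!inherits(tr, "tracer_spec")) next
    have <- if (tr$element %in% names(formula)) formula[[tr$element]] else 0L
    if (tr$n_positions > have)
      add(sprintf("tracer %d%s claims %d positions but formula has %d %s atoms",
                  tr$isotope, tr$element, tr$n_positions, have, tr$element))
  }
  if (length(tracers) == 2L && inherits(tracers[[1]], "tracer_spec") &&
      inherits(tracers[[2]], "tracer_spec") &&
      tracers[[1]]$element == tracers[[2]]$element)
    add("dual tracers must label distinct elements")
  if (is.null(isotopologues)) {
    isotopologues <- if (length(tracers) == 1L) 0:tracers[[1]]$n_positions
                     else .dual_channels(tracers[[1]]$n_positions, tracers[[2]]$n_positions)
  }
  if (length(tracers) == 2L) {
    isotopologues <- as.matrix(isotopologues)
    storage.mode(isotopologues) <- "integer"
    if (ncol(isotopologues) != 2L) add("dual-tracer isotopologues must be (i, j) pairs")
    else {
      if (anyDuplicated(isotopologues)) add("duplicate isotopologue channels")
      if (any(isotopologues < 0L) ||
          any(isotopologues[, 1L] > tracers[[1]]$n_positions) ||
          any(isotopologues[, 2L] > tracers[[2]]$n_positions))
        add("isotopologue pairs outside tracer bounds")
    }
  } else {
    isotopologues <- as.integer(isotopologues)
    if (length(isotopologues) == 0L) add("isotopologues must be non-empty")
    if (anyDuplicated(isotopologues)) add("duplicate isotopologue channels")
    if (inherits(tracers[[1]], "tracer_spec") &&
        any(isotopologues < 0L | isotopologues > tracers[[1]]$n_positions))
      add("isotopologue label counts outside 0..n_positions")
  }
  if (length(errs)) stop("invalid target '", compound, "': ",
                         paste(errs, collapse = "; "))
  structure(list(compound = compound, ion = ion, formula = formula,
                 charge = charge, base_mz = base_mz, tracers = tracers,
                 expected_rt = expected_rt, rt_window = rt_window,
                 ms_level = ms_level, precursor_mz = precursor_mz,
                 is_characteristic = isTRUE(is_characteristic),
                 isotopologues = isotopologues),
            class = "target_ion")
}

#' @export
print.target_ion <- function(x, ...) {
  trs <- paste(vapply(x$tracers, function(t)
    sprintf("%d%s(n=%d)", t$isotope, t$element, t$n_positions), ""), collapse = " + ")
  nch <- if (is.matrix(x$isotopologues)) nrow(x$isotopologues) else length(x$isotopologues)
  cat(sprintf("<target_ion> %s / %s  %s z=%+d  base m/z %.4f  RT %.1f±%.0f s  MS%d  %s  %d channels%s\n",
              x$compound, x$ion, format_formula(x$formula), x$charge, x$base_mz,
              x$expected_rt, x$rt_window, x$ms_level, trs, nch,
              if (x$is_characteristic) " [characteristic]" else ""))
  invisible(x)
}

# Number of quantified channels of a target.
n_channels <- function(target) {
  if (is.matrix(target$isotopologues)) nrow(target$isotopologues)
  else length(target$isotopologues)
}

# Channel labels like "M+2" / "M+1.1" (c13.n15) for output tables.
channel_labels <- function(target) {
  ch <- target$isotopologues
  if (is.matrix(ch)) paste0("M+", ch[, 1L], ".", ch[, 2L]) else paste0("M+", ch)
}

#' Theoretical m/z of an isotopologue
#'
#' \code{base_mz + sum_t(count_t * mass_shift_t) / |charge|} with the exact
#' heavy-light isotope mass differences (e.g. 13C-12C = 1.003355 Da).
#'
#' @param target a [target_ion()].
#' @param label_count integer label count (single tracer) or length-2 vector
#'   of counts (dual tracer).
#' @return m/z value.
#' @export
#' @examples
#' t <- target_ion("gln", formula = "C5H11N2O3", charge = 1, base_mz = 147.0764,
#'                 tracers = tracer_spec("C", 13, 5), expected_rt = 300)
#' isotopologue_mz(t, 5)   # 147.0764 + 5 * 1.003355
isotopologue_mz <- function(target, label_count) {
  label_count <- as.integer(label_count)
  if (length(label_count) != length(target$tracers))
    stop("label_count must give one count per tracer")
  shift <- 0
  for (k in seq_along(target$tracers)) {
    tr <- target$tracers[[k]]
    if (label_count[k] < 0L || label_count[k] > tr$n_positions)
      stop("label count ", label_count[k], " outside 0..", tr$n_positions,
           " for tracer ", tr$isotope, tr$element)
    shift <- shift + label_count[k] * tr$mass_shift
  }
  target$base_mz + shift / abs(target$charge)
}

# m/z of every quantified channel, in method order.
channel_mzs <- function(target) {
  ch <- target$isotopologues
  if (is.matrix(ch)) apply(ch, 1L, function(p) isotopologue_mz(target, p))
  else vapply(ch, function(k) isotopologue_mz(target, k), 0)
}

#' Assemble a processing method
#'
#' Bundles the target list with instrument and processing parameters. All
#' parameters have conventional, overridable defaults.
#'
#' @param targets list of [target_ion()] objects.
#' @param resolution_mode \code{"high_res"} or \code{"low_res"}; selects the
#'   m/z tolerance default and the correction-matrix algorithm.
#' @param mz_tolerance_ppm,mz_tolerance_da extraction tolerance (ppm in
#'   high-res mode, Th in low-res mode).
#' @param smoothing_window,smoothing_order Savitzky-Golay parameters (window
#'   in scans, odd, greater than the order).
#' @param noise_multiplier_k detection/bound threshold is
#'   baseline + k * noise.
#' @param asymmetry_cap maximum ratio of the longer to the shorter
#'   apex-to-edge width (>= 1).
#' @param correction_enabled apply natural-abundance correction.
#' @return Object of class \code{ms_method}.
#' @export
ms_method <- function(targets,
                      resolution_mode = .method_defaults$resolution_mode,
                      mz_tolerance_ppm = .method_defaults$mz_tolerance_ppm,
                      mz_tolerance_da = .method_defaults$mz_tolerance_da,
                      smoothing_window = .method_defaults$smoothing_window,
                      smoothing_order = .method_defaults$smoothing_order,
                      noise_multiplier_k = .method_defaults$noise_multiplier_k,
                      asymmetry_cap = .method_defaults$asymmetry_cap,
                      correction_enabled = .method_defaults$correction_enabled,
                      isotopes = default_isotope_table()) {
  if (inherits(targets, "target_ion")) targets <- list(targets)
  errs <- character(0)
  if (!length(targets) || !all(vapply(targets, inherits, TRUE, "target_ion")))
    errs <- c(errs, "targets must be a non-empty list of target_ion objects")
  else {
    by_comp <- split(targets, vapply(targets, `[[`, "", "compound"))
    for (comp in names(by_comp))
      if (!any(vapply(by_comp[[comp]], `[[`, TRUE, "is_characteristic")))
        errs <- c(errs, paste0("compound '", comp, "' has no characteristic ion"))
  }
  if (!resolution_mode %in% c("high_res", "low_res"))
    errs <- c(errs, "resolution_mode must be 'high_res' or 'low_res'")
  if (mz_tolerance_ppm <= 0 || mz_tolerance_da <= 0)
    errs <- c(errs, "mz tolerance must be > 0")
  smoothing_window <- as.integer(smoothing_window)
  smoothing_order <- as.integer(smoothing_order)
  if (smoothing_window %% 2L != 1L || smoothing_window <= smoothing_order)
    errs <- c(errs, "smoothing window must be odd and greater than the polynomial order")
  if (noise_multiplier_k < 0) errs <- c(errs, "noise_multiplier_k must be >= 0")
  if (asymmetry_cap < 1) errs <- c(errs, "asymmetry_cap must be >= 1")
  if (length(errs)) stop("invalid method: ", paste(errs, collapse = "; "))
  structure(list(targets = targets, resolution_mode = resolution_mode,
                 mz_tolerance_ppm = mz_tolerance_ppm,
                 mz_tolerance_da = mz_tolerance_da,
                 smoothing_window = smoothing_window,
                 smoothing_order = smoothing_order,
                 noise_multiplier_k = noise_multiplier_k,
                 asymmetry_cap = asymmetry_cap,
                 correction_enabled = isTRUE(correction_enabled),
                 isotopes = validate_isotope_table(isotopes)),
            class = "ms_method")
}

#' @export
print.ms_method <- function(x, ...) {
  tol <- if (x$resolution_mode == "high_res")
    sprintf("%.3g ppm", x$mz_tolerance_ppm) else sprintf("%.3g Th", x$mz_tolerance_da)
  cat(sprintf("<ms_method> %d targets, %s (tol %s), SG %d/%d, k=%g, asymmetry cap %g, correction %s\n",
              length(x$targets), x$resolution_mode, tol, x$smoothing_window,
              x$smoothing_order, x$noise_multiplier_k, x$asymmetry_cap,
              if (x$correction_enabled) "on" else "off"))
  for (t in x$targets) print(t)
  invisible(x)
}

# Absolute extraction half-window (Th) at a given m/z.
mz_halfwindow <- function(method, mz) {
  if (method$resolution_mode == "high_res") mz * method$mz_tolerance_ppm * 1e-6
  else method$mz_tolerance_da
}

#' Load a method from a JSON config file
#'
#' Parses and fully validates a declarative method config (schema_version 1).
#' Every invariant violation found is reported, not just the first.
#'
#' @param path JSON file path.
#' @return An [ms_method()] object.
#' @export
load_method <- function(path) {
  if (!file.exists(path)) stop("method file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.integer(cfg$schema_version %||% 1L), 1L))
    stop("unsupported method schema_version: ", cfg$schema_version)
  isotopes <- default_isotope_table()
  if (!is.null(cfg$isotopes)) {
    for (el in names(cfg$isotopes)) {
      d <- cfg$isotopes[[el]]
      isotopes[[el]] <- data.frame(mass_number = unlist(d$mass_number),
                                   mass = unlist(d$mass),
                                   abundance = unlist(d$abundance))
    }
  }
  errs <- character(0)
  targets <- list()
  for (i in seq_along(cfg$targets)) {
    tj <- cfg$targets[[i]]
    t <- tryCatch({
      tracers <- lapply(tj$tracers, function(tr)
        tracer_spec(tr$element, tr$isotope, tr$n_positions))
      iso <- tj$isotopologues
      if (!is.null(iso)) {
        iso <- if (length(tracers) == 2L)
          do.call(rbind, lapply(iso, function(p) as.integer(unlist(p))))
        else as.integer(unlist(iso))
      }
      do.call(target_ion, c(
        list(compound = tj$compound, formula = tj$formula,
             charge = tj$charge, base_mz = tj$base_mz, tracers = tracers,
             expected_rt = tj$expected_rt, isotopologues = iso),
        if (!is.null(tj$ion)) list(ion = tj$ion),
        if (!is.null(tj$rt_window)) list(rt_window = tj$rt_window),
        if (!is.null(tj$ms_level)) list(ms_level = tj$ms_level),
        if (!is.null(tj$precursor_mz)) list(precursor_mz = tj$precursor_mz),
        if (!is.null(tj$is_characteristic)) list(is_characteristic = tj$is_characteristic)))
    }, error = function(e) {
      errs <<- c(errs, sprintf("target %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(t)) targets <- c(targets, list(t))
  }
  m <- tryCatch(do.call(ms_method, c(
    list(targets = targets, isotopes = isotopes),
    cfg[intersect(names(cfg), c("resolution_mode", "mz_tolerance_ppm",
                                "mz_tolerance_da", "smoothing_window",
                                "smoothing_order", "noise_multiplier_k",
                                "asymmetry_cap", "correction_enabled"))])),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  if (length(errs)) stop("method validation failed:\n  - ",
                         paste(errs, collapse = "\n  - "))
  m
}

#' Save a method to a JSON config file
#'
#' Inverse of [load_method()]: \code{load_method(save_method(m, f))}
#' reproduces \code{m}.
#'
#' @param method an [ms_method()].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
save_method <- function(method, path) {
  stopifnot(inherits(method, "ms_method"))
  tj <- lapply(method$targets, function(t) {
    iso <- t$isotopologues
    c(list(compound = t$compound, ion = t$ion,
           formula = format_formula(t$formula), charge = t$charge,
           base_mz = t$base_mz,
           tracers = lapply(t$tracers, function(tr)
             list(element = tr$element, isotope = tr$isotope,
                  n_positions = tr$n_positions)),
           expected_rt = t$expected_rt, rt_window = t$rt_window,
           ms_level = t$ms_level, is_characteristic = t$is_characteristic,
           isotopologues = if (is.matrix(iso))
             lapply(seq_len(nrow(iso)), function(r) as.integer(iso[r, ]))
           else as.list(as.integer(iso))),
      if (!is.null(t$precursor_mz)) list(precursor_mz = t$precursor_mz))
  })
  cfg <- list(schema_version = 1L,
              resolution_mode = method$resolution_mode,
              mz_tolerance_ppm = method$mz_tolerance_ppm,
              mz_tolerance_da = method$mz_tolerance_da,
              smoothing_window = method$smoothing_window,
              smoothing_order = method$smoothing_order,
              noise_multiplier_k = method$noise_multiplier_k,
              asymmetry_cap = method$asymmetry_cap,
              correction_enabled = method$correction_enabled,
              isotopes = lapply(method$isotopes, function(d)
                list(mass_number = d$mass_number, mass = d$mass,
                     abundance = d$abundance)),
              targets = tj)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
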