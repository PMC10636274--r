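#' Natural isotope abundance table
#'
#' Per-element isotope data used to build natural-abundance distributions and
#' correction matrices: mass number, exact mass (Da) and natural fractional
#' abundance (CIAAW representative values). Abundances sum to 1 per element.
#'
#' @return A named list; one data frame per element with columns
#'   \code{mass_number}, \code{mass}, \code{abundance} (lightest isotope
#'   first).
#' @export
#' @examples
#' default_isotope_table()$C
default_isotope_table <- function() {
  iso <- function(mn, mass, ab) data.frame(mass_number = mn, mass = mass, abundance = ab)
  list(
    H  = iso(c(1, 2),          c(1.0078250319, 2.0141017781),              c(0.999885, 0.000115)),
    C  = iso(c(12, 13),        c(12.0000000000, 13.0033548351),            c(0.9893, 0.0107)),
    N  = iso(c(14, 15),        c(14.0030740052, 15.0001088984),            c(0.99636, 0.00364)),
    O  = iso(c(16, 17, 18),    c(15.9949146221, 16.9991315012, 17.9991604), c(0.99757, 0.00038, 0.00205)),
    S  = iso(c(32, 33, 34, 36), c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
             c(0.9499, 0.0075, 0.0425, 0.0001)),
    P  = iso(31, 30.97376151, 1),
    F  = iso(19, 18.99840320, 1),
    Na = iso(23, 22.98976928, 1),
    K  = iso(c(39, 40, 41),    c(38.96370649, 39.96399817, 40.96182526),   c(0.932581, 0.000117, 0.067302)),
    Cl = iso(c(35, 37),        c(34.96885268, 36.96590260),                c(0.7576, 0.2424)),
    Si = iso(c(28, 29, 30),    c(27.97692653, 28.97649466, 29.97377014),   c(0.92223, 0.04685, 0.03092)),
    Br = iso(c(79, 81),        c(78.9183376, 80.9162897),                  c(0.5069, 0.4931)),
    I  = iso(127, 126.904473, 1)
  )
}

#' Validate (and lightly renormalize) an isotope table
#'
#' Checks the structural invariants: abundances in [0, 1] and summing to 1 per
#' element, mass numbers unique and sorted ascending. Abundance sums off by
#' less than 1e-6 (e.g. user overrides quoted to 4 digits) are renormalized;
#' larger discrepancies are an error.
#'
#' @param table list as returned by [default_isotope_table()].
#' @return The validated table.
#' @export
validate_isotope_table <- function(table) {
  stopifnot(is.list(table), length(table) >= 1)
  for (el in names(table)) {
    d <- table[[el]]
    if (!all(c("mass_number", "mass", "abundance") %in% names(d)))
      stop("isotope table entry for ", el, " lacks required columns")
    if (is.unsorted(d$mass_number, strictly = TRUE))
      stop("isotope table entry for ", el, ": mass numbers must be strictly increasing")
    if (any(d$abundance < 0 | d$abundance > 1))
      stop("isotope table entry for ", el, ": abundances outside [0, 1]")
    s <- sum(d$abundance)
    if (abs(s - 1) > 1e-6)
      stop("isotope table entry for ", el, ": abundances sum to ", format(s), ", not 1")
    table[[el]]$abundance <- d$abundance / s
  }
  table
}

# Supported tracer isotopes: element, heavy mass number, exact mass shift vs
# the lightest isotope, and the nominal (integer) shift used for channel
# spacing.
.tracer_registry <- function(isotopes = default_isotope_table()) {
  spec <- list(H = 2L, C = 13L, N = 15L, O = 18L, S = 34L)
  out <- lapply(names(spec), function(el) {
    d <- isotopes[[el]]
    i <- match(spec[[el]], d$mass_number)
    shift <- d$mass[i] - d$mass[1]
    list(element = el, isotope = spec[[el]], mass_shift = shift,
         nominal_shift = as.integer(round(shift)))
  })
  names(out) <- paste0(vapply(out, `[[`, 1L, "isotope"), names(spec))
  out
}

#' Tracer specification
#'
#' Describes one stable-isotope tracer on a target ion: the labeled element,
#' the heavy-isotope mass number, and how many atom positions of that element
#' can carry label. Supported (element, isotope) pairs: (H,2), (C,13),
#' (N,15), (O,18), (S,34).
#'
#' @param element element symbol ("H", "C", "N", "O" or "S").
#' @param isotope heavy-isotope mass number (2, 13, 15, 18 or 34).
#' @param n_positions number of potentially labeled atoms (0 gives a
#'   degenerate tracer with the single unlabeled state, useful to reduce a
#'   dual-tracer layout to a single-tracer one).
#' @return An object of class \code{tracer_spec} with fields \code{element},
#'   \code{isotope}, \code{n_positions}, \code{mass_shift} (exact Da per
#'   label) and \code{nominal_shift} (integer mass-unit spacing per label).
#' @export
#' @examples
#' tracer_spec("C", 13, 5)   # [U-13C5]-style carbon tracer
tracer_spec <- function(element, isotope, n_positions) {
  reg <- .tracer_registry()
  key <- paste0(isotope, element)
  if (!key %in% names(reg))
    stop("unsupported tracer isotope: ", isotope, element,
         " (supported: 2H, 13C, 15N, 18O, 34S)")
  n_positions <- as.integer(n_positions)
  if (is.na(n_positions) || n_positions < 0L)
    stop("n_positions must be a non-negative integer")
  r <- reg[[key]]
  structure(list(element = r$element, isotope = r$isotope,
                 n_positions = n_positions, mass_shift = r$mass_shift,
                 nominal_shift = r$nominal_shift),
            class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("<tracer> %d%s x %d positions (+%.6f Da per label)\n",
              x$isotope, x$element, x$n_positions, x$mass_shift))
  invisible(x)
}

#' Parse a molecular formula
#'
#' Parses a Hill-notation-like elemental formula (element symbols followed by
#' optional counts, no parentheses) into a named count vector. Element symbols
#' must be present in the isotope table.
#'
#' @param text formula string, e.g. \code{"C5H10N2O3"}.
#' @param isotopes isotope table (for the set of known elements).
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C5H10N2O3")
parse_formula <- function(text, isotopes = default_isotope_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m))
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    bad <- substr(text, which(!covered)[1], nchar(text))
    stop("malformed formula '", text, "': unparseable at '", bad, "'")
  }
  counts <- integer(0)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(isotopes))
      stop("malformed formula '", text, "': unknown element '", el, "'")
    if (n < 1L) stop("malformed formula '", text, "': zero count for '", el, "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

# Format a count vector back to a formula string (canonical element order).
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return("")
  ord <- order(match(names(counts), c("C", "H"), nomatch = 3L), names(counts))
  paste0(names(counts)[ord], ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}
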