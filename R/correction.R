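# Natural-abundance correction: build the linear map from fractional label
# distributions to observable mass-isotopologue fractions, and invert it.

# Multiply two abundance polynomials (index = nominal mass shift, 0-based).
.polymul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(numeric(0))
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# a^n by binary exponentiation.
.polypow <- function(a, n) {
  out <- 1
  base <- a
  while (n > 0L) {
    if (n %% 2L == 1L) out <- .polymul(out, base)
    base <- if (n > 1L) .polymul(base, base) else base
    n <- n %/% 2L
  }
  out
}

#' Natural isotopic distribution of a molecular formula
#'
#' Probability that a molecule of the given elemental composition, with every
#' atom at natural isotopic abundance, carries a total nominal mass shift of
#' 0, 1, ..., \code{max_shift} (shift of an isotope = its mass number minus
#' the element's lightest mass number). Computed by polynomial expansion:
#' each atom contributes its element's per-atom shift distribution and the
#' per-atom polynomials are convolved.
#'
#' @param formula named count vector (from [parse_formula()]) or formula
#'   string. An empty formula yields the identity distribution \code{c(1)}.
#' @param max_shift largest shift to report; \code{Inf} (default) keeps the
#'   full support.
#' @param isotopes isotope table.
#' @return Numeric vector over shifts \code{0:max_shift} (or the full
#'   support), with attribute \code{tail_mass} giving the truncated
#'   probability mass beyond \code{max_shift}.
#' @export
#' @examples
#' natural_distribution("C1")       # c(0.9893, 0.0107)
#' natural_distribution("C6H12O6", max_shift = 3)
natural_distribution <- function(formula, max_shift = Inf,
                                 isotopes = default_isotope_table()) {
  if (is.character(formula)) formula <- parse_formula(formula, isotopes)
  formula <- formula[formula > 0]
  dist <- 1
  for (el in names(formula)) {
    d <- isotopes[[el]]
    if (is.null(d)) stop("unknown element '", el, "' in formula")
    atom <- numeric(max(d$mass_number) - min(d$mass_number) + 1L)
    atom[d$mass_number - min(d$mass_number) + 1L] <- d$abundance
    dist <- .polymul(dist, .polypow(atom, formula[[el]]))
  }
  if (is.finite(max_shift)) {
    keep <- seq_len(min(length(dist), max_shift + 1L))
    tail_mass <- sum(dist[-keep])
    dist <- dist[keep]
    if (length(dist) < max_shift + 1L) dist <- c(dist, numeric(max_shift + 1L - length(dist)))
  } else {
    tail_mass <- 0
  }
  structure(dist, tail_mass = tail_mass)
}

# Look up distribution values at the given nominal shifts (0 outside support).
.dist_at <- function(dist, shifts) {
  out <- numeric(length(shifts))
  ok <- shifts >= 0 & shifts < length(dist)
  out[ok] <- dist[shifts[ok] + 1L]
  out
}

.new_correction_matrix <- function(M, mode, formula, tracers, channels,
                                   channel_shifts, states = channels) {
  dimnames(M) <- list(
    channel = vapply(seq_len(nrow(M)), function(i) .channel_label(channels, i), ""),
    label_state = vapply(seq_len(ncol(M)), function(j) .channel_label(states, j), ""))
  structure(list(matrix = M, mode = mode, formula = formula, tracers = tracers,
                 channels = channels, channel_shifts = channel_shifts),
            class = "correction_matrix")
}

.channel_label <- function(channels, i) {
  if (is.matrix(channels)) paste0("M+", channels[i, 1L], ".", channels[i, 2L])
  else paste0("M+", channels[i])
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("<correction_matrix> %s, formula %s, %d channels x %d label states\n",
              x$mode, format_formula(x$formula), nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Single-tracer natural-abundance correction matrix
#'
#' Column \eqn{j} holds the observable mass-isotopologue distribution of a
#' molecule carrying exactly \eqn{j} tracer labels. At low resolution every
#' atom of the ion contributes natural background; at high resolution only
#' atoms of the tracer element do (heavy isotopes of other elements are
#' mass-resolved away from the tracer channels). Rows are the tracked
#' channels; mass shifts falling between tracked channels are dropped, so
#' column sums may be below 1.
#'
#' @param formula elemental composition of the ion (vector or string).
#' @param tracer a [tracer_spec()].
#' @param mode \code{"low_res_ms1"} or \code{"high_res_ms1"}.
#' @param channels integer label counts tracked (default
#'   \code{0:n_positions}).
#' @param isotopes isotope table.
#' @return A \code{correction_matrix} object; \code{$matrix} is
#'   lower-triangular in the label ordering (natural background only adds
#'   mass).
#' @export
#' @examples
#' build_correction_matrix("C2", tracer_spec("C", 13, 2), "high_res_ms1")
build_correction_matrix <- function(formula, tracer,
                                    mode = c("high_res_ms1", "low_res_ms1"),
                                    channels = NULL,
                                    isotopes = default_isotope_table()) {
  mode <- match.arg(mode)
  if (is.character(formula)) formula <- parse_formula(formula, isotopes)
  stopifnot(inherits(tracer, "tracer_spec"))
  el <- tracer$element
  n_el <- if (el %in% names(formula)) formula[[el]] else 0L
  if (n_el < tracer$n_positions)
    stop("tracer claims ", tracer$n_positions, " labeled ", el,
         " positions but the formula has only ", n_el)
  if (is.null(channels)) channels <- 0:tracer$n_positions
  channels <- as.integer(channels)
  if (anyDuplicated(channels) || any(channels < 0L | channels > tracer$n_positions))
    stop("channels must be distinct label counts in 0..n_positions")
  states <- 0:tracer$n_positions
  s <- tracer$nominal_shift
  max_obs_shift <- max(channels) * s
  M <- matrix(0, nrow = length(channels), ncol = length(states))
  for (j in seq_along(states)) {
    nlab <- states[j]
    # A tracer with zero tracked positions reverts to a plain background
    # element: at high resolution its heavy isotopologues are mass-resolved
    # away from (and excluded by) the tracer channels.
    corr <- switch(mode,
      low_res_ms1  = { f <- formula; f[[el]] <- f[[el]] - nlab; f },
      high_res_ms1 = if (tracer$n_positions == 0L) integer(0)
                     else c(setNames(n_el - nlab, el)))
    dist <- natural_distribution(corr, max_shift = max(0L, max_obs_shift - nlab * s),
                                 isotopes = isotopes)
    M[, j] <- .dist_at(dist, channels * s - nlab * s)
  }
  .new_correction_matrix(M, mode, formula, list(tracer), channels,
                         channel_shifts = channels * s, states = states)
}

# Row-major flattening of dual-tracer label pairs: first tracer outer.
.dual_channels <- function(n1, n2) {
  as.matrix(expand.grid(t2 = 0:n2, t1 = 0:n1))[, c("t1", "t2"), drop = FALSE]
}

#' Dual-tracer correction matrix
#'
#' Correction matrix over flattened (i, j) label pairs for two distinct
#' tracer elements (row-major, first tracer outer). In high-resolution mode
#' the matrix is the Kronecker-style combination of the two single-tracer
#' matrices; in low-resolution mode columns are natural distributions of the
#' formula with both tracers' labeled atoms removed, placed at the pair's
#' combined nominal shift. Tracked (i, j) channels that are isobaric at unit
#' resolution (identical combined nominal shift) cannot be distinguished and
#' raise a validation error unless \code{sum_isobaric = TRUE}, which merges
#' them into declared summed channels.
#'
#' @param formula elemental composition of the ion.
#' @param tracer1,tracer2 [tracer_spec()] objects with distinct elements.
#' @param mode \code{"high_res_ms1"} or \code{"low_res_ms1"}.
#' @param channels two-column integer matrix of tracked (tracer1, tracer2)
#'   label pairs; default all pairs, row-major.
#' @param sum_isobaric merge unit-resolution isobaric channels instead of
#'   erroring (low-res only).
#' @param isotopes isotope table.
#' @return A \code{correction_matrix}; \code{$channels} is the pair matrix.
#' @export
build_dual_matrix <- function(formula, tracer1, tracer2,
                              mode = c("high_res_ms1", "low_res_ms1"),
                              channels = NULL, sum_isobaric = FALSE,
                              isotopes = default_isotope_table()) {
  mode <- match.arg(mode)
  if (is.character(formula)) formula <- parse_formula(formula, isotopes)
  stopifnot(inherits(tracer1, "tracer_spec"), inherits(tracer2, "tracer_spec"))
  if (tracer1$element == tracer2$element)
    stop("dual tracers must label distinct elements")
  n1 <- tracer1$n_positions; n2 <- tracer2$n_positions
  if (is.null(channels)) channels <- .dual_channels(n1, n2)
  channels <- as.matrix(channels)
  storage.mode(channels) <- "integer"
  if (ncol(channels) != 2L || any(channels < 0L) ||
      any(channels[, 1L] > n1) || any(channels[, 2L] > n2))
    stop("channels must be (tracer1, tracer2) label pairs within bounds")
  states <- .dual_channels(n1, n2)
  s1 <- tracer1$nominal_shift; s2 <- tracer2$nominal_shift
  chan_shift <- channels[, 1L] * s1 + channels[, 2L] * s2

  if (mode == "high_res_ms1") {
    M1 <- build_correction_matrix(formula, tracer1, mode, channels = 0:n1,
                                  isotopes = isotopes)$matrix
    M2 <- build_correction_matrix(formula, tracer2, mode, channels = 0:n2,
                                  isotopes = isotopes)$matrix
    M <- matrix(0, nrow(channels), nrow(states))
    for (r in seq_len(nrow(channels)))
      for (cjs in seq_len(nrow(states)))
        M[r, cjs] <- M1[channels[r, 1L] + 1L, states[cjs, 1L] + 1L] *
                     M2[channels[r, 2L] + 1L, states[cjs, 2L] + 1L]
  } else {
    if (anyDuplicated(chan_shift)) {
      if (!sum_isobaric)
        stop("isobaric label-pair channels at unit resolution (equal nominal ",
             "shifts: ", paste(unique(chan_shift[duplicated(chan_shift)]),
             collapse = ", "), "); declare summed channels (sum_isobaric = TRUE)")
      # a summed channel measures each nominal mass once: collapse the
      # tracked pairs to their distinct nominal shifts before building M
      keep <- !duplicated(chan_shift)
      channels <- channels[keep, , drop = FALSE]
      chan_shift <- chan_shift[keep]
    }
    e1 <- tracer1$element; e2 <- tracer2$element
    M <- matrix(0, nrow(channels), nrow(states))
    for (cjs in seq_len(nrow(states))) {
      j1 <- states[cjs, 1L]; j2 <- states[cjs, 2L]
      f <- formula
      f[[e1]] <- f[[e1]] - j1
      f[[e2]] <- f[[e2]] - j2
      state_shift <- j1 * s1 + j2 * s2
      dist <- natural_distribution(f, max_shift = max(0L, max(chan_shift) - state_shift),
                                   isotopes = isotopes)
      M[, cjs] <- .dist_at(dist, chan_shift - state_shift)
    }
  }
  .new_correction_matrix(M, mode, formula, list(tracer1, tracer2), channels,
                         chan_shift, states = as.matrix(states))
}

#' Tandem-MS (product ion) correction matrix
#'
#' Correction matrix for the MID of a product ion measured after precursor
#' fragmentation. Atoms lost as the neutral fragment do not contribute to the
#' measured product m/z, so the matrix is built from the product-ion formula
#' only, with the number of tracer positions retained by the product.
#'
#' @param precursor_formula,product_formula elemental compositions; the
#'   product must be an element-wise subformula of the precursor.
#' @param tracer [tracer_spec()] defined on the precursor.
#' @param product_positions tracer positions retained in the product
#'   (<= tracer's positions).
#' @param mode,channels,isotopes as in [build_correction_matrix()].
#' @return A \code{correction_matrix} over the product-ion channels.
#' @export
build_tandem_matrix <- function(precursor_formula, product_formula, tracer,
                                product_positions,
                                mode = c("high_res_ms1", "low_res_ms1"),
                                channels = NULL,
                                isotopes = default_isotope_table()) {
  mode <- match.arg(mode)
  if (is.character(precursor_formula)) precursor_formula <- parse_formula(precursor_formula, isotopes)
  if (is.character(product_formula)) product_formula <- parse_formula(product_formula, isotopes)
  for (el in names(product_formula)) {
    have <- if (el %in% names(precursor_formula)) precursor_formula[[el]] else 0L
    if (product_formula[[el]] > have)
      stop("product formula is not a subformula of the precursor (element ", el, ")")
  }
  product_positions <- as.integer(product_positions)
  if (product_positions < 0L || product_positions > tracer$n_positions)
    stop("product_positions must be in 0..tracer n_positions")
  if (product_positions == 0L) {
    dist <- natural_distribution(product_formula, max_shift = 0, isotopes = isotopes)
    return(.new_correction_matrix(matrix(dist[1L], 1, 1), paste0("tandem_", mode),
                                  product_formula,
                                  list(tracer_zero = tracer), channels = 0L,
                                  channel_shifts = 0L))
  }
  prod_tracer <- tracer_spec(tracer$element, tracer$isotope, product_positions)
  cm <- build_correction_matrix(product_formula, prod_tracer, mode,
                                channels = channels, isotopes = isotopes)
  cm$mode <- paste0("tandem_", mode)
  cm
}

#' Correct a raw MID for natural isotopic background
#'
#' Solves the non-negative least squares problem
#' \eqn{\min_x \|Mx - m\|_2, x \ge 0} where \eqn{m} is the measured
#' (raw) MID and \eqn{M} the correction matrix, then renormalizes \eqn{x} to
#' sum to 1. When the matrix is square and well conditioned this matches
#' direct inversion whenever the direct solution is already non-negative;
#' unlike inversion it never returns unphysical negative fractions.
#'
#' @param raw_mid fractional abundances over the tracked channels (length =
#'   matrix rows); need not sum exactly to 1.
#' @param cm a \code{correction_matrix}.
#' @return Object of class \code{corrected_mid}: \code{fractions}
#'   (non-negative, sum 1), \code{residual_norm} (L2 residual of the
#'   constrained fit), \code{flag} ("ok" or "correction_failed").
#' @export
correct_mid <- function(raw_mid, cm) {
  stopifnot(inherits(cm, "correction_matrix"))
  M <- cm$matrix
  if (length(raw_mid) != nrow(M))
    stop("raw_mid length (", length(raw_mid), ") != matrix rows (", nrow(M), ")")
  fail <- function() structure(list(fractions = rep(NA_real_, ncol(M)),
                                    residual_norm = NA_real_,
                                    flag = "correction_failed"),
                               class = "corrected_mid")
  if (any(!is.finite(raw_mid))) return(fail())
  if (kappa(M, exact = TRUE) > 1e12) return(fail())
  x <- pracma::lsqnonneg(M, as.numeric(raw_mid))$x
  if (sum(x) <= 0) return(fail())
  resid <- sqrt(sum((M %*% x - raw_mid)^2))
  structure(list(fractions = x / sum(x), residual_norm = resid, flag = "ok"),
            class = "corrected_mid")
}

#' @export
print.corrected_mid <- function(x, ...) {
  cat("<corrected_mid>", x$flag, "\n")
  print(round(x$fractions, 6))
  cat("residual L2:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}
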