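---
title: "Quantifying mass isotopomer distributions: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mass isotopomer distributions: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midquant)
```

# The problem

A stable-isotope labeling experiment measures, for each target metabolite,
the fractional abundances of its mass isotopologues M+0, M+1, ... — the mass
isotopomer distribution (MID). Two properties make MIDs harder to quantify
than plain abundances. First, the quantity of interest is a *ratio* between
channels whose intensities can differ by orders of magnitude, so any
inconsistency in how the channels are integrated (different bounds, different
baseline treatment) biases the MID directly. Second, naturally occurring
heavy isotopes (1.07% ¹³C per carbon, 0.36% ¹⁵N per nitrogen, ...) produce an
isotopologue background that must be deconvolved from tracer incorporation
before the MID is interpretable.

midquant's pipeline addresses both: a single set of integration bounds is
derived from the *composite* (summed-isotopologue) chromatographic peak and
applied to every channel of the cluster, and the measured MID is corrected by
inverting an explicit forward model of natural abundance.

# Peak model and processing steps

## Extraction

Each isotopologue channel is an extracted ion chromatogram (EIC): per scan of
the configured MS level, the sum of centroided intensities within
`mz ± tol`. Profile scans are centroided first (intensity-weighted m/z over
each local maximum's contiguous support). All channels of one target are read
from the same scan set, so they share one retention-time grid by
construction; for MS2 targets, scans are selected by precursor isolation
window. The tolerance is ppm-relative in high-resolution mode and absolute
(Th) in low-resolution mode.

## Peak matching

The composite trace (point-wise channel sum) is smoothed with a
Savitzky–Golay filter, which preserves peak heights and widths far better
than moving averages (it reproduces polynomials up to the filter order
exactly — a property the test suite asserts). Candidate apexes are local
maxima inside `expected_rt ± rt_window` that clear `baseline + k × noise`.
Each candidate is scored

$$S = \exp\!\left(-\frac{\Delta rt^2}{2\sigma^2}\right)\cdot
      \frac{\text{apex} - \text{baseline}}{\max_c(\text{apex}_c - \text{baseline})},
      \qquad \sigma = \tfrac{1}{2}\,rt\_window,$$

optionally multiplied by the same Gaussian proximity term to the nearest
matched characteristic-ion apex of the compound. The form is a deliberate
design choice: a Gaussian RT kernel encodes "the right peak is near the
expected RT" with a scale tied to the user's stated uncertainty, and the
normalized-height factor prefers the dominant feature without letting a huge
distant peak outrank a plausible nearby one. Ties break toward the smaller
|Δrt|. Because the height term is normalized within the candidate set, the
score — and hence the match — is invariant to uniform intensity scaling of
the cluster.

Before matching, expected RTs are warped by a piecewise-linear map anchored
at the matched apexes of characteristic ions (expected → observed), constant
(offset-extrapolated) beyond the outermost anchors; with one anchor it is a
constant offset, with none the identity (with a warning).

## Noise, baseline, bounds

*Noise* is estimated as `1.4826 × median(|diff(y)|) / sqrt(2)` on the raw
composite: successive differencing cancels the slowly varying peak and
baseline, so no peak-free region has to be identified, and the median makes
the few large differences across the peak flanks irrelevant. The constant
makes the estimator consistent for the SD of i.i.d. Gaussian noise (checked
by Monte-Carlo in the tests).

*Baseline* is the straight line through the minimum smoothed intensity in the
leading and trailing 10% of the extraction window, extended linearly and
clamped at zero — exact for a linear drift, cheap, and robust as long as the
peak does not occupy an entire window edge.

*Bounds* walk outward from the apex until the smoothed composite drops below
`baseline + k × noise` or a local minimum falls below 5% of the
baseline-subtracted apex height (the 5% valley rule prevents merging shoulder
peaks into the integration region). Larger `k` can only tighten bounds
(asserted as a property test). Finally the asymmetry cap: if the longer
apex-to-edge width exceeds `asymmetry_cap ×` the shorter, the longer side is
*clipped* to exactly that multiple. Clipping (rather than extending the short
side) was chosen deliberately: it never integrates beyond detected signal,
trading a small, shared truncation of the tail — identical for every channel,
so nearly neutral for the MID — against the risk of sweeping a neighboring
compound into the integral.

## Integration, MID, APE

Channels are integrated on the *raw* intensities (smoothing is for locating
the peak only): `area = Σ max(yᵢ − bᵢ, 0)` between the shared bounds, where
`b` is the channel's own straight line between its intensities at the two
bound indices. Subtracting a per-channel edge-to-edge baseline — rather than
a share of the composite baseline — avoids negative areas and handles
channels that sit on different backgrounds. The raw MID is the area vector
normalized to 1 (records with zero total are flagged `low_signal` rather than
erroring); the APE per tracer is `100 × Σᵢ labelᵢ · midᵢ / n_positions`, with
dual-tracer MIDs marginalized per tracer.

# Natural-abundance correction

The forward model is linear: `m = M x`, where `x` is the fractional
distribution over label states and column `j` of `M` is the observable
isotopologue distribution of a molecule carrying exactly `j` labels. Columns
are natural-abundance distributions computed by polynomial convolution of
per-element multinomial isotope distributions (the implementation is verified
against a brute-force enumeration oracle to 1e-12), placed at the label
state's nominal mass shift and sampled at the tracked channel shifts —
channels the method does not track are simply dropped, so column sums may be
below 1, which is correct rather than an error.

The *resolution mode* decides which atoms contribute:

- **low_res**: every atom of the ion formula (minus the `j` labeled tracer
  atoms) contributes — at unit resolution all isobars fall into the same
  channel.
- **high_res**: only atoms of the tracer element contribute. Heavy isotopes
  of other elements are mass-resolved away from the tracer channels (e.g.
  ¹⁵N at +0.9970 vs ¹³C at +1.0034); because their loss scales all channels
  by the same factor it cancels in the MID normalization. This binary
  resolved/unresolved semantics is intentional — a numeric resolving-power
  model is out of scope.
- **tandem**: the matrix is built from the *product-ion* formula with the
  tracer positions the product retains; neutral-loss atoms never reach the
  detector. A product retaining the full precursor reduces exactly to the
  MS1 matrix.
- **dual tracer**: channels are (i, j) label pairs flattened row-major
  (first tracer outer). In high-res mode the matrix is the Kronecker-style
  product of the two single-tracer matrices; in low-res mode columns are
  full-formula distributions at combined nominal shifts. Tracked pairs that
  are isobaric at unit resolution (e.g. ¹³C₁ vs ¹⁵N₁) are physically
  indistinguishable there; the package refuses to build such a matrix unless
  the method declares summed channels, in which case the distinct nominal
  shifts become the channels. A tracer declared with 0 positions degenerates
  cleanly: the dual matrix reduces to the single-tracer matrix exactly.

Correction solves `min ‖Mx − m‖₂, x ≥ 0` (non-negative least squares) and
renormalizes `x` to sum to 1. NNLS was chosen over direct inversion because
negative fractions are unphysical; when the matrix is square, well
conditioned and the unconstrained solution is already non-negative the two
coincide, and the Monte-Carlo tests show the estimator is approximately
unbiased under small multiplicative noise. A condition number above 1e12
flags the record `correction_failed` instead of returning garbage. Isotope
abundances are CIAAW representative values, overridable per method config
(the `isotopes` section) for users who calibrate their own background.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mz_tolerance_ppm` | 10 | ppm | EIC half-window, high-res mode |
| `mz_tolerance_da` | 0.3 | Th | EIC half-window, low-res mode |
| `rt_window` | 30 | s | RT search half-window; also sets σ of the match score |
| `smoothing_window` / `order` | 7 / 3 | scans / – | Savitzky–Golay filter |
| `noise_multiplier_k` | 3 | – | detection & bound threshold baseline + k·noise |
| `asymmetry_cap` | 2.0 | – | max longer/shorter apex-to-edge width ratio |
| `low_signal_factor` | 10 | – | flags records with Σareas < 10·noise·width |

The defaults are conventional working values for LC–MS chromatography (scan
rates of 1–5 Hz, peak widths of tens of seconds); none is derived from a
fitted dataset, and all are overridable per method file.

# The synthetic-data generator

`simulate_run()` writes valid mzML (64-bit, zlib) with a ground-truth
sidecar: per target, a Gaussian or exponentially-modified-Gaussian peak
(τ = 2σ in the asymmetric fixtures) whose channel intensities follow
`M x` — the *same* forward model the corrector inverts — plus constant +
linear baseline and `y·(1 + N(0, σ_mult)) + N(0, σ_add)` noise clamped at
zero. Determinism under a fixed seed is byte-exact and tested.

What it emulates: isotopologue intensity ratios with natural background,
chromatographic shape and tailing, baseline drift, detector-like noise,
RT drift between runs (via shifted apex RTs), MS1 and MS2 scan series. What
it does not: electrospray saturation and ion suppression, isotopic fine
structure within a nominal channel, mass-accuracy drift, co-eluting
interferences beyond deliberately overlapping targets. Passing tests
therefore demonstrate correctness of the *algorithms* under a realistic but
idealized signal model, not robustness to every artifact of real
instruments.

Validation problem sizes (the package's own choices): end-to-end checks use
a five-standard glutamine suite (unlabeled, [1-¹³C], [1,2-¹³C₂], [¹⁵N₂],
[U-¹³C₅]) on an 18-channel dual-tracer layout at 0.5 s scan spacing;
noise robustness uses 100 Monte-Carlo replicates at 2% multiplicative and
1%-of-apex additive noise; oracle equivalence uses 20 random formulas of up
to 12 atoms.

# Degenerate inputs and numerical conventions

- EICs shorter than the smoothing window pass through unsmoothed with a
  warning; runs with no scans at the requested MS level are errors.
- A target whose peak is not matched produces a record flagged
  `peak_not_found` (areas 0, MID missing) — batches never abort on a single
  compound or file; corrupt files are skipped with a warning.
- Zero total area → `low_signal`, MID missing; `correction_failed` preserves
  the raw MID.
- Matching ties break toward the smaller |Δrt|; plateau maxima report their
  last point; bound clipping uses floor() on the capped width so a cap of
  2.0 yields an exactly 2:1 index-width ratio on the grid.
- The method file is declarative JSON (methods are data, not code), with a
  `schema_version` field and full-file validation that reports *every*
  violation at once.
- The exported workbook is a directory of CSV sheets plus a JSON manifest —
  deliberately plain text: byte-identical under reruns, diffable, and
  readable by every spreadsheet tool; numeric cells are written at 15
  significant digits so a re-read reproduces the values.

# Known limitations

- No untargeted peak detection; compounds must be declared with expected RTs.
- No deconvolution of co-eluting compounds beyond the valley rule and
  asymmetry cap.
- Tracer isotopic impurity is not modeled in the correction.
- SRM/MRM chromatogram objects stored natively in mzML are not read (only
  scan spectra); vendor-proprietary formats require prior conversion.
- At unit resolution, dual-label isobars are only handled as declared summed
  channels; a resolving-power-dependent partial-overlap model is out of
  scope.
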