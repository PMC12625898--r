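---
title: "Models and methods in paleotrail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleotrail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleotrail)
```

`paleotrail` chains four analyses that together support a
dispersal-ecology argument for Pleistocene hominins: taxonomic screening
of bone fragments by collagen peptide mass fingerprinting (ZooMS),
radiocarbon calibration of the resulting finds, mitochondrial-DNA
dissimilarity statistics, and a Monte Carlo Mahalanobis-distance habitat
suitability model driven by dated occurrences and a gridded paleoclimate
field. This vignette describes each model, its assumptions and tunable
parameters, the synthetic-data generators used for validation, and the
numerical choices and limitations a user should know about.

## ZooMS marker matching

A ZooMS reference library maps each taxon to the monoisotopic [M+H]⁺
masses of up to seven named collagen peptide markers (A–G). Matching is
deliberately minimal: marker *m* of a taxon matches when at least one
observed peak lies within ±`tol` of its reference mass, and the closest
peak is reported. A spectrum is assigned to the taxon with the most
matched markers, provided at least `min_markers` match; otherwise it is
`"unidentified"`.

Parameter choices:

* `tol = 0.2` Da. External calibration of linear MALDI-TOF instruments
  is typically good to ~0.1–0.3 Da in the 1–3 kDa range; ±0.2 Da accepts
  well-calibrated peaks while keeping the six-marker hominin match
  specific against the rest of the library.
* `min_markers = 4`. A majority of the seven markers; low enough to
  identify degraded spectra missing two or three peptides, high enough
  that random noise peaks essentially never reach it (the probability
  that 8 uniform noise peaks over a 2,800 Da range hit 4 specific
  ±0.2 Da windows is ≪ 10⁻⁶).

Both are configurable; neither is treated as physically meaningful
beyond this screening role. Ties between taxa are reported as a
composite label (e.g. `"Bovidae/Cervidae"`): collagen peptides are
genuinely shared across closely related clades, so a tie is a statement
about the data, not a failure. For the same reason one peak may satisfy
markers of several taxa — no peak exclusivity is enforced. Deamidation
and oxidation mass shifts are not modelled; matching is against the
reference masses only. The bundled library holds the six published
hominin marker masses; the other taxa carry illustrative masses chosen
to be mutually separable at the default tolerance (the file is named
`zooms_markers_synthetic_library.csv` to make its status explicit).

The peak-list generator `make_peaklist()` emulates a processed spectrum:
reference masses plus Gaussian jitter, optional marker dropout
(degraded peptides), and uniform noise peaks over the instrument range.
It does not emulate raw profile spectra, baselines, isotope envelopes,
or intensity physics — so passing tests validate the matching logic, not
peak picking.

## Radiocarbon calibration

A conventional radiocarbon determination *a* ± σ is calibrated against a
curve (μ(t), σ_c(t)) under the standard single-determination model with
a uniform prior over calendar time:

p(t) ∝ exp( −(a − μ(t))² / 2(σ² + σ_c(t)²) ).

Numerical choices:

* **Grid.** The posterior is evaluated on a 1 cal-yr grid over the
  curve's support (linear interpolation of μ and σ_c), removing grid
  discretization as a source of mismatch with published ranges.
* **Error combination.** The curve error is combined with the
  measurement error in quadrature — standard practice.
* **HPD intervals.** The smallest set of grid years holding the
  requested mass is found by sorting grid points by descending density
  and accumulating mass, then merging selected years into contiguous
  intervals. Multimodal posteriors (common on wiggly curves) naturally
  yield several disjoint intervals.
* **Endpoint rounding.** Endpoints are rounded *outward* to the nearest
  10 cal yr, the conventional reporting resolution for dates with
  multi-decade errors; `round_to = 0` disables this. Comparisons with
  published ranges should therefore tolerate ±10 yr at each endpoint.
* The density is computed in log space and normalized by its maximum
  before exponentiation, so extreme dates degrade gracefully rather than
  underflowing.

No reservoir or ΔR corrections, outlier models, or Bayesian
sequence/phase modelling are provided; those are deliberate non-goals.
The synthetic generator `make_calcurve()` produces an identity-mean
curve (μ(t) = t) plus seeded smooth sinusoidal wiggles and a constant
curve error. On the identity curve the posterior collapses to the
sampling Gaussian, giving a closed-form oracle: total-variation distance
below 10⁻⁶ and HPD intervals at ±1σ/±2σ are verified in the tests. The
parser reads the published IntCal text dialect (`#` headers; comma- or
whitespace-separated cal BP, ¹⁴C age, error columns, oldest first), so a
user-supplied IntCal20 file can be dropped in directly.

## mtDNA pairwise differences

For two rows of a multiple sequence alignment, *comparable sites* are
the columns where **both** sequences carry an unambiguous base
(A/C/G/T). Gaps, `N`, and IUPAC ambiguity codes are treated as missing
data and excluded from both numerator and denominator — the conservative
convention for low-coverage ancient consensus sequences, where
undercalled regions would otherwise masquerade as similarity.
`rank_dissimilarity()` sorts all other rows by descending difference
count, breaking ties lexicographically by name so output is
deterministic. Coordinates are 1-based alignment columns; no projection
to reference coordinates is attempted.

`make_alignment()` plants a known number of substitutions per derived
sequence at positions disjoint across sequences. Disjointness makes the
construction its own oracle: each derived sequence differs from the
reference by exactly its planted count, and two derived sequences differ
by the sum of theirs. Masking a fraction of sites to `N` emulates patchy
coverage; tests verify that masking can only decrease both counts. The
generator does not emulate alignment error, indel placement, or
rate heterogeneity along the molecule (e.g. hypervariable D-loop
structure), so planted-count recovery validates the counting logic, not
alignment quality.

`diagnostic_allele_fraction()` tallies read support at lineage-diagnostic
positions: covered reads are those with a called base (≠ N) at a
diagnostic site, matching reads those equal to the derived allele.

## The Monte Carlo habitat suitability model

The core model asks: given a handful of dated occurrences in a few
regions, when and where was climate similar to the conditions those
occurrences sampled? Each ensemble member:

1. **Balanced resampling.** Draws `k_per_box` records uniformly without
   replacement from each region box. Equal numbers per box prevent
   well-sampled regions from dominating the envelope. A box holding
   exactly `k_per_box` records (the Crimean box holds two) always
   contributes all of them.
2. **Age draw.** Each sampled record's age is drawn uniformly within its
   uncertainty bracket `(younger, older)`. Fossil tables conventionally
   print the older bound in the `min_age` column; the loader normalizes
   any row with `min_age > max_age` by swapping, with a warning.
3. **Climate extraction.** (T, P) at the nearest grid cell center
   (nearest independently per axis; longitude is wrap-aware across the
   dateline) and nearest 1,000-y time slice. Ages outside the field's
   span are clamped with a warning.
4. **Envelope fit.** Mean vector C̄ and inverse sample covariance Σ⁻¹
   (unbiased n−1 estimator) of the member's n×2 condition matrix.
5. **Suitability map.** For every grid cell and slice,
   d = (c − C̄)ᵀ Σ⁻¹ (c − C̄) and s = exp(−d) ∈ (0, 1], equal to 1
   exactly at the envelope mean.

The ensemble (default 5,000 members for the primary configuration of two
samples per box) is summarized by the arithmetic-mean suitability grid
and per-box time series: per slice, the unweighted mean of s over cells
whose centers fall inside the box, for each member and for the ensemble
mean.

Design choices made where the design was genuinely open:

* **Quadratic vs rooted distance.** The default exponentiates the
  quadratic form itself, `exp(−d)`; `distance_mode = "root"` instead
  uses the conventional Mahalanobis distance `exp(−√d)`. The quadratic
  form is the default because it is the natural Gaussian-kernel reading
  of "exponential decay of Mahalanobis distance" written without an
  explicit root; both are first-class and produce identical rankings of
  cells (the map between them is monotone), differing only in contrast.
* **Degenerate covariance.** If the member covariance is singular or has
  condition number > 10¹², it is ridge-regularized as S + εI with
  ε = 10⁻⁶ · trace(S)/2 (tiny absolute floor if the trace vanishes),
  with a warning. Members whose fit fails outright are skipped; a run
  with > 10% failed members errors.
* **Seeding.** One master seed derives an independent stream seed per
  member up front, so member *m* depends only on (master, m): results
  are identical regardless of scheduling, and the fast internal sampling
  path is RNG-identical to calling `sample_ensemble_member()` under the
  member's stream seed (asserted in the tests).
* **Memory.** Member grids are ~3 MB each; 5,000 are not retained.
  The ensemble accumulates the running mean grid and stores per-member
  box series for the requested boxes (`keep_members = TRUE` retains
  full grids for small ensembles).
* **Region membership** is by cell center, with boxes supplied in
  lon/lat bounds; region boxes are configuration, not code, since the
  published set of boxes is open-ended.

## The synthetic climate generator

`make_climate()` emulates 1,000-year averages of annual-mean temperature
and precipitation from a long transient simulation on a coarse global
grid (defaults 5.75° × 3.75°, 150→30 ka BP — a 63 × 49 × 121 field):

T(lon, lat, t) = T₀ + g_T·lat + A_T·sin(2πt/τ) + ε_T,

and analogously for P (clamped at zero). Defaults: T₀ = 10 °C,
g_T = −0.25 °C/°, A_T = 4 °C, τ = 100 ky, ε_T ~ N(0, 0.5²);
P₀ = 600 mm/yr, g_P = −2 mm/yr/°, A_P = 150 mm/yr, ε_P ~ N(0, 30²).
A single sinusoid is the simplest structure that creates
glacial–interglacial "windows": with τ = 100 ky the warm peak falls at
125 ka (a stand-in for the Last Interglacial, MIS5e) and the cold
trough at 75 ka (MIS4). Temperature and precipitation noise have
separate standard deviations because their units are incommensurate.
The generator does not attempt realistic atmospheric physics, orbital
forcing, land masking, or spatial autocorrelation of the noise; it
provides a field with known structure on which the niche model's
behaviour can be proven. Consequently, passing tests demonstrate that
the *model machinery* recovers planted structure — not that any
particular real-world reconstruction is correct.

`make_occurrences()` draws records inside each box with probability
proportional to a known bivariate-normal niche density evaluated at each
candidate (cell, slice)'s climate, storing the true age and climate in
`.true_*` columns that pipeline stages never read. Recovery is testable
because the generating truth is known: with climate availability
symmetric around the truth mean, the mean of sampled climates converges
to it (asserted within 3 standard errors at n ≈ 500).

## Validation experiments and problem sizes

The test suite runs every oracle at small, fixed sizes; the two larger
experiments are sized to be decisive yet quick:

* **Niche recovery** (`assess_envelope_recovery()`): 100 independent
  runs; each generates a fresh 63 × 49 × 121 climate field, draws 25
  occurrences per box from a truth envelope centred at (−2 °C,
  500 mm/yr) — comfortably inside the climate available in the study
  boxes — and runs a 100-member ensemble with 5 samples per box. A run
  passes when ≥ 90% of the top-decile ensemble-mean suitability elements
  (over all cells and slices) lie inside the truth's 99% Mahalanobis
  ellipse (χ²₂ quantile 9.21). The acceptance threshold is a ≥ 90%
  pass rate. The per-run rule is the package's own operationalization of
  "the model's best cells are the truth's niche"; it is deliberately
  strict (a miscentred or inflated envelope fails it quickly).
* **Full-size ensemble**: 5,000 members on the default synthetic grid
  with the bundled 12-specimen table, two samples per box — the primary
  study configuration — runs in well under ten minutes on one CPU
  (about two in practice).
* **Balance audit**: 10,000 members are drawn and checked for exact
  per-box balance and age-bound containment, expecting zero violations.

## Known limitations

* Suitability is a presence-only climate-envelope construct; it ignores
  biotic interactions, dispersal barriers other than climate, and any
  non-climatic taphonomy in the occurrence record.
* A two-variable (T, P) envelope with a single covariance cannot express
  multimodal or strongly non-elliptical niches.
* Nearest-gridpoint climate extraction does not interpolate; at 5.75°
  resolution a coastal or montane site inherits its coarse cell's
  climate.
* The identification logic matches reference masses only; heavily
  deamidated spectra may need a wider tolerance than the default.
* Calibration covers single determinations only — no sequence models,
  no marine or mixed curves.
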