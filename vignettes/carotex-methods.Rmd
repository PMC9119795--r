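---
title: "Methods: the carotex feature and classification pipeline"
author: "carotex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the carotex feature and classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Problem and scope

`carotex` classifies B-mode carotid ultrasound regions of interest as
containing a plaque deposit or not. The pipeline is: extract 63 named
features per image → stratified 75/25 split → normalize on the training rows
→ select the 22 most discriminant features → train Gaussian Naive Bayes and
dynamic learning vector quantization (DLVQ) → report a confusion-matrix
metric suite. This vignette records the models, the parameters that matter,
and every place where the design was genuinely open and a choice had to be
made.

# The 63-column feature table

The table is fixed at 33 texture + 5 shape + 10 histogram/correlogram + 15
morphology columns. (One sometimes sees the same inventory quoted as 65; the
family counts 33+5+10+15 = 63 are taken as authoritative, and the extractor
enforces exactly 63 finite, uniquely named columns.)

Families are computed by the operations they are named after, but several
operations return vectors (a 10-bin LBP histogram, per-filter Gabor
statistics, five run-length emphases, Krawtchouk moment vectors). The
*column* inventory therefore takes scalar summaries, chosen once:

* `glcm.*` — six co-occurrence statistics at distance 1, 32 gray levels,
  averaged over the four standard angles. The matrix is left asymmetric as
  defined (no transpose symmetrization); all six statistics are
  transpose-invariant, so the 4-angle mean is still invariant to 90°
  rotation. *Inertia* is reported as an alias of *contrast*: only one
  second-moment difference form is defined, and both names are in common
  use for it.
* `fos.*` — mean, median, excess kurtosis, skewness (moment estimators
  `g1`/`g2`; a near-constant sample reports 0 for both rather than 0/0).
* `glds.*` — mean, entropy, contrast, angular second moment and homogeneity
  of `|I(p) − I(p+d)|`, averaged over the four unit displacements.
* `fdta.fd` — differential box-counting dimension, least-squares slope of
  `log N(s)` vs `log(1/s)` over block sizes 2–4 ("resolution 4"). A flat
  surface scores ≈ 2.
* `fps.radial` / `fps.angular` — power-weighted centroids of the DFT power
  spectrum's normalized radius and unsigned angle (DC excluded); the
  underlying ring/wedge sums are available from `fourierSpectrumSums()`.
* `ngtdm.*` — classical neighbourhood gray-tone difference features
  (coarseness, contrast, complexity, strength), computed over pixels whose
  full 3×3 window lies in the ROI; the source names these features without
  formulas, so the standard literature definitions are used.
* `sfm.*` — statistical-feature-matrix summaries over the four unit
  displacements: coarseness `1/(ε + mean DSS)`, contrast `sqrt(mean CON)`,
  periodicity `(mean DSS − min DSS)/mean DSS`, and roughness as the log2
  ratio of distance-2 to distance-1 dissimilarity (an increment-slope
  reading; 0 for a flat image). At a single displacement SFM contrast² and
  GLDS contrast coincide by construction, which the tests exploit.
* `grad.*` — mean and variance of `√(Gx²+Gy²)` from central differences.
* `lbp.entropy` — entropy of the 10-bin uniform rotation-invariant LBP
  histogram (ties broken by `≥`, so a constant image lands in the all-ones
  bin).
* `gabor.energy` — mean response magnitude over a 2-frequency ×
  4-orientation bank (frequencies 0.15 and 0.3 cycles/px, σ = 0.56/f,
  zero-DC even part).
* `rle.sre`, `rle.lre`, `rle.rp` — short-run emphasis, long-run emphasis and
  run percentage averaged over the four directions (runs break at the ROI
  boundary). All five classical statistics are available from
  `runLengthFeatures()`.
* `shape.*` — the five contour features below, computed on the echogenic
  candidate region (see *Morphology*), falling back to the ROI outline when
  no candidate exists. The region descriptors (area, crack perimeter,
  perimeter²/area, centroid) are exported via `regionProps()` and feed the
  plaque geometry, but the shape family's column count stays at five.
* `hist.* / mrh.* / gld.* / hog.* / corr.*` — grayscale median, 32-bin
  histogram entropy and energy; inner-minus-outer band mean of the 3-band
  multiregion histogram; mean/variance/entropy of the absolute gray-level
  difference at unit displacement; HOG descriptor mean and max (8-px cells,
  9 unsigned bins, bilinear votes in orientation and position, per-cell L2
  normalization — the descriptor length is resolution-dependent, so the
  table keeps two fixed summaries); and the slope of the correlogram's
  band-mean intensity profile over normalized centre distance (8 bands).
* `morph.*` — see below.

Two textual features of the source family inventory have no operational
definition and are deliberately not columns: the "T₂ histogram for a known
mean scalar A" (no formula; the 32-bin first-order histogram serves) and a
separate Krawtchouk column (the moments are exported and tested via
`krawtchoukMoments()`, with the classical polynomials
`K_m(x; p, N) = ₂F₁(−m, −x; −N; 1/p)` computed by the three-term
recurrence; defaults p = 0.5 — which centres the basis so odd moments of
symmetric maps vanish — support = ROI bounding box, orders ≤ 3).

## Morphology and the candidate region

Morphology features describe *what the plaque is made of*, so they need a
plaque region. Clinical pipelines take a radiologist's outline; `carotex`
derives an **echogenic candidate** automatically: normalize intensities to
[0, 1] (divide by 255), threshold at t₁ inside the analysis ROI, and open
with a radius-1 cross to remove isolated speckle spikes. The ground-truth
phantom mask is never consulted during extraction.

The multilevel decomposition thresholds at t₁ = 1/3 and t₂ = 2/3 of the
normalized range (the cutoffs are not prescribed anywhere; equal thirds are
the neutral choice). Low (dark) components indicate echolucent, unstable
plaque; high components indicate calcified, stable plaque. From this come
the three per-level DFT powers, the pattern-spectrum granulometry (openings
with cross-shaped elements of radius 1–4; the PDF is the area fraction
removed per scale, the mean scale counts surviving mass at radius max+1),
the dark/bright fractions and the lipid-core / haemorrhage flags (largest
dark component above 0.2 / 0.35 of the filled candidate; rule-based
surrogates, since only the clinical concepts are named). Plaque size is
pixel count × spacing²; **volume is a 2-D surrogate** (per-column vertical
extent × spacing²) because true volume needs 3-D or cine data this pipeline
does not consume. Lumen surface roughness is the RMS deviation of the
per-column candidate interface from its 11-point moving average — a smooth
interface scores 0, a short-wavelength irregularity of amplitude a scores
≈ a/√2.

## Shape-feature readings

Two of the printed contour formulas are typographically ambiguous; the
package documents its readings rather than asserting authorial intent:

* sharpness uses `max(0, 1 − |2θ−π|/π)²` per vertex — the absolute value
  restores the symmetry the formula loses at reflex angles and keeps the
  term in [0, 1]; interior angles come from signed turning angles of the
  counter-clockwise boundary, so reflex vertices are handled.
* complexity is read as `10⁻³·n` (vertex count at a milli scale); the
  alternative reading `10 − 3n` goes negative for every polygon and is
  rejected.
* aspect ratio `(p₁+p₂)/C` needs a definition of C: the chord length along
  the principal axis of the boundary, which makes a circle score exactly 1
  and a 1×4 rectangle 0.25.
* circularity `4πA/P²` uses the Douglas–Peucker-simplified boundary
  (tolerance 1 px) for masks, so digital staircase steps do not inflate the
  perimeter — a digitized disk of radius 20 scores within 5% of 1.
  `regionProps()` deliberately uses a different convention (crack-edge
  perimeter, so a 10×10 square reports 40) because those descriptors
  feed size-style measurements, not isoperimetric ratios.

# The phantom

`generatePhantom()` draws a longitudinal view: adventitia bands (8 px, mean
180), intima/media wall bands (IMT default 5 px, mean 120), dark lumen
(mean 20), all multiplied by i.i.d. unit-mean gamma speckle with shape k
(default 16; smaller k = heavier speckle). A plaque is a half-ellipse on
the near wall protruding into the lumen (default echogenicity 150, width
3× height). Datasets draw per-image parameters uniformly from ranges
(`phantomRanges()`): lumen 15–30, wall 100–140, adventitia 160–200, IMT
3–8 px, plaque height 8–18 px, echogenicity 130–180, speckle shape 10–20,
at 202 normal / 159 plaque images of 64×64 px (0.1 mm/px) by default. The
analysis ROI handed to the extractor is the lumen/interface band a reader
would trace, derived from the geometry, not from the plaque.

What the phantom does emulate: band ordering and contrast, multiplicative
speckle with controllable contrast, plaque protrusion geometry and
echogenicity, and a difficulty dial (contrast → 0 makes the class
distributions converge). What it does not: wave propagation (no
point-spread function, attenuation shadows, refraction or anisotropy),
curved or bifurcating vessels, operator variability in the ROI. Passing
tests therefore certify the *computations*, not clinical performance.

# Normalization and selection

Features are z-scored then min-max rescaled to [0, 1]
(`zscoreUnitNormalize()`); a constant feature maps to 0.5 so degenerate
columns never abort a run. Statistics are fitted on the training rows only
and frozen onto test rows (clipped to [0, 1]) — the split must precede
normalization or test information leaks into the scaling. Following the
source convention, histogram and correlogram columns enter the table
unnormalized; texture, shape and morphology columns are normalized.

Selection ranks features by `|m₁−m₂|/√(σ₁²+σ₂²)` (sample standard
deviations; ties broken lexicographically by name so the result is
column-order invariant) and gates the ranking by PCA loadings: components
are kept to 95% variance, a feature is eligible if it is in the top
loading quartile of any kept component, the top k eligible features by
distance are taken, topped up by pure distance rank. The combination rule
of "distance criterion alongside PCA" is not prescribed; this hybrid is
fully parameterized so each pure method is recoverable (`variance_keep = 0`
→ pure distance; `k = F` → PCA report only). One refinement proved
necessary: because the unnormalized histogram columns have variances orders
of magnitude above the [0, 1] columns, a covariance-scale PCA gate
degenerates into "prefer the unnormalized features"; the gate therefore
standardizes columns first (correlation-scale PCA), which restores the
intended meaning — eligibility by correlation structure. `pcaFit()` itself
keeps the population (1/l) covariance, eigenvalues clamped at 1e-10 and
eigenvector signs fixed so the largest loading is positive. Optional
mutual-information screening (plug-in estimate on equal-frequency bins,
default threshold 0.01 bits) is off by default.

# Classifiers

**Gaussian Naive Bayes** stores empirical priors and class-conditional
means/variances (floored at ε = 1e-9). Posteriors are computed in the log
domain and normalized by log-sum-exp, so 63 small likelihoods cannot
underflow. The kernel variant replaces each 1-D Gaussian with a
Gaussian-kernel density estimate (Silverman bandwidth per class and
feature); as bandwidth → ∞ its posteriors collapse to the priors, which the
tests check.

**DLVQ** starts from class-mean prototypes. The winner for a sample
minimizes the win-count-scaled distance `‖y−n‖·(1 + c/Σc)`
(frequency-sensitive competitive learning; switchable off, giving plain
LVQ1) and moves by `±ρ_t(y − n)` — toward same-label samples, away from
different-label ones; for ρ ∈ (0,1) an attract step strictly contracts the
distance and a repel step strictly expands it, which is asserted on random
vectors. The step decays linearly, `ρ_t = ρ₀(1 − t/T)` with ρ₀ = 0.3 and
T = epochs × N. After each epoch any class with training error above
τ = 0.1 and fewer than 10 prototypes receives one prototype at the centroid
of its misclassified samples; the per-epoch error and prototype count are
kept in a training trace so growth behaviour is inspectable. The growth and
frequency-sensitivity mechanisms are named but not specified in the source;
both reconstructions are config-switchable. Prediction is plain
nearest-prototype (unscaled distance, ties to the lower index); the ROC
score is `d₋/(d₊+d₋)`.

Naive Bayes assumes feature independence within a class; when the
discriminative structure is a within-class correlation with identical
marginals, NB is near chance while DLVQ with growth carves the clusters.
The suite constructs exactly this case and checks DLVQ ≥ NB.

# Evaluation

Metrics are percentages from the confusion matrix (positive class =
plaque); any metric with a zero denominator is reported as undefined (NA),
never as 0. Two AUCs are reported separately because they are different
quantities: the balanced-accuracy form `(sensitivity+specificity)/2`
(algebraically the mean of two other reported metrics, asserted on random
matrices) and the trapezoidal ROC AUC, which equals the Mann–Whitney
statistic with midrank ties (asserted against `wilcox.test`). Published
tables in this area round or truncate to two decimals; `formatMetrics()`
truncates for display while full precision is kept internally, and
table-reproduction tests use a ±0.05 percentage-point slack for exactly
this rounding-vs-truncation ambiguity. Box-Cox λ is chosen by profile
log-likelihood on a grid (default −2…2 step 0.01), cross-checked against
`MASS::boxcox`.

# Numerical conventions

Coordinates are 0-based (row, col); contour polygons are closed and
counter-clockwise (positive shoelace area). All guarded divisions use
ε = 1e-9; NGTDM/SFM coarseness is capped at 1e9 for perfectly flat input.
Quantization to 32 gray levels (`floor(I·L/256)`) is shared by GLCM, NGTDM
and run-length features, matching the 32-bin histogram. Entropies are in
bits with 0·log 0 = 0. Every seed consumed by the package
(`splitDataset`, `generatePhantom`, `generateDataset`, `dlvqTrain`,
`dlvqInit`) is an explicit argument, and seeded code runs under
`withr::with_seed` so the caller's RNG state is untouched.

# Problem sizes in the test suite

Unit tests run on 6×6 to 32×32 images against brute-force oracles
(pair-enumeration GLCM, per-pixel NGTDM, run enumeration, bit-level LBP,
hypergeometric Krawtchouk sums). The end-to-end property tests use the full
361-image phantom study once (64×64 px) and a 120-image moderate-contrast
study for selection recall; these sizes keep the whole suite around two
minutes while still exercising the published class sizes.

# Known limitations

* The phantom's realism limits are listed above; in particular the
  morphology flags (lipid core, haemorrhage) are rule-based surrogates and
  have no synthetic positive controls beyond constructed maps.
* The 63-column scalarization is one defensible reconstruction of a family
  inventory that mixes scalars, vectors and concepts; the full vector
  outputs remain available through the per-family functions.
* `aspect_ratio` and the two corrupted contour formulas implement documented
  readings, not certain authorial intent.
* DLVQ growth uses one reconstruction (error-threshold + misclassified
  centroid); the training trace exists precisely so alternatives can be
  compared.
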