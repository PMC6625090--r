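---
title: "Methods: spatial statistics for immunogold nanocluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics for immunogold nanocluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

The pipeline analyzes 2-D coordinates of gold nanoparticles immunolabeling
a protein or lipid probe on an intact plasma-membrane sheet, digitized from
transmission-EM micrographs. The unit of observation is one rectangular
analysis window — by convention 1 µm² (1000 × 1000 nm) — holding typically
150–300 gold particles. Coordinates are continuous nanometer positions with
the origin at the window's lower-left corner; points on the boundary are
kept (the window is closed), because digitized edge particles are real
observations. Distances are Euclidean. The statistical assumptions are the
usual ones for windowed point-pattern analysis: the pattern is a partial
observation of a wider stationary, isotropic process, so pair counts near
the boundary must be edge-corrected, and each image is treated as one
replicate of its experimental condition.

## Univariate clustering

`k_function()` computes Ripley's K,

\[ \hat K(r) = A\,n^{-2} \sum_{i \ne j} w_{ij}\,\mathbf 1(\lVert x_i - x_j
\rVert \le r), \]

with the indicator inclusive of ties and `w_ij` the isotropic
edge-correction weight: the reciprocal of the fraction of the circumference
of the circle centered at \(x_i\) with radius \(\lVert x_i - x_j \rVert\)
that lies inside the window. For a rectangle this fraction has an exact
closed form assembled from per-edge arcs \(2\arccos(d/r)\) and
corner-overlap terms \(\pi/2 - \arcsin(d_i/r) - \arcsin(d_j/r)\); the
implementation falls back to numerical arc integration (4,096 circumference
samples) in the geometrically degenerate case of a circle exiting through
two opposite edges, which cannot occur on the default window and radius
grid. Pairs farther apart than the largest grid radius never enter the
indicator, so their weights — circles wider than the window, where the
fraction can reach zero — are never evaluated. The variance-stabilized
transform \(L(r) - r = \sqrt{\hat K(r)/\pi} - r\) is zero in expectation
under complete spatial randomness (CSR).

**Standardization.** `csr_envelope()` simulates `n_sims` CSR patterns
conditioned on the observed count *n* (labeling intensity is an
experimental nuisance, so the null holds it fixed), computes each
\(L(r)-r\), and takes the pointwise `level`-quantile per radius (linear
interpolation between order statistics, `stats::quantile` type 7). The
envelope is pointwise rather than global: the clustering claim is made "at
the corresponding value of r", not as a single curve-wide test.
`standardize_curve()` divides the raw curve by this envelope, so 1 marks
the confidence limit; the peak of the standardized curve over the radius
grid is `Lmax` (ties broken toward the smaller radius). At very small radii
most null curves sit at \(-r\) and the envelope quantile can be zero or
negative; radii with envelope \(\le 10^{-9}\) nm are flagged undefined and
excluded from the peak rather than allowed to blow up or flip sign.

Defaults: radius grid 1–240 nm in 1-nm steps; level 0.99; 1,000
simulations. All are arguments.

## Bivariate co-localization

For a big-gold/small-gold channel pair, `bivariate_k()` computes the cross
K-functions \(K_{bs}\) (edge weights at big centers) and \(K_{sb}\)
(weights at small centers), combined as
\(K_{biv}(r) = (n_b + n_s)^{-1}[\,n_b K_{sb}(r) + n_s K_{bs}(r)\,]\) and
transformed to \(L_{biv}(r) - r\). The combination is exchangeable in the
channel labels for interior points.

**Null model.** The statement being tested is cross-channel association,
not within-channel randomness, so the default null (`"csr_small"`) holds
the observed big pattern fixed and redraws the small channel as CSR with
its observed count. This was a genuinely open design point: a
toroidal-shift null, which preserves both channels' internal clustering and
only randomizes their relative placement, is implemented behind
`null = "toroidal"` for users whose small channel is itself strongly
clustered. The envelope level defaults to 0.95 for the bivariate analysis.

**LBI.** `lbi()` integrates the standardized curve over the closed range
[10, 110] nm by the trapezoidal rule on the 1-nm grid. The closed reading
of the range is deliberate: a curve held exactly at its envelope then
integrates to 100, which is the reference value the index is quoted
against; a half-open reading would shift that constant. Signs are
preserved — no truncation of negative standardized values — so LBI below 0
signals segregation. Significance is the one-sided rank of the observed
LBI among null-simulation LBIs, \(p = (1 + \#\{LBI^* \ge LBI\})/(1 + m)\);
`lbi_test()` computes the null LBIs from the same draws that define the
envelope, which keeps one image's full analysis at one set of simulations.

## Oligomer populations

`classify_oligomers()` partitions particles into connected components of
the graph linking pairs within 15 nm, via single-linkage clustering
(`hclust` + `cutree` at the threshold height, inclusive of exact ties).
Single linkage is the natural reading of "particles within a distance of
15 nm": visible chains of gold belong to one cluster even when their end
points are farther apart; complete linkage, which would split such chains,
is available behind `linkage = "complete"`. Components map to monomer /
dimer / trimer / multimer (≥ 4) classes. Both particle fractions and
component counts are reported, since either can be the quantity of
interest; plots default to particle fractions.

## Group comparison

`bootstrap_group_test()` compares two replicate groups of per-image `Lmax`
values with the statistic \(T = |\bar L_{max}(A) - \bar L_{max}(B)|\) and a
permutation null: group labels are reshuffled (group sizes fixed) `n_boot`
times and \(p = (1 + \#\{T^* \ge T\})/(1 + n_{boot})\), which is never
exactly zero. The choice of statistic was open — published pipelines
delegate it to earlier work without formulas — so a whole-curve alternative
(integrated squared difference of group mean standardized curves,
`statistic = "curve_ssd"`) is provided alongside. Group summaries default
to the unweighted mean over images with SEM; an n-weighted mean is
available in `summarize_group()`. Measured during development at the
defaults: type-I rate 5% at nominal 5% over 500 null comparisons, and every
clustered-vs-random comparison in the power suite at p ≤ 0.01.

## The synthetic generator

`simulate_thomas()` draws a Thomas cluster process: Poisson(κA) parents,
Poisson(µ) offspring per parent, isotropic Gaussian(σ) displacement.
Parents are placed in the window expanded by a 4σ guard band so clusters
seeded just outside still contribute points — the estimator already
edge-corrects, and the generator should not add a second, artificial edge
effect. Defaults κ = 5×10⁻⁵ nm⁻² (50 parents/µm²), µ = 5, σ = 10 nm give
~250 points/µm² with clustering peaking at tens of nanometers, matching
realistic immunogold densities and cluster scales; all are overridable.
The closed form \(K(r) = \pi r^2 + (1 - e^{-r^2/4\sigma^2})/\kappa\)
(`thomas_k_closed_form()`) serves as the validation oracle, and
`fit_thomas()` inverts it by Levenberg–Marquardt least squares on the
pooled empirical K over r ∈ [5, 100] nm.

`simulate_curvature_response()` mixes a clustered fraction φ of Thomas
offspring with CSR at a fixed total count, emulating how a condition that
disrupts nanoclustering shifts multimers toward monomers without changing
labeling. `simulate_bivariate()` produces co-clustered (shared parents),
independent (separate parents), or segregated pairs; segregation uses
hard-core rejection of small-channel points within 3σ of big-channel
parents — simple, and sufficient to depress LBI well below the independent
case. `thin_by_labeling()` deletes points independently, the standard model
of incomplete antibody labeling.

**What the generator does and does not emulate.** It reproduces the
*statistical* structure the estimators assume: clustered/random/segregated
geometry, realistic densities, incomplete labeling, two-channel coupling.
It does not emulate micrograph artifacts (detection errors, gold–gold
steric exclusion at contact distances, antibody linker offsets of a few
nm, non-stationary labeling across a sheet), so passing tests validate the
statistical machinery, not robustness to those acquisition effects.

**Density independence.** Independent thinning leaves K — and therefore
the raw \(L(r)-r\) curve — invariant in expectation, which is the basis of
the claim that clustering readouts do not depend on labeling density. The
package tests this on the raw-curve peak (`l_max_raw` in `group_lmax()`
output): across labeling efficiencies 0.3/0.6/1.0 of a Thomas pattern its
mean varies by under 10%. The *standardized* `Lmax` is not
thinning-invariant by construction: its envelope narrows roughly as 1/n,
so the same physical clustering scores higher at higher labeling density.
Comparisons of standardized `Lmax` across conditions should therefore be
made at comparable labeling densities (as replicate experimental designs
do), or fall back on the raw peak.

## Numerical choices

- Quantiles: type 7 (linear interpolation between order statistics).
- Envelope tolerance 10⁻⁹ nm; radii at or below it are undefined for
  standardization and excluded from `Lmax` and refused inside the LBI
  range (with the offending radii named).
- Indicator inclusive (≤ r); `Lmax` ties resolved to the smallest radius;
  oligomer linkage inclusive of exact-threshold pairs.
- Every stochastic function takes an explicit integer seed and restores
  the caller's RNG state; no global seed is consumed.
- Degenerate inputs fail loudly: < 2 points for K, empty channels,
  mismatched grids or regions, empty patterns for oligomer classification,
  non-positive lifetimes, zero-area regions.

## Pipeline and reproducibility

`run_group_analysis()` drives the whole analysis from a config (R list,
YAML, or a previously written manifest JSON): it resolves every input
directory to an explicit sorted file list *before* any output is written
(fail-fast), runs the per-image analyses, and writes CSV tables plus a
manifest recording every parameter, seed, and input file. Re-running a
manifest reproduces all tables byte-identically, which the tests assert.
The package's interface is R functions — `run_group_analysis()` /
`render_report()` are the batch entry points; no shell wrapper is shipped.

Problem sizes used in the test suite are chosen to keep each statistical
check's Monte-Carlo error well inside its asserted tolerance at desk
scale: 1,000-simulation envelopes; 2,000-draw (per-envelope) coverage
checks averaged over independent envelope replicates, since a single
envelope's coverage carries ~1 percentage point of order-statistic noise;
500-simulation closed-form comparisons; 200 simulations per thinning
level; 500 null and 100 alternative permutation-test replicates; 30 images
for parameter recovery.

## Known limitations

- Estimators assume a rectangular window; irregular membrane-sheet
  outlines are not supported (choose windows inside the sheet upstream).
- No inhomogeneous-intensity K variants, pair-correlation functions, or
  3-D extensions; no marked processes beyond the two-channel case.
- Gold stoichiometry is not modeled: oligomer classes count gold
  particles, not protein copy numbers.
- The bivariate null choice matters when the small channel is internally
  clustered; both implemented nulls are reported options, and no claim is
  made about which matches any particular published dataset.
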