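# nanoclust

Spatial statistics for immunogold nanocluster analysis on intact
plasma-membrane sheets.

Membrane proteins and lipids organize laterally into nanometer-scale
assemblies ("nanoclusters") on the plasma membrane. A standard way to
quantify this is electron microscopy of intact membrane sheets whose target
proteins are immunolabeled with gold nanoparticles: each micrograph yields a
2-D point pattern of gold coordinates inside a 1 µm² analysis window, and
the biology (how clustered is the protein? do two species co-cluster? how
do populations of monomers/dimers/multimers shift?) becomes a question
about spatial point-pattern statistics. `nanoclust` implements that
analysis pipeline for researchers doing EM-immunogold spatial mapping, with
a synthetic point-process generator so every stage is testable without
experimental data.

## The statistics

**Univariate nanoclustering.** For *n* gold particles at positions *x_i*
in a window of area *A*, Ripley's K-function with isotropic edge
correction is

    K(r) = A n^-2 Σ_{i≠j} w_ij 1(‖x_i − x_j‖ ≤ r)

where `w_ij` is the reciprocal of the fraction of the circumference of the
circle centered at *x_i* with radius ‖x_i − x_j‖ that lies inside the
window (computed in closed form for a rectangle). K is evaluated on
r = 1, 2, …, 240 nm and linearized to

    L(r) − r = sqrt(K(r)/π) − r

which is 0 under complete spatial randomness (CSR), positive for
clustering. The raw curve is divided pointwise by the 99th percentile of
L(r) − r over 1,000 Monte-Carlo CSR simulations with the same *n*
("standardization"), so the value 1 marks the 99% confidence limit. The
peak of the standardized curve, **Lmax**, is the scalar summary of
nanoclustering extent; groups of images are compared with a permutation
test on per-image Lmax.

**Bivariate co-localization.** For two channels (6-nm "big" gold on one
protein, 2-nm "small" gold on another), the cross K-functions K_bs and
K_sb (edge weights at the centers of the first index) combine as

    K_biv(r) = (n_b + n_s)^-1 [ n_b K_sb(r) + n_s K_bs(r) ]

and transform to L_biv(r) − r, standardized against the 95% envelope of a
null that redraws the small channel. The standardized curve integrated
over 10–110 nm is the **LBI** index: a curve held at its envelope gives
LBI = 100, larger values indicate co-clustering, and significance comes
from ranking against the Monte-Carlo null LBIs.

**Oligomer populations.** Particles linked within 15 nm (single linkage)
form connected components classified as monomers, dimers, trimers, and
higher multimers, giving the population distribution of oligomeric states.

The package also ships a Thomas cluster-process simulator with its
closed-form K as an oracle, thinning for incomplete labeling, two-channel
co-clustered/independent/segregated generators, and small auxiliary
metrics used alongside the spatial statistics (RMS surface roughness R_q,
donor-lifetime FRET efficiency E = 1 − τ_DA/τ_D, nanobar end/center
fluorescence ratios with averaged heat maps, SPR RU_S/RU_L binding
tables).

## Worked example

Two synthetic conditions — five clustered membrane sheets (Thomas process,
~250 points/µm², cluster dispersion σ = 10 nm) against five CSR sheets —
analyzed exactly as real micrograph coordinate tables would be:

```r
library(nanoclust)

clustered <- lapply(1:5, function(i) simulate_thomas(thomas_params(), seed = i))
random    <- lapply(1:5, function(i) simulate_csr(250, seed = 100 + i))

lm_clust <- group_lmax(clustered, n_sims = 1000, seed = 7)
lm_clust
#> # A tibble: 5 × 5
#>   image     n l_max r_at_max l_max_raw
#>   <int> <int> <dbl>    <dbl>     <dbl>
#> 1     1   241  13.8       23      49.9
#> 2     2   198  13.3       33      58.3
#> 3     3   217  13.1       30      53.7
#> 4     4   242  13.4       29      49.6
#> 5     5   206  13.3       29      53.0

summarize_group(lm_clust)
#> # A tibble: 1 × 3
#>   n_images mean_lmax sem_lmax
#> 1        5      13.4    0.113

lm_rand <- group_lmax(random, n_sims = 1000, seed = 7)
summarize_group(lm_rand)
#> # A tibble: 1 × 3
#>   n_images mean_lmax sem_lmax
#> 1        5     0.737    0.196

bootstrap_group_test(lm_clust, lm_rand, n_boot = 1000, seed = 8)
#> <nanoclust_test> mean_lmax permutation test: T = 12.64, p = 0.007992
#> (5 vs 5 images, 1000 permutations)
```

Every clustered image has standardized Lmax ≈ 13 — far above the 99%
confidence line at 1 (its peak sits near r ≈ 30 nm, the cluster length
scale), while the CSR images stay below 1; the permutation test separates
the groups at p < 0.01. The same patterns classified into oligomer
populations and a co-clustered two-channel pair:

```r
classify_oligomers(clustered[[1]], threshold = 15)
#> # A tibble: 4 × 5
#>   class    components particles particle_fraction component_fraction
#> 1 monomer          36        36            0.149               0.45
#> 2 dimer             9        18            0.0747              0.112
#> 3 trimer            4        12            0.0498              0.05
#> 4 multimer         31       175            0.726               0.388

pair <- simulate_bivariate("colocalized", n_b = 100, n_s = 100, seed = 9)
lbi_test(pair, n_sims = 1000, seed = 10)
#> <lbi_test> LBI = 601.91 over [10, 110] nm, p = 0.000999 (1000 null draws)
```

An LBI of ~602 against the 95% reference value of 100 reflects the shared
cluster centers of the two channels. For batch work,
`run_group_analysis()` drives the same computations over directories of
coordinate CSVs from a YAML/JSON config and writes curves, summary tables,
pairwise tests and a replayable manifest; `render_report()` turns a result
bundle into the standard figures (curves with the CI line at 1, Lmax/LBI
bars with SEM, population histograms).

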