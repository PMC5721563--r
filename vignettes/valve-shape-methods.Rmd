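---
title: "Models and methods for paired-valve shape evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for paired-valve shape evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvemorph)
```

This vignette explains the models behind `valvemorph`, the numerical and
design choices that were genuinely open, and what the synthetic-shell
generator does and does not emulate. It states no empirical result that
the package's tests and `scripts/acceptance.R` do not themselves compute.

## The measurement model

A valve is a configuration of k labelled points in 3D: a few fixed
anatomical landmarks (around the auricles and umbo) and many
semilandmarks on the valve outline and surface. Shape is what remains
after removing position, scale and orientation: configurations are
centred, scaled to unit centroid size, and rotated onto a consensus by
generalised Procrustes analysis (GPA). Two conventions matter here:

* **Reflections are never introduced silently.** All optimal rotations
  are proper (determinant +1); improper SVD solutions are corrected by
  flipping the smallest singular direction (ties broken at the highest
  index, so rank-deficient cases are deterministic). Handedness is
  handled explicitly by `mirror_configuration()`: a silent reflection
  would erase exactly the left-right signal the asymmetry analysis
  measures.
* **Semilandmarks slide to minimise Procrustes distance.** Curve points
  move only along the chord between their along-curve neighbours;
  surface points only within the best-fit plane (two leading principal
  directions) of their neighbour set, which is the standard
  tangent-estimation rule when no analytic surface is available. The
  displacement is the orthogonal projection of the residual to the
  consensus onto that tangent subspace — the within-subspace minimiser —
  so one pass can only reduce each point's squared distance to the
  reference, and the total Procrustes sum of squares is non-increasing
  per pass (asserted in the tests).

**Number of sliding passes.** Sliding is applied during the first
`slide_iter` (default 5) GPA iterations only, after which plain
superimposition iterations run to the consensus tolerance (1e-9, max 100
iterations). The reason is a gauge mode of Procrustes-distance sliding on
closed outlines and surface grids: semilandmarks can migrate collectively
along the contour, gaining a fraction of a percent of fit per pass
indefinitely while the consensus never settles (measured on generated
data: consensus displacement was still ~1e-3 after 1500 slide-every-pass
iterations, with the first pass contributing the overwhelming share of
the total fit gain). A small fixed number of passes captures the
correspondence improvement without letting the texture of points crawl;
this mirrors how the field's production implementations behave.

Alignment is order-independent: the initial reference is the first
configuration by label key, not by array position, and the tests check
that pairwise aligned distances are invariant to specimen permutation.
Replicate digitisations are averaged after alignment (aligned-shape
means, renormalised); species means are computed the same way and ordered
by the pruned tree's tip order.

## Matching asymmetry

The magnitude of directional asymmetry (DA) of a shell is the Procrustes
distance between its left valve and its mirrored right valve after one
joint GPA over all valves of both sides (with sliding). The distance is
taken on the jointly aligned coordinates *without* re-rotating each pair:
the joint superimposition already put every valve into a single frame,
and per-pair re-rotation would remove genuine hinge-orientation
asymmetry. Species means and variances of DA are reported together
because the spread of asymmetry within a life habit is itself
informative. Replicates are averaged before pairing (configurable).

## Phylogenetic transformation

Species are not independent; under Brownian motion on a rooted tree with
covariance `C[i, j]` = shared root-to-MRCA path length, the generalised
least squares mean is `a = (1'C^-1 1)^-1 1'C^-1 Y` and the transformed
deviations are `U = C^(-1/2)(Y - 1a)`. `C^(-1/2)` is the symmetric
eigendecomposition root (unique and order-independent, unlike Cholesky;
the choice slightly affects PLS score correlations, which is why the test
suite compares the two roots only on replicate averages). Eigenvalues are
floored at 1e-12 of the largest; a violation names the closest tip pair,
which is almost always a zero-length cherry.

## Integration: two-block PLS

The first left/right singular vectors of the cross-block covariance give
per-block scores; rPLS is the absolute Pearson correlation of those
scores. Note that the first PLS axis pair maximises *covariance*, not
correlation — rPLS is the correlation at the covariance optimum, which is
generally below the canonical correlation; the test oracle searches
projection vectors accordingly. In the phylogenetic variant both blocks
are replaced by their transformed residuals `U` (no re-centering: the GLS
mean is already removed), and the permutation test permutes species rows
of the transformed second block, where rows are exchangeable under the
null. P-values use the +1 correction and are never zero; effect sizes
standardise the Fisher-transformed observed rPLS against the
Fisher-transformed permutation distribution.

**Comparing integration across groups.** The pairwise statistic is
`|z_i - z_j| / sqrt(se_i^2 + se_j^2)` on the Fisher scale, with
`z_i = f(r_obs) - mean(f(r_perm))` and
`se_i^2 = 1/(N_i - 3) + var(f(r_perm))/n_perm` — the sampling variance of
a Fisher-transformed correlation plus the Monte Carlo error of the null
mean. Using the spread of the permutation distribution itself as the
standard error is noticeably anticonservative for this statistic (the
null spread of the leading-axis correlation is tighter than its sampling
spread under integration); the calibration simulations in the test suite
cover both the type-I and the power behaviour of the implemented choice.
Per-ecomorph PLS analyses prune the tree to the group's species and
refuse groups with fewer than 4 species.

## D-PGLS

For a multivariate response and a categorical predictor, both the
response and the indicator design matrix are premultiplied by
`C^(-1/2)`; sums of squares are traces of cross-product matrices and
`F = (SS_model/df_model)/(SS_resid/df_resid)`. Significance comes from
residual randomisation of the reduced (intercept-only) model (RRPP):
reduced-model residuals are permuted in the transformed space and added
back to the reduced fit. On a star tree with a 1-D trait this reproduces
the classical one-way ANOVA F exactly (tested). The response used in the
study workflow is the 1-D species-mean DA, but any p >= 1 works.

## Evolutionary rates

The net rate of a p-dimensional trait is
`sigma^2 = sum_i ||u_i||^2 / (N p)`: the mean squared transformed
deviation per species *per trait dimension*. The division by p makes
1-D asymmetry rates and 3k-D valve-shape rates comparable per dimension;
other conventions omit it, so absolute rate values are
convention-dependent (set `per_dim = FALSE` to cross-check against the
per-species convention) while all max/min ratio statistics are unchanged.
Rates scale exactly as 1/c under branch-length rescaling by c and as c^2
under trait rescaling (tested).

**Null distributions for ratio tests.** Two realisations of the
single-process null are provided. The default is permutation: under the
null the transformed species rows are exchangeable, so group labels are
permuted across species (group comparisons) or block membership is
permuted within species (left/right comparisons, preserving the
integration structure by construction); this is exactly calibrated. The
alternative (`null_method = "simulation"`) re-draws tip data under one
Brownian process whose trait covariance is the pooled estimate `U'U/N`
rescaled to the pooled rate; it is the classical procedure but measurably
conservative at moderate N and p, because the estimated covariance smears
the simulated ratio distribution (measured rejection ~0.03 at nominal
0.05 under the package's calibration conditions, against ~0.05 for the
permutation null). Pairwise group p-values reuse the same null draws and
are deliberately left uncorrected for multiplicity, matching how such
tables are usually reported. Groups with a single species are kept and
flagged: they receive point estimates (from the full-tree transform,
since no within-group GLS mean exists) but no test.

**Bootstrap.** Confidence intervals for any rate statistic come from
resampling specimens within species with replacement, rebuilding species
means, and recomputing the statistic; the tree is fixed. Species with one
specimen contribute a constant mean — with one specimen everywhere the
intervals collapse to the point estimate, which the tests assert.

## The synthetic-shell generator

No real scans ship with the package; the generator stands in for a
museum sample of a scallop-like clade and is the substrate for all
simulation-based tests. What it emulates:

* **Sampling design.** 86 species split 2 cementing / 1 nestling /
  48 byssal-attaching / 11 recessing / 18 free-living / 6 gliding, with
  2-14 specimens per species (about 8 on average, i.e. roughly a
  669-shell sample) and 2 digitising replicates per valve. Reduced
  presets (fixed 2-3 specimens per species, 45 semilandmarks) keep
  simulation studies fast; `k_semi = 197` reproduces the full digitising
  scheme.
* **Trees.** Pure-birth trees rescaled to unit depth, with species-level
  sampling emulated by simulating a three-fold larger clade, dropping one
  member of any sister pair closer than 0.5% of tree depth (a
  species-level chronogram does not resolve such splits), and sampling
  down. This bounds pendant branches away from zero, which matters
  because the GLS whitening divides non-phylogenetic noise (measurement
  error, individual variation) on a species mean by its pendant length.
* **Shape.** Ten latent parameters (dome convexity, outline
  eccentricity, auricle width/height, umbo height, skew, apex offsets,
  ring flare, dome tilt) map smoothly to a valve template: five fixed
  landmarks on the commissural plane and semilandmarks on a domed radial
  grid, `z = convexity (1 - r^2)`, whose outer ring is the closed
  boundary-contour curve. Latent deviations are rescaled by the inverse
  template Jacobian norms so every latent dimension contributes equally
  to shape variance; latent Brownian motion then induces approximately
  Brownian landmark evolution (the map is smooth but not linear — an
  approximation, stated as such).
* **Rates and asymmetry.** Each ecomorph multiplies the latent rate on
  its terminal branches (ecomorph is a tip state; the multipliers were
  calibrated through the measured multiplier-to-observed-rate map so the
  *estimated* per-ecomorph rates reproduce the study pattern: elevated
  gliding/recessing/nestling, slowest byssal-attaching, left-valve
  spread of about 3x). The right valve is a paired Brownian field whose
  per-edge increments correlate with the left valve's at rho = 0.95 and
  whose rate is 1.2x the left on internal branches (the across-species
  right/left excess) and ecomorph-specific on terminal branches
  (calibrated so observed within-ecomorph right/left ratios match the
  study pattern, nestling by far the largest). Directional asymmetry is
  a per-ecomorph offset on right-valve convexity, largest for recessing
  (0.10) and smallest for gliding (0.01) shells.
* **Ecomorph placement.** Derived ecomorphs arise as one to three
  phylogenetically clumped clusters with mutually distant seeds and deep
  boundary splits, on a byssal-attaching background — matching the
  repeated-but-clade-like origins of the real habits. This is not
  cosmetic: with ecomorphs scattered randomly over tips, the whitening
  leaks the derived groups' large private pendant variance into
  neighbouring species and the group-rate ranking degrades badly.
* **Noise.** Individual (within-species) latent variation with SD 0.01
  and per-replicate coordinate noise with SD 0.002 (about 0.2% of valve
  radius, a realistic digitising error).

What it does *not* emulate: real surface correspondence (the template
defines its own), shell ornamentation and growth, ancestral ecomorph
history (rates shift only on terminal branches), within-species
phylogenetic structure, and non-Brownian processes. Passing tests
therefore demonstrate correct behaviour of the estimators and tests under
a Brownian world with known truth — not that any particular empirical
dataset satisfies those assumptions.

## Problem sizes used by the test suite

The simulation studies in the tests use deliberately reduced but
representative sizes, chosen once: calibration at N = 64 species with
199 permutations/draws over 500 datasets; estimator recovery at N = 128
(unbiasedness), N = 64 (two-clade ratio 2.0) and N = 86 (right/left
ratio 1.2) over 200 replicates; asymmetry ordering over 100 generator
runs at 2 specimens per species; end-to-end pattern recovery over 100
generator seeds at 3 specimens per species with 45 semilandmarks. The
acceptance script runs the same reduced design with 199 resampling draws
per test.

## Known limitations

* Sliding is path-dependent across relabelings at the 1e-4 level (the
  initial reference changes), so only the rigid pipeline is exactly
  mirror-symmetric; tests bound the sliding discrepancy loosely.
* Single-species group rates have heavy-tailed sampling distributions
  (a handful of effective dimensions); their flagged point estimates
  should not be over-read — which is why they are excluded from
  within-group testing.
* Absolute sigma^2 values depend on the per-dimension normalisation
  convention; only ratios are comparable across conventions.
* The plug-in simulation null is retained for fidelity to the classical
  procedure but is conservative; use the default permutation null when
  calibration matters.
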