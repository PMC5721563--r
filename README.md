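# valvemorph

Phylogenetic geometric morphometrics of paired shell valves.

Scallop shells consist of two articulated valves whose shapes evolve under
different selective regimes: the right valve usually rests on the
substrate, the left faces the water column. `valvemorph` implements the
full analysis chain needed to study how such paired structures evolve
across a clade:

- **Superimposition** — generalised Procrustes analysis of 3D landmark
  configurations (fixed landmarks plus curve and surface semilandmarks
  that slide along their tangent directions to minimise Procrustes
  distance), replicate averaging, species mean shapes.
- **Matching asymmetry** — right valves are mirrored onto the left-valve
  frame, both sides are jointly superimposed, and the magnitude of
  directional asymmetry (DA) of each shell is the Procrustes distance
  between its valves.
- **Evolutionary integration** — two-block partial least squares of left
  versus right valve shape; the integration statistic is rPLS, the
  correlation of the first PLS axis pair, tested by permutation in the
  phylogenetically transformed space and compared across groups via
  effect sizes.
- **D-PGLS** — phylogenetic generalised least squares for a
  multidimensional response on a categorical predictor (e.g. species-mean
  asymmetry on ecomorph), with residual-randomisation significance.
- **Evolutionary rates** — the net Brownian-motion rate of a
  p-dimensional trait, `sigma^2 = sum_i ||u_i||^2 / (N p)` with
  `U = C^(-1/2)(Y - 1a)` the phylogenetically transformed deviations, and
  max/min rate-ratio tests among ecomorphs, between valves, and between
  valves within ecomorphs, with bootstrap confidence intervals over
  specimens.
- **Synthetic shells** — a generator that emulates a museum sample of a
  scallop-like clade (86 species in six ecomorphs, uneven sampling, two
  digitising replicates per valve) with controllable group rates,
  left-right integration, asymmetry offsets and measurement error, used
  for simulation studies and end-to-end testing.

File formats: long-format landmark CSV and 3D TPS (`LM3=`) for
coordinates, CSV descriptors for semilandmark topology, Newick for trees.

## Worked example

```r
library(valvemorph)

# simulate a reduced study: 86 species, 3 specimens each, 45 semilandmarks
report <- run_study(generator = paper_pattern_config(seed = 1),
                    n_perm = 199, n_sim = 199, n_boot = 199, seed = 1)
report
#> valve-shape study report (seed 1, mode full)
#>   86 species; rPLS(all) = 0.874
#>   sigma2 left = 1.12e-05, right = 1.4e-05 (ratio 1.25)
#>   pattern: right_gt_left, trio_top3, byssal_low, recess_highest_da, all

report$pls$all
#> two-block PLS: rPLS = 0.8738, Z = 16.38, P = 0.005 (199 permutations)

signif(report$rates$right_groups$sigma2, 3)
#> byssal-attaching        cementing      free-living          gliding
#>         5.96e-06         6.47e-06         1.32e-05         4.74e-05
#>         nestling        recessing
#>         5.11e-05         3.05e-05
```

Reading the output: the left and right valves are strongly integrated
(rPLS near 1, significant against its permutation null); the right valve
evolves faster than the left overall; and the right-valve rates are
highest for the nestling, recessing and gliding ecomorphs while
byssal-attaching species evolve slowest — the qualitative pattern the
generator is built to emulate. `report$asymmetry$by_ecomorph` tabulates
mean DA per ecomorph (recessing shells are the most inequivalve, gliding
shells the most equivalve), `report$pgls` holds the D-PGLS of species
asymmetry on ecomorph, and `report$bootstrap` the specimen-bootstrap
confidence intervals of every rate.

Numbers above are from the exact command shown (seed 1); rerunning it
reproduces them bit for bit.

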