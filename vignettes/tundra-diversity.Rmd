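---
title: "Altitude gradients and metacommunity structure in nested vegetation surveys"
author: "tundradiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Altitude gradients and metacommunity structure in nested vegetation surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundradiv)
```

## The problem

Mountain tundra floras are organised along steep altitude gradients: cover
and species richness typically peak at mid elevations, while community
*composition* can change with altitude in two qualitatively different ways.
If high-altitude assemblages are subsets of the richer low-altitude ones,
the plot-by-species incidence matrix is *nested*; if each elevation belt
carries its own species set, the matrix is *modular* (species turnover).
Distinguishing these regimes, and measuring how compositional variation
(beta diversity) depends on spatial scale, requires a pipeline that couples
classical diversity statistics, ordination-based dispersion measures,
bipartite network statistics, null-model inference, and mixed models that
respect the nested survey design (mountain > transect > station > 1 m^2^
plot).

`tundradiv` implements that pipeline for point-intercept vegetation surveys
of the ITEX type: three mountains, one 1 km transect per elevation band
(700--900, 900--1,100, 1,100--1,300, >1,300 m; bands are treated as
lower-inclusive, upper-exclusive since the nominal band edges touch), five
stations per transect 250 m apart, five 1 m^2^ plots per station, and 25
intercept points per plot (125 per station after pooling).

## Alpha diversity

Per plot we use the visually estimated vegetation cover (analysed on the
logit scale) and the species count. Cover proportions are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.005$ before the logit
-- half the 1% resolution of a visual estimate -- so bare and closed plots
stay finite; clamped values are flagged.

Station evenness uses pooled intercept counts (plot-level counts are too
sparse). With proportions $p_i$ over the $S$ touched species,
$H = -\sum_i p_i \ln p_i$ and the scaled evenness is $J = H / \ln S$, so 1
is complete evenness and a single-species station scores 0 (`scaledShannon`
defines $J = 0$ when $S = 1$). $J$ is base-invariant; entropies are
reported in nats.

## Multi-scale beta diversity

Beta diversity is a plot's distance to a group centroid in
principal-coordinate space, the multivariate-dispersion view of
compositional variation:

1. Binary Bray--Curtis (Sørensen) dissimilarity between plot species sets,
   $d = 1 - 2|A \cap B| / (|A| + |B|)$. Two empty plots are defined as
   identical ($d = 0$) with a warning: barren high-altitude plots must not
   crash the pipeline.
2. Principal coordinates of the full plot-by-plot matrix. Sørensen is not
   Euclidean, so negative eigenvalues occur; their axes are kept as
   *imaginary* coordinates scaled by $\sqrt{-\lambda}$, and squared
   dissimilarities are reconstructed exactly as (real part) $-$ (imaginary
   part). Axes below $10^{-10}$ of the leading eigenvalue magnitude are
   dropped as numerical noise.
3. Per-plot distances to the arithmetic centroid of three groupings:
   the station (25 m patch scale), the transect (1 km scale), and all
   plots of the same altitude band across mountains (landscape scale).
   Negative squared distances -- possible with imaginary axes -- are
   clamped to zero and flagged, the standard treatment in dispersion
   analyses of non-Euclidean dissimilarities.

One *shared* embedding serves all three scales: distances between fixed
points do not depend on the grouping, so per-scale embeddings would add
cost without changing any distance. Distances are computed per plot (one
row per 1 m^2^ plot and scale), which is what the mixed models below
consume; station-level pooling would discard the within-station replication
the design provides.

## Altitude trend models

All responses are modelled with nested random intercepts by maximum
likelihood (ML, not REML, because the linear-vs-quadratic comparisons are
fixed-effect likelihood-ratio tests):

* cover logit and richness: station-in-transect-in-mountain random effects;
  richness uses a Poisson log-link GLMM on the raw per-plot counts;
* evenness: transect-in-mountain (evenness is a station-level quantity);
* centroid distances: station-in-transect-in-mountain, with spatial scale
  and scale-by-altitude interactions as fixed effects.

Altitude is centred and scaled internally before the quadratic term is
formed (the raw metre scale makes `altitude^2` ~10^6^ times larger than
`altitude` and destabilises the optimiser); reported coefficients are
back-transformed to the raw-altitude parameterisation, with standard errors
propagated through the affine reparameterisation, so signs and magnitudes
read directly in metres. Coefficient p-values are Wald normal
approximations; the quadratic-vs-linear comparison is
$\chi^2_1 = 2\Delta\ell$. A negative $\Delta\ell$ beyond tolerance triggers
refits with alternative optimisers and is an error if it persists, which
enforces the nesting invariant. For a fitted quadratic, `trendVertex`
reports the turning point $-\beta_1 / (2\beta_2)$ and warns when it falls
outside the sampled range rather than second-guessing coefficient signs.

The scale-by-altitude interaction is tested as a 2-df LRT on the
quadratic-by-scale terms; per-scale subset models report each scale's own
linear and quadratic terms. Pairwise scale differences are estimated
marginal means at the mean altitude, with a multivariate-$t$ (Tukey-style)
adjustment over the three contrasts using the contrasts' estimated
correlation and $df = n - \mathrm{rank}(X)$; `emmeans` reproduces the
estimates and t statistics and serves as an independent cross-check in the
test suite.

## Nestedness, modularity, and orderings

**NODF** (nestedness by overlap and decreasing fill): for rows $i$ above
$j$, the pair contributes $100\,|A_i \cap A_j| / |A_j|$ when
$|A_j| < |A_i|$ and $|A_j| > 0$, else 0; likewise for columns left to
right; the index averages over all row plus column pairs (0--100). NODF
depends on fill, so inference is always against the null model below.
Zero-fill rows contribute zero to their pairs but are kept, so plot counts
stay consistent across statistics. The *optimal* ordering sorts rows by
decreasing richness and columns by decreasing frequency (single pass,
stable ties -- reproducibility beats marginal gains from re-sorting after
tie-breaks). The *altitude* ordering sorts plots by ascending altitude
(direction is a convention; the descending value is available as a
diagnostic), optionally within each mountain.

**Barber's Q** for the bipartite plot--species network:
$Q = \tfrac{1}{m} \sum_{ij} (B_{ij} - k_i d_j / m)\,
\delta(g_i, h_j)$ with $m$ presences, $k_i$ row and $d_j$ column sums. Q is
maximised with **BRIM**: alternating sweeps that place every plot in its
Q-maximising module given the species modules and vice versa (each
half-sweep can only increase Q; iteration stops when the gain drops below
$10^{-10}$). Because the sweep is a local search, we use `nRestarts`
random starts (default 20) plus one start that bins first-axis
reciprocal-averaging (correspondence analysis) scores into modules, and
search the allowed module count adaptively (start at 2, double while the
best Q improves, then bisect; capped at min(plots, species, 30)). The seed
is stored in the result so any run can be reproduced exactly. On random
5x5 matrices BRIM attains the exhaustively enumerated global maximum
(enumeration is feasible because, for a fixed row partition, each species
column independently joins its best module).

Q itself is invariant to row order, so "altitude-sorted" modularity cannot
literally mean re-sorting the matrix. We interpret it as an
altitude-*constrained* run: BRIM receives an extra initial partition that
assigns plots to their altitude band (optionally crossed with mountain) and
each species to the band holding most of its occurrences; the Q of that raw
band partition is reported alongside. With strong turnover the constrained
and free optima coincide; without altitude structure the band partition
scores near zero.

`reciprocalAveraging` itself iterates mutual weighted averaging of row and
column scores with renormalisation to convergence ($10^{-12}$ on the score
change), standardises to zero weighted mean and unit weighted variance,
and fixes the sign so the highest-altitude plot scores non-negatively. A
disconnected incidence graph yields per-component scores, offset so
components do not overlap in score order, with a warning. Note the first
non-trivial axis is unique only when the leading non-trivial eigenvalue is
simple; ties (common in tiny or highly symmetric matrices) make any vector
in the eigenspace equally valid.

## Null-model inference

"Preserving species frequencies" is implemented as: each species' $d_j$
presences are placed in $d_j$ distinct plots drawn uniformly,
independently per species. Column sums are conserved exactly on every
draw; row sums are free, and rows may become empty (kept, see above;
a resample-until-nonempty variant is deliberately not the default because
it biases the marginal row distribution). Each observed statistic is
compared with `nReps` randomisations (1,000 for publication-grade runs)
via $Z = (\mathrm{obs} - \bar{x}_{null}) / s_{null}$ (sample SD) and a
one-tailed empirical p in the direction of the deviation with the add-one
correction, $p = (\#\{\text{as-or-more-extreme}\} + 1) / (n + 1)$ -- so an
observation beyond every null reports $p = 1/(n+1)$, and a degenerate null
(SD 0, e.g. any fill-conserved statistic) reports the empirical p with
$Z$ undefined rather than a division by zero. Ordering-dependent
statistics re-derive their ordering on each null matrix (for altitude
sortings this is the identical permutation, since plot metadata and column
sums are conserved); optimisation-based statistics are re-optimised per
null matrix with fewer restarts (default 5) -- re-using the observed
partition would bias the null upward, and the re-optimisation dominates
the cost of `metacommunityAnalysis`.

## The synthetic survey generator

No field download is needed to exercise the pipeline: `simulateSurvey`
generates surveys with the statistical structure the analysis assumes.
Species $s$ occupies a plot at altitude $a$ with probability
$\sigma\!\left(\mathrm{logit}\!\big(M_s e^{-(a - \mu_s)^2 / 2\sigma_s^2}\big)
 + u_{mnt} + u_{tr} + u_{st}\right)$: a Gaussian altitude niche (optimum
$\mu_s$, tolerance $\sigma_s$ in metres, maximum occupancy $M_s$) whose
logit is perturbed by nested Gaussian random intercepts (defaults 0.25
each; the logit scale keeps probabilities in (0,1)). Two knobs set the
metacommunity regime:

* `coreFraction` (default 0.3): this share of species get 4x inflated
  tolerances -- ubiquitous "core" species whose heterogeneous occupancies
  generate nestedness;
* `turnoverStrength` (default 2): divides the remaining (specialist)
  tolerances -- sharper niches generate altitudinal turnover, i.e.
  modularity aligned with bands.

Niche optima are uniform over the gradient ±100 m by default (so that edge
species exist) or Normal(`optimaCenter`, `optimaSd`) to concentrate
richness mid-gradient; baseline tolerances are log-normal (median 120 m,
log-SD 0.4, a plausible niche-width spread for a ~800 m gradient). Plot
cover follows an inverse-logit quadratic peaking at 850 m with value 0.8
(curvature $1.1\times10^{-5}$ per m^2^, i.e. cover has dropped strongly
600 m from the peak) plus plot-level logit noise (SD 0.5). Intercept
counts mimic the field protocol: each of the 25 points per plot touches a
present species with probability proportional to a per-species log-normal
abundance weight times plot cover, else records no touch, so sparse
high-altitude stations resemble field data. Transect altitudes are drawn
inside their band, station altitudes jitter around the transect
(SD 15 m, matching the design's low within-transect variation), and the
whole survey is a deterministic function of the seed, with per-mountain
sub-seeds so one mountain's output does not depend on another's
simulation order. `dropOneTransect` removes the highest band of the last
mountain, mimicking an incomplete campaign (11 transects, 275 plots).

What the generator does *not* emulate: spatial autocorrelation within
stations (plots are exchangeable replicates), species interactions,
geological or hydrological covariates, and detection error. Tests passing
on synthetic surveys therefore validate the statistical machinery and the
qualitative regimes (unimodal trends, turnover vs nestedness, scale-ordered
beta diversity), not any field-specific magnitude.

## Validation strategy and problem sizes

Every statistic has an independent oracle in the test suite: NODF against
a direct loop recomputation and `vegan::nestednodf`; BRIM against
exhaustive partition enumeration on 5x5 matrices; reciprocal averaging
against the singular-value decomposition of the standardised incidence
matrix; PCoA against the exact reconstruction identity and, for Euclidean
inputs, against raw point-to-centroid geometry; the mixed models against
their OLS/GLM limits when all fitted variance components are zero and
against parameter recovery (quadratic vertex within ±100 m of a true
1,000 m peak, median over 20 replicates); the LRT against its nominal
type-I error (500 null simulations); the null model against conservation
laws and a chi-square uniformity check. Routine runs use deliberately
modest sizes -- 30-replicate null ensembles on ~100-plot surveys in tests,
200 replicates in the example pipeline -- because the statistics and their
calibration, not wall-clock heroics, are what the checks establish;
publication-grade runs should use `nReps = 1000` and the default BRIM
restart counts.

## A worked synthetic run

```{r, eval = FALSE}
sv <- simulateSurvey(simulationConfig(seed = 7))
cm <- buildCommunityMatrix(sv$records)
cm

bt <- betaDiversityAllScales(cm)
tapply(bt$distance, bt$scale, mean)   # station < transect < landscape

al <- plotAlphaTable(sv$records)
lrtQuadratic(al, "richness", "poisson", "station")

metacommunityAnalysis(cm, nReps = 200, seed = 7)
```

Field data enter the same way: `readPlotRecords()` for long-format plot
records, or `readCommunityMatrix()` for an existing presence--absence
matrix prefixed with `mountain,transect,station,plot,altitude_m` metadata
columns.

## Known limitations

* The Wald-z coefficient p-values and the $\chi^2$ LRT are asymptotic; no
  Satterthwaite or Kenward--Roger degrees-of-freedom corrections are
  provided.
* Only the binary Sørensen dissimilarity is implemented (no
  abundance-weighted Bray--Curtis, no rarefaction), and only the
  fixed-species-frequency null family (no swap/trial-swap chains).
* BRIM is a restarted local search; the stored seed makes any run
  reproducible, but global optimality on large matrices is probabilistic,
  not guaranteed.
* Altitude-band membership uses the half-open convention; surveys whose
  plots sit exactly on a nominal shared band edge are assigned upward.
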