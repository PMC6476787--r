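# tundradiv

Diversity analysis for hierarchical vascular-plant surveys along altitude
gradients. The package targets point-intercept (ITEX-style) surveys with a
nested design — mountains ⊃ 1 km transects ⊃ 25 × 25 m stations ⊃ 1 m²
plots — and answers three questions for ecologists working on tundra and
alpine gradients:

1. **Alpha diversity.** How do vegetation cover, plot species richness and
   station evenness change with altitude — linearly or unimodally?
   Evenness is the scaled Shannon index *J = H / ln S* from pooled
   point-intercept counts (1 = complete evenness, 0 = one species).
2. **Beta diversity across scales.** How variable is composition at the
   patch (station), transect (1 km) and landscape (altitude band) scales?
   Operationalised as each plot's Euclidean distance to its group centroid
   in principal-coordinate space built from binary Bray–Curtis (Sørensen)
   dissimilarities, *d* = 1 − 2|A∩B| / (|A|+|B|), keeping the
   negative-eigenvalue (imaginary) axes non-Euclidean dissimilarities
   produce.
3. **Metacommunity structure.** Is the plot × species incidence matrix
   nested (species-poor plots hold subsets of richer plots; NODF, 0–100)
   or modular (altitude-specific species sets; Barber's bipartite
   modularity *Q* = (1/m) Σᵢⱼ (B**ᵢⱼ** − kᵢdⱼ/m) δ(gᵢ,hⱼ), maximised by the
   BRIM alternating algorithm) — and does either pattern follow altitude?
   Both are tested against a null model that preserves each species'
   occurrence frequency, with Z-scores and empirical p-values.

Altitude trends are fitted by maximum-likelihood mixed models with the
survey's nesting as random intercepts (lme4), linear-vs-quadratic
likelihood-ratio tests, scale × altitude interactions, and
multivariate-*t* (Tukey) adjusted pairwise scale contrasts.

A synthetic survey generator (`simulateSurvey`) draws species with
Gaussian altitude niches on a logit scale with nested random effects, so
the entire pipeline is testable without field data; its `coreFraction` and
`turnoverStrength` knobs move the community between nested and modular
regimes.

## A worked example

```r
library(tundradiv)

sv <- simulateSurvey(simulationConfig(seed = 7))
cm <- buildCommunityMatrix(sv$records)
cm
#> CommunityMatrix: 300 plots x 148 species
#>   fill: 7251 presences (16.3%)
#>   altitude: 738-1456 m; 3 mountain(s), 12 transect(s), 60 station(s)

## beta diversity grows with spatial scale
bt <- betaDiversityAllScales(cm)
round(tapply(bt$distance, bt$scale, mean), 3)
#>   station  transect landscape
#>     0.347     0.387     0.408

## cover follows a unimodal altitude trend ...
al <- plotAlphaTable(sv$records)
lrtQuadratic(al, "cover_logit", "gaussian", "station")
#> LRT: chisq = 54.811, df = 1, p = 1.327e-13

## ... peaking where the generator put it (cover peak at 850 m)
f <- fitAltitudeTrend(al, "cover_logit", 2, "gaussian", "station")
f
#> Altitude trend (gaussian, degree 2, station nesting; n = 300, logLik = -186.18)
#>         term   estimate        se       z         p
#>  (Intercept) -6.721e+00 7.566e-01  -8.883 6.503e-19
#>     altitude  1.898e-02 1.414e-03  13.426 4.251e-41
#>  altitude_sq -1.117e-05 6.390e-07 -17.475 2.213e-68
round(trendVertex(f))
#> [1] 850

## nestedness and modularity against the fixed-frequency null model
metacommunityAnalysis(cm, nReps = 200, seed = 7)
## -> one row per (subset, sorting, statistic) with observed, null mean,
##    Z and empirical p, for the pooled matrix and each mountain
```

The quadratic cover coefficient is negative (−1.1 × 10⁻⁵ per m²) with a
vertex at 850 m: the fitted cover peak recovers the simulated one. The
distance-to-centroid means rank station < transect < landscape, the
expected scale ordering for communities structured above the patch scale.

Field data enter through `readPlotRecords()` (long CSV:
`mountain,transect,station,plot,altitude_m,cover,species`), or
`readCommunityMatrix()` for an existing presence–absence matrix prefixed
with those metadata columns; `runPipeline()` runs every stage and writes
the result tables, incidence images and a run log. A command-line wrapper
lives at `inst/scripts/tundradiv.R`:

```sh
Rscript inst/scripts/tundradiv.R --simulate --seed 7 --reps 200 --out results/
```

## Package layout

- `R/` — S4 containers (`CommunityMatrix`, `PCoAEmbedding`,
  `NestednessResult`, `ModularityResult`, `NullTestResult`) and the
  analysis stages.
- `vignettes/tundra-diversity.Rmd` — the methods vignette: model
  definitions, parameter meanings and defaults, numerical conventions,
  and what the synthetic generator does and does not emulate.
- `tests/testthat/` — unit, property and oracle tests per module.
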