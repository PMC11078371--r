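# taxodive

Taxonomic distinctness, taxonomic beta diversity and the spatial
structuring of presence/absence communities, in one tested R package.

## Who this is for

Benthic and community ecologists who have three tables — a station ×
species occurrence matrix, a Linnaean taxonomy (species → genus → family →
class), and a station table with coordinates and environmental variables —
and want the standard distinctness-based analysis chain:

1. **Average taxonomic distinctness** Δ⁺ and its **variation** Λ⁺ per
   station, with a **randomization confidence funnel** to flag stations
   more or less taxonomically structured than random draws from the master
   species list,
2. **θ⁺ taxonomic dissimilarity** between stations (nearest-relative,
   presence/absence),
3. **exponential distance decay** of θ⁺ with geographic distance
   (log-link Gaussian GLM, station-level bootstrap CIs),
4. **Ward clustering** of the θ⁺ matrix with silhouette-chosen k and
   **ANOSIM** permutation tests between assemblages,
5. **dbMEM** spatial eigenvectors, **forward selection**, **dbRDA**, and
   four-block **variation partitioning** (environment, linear space,
   broad- and fine-scale dbMEMs) with Monte Carlo tests.

## The statistics

With ω\_ij the taxonomic path length between species *i* and *j* (one rank
step to a shared genus, two to a shared family, three to the shared class;
scaled so the maximum is 100), for a station holding S species:

    Δ⁺ = [ΣΣ_{i<j} ω_ij] / [S(S−1)/2]
    Λ⁺ = [ΣΣ_{i<j} (ω_ij − Δ⁺)²] / [S(S−1)/2]

θ⁺ between samples A and B averages each species' distance to its nearest
relative in the other sample, pooled over both directions.  The distance
decay model is E[θ⁺] = a·exp(b·d) with d in km.  Ordination follows the
dbRDA construction: principal-coordinate embedding of θ⁺ (positive axes),
redundancy analysis on explanatory blocks, adjusted R² (Ezekiel)
throughout the variation partitioning.

A first-class synthetic-data module generates taxonomy, stations,
spatially autocorrelated environmental fields and niche/dispersal-
structured communities with known ground truth, at the scale of a
continental-shelf survey (61 stations, 173 species by default), so every
stage of the chain is testable against a stated world.

## Worked example

```r
library(taxodive)

sim <- simulate_survey(synthetic_scenario(seed = 42))   # 61 x 173 survey
omega <- tax_path_lengths(sim$taxonomy)

res <- taxonomic_distinctness(sim$community, omega)
fun <- build_funnel(omega, "delta_plus", n_sim = 1000, seed = 52)
table(classify_stations(res, fun)$funnel_class)
#> below inside  above
#>     0     61      0

theta <- theta_plus_matrix(sim$community, omega)
geo   <- geo_distance_matrix(sim$stations)
fit   <- bootstrap_decay(fit_decay(theta, geo), n_boot = 1000, seed = 62)
fit
#> Exponential distance decay: y = 43.9782 * exp(0.000665 * d_km), 1830 pairs
#> bootstrap (1000 reps): a in [40.865, 47.399], b in [0.000507, 0.000841]

cl <- choose_k(ward_cluster(theta), 2:8)
anosim_test(theta, cl$labels, n_perm = 999, seed = 72)
#> ANOSIM R = 0.4897, p = 0.001 (sampled, 999 permutations)
```

All 61 stations sit inside the 95% funnel: this simulation filters
species on environment and distance but not on taxonomy, so every station
is as taxonomically dispersed as a random subset of the master list of the
same richness — exactly what the funnel should report.  The decay fit says
station pairs ~1000 km apart are on average exp(0.665) ≈ 1.9× more
dissimilar than co-located pairs; the bootstrap interval for b excludes 0,
so dissimilarity genuinely accumulates with distance in this simulation
(it was generated with dispersal limitation switched on).  ANOSIM confirms
the silhouette-chosen assemblages are more separated than random
relabellings (p = 0.001 at 999 permutations).

One call runs everything and writes every intermediate as CSV/JSON plus a
checksummed manifest:

```r
res <- run_pipeline(pipeline_config(scenario = synthetic_scenario(seed = 42),
                                    seed = 42), out_dir = "out")
```

A CLI driver with subcommands (`simulate`, `distinctness`, `funnel`,
`theta`, `decay`, `cluster`, `anosim`, `dbmem`, `dbrda`, `partition`,
`pipeline`) lives at `inst/cli/taxodive.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","taxodive.R",package="taxodive"))') \
  pipeline --seed 42 --out-dir out
```

## Documentation

`vignettes/taxodive-methods.Rmd` describes the models, the synthetic
world, the numerical choices and the known limitations.
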