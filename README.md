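# cryostruct

Atomistic structure modelling of glycerol–water cryoprotectant mixtures
against X-ray total scattering, built around the question of freeze
avoidance in overwintering insects: below which water content can the
body fluid no longer form ice?

Ice nucleation needs a critical water cluster — about 275 molecules by
infrared spectroscopy of size-selected clusters. cryostruct builds
periodic atomistic models of glycerol–water mixtures with semi-rigid
molecule Metropolis Monte Carlo (Lennard-Jones + shifted-force Coulomb
reference potentials, plus tabulated empirical pair potentials refined so
the model's X-ray structure factor approaches a measured pattern, the
EPSR strategy), converts ensembles to S(Q), g(r), G(r) and
T(r) = 4πrρG(r), calibrates the water content of unknown patterns from
the glycerol intramolecular peak in T(r), and analyses the hydrogen-bond
network and water-cluster statistics that decide whether ice can form:

- `pack_box()`, `reference_forcefield()`, `simulate_ensemble()` — build
  and equilibrate mixtures at the measured densities;
- `ensemble_sq()`, `sq_to_gr()`, `gr_to_tr()`, `partial_gr()` — scattering
  transforms with Faber–Ziman X-ray weighting;
- `run_refinement()` — empirical-potential refinement against a target
  S(Q);
- `build_calibration_curve()`, `estimate_composition()`,
  `subtract_background()` — composition of an unknown (chitin-
  contaminated) pattern;
- `water_clusters()`, `crystallization_composition()`,
  `hbonds_per_glycerol()`, `coordination_number()`, `spatial_density()` —
  the structural observables;
- `generate_standard()`, `generate_larva_pattern()`,
  `generate_temperature_series()` — synthetic data so the whole pipeline
  runs without any external measurement.

Results come back as tibbles (with `tidy()`, `glance()` and `autoplot()`
methods), so they drop straight into dplyr/ggplot2 workflows.

## Worked example

Equilibrate a small near-pure-water box at 275 K and look at the
oxygen–oxygen structure:

```r
library(cryostruct)

box <- pack_box(99, 200, 275, seed = 3)
ff  <- reference_forcefield(box)
ens <- simulate_ensemble(box, ff, n_equil = 2400, n_production = 300,
                         snapshot_every = 5, seed = 4)

pf <- partial_gr(ens, "OW-OW", dr = 0.02)
coordination_number(pf, r_cut = 3.43)
#> # A tibble: 1 × 3
#>   pair  cutoff     n
#>   <chr>  <dbl> <dbl>
#> 1 OW-OW   3.43  4.78
```

The first OW–OW peak sits at 2.75 Å and integrating g(r) to its first
minimum gives about 4.7 neighbours — the tetrahedral-ish first shell of
liquid water. Dehydrate the mixture and the network changes character;
at 15 mol% water every water is wrapped in glycerol hydroxyls, and the
hydrogen-bond count per glycerol (all intermolecular O–O contacts within
3.2 Å) becomes the relevant connectivity measure:

```r
mix <- pack_box(15, 300, 275, seed = 7)
ensm <- simulate_ensemble(mix, reference_forcefield(mix),
                          n_equil = 800, n_production = 150,
                          snapshot_every = 3, seed = 8)
hbonds_per_glycerol(ensm)
#> # A tibble: 1 × 4
#>    mean     sd n_snapshots cutoff
#>   <dbl>  <dbl>       <int>  <dbl>
#> 1  6.02 0.0644          50    3.2
```

Water-cluster statistics answer the freezing question directly:

```r
tidy(water_clusters(ensm$box, cutoff = 3.5))
glance(water_clusters(ensm$box, cutoff = 3.5))
#> # A tibble: 1 × 4
#>   n_water n_clusters max_size cutoff
#>     <int>      <int>    <int>  <dbl>
#> 1      45         41        2    3.5
```

At 15 mol% water the largest water cluster in the box holds a handful of
molecules — vastly below the ~275-molecule crystallisation limit, which
is why such a mixture supercools and vitrifies instead of freezing. A
composition series (`crystallization_composition()`) locates the
threshold composition where the ensemble-mean maximum cluster first
reaches that limit.

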