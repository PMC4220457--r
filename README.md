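# trophicflux

Land-use intensification — the conversion of tropical forest to plantation
agriculture — strips species out of litter invertebrate communities, but a
species count alone says little about what those communities *do*.
`trophicflux` quantifies multitrophic ecosystem functioning as the total
annual energy flux through a guild-level food web, so that losses of
diversity, biomass and function can be compared in one currency across an
entire community. It is written for community ecologists working with
individual-level field collections (site, subplot, morphospecies, feeding
guild, body length) along an environmental or land-use gradient.

## The method

The community is reduced to four feeding guilds — predators, omnivores,
detritivores, herbivores — over two unlimited basal resources (plant,
detritus). At each consumer node the assimilated share of the ingoing energy
flux must cover metabolic demand plus loss to predation:

    e_a · F = X + L,    L_c = Σ_k W[c,k] · F_k

* **X** — guild metabolic demand (J h⁻¹ m⁻²): body lengths → fresh masses via
  an editable allometric registry *M = a·Lᵇ* (with median-based imputation for
  damaged specimens), then individual rates *ln I = ln i₀ + a·ln M − E/(kT)*
  summed per guild.
* **W** — a diet matrix; by default a null model with equal splits among
  permissible resources (predators ⅓ from each animal guild; omnivores 25%
  from each other guild + 25% basal; detritivores/herbivores single-resource).
* **e_a** — diet-weighted assimilation efficiency (animal > plant > detritus).
* **F** — solved exactly for all guilds at once, since the predator ↔ omnivore
  loop couples the equations: `(diag(e) − W_cc) F = X`. Fluxes convert to
  kg fresh mass ha⁻¹ yr⁻¹ via the energy content of biomass.

Around the solver the package provides richness estimators (observed,
second-order jackknife from subplot incidence, individual-based rarefaction),
mixed-model biodiversity–ecosystem-functioning regressions with AIC backward
selection (ΔAIC ≥ 2 rule) and Moran's I residual diagnostics, a diet-model
sensitivity comparison, and a fully seeded synthetic study generator
emulating a replicated four-system land-use gradient (32 sites, ~7,500
individuals, ~870 morphospecies) with known ground-truth effect sizes.
See `vignettes/energy-flux-methods.Rmd` for the full model description.

## Worked example

```r
library(trophicflux)

cfg   <- synth_config(seed = 11)      # default 32-site design
study <- generate_study(cfg)
res   <- run_study(study)             # masses -> metabolism -> fluxes -> diversity

summ <- summarize_by_system(res$sites, "flux_kg_ha_yr")
summ
#>         system      response n     mean       se
#>         forest flux_kg_ha_yr 8 500.9922 18.66926
#>  jungle_rubber flux_kg_ha_yr 8 476.3260 14.29254
#>       oil_palm flux_kg_ha_yr 8 322.5296 19.97190
#>         rubber flux_kg_ha_yr 8 527.2642 18.48995

percent_change(322.5296, 500.9922, "loss")
#> [1] 36        # per-cent loss of total flux, forest -> oil palm

res$networks[["forest_L1_r1"]]
#> <energy_network>
#>             X_J_h_m2    e_a F_J_h_m2 F_kg_ha_yr      L
#> predator      3.6085 0.9000   4.8782    61.0466 0.7818
#> omnivore      0.7390 0.7563   3.1274    39.1367 1.6261
#> detritivore   2.3854 0.2000  23.9663   299.9212 2.4079
#> herbivore     0.8797 0.4500   7.3057    91.4258 2.4079
```

Reading the network: detritivores carry the largest flux not because their
demand X is highest but because detritus assimilates poorly (e = 0.2), so
covering a given demand requires a much larger intake; each guild's `L` is
the part of its flux eaten by predators and omnivores, and
`e_a · F − X − L = 0` holds at every node by construction.

The per-site table `res$sites` also carries observed, jackknife2-extrapolated
and rarefied richness, density, biomass and community metabolism, ready for
`fit_bef_models()` (flux on log10 richness × system, random landscape
intercept) and `morans_i()` on the model residuals.

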