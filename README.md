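# aamix

Quantifying how much of each **essential amino acid** (AA_ESS: Thr, Lys,
Phe, Val, Ile, Leu) in host muscle was synthesized de novo by the **gut
microbiome**, from natural-abundance carbon isotope data.

Hosts cannot make essential amino acids themselves: every AA_ESS molecule in
muscle was either routed directly from dietary protein or supplied by gut
microbes, which can build amino acids from non-protein carbon. A diet that
pairs C3-based protein (casein, δ¹³C ≈ −26.5‰) with C4-based carbohydrates
(sucrose ≈ −12.2‰, cornmeal ≈ −12.0‰) gives the two routes naturally
distinct isotope labels, so the δ¹³C of each muscle amino acid records the
mixture. For amino acid *i* of an individual, the microbial fraction is

```
p_i = (δ_muscle,i − δ_diet,i) / (δ_microbe,i − δ_diet,i)
```

where the **dietary end member** δ_diet is a concentration-weighted mixture
over the diet's protein sources (casein + cornmeal protein) and the
**microbial end member** δ_microbe is the dietary carbohydrate pool value
plus a compound-specific fractionation offset Δ_i. The package is intended
for trophic and physiological ecologists working with compound-specific
stable isotope analysis (CSIA-AA) alongside 16S community profiling.

## What's inside

| Stage | Functions |
| --- | --- |
| Derivatization carbon correction | `calibrate_added_carbon()`, `correct_derivatization()` |
| End-member construction | `dietary_aa_delta()`, `carbohydrate_pool_delta()`, `microbial_endmember_delta()`, `build_endmembers()` |
| Two-source mixing model | `mixing_fraction()`, `estimate_mixing()`, `contribution_table()` |
| Amino acid supply vs demand | `aa_supply()`, `supply_vs_demand()`, `experiment_ration()` |
| Community ecology statistics | `bray_curtis()`, `anosim_test()`, `pcoa_ord()`, `dbrda_test()`, `community_isotope_association()`, `rank_correlation()`, `shannon_diversity()`, `relative_abundance()` |
| Synthetic data with known truth | `simulate_experiment()`, `simulate_isotope_dataset()`, `simulate_otu_table()` |
| Orchestration | `run_pipeline()`, `validate_inputs()` (plus `inst/scripts/aamix-pipeline.R`) |

The Bray–Curtis/ANOSIM/PCoA/db-RDA stack is implemented in the package and
cross-checked against vegan and ape in the test suite.

## Worked example

Simulate the standard design (4 diets × 6 mice × 6 amino acids, plus 5 ceca
per diet) and estimate microbial contributions:

```r
library(aamix)
sim <- simulate_experiment(seed = 1)
est <- estimate_mixing(sim$isotopes, sim$endmembers)
subset(contribution_table(est), treatment == "9P:75C")
#>    treatment  aa   mean      se n n_clipped_low n_clipped_high separation
#> 19    9P:75C Ile 0.3638 0.02563 6             0              0       7.00
#> 20    9P:75C Leu 0.1334 0.05845 6             2              0       3.21
#> 21    9P:75C Lys 0.1421 0.00712 6             0              0       9.28
#> 22    9P:75C Phe 0.0528 0.02893 6             1              0       4.69
#> 23    9P:75C Thr 0.1688 0.02775 6             0              0       7.76
#> 24    9P:75C Val 0.5782 0.01001 6             0              0       6.29
```

In the low-protein diet (9% protein : 75% carbohydrate) the estimated
microbial contribution reaches ~58% for Val and ~36% for Ile while Phe
stays near 5% — the generator's ground truth for these cells is 0.60, 0.40
and 0.03, so the estimator recovers truth within the n = 6 sampling error
(`se`). `separation` is the end-member gap in ‰; `n_clipped_*` counts
individuals whose raw fraction fell outside [0, 1] before clipping.

Community structure separates by diet, and supply falls short of demand in
this diet:

```r
anosim_test(bray_curtis(sim$otu), sim$otu$group, n_perm = 999, seed = 1)
#> ANOSIM: R = 0.594, p = 0.001 (999 permutations)

supply_vs_demand(aa_supply(default_diets()[["9P:75C"]]))[1:3, ]
#>    aa supply_pct demand_pct  ratio   class
#> 1 Thr     0.1248       0.40 0.3121 deficit
#> 2 Lys     0.2383       0.40 0.5957 deficit
#> 3 Phe     0.2282       0.76 0.3002 deficit
```

`supply_pct` is bioavailable content (% of dry food) after digestibility
and mucosal-catabolism discounts; `ratio` is supply/demand.

A config-driven end-to-end run writing tidy TSVs and a run log:

```r
cfg <- system.file("extdata", "config_synthetic.yaml", package = "aamix")
run_pipeline(cfg, out_dir = "aamix-results")
```

See `vignettes/microbial-amino-acids.Rmd` for the model, its assumptions,
and every numerical policy (clipping order, separation floor, axis
retention, permutation conventions).

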