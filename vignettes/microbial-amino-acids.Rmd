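---
title: "Estimating gut-microbial contributions to essential amino acids from natural-abundance carbon isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gut-microbial contributions to essential amino acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aamix)
```

## The scientific problem

Eukaryotic hosts cannot synthesize essential amino acids (here Thr, Lys,
Phe, Val, Ile, Leu) de novo: every essential amino acid in host muscle was
either routed directly from dietary protein or supplied by gut microbes,
which can build amino acids from non-protein carbon. When the diet pairs a
C3-based protein (casein, $\delta^{13}\mathrm{C} \approx -26.5$‰) with
C4-based carbohydrates (sucrose $\approx -12.2$‰, cornmeal $\approx
-12.0$‰), the two supply routes carry naturally distinct carbon isotope
labels, and the $\delta^{13}$C of each muscle amino acid records the mixture.
`aamix` implements the full quantitative chain from raw derivatized isotope
measurements to per-amino-acid microbial contribution estimates, plus the
community-ecology statistics used to relate gut community composition to
those estimates.

## The two-model mixing chain

**Derivatization correction.** Amino acids are derivatized before GC
combustion IRMS, adding exogenous carbon. With $n_{AA}$ amino acid carbons
and $n_{add}$ added carbons, the measured derivative value is a
carbon-weighted average, so the amino acid value is recovered by mass
balance:

$$\delta_{AA} = \frac{(n_{AA}+n_{add})\,\delta_{meas} -
  n_{add}\,\delta_{add}}{n_{AA}},$$

with $\delta_{add}$ calibrated from standards of known composition
(`calibrate_added_carbon()`). The pair of operations is an exact algebraic
inverse, which the test suite checks to machine precision. We work on the
per-mil scale throughout; the error of the linear-in-$\delta$ approximation
is far below measurement noise at natural abundance. The default
added-carbon counts correspond to N-acetyl isopropyl ester chemistry and are
deliberately configurable, since derivatization schemes differ between labs.

**Dietary end member (first mixing model).** The $\delta^{13}$C a muscle
amino acid would have if wholly routed from dietary protein is a
concentration-weighted mixture over the two protein sources (casein, and
cornmeal at 10% protein by weight):

$$\delta_{diet,AA} = \frac{m_{cas} c_{cas,AA} \delta_{cas} +
  m_{cornP} c_{corn,AA} \delta_{corn}}
 {m_{cas} c_{cas,AA} + m_{cornP} c_{corn,AA}}$$

where $m$ are protein masses per gram of diet and $c$ are amino acid
concentrations per gram of protein. Concentration weighting matters because
maize protein is lysine-poor and leucine-rich relative to casein; with equal
concentrations the formula collapses to plain protein-fraction weighting
(an oracle equivalence the tests exploit). Direct routing is treated as
isotopically neutral by default (`routing_offset = 0`, configurable),
consistent with using the dietary protein value itself as the routed end
member.

**Microbial end member.** Gut microbes building amino acids de novo draw
carbon from the dietary carbohydrate pool, whose value is the mass-weighted
mean of sucrose and the non-protein fraction of cornmeal. Each amino acid's
microbial end member is that pool value plus a compound-specific
fractionation offset $\Delta_{AA}$. The shipped offsets (−1 to −4‰) are
placeholders of realistic magnitude, exposed in configuration, because
measured factors are lab- and organism-specific.

**Microbial fraction (second mixing model).** For each individual and amino
acid,

$$p = \frac{\delta_{muscle} - \delta_{diet}}
           {\delta_{microbe} - \delta_{diet}}.$$

Per-treatment summaries report the mean and standard error (sample SD /
$\sqrt{n}$) over the individuals of a treatment, matching a design with six
mice per diet.

### Numerical choices in the mixing stage

* **Separation floor.** When the end members are closer than 1‰ (about
  twice a typical compound-specific measurement SD of 0.5‰) the fraction is
  unidentifiable; `mixing_fraction()` returns `NA` with a warning instead of
  dividing by a near-zero separation. No `NaN` ever propagates silently.
* **Clipping policy.** Measurement noise can push individual fractions
  slightly outside $[0,1]$. Raw fractions are always preserved for
  diagnostics; for reporting, the default clips each individual to $[0,1]$
  before averaging (`clip_order = "before"`), with the alternative
  (average raw, clip the mean) a policy switch. Clipping before averaging
  biases very small true fractions upward by roughly
  $\sigma_p \phi(\mu/\sigma_p)$ — for a true 3% contribution at a 4.7‰
  separation this is about +3 points — which is why near-floor estimates
  should be read alongside `n_clipped_low`.
* **Single replicates.** With one individual the mean is reported and the
  SE is `NA`, never zero.
* **SE coverage at $n=6$.** A $\pm1$ sample-SE interval has exact coverage
  $P(|t_5|<1) = 0.637$ rather than the normal-theory 0.683; the acceptance
  test checks empirical coverage against the exact $t$ value.

## Supply and demand

Bioavailable supply of each amino acid, as percent of dry food, is the gross
dietary content discounted by true ileal digestibility and by mucosal
catabolism (the fraction consumed by the intestinal mucosa and its microbes
before reaching circulation: 30% for Ile, 40% for Leu and Val, 45% for Phe,
50% for Lys, 60% for Thr):

$$supply_{AA} = (m_{cas} c_{cas,AA} + m_{cornP} c_{corn,AA})
  \cdot D_{AA} \cdot (1 - M_{AA}) \cdot 100.$$

Demand is expressed on the same percent-of-dry-food scale so the
supply:demand ratio is unitless; ratios inside $[0.9, 1.1]$ are classified
"balanced" by default. Digestibility and demand defaults are representative
placeholders — the module validates completeness of user-supplied tables
rather than asserting literature values. `experiment_ration()` converts a
daily ration to an experiment ration (e.g. 3 g/day over a 120-day
experiment) when cumulative budgets are wanted.

## Community statistics

The community module implements the ecology statistics directly (they are
part of what this package provides), with vegan/ape serving as independent
cross-checks in the test suite:

* **Bray–Curtis** $d(x,y)=\sum|x_i-y_i| / \sum(x_i+y_i)$, computed on
  total-sum-scaled proportions by default (rarefaction is deliberately not
  implemented; scaling is the simpler, deterministic choice).
* **ANOSIM** on midranked distances, $R = (\bar r_B - \bar r_W) /
  (n(n-1)/4)$, with label-permutation $p = (1+\#\{R^* \ge R\})/(1+n_{perm})$.
* **PCoA** by Gower double-centering and eigen-decomposition; negative
  eigenvalues (routine for Bray–Curtis) are reported and their axes dropped
  by default, with a Lingoes additive correction available. Coordinates
  reproduce Euclidean-embeddable input distances to $10^{-8}$.
* **db-RDA**: multivariate least squares of the per-sample amino acid
  $\delta^{13}$C matrix on the leading PCoA axes, reporting $R^2$, adjusted
  $R^2$, pseudo-F, a permutation p (rows of the response permuted), and a
  Gaussian least-squares AIC for comparability (never used for selection).
  The regression direction is a policy switch
  (`dbrda_direction`) because either orientation is defensible; isotopes as
  response is the default. Axes retained: the smallest leading set
  explaining ≥ 80% of positive-eigenvalue variance, capped at $n-2$ — the
  cap keeps residual degrees of freedom for the F statistic.
* **Spearman rank correlation** with midrank ties and a two-sided
  permutation p.

Permutation counts default to 999 (the analysis convention here is on the
order of 1000); all permutation streams are seedable, and
$\alpha(n_{perm}+1)$ integer keeps the tests exact.

## What the synthetic generator emulates

`simulate_experiment()` produces a paired isotope dataset and OTU table with
shared sample identifiers, under the standard design: four diets (40P:40C,
21P:45C, 12P:55C, 9P:75C with sucrose fixed at 36% of the diet), six mice
per diet for isotopes, five ceca per diet for 16S.

* **Isotopes:** $\delta_{muscle} = (1-p)\delta_{diet} + p\,\delta_{microbe}
  + \varepsilon$, $\varepsilon \sim N(0, 0.5\text{‰})$. The default
  ground-truth fractions encode the reported contribution pattern for this
  system — Val rising to 0.60 and Ile to 0.40 in the lowest-protein diet, a
  below-5% floor for Phe there and for Thr/Lys in the high-protein diets,
  10–40% elsewhere — so recovering them end-to-end is a meaningful
  round-trip. The noise SD (0.5‰) is a typical compound-specific
  measurement SD; it is config-exposed, not asserted as any study's value.
* **Communities:** per sample, taxon proportions are drawn
  $\mathrm{Dirichlet}(\kappa \cdot e)$ around the treatment's expected
  phylum mixture $e$ (split evenly across 8 OTUs per phylum) and counts are
  multinomial at depth 10,000. The default mixtures mirror the reported
  per-diet phylum structure (Firmicutes/Bacteroidetes ≈ 49.5/46.9 and
  45.5/47.6 in the high-protein diets, 82.5 and 66.2% Firmicutes in the
  low-protein diets). $\kappa = 50$ gives inter-individual variability
  large enough that ANOSIM is a real test but separation remains
  detectable — a realistic middle ground chosen once.

What the generator does **not** emulate: sequencing error, chimeras,
amplicon/primer bias, compositional zero-inflation beyond the multinomial,
overdispersion differences between taxa within a phylum, per-amino-acid
noise heterogeneity, and any correlation between an individual's community
and its isotope noise. Passing tests on synthetic data therefore validate
the estimators and their calibration, not the biology of any real dataset.

## Problem sizes and reproducibility

The test-suite and acceptance computations use the study-scale design (4 ×
6 mice, 4 × 5 ceca, depth 10⁴) with 500 replicate experiments for parameter
recovery and calibration checks and 999 permutations for single tests —
sizes at which every check completes in seconds while Monte-Carlo error
stays well below the asserted tolerances. All randomness flows through
explicit integer seeds; isotope and OTU artifacts use separate derived
streams so each is independently reproducible, and pipeline outputs are
byte-identical across reruns of the same config and seed.

## Known limitations

* Two sources only: lipid-derived carbon is not modelled as a third pool,
  and no Bayesian (MixSIAR-style) posterior machinery is provided — the
  estimator is the study-style deterministic linear model with empirical
  SEs.
* End-member uncertainty is not propagated into $p$; the SE reflects only
  between-individual spread.
* Shipped concentration profiles, fractionation offsets, digestibility and
  demand tables are labelled placeholders; real analyses must supply
  measured tables, and conclusions are conditional on those inputs.
* ANOSIM and db-RDA assume exchangeability under the null; with strong
  within-treatment structure (cages, batches) the permutation p-values are
  optimistic.

## A minimal run

```{r example, eval = FALSE}
library(aamix)
sim <- simulate_experiment(seed = 1)
est <- estimate_mixing(sim$isotopes, sim$endmembers)
subset(contribution_table(est), treatment == "9P:75C")

d  <- bray_curtis(sim$otu)
anosim_test(d, sim$otu$group, n_perm = 999, seed = 1)
community_isotope_association(sim$otu, sim$isotopes, seed = 1)
```

Or, config-driven with all outputs on disk:

```{r pipeline, eval = FALSE}
cfg <- system.file("extdata", "config_synthetic.yaml", package = "aamix")
res <- run_pipeline(cfg, out_dir = "aamix-results")
```
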