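# amphistomy

Leaf dorsiventral CO₂ gradients from epicuticular-wax carbon isotopes,
and the patterning of stomata and wax between the two leaf sides.

## The problem

Many herbaceous plants are amphistomatous — they bear stomata on both
leaf surfaces — and the fraction of stomata on the upper (adaxial) side,
the **amphistomy level** `ASL = SD_ad / (SD_ad + SD_ab)`, responds to
growth light. Opening the upper surface to CO₂ should reduce the CO₂
concentration gradient between the two sides of the mesophyll. That
gradient is hard to measure directly, but the epicuticular wax laid down
by each epidermis records the CO₂ environment of its own side in its
carbon-isotope composition. The **isotopic polarity** of the wax,
`δ_ab − δ_ad` (abundance-weighted over the wax compounds of each side,
‰ vs VPDB), can therefore be inverted into the relative CO₂ difference
between the subepidermal tissues:

```
D = (c_ad − c_ab) / c_ab = −( 1 + (δ_l − δ_b + a) / (δ_ab − δ_ad) )⁻¹
```

where `δ_l` is the bulk leaf dry-mass δ¹³C, `a = 4.4 ‰` the
fractionation by CO₂ diffusion in still air, and
`δ_b = δ_a − a (1 − c_i/c_a) = −9.6 ‰` the composition of CO₂ after
partial fractionation through the stomatal pore (with `δ_a = −8.5 ‰`
and `c_i/c_a = 0.75`). A ±1 ‰ error in `δ_b` changes the inferred
`c_ad : c_ab` ratio by less than 1 %.

The package also quantifies side patterning: stomatal densities of the
two sides couple linearly (`SD_ad = k·SD_ab + a`), which makes ASL
approach an asymptote `ASL_pot = k/(k+1)` at high density; wax coverages
couple log-linearly, giving the analogous **amphiwaxy level** (AWL) and
its near-asymptotic `AWL_pot` evaluated at `W_ad = 10 µg cm⁻²`. A
least-squares path model with a cluster bootstrap over replicate plants
separates the direct ASL–polarity association from associations mediated
by light and leaf age. A forward generator produces study-shaped
synthetic datasets (2 species × 2 light levels × 3 leaf ages × 9
replicates, five odd-chain alkanes for the pepper-like species, 0.1 ‰
instrument noise) with known ground truth, so every stage is validated
by parameter recovery.

It is written for plant ecophysiologists working with compound-specific
(GC-IRMS) or bulk wax isotope data alongside stomatal counts.

## Worked example

```r
library(amphistomy)
p <- disc_params()
p$delta_b
#> [1] -9.6
co2_drawdown(delta_leaf = -30, polarity = 1, p)
#> [1] 0.06666667

study  <- generate_study(synthetic_config(seed = 42))
leaves <- as_leaf_records(study$leaves)
pol    <- polarity_table(study$compounds, leaves, p)
head(pol[c("leaf_id", "polarity", "drawdown", "ratio")], 3)
#>                  leaf_id polarity  drawdown ratio
#> 1 broccoli_HL_P01_mature  -0.6667 -0.047482 0.953
#> 2    broccoli_HL_P01_old  -0.6996 -0.048972 0.951
#> 3  broccoli_HL_P01_young  -0.0108 -0.000797 0.999

sub <- leaves[leaves$species == "pepper", ]
fit <- fit_coupling(sub$sd_ab, sub$sd_ad)
fit
#> Side coupling (identity): k = 0.3817, a = -24.79, r2 = 0.9437, n = 54
asl_pot(fit)
#> [1] 0.276
```

A polarity of +1 ‰ in a leaf with `δ_l = −30 ‰` implies CO₂ about 6.7 %
higher under the adaxial than the abaxial epidermis; the negative
drawdowns of the simulated high-light broccoli leaves mean the opposite
gradient. The stomatal coupling slope `k = 0.38` caps the pepper-like
species' amphistomy at `ASL_pot ≈ 0.28` however dense its stomata
become.

## The analysis workflow

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables under `results/analysis/`:

1. `01_simulate.R` — generate the study (leaves, compounds, truth);
2. `02_polarity.R` — weighted side means, polarity, drawdown, `δ_b`
   sensitivity, intercellular CO₂ from bulk δ¹³C;
3. `03_patterning.R` — ASL/AWL, side-coupling fits by light and by age,
   `ASL_pot`/`AWL_pot`, ASL-on-polarity regressions and their
   zero-polarity intercepts;
4. `04_path.R` — direct vs light/age-mediated associations with cluster
   bootstrap;
5. `05_recovery.R` — bias/RMSE/coverage of every estimator across 50
   generator replicates.

`run_pipeline()` performs stages 2–4 in one call on any pair of
contract-conformant tables (see `?read_leaves`).

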