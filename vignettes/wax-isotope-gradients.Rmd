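---
title: "Inferring leaf dorsiventral CO2 gradients from wax carbon isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring leaf dorsiventral CO2 gradients from wax carbon isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amphistomy)
```

## The model

Epidermal cells synthesize their epicuticular wax locally, from carbon
fixed in the chloroplasts adjacent to their own leaf side, and wax is
renewed throughout the leaf's life. The carbon-isotope composition of
the wax on each side therefore integrates the CO2 environment of that
side. Writing the abundance-weighted wax compositions of the two sides
as δ_ad and δ_ab (‰ vs VPDB, `weighted_side_delta()`), their difference
— the isotopic polarity δ_ab − δ_ad — reflects the difference in CO2
concentration between the subepidermal tissues, because carboxylation
discriminates more strongly where CO2 is more abundant.

The inversion (`co2_drawdown()`) is

$$D = \frac{c_{ad} - c_{ab}}{c_{ab}}
   = -\left(1 + \frac{\delta_l - \delta_b + a}
                    {\delta_{ab} - \delta_{ad}}\right)^{-1},$$

with the bulk leaf dry-mass composition δ_l anchoring the leaf's overall
discrimination, the diffusion fractionation in still air a = 4.4 ‰, and
δ_b the composition of CO2 that has passed the stomatal pore. δ_b is
modelled as a single leaf-level constant,
δ_b = δ_a − a(1 − c_i/c_a) = −9.6 ‰ for δ_a = −8.5 ‰ and c_i/c_a = 0.75
(`boundary_delta()`). Treating δ_b as one constant for both sides is a
deliberate simplification; `boundary_sensitivity()` quantifies its cost:
over leaves with δ_l ∈ [−41, −28] ‰ and |polarity| ∈ [0.1, 1.5] ‰, a
±1 ‰ error in δ_b moves the inferred ratio c_ad : c_ab by under 1 %.

Assumptions the user inherits: wax carbon is not exchanged between leaf
sides (epidermal lipid autonomy), the post-photosynthetic fractionation
of wax synthesis is side-symmetric (so it cancels from the polarity),
and the leaf is near a quasi-steady isotopic state over the integration
time of wax turnover.

### Intercellular CO2 from bulk composition

`ci_from_bulk_delta()` back-calculates c_i from δ_l under the
two-endmember discrimination model with infinite mesophyll conductance,
using the exact bulk discrimination
Δ = (δ_a − δ_l)/(1 + δ_l/1000) rather than its linear approximation —
exactness costs nothing and matters at the ~1 µmol mol⁻¹ level. The net
carboxylation fractionation defaults to b = 30 ‰; it is the least
certain constant in the chain, is exposed in `disc_params()`, and only
rescales c_i between its 0 and c_a limits. Δ outside [a, b] is clamped
with a warning rather than rejected: such values arise from perfectly
legitimate measurement noise near the limits.

## Patterning and asymptotes

Stomatal densities of the two sides couple linearly,
SD_ad = k·SD_ab + a (`fit_coupling()`, ordinary least squares with the
abaxial side as regressor — the panels this mirrors are OLS fits, not
errors-in-variables). Substituting the coupling into the ASL definition
gives `asl_curve()`,

$$\mathrm{ASL} = \frac{k}{k + 1 - a/\mathrm{SD}_{ad}},$$

which tends to ASL_pot = k/(k+1) as density grows. On data lying exactly
on the coupling line the curve reproduces the direct ASL identically
(tested to 1e−12).

Wax coverage couples log-linearly (log10 on both axes; the base only
shifts the intercept and every derived AWL value is base-consistent).
The AWL analogue of the curve has a degenerate mathematical limit — 0
for k < 1, 1 for k > 1 — so `awl_pot()` reports the near-asymptotic
value at a reference adaxial coverage w_ref = 10 µg cm⁻² and the limit
class separately; the reference value is the informative one.

`regress_asl_on_polarity()` estimates, per group, the ASL at which the
isotopic polarity vanishes — the amphistomy level at which both sides
experience the same CO2 — as the intercept of an OLS line of ASL on
polarity, with a classical t-based 95 % interval (the method behind the
"95 % confidence band" is not specified where such bands are usually
drawn, so the standard mean-response interval is used). Grouping is
caller-controlled (`group` keys) rather than hard-wired, because
reasonable analyses stratify either by species, by light within
species, or by age.

## The path stage

`fit_path_model()` separates a direct ASL–polarity association from
associations mediated by light and age with two least-squares equations
(polarity ~ ASL + light + age; ASL ~ light + age). A Bayesian
hierarchical fit of the same structure is deliberately replaced by least
squares plus a cluster bootstrap: the scientific content is the path
decomposition, not the sampler, and resampling whole replicate plants
honours the repeated-measures structure nonparametrically — the role a
random replicate intercept plays in a mixed model. Percentile intervals
are used (simplest defensible choice; BCa adds machinery without
changing any qualitative call at these cluster counts). Age enters with
reference level "old" and light as an HL indicator; no mediation formula
is standard for this design, so the reported "indirect light
association" — the light effect on ASL times the marginal ASL–polarity
slope — is this package's labelled convention.

Identifiability caveat: when ASL barely varies (one species here is
exactly such a case), the direct effect is inestimable and the function
says so rather than returning a fragile number.

## The synthetic generator

`generate_study()` emulates the study design: 2 species × 2 light
levels × 3 leaf-age classes × 9 replicate plants, each plant
contributing one leaf per age (108 leaves). Per leaf: SD_ab is drawn
normally (truncated at 0, truncations counted and reported), SD_ad
follows the species' linear coupling plus residual, the true drawdown
follows D = d0 + d1·ASL + d2·I(HL) + noise, and the true polarity is
the exact algebraic inverse of the drawdown equation at the leaf's δ_l.
Compound-level δ values are side target + compound offset + plant
random intercept + 0.1 ‰ measurement noise; offsets are centred under
the abundance weights so the weighted side mean is exact at zero noise.
Wax coverages follow the log-linear coupling.

The defaults are chosen once to be realistic for the system emulated:
bulk δ_l per species and light at the published bulk-tissue scale
(−28.26/−33.91 ‰ and −27.63/−33.95 ‰ for HL/LL), a wax depletion of
−3.0 ‰ against dry mass, five odd-chain alkanes (C27–C35) for the
pepper-like species and three C29 aliphatics for the broccoli-like one,
compound offsets spanning ±1 ‰, stomatal couplings (k ≈ 0.37 and
k ≈ 1.0) that put the ASL asymptotes near 0.27 and 0.5, and drawdown
coefficients (d0 = 0.10, d1 = −0.25, d2 = −0.04) that give low-light
leaves a polarity near +1.4 ‰ shrinking toward zero in high light.
Biological scatter magnitudes are not published as numbers anywhere, so
they are set to visually plausible scales and exposed in the config;
only the 0.1 ‰ instrument σ is a stated quantity.

What passing recovery tests show — and what they do not: the pipeline
is unbiased and calibrated *under this generator* (Gaussian noise,
linear couplings, exact design balance). Real data bring unbalanced
designs, non-Gaussian compound scatter, shared-compound mismatches
between sides and possible side-specific wax fractionation; the
generator does not emulate those, which is why `leaf_polarity()` exposes
`shared_only` pairing and the io layer validates rather than repairs.

## Numerical choices

* Polarity 0 maps to drawdown 0 by continuous extension; the raw
  inversion is singular there.
* Physical-regime guard: inputs with |N/polarity| ≤ 1 + 1e−6
  (N = δ_l − δ_b + a) are rejected with a classed error carrying N,
  polarity and their ratio; inside that band the implied CO2 ratio is
  non-positive or explosive and silently returning it would poison
  downstream regressions.
* The symbol "a" is used in the field both for the diffusion
  fractionation and for regression intercepts; the code names them
  `frac_a` and `intercept_a` to prevent collision.
* Pipeline outputs are serialized with six significant digits and fixed
  row order, so identical inputs give byte-identical files.
* Problem sizes: the test suite validates identities on exhaustive small
  grids (n ≤ 20 for the regression oracle), recovery on 200 generator
  replicates with 500 bootstrap resamples each, and the coverage claims
  on 500 replicated regressions; these sizes give Monte-Carlo standard
  errors comfortably below the margins being asserted.

## Limitations

No finite mesophyll conductance, no ternary diffusion corrections, no
mechanistic model of the −3 ‰ wax offset (it is treated as descriptive
and side-symmetric), and no attempt to reproduce posterior summaries of
any particular Bayesian fit — the path stage is a structural analogue.
The zero-polarity intercepts and asymptote values computed on synthetic
data characterize the estimators, not any real species.
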