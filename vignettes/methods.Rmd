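---
title: "Floral-resource maps, land-cover maps and two-step models for aphid predators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floral-resource maps, land-cover maps and two-step models for aphid predators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidscape)
```

## The scientific problem

Predatory insects — hoverflies, ladybirds and lacewings — suppress aphid
pests in arable crops, and many of them consume pollen or nectar during
parts of their life cycle. A long-standing proposal in landscape ecology
is that *functional resource maps* (here: maps of floral-resource
availability) should predict the abundance of such beneficials better
than coarse *land-cover maps* that only record habitat classes.
`aphidscape` implements the complete analytical chain needed to test that
proposal in a study design built around circular landscape sectors
(default radius 500 m) whose centres hold standardized faba-bean
phytometer plants infested with a known starting population of black bean
aphids:

1. **Land cover**: habitat patches are summarised per sector into areas
   and proportions of four analysis categories (forest edge, semi-open
   habitat, grassland, crop) plus a residual "other" class; forest edge,
   semi-open habitat and grassland pool into the semi-natural habitat
   (SNH) fraction.
2. **Floral resources**: field flower surveys (assessment cubes,
   woody transects with calibration cubes, crop-field cubes) are turned
   into species-specific availability values
   \(F = N \cdot S \cdot T\), where \(N\) is the flower number in a
   landscape, \(S\) the volume of one open flower (m^3) and \(T\) the
   flowering duration (days), pooled per habitat and per landscape.
3. **Outcomes**: predator observations are pooled over plants, sampling
   rounds, taxa and life stages into one count \(P\) per landscape;
   aphid control is measured as population growth
   \(G = \sum \text{day-14} - \sum \text{day-0}\) (negative values mean
   net suppression).
4. **Models**: predator counts are zero-inflated, so they are analysed
   with a two-step (hurdle) approach — a binomial model on
   presence/absence, then a Gaussian linear model on \(\log_{10} P\)
   excluding zero-count landscapes. Aphid growth is analysed with plain
   linear models, including one on \(\log_{10}(P + 1)\). Each predictor
   set is a separate model family (no backwards selection), screened with
   variance inflation factors (threshold 3) and summarised with AICc,
   a likelihood-ratio generalized R^2, standardized coefficients and
   marginal tests.

## The two-step model

For pooled counts \(P_i\) in landscape \(i\) with predictors \(x_i\):

* Step 1: \(\Pr(P_i > 0) = \operatorname{logit}^{-1}(\alpha_0 + \alpha^\top x_i)\),
  fitted by maximum likelihood; per-predictor inference uses Type II
  likelihood-ratio chi-squared tests. The statistic column is labelled by
  its actual type (`LR_chisq`) rather than relabelled as an F value.
* Step 2: \(\log_{10} P_i = \beta_0 + \beta^\top x_i + \varepsilon_i\) on the
  positive subset only, with Type II marginal F tests (for a
  single-predictor model this is the overall F test).

The steps are estimated independently; no joint hurdle likelihood is
maximised. A step is reported as *unfit*, with the reason, when its data
are degenerate: a single-class presence response, perfect separation, or
fewer positive counts than `p + 2`.

Model quality is reported as
\(\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)\) (with \(k\) counting the
residual variance for Gaussian fits) and the likelihood-ratio generalized
\(R^2 = 1 - \exp\{-\tfrac{2}{n}(\ell_{\text{full}} - \ell_{\text{null}})\}\),
which reduces to the classical \(R^2\) for Gaussian linear models — a
property the test suite checks numerically. A permutation test
(default 500 permutations, two-sided, the observed statistic counted into
the null set so \(p \ge 1/(n_{\text{perm}}+1)\)) is available as a
distribution-free robustness check.

### Standardization convention

Reported standardized coefficients are slopes for z-scored predictors
(\(\beta_{\text{std}} = \beta \cdot \mathrm{sd}(x)\)); the response is left
on its model scale. `run_model_suite()` z-scores the predictor columns
before fitting, so raw and standardized slopes coincide there. This is a
declared convention: published tables of this kind rarely define their
standardization, and other conventions (e.g. dividing by the response SD)
would change magnitudes but not tests or signs.

## Tunable parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `sector_radius` | m | 500 | the landscape scale at which composition is summarised |
| `h_layer` | m | 1 | depth of the flower-bearing layer used to convert a per-m^3 density into an area-based flower number; 1 m is the assessment-cube height. A per-m^3 density applied to an area needs this depth for dimensional closure; it rescales all herbaceous/crop \(F\) values linearly and therefore cancels out of standardized analyses |
| `predator_offset` | count | 1 | offset in \(\log_{10}(P + \text{offset})\) so zero-predator landscapes stay in the aphid model (the aphid model keeps all landscapes) |
| VIF threshold | — | 3 | conventional screening cut-off for collinearity among landscape predictors |
| `n_perm` | — | 500 | permutation-test resolution; smallest attainable p is 1/501 |
| significance mark | — | p < 0.05 | bolding threshold in reports; no multiple-testing correction is applied across families, matching how such tables are conventionally reported (each family stands alone) |

## The synthetic-data generator

Field data of this kind are rarely public, so the package ships a
generator whose defaults define the study conditions used by every
calibration experiment:

* **Landscapes.** 19 sectors of 500 m radius; habitat composition is
  Dirichlet over {forest edge, semi-open, grassland, crop, other} with
  concentrations (0.8, 1.0, 2.4, 6.0, 9.8), i.e. mean shares of about
  4%, 5%, 12%, 30% and 49% and realistic between-sector spread. The
  "other" class absorbs roads, settlements and water, so the four
  analysis categories deliberately do not fill the circle.
* **Species pool.** 40 flowering species with log-uniform flower sizes in
  [1e-8, 1e-5] m^3 and uniform flowering durations in [7, 42] days; each
  species has one primary habitat, a growth form implied by it, and a
  mean flower density drawn around a habitat-level log10 mean
  (1.7 for the two woody categories, 1.0 for grassland, 1.5 for crops,
  between-species SD 0.4). About 15% of grassland species are grasses and
  carry the exclusion flag.
* **Surveys.** Cube counts are Poisson around the species' mean density —
  the simplest count model consistent with how densities are measured.
  Woody elements get per-species flower-bearing volumes proportional to
  patch area with log-normal noise, plus a 10-individual x 2-cube
  calibration set per species; crops get 10 fields per insect-pollinated
  crop type.
* **Outcomes.** Presence is Bernoulli with logit
  \(1.3 + 1.0\,z\) on the forest-edge proportion standardized across the
  sectors of the study (so slopes are comparable across simulated
  studies); conditional counts are
  \(P = \max(1, \operatorname{round}(10^{0.9 + 0.5 z + \varepsilon}))\),
  \(\varepsilon \sim N(0, 0.3)\). Flooring presence-conditional counts at
  one makes the hurdle exact in the generator: zeros arise only from the
  presence step. With these values a typical study has about four
  zero-predator landscapes out of 19 and per-landscape counts mostly in
  the single to low-double digits, matching the zero fraction implied by
  the degrees of freedom of such two-step analyses. Starting aphids are
  Poisson around 20 per plant on 10 plants; growth is
  \(G = 1200 - 300 \log_{10}(P+1) + \eta\), \(\eta \sim N(0, 250)\), and
  the day-14 census is floored at zero. These values put day-0 pools near
  200 aphids, mean growth near 900 and a clearly negative
  predator-growth relationship of plausible relative strength.
* **Seeds.** One master seed; each generator component uses a fixed,
  documented offset of it, so a component can be regenerated alone and
  reproduce exactly what `generate_study()` produced.

The generator emulates *composition only*: no patch geometry, spatial
autocorrelation, neighbourhood effects, observer error, phenological
turnover between survey rounds, or predator taxon-specific ecology (taxon
labels are drawn from fixed proportions). Passing calibration tests
therefore demonstrates that the statistical machinery is correct and well
calibrated under the declared generating process — not that the
ecological conclusions of any particular field study are right.

Within-season aphid dynamics are not modelled beyond the two census
days; the linear growth model with additive Gaussian noise is one
admissible choice among several (e.g. multiplicative growth), and is
flagged as such.

## Numerical and design choices

* **Rounds are averaged, not summed.** The duration term \(T\) already
  carries phenology into \(F\); summing survey rounds would double-count
  it. The across-round mean is a declared choice — the alternative
  (summing per-round availabilities over round-specific durations) would
  need round-level duration data the protocol does not provide.
* **Representative-patch extrapolation.** A density estimated in the
  representative patch of a grassland management type applies to all area
  of that sub-type in the landscape; a missing (landscape, sub-type,
  species) estimate falls back to the across-landscape mean for that
  sub-type and is flagged `imputed` in the map.
* **Woody volumes.** Transect volumes enter \(D \times V\) uncorrected;
  no crown-openness factor is applied (none is defined in the protocol).
* **Proportion denominator.** Habitat proportions divide by the full
  sector area \(\pi r^2\), not the mapped area, so unmapped area dilutes
  proportions — habitat shares are shares *of the landscape*.
* **Geometry.** Polygon input is planar (projected, metric); areas use
  the shoelace formula and sector clipping uses Sutherland–Hodgman
  against a 360-gon approximation of the circle (relative area error
  about 5e-5, far below mapping accuracy).
* **Overlapping polygons** are treated as an input error upstream, not
  resolved silently; patch tables are assumed amalgamated.
* **Degenerate fits.** A constant response yields F = 0 by convention; a
  perfect fit yields an infinite F with p = 0. `car::Anova()` refuses
  zero-residual fits, so the package falls back to the defining drop-one
  sums of squares in that case. Perfect separation in the binomial step
  is detected via a near-zero deviance and reported, not silently
  accepted.
* **Aphid control sign.** The suite models growth \(G\) itself (not
  \(-G\)); a *negative* predator coefficient on \(G\) therefore means
  *positive* aphid control. This is an interpretive convention and is
  stated in the report rather than baked into a sign flip.
* **Zero-variance predictors** are left unscaled with a warning at frame
  construction, and any family using them is marked unfit with its
  reason, so one degenerate column cannot abort the remaining families.

## Problem sizes for calibration

The calibration experiments shipped with the package use 1000 simulated
19-landscape studies for the type-I error of the step-2 forest-edge
F test (nominal 5%), 500 studies per point of the effect-size grid
{0, 0.25, 0.5, 1} for power and parameter recovery (at abundance SD
0.3), and 200 studies each for sign recovery of the two headline
relationships and for the two-step versus plain-OLS concordance check.
These sizes give Monte-Carlo standard errors comfortably below the
decision margins involved (e.g. about 0.007 on a 5% rejection rate at
1000 replicates).

## Known limitations

* Floral availability collapses the survey window into a single \(F\)
  per species; no phenological time series, nectar/pollen chemistry or
  per-taxon resource weighting.
* Only composition is analysed; configuration metrics (edge density,
  isolation) are out of scope.
* The two steps of the hurdle are fitted independently; no joint
  likelihood, and no spatial autocorrelation structure.
* GeoJSON input supports plain `Polygon` features only; multi-polygons
  should be split upstream.
* With 19 landscapes and four predictors the binomial step is fragile:
  separation-induced unfit steps are expected in a few percent of
  simulated studies and are reported as such rather than forced to
  converge.
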