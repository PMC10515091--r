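---
title: "Predicting bamboo distribution zones from leaf indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bamboo distribution zones from leaf indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafzone)
```

## The problem and the model

Bamboo species differ widely in low-temperature tolerance, and their
northernmost viable distribution in China is conventionally expressed as an
integer hardiness zone from 1 (coldest) to 12 (warmest). Leaf morphology
and anatomy integrate a species' long-term climatic adaptation: northern
species tend toward smaller, narrower blades with denser veins and a higher
proportion of protective tissue per unit area. `leafzone` operationalises
this relationship as a supervised regression of zone on a screened set of
leaf indicators.

The pipeline makes three substantive assumptions:

1. **Stable indicators carry the signal.** Indicators that vary strongly
   with season or growing region reflect plasticity rather than genotype,
   so they are removed before modelling. Stability is measured by the
   coefficient of variation, CV = 100·SD/M, with the sample SD (n − 1
   denominator). CV classes are weak [0, 15)%, middle [15, 35)%, strong
   [35, ∞)%; only strong-variation indicators are rejected.
2. **A single common-garden stratum isolates the zone signal.** The
   correlation screen uses species means from one season and one site, so
   that between-region environmental differences do not masquerade as
   inter-species signal. The stratum is a parameter of
   `correlate_with_zone()`.
3. **Responses may be nonlinear but additive.** The composed nonlinear
   model (MNLR) assumes zone is an additive combination of univariate
   transforms of single indicators; interactions are deliberately out of
   scope, mirroring standard curve-estimation practice.

## Indicator panel and units

`compute_indicator_panel()` derives 33 indicators per leaf. Lengths and
widths are in mm, areas in mm², vein density per cm of counting span,
stomatal density per mm². Section thicknesses are kept on the numeric scale
on which anatomical tables of this kind are printed (micrometre-magnitude
values, e.g. a leaf thickness of ~130); the package treats them as opaque
"printed units" and never converts them. This matters because the published
fitted equations encoded in `published_model()` were estimated on exactly
those scales — e.g. leaf length/leaf thickness near 1.15 for a 150 mm blade
of thickness 130 — and converting units would silently rescale every ratio
indicator. Ratios such as `length_per_area` are defined
numerator-over-denominator (leaf length / leaf area); the reverse
convention occasionally seen in prose is not used.

Vein density uses a separately recorded counting span in cm; when that span
is missing the leaf width (mm/10) is substituted with a logged message,
since the two are separate measurements of the same physical width.
Missing measurements propagate as `NA` indicators and are removed pairwise
downstream; nothing is imputed.

## Screening decisions

* **Per-species CVs are averaged arithmetically** into the per-indicator
  seasonal/regional summary. How individual species' CVs combine into one
  bar is genuinely open; the arithmetic mean is the simplest symmetric
  choice, and the per-species values are retained as an attribute for
  audit.
* **Bin boundaries are left-closed** ([0,15), [15,35), [35,∞)), resolving
  the overlapping prose bounds ("0–15%", "15–35%", "35–100%")
  deterministically. Correlation-magnitude classes follow the explicit
  inequalities |r| ≥ 0.8 high, 0.5 ≤ |r| < 0.8 moderate, 0.3 ≤ |r| < 0.5
  weak, |r| < 0.3 extremely weak.
* **No multiple-testing correction** is applied by default: the screen is
  a raw P < 0.05 filter, as is conventional in this literature. Users can
  pass `p.adjust()`-ed values into `select_model_indicators()` if they
  prefer a false-discovery-rate screen.
* `select_model_indicators()` consumes the report's significance and class
  columns as given rather than recomputing p from r. This keeps the
  selection arithmetic well-defined even for reports transcribed from
  printed summaries, whose r magnitudes and significance flags are not
  always mutually consistent.

## Curve catalogue and family selection

`curve_catalogue()` mirrors a standard curve-estimation set — linear,
quadratic, cubic, logarithmic, inverse, power, exponential, growth,
S-curve, logistic — plus `shifted_inverse`, y = b₀ + b₁/(b₂ + x), which is
required because hyperbolic terms with an estimated offset (of the form
c/(k + x)) appear in the published composed equations and no standard
family produces them. Transform-fittable families are estimated in closed
form on the transformed scale, but **R² is always recomputed on the
original response scale** so that families are comparable.

`best_family()` compares R² **rounded to two decimals** (configurable via
`r2_digits`), breaking ties by fewest parameters and then catalogue order.
The rounding is not cosmetic: polynomial families are nested, so at machine
precision a cubic never loses to the quadratic or linear family it
contains, and every response would be classified cubic. Comparing at
reporting precision restores the intended behaviour — a higher-order family
must *visibly* improve the fit to be chosen — and matches how analysts
reading software output actually select curves. Degenerate inputs (domain
violations, constant responses, fewer points than parameters) mark a family
infeasible rather than raising, so selection degrades gracefully.

`joint_nls_fit()` refits the additive composition by Levenberg–Marquardt
least squares from the univariate initialisation (tolerance 1e−8 on the
relative SSE change, 500 iterations maximum, both configurable).
Non-convergence is a reported state (`converged`, `iterations`,
`message`), never silent. Because the refit starts at the univariate
solution, the joint SSE never exceeds the un-refit composition's SSE.
When the composed parameter count would reach the row count,
`fit_mnlr()` demotes the least informative predictors (lowest univariate
R²) to the linear family until the fit is identifiable — with 13
indicators, mostly cubic selections and only 29 species, the unconstrained
composition would otherwise be over-parameterised.

## Principal-component models

`fit_pca()` standardises indicators, eigendecomposes the correlation
matrix, and retains components with eigenvalue strictly greater than 1.
Score coefficients follow the regression method (loading/λ), giving
training scores unit variance and zero mean; contribution rates are
100·λ/Σλ. Whether published component-score equations of this kind were
applied to raw or standardised indicators is not stated in the sources
that print them; both modes are therefore available in `pc_scores()`, and
the bundled published score matrices default to raw application since they
carry no standardisation constants.

## Published reference equations

All printed equations are encoded verbatim, including suspected
typographical slips (a duplicated cubic term in one PC-score model; one
score coefficient printed without its decimal point, encoded at the
magnitude its column implies). Evaluations at the all-zero input are
insensitive to these ambiguities, which is why the zero-vector constants
anchor the package's reference checks. The reduced composed nonlinear
equation (MNLR-E) was published only as an image; its coefficients are not
recoverable from text, and `published_model("MNLR-E")` says so rather than
guessing.

Continuous predictions are mapped to integer zones by nearest-integer
rounding (half away from zero), clipped to [1, 12]; the sources compare
continuous predictions with integer zones without stating a rule, and this
is the least surprising one.

## The synthetic generator

`paper_analogue_config()` emulates the study design the method assumes: 29
fitting species plus 6 holdout species with zones cycling over 1–12, 30
leaves per species (the scale of a ~3000-leaf, ~100-collection field
campaign), 18 species re-sampled in summer, and 3 species re-sampled in
five regions. Base measurements are generated first and ratio indicators
derived from them, so internal consistency holds exactly; counts are
fractional (density × counting window) so zero-noise draws reproduce the
planted responses bit-exactly.

Design choices worth knowing:

* **Responses.** Blade length and width grow linearly with zone (width a
  fixed fraction of length), leaf area follows a monotone cubic with an
  inflection mid-range, adaxial epidermis a gentle quadratic, vein density
  a declining line; thickness, cuticles, mesophyll and stomatal density
  are zone-flat. This yields the observed sign pattern: positive zone
  correlations for x₂–x₉, negative for x₁ and the per-area ratios
  x₁₀–x₁₃.
* **Noise.** All noise is multiplicative mean-one lognormal, which keeps
  traits positive and makes CVs directly controllable: per-leaf CV 10%,
  plus an 8% per-species idiosyncrasy CV. The species-level term is not
  part of the minimal leaf/season/region noise description, but without
  it species means are nearly noiseless (leaf noise shrinks by √30) and
  every regression family fits R² ≈ 1, which would make model comparison
  degenerate; real species differ for reasons beyond their zone.
* **Planted instability.** Regional multipliers are chosen so that
  exactly three indicators exceed the strong-variation threshold — leaf
  area, abaxial cuticle/leaf area and mesophyll/leaf area. The key device
  is that the adaxial cuticle's regional multiplier tracks leaf area's
  (areal plasticity affects both), so adaxial cuticle/leaf area stays
  stable while the untracked abaxial-cuticle and mesophyll ratios vary
  strongly. The multiplier vectors were fixed analytically from the CV
  formula before any pipeline run. A fully consistent derived panel
  cannot make ratios such as thickness/area *uncorrelated* with zone once
  area responds to zone; in the generator, as in the screening logic,
  those companions are removed by the stability screen, not by the
  correlation screen.
* **What is not simulated.** Physiology (photosynthesis, sugars,
  moisture), within-canopy structure, measurement rounding, spatial or
  phylogenetic correlation between species. Passing recovery benchmarks
  therefore demonstrates the pipeline's statistical correctness under its
  own assumptions, not field validity.

## Benchmark problem sizes

The recovery benchmark (`recovery_benchmark()`) uses 50 seeds of the
29-species analogue for screening recovery and model ranking; the
family-identification component runs at reduced noise (species CV 1%, leaf
CV 5%, i.e. species-mean noise near 1.5% of each response range) because
polynomial-degree identification is information-limited: at high noise no
R²-based selector can separate nested families at reporting precision.
The linear-truth comparison of MNLR against MLR likewise uses a small
response noise (6% of the signal SD), since the composed model's extra
parameters inflate training R² by roughly (1 − R²)·k/(n − p), which no
implementation can keep within a tight band at high noise. These sizes are
the package's own benchmark definitions and run in a few minutes on one
core.

## Known limitations

* Training R² of the saturating MNLR on 29 species is an optimistic
  estimate of predictive skill; the holdout comparison in
  `verify_models()` is the honest check, and with very small holdout sets
  it reports error and exact-match counts rather than an unstable R².
* The "-E" reduction drops extremely weakly correlated indicators, which
  may *lower* fit (nested-model R² can only drop for the linear family);
  it trades fit for parsimony.
* PCA-based variants compress away low-variance directions that may still
  predict zone; on both the analogue benchmark and in the encoded
  reference results they trail the raw-indicator models.
* The zone scale is ordinal; treating it as numeric is a modelling
  convenience inherited from the method being implemented.
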