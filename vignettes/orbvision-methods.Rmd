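---
title: "Models and methods behind orbvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orbvision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbvision)
```

orbvision packages three linked analyses of ontogenetic colour variation in
orb-weaver spiders — whether a hymenopteran prey can see the spider's body
patches against vegetation, whether web properties and body size predict
foraging success in the field, and whether webs bearing a spider intercept
more bees in a two-choice tunnel. This vignette explains the models, the
choices that were genuinely open, and what the synthetic-data generators do
and do not emulate.

## The trichromatic colour-hexagon model

Hymenopteran colour vision is modelled with three photoreceptors (UV, blue,
green). For a stimulus with reflectance $R(\lambda)$ viewed under an
illuminant $I(\lambda)$, the quantum catch of receptor $i$ with spectral
sensitivity $S_i(\lambda)$ is

$$P_i = \frac{\int R(\lambda)\, S_i(\lambda)\, I(\lambda)\, d\lambda}
             {\int R_b(\lambda)\, S_i(\lambda)\, I(\lambda)\, d\lambda},$$

normalized by the same integral for the adapting background $R_b$ (von
Kries adaptation), so the background yields $P_i = 1$ for every receptor.
Receptor excitation follows the hyperbolic transform $E_i = P_i/(P_i+1)$:
the adapted background sits at $E = 0.5$, half the maximum. The hexagon
coordinates are

$$x = \frac{\sqrt{3}}{2}(E_g - E_u), \qquad
  y = E_b - \tfrac{1}{2}(E_u + E_g),$$

which place the background at the origin and the six corners of the
excitation cube at distance exactly 1. **Chromatic contrast** is the
Euclidean distance between a sample and the background in this plane
(short-range, colour-based detection); it is bounded by $[0,1]$.
**Achromatic contrast** is the ratio of green-receptor quantum catches,
sample over background (long-range, brightness-based detection): 1.0 means
equal brightness. The linear catch ratio is used rather than a ratio of
saturating excitations — an excitation ratio is bounded above by
$E_{\max}/E_b < 2$, which cannot express a patch twice as bright as the
background, while measured bright patches routinely are.

Note that chromatic contrast is *not* invariant to flat (wavelength-
independent) scalings of an arbitrary sample: scaling all catches by $c$
moves the excitations nonlinearly. The invariance holds exactly at the
background itself — any flat scaling of the background still maps to the
origin — and that is the property the tests assert.

### Defaults and their rationale

* **Receptor sensitivities.** The peak wavelengths default to an *Apis
  mellifera*-like triple $\lambda_{\max} = \{344, 436, 544\}$ nm, rendered
  with the Govardovskii et al. (2000) A1 visual-pigment template (alpha
  plus beta band), max-normalized. Published sensitivity curves can be
  supplied as CSV spectra to override the template. The beta band drags
  the rendered UV peak 2–3 nm below its nominal $\lambda_{\max}$; this is
  a property of the template, not an error.
* **Illuminant.** The bundled CIE D65 tabulation (300–700 nm at 10 nm,
  energy units) is interpolated to the working grid and converted to
  relative quanta by multiplying by $\lambda$ (`quantal = TRUE`), because
  receptor models are photon-counting. The overall illuminant scale
  cancels in the von Kries normalization, so only the spectral *shape* of
  this conversion matters; a flag disables it for users whose sensitivity
  curves already absorb the conversion.
* **Integration.** Trapezoidal rule on a common 300–700 nm, 1 nm grid.
  Against a 0.1 nm rectangle-rule oracle on smooth spectra the relative
  error is below $10^{-4}$.
* **Background.** The mean of all vegetation spectra, averaged after
  resampling, is the single adapting background; contrasts are computed
  per specimen and aggregated afterwards, which is what gives the
  per-patch standard deviations their meaning.
* **Units.** Reflectance in percent is detected (maximum value above 1.5)
  and converted to proportion; sub-zero instrument noise is clamped to 0
  with a warning; values above the white standard are kept but flagged.

## Field foraging models

The capture area of an orb web is the ellipse-hub formula
$A = \pi (d_v/2)(d_h/2) - \pi (H/2)^2$ (vertical and horizontal diameters,
free-zone height), clamped to zero with a warning when the free zone
exceeds the ellipse. Foraging success — the count of damaged areas in a
web — is modelled per ontogenetic stage with a log-link Poisson GLM on web
height, web inclination, capture area and body size, fitted by IRLS
(`stats::glm`) with a tight convergence tolerance so the score equations
$X^\top(y - \hat\mu) = 0$ hold to numerical precision.

Model reduction is greedy backward selection on AIC: at each step the
single term whose removal lowers AIC the most is dropped, stopping when no
removal lowers AIC. AIC rather than p-value deletion is used deliberately:
AIC retains terms with $|z|$ around 1.4–2 that a $p < 0.05$ rule would
discard, and the reduced models are expected to keep such marginal terms.
Greedy deletion agrees with exhaustive all-subsets AIC minimization on the
simulated fixtures the tests run, but the equivalence is not guaranteed in
general, which is why both are exercised.

Goodness of fit is the variance-function-based coefficient of
determination (Zhang 2017),

$$R^2_V = 1 - \frac{\sum_i (y_i-\hat\mu_i)^2/V(\hat\mu_i)}
                   {\sum_i (y_i-\hat\mu_{0i})^2/V(\hat\mu_{0i})},$$

with $V(\mu)=\mu$ for the Poisson family; the deviance-based
$1 - D/D_0$ is exposed as an alternative (`glm_r2(fit, type =
"deviance")`), since several variants circulate under the same name. A
Pearson dispersion diagnostic is reported but not acted on — the models
stay plain Poisson.

The surrounding report mirrors the study design: a pooled GLM with stage
as the only predictor, a Wilcoxon comparison of body sizes between stages
(the unpaired rank-sum form — the two stages are independent groups of
different sizes, so a signed-rank pairing is not defined), and Pearson
collinearity checks between web height and body size.

## The choice experiment and beta regression

Each tunnel replicate releases about ten bees towards a pair of web
frames; the response is the per-replicate, per-treatment proportion
intercepted, with the replicate's actual release count as denominator.
Proportions can hit 0 or 1, where the beta likelihood is undefined, so the
standard boundary squeeze $y' = (y(n-1) + 0.5)/n$ (with $n$ the total
number of observations) is applied to all values before fitting.

The beta regression parameterizes the beta law by a logit-linked mean
$\mu$ and a single log-parameterized precision $\phi$
($\mathrm{var} = \mu(1-\mu)/(1+\phi)$), and maximizes the likelihood by
BFGS with an analytic gradient, started from least squares on the logit
scale and a method-of-moments $\phi$. Wald $z$ statistics come from the
inverse Hessian at the optimum. The model for the experiment is
`treatment * age`; the headline test is the interaction, and the per-age
treatment effects are computed twice — as linear contrasts of the
interaction fit and by releveled refits — which must agree (they are the
same ML problem under a linear reparameterization). A response with zero
variance (all proportions identical) makes $\phi$ diverge; that case is
caught and returned as a degenerate fit with zero effects and a warning
rather than a runaway optimization. An independently implemented
TMB-based beta fit is used in the test suite as a cross-check of
coefficients and precision.

## What the synthetic generators emulate

The generators stand in for the raw measurements, which are not published
in machine-readable form. They are seeded, and a global seed fans out to
fixed per-generator substreams, so adding a generator never changes the
draws of an existing one.

* **Spectra** (`sim_reflectance`): smooth parametric curves on 300–700 nm
  — vegetation as a Gaussian green peak (~18% at 550 nm on a 5%
  baseline), adult yellow as a sigmoidal long-pass step near 515 nm with
  a slight UV bump at 360 nm, pale red as a low curve rising beyond
  600 nm, black flat at ~3.5%. Amplitudes were fixed once so the patches
  sit where the study places them relative to vegetation: yellow about
  twice as bright to the green receptor, pale red near equal brightness,
  black much darker. Specimen variation is multiplicative log-normal
  jitter on the shape amplitudes.
* **Field data** (`sim_field_data`): 35 juvenile and 28 adult webs by
  default; capture areas and body sizes drawn from truncated normals
  matching the reported summaries (76 ± 42 vs 166 ± 78 cm²; 2.6 ± 0.7 vs
  3.3 ± 1.5 mm); web geometry back-solved so `capture_area(d_v, d_h, H)`
  reproduces the drawn area exactly; counts Poisson with log-linear
  effects (juveniles: web height only; adults: web height, a small
  negative inclination effect, body size). Web heights are not reported
  in the study, so they were chosen once as ~N(160, 50) cm for juveniles
  and ~N(120, 45) cm for adults, consistent with the reported negative
  correlation between body size and web height. The stage intercepts are
  solved so the expected count at the mean predictors matches the
  reported mean damage counts (3.4 and 4.9).
* **Choice trials** (`sim_choice_trials`): 12 replicates per age of 10
  bees (two juvenile replicates of 9), binomial interceptions per
  replicate and treatment with cell probabilities 0.5/0.15 for adults and
  0.3/0.3 for juveniles — an adult spider-web advantage and no juvenile
  effect, which is the designed power scenario the tests verify (the
  interaction and adult contrast significant, the juvenile contrast not,
  in at least 80% of seeds).

What the generators do *not* emulate: measured spectra are noisier and
less smooth than the parametric shapes, so between-specimen spread in
chromatic contrast is smaller here than in real data — in particular, the
dark red and black patches come out with small chromatic SDs and hence
"significant" chromatic t-tests where the study, with real measurement
spread, found none. Passing the simulated pipeline therefore validates the
computations and the study's power structure, not the empirical contrast
values of real spiders; those require the original reflectance
measurements, which can be dropped into `inst/extdata/esm/` if obtained.

## Problem sizes and numerical choices

The simulation-based checks run at the study's own sizes (n = 63 webs,
48 choice trials, 8 specimens per patch): parameter-recovery sweeps use
200 replicates and the power property 100 seeds, which keeps the full
suite in the low minutes on one core while leaving Monte-Carlo error well
inside the asserted margins. Tolerances follow the quantity being checked:
closed-form identities at $10^{-10}$ or tighter, oracle recomputations of
the same mathematics at $10^{-6}$, cross-implementation agreement
(different optimizers) at $10^{-3}$–$10^{-4}$, and integration-rule
agreement (different quadratures) at $10^{-4}$ relative.

## Known limitations

* The exact sensitivity curves behind "standard trichromatic Hymenoptera"
  are a documented stand-in (template at Apis-like peaks); users with the
  species' measured curves should supply them.
* Whether D65 should enter in energy or quantal units is not fully
  settled for every published workflow; both are supported, quantal is
  the default.
* Overdispersion in the damage counts is diagnosed but not modelled.
* The beta regression fits a constant precision; dispersion covariates
  are out of scope.
* The Wilcoxon/collinearity wrappers are thin layers over base R tests
  and inherit their tie-handling behaviour.
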