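---
title: "Corneal raytracing: best focus, power and spherical aberration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal raytracing: best focus, power and spherical aberration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneatrace)
```

## The model

The cornea is treated as a centred, rotationally symmetric optical system of
two refracting interfaces. Each interface is a conic of revolution with
central radius of curvature $R$ (mm) and asphericity $Q$, with sag

$$z - z_0 \;=\; \frac{r^2/R}{1 + \sqrt{1 - (1+Q)\,r^2/R^2}},$$

so that $Q = 0$ is a sphere, $Q < 0$ a prolate ellipsoid (the typical
cornea) and $Q = -e^2$ for eccentricity $e$. The front apex sits at the
origin, the back apex at $z = \mathrm{CCT}$. Refractive indices are the
Liou–Brennan schematic-eye values: stroma 1.376, aqueous humour 1.336.
Because the system is rotationally symmetric and untilted, a meridional
(2D) trace is sufficient: a collimated fan of rays (default 1001) starts on
the plano wavefront at $z = 0$, equally spaced across the pupil projection
onto the front surface, and each ray is refracted by Snell's law at both
interfaces. A meridional ray at height $r$ stands in for an annulus of the
pupil, so rays carry area weights $w \propto |r|$ by default; a
$w \propto r^2$ variant is available (`weighting = "quadratic"`) for
compatibility with pipelines that weight by squared distance. The chief ray
has zero statistical weight but is retained as the axial reference.

## Best focus is not unique

Behind the cornea, four merit functions define four different "best" focal
planes:

* **WFE** — RMS wavefront error: the weighted RMS spread of total optical
  path length from the starting plane to the candidate focus point
  $(0, z)$, after removing the weighted mean (piston). No reference-sphere
  ray re-aiming is performed; at these apertures the OPL-to-point form is
  equivalent to reference-sphere OPD well below the reported precision.
* **RMSS** — RMS transverse ray scatter at the plane.
* **MAS** — mean absolute transverse scatter.
* **TSD** — total spot diameter (max minus min ray height).

Each focal distance $z_F$ converts to corneal power referenced to the front
apex plane as $CP = 1000 \cdot n_{aq}/z_F$ dioptres, and to a per-eye
keratometer index $n_K = 1 + CP \cdot R_f/1000$.

For a cornea with positive spherical aberration, classical primary-SA
theory orders the pupil-limited planes: writing the wavefront as
$W = a\rho^4 + d\rho^2$, the balanced-defocus minimum of the RMS wavefront
sits at $d = -a$, the minimum-RMS-spot plane at $d = -\tfrac{4}{3}a$, the
minimum mean-absolute plane at $d \approx -1.26\,a$ and the disk of least
confusion (TSD) at $d = -\tfrac{3}{2}a$. The package's traced planes
reproduce these ratios.

### The wavefront-criterion zone

Large-cohort raytracing results show the *wavefront* plane shortest of the
four ($z_{WF} < z_{TSD} < z_{RMS} < z_{MA}$), which no pupil-limited
weighting can produce: the required defocus shift is about
$(3\,\mathrm{mm}/2.2\,\mathrm{mm})^2 \approx 1.85$ balanced-defocus units,
exactly the ratio of the fixed 6-mm wavefront-analysis zone to the mean
pupil radius. `find_best_foci()` therefore evaluates the wavefront
criterion on a dedicated fan spanning the fixed 6-mm zone (the same zone
the Zernike fit uses), independent of the individual pupil, and the three
spot criteria on the pupil-limited fan. On the cohort-mean cornea this
yields $z_{WF} = 31.068$ mm ($CP = 43.00$ dpt) and reproduces the cohort
plane ordering including the relative gaps. Setting `wf_zone = NULL`
evaluates the wavefront criterion on the pupil fan instead; in that
configuration all four criteria collapse onto the paraxial focus as the
aperture shrinks, which is how the package's small-aperture consistency
tests are run.

## Numerical choices

* **Ray–conic intersection** is solved as a quadratic in the travel
  parameter in the numerically stable formulation (no cancellation for
  paraxial rays), keeping the smallest non-negative root on the apex
  branch; rays beyond a surface's geometric extent raise a typed miss
  condition, total internal reflection a TIR condition.
* **Focus search**: the preset is the centre of a least-squares circle
  (centre constrained to the axis) through the exit wavefront — exact for a
  stigmatic bundle. The default minimizer is a coarse scan (61 points over
  a ±3 mm bracket) plus Brent refinement to $10^{-7}$ mm; the merit
  functions are unimodal in practice. TSD is only piecewise smooth (a max
  over rays), so its scan uses 1000 points before refinement. A seeded
  simulated-annealing search (`method = "anneal"`, geometric cooling,
  followed by the same local polish) is provided for pipelines that prefer
  a stochastic search; both agree to well below $10^{-4}$ mm.
* **Zernike fit**: weighted least squares of the OSA/ANSI radial
  polynomials $Z_0^0, Z_2^0, Z_4^0, Z_6^0$ on $\rho = r/3$ mm over the 6-mm
  zone (201 rays). $Z_6^0$ is included to stabilize $Z_4^0$ against
  higher-order leakage under discrete weighted sampling; defocus is fitted
  jointly rather than pre-subtracted. The OSA $\sqrt{5}$ normalization is
  assumed — it is the only convention under which typical corneal SA at
  6 mm lands near $+0.1$ to $+0.2\ \mu$m.
* **Keratometer index**: the least-squares fit
  $\min_{n_K}\sum_i (CP_i - 1000(n_K-1)/R_{f,i})^2$ has the closed form
  $n_K = 1 + \sum x_i CP_i / \sum x_i^2$ with $x_i = 1000/R_{f,i}$. A
  `mean_zero` mode instead zeroes the mean deviation $CP - P_K$ exactly,
  matching pipelines that report identically-zero mean deviations; both
  are reported in batch output, least squares being the default.
* **Power models**: the deviation of corneal power from keratometric power
  is fitted by OLS on the six covariates ($R_f, Q_f, R_b, Q_b, CCT, PUP$,
  lengths in mm) with the keratometric offset held fixed. The four
  published coefficient sets are stored verbatim and exposed through
  `evaluate_printed_model()`.

## The synthetic population

No per-eye dataset ships with the package, so population-level behaviour is
exercised on synthetic cohorts drawn by `sample_population()`: truncated
multivariate Gaussians whose marginal means, SDs and truncation bounds are
the published descriptive statistics of a 10,218-eye cataract cohort
(`POPULATION_DEFAULTS`; e.g. $R_f$ 7.733 ± 0.283 mm on [6.770, 8.800]).
Only marginals are published, so the default correlation matrix is the
identity; a literature-style correlation (e.g. $R_f$–$R_b \approx 0.8$) can
be supplied but is a modelling choice, not ground truth.

What this emulates — and what it does not: marginal plausibility of every
generated eye, and the full pipeline's behaviour across the clinically
observed parameter ranges. It does **not** emulate the real cohort's joint
covariate structure. Quantities that depend on that joint structure —
cohort SDs of power deviations, the residual RMS and $R^2$ of refitted
linear models, cohort-mean $n_K$ and $Z_4^0$ — are therefore checked as
properties (bounds), not reproduced numerically. Concretely, on a 2,000-eye
identity-correlation cohort the deviation $CP - P_K$ has SD ≈ 0.50 dpt
(real cohort: 0.17) because independently drawn back radii and
asphericities add variance that the real, strongly correlated anatomy does
not explore; a refitted linear model then leaves ≈ 0.06–0.15 dpt RMS
residual (real cohort: 0.04–0.11), of which almost all is smooth model
nonlinearity (a quadratic expansion reduces it to ≈ 0.03). Similarly the
identity-correlation mean $Z_4^0$ (≈ 0.12 µm) sits below the cohort mean
(0.17 µm). Passing the property suite shows the pipeline is correct over
the plausible range, not that the synthetic cohort is anatomically
faithful.

## Problem sizes and tolerances

Defaults follow the study conditions: 1001 rays across the pupil, 201
across the 6-mm Zernike zone, area-linear weighting, Brent search to
$10^{-7}$ mm. The package's own test suite uses 201–501-ray fans for
property sweeps and a 2,000-eye synthetic cohort for population checks —
sizes chosen so the full population behaviour (keratometer index within
±0.002, model $R^2$, 3-SE marginal agreement) is resolved with comfortable
statistical margin.

## Known limitations

* Astigmatic, toric, biconic or decentred/tilted surfaces are out of scope;
  the model is strictly rotationally symmetric, so odd and non-rotationally
  symmetric Zernike terms are zero by construction.
* Collimated input only (object at infinity); no wavelength dispersion; no
  surfaces beyond the cornea.
* Strehl-ratio or MTF-based focus criteria are not implemented.
* The published models' dispersion statistics on the real cohort cannot be
  reproduced without the unpublished covariate correlations (see above).
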