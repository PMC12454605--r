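---
title: "Modeling aortic aneurysm growth with stress-homeostasis kinematic growth laws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling aortic aneurysm growth with stress-homeostasis kinematic growth laws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselgrow)
```

## The modeling problem

Ascending thoracic aortic aneurysms enlarge through maladaptive growth and
remodeling (G&R): wall stress above its homeostatic level drives tissue
growth, growth enlarges the vessel, and in a diseased wall the enlargement
raises the stress further — a positive feedback loop. `vesselgrow`
implements a desk-scale version of the workflow used to study this loop in
longitudinal rodent imaging: measure the vessel geometry at successive ages,
fit the time constants of a kinematic growth law so that a forward
simulation reproduces the observed change over the first interval, predict
the geometry one interval further, and ask whether the fitted constants
carry prognostic information about the outcome (lifespan).

## The growth model

Growth is anisotropic and kinematic. Each wall element carries a diagonal
growth tensor in its local radial/circumferential/axial frame,

$$ G = \mathrm{diag}(\lambda_{gr},\; \lambda_{g\theta},\; \lambda_{gs}), $$

and the total deformation splits multiplicatively, $F = F^e G$, with $F^e$
the elastic deformation under load. The stretches evolve toward stress
homeostasis:

$$ \dot\lambda_{gr} = \frac{1}{T_r}\Big(\frac{\sigma_{\theta\theta}}{\hat\sigma_{\theta\theta}} - 1\Big)\lambda_{gr}, \qquad
   \dot\lambda_{g\theta} = \Big[\frac{1}{T_\theta}\Big(\frac{\sigma_{\theta\theta}}{\hat\sigma_{\theta\theta}} - 1\Big) + \frac{1}{T_\tau}\Big(\frac{\tau_w}{\hat\tau_w} - 1\Big)\Big]\lambda_{g\theta}, \qquad
   \dot\lambda_{gs} = \frac{1}{T_s}\Big(\frac{\sigma_{ss}}{\hat\sigma_{ss}} - 1\Big)\lambda_{gs}. $$

Hats denote homeostatic targets; $T_r, T_\theta, T_\tau, T_s$ are time
constants in days. At the target stresses all rates vanish exactly — the
homeostatic state is a fixed point (`growth_rates()`). Only $T_\theta$ and
$T_s$ are fitted: radius and length are observable in images, wall
thickness is not, so $T_r$ stays fixed, and because no wall-shear target is
identifiable from geometry alone the shear term defaults to off
($T_\tau = \infty$), configurable when a target is available.

## The hemodynamic surrogate

The wall stresses that drive growth come from a deliberately reduced
hemodynamic model rather than a 3-D fluid–structure simulation:

* **Pressure** from a three-element Windkessel (RCR) per outlet,
  $\dot P_c = (Q - P_c/R_d)/C$, $P = Q R_p + P_c$, integrated with
  `deSolve` to periodic steady state. The period-mean pressure is
  $\bar Q\,(R_p + R_d)$, independent of the compliance — a property the
  tests assert. The four packaged outlet parameter sets reproduce a mean
  aortic pressure of about 90 mmHg under the calibrated mean inflow (the
  inflow is back-computed from that calibration, not measured data). The
  packaged compliances are stored in mm³/Pa, the unit the RCR ordinary
  differential equation requires dimensionally.
* **Wall stress** from thin-wall (Laplace) relations on each ring of the
  vessel: $\sigma_{\theta\theta} = p\,r/h$ and $\sigma_{ss} = p\,r/(2h)$
  for a capped cylinder.
* **Wall shear** from Poiseuille flow, $\tau_w = 4\mu_{\rm eff}Q/(\pi r^3)$,
  with the apparent viscosity from the Carreau–Yasuda shear-thinning law
  evaluated at the wall shear rate. The Carreau–Yasuda constants default to
  standard whole-blood values ($\mu_0 = 0.056$, $\mu_\infty = 0.00345$
  Pa·s, $\lambda = 3.313$ s, $a = 2$, $n = 0.3568$) and are fully
  configurable.
* **Elastic deformation** of the wall from incompressible Neo-Hookean
  membrane inflation with the axial stretch held at one:
  $\mu(\lambda^2 - \lambda^{-2}) = p\lambda^2 R/H$. This has the closed
  form $\lambda = (1 - pR/(\mu H))^{-1/4}$, valid below the limit-point
  pressure $p < \mu H/R$; `membrane_inflation()` solves the residual by
  bracketed root-finding and the closed form serves as its cross-check.
  The compressible Neo-Hookean energy
  $W = \tfrac{\mu}{2}(I_1 - 3) - \mu\ln J + \tfrac{\lambda}{2}(\ln J)^2$
  is implemented for material evaluation, with the Lamé constants from
  $E$ and $\nu$ (default $\nu = 0.44$, nearly incompressible tissue).

This surrogate is the package's central simplification: the growth laws
consume only $(\sigma_{\theta\theta}, \sigma_{ss}, \tau_w)$, and for a
thin-walled, nearly tubular vessel the Laplace relations supply those at a
fraction of the cost of a fluid–structure simulation. What is lost:
secondary flows, spatial wall-shear patterns, residual stresses between
unevenly growing regions, and any circumferential stress variation. The
finite-element equilibrium step of a full implementation is likewise
replaced by a ring-wise kinematic update — unloaded ring radius scales by
the circumferential increment, segment lengths by the mean axial increment
of adjacent stations, thickness by the radial increment — followed by
membrane re-inflation.

## Geometry measurement

The vessel wall is a triangulated surface with two open boundary loops.
Two harmonic (Laplace) coordinates parameterize it, discretized with
cotangent finite-element weights and solved as a sparse Dirichlet problem
(`Matrix`, direct solve): the axial coordinate $s$ with $s = 0$ on the
inlet loop and $s = 1$ on the outlet, and the circumferential coordinate
$\theta$ on the mesh cut open along the shortest inlet-to-outlet path in
the edge graph (`igraph` shortest path — a graph approximation of the
geodesic; the seam only needs topological correctness). Cut vertices are
duplicated into two seam copies carrying Dirichlet data 0 and 1, and
$\theta$ is taken modulo the seam with the periodic distance
$d(\theta_1, \theta_2) = \min(|\Delta|, 1 - |\Delta|)$. On a regular
cylinder both coordinates reproduce their analytic counterparts ($z/L$,
azimuth$/2\pi$) to near machine precision; ties among equidistant
inlet/outlet pairs break to the lowest vertex index, so runs are
deterministic.

Measurements follow a ring protocol: six equally spaced rings along $s$
(configurable), ring radius as the mean distance from ring vertices to
their centroid, segment lengths between consecutive centroids, total
length as their sum. Ring vertices are selected adaptively — the vertex
row nearest each target $s$ plus a 2%-of-spacing tolerance — rather than
by bands tiling the axis: wide bands mix vertices at different axial
positions and inflate the mean point-to-centroid distance by several
percent on an ideal cylinder, while the thin adaptive band keeps the
measured radius within 0.5% of truth. Fixed-width bands remain available
through `band_width` for sensitivity checks. Observations enter the fit as
the $2n-1$ vector of $n$ radii followed by $n-1$ segment lengths, in
absolute millimetres.

## Fitting and validation

Tuning minimizes the chi-square mismatch
$\chi^2 = \sum_i [(X^{\rm obs}_i - X^{\rm pred}_i)/\sigma]^2$ over
$(T_\theta, T_s)$ — or $(T^k_\theta, T^k_s)$ over $K = 4$ equal axial
domains — with a damped least-squares (Levenberg–Marquardt) iteration:
finite-difference Jacobian, damping multiplied by 10 on rejected steps and
divided by 10 on accepted ones, convergence on relative $\chi^2$ change
below 1e-10 or parameter change below 1e-9. Time constants are optimized
in log space, which enforces positivity without constraints. The
measurement scale $\sigma$ defaults to 0.02 mm (imaging-voxel order);
being uniform, it rescales $\chi^2$ without moving the optimum. Initial
guesses default to 200 days for both constants. A forward-model failure
during a trial step (e.g. a parameter proposal that drives the membrane
past its limit point) simply rejects the step and increases the damping.

Validation re-runs the fitted model over the longer horizon and scores
$\Delta r = (r^p - r^m)/r^m$ per ring — averaged over the four interior
rings only, excluding the inlet and outlet rings to avoid
boundary-condition bias — and $\Delta l = (l^p - l^m)/l^m$ over the full
length. The comparison baseline is the linear projection
$x_{t_2} = x_{t_1} + (x_{t_1} - x_{t_0})$ for equally spaced time points;
because stress-feedback growth is convex in time, the projection
systematically under-predicts, and the fitted model beats it on synthetic
exponential-like growth.

Single- versus multi-domain models are compared with the nested F-test on
residual sums of squares. One sampling choice matters here: with the
default six rings the 8-parameter four-domain fit leaves only three
residual degrees of freedom, and an $F(6,3)$ test cannot reach high power
at realistic effect sizes. The multi-domain analyses therefore measure ten
rings (19 observables, 11 residual degrees of freedom); the six-ring
default and the rings-2–5 validation convention are unchanged.

## Outcome statistics

Lifespan in the packaged ten-animal cohort is right-censored: four animals
alive at 25 months were euthanized, so their lifespans are recorded at the
cutoff. The censoring-aware regression is a Tobit model — censored-normal
maximum likelihood with $\log\sigma$ optimized by BFGS from the
least-squares start, standard errors from the inverse observed information
— and goodness of fit is the McKelvey–Zavoina pseudo-$R^2$,
$S/(S + N\sigma^2)$ with $S$ the variance sum of the latent predictions
$X\hat\beta$. Uncensored data reduce the Tobit fit exactly to least
squares with the maximum-likelihood variance; the test suite also
cross-checks the estimates against `survival::survreg`. Pearson
correlations (two-sided p from the t-transform, $n-2$ df) are reported on
the observed values next to the Tobit slopes, with Bonferroni correction
over the number of distinct variable pairs in the displayed map. The
headline covariate is the growth driving force $T_\theta/\bar\sigma_{\theta\theta}$
— the fitted circumferential constant over the time-averaged mean hoop
stress.

## The synthetic cohort: what it does and does not emulate

No raw imaging data accompany the study this package emulates, so the
generator supplies the statistical structure every stage assumes:

* structured triangulated tubes (radius 0.6 mm, length 3 mm, wall
  0.06 mm — murine ascending-aorta scale), optionally bulged (Gaussian
  aneurysm) and bent;
* forward growth under known $(T_\theta, T_s)$ with scan times at 0, 60
  and 120 days (2, 4 and 6 months at the fixed 30 days/month convention);
* independent re-triangulation of later time points and Gaussian surface
  noise of 0.01 mm along vertex normals (segmentation-like error);
* cohorts with log-normal true constants (medians 180 and 360 days,
  sdlog 0.2) and lifespan
  $LS = 13 + 8000\,(T_\theta/\bar\sigma_{\theta\theta}) + \varepsilon$,
  $\varepsilon \sim N(0, 3^2)$ months, censored at 25 months — chosen to
  give roughly the 4/10 censored fraction of the emulated design.

Defaults were set once to land in the observed physiological ranges: with
$T_\theta = 180$ d and targets at 0.8 of the baseline stress state, the
feedback loop produces about 29% radius growth over 120 days, matching the
20–35% range reported for aneurysmal animals; mean pressure is 90 mmHg and
mean flow 114 mm³/s through the packaged outlet resistances.

What passing tests on this generator do **not** show: robustness to real
segmentation artifacts (topological defects, non-axisymmetric noise),
heterogeneous wall thickness, true material anisotropy, branch vessels, or
any biology beyond stress feedback (inflammation, matrix turnover). The
generator's geometries satisfy the model's own assumptions by
construction, so parameter-recovery results quantify the inverse problem's
conditioning, not model adequacy on real vessels.

## Numerical choices and degenerate inputs

* Explicit Euler at $\Delta t = 10$ days matches the loop granularity of
  the emulated workflow; substeps refine the inner ODE where needed.
  Convergence toward the constant-stress closed form
  $\lambda(t) = e^{(\rho - 1)t/T}$ is first order, and 1-day substeps stay
  within 0.1% over 120 days. Positivity of the stretches is checked after
  every step.
* The growth engine discretizes the vessel as 26 axial stations (28 for
  the ten-ring analyses) so that measurement rings coincide with stations;
  element values aggregate to rings by arithmetic means.
* Homeostatic targets default to the element-mean baseline stresses scaled
  by 0.8, making the baseline growth-positive — the aneurysmal regime. A
  scale of 1 reproduces exact homeostasis (constant trajectories), which
  the tests use as a null.
* The membrane model is only valid below its limit point
  $p < \mu H/R$; sustained feedback growth with $T_\theta$ below roughly
  85 days reaches that point within 120 days at the default load, so the
  cohort generator floors sampled constants at 90 days and the engine
  fails loudly rather than returning post-limit geometry.
* Laplace solves use a sparse direct factorization; harmonic fields obey
  the discrete maximum principle on the non-obtuse structured meshes used
  here. Degenerate meshes (closed surfaces, extra boundary loops,
  non-manifold edges) are rejected with structured errors; coincident ring
  centroids produce a warning and a zero segment length.
* Windkessel integration runs 20–40 periods and reports the last-period
  drift; non-stationarity above 0.1% warns rather than fails.

Test and acceptance problem sizes — meshes of 800–1500 vertices, cohorts
of 10–50 subjects, 10–50 Monte-Carlo replicates — were chosen as the
smallest sizes at which each property is sharply distinguishable from its
null; the full suite plus the acceptance script run in a few minutes on
one CPU.

## A minimal run

```{r, eval = FALSE}
ctx  <- hemo_context()                      # 90 mmHg, murine wall
s    <- seq(0, 1, length.out = 26)
R    <- deflate_radii(rep(0.6, 26), ctx$wall$thickness, ctx$mu,
                      ctx$hemo$pressure)
prof <- tube_profile(s, R, rep(3 / 25, 25))
truth  <- default_growth_params(ctx, prof)
series <- generate_longitudinal_geometries(tube_spec(), truth, seed = 1)
tuned  <- run_tuning(series$meshes[[1]], series$meshes[[2]], run_config())
report <- run_validation(series$meshes[[3]], tuned, run_config())
tuned$fit; report$mean_delta_r
```

## Known limitations

Uniform wall thickness and isotropic elasticity; no residual stress
between unevenly growing regions (the ring-wise update cannot represent
it); no wall-shear-driven term unless a shear target is supplied; no
branched topologies in the parameterization; lifespans and growth
constants in the synthetic cohort are linked by a deliberately simple
linear model. The ten-animal fixture is far too small for sex-stratified
or multivariable outcome models, and the package does not attempt them.
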