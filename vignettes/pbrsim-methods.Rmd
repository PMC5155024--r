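---
title: "Modelling flat-panel photobioreactor production with pbrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flat-panel photobioreactor production with pbrsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrsim)
```

## The problem

Industrial microalgal production in arrays of vertical flat-panel
photobioreactors couples two very different pieces of physics and biology:
a light field that varies with latitude, season, time of day, atmospheric
clearness and panel-to-panel shading, and a cell physiology whose elemental
composition (C:N:P:Chl) acclimates to that light field and to the nutrient
supply on time scales of hours to days. `pbrsim` implements a deliberately
inexpensive irradiance description coupled to an acclimative,
variable-stoichiometry growth model, and uses the pair to project annual
volumetric biomass production (VP, mg C L⁻¹ d⁻¹) and areal production of
C-rich storage feedstock (AXP, g C m⁻² d⁻¹) under different
harvest/dilution strategies.

## Irradiance

Overhead photon flux density follows the solar cycle

$$E_0 = \mathrm{SC}\,(\sin\varphi\sin\delta - \cos\varphi\cos\delta\cos\theta)\,\Lambda,$$

with latitude $\varphi$, solar declination $\delta$, diel angle $\theta$
and a monthly clearness index $\Lambda$ that absorbs atmospheric
transmission. Conventions the package fixes where the formulation leaves
them open:

* **Declination**: the Cooper-style approximation
  $\delta = -23.45^\circ \cos(2\pi(d + 10)/365)$ on a 365-day calendar.
  Leap days are ignored; monthly averages are insensitive to them.
* **Diel angle**: $\theta = 2\pi\,\mathrm{hour}/24$ with the hour counted
  from local solar midnight, the only convention that makes the expression
  peak at solar noon.
* **Night**: the expression goes negative below the horizon and is clamped
  to zero.
* **Units**: SC is expressed directly as a PAR photon flux
  (2500 µmol photons m⁻² s⁻¹ by default). Only the product
  $\mathrm{SC}\cdot\Lambda\cdot\alpha$ is identified by production data, so
  any spectral or W-to-photon conversion is absorbed into calibration.

A point a depth $z$ below the top of a panel sees a wedge of sky of angle
$\beta(z) = 2\tan^{-1}(s/2z)$ between its neighbours, so
$E(z) = E_0\,\beta(z)/\pi$, and the height average over the panel face has
the closed form implemented in `panel_shading_ratio()`. The average depends
only on $s/h$; for the default geometry (0.05 × 0.28 × 17.3 m panels,
0.15 m apart) it is 0.397. The closed form is verified against adaptive
quadrature of $E(z)$ in the test-suite. Diffuse/direct splitting,
refraction, reflection and light transmitted through neighbouring panels
are deliberately out of scope: for a dense industrial array the
visible-sky fraction dominates.

## Depth-integrated photosynthesis

Within the culture, light decays as $E(z) = \bar E_0 e^{-kz}$ with
$k = k_{bg} + k_{chl}[\mathrm{Chl}]$ (defaults $k_{bg} = 0.1$ m⁻¹,
$k_{chl} = 0.012$ m² (mg Chl)⁻¹, mid-range of published Chl-specific
attenuation). The local C-specific photosynthesis rate follows the Smith
saturating curve, and averaging it over the optical half-depth $\tau$
(half the panel width — both faces are lit) gives

$$\mathrm{PS} = \frac{P_{qm}}{k\tau}\left[\mathrm{asinh}(x) -
\mathrm{asinh}\!\left(x e^{-k\tau}\right)\right],
\qquad x = \frac{\bar E_0\,\alpha\,\mathrm{ChlC}}{P_{qm}}.$$

Numerical choices: the $\mathrm{asinh}$ primitive avoids cancellation of
$\log(y + \sqrt{1+y^2})$ at small $y$; below $k\tau = 10^{-7}$ the
analytic optically-thin limit $P_{qm}\,x/\sqrt{1+x^2}$ is used, and the
switchover is continuous to $10^{-6}$ relative. The ceiling is closed
against growth: $P_{qm} = (\mu_m + R_{basal})/(1-\zeta)$, recomputed each
step as $\mu_m$ tracks the season, so that fully light-saturated
photosynthesis net of respiration supports exactly $\mu_m$. Respiration is
the standard basal-plus-cost-of-growth decomposition
$R = R_{basal} + \zeta\,\mathrm{PS}$ with $R_{basal} = 0.03$ d⁻¹ and
$\zeta = 0.2$; these forms are calibratable defaults, not measurements.

## Cell physiology

The state of the culture is its C-biomass concentration, its N:C and P:C
quotas, its Chl:C ratio, the dissolved pools (nitrate, ammonium,
phosphate, DIC), and the cumulative harvest ledgers. Four nested
stoichiometric descriptions share this state:

* **CNPCHL** (default): quota-regulated growth on N and P with dynamic
  photoacclimative Chl:C.
* **CNCHL**: P held replete; **CN**: additionally constant Chl:C;
* **FIXED**: Redfield mass ratios (N:C 0.176, P:C 0.024), constant Chl:C
  and a constant storage fraction. This description carries *no*
  nutrient-status feedback on growth: pools are debited for bookkeeping
  and any shortfall is met by an implicit make-up supply recorded in the
  accounting. That naivety is the point of the variant — it is the
  strawman whose production projections overshoot whenever the real
  system is nutrient-constrained.

Growth combines limitations by a threshold (Liebig) law,
$\mu = \min(\mathrm{PS} - R,\ \mu_m f_N,\ \mu_m f_P)$, consistent with the
framing of light/nutrient co-limitation in this model family; a
multiplicative law would double-penalise co-limited states. The quota
limitation factors use the normalised curve
$f = (1+k_q)\,q_n/(q_n + k_q)$ with $q_n$ the 0–1 normalised quota.
The curvature default `kq_n` = 2 gives a
gradual, luxury-consumption-style response in which growth slows well
before the quota reaches subsistence; a smaller curvature (a near-step
response) makes nutrient history almost invisible in realised growth,
which in turn makes the fixed-stoichiometry strawman almost as good as the
acclimative model — contrary to how such systems behave. Uptake is
Michaelis–Menten in the substrate with a linear quota-feedback shutdown,
and ammonium is consumed before nitrate (the shipped runs use nitrate-only
f/2-style medium, so that path is exercised only in tests).
Chl:C relaxes first-order (rate 1 d⁻¹) towards
$\mathrm{ChlC}_m f_N (1 - \mathrm{PS}/P_{qm})$, i.e. pigment is built
under light limitation when N allows and shed under saturation or
N-stress, clipped to [0.002, ChlC$_m$] with ChlC$_m$ = 0.033 g Chl g C⁻¹.
The C-storage fraction of biomass (carbohydrate + lipid, the feedstock
proxy) has a linear, monotone-decreasing *target* in the N:C quota between
its replete and exhausted endpoints; the realised fraction relaxes towards
that target first-order (`rho_cexc`, fitted ≈ 0.37 d⁻¹, a storage turnover
time of a few days). An instantaneous composition map would convert
biomass to storage as fast as the quota moves, producing storage-production
spikes within long harvest cycles that have no physiological counterpart;
the finite build/burn rate is both more realistic and what the
harvest-interval comparison requires.

DIC is treated as non-limiting (an aerated reservoir, debited for
bookkeeping only). The integration is forward Euler at 11.25-minute steps
— the natural scheme for this system-dynamics model family — with a
classical RK4 reference mode used in the tests; at the production step
size the two agree to about 1% on annual mean VP. The Euler update is
written conservatively (cellular element pools advanced as extensive
quantities), so dissolved + cellular N and P balance to rounding error
over arbitrary runs, and the C ledger (fixed − respired − standing change
− harvested) closes identically.

## Reactor operation

Temperature enters only through a sinusoid in $\mu_m$ between the
mid-winter (1.04 d⁻¹) and mid-summer (1.5 d⁻¹) endpoints; over a ~5 °C
seasonal swing this is a Q10 of roughly 2, and no explicit temperature
state is carried — there is rarely enough data to support more. Harvests
fire at local midnight every 1, 4 or 7 days (any interval ≥ 1 d is
allowed): a fraction `dil` of the culture is replaced with fresh medium
(61.6 mg N L⁻¹, 5.5 mg P L⁻¹ — five-fold-enriched f/2), crediting the
harvest ledger and never drawing the biomass below a 10 g C m⁻³ inoculum
floor (slow-growing winter cultures must not wash out). A continuous
dilution mode supports chemostat-style validation: at steady state under
constant light the realised growth rate equals the imposed dilution rate,
the classical quota-model property asserted in the tests.

Production accounting reports VP from the harvest ledger per culture
volume and AXP (harvested storage C) per ground footprint. The footprint
convention is ground area per panel $(w + s)L$, giving a volume-to-area
factor $wh/(w+s) = 0.07$ m for the default geometry; the areal basis of
legacy data sets is rarely stated, so this choice is flagged in the run
metadata. Peak VP/AXP are the maxima of the daily production series
(standing-stock change plus harvests, per day); with daily harvesting this
is the harvest yield series, while longer intervals superimpose the
within-cycle boom (post-refill growth spree) and bust (N exhaustion) on
the seasonal cycle — which is why weekly harvesting shows a much larger
peak-to-mean ratio at essentially the same annual total.

## Calibration and fitted defaults

Several operating inputs of the reference scenario are not observable from
published information: the monthly clearness calendar, the photosynthetic
efficiency α (which absorbs unit conversions), the per-strategy dilution
fractions, and the storage-curve endpoints. These were fitted with the
package's own `random_search()` — a seedable (1+1)-style adaptive random
search with uniform restarts, chosen because any bounded derivative-free
method satisfying a monotone-running-best contract suffices here — against
the reference annual statistics, and shipped as documented defaults:

* clearness calendar: $0.8 - 0.1(1 - \cos(2\pi(m-1)/12))$, clearest
  mid-winter (0.80), cloudiest mid-summer (0.60), inside the plausible
  0.55–0.8 envelope for a high-plains site;
* `alpha` = 0.47 (with `kq_n` = 2 quota curvature);
* dilution fractions 0.095, 0.31 and 0.52 for 1-, 4- and 7-day harvesting;
* storage endpoints (0.26, 0.40) with relaxation rate 0.37 d⁻¹, placing
  the annual harvested storage near one-third of biomass carbon.

These are *fitted* quantities; none is a measurement. The operating regime
they imply is scientifically coherent: winters are light-limited with
N-replete, pigment-rich cells; summers are nitrogen-budget-limited with
the quota pressed towards subsistence and the storage fraction near its
ceiling — the classical N-starvation route to lipid-rich biomass.

## The synthetic fixtures

`make_reference_fixtures()` generates everything the test-suite needs at
run time: a clearness calendar drawn uniformly in 0.55–0.8, the implied
monthly irradiance targets, a 10-day fast configuration (1,280 steps), and
monthly VP/AXP targets from a known 31-day run. These emulate the *shape*
of monthly-averaged facility data (a single deterministic monthly mean per
quantity) but none of its noise structure: no measurement error, no
weather anomalies, no strain drift, no within-month data gaps. Passing the
parameter-recovery tests therefore demonstrates that the estimation
machinery is consistent — not that field data of realistic noisiness would
constrain every parameter equally well.

## Problem sizes used by the checks

The acceptance analysis runs three 1-year simulations (46,720 steps each)
plus four 1-year variant runs and one year-long conservation run; the
unit tests use 5–60-day runs, a 2,000-iteration clearness recovery (cheap,
the irradiance model is linear in Λ) and a ~120-iteration two-parameter
production recovery on a 10-day run. A 1-year run takes a couple of
seconds in plain R; nothing here needs compiled code.

## Known limitations

* The irradiance model ignores azimuthal geometry, diffuse/direct split
  and inter-panel transmission; it is a monthly-average instrument, not a
  clear-sky model.
* The Beer–Lambert + Smith description excludes photoinhibition and
  spectral effects.
* The quota model's uptake-regulation, respiration and Chl-synthesis
  closures are representative of the acclimative model family, with
  defaults declared as calibratable; they are not a transcription of any
  specific strain's physiology.
* Harvest timing is fixed at midnight; sub-daily harvest scheduling and
  flow/mixing heterogeneity are out of scope (the well-mixed assumption is
  good for thin panels at industrial flow rates).
* A single aggregate storage pool stands in for carbohydrate and lipid
  classes.

## A worked example

```{r example, eval = FALSE}
cfg <- load_config(system.file("extdata", "fort_collins.yaml",
                               package = "pbrsim"))
sim <- run_simulation(cfg)
glance(sim)
monthly_summary(sim)
autoplot(sim)
```
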