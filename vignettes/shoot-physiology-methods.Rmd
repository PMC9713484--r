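---
title: "Methods: coupled leaf gas exchange, energy balance and carbon budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled leaf gas exchange, energy balance and carbon budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shootphys)
```

`shootphys` is a standalone shoot-physiology engine of the kind embedded in
functional-structural plant/soil simulators: it predicts leaf- and
canopy-level photosynthesis, stomatal behaviour, leaf temperature,
transpiration and whole-plant carbon dynamics from weather forcing and a
collar-water-potential drought signal, without requiring a root
architecture or soil water model. This vignette explains the science in
the package, the numerical choices, and the boundaries of what its tests
demonstrate.

## The leaf model

### Photosynthesis

Assimilation follows the Farquhar–von Caemmerer–Berry (FvCB) family. For
C3 leaves the realised rate is the minimum of the RuBisCo-limited rate

$$A_c = \frac{V_{cmax}(C_m - \Gamma^*)}{C_m + K_C(1 + O_m/K_O)}$$

and the electron-transport-limited rate
$A_j = (C_m-\Gamma^*)\,J/(4C_m + 8\Gamma^*)$, with the potential electron
transport rate $J$ the smaller root of a non-rectangular hyperbola in the
absorbed photosystem-II light $I_2 = \beta I_s \alpha (1-f)/2$. Phosphate
limitation is assumed absent. For C4 leaves the analogous rates act on
bundle-sheath concentrations $C_s, O_s$, with $\gamma^* = 0.5/S_{c/o}$ (half
the reciprocal RuBisCo specificity) defining the bundle-sheath compensation
term, and PEP carboxylation
$V_p = \min\{C_m V_{pmax}/(C_m + K_P),\, V_{pr}\}$ pumping CO2 from
mesophyll to bundle sheath.

The returned `A` excludes dark respiration; wherever a net flux is needed
the model uses $A - R_d$. For the C4 reservoir equations the bundle-sheath
assimilation term ("not including dark respiration") is taken equal to
this `A`, so that whole-leaf net uptake is $A - (R_m + R_s) = A - R_d$,
exactly parallel to the C3 form. The mesophyll and bundle-sheath
respiration rates default to an even split of dark respiration
($R_m = R_s = R_d/2$, the convention of the C4 source model), as the
published constant set only fixes $R_{d,25} = 1.95\ \mu mol\,m^{-2}s^{-1}$.

### Gas concentrations

Leaf-interior gas pools equilibrate within a minute, far faster than any
simulation timestep, so their dynamics are collapsed to quasi-steady
state. For C3, $C_m = C_A - 1.6 (A - R_d)/g_w$ and
$O_m = O_A + 1.25 (A - R_d)/g_w$; the 1.6 and 1.25 are the diffusivity
ratios of water to CO2 and O2. For C4 the mesophyll and bundle sheath are
connected reservoirs; their four balance equations are linear in the four
concentrations and are solved as two $2\times 2$ systems (CO2 side, O2
side; the bundle-sheath O2 conductance is $0.047\,g_s$). Tests verify that
every steady state zeroes the balance equations to $10^{-9}$ and agrees
with numerically integrating the full reservoir dynamics to equilibrium.

### Stomatal conductance and drought

Stomata follow a vapour-pressure-deficit variant of the Ball–Berry model,

$$g_w = m\,S_w(\Psi_c)\,\frac{A - R_d}{C_A - \Gamma}
        \left(1 + \frac{VPD}{VPD_{ref}}\right)^{-1} + g_{w0},$$

floored at the residual conductance $g_{w0}$ — full stress, darkness or
net carbon loss closes stomata only to the residual. $VPD_{ref}$ is stored
in kPa (10 kPa by default) and `VPD` must be supplied in kPa, so the ratio
is dimensionless; 10 kPa is the magnitude typical of the Leuning
formulation this slope calibration comes from. Drought enters through
$S_w \in [0,1]$, a piecewise-linear function of the collar water potential
$\Psi_c$ (hPa): 1 above $-3000$, declining to 0.4 at $-8000$, to 0 at
$-12000$ and 0 below. The collar potential is an exogenous forcing here —
in a full root/soil simulator it would come from the root hydraulic
network — and the curve type accepts arbitrary user-defined breakpoints.
The stress factor also optionally scales growth demand
(`growth_config(growth_stress = TRUE)`); no other stress transfer is
implemented because none is specified beyond stomatal closure.

The compensation point with dark respiration, $\Gamma$, uses the standard
C3 closed form. The C4 forms (bundle-sheath compensation point with a
$1 + R_d/V_{cmax}$ denominator, and
$\Gamma = (K_P/V_{pmax})(g_s\Gamma_s - R_m)$) are implemented exactly as
stated in the C4 source model even though the denominator's sign differs
from the C3 analogue and the leaf-level form can go slightly negative with
the default constants; both are isolated in `compensation_points()` so a
corrected rendering can be swapped in if the printed forms prove
typographic.

### Temperature responses

Kinetic constants and capacities scale from their 25 °C values with either
a simple Arrhenius form or, for $J_{max}$, $V_{pmax}$ and $g_s$, a peaked
Arrhenius form with deactivation energy $D$ and entropy factor $S$. Both
forms return exactly the 25 °C value at 298.15 K; the peaked form has a
single interior optimum over the physiological range (verified by grid
search in tests). Temperature dependence is modelled for $\Gamma^*$,
$K_C$, $K_O$, $K_P$, $R_d$, $R_m$, $R_s$, $0.5/S_{c/o}$ and $V_{cmax}$
(simple form) and the three capacities above (peaked form).

Unit conventions, fixed at entry to avoid silent $10^3$ errors: all gas
concentrations are carried internally in µmol/mol; the oxygen-side inputs
$O_A$ and $K_{O,25}$ are specified in mmol/mol (their published
convention) and converted once. Leaf thickness is stored in metres (the
constant table prints 0.1 cm) because the flux-to-concentration conversion
divides by it in SI units.

### Leaf temperature

The leaf energy balance sums absorbed solar radiation $\alpha I$ (the
surround-reflection fraction is zero by a symmetry argument between
neighbouring leaves), infrared absorption
$\alpha_{IR}\sigma(T_{surr}^4 + T_{sky}^4)$ with $T_{surr} = T_a$ and
$T_{sky} = T_a - 40$ K, infrared emission $2\alpha_{IR}\sigma T_L^4$,
boundary-layer conduction $2 K_{air}(T_a)(T_L - T_a)/\delta_{bl}$, and
latent heat $J_v H_{vap}(T_a)$; the factors of two account for the two
leaf faces, and the metabolic terms (a few W/m²) are omitted. The
boundary-layer thickness uses the laminar flat-plate scaling
$\delta_{bl} = 10.97\sqrt{d\,\nu(T_a)/v}$ — the square root is the only
dimensionally consistent reading of the source expression, and the
coefficient is configurable. The balance is a quartic in $T_L$, strictly
decreasing over the physical range; it is solved by Newton–Raphson from
$T_L = T_a$ with an analytic derivative and a guarded bisection fallback
on a ±50 K bracket, to $|E| < 10^{-6}$ W/m².

Two auxiliary linear fits deserve a caution. As printed, the kinematic
viscosity slope (0.09 per K, in $10^{-5}$ m²/s) gives
$\nu(25\,°C) \approx 3.7\times10^{-5}$ m²/s, about 2.3× the physical
value, and the latent-heat slope (425 J/mol/K) gives
$H_{vap}(25\,°C) = 34{,}435$ J/mol versus the physical ≈ 44,000. Both are
implemented as printed — they are part of the model definition — and both
coefficients are exposed in `leaf_params()` for users who prefer physical
values. Transpiration itself is computed from the leaf-to-air vapour
gradient, $J_v = g_w (e_{sat}(T_L) - e_{air})/P$ with the Tetens
saturation formula, a deliberately simple stand-in for the root hydraulic
supply that the full simulator would provide.

## The coupled solver

Assimilation, gas concentrations, conductance, transpiration and leaf
temperature form a fixed-point system $x_i = F_i(x)$. `nested_root_find()`
implements a nested Newton–Raphson scheme that never assembles the full
system: variable 1 is outermost; every Newton iteration on $x_i$ first
re-solves all inner variables, so residuals are always evaluated on an
inner-consistent state. Design choices where the scheme's description
leaves freedom:

* **Derivatives** are central finite differences with relative step
  $10^{-6}$.
* **Steps** are guarded: a Newton step is accepted only if it reduces the
  residual magnitude, with up to five backtracking halvings, then a damped
  substitution step; if a level stalls (the assimilation law has
  near-vertical stretches under severe drought, and `min()` kinks at the
  carbon/light crossover and the PEP regeneration cap), the solver hunts
  outward for a sign change and bisects. A global evaluation budget bounds
  worst-case cost.
* **Tolerances** default to $10^{-6}$ in each variable's native units at
  the outermost level, with inner levels solved three and two orders
  tighter ($10^{-9}$ for $g_w$, $10^{-8}$ for $A$): inner solution noise
  must sit below the outer tolerance or the outer residual becomes
  unresolvable.
* **Iteration cap**: 40 Newton steps per level, interpreted from the
  scheme's "40 steps"; on failure the previous timestep's state (or the
  night state on the first step) is returned flagged `converged = FALSE`.
* **Ordering** for the leaf system is leaf temperature outermost, then
  stomatal conductance, then assimilation — slowest feedback outermost.
  The gas concentrations are *not* nested variables: given
  $(T_L, g_w, A)$ they are linear and are solved exactly inside the
  assimilation update. Nesting them as Newton levels would multiply the
  cost by orders of magnitude (the scheme's cost is exponential in
  nesting depth) without changing the solution; tests confirm the
  converged state zeroes every balance equation simultaneously.
* **Physical clamps**: within update maps, transient iterates are clamped
  to $g_w \ge g_{w0}$, $T_L \in T_a \pm 60$ K, and non-negative gas
  concentrations. The clamps matter: without them the rational FvCB forms
  admit spurious fixed points with negative $C_m$ (for example, an
  apparently assimilating leaf behind closed stomata), which a naive
  iteration can reach.
* **Pre-iteration and branch selection**: the coupled stomatal/energy
  system can be bistable under strong radiative load (an open-stomata,
  evaporatively cooled state and a closed-stomata, hot-leaf state can both
  satisfy every equation). Before Newton polishing, the solver follows the
  damped fixed-point flow from its starting state (a diagonally damped
  substitution sweep, per-variable damping from the local slope), so it
  converges to the branch continuous with that state — the night state on
  a cold start, the previous timestep's state in time stepping. The whole
  scheme is fully deterministic.

The solver is validated against an independent damped simultaneous
iteration built from the public module functions (not the solver's
internal fast path): on randomized environments spanning 278–318 K,
0–1000 W/m², 0.1–4 kPa VPD, 0.3–8 m/s wind and the full stress range, both
routes agree to $10^{-4}$ (relative, floored at each variable's unit
scale) in $A$, $g_w$ and $T_L$.

## Canopy scaling

The canopy is split into sunlit and shaded fractions (two-big-leaf):
black-leaf beam extinction $k_b = 0.5/\cos\theta_z$ for a spherical
leaf-angle distribution, $LAI_{sun} = (1 - e^{-k_b\,LAI})/k_b$. Sunlit
leaves receive the projected beam ($k_b I_{beam}$ per unit leaf area) plus
the per-leaf-area share of intercepted diffuse light (extinction
$k_d = 0.7$); shaded leaves receive only the diffuse share. The full
coupled leaf model is solved separately for each fraction and
area-weighted. The source model defers its radiation equations to cited
literature, so the canonical formulations above were adopted; all canopy
tests are property-based (leaf-area conservation, energy conservation,
bounds between the all-sunlit and all-shaded big-leaf limits, sunlit
leaves at least as warm as shaded). The beam/diffuse split is not
specified either; clear skies default to 15% diffuse, configurable.

Solar geometry uses the standard declination approximation
($23.45°\sin(2\pi(284 + doy)/365)$), the hour-angle zenith construction,
and day length $\tfrac{2}{15}\arccos(-\tan\phi\tan\delta)$ in hours.
Clear-sky irradiance is the solar constant scaled by orbital eccentricity
and $\tau^{1/\cos\theta_z}$ attenuation.

## Nitrogen limitation

Leaf nitrogen content follows a three-branch piecewise map of whole-plant
nitrogen between organ-level minimum and optimum contents, continuous at
both breakpoints. Photosynthetic capacities are proportional to leaf
nitrogen concentration: $J_{max} = n_1 N_{leaf}$,
$V_{cmax} = n_2 N_{leaf}$. The proportionality constants are not published
in the source constant set; the defaults are calibrated by an identity — a
reference leaf nitrogen concentration of 2 g N/m² (a typical well-fertilised
maize upper-canopy value) reproduces the default 25 °C capacities —
so that nitrogen-replete runs are exactly the unlimited model.

## Carbon reserves and the diurnal driver

Available carbon $C_a$ (canopy photosynthesis plus, initially, the seed)
pays costs $C_c$ first, then growth demand $C_g$; the remainder flows to
the starch reserve pool $C_p$ at rate $C_r = C_a - C_c - C_g$. Under
deficit, remobilisation ($C_r < 0$) is capped: **at night** the cap is set
at dusk so at most 95% of dusk reserves are consumed over the night
($C_r \ge -0.95 C_p^{dusk}/t_n$); **during the day** at most half the
current reserves per day ($C_r \ge -C_p/2$). The night rule supersedes the
daily half-rule at night: the two caps cannot bind simultaneously, since
for any night shorter than 1.9 days the half-rule would make the 95%
night rule unreachable, contradicting its stated purpose. A daytime
hoarding rule protects the coming night: if projected sunset reserves fall
below 110% of the estimated night need $C_{cN}$, the reserve flux is
raised to $\min\{C_a - C_c,\ (1.1 C_{cN} - C_p)/t_s\}$ at the expense of
growth. $C_{cN}$ is estimated as the current maintenance rate times the
night duration (the source leaves its estimator unspecified). Realised
growth is $C_h = C_a - C_c - C_r$, clamped to $[0, C_g]$, and the identity
$C_a - C_c - C_r - C_h = 0$ holds exactly at every step, which is what
makes the simulation's cumulative carbon balance close to $10^{-8}$ g by
construction rather than approximately.

The diurnal driver (`simulate_growth()`) steps at 0.1 d through a weather
table: solar state, canopy assimilation in daylight (zero at night),
carbon accounting, reserve allocation, growth. Because the engine has no
organ-level growth model, potential growth demand follows a logistic
schedule in structural carbon (relative growth rate 0.18 /d, ceiling 80 g
C — early-vegetative maize magnitudes), maintenance costs 0.015 g C per g
C per day, a fixed 35% of realised growth goes to roots, and leaf area
derives from shoot carbon through a constant specific leaf area (0.055 m²
per g leaf C, i.e. ≈25 m²/kg dry mass at 45% carbon) at a planting
density of 8 plants/m². The seed is modelled as an initial reserve
endowment (0.15 g C). The characteristic leaf length for the boundary
layer is 0.05 m, a maize leaf-width scale; it is absent from the published
constant table.

The synthetic weather generator produces a sinusoidal diurnal temperature
cycle (coolest 02:00, warmest 14:00, range exactly the configured mean ±
amplitude), clear-sky irradiance from the solar model, VPD tracking
temperature, and optional seeded day-to-day noise on wind and VPD. The
terminal-drought schedule holds the collar potential at a well-watered
value until onset (day 21 by default in the examples, matching a
mid-vegetative drought) and declines linearly thereafter. What the
generator does *not* emulate: weather fronts, cloud variability, rain
events, correlated humidity, or any feedback of the plant on its
microclimate — so passing tests demonstrate internal consistency and
qualitative drought behaviour, not predictive skill against field data.
The headline field-scale results of the source study (shoot dry weights
across pedoclimatic environments, rooting-depth distributions) require
the full 3D root architecture, soil water transport and measured
soil/weather data, and are out of scope here by design.

Simulation sizes in the test suite — a 42-day run at 0.1 d steps for the
budget-conservation check, 100 randomized environments for the solver
cross-check, 50 draws for the steady-state suite — were chosen to exercise
every regime (day/night transitions, drought onset, carbon deficit) while
keeping the whole suite comfortably runnable on a laptop.

## Phene-interaction statistic

For root-phenotype screens, the additive null model predicts the response
of a phene combination as the reference phenotype's mean plus the sum of
single-phene deltas (each single-phene mean minus the reference mean). The
variance of the expectation sums the variances of its summands — each
delta contributes $\mathrm{var}(single) + \mathrm{var}(ref)$ and the
baseline adds one more $\mathrm{var}(ref)$, so for $k$ phenes
$\mathrm{var} = \sum_i \mathrm{var}(single_i) + (k{+}1)\mathrm{var}(ref)$ —
and the standard error divides by the replicate count (5 in the source
simulations). The interaction percent is
$100(actual - expected)/expected$; the synergistic/antagonistic label is
gated by a two-sided z-comparison at $\alpha = 0.05$ on the propagated
standard errors. The gate is declared rather than inherited: the source
marks significant cases without naming its test, so a z-comparison on the
stated SEs is the package's own choice, with the threshold configurable.
On synthetic data with truly additive effects the estimated interaction
shrinks to zero as replicates grow (parameter recovery), and the
deep-carbon accounting (0.3 g C per plant at 8 plants/m² → 24 kg C and 88
kg CO2 per hectare) is exact arithmetic.

## Worked example

```{r example, eval = FALSE}
params <- leaf_params("C4")

# a single leaf in bright, mildly dry air
st <- solve_leaf_state(params, T_a = 298.15, I_s = 500, VPD = 1.5, v = 2,
  S_w = 1)
tidy(st)

# six weeks of growth with a terminal drought from day 21
weather <- synthetic_weather(n_days = 42, timestep = 0.1)
drought <- terminal_drought_schedule(onset_day = 21, end_psi = -15000,
  n_days = 42)
sim <- simulate_growth(weather, params, drought = drought)
glance(sim)
autoplot(sim)
```

## Known limitations

* The collar potential is exogenous: there is no feedback from
  transpiration demand to water supply, so the drought response is as
  steep as its schedule.
* The printed viscosity and latent-heat fits are physically off by about a
  factor of two (see above); leaf-air temperature differences and
  transpirational cooling inherit that bias unless the coefficients are
  overridden.
* The C4 leaf-level compensation point can be slightly negative with the
  default constants; it only enters through $C_A - \Gamma$, where the
  effect is sub-percent.
* Growth, allocation and leaf area are deliberately coarse scalar models;
  they close the carbon budget but do not resolve organs or phenology.
* Nitrogen limitation is available as an explicit capacity map but the
  diurnal driver runs nitrogen-replete by default.
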