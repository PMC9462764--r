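---
title: "A multiscale model of desquamation in the interfollicular epidermis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of desquamation in the interfollicular epidermis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episkin)
```

## The model

Desquamation — the shedding of dead corneocytes from the skin surface — is
driven by enzymatic degradation of the corneodesmosomes (CNDs) that hold
stratum-corneum cells together. Kallikrein proteases (KLKs) cleave CNDs; the
inhibitor LEKTI binds KLK and blocks the reaction; and the vertical pH
gradient of the corneum tunes both the KLK–LEKTI association and
dissociation. `episkin` couples a per-cell mass-action model of this
chemistry to a three-dimensional overlapping-spheres (cell-centre) model of
the epidermis in which degraded adhesion plus a vertical removal force
produces cell loss, closing the proliferation–desquamation balance that sets
tissue thickness.

### Subcellular chemistry

Within each cell the competitive-inhibition scheme

$$E + S \underset{k_{-1}}{\overset{k_{+1}}{\rightleftharpoons}} C_S
  \overset{k_2}{\rightarrow} E + P, \qquad
  E + I \underset{k_{-3}}{\overset{k_{+3}}{\rightleftharpoons}} C_I$$

is nondimensionalised with $s = [S]/s_0$, $i = [I]/s_0$, $p = [P]/s_0$,
$e = [E]/e_T$, $c_s = [C_S]/e_T$, $c_i = [C_I]/e_T$, giving six mass-action
ODEs with three exact linear invariants (enzyme, substrate and inhibitor
totals). The KLK–LEKTI rates depend on local pH:

$$k_{+3}(\mathrm{pH}) = (5.2\,\mathrm{pH} - 19.5)\times 10^7
  \ \mathrm{M^{-1}h^{-1}}, \qquad
  k_{-3}(\mathrm{pH}) = 2.3\times10^6 e^{-3\,\mathrm{pH}}\ \mathrm{h^{-1}},$$

and the pH follows a cubic fit over the normalised corneum height
$\xi \in [0,1]$:
$\mathrm{pH}(\xi) = 6.8482 - 0.3765\xi - 5.1663\xi^2 + 3.1792\xi^3$
(neutral at the corneum base, acidic at the surface). Deep in the corneum
nearly all enzyme is held in the KLK–LEKTI complex; as the cell rises, the
falling pH shifts the balance toward free enzyme and CND degradation
accelerates. `k_minus1 = 0` is used throughout (the Michaelis constant
$K_M = (k_{-1}+k_2)/k_{+1} = 4.60\times10^{-5}$ M then fixes $k_{+1}$ given
$k_2$); it remains configurable.

### Initial conditions and stiffness

On corneum entry, $s = 1$ and all inhibitor is taken to be pre-bound
($c_i = i_T/e_T$, $i = 0$). Placing the remaining enzyme in the free pool
makes the system stiff, so the free enzyme and the substrate complex start
on their instantaneous quasi-equilibrium,
$e(0) = \frac{k_2}{k_{+1} s_0 + k_2}\left(1 - i_T/e_T\right)$,
$c_s(0) = 1 - e(0) - c_i(0)$. A consequence worth knowing when testing: the
substrate total $s + (e_T/s_0)c_s + p$ then starts at $1 + (e_T/s_0)c_s(0)$,
not exactly 1 — the invariant is its *constancy* along the trajectory. In
the effective-concentration regime used by the tissue model the offset is
$\le 2\times10^{-6}$.

### Reference concentrations

Two regimes are used. The *literature* single-cell run takes
$s_0 = 10\ \mu$M and $e_T = i_T = 1\ \mu$M. The concentration tables in the
source literature derive $0.72$–$0.73\ \mu$M for KLK5 (reproduced by
`estimate_enzyme_concentration(3.1, 33, 0.5, 0.13)`), but the printed
single-cell results are only consistent with the effective association rate
$k_{+1} e_T = 49.7\ \mathrm{h^{-1}}$, i.e. $e_T = 1\ \mu$M; with that value
this package reproduces all three published single-cell statistics
($s(24\,\mathrm{h}) = 0.009$, peak rate $0.13\ \mathrm{h^{-1}}$ near 2 h,
mean $c_i = 0.996$), and with $0.7\ \mu$M it does not ($s(24) = 0.021$). We
therefore treat $1\ \mu$M as the reference and keep $0.7/0.723\ \mu$M as
configuration alternatives. Because these literature rates degrade CNDs in
a day instead of the observed ~20-day migration (homogeneous mass action
ignores the diffusion barriers of the crowded extracellular space), tissue
simulations use an *effective* enzyme concentration $e_T = i_T = 0.1$ nM,
which restores a 20-day degradation timescale.

The corresponding CND geometry helper (`estimate_cnd_concentration`)
interprets the published protein densities on a square-slab corneocyte; its
output does **not** reproduce the published $6.6\ \mu$M (the original
derivation relies on unpublished supplementary conventions), so the default
$s_0$ is a configuration constant rather than this helper's output.

### Time rescaling

Tissue runs compress the physiological 480-h corneum transit to
$\hat T_M = \tau_T / v_z = 8/0.05 = 160$ h, so every kinetic rate is
multiplied by $\lambda = T_M/\hat T_M = 3$. This is an exact symmetry of the
kinetics: integrating $\lambda$-scaled rates for $T/\lambda$ with a
$\lambda$-compressed height schedule reproduces the unscaled trajectory, and
the test suite asserts it numerically.

### Multicellular mechanics

Cells are overdamped spheres in a laterally periodic box with a rigid basal
plane at $z = 0$, evolved by forward Euler
$\eta\,\dot{\mathbf c}_i = \sum_j \mathbf F_{ij} + \mathbf F^{Rt}_i +
\mathbf F^{D}_i$ at $dt = 30$ s. The pair force on the boundary gap
$r_{ij} = \lVert \mathbf c_j - \mathbf c_i\rVert - R_{ij}$ is logarithmic
repulsion $k\log(1+r_{ij})$ for overlap and, for separation, the adhesion
envelope
$\alpha_{ij}\left[(r^* + c)e^{-\gamma(r^*+c)^2} - c\,e^{-\gamma(r^{*2}+c^2)}\right]$
with $r^* = r_{ij}/R_0$ and $c = 1/(2\gamma)$; it vanishes at contact.
Adhesion is scaled by the pair's mean CND level,
$\alpha_{ij} = \tfrac12(s_i + s_j)\alpha_0$ — the bridge from chemistry to
mechanics. Stem cells divide asymmetrically when their age reaches a cycle
time drawn from $U(13,17)$ h; a torsional force $-k_\phi\,\phi\,\hat n$
rotates the daughter pair toward the vertical, keeping stems basal, and the
daughter inherits its stem's inhibitor level with chemistry re-initialised
at birth.

Three unit/parameter decisions deserve an explicit record:

* **Drag.** The source parameter table gives $\eta = 0.1$
  $\mu$N·h·$\mu$m$^{-1}$ without a CD↔$\mu$m conversion. We use
  $\eta = 10\ \mu$N·h·CD$^{-1}$ (i.e. 100 $\mu$m per CD), for three reasons:
  it reproduces the published free-cell removal time exactly (0.7 CD at
  $F_D/\eta = 0.5$ CD/h takes 1.4 h); it is consistent with the published
  0.31 CD/h surface-cell velocity; and it keeps forward Euler stable against
  the $k = 150\ \mu$N repulsion at $dt = 30$ s (with
  $\eta = 0.1\ \mu$N·h·CD$^{-1}$ the update amplifies with
  $dt\,k/\eta \approx 12$ and explodes).
* **Adhesion calibration.** The published coefficient
  $\alpha_0 = 374.7\ \mu$N is inconsistent with the stated peak adhesion
  force of $10\ \mu$N under this force law ($374.7 \times g_{\max} \approx
  42\ \mu$N, where $g_{\max} \approx 0.112$ at $r^* \approx 0.23$ is the
  envelope maximum). The peak force is what the desquamation-threshold
  argument $s^* = F_D/(3F_{\max}) \approx 0.17$ relies on, so
  `calibrate_alpha0()` makes $F_{\max}$ authoritative
  ($\alpha_0 = F_{\max}/g_{\max} \approx 89.3\ \mu$N) and the historical
  value is kept as `alpha_0_reference`.
* **Dual proliferative populations.** When comparing one against two
  proliferative populations matched by harmonic mean, the fast/slow
  composition is allocated exactly (`round(fraction_fast * n)` fast stems,
  randomly placed) rather than by independent coin flips: composition noise
  of order $1/\sqrt{n}$ otherwise swamps the equivalence being tested at
  $n = 100$ stems.

### Desquamation and coupling

Surface cells — the highest cell centre in each 1-CD lateral grid square —
receive a constant vertical removal force $F_D = 5\ \mu$N. Each step, the
main tissue body is the connectivity closure of the basal seed band (cells
within $R_0 + 0.7$ CD of the membrane) under the contact relation
"boundary gap < 0.7 CD" (the published 0.7-CD separation criterion is read
as a boundary gap, and the same threshold defines the seed band); everything
else is removed, with cells removed together and in mutual contact sharing
a clump id. The connectivity uses the neighbour list already built for the
force assembly (pre-move positions, with an explicit stem–daughter edge so
newborns are never orphaned); positions move $\ll 10^{-2}$ CD per step, so
this is indistinguishable from a fresh scan and halves the pair-scan cost.

The per-step order is: chemistry (with $\xi = (z - h)/\tau$ from the cached
corneum thickness $\tau$; frozen below the corneum base $h = 4$ CD, so cells
enter the corneum with $s = 1$ exactly) → force assembly → position update →
divisions → detachment cull → surface refresh → scheduled thickness refresh
(hourly; the tissue height is the mean surface-cell height, and the run
statistics are insensitive to refreshing every step instead).

Tissues are initialised by a *filling simulation*: stems only, no removal
force, cells deleted above a provisional ceiling (12 CD — the published
value is unstated; configurable), run for 12 days, followed by a burn-in
before sampling. Burn-in adequacy is asserted statistically rather than
visually: after the configured minimum, `run_scenario()` extends the burn-in
in 5-day increments until the slope of a linear fit through the trailing
5-day means of corneum thickness is insignificant at the 5% level
(`burn_in_stationary()`), up to a configurable cap. This matters: scenarios
far from the filled configuration — inhibitor-free tissue in particular —
carry the over-filled transient for tens of days (the weakly bonded upper
tissue sheds in a few large collapses) before settling at their thin steady
state, and a fixed burn-in samples mid-transient.

## Numerical choices

* `integrate_chem` uses an adaptive Cash–Karp RK45 with `rtol = 1e-4`,
  `atol = 1e-6` (no ODE-solver package exists in the supported environment,
  so the integrator is implemented here and verified in the tests against an
  independently written fixed-step RK4 oracle at $10^4$ substeps). Negative
  undershoot beyond $-10^{-9}$ triggers a tighter re-integration; smaller
  undershoot is clipped to zero.
* The compiled tissue loop integrates each cell's chemistry with fixed-substep
  RK4, the substep count chosen from the fastest local relaxation rate
  ($h\lambda \le 2$, inside the RK4 stability region); the test suite pins
  it to the R reference path within the integration tolerance.
* The quasi-equilibrium initial condition is always used (also at $i_T = 0$,
  the stiffest case).
* $k_{+3}$ is floored at zero below its root at pH 3.75; physiological
  $\xi$ never reaches that regime (pH spans 4.48–6.85).
* Division ties on a perfectly vertical axis give zero rotational force;
  equal-height partner pairs break the lower/upper tie by cell id.
* A per-step displacement above 1 CD raises an instability error naming the
  cell rather than silently continuing.

## What the synthetic world does and does not establish

Fixtures (`make_fixture`) and tissue runs are generated in code; there is no
external data. The reduced-scale acceptance runs use a 5×5 CD domain
(25 stem cells, one realisation per scenario, matched seeds) against the
reference 10×10 domain with 10 realisations — at this scale the model
reproduces the homeostatic corneum thickness band, the emergent migratory
velocity, and the relative thinning under inhibitor depletion, but min/max
ribbons and quartile statistics are noisier than the published ones. A green
suite establishes internal consistency and reproduction of the published
desk-scale statistics; it does not validate the biology beyond the model's
own assumptions: spherical cells of a single size, a flat basal membrane,
isotropic CND degradation, vertical-only environmental force, and
mass-action chemistry with an effective enzyme concentration standing in
for diffusion limitation.

## Known limitations

* The corneocyte slab geometry cannot reproduce the published CND
  concentration estimate; `s_0` is a configuration constant.
* The corneum-total free-enzyme contrast between inhibitor-free and normal
  tissue is directional but small here (~1.01x at reduced scale), not the
  published ~1.9x. At the effective enzyme concentration, free inhibitor is
  of order $i_T/s_0 = 10^{-5}$, so KLK-LEKTI rebinding is negligible and the
  complex largely unbinds over the migration even with full inhibitor (mean
  $c_i \approx 0.3$ in the package's own single-cell solution of that
  regime); mean free enzyme in normal corneum is then ~0.65 per cell,
  close to the inhibitor-free ~0.9 over a thinner column. The acceptance
  suite asserts the direction only.
* Tissue-scale statistics at desk scale use one realisation per scenario;
  the published min/max ribbons require the full 10-realisation ensemble
  (tens of CPU-hours).
* The filling ceiling and daughter placement offset are modelling choices
  exposed as configuration, not published values.
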