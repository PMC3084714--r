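---
title: "The receptor-desensitization model of gradient sensing and migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The receptor-desensitization model of gradient sensing and migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxsim)
```

## The model

`chemotaxsim` simulates how a eukaryotic cell — the motivating system is the
human neutrophil with its G-protein-coupled chemoattractant receptors —
senses and follows chemoattractant gradients when ligand-induced
*homologous receptor desensitization* is part of the receptor's life cycle.

### Receptor recycling kinetics

Each receptor species cycles through four pools at every
receptor-expressing unit of the cell:

* $R$ — free surface receptors,
* $LR^*$ — active (signaling) ligand–receptor complexes,
* $LR_d$ — desensitized surface complexes,
* $R_i$ — internalized receptors awaiting re-expression,

with mass-action transitions

$$
\begin{aligned}
dR/dt &= -k_f L R + k_r LR^* + k_{up} R_i\\
dLR^*/dt &= k_f L R - (k_r + k_{des}) LR^*\\
dLR_d/dt &= k_{des} LR^* - k_i LR_d\\
dR_i/dt &= k_i LR_d - k_{up} R_i .
\end{aligned}
$$

Ligand dissociation from desensitized complexes is neglected (a standard
assumption for these receptors), total receptor number is conserved, and
all receptors start free on the surface. The model keeps a *single*
internalized pool: desensitized complexes internalize at $k_i$ and return
to the surface at $k_{up}$. A finer split of the intracellular pool into
internalized complexes and free intracellular receptors would need a sixth
rate constant that the measured parameter set does not provide; with five
rates there is exactly one transition per constant.

Default rates are the measured neutrophil formyl-peptide-receptor values:
$k_f = 0.084\ \mathrm{nM^{-1}s^{-1}}$ ($8.4\times10^7\ \mathrm{M^{-1}s^{-1}}$),
$k_r = 0.37\ \mathrm{s^{-1}}$, $k_{des} = 0.065\ \mathrm{s^{-1}}$
(0 for the nondesensitizable variant), $k_i = 0.0033\ \mathrm{s^{-1}}$,
$k_{up} = 0.004\ \mathrm{s^{-1}}$. Internal units are seconds, nM, µm and
continuous receptor counts.

Setting the rates to zero under conservation gives the closed form used
throughout the steady-state analyses:

$$
LR^* = \frac{R_u\,k_f L}{(k_r + k_{des}) + k_f L\,
  (1 + k_{des}/k_i + k_{des}/k_{up})},
$$

which reduces exactly to the Langmuir isotherm
$LR^* = R_u L/(K_d + L)$, $K_d = k_r/k_f \approx 4.4$ nM, when
$k_{des} = 0$. Desensitization both lowers the plateau and shifts the
effective saturation to much lower concentrations — the source of
high-dose inhibition of chemotaxis.

### Ligand fields

A chemoattractant source is a fixed, radially symmetric power profile

$$
L(\rho) = L_0 + (L_{max} - L_0)\,(1 - \rho/A)^n, \qquad \rho \le A,
$$

and $L_0$ beyond the field radius; defaults $L_{max} = 17.6$ nM,
$L_0 = 0$, $A = 1000$ µm, $n = 3$. The cubic kernel is a standard fixed
approximation to a point-source diffusion profile. Fields of the *same*
ligand superpose additively; distinct ligands coexist and are sensed by
separate receptor species. Fields are truncated exactly at $\rho = A$, so
a cell outside every support receives no signal. Note that the kernel is
*convex* in $\rho$: this has real consequences for two-source geometries
(see "Why some endpoint patterns cannot occur", below).

### The orientation vector

The cell is a ring of $N$ receptor-expressing units (default $N = 4$,
radius $r = 5$ µm, units exactly on the $\pm x$, $\pm y$ axes). The
orientation vector is the front–back difference of active complexes:

$$
\Delta LR^* =
\frac{4}{N} \sum_{j=1}^{N} LR^*_j\, \hat d_j ,
$$

which for $N = 4$ is exactly
$(LR^*_{+x} - LR^*_{-x},\; LR^*_{+y} - LR^*_{-y})$. The $N/4$
normalization makes finer rings directly comparable to the 4-unit cell;
the acceptance suite verifies that 36- and 72-unit rings agree with the
4-unit magnitude to within 0.03 % at representative positions, so the
4-unit cell is used everywhere for speed. A cell is *directed* when
$|\Delta LR^*| \ge 10$ (at the threshold counts as directed), the
conventional minimal receptor-occupancy difference for detecting a ~1 %
concentration difference across a 10 µm cell.

**Per-unit receptor endowment.** The total receptor complement is
$R_{tot} = 25{,}000$ per receptor species. The package gives *each unit*
the full $R_u = 25{,}000$, so that one front–back unit pair realizes the
receptor endowment of a two-compartment (1-D) cell along its axis. This
calibration was chosen because it produces a directed annulus in the
17.6 nM field (random core from saturation and desensitization, oriented
outer band) *and* a directed band at the 2 nM dose; splitting
$R_{tot}$ over units leaves the 2 nM field entirely below the
$|\Delta LR^*| = 10$ threshold, i.e. no low-dose chemotaxis at all, which
contradicts the migratory behaviour the model is meant to exhibit.
`R_u` is an ordinary parameter of `kinetic_params()` for users who want
other conventions.

### Migration

Migration is a threshold-gated biased persistent random walk at constant
speed (default 10 µm/min — motion never pauses, so path length is exactly
speed × time):

1. At each step the net orientation vector $v$ is computed from the
   *dynamically integrated* receptor states (not the steady state), so the
   receptor pools carry memory of the concentrations the cell has visited.
2. Step duration is
   $\tau = \mathrm{clamp}(\tau_{opt}\,|v|/v_{sat},\ \tau_{min},\ \tau_{opt})$
   with $\tau_{opt} = 2.5$ min (the characteristic persistence time of
   these cells), $\tau_{min} = 0.25$ min and $v_{sat} = 100$ counts. The
   clamp is continuous at the threshold
   ($\tau_{opt} \cdot 10/100 = \tau_{min}$).
3. If $|v| \ge 10$ the cell turns toward $\arg v$ over sub-steps of
   0.05 min at angular speed $\omega = (\pi/\tau_{opt})(|v|/v_{sat})$,
   capped so it never overshoots the target: a cell at saturation
   completes a half-turn within one optimal step.
4. If $|v| < 10$ the cell adopts one uniformly drawn heading for the step
   and moves straight. Instantaneous reorientation (rather than applying
   the magnitude-proportional turning law, which would freeze the heading
   as $|v| \to 0$) is what makes the sub-threshold mode a genuine
   unbiased random walk: with zero signal the mean displacement is a
   small fraction of the path length, as the test suite checks over 200
   seeds.
5. During every sub-step the cell advances and the receptor pools of all
   units are integrated by fixed-step 4th-order Runge–Kutta
   ($dt = 0.1$ s) against the ligand concentrations at the unit
   positions, re-evaluated each sub-step (the cell moves 0.5 µm per
   sub-step, so holding the concentration fixed within one sub-step is
   far below every other discretization error).

Randomness is consumed in a fixed documented order — one uniform draw for
the initial heading, then one per sub-threshold step — from R's global
generator, so a track is a pure function of its seed. The compiled engine
and the pure-R reference engine (`engine = "r"`, built on
`advance_step()`) consume the stream identically and are cross-checked in
the tests to floating-point accuracy. Cohorts give track $i$ the seed
$\texttt{base\_seed} + i - 1$.

Numerical guards: an RK4 step that turns a pool negative by more than
$10^{-9} R_u$ aborts with advice to reduce the step (this happens only
with step sizes far above the default at high ligand doses); smaller
overshoot is clamped to zero. Receptor conservation is monitored along
every trajectory and reported as an attribute; tests require it to hold
to $10^{-6} R_u$.

## Scenario presets as study conditions

The presets in `scenario_names()` are the package's synthetic study
conditions; their defaults are fixed once, here, and the tests treat them
as given.

* **Single gradients** (`single_{2nM,20nM,200nM}_{desens,nondesens}`):
  one source at the origin, peak 2/20/200 nM, 7 cells scattered over
  $\rho = 600$–900 µm at spread angles, 150 min. The doses span the
  regimes of low-dose chemotaxis, intermediate behaviour, and high-dose
  arrest of desensitizable cells.
* **Opposing gradients** (`opposing_{desens,nondesens,mixed}`): two
  identical-profile sources of *different* ligands at $(\pm 500, 0)$ µm
  (heavily overlapped 1000 µm fields), 12 cells along the axis including
  two just off the midpoint, 75 min. In `opposing_mixed` ligand 1's
  receptor is nondesensitizable.
* **Angled gradients** (`angled_{same,diff}_{desens,nondesens}`,
  `angled_mixed`): two sources forming an equilateral triangle with the
  start cluster (nine cells on a $\pm 40$ µm grid at the origin). The
  side length is 800 µm, chosen so that (i) the triangle is exactly
  equilateral, (ii) the starts lie inside the sensing annulus of both
  17.6 nM fields rather than at the zero-signal field edge, and (iii) the
  inter-source region is reachable within the 75-minute budget at
  10 µm/min. With sources 1000 µm from the starts neither condition
  holds and the cohort never launches.
* **Multi-step navigation** (`nav_A`–`nav_D`): a distant target source
  `L3` at $(0, 1100)$ µm — outside the support of the start cluster at
  the origin, but within sensing reach of the balanced zone of the
  angled pair — alone (A), with a single nearer stepping-stone source at
  $(0, 750)$ (B), with an identical-ligand angled pair (C), or with a
  different-ligand angled pair (D); 150 min. In B the stepping stone's
  high-dose arrest shelf lies below the distant target's detection range,
  so the relay fails by construction of the arrest physics, not by fiat.
* **Orientation maps** (`orientmap_{single,opposing}`): field layouts
  without migrating cells, for `orientation_map()` and
  `sweep_orientation()`.

What the generator emulates: fixed ligand profiles, receptor-limited
sensing, threshold-gated persistent migration, seed-reproducible cohorts.
What it does not: ligand diffusion dynamics and depletion, stochastic
single-molecule binding, cell–cell interactions, downstream signal
amplification, variable speed, 3-D motion. Passing tests therefore
support conclusions about the *receptor-level mechanism*, not about any
particular experimental assay geometry.

## What the model robustly shows

With desensitizable receptors, cells orient and migrate up shallow
gradients but arrest on an annulus around strong sources (high-dose
inhibition); nondesensitizable cells reach the source at every dose. In
opposing gradients, desensitizable cells on one side orient toward the
*distant* source, are trapped in a stable balanced zone at the midpoint,
and the orientation flips from local to distant as the desensitization
rate of the near ligand's receptor increases; nondesensitizable cells
orient toward the near source and escape the (for them unstable)
midpoint. Orientation strength decreases monotonically with $k_{des}$ and
increases with $k_i$ and $k_{up}$. A different-ligand angled pair plus a
distant third attractant relays cells far beyond their initial detection
range (`nav_D` beats `nav_A`–`nav_C` on median final distance to the
target) — the multi-step navigation mechanism. All of these are asserted
by the test suite.

## Why some endpoint patterns cannot occur

Two of the five angled-gradient endpoint patterns that one might expect
by symmetry with the opposing-gradient results are *structurally
excluded* by this model, and the test suite reports them as failures
rather than weakening the assertions:

* **Identical ligands, nondesensitizable receptors, "collect at the
  midpoint".** The power kernel is convex in $\rho$, so the sum of two
  identical fields has a *saddle* at the midpoint between the sources —
  a local minimum along the inter-source axis — at any separation. There
  is no superposition peak between the sources; a concentration-climbing
  (nondesensitizable) cell near the midpoint is always deflected toward
  one source.
* **Different ligands, nondesensitizable receptors, "capture by the
  nearer source".** The attraction toward a source scales as
  $\partial LR^*\!/\partial L \times |\nabla L|$. At the balanced-zone
  concentrations of the 17.6 nM equilateral geometry ($L$ of order
  $K_d$), Langmuir saturation makes this product *increase* with distance
  from a source: the farther, weaker gradient wins and the midpoint is
  attracting. Nearer-source capture requires balanced-zone concentrations
  far below $K_d$, i.e. a much larger triangle — which would put the
  start cluster outside sensing range entirely. The two patterns above
  therefore cannot both be produced in a single near-equilateral
  geometry under the default kinetics.

A third assertion — identical ligands with desensitizable receptors
splitting toward one or the other source — holds for individual tracks
only about 60 % of the time within 75 min: the split exists (committed
tracks end on both sides of the bisector at the high-dose arrest
distance), but high-dose inhibition stalls the rest of the cohort near
the bisector before they commit, so a strict per-track majority criterion
sits on the boundary.

## Numerical and design choices, in brief

* RK4 step 0.1 s (binding rate at 200 nM is ~17 s⁻¹, well inside the
  stability region; the integrator refuses steps that drive pools
  negative beyond tolerance).
* Steady-state formulas take $k_{des}/k_i$ and $k_{des}/k_{up}$ as zero
  when $k_{des} = 0$ — no division by zero for nondesensitizable
  receptors, and the Langmuir limit is exact.
* Threshold comparison is $\ge$: exactly 10 counts is directed.
* Sub-step count per migration step is the rounded ratio
  $\tau/\mathrm{substep}$, at least one, truncated at the simulation end;
  the default total times are exact multiples of the sub-step.
* Unit directions use `cospi`/`sinpi`, so axis units are exact and
  mirror/rotation symmetries of the orientation vector hold to machine
  precision.
* Scenario configs serialize to a single JSON document (µm, min, nM,
  s⁻¹); tracks to plain CSV. Test problem sizes (cohorts of 7–24 tracks,
  75–150 simulated minutes, 20-seed stochastic comparisons) keep the full
  suite in the seconds-to-minutes range on one core.

## Limitations

The cell is a rigid ring of point sensors; there is no membrane receptor
diffusion, no downstream adaptation or amplification, no chemokinetic
speed modulation, and no cross-desensitization between receptor species.
Fields are static and unbounded below by $L_0$; sources do not move or
deplete. The step-time and turning-rate proportionality constants
($v_{sat}$, $\tau_{min}$, and the half-turn normalization) are calibrated
package conventions, not measured quantities, and are exposed in
`migration_config()`.
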