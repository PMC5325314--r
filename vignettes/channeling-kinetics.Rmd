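---
title: "Does channeling make a two-enzyme cascade faster? Models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does channeling make a two-enzyme cascade faster? Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chankin)
```

# The question and the model

Substrate (metabolite) channeling is the direct hand-off of an intermediate
from the active site of one enzyme to the next, inside an enzyme--enzyme
complex (a metabolon), without release into the bulk. It is widely assumed
to accelerate cascade reactions. `chankin` implements the kinetic models
needed to examine that assumption quantitatively for the smallest
interesting case, a two-step cascade.

The **non-channeled cascade** is ordinary Michaelis--Menten kinetics run
twice in series:

$$\mathrm{S} + \mathrm{E}_1 \underset{d_1}{\overset{a_1}{\rightleftharpoons}}
  \mathrm{SE}_1 \xrightarrow{k_1} \mathrm{E}_1 + \mathrm{I}, \qquad
  \mathrm{I} + \mathrm{E}_2 \underset{d_2}{\overset{a_2}{\rightleftharpoons}}
  \mathrm{IE}_2 \xrightarrow{k_2} \mathrm{E}_2 + \mathrm{P}.$$

The **channeled reaction** runs on a complex $\mathrm{E}_{12}$ that binds
the substrate, converts it, hands the intermediate to the second site at
the channeling rate $k_{ch}$, and releases the product:

$$\mathrm{S} + \mathrm{E}_{12}
  \underset{d_{ch}}{\overset{a_{ch}}{\rightleftharpoons}} \mathrm{SE}_{12}
  \xrightarrow{k_1} \mathrm{IE}_{12} \xrightarrow{k_{ch}} \mathrm{E}_{12}\mathrm{I}
  \xrightarrow{k_2} \mathrm{E}_{12} + \mathrm{P},$$

with one metabolite in the complex at a time (see "Two-occupancy extension"
below for the relaxation of this). All catalytic steps and the channeling
step are irreversible unless an extension is switched on.

**Fairness assumptions.** To isolate the effect of channeling itself, the
turnover numbers inside the complex equal those of the free enzymes, and
the *microscopic* association/dissociation constants are shared between the
channeled and non-channeled reactions. What may differ is the diffusional
part: every macroscopic association constant is split as
$1/a = 1/k_a + 1/k_D$, with $k_a$ the intrinsic rate and $k_D \approx 4\pi D R$
the diffusional encounter rate, giving the degree of diffusion control
$\gamma = k_a/k_D$, so $a = k_a/(1+\gamma)$ and $d = k_d/(1+\gamma)$.
Forming a complex changes the geometry seen by a diffusing substrate, hence
possibly $\gamma$, but not the chemistry. `params_from_micro()` and
`mapk_params()` build parameter sets this way.

# Closed-form steady states

With the substrate clamped (the cellular situation), the steady channeled
velocity is the flux through the four-state cycle,

$$v_{ch} = \frac{k_1 k_{ch} k_2 \,[\mathrm{S}]\,[\mathrm{E}_{12}]}
  {k_{ch} k_2 K_M^{ch} + [\mathrm{S}]\,(k_{ch} k_2 + k_1 k_2 + k_1 k_{ch})},
  \qquad K_M^{ch} = \frac{k_1 + d_{ch}}{a_{ch}},$$

whose saturation limit is the harmonic combination
$(1/k_1 + 1/k_{ch} + 1/k_2)^{-1}[\mathrm{E}_{12}]$ — the price of strictly
serial processing — and whose low-substrate limit is
$k_1 [\mathrm{E}_{12}][\mathrm{S}]/K_M^{ch}$. The denominator above is the
one this package derives from the occupancy balance of the cycle; it is the
unique form consistent with both limits (`v_channeled()` documents the
derivation route: the occupancies of the three bound states are $v/k_1$,
$v/k_{ch}$, $v/k_2$ and the free fraction $v\,K_M^{ch}/(k_1 [\mathrm{S}])$,
summing to $[\mathrm{E}_{12}]$).

The non-channeled cascade has two regimes split by the threshold
$[\mathrm{S}]_{th} = K_M^{(1)} k_2 [\mathrm{E}_2] / (k_1[\mathrm{E}_1] -
k_2[\mathrm{E}_2])$: below it the intermediate pool is finite and
$v_{non} = k_1 [\mathrm{S}][\mathrm{E}_1]/(K_M^{(1)} + [\mathrm{S}])$;
above it the first enzyme outruns the second, the pool grows without bound,
and the velocity saturates at $k_2[\mathrm{E}_2]$ (`v_nonchanneled()`,
`s_threshold()`). Note the saturated branch is the *concentration-free*
$k_2[\mathrm{E}_2]$; an $[\mathrm{S}]$-dependent saturated branch would be
dimensionally inconsistent and would contradict the threshold formula,
which follows from equating the two branches.

Consequences explored by the package:

* In saturation, channeling always loses at equal totals:
  the harmonic sum is strictly below $k_1$ (`v_max()`).
* At low substrate, the comparison reduces to $K_M^{ch}$ versus
  $K_M^{(1)}$: channeling can only win by *lowering the degree of diffusion
  control* (`low_s_velocities()`).
* In a mixed system (free enzymes plus complexes, degree of channeling
  $x_{ch} = [\mathrm{E}_{12}]/\min([\mathrm{E}_1],[\mathrm{E}_2])$), the
  bulk intermediate pool is set by the *free* enzymes alone. Under the
  balanced-capability constraint $k_1[\mathrm{E}_1] = k_2[\mathrm{E}_2]$
  the pool is flat in $x_{ch}$ for equal enzyme totals, shrinks when the
  second enzyme is more abundant, and *grows* when the first is — direct
  differentiation of the pool formula gives the sign of
  $[\mathrm{E}_1]-[\mathrm{E}_2]$ (`iss_mixed()`, `pool_size_curve()`).
* With intermediate degradation $k_{deg}[\mathrm{I}]$ or a reversible first
  step, the non-channeled velocity erodes while the channeled one is
  untouched; the package solves the corresponding algebraic steady states
  (`solve_degradation()`: a quadratic with a unique non-negative root,
  written in the cancellation-free form; `solve_reversible()`: bracketed
  root finding on the intermediate, bracket end at the pool where the net
  forward flux vanishes, one Newton polish).

# The ODE system and its numerics

`build_rhs()` assembles the mass-action system of the full mixed model
(11 species, reduced to 8--9 integrated coordinates by the enzyme
conservation laws) under three feeding modes: batch, constant substrate
(clamped $[\mathrm{S}]$, with the implied supply velocity recoverable post
hoc), and constant feed. `integrate_cascade()` uses `deSolve`'s LSODA with
default tolerances `rtol = 1e-10`, `atol = 1e-12` nM — deliberately tight,
because trajectories are routinely compared against closed forms at
`1e-4` relative or better.

`steady_state_numeric()` integrates over doubling time horizons (BDF, since
the effective stiffness grows with the intermediate pool) and stops on the
first of:

* **derivative convergence** — all derivatives (production excluded) below
  `tol` (default `1e-10` nM/s);
* **state stillness** — the state unchanged to about `1e-8` relative across
  a doubling of the horizon. This matters at extreme clamped substrate,
  where the derivative floor set by integration error scales with the
  enormous binding fluxes and the absolute criterion is unattainable;
* **divergence verdict** — the intermediate pool is recognised as unbounded
  when the maximal source exceeds the maximal sink
  ($k_1[\mathrm{SE}_1] > k_2 [\mathrm{E}_2]_{tot}$, with $\mathrm{SE}_1$ at
  its relaxed value — impossible below the threshold), the pool keeps
  filling, every bound species has relaxed relative to the filling rate,
  and this holds over two consecutive doublings. The accumulation rate
  approaches the source--sink excess *from above* in this system, so a
  settled positive excess, not the rate's own stationarity, is the
  discriminating signal.

Deep in saturation the pool fills like $\sqrt{t}$ and the plain velocity
would need unreachable horizons to converge to $10^{-6}$; the optional
`watch_velocity` mode therefore applies Aitken $\Delta^2$ extrapolation to
the per-horizon velocities (geometric convergence per doubling makes the
extrapolation asymptotically exact) and stops when two successive
extrapolants agree.

`time_to_product_fraction()` locates $[\mathrm{P}](t) = \alpha
[\mathrm{S}]_0$ by LSODAR root detection, not by grid interpolation.

# Channeling diagrams

`steady_demarcation()` and `batch_demarcation()` trace, per substrate
level, the $\gamma_{ch}$ at which the channeled and non-channeled systems
tie (equal steady velocity, or equal time to convert the fraction $\alpha$
of a batch dose). Roots are searched in $\log_{10}\gamma_{ch} \in [-6, 6]$;
outside that range the point is flagged rather than extrapolated, since
degrees of diffusion control beyond six decades of the reference are not
physically meaningful. `s_max()` finds the substrate level above which even
the reaction-limited complex ($\gamma_{ch} = 0$) cannot tie — the absolute
ceiling of the acceleration window, which grows with $\gamma_1$.

A note on the batch comparison at strongly diffusion-limited channels: at
early times both systems produce at rates $\propto t^3$, with coefficient
ratio $(a_{ch} k_{ch})/(a_1 a_2 [\mathrm{E}_2])$. For the reference
constants this drops below one once $\gamma_{ch}/\gamma_1 \gtrsim 2$, so
the often-quoted short-time advantage of channeling is *not* universal: a
complex that binds substrate much more slowly than the free enzyme never
leads, at any time. The package's tests assert the advantage where the
model actually predicts it.

# Reference parameters and the scenario generator

The default constants (`mapk_params()`) are the package's study conditions
throughout: microscopic $k_a = 0.027\ \mathrm{nM^{-1}s^{-1}}$,
$k_d = 1.35\ \mathrm{s^{-1}}$ (representative of the first two reactions of
the MAPK pathway), turnovers $k_1 = k_2 = 1.5\ \mathrm{s^{-1}}$, channeling
rate $k_{ch} = 1\ \mathrm{s^{-1}}$, totals of 50 nM, substrate clamped at
90 nM, and $\gamma = 1$ for every reaction unless swept. Balanced-capability
variants (`mapk_scenario(variant =)`) adjust $k_2$ and $[\mathrm{E}_2]$
jointly so that $k_1[\mathrm{E}_1] = k_2[\mathrm{E}_2]$.

`random_ensemble()` generates reproducible property-test scenarios: each
rate is the reference value times a log-uniform factor in $[10^{-3}, 10]$,
the $\gamma$s are log-uniform in $[0.1, 10]$ (reaction-limited to
diffusion-limited), totals log-uniform in $[5, 500]$ nM (realistic cellular
enzyme abundances), substrate log-uniform in $[1, 10^4]$ nM. When the
consumer needs convergent steady states, draws are kept only if the
substrate sits below 90 % of the divergence threshold — draws *at* the
threshold converge arbitrarily slowly and would make equivalence tests
about patience, not correctness. What the generator does **not** emulate:
correlated rate constants (real enzymes do not draw their rates
independently), crowded or anomalous diffusion, and concentration
fluctuations at nanomolar copy numbers; passing tests demonstrate internal
consistency of the kinetics, not fidelity to any particular measured
pathway.

# Two-occupancy extension and conservation bookkeeping

With `two_site = TRUE` the complex may hold a substrate at site 1 while an
intermediate occupies site 2, via
$\mathrm{S} + \mathrm{E}_{12}\mathrm{I} \rightleftharpoons
\mathrm{SE}_{12}\mathrm{I} \to \mathrm{IE}_{12} + \mathrm{P}$, with the
binding constants of the first site and turnover $k_2$ by default (all
three independently overridable). Its saturation velocity is
$k_2 k_{ch} [\mathrm{E}_{12}]/(k_2 + k_{ch})$ — better than the
single-occupancy harmonic sum, still below $k_1[\mathrm{E}_1]$. Note that
$\mathrm{SE}_{12}\mathrm{I}$ holds *two* metabolites; the batch
conservation sum therefore counts it twice. This is verified symbolically
in the test suite (the weighted metabolite derivative sums exactly to the
supply rate).

# Brownian-dynamics rate estimation

To ask whether complex formation itself changes the diffusional encounter
rate, the package ships a bead-model Northrup--Allison--McCammon (NAM)
estimator. An enzyme is 42 Lennard-Jones beads (radius 0.37 nm) at the
vertices of a once-subdivided icosahedron projected on a 1.5 nm sphere,
one bead being the active site; the complex merges two such shells with
centers 1.4 nm apart, the active site of the first enzyme pointing away
from the second, beads swallowed by the partner core removed, and the
assembly recentred at the midpoint of the cores so that the whole
interaction envelope fits inside the 5 nm launch sphere. The substrate is a
0.4 nm LJ sphere; interactions are the *repulsive branch* of the 12-6
potential (the Weeks--Chandler--Andersen split: $4\epsilon[(\sigma/r)^{12} -
(\sigma/r)^6] + \epsilon$ for $r \le 2^{1/6}\sigma$, zero beyond) with
$\sigma = 0.77$ nm. The repulsive-only choice is deliberate: the beads are
soft excluded volume whose stiffness is set by $\epsilon_{LJ}$. With a full
12-6 potential the reaction surface at 0.82 nm would sit inside the
attractive well ($U(0.82\,\mathrm{nm}) \approx -0.87\epsilon$ from the
active bead alone, about $-1.8\epsilon$ with neighbours), so strengthening
the interaction would *raise* the association rate through surface
adsorption — the opposite of the excluded-volume physics the bead model is
meant to probe, where a stiffer enzyme surface hinders the approach to the
active site.

Trajectories start uniformly on the $b$-sphere ($b = 5$ nm), react within
$r_{react} = 0.82$ nm of the active-site bead center, and escape at the
$q$-sphere; the rate is $k_D(b)\beta / (1 - (1-\beta)k_D(b)/k_D(q))$ with
$k_D(x) = 4\pi D x$, which corrects analytically for returns from beyond
$q$ and makes the estimate insensitive to its exact value (tested at
$q \in \{15, 25, 50\}$ nm; default 25 nm). $D$ defaults to
1 nm$^2$/ns, the order of a small metabolite's aqueous diffusivity; rates
are reported in nm$^3$/ns and in nM$^{-1}$s$^{-1}$ (factor 0.602214076).

Numerical choices that matter:

* **Base step** `dt = 2e-4` ns wherever a bead force acts (within the
  $2^{1/6}\sigma$ cutoff of a bead). The rms free step is then 0.035 nm, a
  tenth of a bead radius.
* **Adaptive far steps**: outside interaction range the Gaussian step's
  standard deviation is a quarter of the gap to the nearest constraint
  (interaction envelope or reaction surface), making the far-field cost
  logarithmic.
* **Near-absorber refinement**: approaching an absorbing surface outside
  any force zone, the step shrinks with the gap (floored at `dt`/64). The
  first-passage discretisation bias of a fixed-step walk scales with the
  step length at the boundary; without refinement the bare-sphere
  validation sits visibly (about 2 sigma at $n = 10^4$) below the
  Smoluchowski value.
* **Drift cap**: the drift displacement per step is capped at twice the
  base step's standard deviation. Deep on the $r^{-12}$ wall — reachable
  only through rare noise excursions — the raw drift would otherwise
  catapult the substrate across the bead shell in one step.
* **Impenetrable cores**: the substrate reflects off the core sphere(s).
  Without this it can occasionally squeeze between beads into the hollow
  interior of the shell, where it is unphysically trapped (and could even
  "react" from inside).
* **Reproducibility**: the propagation uses R's RNG, so a fixed seed gives
  bit-identical results; capture is checked after each step with no
  interpolated crossing detection, and a half-step convergence comparison
  belongs to the validation suite.

The estimator is validated against closed forms (Smoluchowski rate and the
concentric-sphere first-passage capture probability) on a bare absorbing
sphere, where no force and no geometry approximations enter.

# Problem sizes and known limitations

The shipped tests and the acceptance script use 10--50-draw ensembles for
the analytic--numeric equivalences, 5-point sweeps with $10^4$ trajectories
per point for the LJ-strength dependence of the diffusion-limited rates,
and $10^4$--$4\times10^4$ trajectories for the bare-sphere validation;
these sizes give Monte-Carlo errors of 2--4 % on the rates, comfortably
below the effects being demonstrated, while keeping a full run on one CPU
in the minutes range.

Limitations, deliberate and otherwise: no stochastic (Gillespie) kinetics
and no spatial models; no reversible second step or reversible channeling;
no bi-substrate mechanisms; the bead model is uncharged (no electrostatic
steering, which is exactly the mechanism by which a complex *could* lower
its degree of diffusion control), rigid, and generic rather than derived
from any protein structure; hydrodynamic interactions are ignored and the
enzyme is held fixed, so $D$ is the substrate's coefficient alone. The
absolute rate scale of the bead model therefore carries the geometry and
potential conventions described above, and only its *trends* (decrease
with LJ strength, near-equality of single enzyme and complex) are
meaningful for the channeling question.
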