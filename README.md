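# chankin — kinetics of substrate channeling in two-enzyme cascades

Substrate (metabolite) channeling is the direct transfer of an intermediate
from the active site of one enzyme to the next, inside an enzyme–enzyme
complex (metabolon), without release into the bulk. It is widely credited
with accelerating cascade reactions. `chankin` provides the kinetic
machinery to test that claim for a two-step Michaelis–Menten cascade

    S + E1 <=> SE1 -> E1 + I,   I + E2 <=> IE2 -> E2 + P

run against its channeled counterpart on the complex E12:

    S + E12 <=> SE12 -> IE12 -> E12·I -> E12 + P

with a single metabolite in the complex at a time (a two-occupancy
extension is available). Turnovers and *microscopic* binding constants are
shared between the two systems; what may differ is the diffusional part of
each association constant, `1/a = 1/k_a + 1/k_D`, summarized by the degree
of diffusion control `γ = k_a/k_D` so that `a = k_a/(1+γ)`,
`d = k_d/(1+γ)`.

The package implements, as tested closed forms plus a stiff mass-action ODE
oracle:

* steady-state velocities of both systems; the channeled saturation limit
  `(1/k1 + 1/k_ch + 1/k2)^-1 [E12]` (serial processing can never beat
  `k1[E1]` at equal totals);
* the substrate threshold `K_M^(1) k2[E2] / (k1[E1] − k2[E2])` above which
  the intermediate pool grows without bound, with a numerical divergence
  verdict that flips at the same level;
* the steady intermediate pool of mixed systems as a function of the degree
  of channeling `x_ch = [E12]/min([E1],[E2])` — flat, falling, or *rising*
  with channeling depending on the sign of `[E1] − [E2]`;
* degradation and reversible-first-step extensions, where channeling earns
  its keep by protecting intermediates;
* channeling phase diagrams: the `γ_ch(S)` demarcation between acceleration
  and deceleration in steady state and in batch reactors;
* a Brownian-dynamics Northrup–Allison–McCammon estimator of
  diffusion-limited association rates for bead-model enzymes and
  enzyme–enzyme complexes (Rcpp core, validated against the Smoluchowski
  rate `4πDR` and the concentric-sphere capture probability).

## Worked example

The reference parameter set (rate constants representative of the first two
MAPK-pathway reactions): `k_a = 0.027 nM⁻¹s⁻¹`, `k_d = 1.35 s⁻¹`,
`k1 = k2 = 1.5 s⁻¹`, `k_ch = 1 s⁻¹`, totals 50 nM, `γ = 1` everywhere.

```r
library(chankin)

macroscopic_from_micro(k_a = 0.027, k_d = 1.35, gamma = 1)
#> Rate decomposition (nM^-1 s^-1 / s^-1):
#>   microscopic : k_a = 0.027, k_d = 1.35
#>   diffusional : k_D = 0.027  (gamma = 1)
#>   macroscopic : a = 0.0135, d = 0.675

# steady velocities at 90 nM clamped substrate, 50 nM of catalyst each
v_channeled(mapk_params(E1_tot = 0, E2_tot = 0, E12_tot = 50), 90)
#> [1] 14.17736
v_nonchanneled(mapk_params(E12_tot = 0), 90)$v
#> [1] 26.88053

v_max(mapk_params())
#>         v_non_max          v_ch_max v_ch_max_two_site
#>          75.00000          21.42857          30.00000

s_threshold(mapk_params(E2_tot = 40))   # divergence threshold, nM
#> [1] 644.4444

# batch reactor: time to convert half of a 90 nM dose
time_to_product_fraction(mapk_params(E1_tot = 0, E2_tot = 0), 90, 0.5)
#> [1] 5.186418
time_to_product_fraction(mapk_params(E12_tot = 0), 90, 0.5)
#> [1] 5.652487
```

At these conditions the channeled system is roughly half as fast in steady
state (14.2 vs 26.9 nM/s: the complex processes metabolites strictly in
series), yet slightly *faster* in an early batch comparison (5.19 vs 5.65 s
to 50 % conversion: the non-channeled cascade must first build its
intermediate pool). Whether channeling accelerates or decelerates is a
question of substrate level, comparison time, and how complex formation
changes the degree of diffusion control — `steady_demarcation()`,
`batch_demarcation()` and `s_max()` map the full diagrams, and `nam_rate()`
asks the bead-model question of whether an enzyme–enzyme complex actually
diffuses substrates to its active site any worse than a lone enzyme.

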