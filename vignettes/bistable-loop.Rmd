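---
title: "A bistable thalamocortical loop: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable thalamocortical loop: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcloop)
```

## The model

`tcloop` studies a mean-field firing-rate model of the first supraspinal relay
of pain processing: a loop formed by the thalamic ventroposterolateral nucleus
(VPL, variable $V$), the primary somatosensory cortex treated as one functional
element (SC, variable $S$), and the thalamic reticular nucleus (TRN, variable
$T$), the loop's only inhibitory (GABAergic) node. Each variable is a mean
firing rate in Hz, relaxing with a common time constant $\tau$:

$$\tau \dot S + S = f(V), \qquad
  \tau \dot T + T = f_2(V + S), \qquad
  \tau \dot V + V = \frac{g(aT)\,S^p}{S^p + h(aT)^p},$$

with increasing Hill responses $f(x) = m_1 x^p/(e^p + x^p)$ and
$f_2(x) = m_2 x^p/(e^p + x^p)$. TRN inhibition acts on the VPL response to
cortical drive in the two ways inhibition is observed to act on neuronal
input–output curves: it divides the gain,
$g(u) = m_1/(1 + (u/e)^p)$, and it shifts the half-activation rightward,
$h(u) = e_0 + m_2 u^p/(e^p + u^p)$, where $u = aT$ and the dimensionless
efficacy $a \in [0,1]$ scales how much of the TRN output actually reaches VPL.
$a$ lumps every upstream (immunoendocrine, pharmacological) modulation of
GABAergic transmission into one external parameter, and is the bifurcation
parameter of the whole analysis.

Default parameters (`loop_params()`): $\tau = 0.5$ s, $m_1 = 100$ Hz,
$m_2 = 80$ Hz, $e = 20$ Hz, $p = 2.5$, $a = 1$. These are the nominal values
the package's acceptance checks are anchored to. $e_0$ is not an independent
literature value; it is fixed to $e$ because at $a = 0$ the V equation must
collapse to the plain excitatory Hill response $m_1 S^p/(S^p + e_0^p)$ — the
same functional form as $f$ — and we take "same form" to include the same
half-activation. `e0` remains an independent field for sensitivity work.

Three structural loops coexist: one positive (VPL–SC–VPL, excitation only) and
two negative ones through TRN. When $a$ is large the negative loops dominate
and the only attractor is the quiescent state; when $a$ falls the positive
loop dominates and a second, high-firing attractor appears. The high state is
read as a self-sustaining, pathogenic pain-processing mode; the transition is
a saddle-node (fold) bifurcation.

### Variants

* `standard` — the model above.
* `reversed_gaba` — the TRN projection made excitatory (chloride-gradient
  inversion): $\tau\dot V + V = f(S + T)$. With no inhibition anywhere the
  system is structurally a candidate bistable switch for every $a$; indeed the
  equilibrium equations no longer involve $a$ at all, so bistability holds on
  the whole interval.
* `fixed_g` / `fixed_h` — robustness probes that freeze one of the two
  inhibition channels at its basal value ($g \equiv m_1$, resp.
  $h \equiv e_0$). With only the shift channel active (`fixed_g`) the
  remaining inhibition is too weak to ever destroy bistability on $[0,1]$:
  the fold moves right past $a = 1$ and `find_threshold()` reports
  `bistable_throughout`. With only the gain channel active (`fixed_h`) the
  fold survives and sits at $a \approx 0.547$, well to the right of the
  standard $\approx 0.264$. Both outcomes are the "fold never moves left"
  direction asserted in the test suite.

## Finding equilibria: scalar reduction

At a fixed point, $S^* = f(V^*)$ and $T^* = f_2(V^* + S^*)$ are explicit in
$V^*$, so all equilibria are zeros of one scalar residual $R(V)$
(`steady_state_residual()`). No multidimensional root-finding is needed.
`find_equilibria()` scans $R$ on a uniform grid of 5000 intervals over
$[0, 1.05\,m_1]$ (no equilibrium can exceed the Hill ceiling $m_1$), refines
every bracketed sign change with Brent's method to a width of $10^{-12}$,
deduplicates roots closer than $10^{-6}$ Hz and always includes the
structural root at the origin. Because $R(0^+) < 0$ and $R(1.05\,m_1) < 0$,
a well-resolved scan yields an odd total root count; an even count signals an
unresolved tangency near a fold and triggers automatic grid refinement
(up to four 4-fold refinements before warning).

Stability comes from the eigenvalues of the analytic Jacobian
(`loop_jacobian()`): stable iff all real parts are below $-10^{-9}$;
eigenvalues within $\pm 10^{-9}$ of zero raise a marginal-stability warning
rather than silently classifying — that situation only arises essentially on
the fold itself. At the origin, with $p > 1$ every Hill derivative vanishes
and the Jacobian is exactly $-\tau^{-1} I$: the quiescent state exists and is
stable for every variant and every $a$.

Labels order the equilibria by $V$ (they are in fact componentwise ordered):
`zero`, then `mid` (the unstable separatrix state), then `high`.

## The fold in the efficacy

`find_threshold()` bisects on the boolean "three or more equilibria" over
$a$, to a default width of $10^{-5}$. The scalar reduction makes each count
cheap, so bisection is both simpler and more robust than numerical
continuation with fold detection, which we deliberately avoid. If the
indicator is equal at both interval ends there is no fold to find and the
status says whether the system is bistable or monostable throughout — this is
also what the degenerate input $m_2 = 0$ returns, since then $T$ never feeds
back and $a$ has no effect.

With the default parameters the fold is at $\hat a = 0.26420 \pm 10^{-5}$.
The reference description of this model places it at $0.265$; the
$8\times10^{-4}$ discrepancy is within one unit of the third decimal and is
consistent with a grid-rounded report, so the package's checks compare at
that precision. Two caveats from the same source are worth stating plainly,
because our computations pin them down: the description of the
high equilibrium "immediately below" the fold as $V \approx 40$ Hz with
$S \approx 80$ Hz corresponds to $a \approx 0.235$–$0.24$ rather than to
$a = 0.26$ (where the high state is at $V = 29.3$, $S = 72.2$ Hz); and the
claim that freezing either Hill modulation always leaves an observable fold
holds on $[0,1]$ only for `fixed_h` (see above). The corresponding acceptance
checks are encoded at their stated nominal values and report whatever the
computation yields.

`bifurcation_sweep()` tabulates all branches on a default grid
$a \in [0, 0.5]$ in steps of $0.001$ (all structure lives below $0.5$),
stitching branches across adjacent $a$ by nearest-neighbour matching in state
space; `autoplot()` renders the classic fold diagram with stable branches in
blue and unstable in red.

## Trajectories and attractor classification

`simulate_loop()` integrates with an embedded Dormand–Prince 5(4) pair
(compiled, FSAL, step control with safety factor 0.9 and step-ratio clamps
[0.2, 5]), at relative/absolute tolerances $10^{-8}/10^{-10}$. The dynamics
are only mildly stiff — one shared $\tau$ — so an explicit pair is the right
tool; an independent `lsoda` integration of the pure-R right-hand side is used
as a cross-check in the tests, and a fixed-step RK4 mode exists for
bit-reproducible tables. Floating-point undershoots below zero are clamped
before Hill evaluation (non-integer $p$ makes negative bases undefined); the
linear decay terms see the raw state, which restores non-negativity.

`settle()` classifies the attractor reached from a start: the trajectory must
be within 0.5 Hz (max-norm) of a stable equilibrium *and* moving slower than
$10^{-3}$ Hz/s, checked every 0.25 s of model time up to a 200 s horizon.
Requiring proximity and low speed together prevents mislabelling the slow
drift past the saddle. A start that fails to resolve (separatrix starts, a
measure-zero set) is labelled `"unresolved"`, a value, not an error.

## Basins of attraction

`map_basins()` classifies a grid of initial conditions $(S_0, V_0)$ with
$T(0) = T_{\mathrm{init}}$ fixed, integrating the **full three-dimensional
flow** from each cell: the 2-D panels are initial-condition sections of the
3-D flow, not a frozen-$T$ planar system. (A `freeze_T` mode exists purely
for comparison.) The default slice $T_{\mathrm{init}} = 80$ Hz — the maximal
TRN rate — is the section on which the quiescent basin is widest, making it
the conservative choice for demonstrating how small the quiescent basin
becomes; the default grid is $101 \times 101$ cells over $[0,100]^2$ Hz so
area fractions are comparable across runs. The separatrix here is planar-like
(no fractal boundaries), so unresolved cells are expected only within about
one cell width of the boundary; in practice the default tolerances resolve
every cell.

`basin_area_fraction()` turns a map into the per-label fraction of cells
(all labels, including `unresolved`, partition the grid). The package's
checks verify the monotone growth of the high basin as $a$ falls
($a \in \{0.10, 0.15, 0.20, 0.25\}$), stability of fractions under grid
refinement (within 2 percentage points when doubling resolution), and the
reversed-GABA variant's uniformly wider high basin.

`switching_threshold()` measures ultrasensitivity: the minimal amplitude
along a state-space ray from the origin (default: pure $V$, a transient
spinothalamic volley into VPL) whose trajectory lands in the high basin,
located by bisection to 0.01 Hz. Just below the fold this is ~16 Hz —
a brief, modest VPL activation permanently flips the cortex to the
high-firing state — and it shrinks as $a$ decreases.

## Problem sizes and determinism

The default analysis sizes — 5000-interval residual scans, $10^{-5}$ fold
bisection, $101 \times 101$ basin grids, 200 s settling horizon — were chosen
as the smallest sizes at which all reported quantities are converged (the
suite checks invariance under doubling the scan and grid resolutions); a full
bifurcation sweep plus three basin maps completes in seconds on one core.
Everything in the package is deterministic given its inputs; random numbers
appear only in property tests (random parameter sets and initial conditions
under fixed seeds).

## Limitations

The model is a deliberate mean-field caricature: three lumped populations, one
shared time constant, no synaptic delays, no noise, no explicit external input
term (perturbations are modelled as initial conditions), and baseline firing
set to zero so the quiescent attractor is exactly the origin. Passing tests
show the *switch mechanism* — fold location, basin geometry,
ultrasensitivity — is implemented faithfully; they say nothing about whether
real thalamocortical circuits realise these parameter values. The negative
(oscillatory) regime of the loop is out of scope: no Hopf detection, no
delay-induced rhythms, no two-parameter bifurcation surfaces, and no
separatrix tracing beyond grid classification.
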