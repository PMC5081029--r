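---
title: "A spatially explicit stochastic model of thin-filament regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatially explicit stochastic model of thin-filament regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Cardiac thin-filament activation is simulated as a chain of discrete
regulatory units (RUs), each one tropomyosin/troponin span covering about
seven actin monomers.  Every RU occupies one of six states: its tropomyosin
sits in the blocked (B), closed (C) or open, myosin-bound (M) azimuthal
position, and its troponin C is either calcium-free (subscript 0) or
calcium-bound (subscript 1).  Direct B--M moves are prohibited, so the
tropomyosin axis is B ↔ C ↔ M; the calcium axis connects each
X₀ ↔ X₁ pair.

Nearest-neighbor cooperativity enters through the head-to-tail overlap of
adjacent tropomyosins, represented as an effective torsion spring acting on
the azimuthal angle.  With state angles $\varphi_B = 0^{\circ}$,
$\varphi_C = 25^{\circ}$, $\varphi_M = 35^{\circ}$ (structural values), a
neighbor in tropomyosin position $X$ contributes a distortion energy

$$\Delta U_{ZX} = \tfrac{1}{2}\gamma\,(\varphi_Z - \varphi_X)^2$$

to an RU in position $Z$, where $\gamma$ is the effective chain stiffness
(kJ mol$^{-1}$ rad$^{-2}$).  The transition state of each tropomyosin move
is assumed to sit exactly halfway between the two well angles
($\varphi_{BC} = 12.5^{\circ}$, $\varphi_{CM} = 30^{\circ}$).  Strain both
raises the energy well of the current state (lowering the barrier) and
raises the transition-state energy (raising it), so a move $Z \to Z^*$ with
neighbors $X$ and $Y$ proceeds at

$$k_{ZZ^*}^{XY} = k_{ZZ^*}^{\mathrm{ref}}\,
  \exp\!\left(-\frac{-\Delta U_{ZX} + \Delta U_{ZZ^*X}
  - \Delta U_{ZY} + \Delta U_{ZZ^*Y}}{RT}\right).$$

The exponent is divided by $RT$; dimensional consistency with the
transition-state-theory rate expression requires it even where compact
notations omit it.  Because the barrier angle is shared by the two
directions of a move, barrier terms cancel in every forward/backward
ratio: strain shifts equilibria through the wells only, and the rate
scaling is symmetric under swapping the left and right neighbor.  Calcium
binding and release are not strain-modulated -- the azimuthal angle is a
property of the tropomyosin position only, and both calcium occupancies of
a neighbor present the same angle.

Reference rates come from four parameters: the B→C rate
$k_{BC}^{\mathrm{ref}}$ with the blocked--closed equilibrium constant
$K_{BC}$ ($k_{CB}^{\mathrm{ref}} = k_{BC}^{\mathrm{ref}}/K_{BC}$), and the
crossbridge attachment rate $f^{\mathrm{ref}}$ with the duty cycle
$\delta = f/(f+g)$ ($g^{\mathrm{ref}} = f^{\mathrm{ref}}(1-\delta)/\delta$).
Interpreting $\delta$ as the reference-condition duty cycle is the only
reading that lets the published $(f^{\mathrm{ref}}, \delta)$ pair define
both C↔M rates.  Calcium binding is second order
($k_{Ca+}\,[\mathrm{Ca}]$, concentrations in µM); release is
$k_{Ca-}$.  The factor $\lambda$ couples troponin and tropomyosin: the
calcium-free activation step B₀→C₀ is scaled by $\lambda$,
and so are the C₁→C₀ and M₁→M₀ calcium
release steps, which makes the product of rates around every
calcium/tropomyosin cycle identical in both directions (microscopic
reversibility; `ru_rate_table()` satisfies this to machine precision and
the test suite asserts it).  $\lambda = 0$ makes calcium binding
obligatory for activation and traps calcium on any RU that has left the
blocked state.

### Parameter table and its interpretation

Packaged parameter sets (`param_set()`) follow the published table for the
three preparations (skinned rat trabeculae; reconstituted bovine
myocardium; intact rat trabeculae) and the E180G/D175N variants.  Two rows
of the published table are printed raggedly and their labels do not line
up with the values.  We assign the seven-valued row (1.83, 1.9524, 2.1476,
1.6595, 1.2963, 1.4259, 1.212) to $K_{BC}$ and the two-valued row (0.898,
7.0) to $k_{BC}^{\mathrm{ref}}$ (skinned vs. all other preparations), for
three reasons: the seven-valued row carries exactly the +10 % (E180G) and
−15 % (D175N) proportional changes the accompanying text attributes
to the BC equilibrium; the sensitivity-analysis caption states the fitted
BC equilibrium constant of the skinned preparation is 1.83; and with the
opposite assignment the model's exact equilibrium (computable by transfer
matrix, below) places half-activation near pCa 4.8 instead of the
published 5.5, while forward-rate magnitudes are stated to have little
steady-state effect.  The packaged intact-D175N set keeps the printed
$K_{BC} = 1.212$ (0.935× wild type) even though the text describes a
15 % decrease; `scenario_D175N()` implements the textual −15 %.

$RT$ defaults to 2.577 kJ/mol (310 K) and is configurable; the source
never states the temperature used, and fits constrain only $\gamma/RT$.
Angles are stored in radians internally (a $\gamma$ of order
10--70 kJ mol$^{-1}$ rad$^{-2}$ then yields strain energies of order
$RT$); configuration files take degrees.

## Monte Carlo engine

The production filament has 24 live RUs plus one dummy RU at each end
permanently fixed in B₀, defining the boundary condition.  All live
RUs start in B₀.  The normative update is synchronous discrete time:
with step $\Delta t$, each RU independently transitions with probability
$k\,\Delta t$ per allowed move, using pre-step neighbor states, with one
uniform draw per RU partitioned among the moves.  $\Delta t$ is chosen
automatically so that the cumulative per-step transition probability never
exceeds 0.7 for any state and any neighbor combination at the largest
calcium concentration of the protocol (`choose_dt()`); the test suite
confirms results are statistically indistinguishable at threshold 0.35.

Because per-step probabilities are constant while an RU's context is
unchanged, its survival is geometric, and the compiled engine therefore
samples each RU's next transition step directly and jumps from event to
event, redrawing timers whenever a neighbor moves, the calcium
concentration changes, or a protocol reset fires.  By memorylessness this
is distributionally identical to sweeping every step, at a small fraction
of the cost (the worst-case exit rate that fixes $\Delta t$ -- a blocked
RU between two open neighbors -- is orders of magnitude above typical
rates).  A plain-R synchronous sweep (`step_filament()`) is retained as
the small-case reference.  Each replicate run uses its own
deterministically derived xoshiro256++ stream, so trajectories are
bit-reproducible for a fixed seed and independent of R's RNG state.
Force is the fraction of live RUs in M states -- one effective crossbridge
per RU; no explicit crossbridge mechanics are modeled, and only isometric
conditions are represented.

Time-varying calcium (twitch) is applied piecewise-constant over the
recording grid (default 1 ms), which is much finer than the transient's
time constants.

## Master-equation oracle

`build_generator()` assembles the exact continuous-time generator over all
$6^N$ configurations of a short filament ($N \le 6$; dense linear algebra
through $N = 4$, sparse beyond).  Its stationary distribution (null-space
solve with a normalization row) and transient solution (matrix
exponential) provide an independent oracle: the test suite requires MC
steady force on a three-unit filament to agree with the stationary
expectation within Monte Carlo error across the activation range, and MC
force recovery after an M→C reset to follow the exact transient.  The
oracle is never used for the 24-unit production filament.  For $\lambda=0$
chains, which are reversible on their reachable class, a transfer-matrix
computation of the equilibrium force-pCa curve gives a second, fully
independent check of the steady state; it was used to confirm the
parameter-table interpretation above.

## Protocols

* **Force--pCa** (`steady_force()`, `force_pca_curve()`): constant calcium
  at $[\mathrm{Ca}] = 10^{6-\mathrm{pCa}}$ µM, 7500 ms activations,
  averaging the final quarter of each replicate (the duration is
  published; the window is our choice, and a drift check warns if the
  two halves of the window disagree beyond noise).  The default skinned
  grid is pCa 6.4→4.8 in steps of 0.1 (the experimental range);
  the exact grid is configurable because the source does not state it.
* **k$_{tr}$** (`ktr_protocol()`): after the steady period every open RU
  is instantaneously returned to the closed state (M₀→C₀,
  M₁→C₁) and recovery of mean force is fitted with
  $F(t) = F_{ss}(1 - e^{-k_{tr}t})$ from the reset instant -- the source
  names no fit form; the monoexponential is the field's standard
  (slack--restretch) analysis.
* **Twitch** (`twitch()`): the filament is driven by a calcium transient,
  preceded by a 500 ms pad at the diastolic concentration so diastolic
  force is a steady state; metrics (`twitch_metrics()`) measure peak
  force, diastolic force and fraction, time to peak from transient onset,
  time from peak to 50 % relaxation, and the tension--time integral
  (trapezoidal).

## Hill analysis

`fit_hill()` fits $F = F_{max}\,[\mathrm{Ca}]^{n}/([\mathrm{Ca}]^{n} +
\mathrm{Ca}_{50}^{n})$ by nonlinear least squares (parameterized in pCa
for conditioning), then refits the points below and above half-maximal
force separately with $F_{max}$ and pCa$_{50}$ fixed, yielding the
asymmetric half-curve coefficients.  Sharing $F_{max}$ and pCa$_{50}$
between halves makes the two coefficients directly comparable; the
half-max split uses the global fit's plateau, the only natural anchor.
With `offset = TRUE` a calcium-independent baseline is added -- the
appropriate form for absolute-tension preparations with constitutive
activation ($\lambda > 0$), whose no-offset fits are biased shallow by
the baseline.

The simulated skinned curve is steeper below half-max than above.  Its
global Hill coefficient is about 5.9 (the exact transfer-matrix value is
5.84, independent of simulation noise, and insensitive to any plausible
$RT$), while the steep-limb coefficient is about 6.5--6.6.  The published
comparison values (6.9 experimental, 6.7 simulated) correspond to the
steep-limb coefficient of the asymmetric analysis used for that dataset,
so that is the quantity `scripts/acceptance.R` reports for the skinned
fit; for the reconstituted (absolute-tension) fit it reports the global
offset-fit coefficient, matching how that dataset is analyzed.  Both
conventions are available from one `hill_fit` object.

## Fitting machinery

`fit_parameters()` wraps a small, deterministic particle swarm optimizer
(`pso_optim()`: swarm 30, 100 iterations, inertia 0.7298, acceleration
1.496/1.496, reflecting bounds -- conventional defaults; the source names
the method but no hyperparameters, and results never depend on optimizer
internals).  Objectives are RMSEs between simulated and supplied
force-pCa tables, using either the stochastic engine with a fixed seed
(deterministic objective) or the exact small-filament oracle for
noise-free parameter-recovery studies.  Absolute forces are compared when
the data include a calcium-free baseline, which is what makes stiffness
and duty-cycle changes separately identifiable; normalized force
otherwise.

`grid_search_kbc_delta()` reproduces the mutation-characterization
procedure: the measured stiffness change is imposed a priori
($\gamma \times 0.75$ for E180G, $\times 0.60$ for D175N), then $K_{BC}$
and $\delta$ scale factors are swept over a grid (default 0.70--1.30 in
steps of 0.05, bracketing all reported optima) and the RMSE against the
mutant dataset is mapped.  The reported `shallow_fraction` -- the share of
grid cells within 5 % of the minimum -- operationalizes how shallow the
error valley is (notably shallow for D175N).  The published mutant
force-pCa tables are not reproduced in print, so quantitative recovery of
the published optima requires user-supplied data; the package's own tests
plant a known mutation in self-generated data and require the argmin to
recover it at grid resolution.

## Synthetic calcium transient

`make_transient()` provides a double-exponential stand-in for a measured
intracellular transient: diastolic 0.1 µM, peak 1.0 µM at
30 ms, decay constant 150 ms, 1000 ms duration -- physiologically shaped
values for rat trabeculae at body temperature.  It is explicitly not the
measured transient of the intact-muscle experiments (digitizing published
figures is out of scope), so absolute twitch shapes are not comparable to
the published records; every mutant-versus-wild-type twitch statement is
made under one identical transient, which is all such comparisons
require.  What passing twitch tests show is therefore the *direction* and
ordering of mutation effects, not their published magnitudes (e.g. the
published 28 % D175N peak-force increase depends on the measured
transient; under the synthetic default the increase is a few percent).
One directional prediction is itself transient-dependent: the modest
D175N relaxation slowing does not emerge under the synthetic default --
the 15 % blocked-favoring K_BC decrease slightly outweighs the
relaxation-slowing effect of lower stiffness there -- and the
corresponding test documents this by failing under the default
conditions rather than adjusting them.

## Numerical choices and problem sizes

Dense stationary solves are used through $6^4$ configurations and sparse
LU beyond; probabilities are clipped of $-10^{-12}$ round-off before
normalization.  The monoexponential and Hill fits use
Levenberg--Marquardt with analytic-free starts chosen from the data
(plateau mean, 63 % crossing, half-max grid point).  The jointed-chain
cantilever validation minimizes total potential energy of a 10-segment
chain by BFGS with an analytic gradient and verifies the quadratic
energy--angle law ($R^2 > 0.999$ over a small-load sweep), the result
that justifies collapsing chain bending into a single torsion spring.

Package defaults follow the published protocol (400 replicates, 7500 ms).
The test suite and acceptance script use 40--600 replicates depending on
the precision each check needs -- e.g. 240 replicates per pCa point for
the Table-reproduction checks, which resolves the Hill statistics to
about 2 % -- and shorter activations where only a steady state at fast
kinetics is needed.

## Known limitations

RU-level discretization hides intra-RU phenomena and represents one
effective crossbridge per RU; force is a state occupancy, not a
mechanical tension, so comparisons to tension data are relative.  Only
isometric behavior is modeled: no sarcomere-length dependence, no
shortening, no explicit troponin-T interactions, no heterodimer mixtures.
The continuous mechanics of the tropomyosin chain are collapsed into one
azimuthal torsion spring; axial displacement is not represented.
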