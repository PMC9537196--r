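---
title: "Models, methods and numerical choices in sbtabflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, methods and numerical choices in sbtabflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbtabflow)
```

# Scope

sbtabflow is a modular workflow for deterministic modeling of subcellular
signaling cascades. The model and its data live together in one
human-editable SBtab document; everything else — ODE compilation,
stoichiometric pre-processing, experiment simulation, parameter
estimation, global sensitivity analysis, and export to SBML/NMODL/VFGEN —
is derived from that document. This vignette explains the underlying
models and the numerical decisions, in the spirit of a methods section.

# The model class

A document defines a reaction network over species concentrations
(nanomolar) in one or more compartments. Each reaction carries a
reaction-scheme string (`"CaM + Ca <=> CaM_Ca2"`) and a kinetic-law
string. **The kinetic law is the net flux of the reaction** — for a
reversible binding reaction typically
`kf*CaM*Ca - kr*CaM_Ca2` — not separate forward/backward laws. The ODE
system is

$$\dot x(t) = S\,v(x, \theta, u(t)),$$

with `S` the integer stoichiometric matrix (species × reactions, product
minus reactant counts) and `v` the stacked kinetic laws. Assignment
expressions (the Expression table) are evaluated before the fluxes in
topological order; cyclic assignment dependencies are rejected. Inputs
(Input table) are time-dependent quantities readable inside kinetic laws;
they are not states.

**Cross-compartment fluxes.** When a reaction located in compartment
$c$ changes a species residing in compartment $c'$, the species'
concentration derivative is scaled by the volume ratio $V_c / V_{c'}$.
The source format does not pin this convention down, so it is stated here
explicitly and the bundled fixtures use equal volumes, where the scaling
is the identity.

# Stoichiometric pre-processing

Conserved moieties are integer vectors $c$ with $c^{\mathsf T} S = 0$;
Wegscheider thermodynamic constraints are integer vectors in the right
null space of `S` restricted to reversible reactions, each imposing
$\prod_j (k_{f,j}/k_{r,j})^{c_j} = 1$ at equilibrium. Both are computed
with **exact rational elimination** (numerators/denominators held as
exact small integers, denominators cleared, gcd- and sign-normalized),
never a floating SVD: these constraints are combinatorial objects and the
output must be reproducible bit for bit. The basis is deterministic — one
vector per free column of the row-reduced system, in column order, first
nonzero coefficient positive. Irreversible reactions are excluded from
cycles entirely, matching the forward/backward rate-constant pairing of
the Parameter table. Constraints must be re-examined after every
structural model edit; the command-line `preprocess` report says so in
its footer.

# Simulation of experiments

Every experiment follows the same protocol: **equilibrate** the model
with all inputs at their resting values (default 0), apply the
experiment's initial-value overrides, then integrate with the
experiment's stimulus channels and map states to outputs.

* Integrator: `deSolve::lsoda` (stiff-capable), `rtol = 1e-6`,
  `atol = 1e-9` nM by default, configurable.
* Equilibration: integration in doubling windows until
  $\lVert \dot x \rVert_\infty / \max(\lVert x \rVert_\infty, 1) \le$
  `steady_tol` (default `1e-8`), capped at `max_time = 10000` s with a
  warning. No direct steady-state solver is used.
* Output grids: `"default"` = 0.05 s step, `"detailed"` = 0.01 s step.
  The data tables' 0.01 s spacing motivates the detailed value; a 20 s
  window at 0.01 s yields 2001 rows.
* Conservation reduction (`compile_model(..., reduce_conservation =
  TRUE)`) removes one state per independent moiety — deterministically the
  largest-index species in each moiety — and reconstructs it
  algebraically from the conserved total evaluated at the initial state.

Stimuli are built from two primitives. The **double-exponential
transient** is
$A\,\eta\,(e^{-(t-t_0)/\tau_d} - e^{-(t-t_0)/\tau_r})$ for $t \ge t_0$,
with $\eta$ chosen so the peak equals the amplitude $A$ exactly. The
**spike train** superposes `count` transients at interval
`1/frequency`. The use-case-like fixture drives a calcium channel with a
burst of 10 spikes at 10 Hz reaching 5 µM starting at 4 s, and a dopamine
channel with a single 1.5 µM transient whose onset is shifted by
$\Delta t \in \{-4,\dots,4\}$ s across experiments E0–E8, plus a
calcium-only experiment E9. Time constants are not pinned by the source
material; the fixtures carry them explicitly
($\tau_r = 5$ ms, $\tau_d = 50$ ms for calcium spikes;
$\tau_r = 50$ ms, $\tau_d = 500$ ms for dopamine) so every test is
self-contained.

# Parameter estimation

The objective is the standard-deviation-weighted least-squares score

$$F(\theta; Y, \tau) = \sum_{k=1}^{l} \sum_{j=1}^{m} \frac{1}{n}
\sum_{i=1}^{n} \left(\frac{Y_{ijk} - y_{ijk}(\theta)}{\tau_{ijk}}\right)^2,$$

summed over experiments $k$, outputs $j$ and the $n$ timepoints of each
output. $\tau$ (the allowed mismatch, analogous to a Gaussian noise SD)
comes from the `SD_` columns; missing columns default to 1. When data
tables have different lengths each table uses its own $n$. Simulated
trajectories are cubic-spline interpolated onto the data time grid; when
the simulation grid contains the data times this is exact. A failed
simulation contributes a large finite penalty (`1e10` plus the number of
completed experiments, keeping the ordering informative for population
searches). One documented variant normalizes residuals by each output's
data maximum instead of $\tau$; it is an extension, not the reference
score.

Optimization runs in $z = \log_{10}\theta$ with box bounds (all bounds
must be positive). The registry offers a local gradient method
(`optim` L-BFGS-B), Nelder–Mead, simulated annealing, differential
evolution and particle swarm. The two stochastic methods finish with a
short bounded Nelder–Mead polish from their best point: a standard
hybrid that removes the last-mile plateau without affecting global
exploration. All optimizers are seeded and bitwise reproducible.

# Global sensitivity analysis

Parameters are sampled from a lognormal prior,
$\log_{10}\theta \sim N(\mu, \sigma)$ with $\mu = \log_{10}\theta^*$ and
$\sigma = 0.1$ by default, on a Saltelli design: base matrices $A$ and
$B$ ($N \times k$) plus $k$ column-substituted matrices $AB_i$, for
$N(k+2)$ model evaluations in total ($k = 6$, $N = 10{,}000$ gives
80,000). First-order indices use the Saltelli estimator
$S_i = \overline{Y_B (Y_{AB_i} - Y_A)} / V[Y]$ and total-order indices
the Jansen estimator
$S_{Ti} = \overline{(Y_A - Y_{AB_i})^2} / (2 V[Y])$, with $V[Y]$ the
variance of the pooled $A$/$B$ evaluations.

**Sampling choice.** The base uniforms come from a Halton sequence with
seeded random digit-permutation scrambling. Plain Halton dimensions are
pairwise correlated (the classic striping pathology), which visibly
biases the Saltelli pairing of $A$ and $B$; scrambling removes the bias
while keeping the low-discrepancy accuracy. Measured on the additive
two-parameter toy at $N = 4096$, the scrambled sequence estimates
$S_i = 0.5$ to within $2\times10^{-3}$, an order of magnitude tighter
than pseudo-random sampling at the same cost. A pseudo-random sampler
remains available (`sampler = "random"`).

Small negative index estimates are reported raw; the bootstrap
Monte-Carlo half-width (200 row resamples, 95%) gives the context.
Zero-variance outputs are flagged as undefined rather than silently NaN.

# Exporters

* **SBML Level 2 Version 4**: sanitized SBtab ids become the SBML ids
  (never opaque hashes), kinetic laws are MathML of the parsed
  expressions, model-wide default units are nanomole substance and
  second time — declared once rather than per entity.
* **NMODL (MOD)**: NEURON's time unit is milliseconds, so every rate
  constant is rescaled by $1000^{e}$ where $e$ is the exponent of the
  second in its declared unit (a first-order `1/s` rate becomes
  $\times 10^{-3}$ `1/ms`); concentration units are never touched.
  Parameters with no declared unit are assumed first-order in time, with
  a warning. Conservation-eliminated species become algebraic
  assignments of their conserved totals. Coupling the mechanism into a
  cell model — wiring the calcium source into the input channel, reading
  the outputs — is deliberately left to the user and flagged in a
  comment block.
* **VFGEN**: plain ODE vector field; inputs and assignments appear as
  `Expression` elements, every species as a `StateVariable` whose
  `Formula` is its full right-hand side.

All writers are byte-stable given identical inputs.

# What the fixtures do and do not show

The `usecase_like` fixture reproduces the *structure* of the
eligibility-trace use case at desk scale: two input cascades (a
calcium-activated kinase, a dopamine-bound receptor sequestering the
opposing phosphatase) converging on the phosphorylation of one
substrate, across two compartments, with four conserved moieties and one
detailed-balanced reversible cycle. Its default rates were chosen once so
the $\Delta t$ protocol has a visible timing effect (substrate
phosphorylation is maximal when dopamine follows calcium closely and
lowest without dopamine). It does **not** reproduce the published
99-species biology, receptor desensitization, CaMKII autophosphorylation
cooperativity, or stochastic single-spine effects — so passing tests
demonstrate the correctness of the machinery, not the biology of any
particular synapse. Problem sizes in the test-suite and in the
reproduction script (recovery on 4 experiments × 49 timepoints × 4
outputs; Sobol oracles at $N \le 16384$) were chosen as the smallest
sizes at which the statistical checks are sharp.

# Known limitations

* No stochastic (SSA/tau-leaping) or spatial solvers; deterministic
  mass-action-style ODEs only.
* No rule-based semantics, no events, no DAEs beyond assignment
  ordering.
* SBML export is one-directional (SBtab is the source of truth); no
  SED-ML/COMBINE archives.
* The `.ods` workbook dialect is not supported; `.xlsx` is read-only and
  the canonical on-disk form is the TSV file set.
* Thermodynamic constraints are reported, never substituted into the
  Parameter table automatically.
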