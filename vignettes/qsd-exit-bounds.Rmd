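---
title: "Quasi-stationary exit bounds: model, algorithm and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-stationary exit bounds: model, algorithm and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

A biochemical reaction network (BCRN) is a list of species and reactions;
each reaction carries an integer count-change vector and a rate law mapping
the current count vector to a propensity in s⁻¹. The induced continuous-time
Markov chain (CTMC) on count vectors is the standard stochastic chemical
kinetics model: well mixed, constant volume and parameters, exponential
waiting times. `qsdbound` assumes in addition that

* the state space restricted to the monitored region is **strongly
  connected** (checked explicitly, never assumed), and
* rate laws vanish wherever the reaction would drive a count negative (the
  built-in mass-action and Hill families guarantee this; custom laws are
  checked at transition enumeration).

The scientific object is the first exit time `T` from a finite region `V`
chosen around a stable state of the deterministic rate equations. `V` is a
modelling choice: it should be large enough that its boundary marks genuine
commitment to another attractor, and small enough that the linear algebra
stays tractable. The package takes `V` as input (a per-species box or an
explicit state list) and never tries to detect stable states itself.

## Cut-off process and quasi-stationarity

The CTMC of a multi-stable circuit has no absorbing state, so "the
distribution around a stable state" has no exact invariant meaning. The
cut-off process makes it exact: transitions inside `V` keep their rates, and
every transition that would leave `V` is redirected to one artificial
absorbing state `a`. Because the two processes agree inside `V`, the
absorption time of the cut-off process and the exit time of the original
process are equal in distribution — the package's simulation oracle checks
exactly this coupling.

Write `Q~` for the cut-off generator (rows sum to zero, absorbing row zero)
and `Qv` for its restriction to `V` with the diagonal *keeping* the exit
rates. `Qv` is then strictly substochastic whenever any state can exit, and
standard absorption theory gives:

* a decay parameter `lambda = -max Re eig(Qv) > 0`;
* the quasi-stationary distribution (QSD) `pi_q`, the normalised left
  eigenvector of `Qv` at that eigenvalue;
* the exponential law `P(T > t) = exp(-lambda * t)` when started from
  `pi_q`, which the test suite verifies against the exact transient solution
  to 1e-8.

### Two estimators, one default

`compute_qsd()` exposes a second estimator, `method = "conditioned"`: the
stationary vector of the *conditioned* generator, built by deleting the
rates into `a` and re-zeroing the diagonal. That conservative matrix
describes a particle forbidden to leave, not one conditioned on not yet
having left; its stationary law is close to the QSD when absorption is slow
but puts more mass near the boundary than the killed process can sustain,
and it does not satisfy the exponential law exactly. It is retained for two
reasons: it is cheap and popular as an approximation, and reference
robustness tables for the toggle-switch family in the literature report
compensatory constants that match this estimator rather than the QSD proper
(see "Reference values" below). The default everywhere is `"restriction"`,
the estimator for which the theory is exact.

## The compensatory constant

For an arbitrary initial distribution `d`, the survival bound acquires a
constant: `P_d(T > t) >= exp(-lambda t) - A`. `compensatory_constant()`
computes `A` by iterative mass matching:

1. `D <- d` (unmatched initial mass, with any mass outside `V` lumped on
   `a`), `q <- pi_q` (unconsumed QSD mass);
2. each sweep cancels `D` against `q` statewise;
3. the unmatched remainder is pushed one step of the embedded jump chain,
   `D_new(y) = sum_x D'(x) J(x, y)` — the push-forward of a (defective)
   distribution. The transpose reading would not conserve mass and is not a
   distribution update;
4. `A = sum(D)` at termination.

Design points worth knowing:

* **Mass on `a` is permanent.** The jump chain holds the absorbing state
  (`J(a,a) = 1`) and `q(a) = 0`, so mass that reaches `a` during
  propagation contributes to `A` forever. That is the algorithm's intent —
  such mass represents initial probability that exits before ever matching
  the QSD — not leakage.
* **Termination.** Because of the previous point, `sum(D)` typically
  converges to a positive limit instead of reaching the target `eps`
  (default 1e-6). The sweep therefore also stops when the per-iteration
  decrease falls below `stall_tol` (default 1e-13, i.e. the limit has been
  reached to numerical precision) or at `max_loops` (default 1e5). Stopping
  early only leaves `A` larger, hence the bound more conservative — never
  invalid. All three knobs are recorded in the result.
* **Degenerate entry.** If `sum(D) <= eps` already at entry (e.g. `d` equals
  the QSD), the loop body never runs and the entry value (0 for the exact
  QSD) is returned.
* `A` increases when `d` concentrates near the boundary of `V`, and is
  monotone along mixtures of `d` with the QSD; both are property-tested.

## Birth-death specialisation

For a bounded birth-death chain the exit probability by any fixed time is
monotone in the distance from the absorbing boundary (verified numerically
by `exit_monotonicity_check()`). Consequently an initial distribution needs
*no* compensatory constant if its mass can be covered by QSD mass lying at
least as close to the exit boundary — a transportation problem whose supply
sets are nested, so feasibility collapses to cumulative domination: counted
from the exit boundary, every partial sum of `d` must be dominated by the
matching partial sum of `pi_q` (`qsd_condition_check()`). The test suite
keeps an independent max-flow oracle and checks the equivalence on hundreds
of randomized instances rather than assuming the reduction.

Point masses at the state farthest from the exit always pass, which yields
the dual-boundary bounds of `boundary_bounds()`: one cut-off over the low
states (absorbing above) bounds exits from the low region by
`exp(-lambda_L t)`, one over the high states (absorbing below) bounds exits
from the high region by `exp(-lambda_H t)`. For a population-level biosensor
whose low/high modes encode "analyte absent/present", these are upper bounds
on false-positive and false-negative rates.

## Numerical conventions

* **State ordering** is lexicographic by species counts, so eigenvectors and
  exports are reproducible; the connectivity root is the lexicographically
  smallest state.
* **Fractional region bounds** (box formulas such as `alpha/(3*beta)*P`
  need not be integer) resolve as ceiling on lower and floor on upper
  bounds — the largest integer box inside the real box.
* **Eigensolver.** Below 1500 states, a dense eigendecomposition. Above, an
  inverse power iteration at shift 0 on a cached sparse LU factorisation of
  the transposed restriction. This is exact for the spectrum at hand: every
  eigenvalue has non-positive real part, so the eigenvalue of largest real
  part is simultaneously the one of smallest modulus and dominates the
  inverse. Convergence tolerance 1e-12 on the eigenvalue; the left-eigen
  residual is reported. Tiny negative eigenvector entries (solver noise) are
  clipped to zero before renormalising; large sign-indefinite entries raise
  an error, since they indicate a wrong eigenpair or a disconnected region.
* **Numerical zero.** Decay parameters below 1e-14 s⁻¹ are reported as 0
  with a `below_floor` flag; double-precision eigenvalues that close to the
  machine epsilon of the generator's scale carry no information. In the
  strong-promoter design scan this floor is reached for all copy numbers
  P ≥ 20 with cooperativity nh ≥ 3: "no switching on any relevant
  timescale".
* **Transient oracle.** The master equation is integrated by uniformization
  (Poisson-weighted powers of the uniformized chain), truncated at tail mass
  1e-12 per step. Uniformization was chosen over stiff ODE integration
  because it is unconditionally stable, its error is a controlled tail
  bound, and decay parameters here span 1e-2 to below 1e-14 s⁻¹; on these
  problem sizes (a few hundred to a few thousand states) it is also faster.
* **Simulation oracle.** Gillespie trajectories of the original process are
  generated from precomputed per-state transition tables over `V` and
  watched until first exit. A master seed fans out one sub-seed per
  trajectory, so single trajectories are reproducible regardless of batch
  size.

## The toggle-switch family and its region conventions

The shipped model family (`toggle_table_config()`, `toggle_table_grid()`)
is a deliberately harsh stress test: per-copy production α = 0.05 s⁻¹ (a
strong promoter) against degradation β = 0.01 s⁻¹ (about one-minute protein
half-life, faster than typical bacterial turnover), so that stochastic
fluctuations — and hence switching — are maximised. Bounds from this family
are worst-case design envelopes, not typical-parameter predictions; for a
concrete circuit, rerun with its own parameters.

The monitored region around the stable state `(alpha/beta * P, 0)` uses
`S1` in `[alpha/(3 beta) P, 2 alpha/beta P]` and one of two `S2` bounds:

* `"copy-number"` (default): `S2 <= P`. Under these parameters this is the
  convention whose decay parameters and qualitative ordering agree with
  published robustness values for this family (e.g. λ = 1.93e-3 s⁻¹ at
  P = 6, nh = 2), and the one used by the acceptance script.
* `"formula"`: `S2 <= alpha/(3 beta) P`, the symmetric counterpart of the
  `S1` lower bound. The larger `S2` margin gives smaller decay parameters
  (6.12e-4 s⁻¹ for the same member).

The two conventions differ by up to an order of magnitude in λ precisely
because λ is dominated by the repressor's escape barrier; documenting both,
rather than silently picking one, is the honest resolution of a genuine
ambiguity in how such regions are specified in the literature. The
weak-promoter illustration (`illustrative_config()`) keeps its own
documented region `S1 in [0, 60], S2 in [0, 10]`. Its Hill coefficient is
genuinely unspecified in the sources this family is drawn from; the package
defaults to `nh = 2`, the lowest cooperative exponent, and exposes it as an
argument because the results depend on it strongly: across nh ∈ {2, 3, 4}
the decay parameter moves from 6.1e-5 to 1.2e-6 to 9.0e-8 s⁻¹ (the
compensatory constant at nh = 2 is A ≈ 0.005).

## What the generators emulate — and what they do not

The random birth-death generator (`random_bd_chain()`) draws strictly
positive interior rates uniformly from `(0.1, 1.1)` per unit rate scale:
connected by construction, with condition numbers typical of small
biochemical chains. The bistable test chain used for simulation-backed
certificates combines a constant basal production, a cooperative
positive-feedback term and first-order loss. These fixtures exercise the
algebra and the bounds; they do not emulate transcriptional bursting,
cell division, extrinsic noise or parameter drift. Passing certificates
therefore show the *mathematics* is implemented correctly, not that any
particular biological system is well described by a constant-rate CTMC.

Problem sizes in the shipped tests were chosen so the whole suite runs in a
few minutes on one core: regions of a few dozen to ~700 states for exact
oracles, 10⁴ simulated trajectories for coverage checks, and the full
15-member design grid (up to ~14 000 states) for the sparse eigensolver
path only.

## Known limitations

* `A` is an upper-bound construction with no tightness guarantee; for
  initial mass near the boundary it can be loose.
* The QSD machinery requires strong connectivity of `V`; regions violating
  it are rejected, not repaired.
* No SBML/automatic model import; models enter through R constructors or
  the YAML schema. Time-varying rates and reactions with state-dependent
  stoichiometry are out of scope.
* Memory, not time, limits region size: the sparse LU of the restriction is
  the binding constraint beyond a few hundred thousand states.
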