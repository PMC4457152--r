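---
title: "Spatial inspection games with heterogeneous punishment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial inspection games with heterogeneous punishment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crimelattice)
```

## The model

`crimelattice` simulates an evolutionary inspection game on an L×L square
lattice with periodic boundaries. Each site holds one player following one of
the competing strategies:

* **O** — ordinary people, who neither commit nor sanction crime. They are
  first-order cooperators but second-order free-riders: they benefit from
  punishment without paying for it.
* **C** — criminals, who gain the temptation payoff β from ordinary victims
  (the victim loses β).
* **Punishers**, who inspect and sanction criminals at a cost. In the
  uniform three-strategy game a single class **P** bears the full punishment
  cost α per interaction and collects the full reward γ when facing a
  criminal, imposing the normalized fine 1 on the criminal. The five-strategy
  game splits punishers into classes **L**, **M**, **H** committing the
  fraction r = 1/3, 2/3, 1 of the full effort; rank r scales the cost, the
  reward, and the fine alike. H is behaviorally identical to P.

Per pairwise interaction the focal player's payoff is:

| focal \\ opponent | O | C | punisher rank r' |
|---|---|---|---|
| **O** | 0 | −β | 0 |
| **C** | β | 0 | β − r' |
| **punisher rank r** | −rα | r(γ − α) | −rα |

Only a fragment of this table is pinned down unambiguously by prose
descriptions of the game (the criminal's β − 1 against a full punisher, the
±β temptation/loss pair, the cost α and reward γ and their 1/3 / 2/3 rank
scaling); the remaining entries encode two modeling commitments made
explicitly here:

1. **Punishers do not suffer the victim loss** when meeting criminals; their
   interaction with a criminal is summarized by the net inspection payoff
   r(γ − α).
2. **The inspection cost is paid in every interaction**, including with
   other punishers and with ordinary people — inspection is an indiscriminate
   activity, not one triggered by meeting a criminal — and the fine imposed
   on criminals scales with the punisher's rank (entry β − r for the
   criminal), so milder punishers are genuinely milder for criminals.

These choices are validated empirically rather than transcribed: the sign
structure they imply (M beats C at low β while L merely coexists with C;
C coexists with M at β = 0.9; L always beats M through its lower cost) is
asserted in the test suite, and the quantitative acceptance checks below
confirm the stationary criminal fractions and the full phase sequence.
`minimal_CLM` is this matrix restricted to {C, L, M}; it is the smallest
model exhibiting the punisher/punisher/criminal interface dynamics.

## Monte Carlo dynamics

The dynamics is imitation under the **Fermi rule** with random sequential
updating. One elementary step: a site x is drawn uniformly at random (with
replacement — a literal reading of random sequential updating, rather than a
permutation sweep); its payoff Π_x is freshly accumulated over its four von
Neumann neighbors; one neighbor y is drawn uniformly; Π_y is freshly
accumulated on the current grid; then x adopts s_y with probability

W = 1 / (1 + exp((Π_x − Π_y) / K)).

K (default 0.5, payoff units) is the selection noise: better performers are
readily imitated, but imitating worse performers stays possible, modelling
errors in payoff assessment. One Monte Carlo step (MCS) is L² elementary
steps, one revision opportunity per player on average. Self-imitation is an
accepted no-op (no re-draw); it only rescales time. The exponent is clamped
at |700| so extreme payoff differences saturate to probability 0/1 without
overflow; at K = 10⁻⁶ the rule is numerically the deterministic step
function, which the tests exercise.

Two interchangeable engines implement this protocol. The compiled kernel
(C++) and a literal pure-R transcription consume R's global RNG stream in an
identical fixed draw order (site, neighbor, acceptance — three draws per
elementary step, always consumed). Seeded trajectories are therefore
bit-identical between the engines, which the test suite asserts on lattices
up to 8×8 over 100 MCS for all three variants; replicate r of a run with
seed s uses seed s + r − 1.

A further engineering oracle uses neutral dynamics: with all payoffs forced
to zero the Fermi probability is 1/2 everywhere and the model reduces to
voter-type drift, whose fixation probability equals the initial density (the
density is a martingale). The suite checks this on a 10×10 lattice over
2000 runs against a 3σ binomial band.

## Initial states

`uniform_random` assigns each site an independent uniform strategy — the
standard starting condition, used for all phase classification.
`blocks` tiles equal-width vertical stripes in strategy order (L | M | C for
the minimal model), the prepared state used to watch interface motion; the
published spatial layout of that prepared state is not available in the
text, and equal stripes are this package's choice. Stationary outcomes are
insensitive to this choice — classification from uniform random and from
stripes agrees at all checked parameter points, consistent with the model's
reported insensitivity to initial fractions. `weighted_random` supports
degenerate and biased mixtures (homogeneous states are absorbing under
imitation, a property the tests assert for every variant).

## Stationarity, classification, sweeps

`is_stationary()` declares a trajectory stationary when the per-strategy
mean fractions of two consecutive non-overlapping windows (default 100 MCS)
agree within `tol` (default 0.01, absolute). Two times are reported:
`onset_mcs`, the first sampled time at which the window pair agrees, and
`stationary_since = onset_mcs − 2·window`, the start of the stretch the two
agreeing windows certify. The *time needed to reach the stationary state* is
`stationary_since`: the window-pair test can only pass once two full windows
lie inside the stationary regime, so its first passing time systematically
exceeds the physical relaxation time by up to two window lengths. In the
prepared-state interface runs of the minimal model the window means are
demonstrably constant from ≈300–400 MCS on, and `stationary_since` ≤ 400 MCS
holds for the majority of replicates at all three β values, matching the
reported relaxation speed.

`classify_point()` decides the surviving-strategy set of a parameter point:
a strategy survives a replicate if its final count is positive **and** its
time-averaged stationary fraction exceeds `eps_extinct` (default 10⁻³, a
noise floor against stray single sites at L ≈ 100–200); the point's set is
the majority vote across replicates, with one 2× replicate escalation on a
tie and an explicit `unresolved` flag otherwise (never a silent guess).
`sweep_phase()` classifies a parameter grid and enumerates a transition
wherever consecutive resolved points change their surviving set, locating it
at the grid midpoint — no bisection refinement, since critical exponents and
precise second-order lines are out of scope. `pairwise_invasion()` starts
from two half-lattice blocks so a single interface decides the outcome,
mirroring the interface analysis of the minimal model.

## Problem sizes and parameters

The package's standard study conditions, chosen once:

* Interface/minimal-model experiments: L = 150, K = 0.5, α = 0.5, γ = 1.5,
  1000 MCS with the final 200 MCS averaged, 10 replicates — the scale at
  which the three stationary outcomes (f_C ≈ 0.46 at β = 0.5, ≈ 0.40 at
  β = 0.9, ≈ 0.27 at β = 0.7) are reproduced.
* Phase sweeps: L = 90 (five-strategy) or L = 80 (three-strategy), 1400–1500
  MCS, 3 replicates per point. These are deliberately smaller than the
  600²–9000² lattices used to pin down transition points in the large-size
  limit; near phase boundaries small lattices suffer accidental extinctions,
  so sweep grids sample the interior of each phase rather than straddling
  boundaries.
* The five-strategy β grid spans 0.1–4.5. The upper end is dictated by the
  reconstructed payoffs: the C+H phase persists until the criminals'
  β − 1 advantage against punishers outweighs the punishers' γ − α = 1
  reward near β ≈ 3.7, where the final transition to the all-criminal phase
  occurs. The lower end starts at 0.1 because at β = 0.05 the narrow
  O+C+L coexistence needs lattices beyond sweep scale to avoid finite-size
  extinction.

## Limitations

* Finite-size effects: surviving sets near boundaries can misclassify on
  small lattices; the majority vote and interior-of-phase grids mitigate but
  do not eliminate this.
* Transition *locations* are midpoints of coarse grids, not critical points;
  the order of the transitions (continuous vs discontinuous) is not
  assessed.
* The payoff table beyond the prose-pinned entries is a validated
  reconstruction, not a transcription; alternative conventions (punishers
  additionally suffering −β, fines not scaling with rank) are not explored.
* Only von Neumann neighborhoods on the square torus are supported; no
  well-mixed or network topologies.
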