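---
title: "Modelling public opinion expression with consensus and reputation seekers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling public opinion expression with consensus and reputation seekers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opinionlattice)
```

## The model

`opinionlattice` simulates how publicly voiced opinions can drift away
from — and oscillate around — the private attitudes of a small society,
even when no attitude ever changes. The society is an `L x L` square
lattice with periodic boundaries (a torus), so every agent has exactly
four von Neumann neighbours. Each agent carries three properties:

* a **type**, fixed for the whole run: a *consensus seeker* wants to
  preserve local harmony and only voices an opinion that affirms an
  undisputed local majority; a *reputation seeker* gains status by
  speaking up exactly when doing so is distinctive — under silence,
  under a stalemate, or as the supported local minority;
* a binary **attitude** (`a` or `b`), fixed for the whole run. Agents
  never misreport: an expressing agent always voices its own attitude;
* a **behaviour** (express or stay silent), the only dynamic variable.

At every step each agent tallies its four neighbours' current
behaviours into counts `(n_a, n_b, n_silent)` and classifies the local
network into one of five states, which partition the 15 admissible
count triples:

| local state            | condition                                  |
|------------------------|--------------------------------------------|
| total silence          | `n_a + n_b = 0`                            |
| stalemate              | `n_a = n_b > 0`                            |
| majority with minority | `n_a, n_b > 0`, `n_a != n_b`               |
| partial majority       | exactly one opinion voiced, by 1–3 agents  |
| full majority          | all four neighbours voice the same opinion |

The decision rule is a function of (type, own attitude, local state):

* **total silence / stalemate** — no majority is visible, so voicing
  could establish one: consensus seekers stay silent, reputation
  seekers express;
* **majority with minority** — dissent is already on the table:
  consensus seekers silence themselves, and only a reputation seeker
  whose attitude matches the voiced *minority* expresses (it echoes a
  distinctive but supported view);
* **partial / full majority** — one undisputed opinion is voiced: only
  a consensus seeker holding that same attitude expresses (affirming
  consensus); reputation seekers will not echo a majority.

All agents update **synchronously** from the same old behaviour grid,
so the dynamics are a deterministic map on the finite set of behaviour
configurations. Every run therefore ends in a limit cycle; a cycle of
length 1 is a fixed point.

## Parameters

| parameter | meaning | default |
|---|---|---|
| `lattice_side` | torus side `L`; `N = L^2` agents | — |
| `r_density` | fraction of reputation seekers; exactly `round(r_density * N)` are placed at uniformly random sites | — |
| `p_attitude_a` | probability an agent's fixed attitude is `a` | 0.5 |
| `p_initial_express` | probability an agent starts out expressing | 0.5 |
| `max_steps` | horizon of one run (steps) | 10000 |
| `epsilon_correspondence` | half-width of the theta band called correspondence | 0.05 |

The exact-count placement (rather than per-agent Bernoulli types) makes
the swept density the *actual* composition of every lattice, which is
what a density sweep is meant to control. The balanced Bernoulli(0.5)
defaults for attitudes and initial expression are the model's reference
condition; the initial-expression probability is a free choice of this
package (it only seeds the transient) and is configurable.

## Observables

With `O_i` the fixed attitude of agent `i` and expression indicated per
step, the package records, per run:

* **silence density** — the fraction of silent agents, averaged over
  the equilibrium window;
* **attitude gap** `delta_A = #a - #b` over attitudes (constant);
* **expressed gap** `delta_E(t) = #voicing a - #voicing b`;
* **public–private opinion discrepancy**
  `theta = mean(delta_E over the final cycle) / delta_A`, defined only
  when `delta_A != 0`;
* the window-averaged fractions of the five local network states.

Theta classifies each equilibrium into four scenarios: *silent
majority* (`theta < 0`: the voiced majority is the attitudinal
minority), *dampened majority* (`0 <= theta < 1 - eps`),
*correspondence* (`|theta - 1| <= eps`), and *amplified majority*
(`theta > 1 + eps`). A windowed mean essentially never equals 1
exactly, hence the symmetric tolerance band; its default half-width is
0.05. The boundary `theta = 0` is assigned to the dampened class (no
sign inversion has occurred). Runs with `delta_A = 0` (tied attitudes;
at `N = 100` roughly 8% of draws) have no theta: they are flagged
`"undefined"`, excluded from theta and scenario aggregates, and
counted — silence and cycle statistics still include them.

## Cycle detection

Because the update map is deterministic, the *first recurrence* of a
behaviour configuration identifies the equilibrium exactly: if the
configuration first seen at step `t1` reappears at step `t2`, the
transient is `t1` and the period is `t2 - t1`. `run_simulation()`
hashes a bit-packed digest of every configuration and, by default,
stops at the first repeat. This is the package's primary detector.

`estimate_cycle_lag()` offers a second, lag-based estimator that does
not presuppose knowledge of the transient: over the second half of a
fixed-horizon trajectory it takes, per step, the minimum positive lag
to an identical configuration, and reports the maximum of those
minima. When the horizon covers the cycle at least twice and the
transient ends before half-horizon the two detectors agree (a tested
property); the lag-based estimator censors when some second-half
configuration never recurs. Recurrence is always evaluated on the full
behaviour configuration, never on a scalar observable: scalars (such
as an opinion ratio) can coincide without true recurrence, and can
equally stay constant across genuinely different configurations.

The practical consequence of that choice is visible in all-consensus
networks (`r_density = 0`). These quickly stop changing *audibly* — the
expressed-opinion ratio freezes — but the exact detector regularly
finds period-2 equilibria: a consensus seeker whose neighbourhood
alternates between a partial majority of its own attitude (so it
expresses) and a partial majority of the other attitude (so it falls
silent) blinks forever, in antiphase with the neighbours it is
reacting to. Whether such a network is called "static" therefore
depends on the detector: on the configuration level the period is 2,
on the level of aggregate expressed opinion it is typically 1. The
package reports the configuration-level answer and exposes the per-step
trajectory so users can aggregate differently if they wish.

**Equilibrium window.** All equilibrium statistics average over exactly
one period of the detected cycle (averages over a full period are
invariant to where the cycle is entered). When no recurrence occurs
within the horizon the run is flagged censored, its cycle length is
capped at the horizon for aggregation, and the last 10% of recorded
steps serve as the window.

## The sweep harness and its study conditions

`run_sweep()` executes a full replicated experiment: for every (size,
density) cell of a `sweep_plan()` it draws independent per-run seeds
from the master seed (one `sample.int()` table, stored per record, so
any row can be replayed in isolation), runs each replicate, and
aggregates with `summarize_by_density()`. The package's reference
conditions for the sweep are a 10x10 torus, densities 0 to 1 in steps
of 0.05, 200 replicates per density and a 2000-step horizon; those are
the sizes at which the test suite and `scripts/acceptance.R` exercise
the model, chosen so a full sweep completes in minutes on one CPU while
leaving per-density sampling error on mean silence below about one
percentage point. Equilibria at low and moderate densities are reached
within tens of steps; at densities above roughly 0.75 a growing share
of runs (up to about half) does not recur within 2000 steps and enters
the aggregates as censored, capped observations — their equilibrium
statistics then rest on the last-10% window rather than an exact cycle.

What the generator emulates is exactly the randomized initial
conditions of the model: random type placement at exact density, iid
attitudes, iid initial behaviours. What it does **not** emulate is any
feature of empirical societies — heterogeneous or correlated network
topology, attitude homophily, more than two attitude values, noise in
decisions, or agents that lie. Passing tests therefore demonstrate
internal correctness of the model and its observables, not external
validity for real opinion data.

## Numerical and degenerate-case choices

* Ties when locating a density extremum are broken toward the lower
  density and the tie count is reported.
* A cell whose defined-theta runs are split equally between two modal
  scenarios is flagged as a tie rather than silently picking one.
* Local-state fractions are accumulated in double precision; their sum
  is 1 up to accumulation error (tested at 1e-9).
* Degenerate densities 0 and 1 are ordinary grid points: all-consensus
  lattices freeze (up to the period-2 blinkers discussed above), and
  all-reputation lattices, started all-silent, flip to all-expressing
  in one step.
* `theta` is undefined (not 0, not dropped silently) for tied
  attitudes.

## Known limitations

* The lag-based period estimator needs the horizon to cover the cycle
  twice; near the long-cycle regime (densities around 0.85) that can
  require horizons well beyond 2000 steps.
* Censored runs make cycle-length means at high densities
  horizon-dependent lower bounds, not unbiased estimates.
* The model is defined on a torus. Bounded lattices, where edge agents
  have fewer than four neighbours, are not implemented; results that
  depend on boundary effects (for example the equilibrium silence level
  in all-consensus networks) can differ between the two conventions.
* Scenario frequencies at a density are descriptive; no inferential
  statistics are attached.
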