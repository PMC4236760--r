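---
title: "Network morphisms and kinetic emulation of reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network morphisms and kinetic emulation of reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnemu)
```

## The model

A chemical reaction network (CRN) is a finite species set $S$ together
with a finite set of irreversible reactions $\rho \to^{k} \pi$, where the
reactant and product complexes $\rho, \pi \in \mathbb{N}^S$ assign integer
multiplicities to species and $k > 0$ is a mass-action rate constant.  Two
reactions with identical complexes are kinetically indistinguishable, so
`crn()` merges them by summing rates; there are no conservation or
detailed-balance assumptions, and the empty complex is allowed on either
side so that open systems (inflows, outflows) are expressible.

Three matrices summarize a network's structure (`stoich_matrices()`): the
reactant matrix $\rho(s,r)$, the net stoichiometry
$\eta(s,r) = \pi_s - \rho_s$, and the *instantaneous stoichiometry*
$\varphi(s,r) = k_r\,\eta(s,r)$.  Bundling the rate into $\varphi$ is
deliberate: rates and stoichiometry are interchangeable to some extent
($s_0 \to^{2k} s_0 + s_1$ and $s_0 \to^{k} s_0 + 2s_1$ act identically on
$s_1$), and $\varphi$ is exactly the state-independent factor of the
mass-action differential system

$$ F(v)(s) \;=\; \sum_{r \in R} \varphi(s,r)\, [r]_v, \qquad
   [r]_v = v^{\rho} = \prod_{s} v_s^{\rho_s}, $$

with the convention $0^0 = 1$ so boundary states are well defined.

## Morphisms and the emulation theorem

A morphism between networks is a pair of total maps $m_S : S \to \hat S$,
$m_R : R \to \hat R$.  Writing $\mathbf{m}_S$, $\mathbf{m}_R$ for their
characteristic 0–1 matrices, the package checks three static conditions:

* **reactant morphism** (`is_reactant_morphism()`):
  $\mathbf{m}_S^{\mathsf T} \boldsymbol\rho =
   \hat{\boldsymbol\rho}\, \mathbf{m}_R^{\mathsf T}$ — each reaction's
  reactants map onto its image's reactants.  Checked in exact integer
  arithmetic.
* **homomorphism** (`is_homomorphism()`): the reaction map is determined
  by the species map, $m_R(\rho \to^k \pi) = m_S(\rho) \to^k m_S(\pi)$,
  where complexes are mapped by summing multiplicities over species
  fibers (`apply_complex_map()`).
* **stoichiomorphism** (`is_stoichiomorphism()`):
  $\boldsymbol\varphi\, \mathbf{m}_R = \mathbf{m}_S \hat{\boldsymbol\varphi}$
  — instantaneous stoichiometry is preserved when summed over *reaction*
  fibers.  The rate-free variant with $\eta$ in place of $\varphi$
  (`is_net_stoichiomorphism()`) is exact integer arithmetic and coincides
  with the rate-weighted condition on unit-rate networks.

The central result these checks feed is the **emulation theorem**: a
morphism that is both a reactant morphism and a stoichiomorphism satisfies
$F(\hat v \circ m_S) = \hat F(\hat v) \circ m_S$ for *every* target state
$\hat v$.  Initial conditions are *copied* through the species map
(`pullback_state()`), never summed, and by uniqueness of ODE solutions
every source trajectory then retraces its image trajectory exactly.  The
**change-of-rates theorem** (`change_of_rates_lift()`) extends this to
arbitrary re-ratings of the target: each source rate becomes
$k \cdot \hat k' / \hat k$, which for homomorphisms means rates are simply
copied.  Steady states transfer from target to source along any emulation
(`steady_state_transfer()`).

```{r mi-am}
m <- builtin_fixture("mi_to_am_morphism")$network
is_reactant_morphism(m)$holds
is_stoichiomorphism(m)$holds
check_emulation_derivative(m, random_state(1, m$target))
```

The counterexample fixtures `fig6b`, `fig6d`, `fig6f` delimit the
conditions: the first two are homomorphisms that fail the
stoichiomorphism sum (fiber sums $-2 \ne -1$ and $1 \ne 2$) and visibly
diverge in simulation; the third trades a doubled rate against a doubled
multiplicity and emulates without being a homomorphism.  They are
reconstructed from figure-caption formulas rather than printed reaction
lists, and are flagged `reconstructed = TRUE`.

## Influence networks and the triplet motif

Activation/inhibition diagrams are compiled to CRNs by an explicit
mechanism rather than by postulating sigmoidal rate laws.  Each node $x$
becomes three species: active $x_0$, intermediary $x_1$, inactive $x_2$;
each incoming influence catalyzes the two transitions of one ladder
direction (activation: $x_1 \to x_0$, $x_2 \to x_1$; inhibition the
reverse), with the catalyst being the source node's $x_0$ (high output) or
$x_2$ (low output).  The intermediary $x_1$ never appears outside its own
node's transitions; every reaction is catalytic, so each node's total mass
$x_0 + x_1 + x_2$ is conserved.  A node may be replaced by its dual
(`dualize()`), the pure renaming $x_0 \leftrightarrow x_2$, without
changing the compiled network.

At steady state under clamped activator/inhibitor levels $a, b$ the motif
balances fluxes at
$x_0 : x_1 : x_2 = \frac{k_{a1}a}{k_{b1}b} : 1 : \frac{k_{b2}b}{k_{a2}a}$
(`triplet_steady_state()`), which at equal rates gives the activated
fraction $a^2 / (a^2 + ab + b^2)$ — a generalized Hill response whose
limiting log–log slope is 2 (`hill_coefficient()`).  Edge rates default
to 1 and each edge carries its own pair of transition rates, so the
classic four-rate single-node motif is recovered when a node has exactly
one activator and one inhibitor, while multi-input nodes remain
unambiguous.

Two bundled influence networks anchor the examples: AM (approximate
majority), a single node whose high side activates and whose low side
inhibits itself — compiling to the three-species, four-reaction bistable
switch — and MI (mutual inhibition), two nodes each activating themselves
and inhibiting each other.  Collapsing MI with `y` mapped directly and `z`
mapped dually reproduces AM exactly (`homomorphic_projection()`), and the
resulting morphism is the bundled unit-rate emulation.

## Searching for emulations

`find_emulations()` implements the unit-rate homomorphism heuristic: set
all rates to 1, enumerate total species maps (optionally only maps sending
triplets to triplets, directly or dually), derive the induced reaction map
where it exists, and keep candidates passing the exact net-stoichiomorphism
test.  Every hit extends to an emulation for any target rate assignment by
copying rates.  An exhaustive mode with free reaction maps and the
rate-weighted check is available for the non-homomorphic cases, but it is
exponential and capped.  For MI $\to$ AM the constrained search space has
4 maps and the unconstrained one $3^6 = 729$; both recover exactly the
dual-collapse morphism and its mirror image.

## Numerical choices

* **Integration**: deSolve's `lsoda` (stiff-capable) with
  `rtol = atol = 1e-9` by default.  Nonnegativity is checked after
  solving, never enforced by clipping; dips below $-10\,\mathrm{atol}$
  mark a trajectory as failed.
* **Verdict thresholds**: the emulation theorem predicts *exact*
  trajectory coincidence, so the default deviation threshold of `1e-6`
  exists only to absorb solver error at the default tolerances; halving
  the tolerances moves measured deviations by far less than an order of
  magnitude.  Derivative-identity checks are preferred where possible
  (they carry no integration error and sit at machine precision,
  `< 1e-12`, for true emulations).
* **Exactness**: all integer-stoichiometry conditions (reactant morphism,
  net stoichiomorphism) are compared exactly; the rate-weighted
  stoichiomorphism uses an absolute tolerance of `1e-12` and reports the
  maximum residual so borderline cases are visible.  Up to 10 failing
  (species, reaction) witnesses are retained per check.
* **Hill slope estimation**: the limiting exponent is a least-squares
  log–log slope over the smallest two decades of the ratio grid; the
  default grid is $10^{-4} \ldots 10^{4}$ at 4 points per decade, where
  the finite-ratio bias at the largest retained point ($r = 10^{-2}$) is
  below 1%.
* **Reaction identity**: reaction maps refer to positions in the ordered
  reaction list; morphism JSON uses 0-based index pairs, or
  `"homomorphic": true` to derive the map.  Partial maps are rejected —
  restrict to a subnetwork explicitly before building a morphism.
* **Duplicate merging**: rate summation happens once, at construction,
  with a message per merge; homomorphic projection instead collapses
  *identical image reactions* without summing (the image is a set), and
  raises an error if two images share complexes but disagree on rate.

## What the generators emulate — and what they do not

`random_crn()`/`random_state()` produce small dense networks
(multiplicities $\le$ `max_stoich`, rates uniform on $(0.1, 2]$) and
uniform or boundary states, seeded and reproducible.  They exercise the
algebraic invariants (matrix identities, parser round-trips, merge rules)
broadly, but they are not biological: real influence networks are sparse,
catalytic, and often stiff over wide rate ranges.  The dynamic test
problems therefore come from the compiled influence fixtures (AM, MI and
derived constructions), at desk scale: trajectory checks use horizons
around $t = 50$ with 101–201 grid points, and the property suites use
tens of seeded random states or rate assignments per claim.  Passing
these suites demonstrates the theorems' machine-precision behavior on
exact mass-action models; it says nothing about robustness to structural
perturbation or stochastic (finite-molecule) semantics, which are outside
the package's scope, as is any form of approximate emulation.

## Known limitations

* Emulation search is exhaustive enumeration with pruning by construction,
  practical only for networks of a handful of species; scalable
  subgraph-matching is out of scope.
* The converse of the emulation theorem is not implemented: a failing
  stoichiomorphism check does not prove the absence of emulation via some
  other morphism.
* Reversible reactions are modeled as two irreversible ones; there is no
  special syntax for them, and SBML is not a native format.
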