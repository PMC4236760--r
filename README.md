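# crnemu

Tools for relating the **structure** and the **kinetics** of chemical
reaction networks (CRNs) through network morphisms, for systems biologists
and CRN theorists who want to show that a complex network *emulates* a
simpler one — reproduces its mass-action trajectories exactly, for every
choice of the simpler network's rates and initial conditions — and to
certify that claim by matrix algebra instead of simulation.

## The idea

A CRN is a species set $S$ with irreversible reactions
$\rho \to^{k} \pi$ under mass action.  Its structure is captured by the
reactant matrix $\rho(s,r)$ and the *instantaneous stoichiometry*
$\varphi(s,r) = k_r(\pi_s - \rho_s)$, which is the state-independent
factor of the ODE system
$F(v)(s) = \sum_r \varphi(s,r)\, v^{\rho_r}$.

A morphism between two networks is a pair of total maps
$m_S : S \to \hat S$, $m_R : R \to \hat R$ with characteristic 0–1
matrices $\mathbf m_S, \mathbf m_R$.  Two static conditions can be read
off the matrices:

* **reactant morphism** —
  $\mathbf m_S^{\mathsf T}\boldsymbol\rho = \hat{\boldsymbol\rho}\,\mathbf m_R^{\mathsf T}$;
* **stoichiomorphism** —
  $\boldsymbol\varphi\,\mathbf m_R = \mathbf m_S\hat{\boldsymbol\varphi}$
  (stoichiometry preserved over reaction fibers).

**Emulation theorem**: a morphism satisfying both is a *kinetic
emulation*: $F(\hat v \circ m_S) = \hat F(\hat v) \circ m_S$ for every
target state $\hat v$, so source trajectories started at *copied* (never
summed) initial conditions retrace the target's trajectories exactly.  A
**change-of-rates theorem** lifts any re-rating of the target across a
stoichiomorphism ($k' = k\,\hat k'/\hat k$; for homomorphisms: copy the
rates), and steady states transfer from target to source.

The package also compiles **influence networks**
(activation/inhibition diagrams) into CRNs through the *triplet motif* —
three species per node (active $x_0$, intermediary $x_1$, inactive
$x_2$) with catalyzed ladder transitions — whose steady-state response is
a generalized Hill function of coefficient 2, derived from mass action
rather than postulated.

## Worked example: mutual inhibition emulates approximate majority

The bundled MI network (two nodes inhibiting each other and activating
themselves) compiles to 6 species and 8 reactions; the bundled AM network
(approximate majority) is the 3-species, 4-reaction bistable switch.
Collapsing MI with `y` mapped directly and `z` mapped *dually*
(`z_0 -> x_2`, `z_2 -> x_0`) is a homomorphism and stoichiomorphism, hence
an emulation:

```r
library(crnemu)
m <- builtin_fixture("mi_to_am_morphism")$network
m$source
#> Chemical reaction network: 6 species, 8 reactions
#> species: y_0 y_1 y_2 z_0 z_1 z_2
#>    y_0 + y_1 ->{1} 2y_0
#>    y_0 + y_2 ->{1} y_0 + y_1
#>    ...
check_emulation_trajectory(m, c(x_0 = 1.2, x_1 = 0.1, x_2 = 0.9))
#> Emulation report
#>   reactant morphism:    TRUE
#>   homomorphism:         TRUE
#>   stoichiomorphism:     TRUE
#>   derivative residual:  5.551e-17
#>   trajectory deviation: 1.221e-14 (tol 1e-06)
#>   verdict:              TRUE
```

The derivative residual and trajectory deviation sit at machine/solver
precision: MI's six trajectories overlap AM's three in pairs, exactly.
Searching for this morphism instead of postulating it:

```r
found <- find_emulations(builtin_fixture("mi")$crn,
                         builtin_fixture("am")$network,
                         respect_triplets = TRUE)
length(found)   # 2 — the dual-collapse morphism and its mirror image
```

And the triplet motif's input–response curve:

```r
triplet_steady_state(c(1, 1, 1, 1), a = 1, b = 1)
#>     x0     x1     x2
#> 0.3333 0.3333 0.3333
hill_coefficient()
#> [1] 1.99817   # limiting log-log slope: Hill coefficient 2
```

Counterexamples with the opposite verdicts (homomorphisms that are not
stoichiomorphisms and visibly diverge in simulation, and a
non-homomorphic emulation that trades rates against stoichiometry) are
available as `builtin_fixture("fig6b")`, `"fig6d"`, `"fig6f"`.

## Command line

A thin wrapper over the same functions is installed at
`system.file("exec", "crnemu", package = "crnemu")`:

```sh
crnemu check   --source mi.crn --target am.crn --map map.json   # exit 0/1
crnemu emulate --source mi.crn --target am.crn --map map.json --seed 1
crnemu compile mi.json --o mi.crn
crnemu simulate net.crn --init init.json --t 50 --csv traj.csv
crnemu search  --source mi.crn --target am.crn
crnemu fixtures list
```

Networks travel as plain-text `.crn` reaction lists
(`2A + B ->{1.5} B + C`, one per line, optional `species:` header);
influence networks, morphism maps, states and rates as small JSON files.
Reports are JSON with per-condition verdicts and failing witnesses.

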