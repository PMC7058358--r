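# crnlyap

Kinetics-independent stability certificates for chemical reaction networks.

## The problem

Most models of cellular processes — binding, enzymatic modification,
transcription and translation, signalling cascades — are chemical reaction
networks whose *stoichiometry* is well known but whose *kinetics* (rate laws
and constants) are not. `crnlyap` asks what can be concluded from the
stoichiometry alone: given only the reactant matrix `A`, the product matrix
`B` and the net stoichiometry `Γ = B − A`, can the network be certified
**structurally attractive** — incapable of multistability, oscillation or
chaos under *every* admissible kinetics (mass-action, Michaelis–Menten,
Hill, or any smooth rate that is monotone in its reactants and vanishes
without them)?

The certificate is a **Robust Lyapunov Function** (RLF): a function
`Ṽ(R(x))` of the reaction rates that vanishes exactly on the steady-state
set `{r : Γr = 0}` and is nonincreasing along the trajectories of
`ẋ = Γ R(x)` for every admissible `R`. The key reduction is that the rate
dynamics `ṙ = (∂R/∂x) Γ r` are embedded in the convex cone spanned by a
finite set of rank-one matrices `Q_ℓ = e_{j} γ_i'`, one per
reaction–reactant pair `(j, i)`; a common Lyapunov function for these `s`
linear systems is an RLF for the network, and that is a finite,
optimization-sized problem.

## What the package does

* **Parse / build networks** from a plain-text reaction list
  (`parse_network`) or stoichiometric matrices, with conservation-law,
  flux-kernel and deficiency analysis in exact integer arithmetic.
* **Construct RLFs** four ways:
  * `graphical_maxmin()` — for M-networks, `V = max(R) − min(R)` over the
    net reaction rates (pure graph conditions, no optimization);
  * `construct_soc()` — weighted sum-of-currents `V = Σ ξ_i |ẋ_i|` by one
    linear program;
  * `construct_pwl_lp()` — general piecewise linear-in-rates `V = |c_k'r|`
    over a conic partition of rate space, by a joint LP with positivity,
    decrease, and facet-continuity certificates;
  * `construct_pwq_sdp()` — piecewise *quadratic*-in-rates certificates by
    a positive-semidefinite + nonnegative relaxation of the copositive
    feasibility problem.
* **Rule RLFs out**: exact P0 test on the negative Jacobian (`check_p0`),
  minimal-siphon enumeration and critical-siphon preclusion
  (`siphon_analysis`), robust non-degeneracy (`check_robust_nondegeneracy`).
* **Validate numerically**: every certificate can be re-verified by LP
  (`verify_pwl`), by sampling admissible directions
  (`sampled_decrease_check`), and along simulated trajectories of concrete
  kinetics (`simulate_network`, `dini_decrease_check`).
* **Use certificates quantitatively**: safety level sets (`safety_level`),
  kinetics-independent flux bounds (`flux_bound`), steady states within a
  stoichiometric class (`steady_state`), and conversion of rate-space
  certificates to concentration coordinates (`rate_to_concentration`).
* A catalog of benchmark networks (`fixture()`): modification cycles and
  cascades, phosphorelays, kinetic proofreading, ERK/RKIP, the ribosome
  flow model, and more.

## Worked example

The phosphorylation–dephosphorylation cycle: a kinase E phosphorylates a
substrate S through a complex SE, and a phosphatase F reverses it.

```r
library(crnlyap)
net <- parse_network("
  S + E <-> SE
  SE -> S+ + E
  S+ + F <-> S+F
  S+F -> S + F")
analyze_network(net)
#> == Network analysis report ==
#> species 6 | reactions 6 | conservative TRUE | laws 3 | positive flux (AS1) TRUE | deficiency 1
#> P0 screen: pass
#> Minimal siphons: 3 (0 critical)
#> Robustly non-degenerate (rho = 1): TRUE
#>   method maxmin  : ok [verified]
#> VERDICT: ATTRACTIVE
```

The verdict means: for *any* admissible kinetics, this network has a unique
steady state in each stoichiometric class (fixed totals of substrate and of
the two enzymes) and it is globally stable there. The certificate is the
Max-Min function `V = max(R) − min(R)` with
`R = {R1−R−1, R2, R3−R−3, R4}` — the spread of the four net loop rates —
re-verified internally by the LP verifier. Deficiency is 1, so classical
deficiency-zero theory says nothing here; the certificate is
kinetics-independent.

With concrete mass-action kinetics (all constants 1) and totals
`[S]_T = [E]_T = [F]_T = 10`, the steady state inside that class is

```r
kin <- make_kinetics(net, "mass_action", k = 1)
steady_state(net, kin, x0 = c(10, 10, 0, 0, 10, 0))$x_e
#>        S        E       SE       S+        F      S+F
#> 1.216991 6.216991 3.783009 1.216991 6.216991 3.783009
```

i.e. free substrate `(−7 + √89)/2 ≈ 1.216991`, and the RLF's level sets are
safety sets: `safety_level()` returns the largest level `α` such that
trajectories starting with `V < α` never drive S above a chosen bound.

By contrast, `analyze_network(fixture("distributive_double"))` — the
double modification cycle with a *distributive* mechanism — is excluded:
a principal minor of the negative Jacobian can be made negative
(P0 failure), no piecewise linear RLF exists, and the package exhibits
bistable mass-action parameters for it by randomized search
(`find_bistability`).

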