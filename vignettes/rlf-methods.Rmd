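---
title: "Robust Lyapunov functions for reaction networks: models, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Lyapunov functions for reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnlyap)
```

## The model and its assumptions

A chemical reaction network has species $X_1,\dots,X_n$ and reactions
$R_j:\ \sum_i \alpha_{ij} X_i \to \sum_i \beta_{ij} X_i$, $j = 1,\dots,\nu$,
with nonnegative integer coefficients collected in the reactant matrix $A$,
the product matrix $B$, and the stoichiometry matrix $\Gamma = B - A$.
A reversible reaction is stored as two adjacent columns (forward, then
reverse). Concentrations evolve as $\dot x = \Gamma R(x)$.

The package never assumes a functional form for $R$. It assumes only
*admissibility*: each $R_j$ is $C^1$, depends exactly on its reactants
($\partial R_j/\partial x_i \ge 0$, $\equiv 0$ for non-reactants, $> 0$ at
positive concentrations), and vanishes when a reactant is absent.
Mass-action, Michaelis–Menten and Hill kinetics are admissible, and
`make_kinetics()` implements all three for simulation-based validation.

A **Robust Lyapunov Function** (RLF) is a locally Lipschitz
$\tilde V : \mathbb{R}^\nu \to \mathbb{R}_{\ge 0}$ with
$\tilde V(r) = 0 \iff r \in \ker\Gamma$ whose composition
$V(x) = \tilde V(R(x))$ is nonincreasing (in the Dini sense at kinks) along
every trajectory of every admissible kinetics. Existence of an RLF makes the
network *structurally attractive*: multistability, oscillation and chaos are
excluded by the reaction graph alone, and claims are always relative to a
stoichiometric class (the affine slice with fixed conserved totals).

The computational handle is the extremal decomposition. In rate coordinates
$r = R(x(t))$,
$\dot r = \rho(t)\,\Gamma\,r$ with $\rho(t) = \partial R/\partial x$ an
unknown nonnegative matrix supported on the reaction–reactant pairs
$P = \{(j,i): \alpha_{ij} > 0\}$. Writing
$Q_\ell = e_{j_\ell} \gamma_{i_\ell}^{\mathsf T}$ ($\gamma_i$ = row $i$ of
$\Gamma$), every admissible rate Jacobian lies in
$\mathrm{cone}(Q_1,\dots,Q_s)$, $s = \mathrm{nnz}(A)$, so an RLF is exactly
a common Lyapunov function for the $s$ rank-one linear systems
$\dot r = Q_\ell r$. All constructions below search that finite object.

## Construction methods

### Graphical Max–Min (`graphical_maxmin`)

If the reversible reactions can be oriented so that the irreversible
subnetwork's stoichiometry $\tilde\Gamma$ has a one-dimensional kernel
spanned by $w \ge 0$ (an *M-network*), and in the oriented subnetwork
(i) every species is a reactant of exactly one reaction and (ii) no product
of an oriented reversible reaction is produced elsewhere, then
$\tilde V(r) = \max(\mathcal R) - \min(\mathcal R)$ is an RLF, where
$\mathcal R$ collects $(r_j - r_{-j})/w_j$ for oriented reversible
reactions and $r_j/w_j$ for irreversible ones. The orientation search is
exhaustive over the $2^{\#\text{pairs}}$ sign choices (fixed lexicographic
order, forward-as-written first), and the side conditions are re-tried for
every acceptable orientation rather than only the first, because condition
(i)–(ii) can hold for one valid orientation and fail for another.

Two deliberate conventions:

* **Zero-flux orientations.** When no orientation yields a one-dimensional
  kernel but some orientation has $\ker\tilde\Gamma = \{0\}$ (pure binding
  networks), the decomposition is accepted with all weights 1 and the
  constant $0$ appended to $\mathcal R$; this reproduces
  $V = |r_1 - r_{-1}|$ for the simple binding reaction. In that case
  condition (i) is relaxed to "at most one reaction per species", since a
  complex that is never consumed in the oriented subnetwork is harmless.
* For verification and sampling the Max–Min function is expanded into its
  convex max form $\max_{a\ne b} (u_a - u_b)^{\mathsf T} r$.

### Sum-of-currents LP (`construct_soc`)

$\tilde V = \sum_i \xi_i |\dot x_i| = \|\mathrm{diag}(\xi)\,\Gamma r\|_1$
with positive weights $\xi$. On the region of rate space with current
signature $\sigma$, decrease along the extremal of pair $(j,i)$ reduces to
the linear inequality
$\sigma_i \sum_{i'} \sigma_{i'} \xi_{i'} \Gamma_{i'j} \le 0$, so all
weights come from one LP over the regions with nonempty interior
(constraints deduplicated; they repeat heavily across regions). Weights are
normalized to $\xi \ge 1$, the sum is minimized for determinism, and the
vertex is scaled to small integers when the entries are rational with
denominator $\le 64$.

Sum-of-currents weights are **not unique**: for the transcription motif the
minimal solution $(1,1,1,1)$ and the larger $(1,1,1,3)$ both pass the LP
verifier, a $5\times10^4$-sample decrease oracle, and Dini checks along
simulated trajectories. The package returns the sum-minimal vertex; tests
that compare against externally reported weight vectors should verify the
reported vector as a certificate rather than expect equality.

### General piecewise linear LP (`construct_pwl_lp`)

Over a conic partition $W_k = \{r : \Sigma_k H r \ge 0\}$ induced by a
partitioning matrix $H$ with $\ker H = \ker\Gamma$ (default $H = \Gamma$;
rows $\gamma_i \pm \gamma_j$ are useful refinements), the candidate is
$\tilde V(r) = |c_k^{\mathsf T} r|$ on $\pm W_k$ with
$c_k^{\mathsf T} = \xi_k^{\mathsf T}\Sigma_k H$, $\xi_k \ge 0$,
$\mathbf 1^{\mathsf T}\xi_k = 1$ (the strict positivity normalization), and
decrease certified per extremal by a Farkas multiplier
$c_k^{\mathsf T} Q_\ell = -\lambda_{k\ell}^{\mathsf T}\Sigma_k H$,
$\lambda_{k\ell}\ge 0$. Continuity on the steady-state set,
$(c_k - c_j)^{\mathsf T}v = 0$ for $v \in \ker\Gamma$, holds automatically
because $\ker H = \ker\Gamma$.

**Facet continuity is enforced explicitly.** A regionally decreasing
piecewise function that is discontinuous across a region facet is not a
Lyapunov function, and the constraint set above does not prevent that: on
the open receptor-gated modification cycle a discontinuous "certificate"
exists that demonstrably increases along simulated trajectories. The
implementation therefore adds $c_k - c_j = \eta\, h$ for every pair of
regions adjacent across a facet with normal $h$ (facets detected by
signature Hamming distance one plus a relative-interior LP), mirroring the
continuity constraint that the piecewise *quadratic* program carries, and
`verify_pwl` rejects facet-discontinuous regional candidates. With this
constraint the open network is reported `infeasible` over the default
partition (verdict: inconclusive), while every certified benchmark still
constructs and verifies.

The construction runs a cheap per-region feasibility sweep first (so
infeasibility — the informative negative result — is detected early), then
one joint LP; the returned vertex is the average of vertices optimal for a
small fan of objectives anchored at each region's Chebyshev-style center,
which avoids rank-deficient solutions without randomness. A feasible
program whose solution has $\mathrm{rank}(C) < \mathrm{rank}(\Gamma)$ is
reported `feasible_degenerate`, never silently accepted.

### Piecewise quadratic SDP (`construct_pwq_sdp`)

$\tilde V(r) = r^{\mathsf T}P_k r + 2c_k^{\mathsf T}r$ on $W_k$. Exact
copositive programming is NP-hard, so positivity and decrease on each
region are relaxed into a PSD block plus an entrywise-nonnegative block;
continuity across facets and vanishing on $\ker\Gamma$ are affine. Two
routes:

* an explicit feasible point lifted from a facet-continuous piecewise
  linear certificate ($P_k = c_k c_k^{\mathsf T}$, $c_k = 0$), with all
  certificate blocks in closed form and residuals reported (exactly zero
  for sum-of-currents seeds), and
* alternating projections between the affine constraint set and the cone
  product (PSD blocks by eigenvalue clipping, symmetric and nonnegative
  blocks by symmetrization/clipping), with the total trace of the $P_k$
  pinned to remove the trivial zero solution and a sampled kernel
  post-check. Projections cannot prove infeasibility; a stall is reported
  as "no certificate found under this relaxation".

### Iterative row growth (`iterate_convex`)

Starting from $C = \Gamma$, each processed row $c_k$ proposes
$c^* = c_k + \mathrm{sgn}(c_{kj})\gamma_i$ for every reaction $j$ in its
support and reactant $i$ of $j$; new rows are appended under exact integer
deduplication, and success is a full pass that adds nothing, giving the
convex RLF $\tilde V(r) = \max(0, \max_k c_k^{\mathsf T} r)$. The
iteration needs neither a positive flux nor non-autocatalysis, but it need
not terminate: on the translation network the recursion closes only for
the core without the free protein (the published three-piece function is
exactly that case); with the protein included the rows grow without bound
and the run is reported `not_converged` — inconclusive, not a refutation.

## Necessary conditions

* **P0 (`check_p0`).** If a PWL RLF exists, every principal minor of the
  negative species Jacobian $-\Gamma M(\rho)$ is nonnegative for all
  $\rho \ge 0$. Each minor is multilinear in $\rho$ and the coefficient of
  each monomial is the exact integer determinant of a column-selected
  submatrix of $-\Gamma$; because each monomial corresponds to exactly one
  reactant assignment, coefficients cannot cancel, so one negative
  coefficient is decisive and yields a numeric witness ($\rho = 1$ on the
  assigned pairs, $\varepsilon \to 0$ elsewhere). The verdict is
  `pass`/`fail` exactly for networks up to the size cap (default 12
  species) and `undetermined` beyond it.
* **Critical siphons (`siphon_analysis`).** Minimal siphons are enumerated
  over the subset lattice with minimality pruning; a siphon is trivial if
  it contains the support of a nonnegative conservation law (an LP per
  siphon). Under a positive steady-state flux, a critical siphon precludes
  a PWL RLF if it is a deadlock, or if the network is a conservative
  M-network, or conservative and robustly non-degenerate; the last clause
  instantiates "some admissible kinetics" at unit pair weights, the same
  single-point evaluation the non-degeneracy theorem licenses, and reports
  are flagged accordingly.
* **Robust non-degeneracy (`check_robust_nondegeneracy`).** The reduced
  Jacobian on $\mathrm{Im}\,\Gamma$ at $\rho = \mathbf 1$, with the
  determinant computed exactly in integer arithmetic.

## Quantitative use of certificates

Level sets of an RLF are **safety sets**. `safety_level()` minimizes
$V$ over the slice of a stoichiometric class where a watched species equals
its bound, by multi-start local search over the class's null-space
parameterization; since the optimizer is local, the returned $\alpha$ is an
upper-bound certificate and is meant to be paired with trajectory
falsification (as in the tests).

`flux_bound()` maximizes a flux subject to
$\|C r\|_\infty \le \|C r_0\|_\infty$, $r \ge 0$ and a cap on the inlet
flux. Two choices of $C$ for a sum-of-currents certificate
$\sum_i \xi_i|\dot x_i|$ are exposed: the exact sign-enumerated expansion
(`soc_to_infnorm`), whose level set gives the tighter bound, and the matrix
$C = \mathrm{diag}(\xi)\Gamma$ taken literally, i.e. the infinity norm of
the weighted currents, which reproduces the reported bound of
$3\,r_1^*$ for the $N = 2$ proofreading chain (the sign-enumerated level
set gives $2\,r_1^*$). Caveat, stated openly: for that network
$\|\mathrm{diag}(\xi)\dot x\|_\infty$ itself does not pass the
extremal-cone decrease verification, so the $3\,r_1^*$ bound rests on a
level set that this package cannot certify as forward-invariant for all
admissible kinetics, while the $2\,r_1^*$ bound does come from a certified
function.

`rate_to_concentration()` converts a rate-space certificate $(C, H)$ into
concentration coordinates via the minimum-norm solutions of $C = B\Gamma$,
$H = G\Gamma$; the result is a Lyapunov function for $x - x_e$ inside the
stoichiometric class of a steady state $x_e$, unique only up to adding
multiples of the conservation laws (the returned $D$ spans them).

## Numerical choices

* All structural linear algebra (kernels, ranks, minors, conservation
  laws) is fraction-free integer arithmetic; floating point enters only in
  optimization and simulation.
* LPs are solved by a deterministic two-phase dense simplex with Bland's
  rule (no dedicated LP package is required); region interiority uses a
  strict margin of $10^{-6}$ inside the unit box, verification tolerates
  violations up to $10^{-8}$, and the SDP routes use $10^{-7}$ residuals.
  Signature enumeration over $2^p$ is pruned by a prefix DFS pre-seeded
  with sampled sign patterns and refuses partitions beyond 20 rows;
  partition-based constructions are intended for networks up to roughly a
  dozen species (the graphical and iterative routes have no such limit).
* Sampling oracles (decrease, kernel, quadratic decrease) draw standard
  normal rate vectors and uniform pair weights; for piecewise linear
  functions the one-sided difference quotient at a small step equals the
  Dini derivative exactly, so these checks are sharp.
* `steady_state()` solves $\Gamma R(x) = 0$ with the class constraints by
  Levenberg–Marquardt, warm-started from a simulation, and reports the
  exact residual; `simulate_network()` uses a stiff-capable integrator with
  conservation drift monitored on every run.

## What the benchmark catalog does and does not show

The fixture catalog regenerates the standard worked networks
(binding motifs, transcription/translation, modification cycles and
cascades, phosphotransfer and relay chains, proofreading, ERK/RKIP,
ribosome flow) with frozen species orderings, plus a generator of random
sparse networks used for property tests (deficiency nonnegativity, siphon
enumeration against an all-subsets oracle). These are *structural*
benchmarks: passing them shows the algorithms reproduce the known
certificates and exclusions at desk scale, under mass-action,
Michaelis–Menten and Hill kinetics with randomized constants. They do not
probe behavior that real data would add — measurement noise, unmodelled
reactions, non-monotone regulation, or stochastic (low-copy) effects, all
outside the admissible-kinetics class.

Test and validation problem sizes are deliberately modest so the whole
suite runs in minutes on one core: sampling oracles use $10^4$ draws
($5\times10^4$ where a published function is being adjudicated),
mono-attractivity uses 10 initializations per class at horizon 3000,
the bistability search for the distributive double cycle uses 40 parameter
draws (log-uniform constants over $[10^{-1.5}, 10^{1.5}]$, substrate total
10 against enzyme totals 3.3 and 2.7 — a substrate-dominated regime chosen
once as the physiologically natural one for a futile cycle), and the
random-network property checks use 50–1000 instances depending on cost.

## Known limitations

* Per-partition infeasibility of the PWL LP never proves that *no* PWL RLF
  exists over any partition; only the necessary conditions (P0, critical
  siphons) give unconditional exclusions.
* The facet-continuity constraint uses the same-sign pairing
  $c_k - c_j \propto h$; a hypothetical certificate continuous only under
  the opposite pairing on some facet would be missed (none of the
  benchmarks needs it, and the verifier accepts either pairing).
* The quadratic route is a relaxation (PSD + nonnegative in place of
  copositive) solved by alternating projections: failures are "not found",
  never "not existing".
* The iterative algorithm may diverge; divergence is inconclusive.
* Global-stability conclusions beyond "unique steady state + RLF decrease"
  (e.g. LaSalle-type arguments on degenerate classes) are reported as
  theorem-implied flags, not re-derived.
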