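---
title: "Analyzing synchronized clusters in multi-layer neuron networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing synchronized clusters in multi-layer neuron networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`clustersync` analyzes exact cluster synchronization in networks of the form

$$\dot{x}_i \;=\; \tilde f_i(x_i(t)) \;+\; \sum_{k=1}^{L} \sigma^k
\sum_{j=1}^{N} A^k_{ij}\, h^k\!\big(x_i(t),\, x_j(t-\delta_k)\big),
\qquad i = 1,\dots,N,$$

where each node is a neuron with an $n$-dimensional state $x_i$ (first
component: the membrane potential $V_i$), $\tilde f_i$ is one of $M$ node
models, and each connection layer $k$ carries its own weighted, possibly
directed adjacency matrix $A^k$ (entry $A^k_{ij}$: weight of the link
$j \to i$), global strength $\sigma^k$, transmission delay $\delta_k$, and
coupling function $h^k$.  Only the membrane-potential component of $h^k$ is
nonzero; its scalar *activation* $a^k(V_i, x_j)$ may depend on both the
post- and the presynaptic side (chemical synapses) or on their difference
(gap junctions), and dynamical chemical synapses carry their gate variable
inside the presynaptic node's state.

A group of nodes can stay exactly synchronized for all time only if it is an
*equitable cluster* (EC): every member must receive, in every layer, the
same total weight from every cluster.  The analysis proceeds in three steps.

**S1 — coarsest equitable partition.**  `refine_equitable()` iterates color
refinement on received-weight signatures: starting from the node-type
partition, each node is re-colored by the vector of weights it receives from
every current color in every layer, until a fixpoint.  The fixpoint is the
coarsest equitable partition refining the node types; an exhaustive search
over all set partitions (feasible up to $N = 8$) is used as the test-suite
oracle.  Signatures are compared with an absolute tolerance of $10^{-9}$,
appropriate because measured connectomes are typically quantized to a few
weight levels; clusters are renumbered by smallest member so results are
deterministic.

**S2 — quotient dynamics.**  Collapsing each cluster to one node gives the
quotient matrices $R^k_{qp}$ (the received weight any member of $C_q$ gets
from $C_p$) and a $Q$-node delayed system whose solution
$s(t) = (s_1(t),\dots,s_Q(t))$ is the synchronous motion; lifting it
(`lift_trajectory()`) gives an exact solution of the full network, which is
the flow-invariance property the test suite checks to $10^{-6}$.

**S3 — transverse stability.**  An orthonormal change of coordinates $T$
(normalized cluster indicators first, per-cluster complements below;
`build_transform()`) block-diagonalizes the perturbation dynamics.  In these
coordinates $B^k = T A^k T^\mathsf{T}$ and every projector
$J_q = T E_{C_q} T^\mathsf{T}$ is diagonal, so the linearized equation
splits into a part along the synchronous manifold (first $Q$ components)
and independent transverse sub-blocks, each a small linear delay system
driven by $s(t)$ through the model Jacobians $Df_q$ and the coupling
derivatives $D_1 h^k$, $D_2 h^k$.  The maximum Lyapunov exponent
$\Lambda_m$ of each sub-block decides stability: a cluster is stable iff
the largest exponent over the sub-blocks that touch it is negative.
Clusters sharing a sub-block are *intertwined* — they can only lose
stability together through that block.

The construction applies to undirected networks and to two directed
regimes: all clusters of size at most two (class A, where the transverse
row of each pair is forced), and networks whose asymmetric links all touch
trivial clusters (class B, which reduces to the undirected construction on
the non-trivial clusters).  Classification checks undirected, then B, then
A: a network satisfying both directed conditions is reported as B because
the class-B reduction is the structurally stronger statement.

## Lyapunov estimation

`block_mle()` integrates a block's perturbation from a random unit initial
state along the stored synchronous trajectory.  Following the sign-focused
stopping rule, integration halts when the perturbation norm exceeds
$\bar\varepsilon = 10^4$ (unstable) or drops below
$\underline\varepsilon = 10^{-4}$ (stable).  When neither threshold
triggers within `t_max`, the exponent is the least-squares slope of the
log-norm over the last half of the run and the result is flagged
*marginal* when $|\Lambda| < 0.01$ — the threshold rule alone cannot
terminate in the $\Lambda \approx 0$ case (for example a cluster that
receives no synaptic input, whose transverse exponent is the neutral phase
exponent of the isolated limit cycle, exactly zero).  Three random initial
directions are used by default and the maximum is reported.  The marginal
band of $0.01$ per time unit is deliberately coarse: it discriminates the
structurally neutral case from genuine contraction, but slow gating
variables (e.g. a $\tau_\chi = 9400$ ms gate, whose transverse decay rate
is $-1/\tau_\chi \approx -10^{-4}$) legitimately produce small negative
exponents that carry the marginal flag while still being correct sign
verdicts.

`direct_check()` validates the variational verdicts independently: it
integrates the *full* network from the lifted synchronous state plus a
small transverse perturbation and watches the intra-cluster spread
(resynchronization below $10^{-6}$ versus divergence above 1).

## Numerical choices

* **Integrator.**  Classical fixed-step RK4 with the method of steps:
  the step is reduced so every positive delay is an integer multiple of it,
  delayed states are read from a ring-buffer history by cubic Hermite
  interpolation (states and derivatives stored, so dense output has the
  integrator's order), and zero-delay layers are evaluated at the current
  RK4 stage.  A fixed step keeps Lyapunov estimates reproducible and makes
  delays exact on the grid.  The pure-R `integrate_dde()` implements the
  same scheme for arbitrary right-hand sides and doubles as a
  cross-validation oracle for the compiled network integrator (which is
  also checked against `deSolve::dede` in the test suite).
* **Steps.**  0.01–0.02 ms for the conductance-based circuit, 0.05 time
  units for Hindmarsh–Rose networks (1 time unit is identified with 1 ms so
  delays in ms are directly comparable).  Halving the step reduces the
  error on smooth linear tests by $\approx 2^4$.
* **Reference trajectory.**  The quotient trajectory is precomputed and
  stored on a decimated uniform grid (every 5–10 steps) with derivatives,
  and the variational coefficients interpolate it; long transients are
  integrated without storage.  Decimation keeps the stored window of the
  cortical case study around 100 MB.
* **Transients and windows.**  19.5 s transient and a 20 s analysis window
  for the cortical network; 10 s and 20 s for the swim circuit.  The
  scaled-down parameter sweeps in the tests use shorter windows (6–8 s),
  which is enough to resolve the sign structure away from bifurcation
  boundaries.
* **Transverse basis refinement.**  For clusters with several transverse
  directions the basis is refined by a randomized simultaneous
  block-diagonalization sweep restricted to per-cluster rotations
  (eigenvectors of a random symmetric combination of the transverse
  blocks).  Restricting to per-cluster rotations preserves the exact
  diagonality of every $J_q$, which the variational equation requires; the
  price is that on adversarial inputs the resulting common block structure
  can be coarser than the true minimum.  Both case studies have only
  size-2 clusters, whose transverse rows are forced, so their block
  patterns are exact.  The block *pattern* (not the basis) is checked to be
  independent of the refinement seed.
* **Delay sweeps.**  The command-line `sweep` over the cortical network
  defaults to eight evenly spaced delays on the inclusive grid
  $[0, 16]$ ms ($0, 2.29, \dots, 16$); endpoints are configurable.
* **Zero thresholds.**  Structural decisions (symmetry, zero entries of
  $B^k$) use $10^{-9}$ absolute on weights and $10^{-8}$ relative to
  $\max|B^k|$ on transformed entries.

## Model library

* **Swim-circuit neuron** (`swim`, $n = 7$): a Plant-type bursting model —
  V, Na-inactivation h, K-activation n, a slow Ca-channel gate $\chi$
  ($\tau_\chi = 9400$ ms), intracellular Ca, plus the two dynamical
  chemical-synapse gates $s_1, s_2$.  Gating rates use the classical
  squid-axon functional forms evaluated at the affine transform
  $V_s = (127V + 8265)/105$; $\alpha_n$ carries the canonical $0.01$ rate
  scale of that kinetics family (without it the K gate is ~70% activated
  at rest and the cell cannot spike).  Two constants deserve note:
  `V_Ca_rev` (the I$_{Ca}$ reversal, +140 mV) and `V_Ca_drive` (the
  driving value in the Ca-removal equation) are distinct parameters; the
  default sets both to +140 mV because a strongly negative drive value
  pushes Ca below $-0.5$ where the
  $\mathrm{Ca}/(0.5+\mathrm{Ca})$ term of I$_{KCa}$ is singular.
  `g_KCa` has no established value for this circuit; the default
  (0.005 nS) was chosen once so the isolated neuron fires periodically
  (~0.6 Hz) and was not revisited.  The $\chi$ gate midpoint and slope are
  exposed (`chi_V0`, `chi_k`; defaults +40 mV, 0.3/mV).  The synapse-gate
  equation has a $1/(1 - s_\infty)$ factor; $s_\infty$ is clamped at
  $1 - 10^{-9}$ (the tanh saturates well outside the reachable voltage
  range, so the clamp never binds in practice).
* **Hindmarsh–Rose** (`hr`, $n = 3$): $b = 2.7$, $\mu = 0.01$, $s = 4$,
  $x_{rest} = -1.6$; $I = 2$ for ordinary nodes and $I = 3$ for the
  visually driven one.
* **Synapses:** dynamical inhibitory ($E^1 = -80$ mV) and excitatory
  ($E^2 = 0$ mV) chemical kinds whose activation is $(E^k - V_i)s_{k,j}$;
  electrical/diffusive $V_j - V_i$; fast threshold modulation
  $(E - V_i)/(1 + e^{\nu(V_j - \theta)})$ with $E = 2$, $\nu = 10$,
  $\theta = -0.6$ (overflow-safe); and a bare `direct` kind $a = V_j$
  used for delayed-feedback test problems.  Analytic Jacobians of every
  model and kind are verified against central differences at $10^{-4}$.

Nodes of different models are padded to a common state dimension; padded
components are masked to exact zero in both the flow and the variational
system, and excluded from perturbation norms — they would otherwise
contribute spurious null exponents.

## The case-study fixtures

The shipped coupling matrices are *synthetic reconstructions* (see
`inst/extdata/README.md`): they were constructed once to satisfy every
published structural property of the two circuits — for the swim central
pattern generator of *Dendronotus iris*: three contralateral size-2
clusters, directed class A, per-layer transverse block patterns
$\{1,1,1\}$ (inhibition), $\{1,2\}$ (excitation), $\{3\}$ (gap junctions),
all clusters intertwined; for the 29-area macaque cortical network:
quantized weight levels $(0, 0.1, 0.5, 1)$, a short-range undelayed and a
long-range delayed layer, exactly three non-trivial clusters (an
input-free pair, the prefrontal pair 8l/9-46v, the inferotemporal pair
TEO/TEpd), class B, pairwise non-intertwined, and four fully disconnected
areas.  Free quantities that no structural statement pins down (the
trivial-area backbone wiring, the coupling strength $\sigma = 0.25$ of the
cortical layers, the 0.1 level of the two pair couplings) were fixed once
so that the known dynamical regimes appear: all swim clusters stable with
chemical coupling removed and all unstable at $(\sigma^1, \sigma^2) =
(120, 100)$ nS; the inferotemporal pair synchronized at $\delta_2 = 5$ ms
and desynchronized at 15 ms.  They are reconstruction conditions, not
fitted parameters, and are not adjusted by any test.

**Disconnected nodes.**  A purely input-based equitable refinement would
merge nodes that receive nothing at all — including fully isolated nodes —
into one cluster with any input-free source nodes.  Isolated nodes share
no dynamical constraint whatsoever, so grouping them is vacuous; the
cortical pipeline therefore forces nodes with zero in- *and* out-degree in
every layer into singleton clusters (`force_singleton`), while input-free
nodes that do project into the network (the pair forming cluster C1) may
still synchronize and keep their cluster.  The generic
`refine_equitable()` keeps the pure definition — an edgeless network is
one big equitable cluster.

## The fixture generator

`plant_partition()` lifts arbitrary quotient matrices to full networks
with exactly equal cluster-wise input sums (random link placement inside
each block; symmetric mode uses cyclic stub assignment plus a shared
within-cluster permutation), and `random_planted_network()` draws random
cluster structures over it.  Generated weights stay on a small integer
grid, mirroring the quantized connectomes the method targets; the
generator does not emulate weight noise, parameter heterogeneity beyond
the discrete node types, or stochastic input, so passing tests demonstrate
correctness of the machinery on exactly-equitable networks, not robustness
of real circuits to imperfect clustering.

## Known limitations

* Directed networks outside classes A/B are detected and rejected, not
  analyzed.
* Delays can create additional synchronous solutions (e.g. delays near the
  oscillation period acting like no delay); the analysis covers the
  synchronous solution it integrates, not all coexisting ones.
* The method is deterministic and says nothing about basins of attraction;
  near-zero exponents (the marginal flag) should be treated as "at the
  edge of stability", not as robust verdicts.
* Bifurcation-type classification of the symmetry-breaking transitions is
  out of scope.
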