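---
title: "Fibration symmetries, threshold dynamics and logic circuits in regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibration symmetries, threshold dynamics and logic circuits in regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibnet)
```

## The model

`fibnet` analyses signed, directed gene regulatory networks: nodes are genes,
an edge $r \to g$ means the product of $r$ regulates the transcription of
$g$, and each edge carries a sign — activator, repressor, or unknown. Two
complementary views of such a network are implemented.

**Dynamics.** Expression levels evolve by a discrete-time, continuous-state
threshold model in the Glass–Kauffman tradition. For a gene $g$ with
regulators $r_1, \dots, r_m$,

$$ s_g(t+1) = (1 - \alpha)\, s_g(t) + P_g(t), $$

where $\alpha \in (0,1)$ is the degradation rate per step and the production
term $P_g$ combines one factor per regulator:
$\gamma_r\,\theta(s_r - k_r)$ for an activator and
$\gamma_r\,\theta(k_r - s_r)$ for a repressor, with $\gamma_r$ the maximum
expression rate (expression units per step), $k_r$ the dissociation
threshold (expression units) and $\theta$ the Heaviside step — the Boolean
logic limit of a strongly cooperative Hill input function. An AND gate
multiplies the factors, an OR gate takes their maximum. Input genes are
pinned to a drive signal (constant or square wave): the environment, not the
decay equation, sets their level.

**Structure.** The symmetry view asks which genes receive *isomorphic input
trees* — the rooted tree of all reversed regulation paths into a gene, with
edge signs as labels. Genes with isomorphic input trees synchronize under
the dynamics above; they form a *fiber*, and collapsing each fiber to one
node yields the quotient *base* graph. Fibers are computed as the coarsest
balanced coloring: the coarsest partition in which same-class genes see
identical multisets of (regulator class, edge sign) over their in-edges.
The divergence of an input tree is summarized by its branching ratio
$n = \lim_t Q_{t+1}/Q_t$, where $Q_t$ counts nodes in layer $t$
($Q_1 = 1$). The canonical classes are $n = 1$ (autoregulation loop, AR,
and the feed-forward fiber FFF), $n = \varphi = (1+\sqrt 5)/2$ (the
Fibonacci fiber, whose layers obey $Q_t = Q_{t-1} + Q_{t-2}$) and $n = 2$
(two coupled autoregulators); the general hierarchy satisfies
$Q_t = n\,Q_{t-1} + m\,Q_{t-d}$ for a fiber with $n$ internal loops and $m$
feedback loops of length $d$.

## Worked example: symmetrizing the feed-forward loop

The coherent feed-forward loop (X activates Y and Z, Y activates Z) has no
symmetry and does not synchronize: with $\alpha = 0.2$,
$\gamma_x = 0.12$, $\gamma_y = 0.7$, $k_x = 0.5$, $k_y = 0.1$ and the drive
held above $k_x$, $y_t \to \gamma_x/\alpha = 0.6$ while
$z_t \to \gamma_x\gamma_y/\alpha = 0.42$:

```{r ffl}
spec <- dynamics_spec(alpha = 0.2, gamma = c(X = 0.12, Y = 0.7),
                      k = c(X = 0.5, Y = 0.1))
tr <- simulate_network(make_circuit("FFL"), spec,
                       initial = c(Y = 0.7, Z = 0),
                       drive = list(X = drive_constant(1)), T = 500)
round(tr$levels[501, ], 4)
```

Adding autoregulation on Y makes the input trees of Y and Z isomorphic —
they become one fiber and their expression synchronizes exactly:

```{r fff}
minimal_balanced_coloring(make_circuit("SAT_FFF"))$fibers
```

## The frustrated fiber: oscillation and the phase diagram

When the autoregulation is a repressor the circuit is frustrated: no
high/low state satisfies every signed interaction (`sat_classify` verifies
this by exhaustive search), and the synchronized pair settles into a limit
cycle rather than a fixed point. With the drive above threshold the
rescaled level $\psi_t = y_t / k_y$ obeys the one-dimensional map
$\psi_{t+1} = \beta\psi_t + \alpha\lambda\,\theta(1 - \psi_t)$ with
$\beta = 1 - \alpha$ and the dimensionless gain
$\lambda = \gamma_x \gamma_y / (k_y\, \alpha)$. Its solution is piecewise
exponential with relaxation time $\tau = -1/\log(1-\alpha)$: decay segments
$\psi_t = \psi_s e^{-(t-s)/\tau}$ while $\psi > 1$, relaxation segments
approaching $\lambda$ while $\psi \le 1$, with ceiling switch times such as
$t_1 = \lceil \tau \log \psi_0 \rceil$
(`unsat_fff_closed_form`, checked step-by-step against the iterated map).
For $\lambda < 1$ the map converges monotonically to $\psi_\infty = \lambda$;
for $\lambda > 1$ it oscillates forever. The phase boundary is therefore
$\gamma_y / k_y = (\gamma_x/\alpha)^{-1}$, which `phase_diagram` tabulates
and `oscillation_threshold` recovers numerically by bisection on simulated
trajectories:

```{r lambda}
unsat_fff_analysis(alpha = 0.205, gamma_x = 0.454, gamma_y = 0.454,
                   k_y = 1)[c("lambda", "phase")]
```

## Broken-symmetry circuits and memory

Replica duplication of a fiber conserves its base; breaking the duplicated
symmetry with distinct inputs turns clocks into memory. The three matchers
implement the resulting patterns: `find_sr_flipflops` (mutual repression
Y ⊣ Y′ plus distinct inputs S, R — the toggle switch / SR flip-flop),
`find_clocked_sr_flipflops` (a duplicated FFF: input layer X, X′, a common
clock gene and distinct S, R), and `find_jk_flipflops` (a duplicated
Fibonacci fiber with parity feedback — Y feeds X′ and Y′ feeds X, the
wiring observed in biological networks; the chiral alternative is matched
only on request). Mutual repression must carry repressor signs; peripheral
edges may carry any sign, including unknown, since drawn circuits leave
them unconstrained. Matches are de-duplicated by the unordered replica pair
plus the unordered input set, and overlapping instances are all reported —
counts are per instance, not per disjoint set.

Statistical significance uses a null model preserving each gene's in- and
out-degree *per sign* (`randomize_network`: double-edge swaps within a sign
class, rejected if they would duplicate an ordered pair). Self-loops form
their own invariant class by default — autoregulation is the structural
core of the AR fiber, so a null that dissolved it would not be comparing
like with like; set `preserve_self_loops = FALSE` for the laxer null. The
swap budget defaults to 10× the edge count, a standard mixing heuristic.
Z-scores follow the census-table conventions (population-sd; `N/A` when
nothing is observed; `Inf`, displayed as the bound "> 3" when the null is
exactly 0 ± 0).

## The synthetic generator

`embed_circuits` plants node-disjoint canonical circuits in a random
background and returns the ground truth. Background edges are drawn
uniformly with a 2:1 activator:repressor ratio and about 1.5 edges per
background gene (sparse, in the range of curated transcriptional networks,
whose edge/node ratios sit between roughly 1.6 and 2); they never target a
circuit gene, so planted input trees — hence planted fibers and pattern
matches — survive by construction, and background self-loops are not drawn.
Two deliberate limitations follow. First, the generator does not imitate
the heavy-tailed degree distributions of real regulatory networks, so
passing recovery tests says nothing about match abundance in real degree
structure. Second, planted input genes have in-degree zero and are
therefore mutually indistinguishable to the coloring: separate planted
replicas of the *same* class can merge into one larger fiber, and a planted
flip-flop whose S and R inputs are both root genes retains its structural
symmetry. Recovery is therefore asserted as set-inclusion — every planted
instance appears within a found match of its class — rather than as an
exact count. In real networks regulators carry distinguishing upstream
inputs and this degeneracy is rare.

## Numerical choices

* $\theta(0) = 1$ (active at exact threshold), configurable via
  `theta_at_zero`. The dynamics never visit the boundary for generic
  parameters; fixing the convention makes trajectories reproducible.
* Genes with neither regulators nor drive decay geometrically, as the
  update equation implies for zero production; `undriven = "hold"` is
  available.
* Oscillation detection is state-recurrence with absolute tolerance
  $10^{-9}$ after a burn-in; because the map contracts within each branch,
  convergent transients are flat within tolerance after $\approx 25\tau$
  steps, and limit cycles are detected with their exact period. Bisection
  for the critical gain uses 2000-step trajectories with a half-length
  burn-in.
* Branching ratios are reported at finite depth (default 40 layers, 20 for
  the integer classes), which separates $1$, $\varphi$ and $2$ far beyond
  the 4-decimal reporting precision; layer sizes are tracked as per-gene
  occurrence counts, so deep trees cost linear work.
* Closed-form/map agreement is asserted to $10^{-9}$ per step over 500
  steps; random parameter draws whose switch times fall within $10^{-6}$
  of an integer are re-drawn, since there the ceiling formula and the
  floating-point comparison in the map can legitimately disagree by one
  step.
* The balanced-coloring refinement is verified against an independent
  oracle (explicit canonical forms of depth-$|V|$ input trees) exhaustively
  over all 2-node signed digraphs and all 3-node digraphs with
  activator/repressor signs, and over random samples of 4–6-node graphs
  with all three sign values.
* `sat_classify` enumerates all $2^k$ states of genes with in-edges
  (in-degree-0 genes are pinned high, playing the external drive); circuits
  here have at most 8 genes, and a guard rejects $k > 20$.

## Design decisions that were genuinely open

* **Fiber classification by (n, ℓ).** A fiber is labelled by its branching
  ratio and the number of distinct external regulator *fibers* (not genes)
  feeding it, since extra regulators of the same class leave the dynamics
  confined to the same loop structure. The toggle pair with no inputs
  correctly lands in the AR class |1,0⟩ — it shares the AR's input tree and
  base.
* **The Fibonacci fixture.** `make_circuit("Fibonacci")` is built by adding
  the feedback edge Y→X to the feed-forward fiber (X→Y, X→Z, Y→Y, Y→Z), so
  the fiber is {Y, Z} with X the external regulator outside the base — the
  construction that matches the uxuR/exuR/lgoR example and yields exactly
  one Fibonacci fiber per fixture.
* **Base graphs are signed multigraphs.** A fiber may feed another through
  edges of different signs; the quotient therefore keys multiplicities by
  (source fiber, target fiber, sign) and bypasses the one-edge-per-pair
  rule that input networks must obey.
* **Dual-sign regulation in inputs is an error, not a merge.** Sign drives
  both the dynamics and the balance condition, so an edge list asserting
  both activation and repression for one ordered pair fails loudly.
* **OR gate as maximum.** The saturating alternative
  ($1 - \prod(1 - \gamma_i\theta_i)$) changes none of the circuits studied
  here, which have at most two regulators per target; the maximum keeps
  production bounded by the strongest regulator and reduces to the single-
  regulator case exactly.

## Problem sizes

The shipped tests simulate trajectories of 500–3000 steps, verify the
fibration oracle on ~20 000 exhaustively enumerated small digraphs plus 500
random 4–6-node graphs, compare the three flip-flop finders against brute
force on 200 random 8-node networks, and check planted recovery on 20
seeds of 200-gene backgrounds; null-model runs in tests use 5–25
replicates, while census-scale analyses default to 1000.

## Limitations

Dynamics are deterministic and synchronous — no stochastic (Gillespie)
simulation, no delay-differential continuum model, and no parameter fitting
to expression data. The finders enumerate the seven named circuit classes
only, and species-level census counts require externally curated networks,
which the package reads through `read_edge_list` but does not ship.
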