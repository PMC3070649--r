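---
title: "Elementary signaling modes and component essentiality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elementary signaling modes and component essentiality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmnet)
```

## The problem

Signaling networks are directed graphs whose edges are not interchangeable:
an interaction can activate or inhibit its target, and several interactions
converging on the same component frequently act synergistically — all of them
are required at once. Classical node-centrality measures (betweenness,
path counts, flux-style measures) treat every edge as an independent,
positive conduit, so they systematically mis-rank components in three ways:
they credit inhibitors with transduction they actually block, they credit
redundant-looking routes that are in fact conditionally dependent, and they
ignore the fact that deleting one component can starve downstream components
of an indispensable regulator and so knock out far more than itself.

`esmnet` implements a structural analysis that repairs all three defects
without requiring a parameterized dynamic model. The three steps are network
*expansion*, cascading *disruption*, and counting *elementary signaling
modes* (ESMs).

## Boolean rules and network expansion

Each non-input node $v$ carries a Boolean rule over its regulators, stored in
irredundant disjunctive normal form (an OR of AND clauses of possibly negated
regulators). Truth-table equivalence is the correctness criterion for every
rule manipulation; the canonical form sorts clauses and literals and removes
absorbed and contradictory clauses. Note that irredundant DNF is unique only
up to consensus terms, which is why equivalence — not syntactic identity — is
the contract.

Expansion produces a graph in which **every edge means activation**:

* a *complementary node* `~v` is created for every component with a direct
  inhibitory role; it represents the absence of `v` and is governed by the
  logical negation of `v`'s rule. Negating a rule can itself demand further
  complements; these are created transitively. This closure is deliberately
  broader than the minimal "direct inhibitory role" criterion: it preserves
  overall-activating routes in which two inhibitory edges are separated by
  several activating edges, a case that is otherwise lost. An explicit
  `deep_negation` flag additionally scans such paths and force-creates any
  complement the closure did not already provide; with the transitive closure
  in place it is almost always a no-op, and it is off by default.
* a *composite node* is created for every AND clause with two or more
  literals; its in-edges (one per literal, drawn from the literal's node or
  complement) are jointly required and its single out-edge activates the
  clause's owner.

If negation demands the complement of an input node, that complement is
created as a rule-less constitutive source and reported in the expansion
notes. Under the sustained-input semantics used throughout (the input is held
ON), the absence of an input is never available, so pruning — which keeps
only nodes that are both activatable from an input (AND-aware at composite
nodes) and able to reach an output — always removes it.

A network whose outputs are unreachable after pruning is returned with
`transduces = FALSE` rather than as an error: "this network cannot transduce"
is a legitimate analytical result (the bare inhibition motif `B = not A` with
`A` as the sustained input is the canonical example).

```{r}
net <- parse_network(c("INPUT: A", "OUTPUT: B", "B = not A"))
expand(net, prune = FALSE)$edges   # the two-complement motif
expand(net)$transduces             # sustained A => no transduction
```

## Cascading disruption

Removing an original node simulates a knockout; removing a complementary
node simulates constitutive activation of its original. The disruption
propagates: a target is lost when its sole (or last remaining) regulator is
lost, and a composite node is lost when *any* of its regulators is lost. The
worklist algorithm touches each edge at most once (O(|E|)) and the resulting
disrupted set is independent of processing order; both properties are
exercised in the test suite against a from-scratch fixpoint oracle.

## Elementary signaling modes

An ESM is a minimal self-contained route from input(s) to an output in the
expanded network: the output is included; every ordinary member carries
exactly one ESM in-edge; every composite member carries *all* of its
expanded-network in-edges; the subgraph is acyclic; every source is an
input. Minimality is relative to the ESM's own subgraph — cascade-removing
any member destroys its transduction. An ESM without composite nodes is
exactly a simple path, and on composite-free networks the ESMs are exactly
the simple paths.

Identity of an ESM is its edge set. Two ESMs may share nodes, and one ESM's
node set may even contain another's (a path together with its chord-shortcut
both count), but no ESM's edge set can contain another's: an extra in-edge
at an ordinary member is forbidden and composite members already carry all
in-edges. This subgraph reading was chosen deliberately: it is the one under
which the composite-free path equivalence, the agreement of the ESM and
simple-path measures on synergy-free networks, and the estimator bracketing
below are exact statements rather than approximations.

Three algorithms operate on ESMs:

* `enumerate_esms()` — exact, complete enumeration by backtracking over the
  defining constraint system (branch on the chosen in-edge of each ordinary
  node, propagate composite requirements, reject support cycles). The search
  explores exactly the feasible region the iterative optimization
  formulation of this problem describes; it is validated in the tests
  against an independent brute-force oracle that enumerates global in-edge
  choice functions. Practical up to a few dozen expanded nodes.
* `count_esms()` — deterministic DFS estimators for larger networks. From
  the output toward the inputs, with on-stack revisit exclusion, an ordinary
  node contributes the *sum* of its in-neighbours' counts and a composite
  node the *product* (`multiplication` mode) or the *maximum* (`max` mode)
  of its in-neighbours' counts. Multiplication counts branch combinations
  without enforcing cross-branch consistency, so it can only overcount;
  max collapses each synergy to its richest branch, so it can only
  undercount: the exact count is bracketed between the two. On
  composite-free networks both equal the simple-path count exactly.
* `shortest_esm()` — dynamic programming on activation timing. An ordinary
  node activates with its *earliest* regulator (`d(v) = 1 + min d(u)`), a
  composite node with its *latest* (`d(c) = max d(u)`, no extra step —
  the composite is bookkeeping, not a reaction). Distances are computed by
  monotone relaxation from infinity, which converges to the least fixpoint
  on any acyclic support; backtracking with a lexicographic tie-break makes
  the reported shortest ESM deterministic. The ESM *length* is the output's
  distance (edges into ordinary nodes only); both size conventions
  (with and without composite nodes) are reported because either may be
  wanted when comparing against published counts.

```{r}
x <- expand(fixtures()$fig3_like)
length(enumerate_esms(x))
shortest_esm(x)
```

## Importance measures

For a perturbation $v$ (a node or set of nodes) with cascade residual
$G_{\Delta v}$:

* `esm_importance()`: $E^{ESM}(v) = (N_{ESM}(G) - N_{ESM}(G_{\Delta v})) / N_{ESM}(G)$,
* `sp_importance()`: the same with simple-path counts,
* `sigflux_importance()`: the no-cascade baseline — only $v$ and its incident
  edges are deleted — equivalent to a flux-style path measure,
* `betweenness_scores()`: classical directed betweenness on the *original*
  signed graph with signs ignored, the pre-existing baseline the structural
  measures are compared against.

All scores live in $[0, 1]$; for the two cascade-aware measures a score of 1
is exactly the loss of all transduction. Because the cascade can only remove
additional paths, `sp_importance` dominates `sigflux_importance` pointwise.
Betweenness is normalized by the maximum raw betweenness in the graph
(relative betweenness), which realizes the conventional reading that the
most central vertex scores 1 — e.g. the middle vertex of a chain or a star
hub — independent of graph size; Brandes' $(n-1)(n-2)$ scaling would make
those anchors size-dependent.

`rank_components()` screens every original and complementary node (and,
optionally, every admissible pair — the contradictory pair $\{v, \sim v\}$
and pairs where one member lies in the other's cascade shadow are excluded
and reported). The report is a tibble; `autoplot()` draws the per-node
measure comparison and `glance()` summarizes it.

```{r}
rep <- rank_components(fixtures()$fig1a_like)
rep[, c("perturbed", "e_esm", "e_sigflux", "betweenness")]
```

The synergy hub `D` is essential ($E^{ESM} = 1$) although the relay `C` has
the higher betweenness — the inversion that motivates the whole approach.

## Boolean dynamics as ground truth

`simulate_boolean()` provides synchronous (deterministic, attractor-detected
by state hashing) and random-asynchronous (per-round random update order,
aggregated over replicates, seed-reproducible) dynamics with clamping.
`classify_essential()` calls a component essential when clamping it OFF
(knockout) or ON (constitutive activation) drives the output away from the
unperturbed steady output under sustained input; for asynchronous updating
the output counts as ON at a configurable consensus fraction (default 1,
i.e. unanimity over replicates — defaults: 100 replicates, horizon 50
rounds). `roc_validation()` sweeps each measure's score threshold and
reports sensitivity/specificity series with the best operating point.

The self-consistency the framework predicts — every knockout lying on *all*
ESMs must be dynamically essential — is verified on the canned motifs in the
test suite.

## The synthetic generator

`generate_network()` draws layered random digraphs (inputs first, outputs
last, regulators always upstream, so generation is acyclic and every node
lies on an input-output route) and synthesizes rules with configurable
inhibitory-edge and AND-clause fractions; candidates whose expansion fails
to transduce are rejection-sampled, and everything is deterministic under a
seed. Defaults (8–12 nodes, ~1.6–1.8 regulators per node, 20% inhibition,
30% synergy, dominant inhibition) emulate the statistical texture of
curated signaling networks — mixed inhibition, sparse synergy, a single
input and output — at desk scale. What the generator does *not* emulate:
feedback loops (generation is layered, hence acyclic, although the analysis
itself handles cyclic inputs), hubs with very high in-degree,
time-dependent rules, and the long inhibitor chains of real maps; passing
properties on the battery therefore demonstrates algorithmic correctness,
not biological coverage. The test batteries use networks whose expansions
stay at or below 14 nodes so that brute-force oracles (subset/choice
enumeration, exhaustive state spaces) remain exact and the whole suite runs
in well under a minute.

## Numerical and degenerate-input choices

* Rules reducing to constant FALSE are rejected (a node that can never
  activate signals a curation error); constant TRUE is reserved for inputs.
* Self-regulation is rejected at parse time; the framework's semantics is
  sustained-signal propagation, not autonomous memory.
* Ties in the shortest-ESM backtrack are broken lexicographically; emitted
  ESM lists are sorted (size, node ids, edge key), so all outputs are
  byte-reproducible.
* Perturbing a node that pruning removed from the expanded network is an
  error in the low-level functions; `rank_components()` simply never screens
  such nodes (their knockout cannot affect transduction — the inhibitor-hub
  motif in `fixtures()$fig1b_like` shows why this is a feature).
* The `max`-mode estimator can return 0 on a network that still transduces;
  importance computations then fall back to the multiplication mode rather
  than dividing by zero.

## Limitations

Exact enumeration is exponential in the worst case and intended for
motif-scale and mid-size networks; the estimators are the supported path at
scale. The expansion focuses on direct inhibitory effects plus the
transitive complements demanded by rule negation; pathological inhibitor
chains can still require `deep_negation`. The dynamics engine is a generic
validation tool — published models with timed decay, thresholds or
self-loops are outside its scope by design.
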