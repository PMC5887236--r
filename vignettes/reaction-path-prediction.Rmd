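---
title: "Predicting reaction paths from connectivity-matrix enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reaction paths from connectivity-matrix enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rxnpath` treats a chemical reaction as a walk through a space of molecular
graphs. A *state* is the whole reacting system — possibly several molecules
— encoded as one symmetric binary atom-connectivity (AC) matrix over a fixed,
ordered atom list; separate molecules appear as blocks of the matrix. An
*elementary reaction* is the addition of a conversion matrix with entries
+1 (bond formation), −1 (bond dissociation) and 0, subject to three
constraints:

* at most `maxForm` formations and `maxBreak` dissociations per step
  (both default 2);
* at most two molecules participate in a step (uni/bimolecular only);
* a reactant bond broken earlier in the run is never re-formed, and a bond
  formed during the run is never broken again. This monotonicity is what
  makes the cycle-wise generation terminate at a fixed point: each atom
  pair can change at most once over a whole run.

Breadth-first application of all admissible conversion matrices, cycle by
cycle, enumerates every intermediate reachable from the reactant.
Permutational isomers are merged through a canonical key: the sorted
eigenvalue spectrum of an element-weighted connectivity matrix (diagonal
$0.5\,Z_i^{2.4}$, off-diagonal $A_{ij} Z_i Z_j$), rounded to $10^{-6}$.
Because distinct graphs can share a spectrum, an exact colored-graph
isomorphism check (color refinement plus backtracking) arbitrates every
spectral collision; cospectral non-isomorphic states therefore receive
distinct keys.

### Active atoms

Most reactions move only a handful of bonds. When reaction-center atoms are
flagged *active*, enumeration operates on the sub-matrix over those atoms
and every candidate is expanded back to the all-atom basis (untouched bonds
come from the reactant template) for screening and duplicate elimination.
Flagging every atom active reproduces all-atom enumeration exactly.

### Plausibility screens

A candidate state survives only if a chemically sensible Lewis structure
exists:

* **Bond orders and formal charges.** Each molecule is solved exactly by a
  small search: every bond gets an integer order (1–3), each main-group
  atom must reach an admissible valence/charge combination (e.g. C: 4/0 or
  3/±1; O: 2/0, 1/−1, 3/+1; H: 1/0 or 0/±1), each molecule's net charge is
  restricted to −1…+1, and the molecular charges must sum to the system
  charge. Among feasible assignments the one minimizing total |formal
  charge| wins — this is what makes CO come out as a triple bond and CO₂ as
  two double bonds with no charges.
* **Charge localization** (option `localizedCharges`). By default a neutral
  system may dissociate into an ion pair (H⁺ + H⁻ is formally admissible).
  The built-in reaction systems switch this off: the number of net-charged
  molecules must equal |system charge|, which forbids spurious ion-pair
  states while still allowing internally zwitterionic but net-neutral
  molecules such as carbon monoxide.
* **Metal complexes.** Bonds to transition metals are ill-defined in a
  Lewis picture, so molecules containing a metal bypass the octet model:
  the metal only obeys a maximum coordination number (default 6, units:
  bonds) and absorbs the residual formal charge of its complex; ligand
  atoms keep ordinary valence limits. A hydride bridging two centers (H
  with two bonds) remains rejected.
* **Ring count.** The cyclomatic number (bonds − atoms + 1) of every
  molecule must lie within `ringMin`…`ringMax`. Metal complexes may take a
  separate bound (`ringMaxMetal`) because a π-coordinated alkene appears as
  a three-membered metallacycle in the connectivity graph; the
  hydroformylation system uses `ringMax = 0`, `ringMaxMetal = 1` (organic
  species stay acyclic, one metallacycle allowed).
* **Energy tolerance.** With an energy evaluator attached, states above
  E(reactant) + `eTol` (kcal/mol, boundary inclusive) are discarded.

### Chemical distance and the ellipse criterion

The distance between two states is the minimal number of bond changes over
all element-preserving atom mappings ("chemical distance", CD). `cdMin()`
solves this exactly by branch-and-bound over within-element assignments; a
node budget (default 2×10⁵) guards pathological cases, falling back to the
best feasible mapping with a warning. Intermediates enter the network only
if

$$\mathrm{CD}(R, I) + \mathrm{CD}(I, P) \le \mathrm{CD}(R, P) + \Delta,$$

the inclusive "ellipse" criterion with digression factor Δ (default 6 bond
changes): geometrically, states inside an ellipse whose foci are the
reactant and product. The same criterion can screen candidates during
enumeration (`inflightEllipse`), which the hydroformylation system uses to
keep the metal-complex state space tractable.

**Basis of the CD.** Between enumerated states every bond outside the
active block is identical, so an all-atom mapping that respects this shared
scaffold reduces to a permutation of active atoms with equivalent inactive
neighborhoods (same element, inactive neighbors with equal refinement
colors on the scaffold graph). The pipeline evaluates all-atom CDs through
exactly this reduction; mappings that scramble the scaffold itself are not
considered. A config switch (`basis = "active"`) drops the neighborhood
constraint entirely, giving the cheaper, smaller active-basis distance.

### Network, path sampling, minimal subnetwork

Surviving states become vertices; two states are linked when a CD-optimal
mapping changes at most `maxForm`/`maxBreak` bonds, the step is
uni/bimolecular on at least one side, and — for catalytic systems — at
least one changed bond touches a catalyst atom. Edge weight = CD.

For every vertex $v$, all loopless reactant→$v$→product paths of minimal
total CD are sampled (Dijkstra shortest-path legs composed at $v$, ties
enumerated exhaustively; when every composition repeats a vertex, loopless
paths are enumerated in increasing length Yen-style until the minimal
through-$v$ length is covered). Distinct sampled paths are ranked by total
CD (ties broken lexicographically on the key sequence) and the shortest
⌈q·n⌉ kept, ties at the cutoff included. Edges on no kept path are
disconnected and the component containing reactant and product is the
minimal subnetwork. Graph-level kinetic filters (`kineticFilter`,
`removeEdgeAndPaths`, `edgeFrequencyRanking`) prune it further once an
energy backend has supplied vertex energies or per-edge barriers.

## The built-in reaction systems

Three systems ship as constructors (`fixtureInterhalogen`,
`fixtureClaisen`, `fixtureHydroformylation`) with explicit atom tables, so
atom indices, active flags and catalyst flags are pinned in code:

* **Interhalogen toy system** (2 ICl + H₂ → 2 HCl + I₂; 6 atoms, all
  active). Small enough that every operation can be checked against
  exhaustive oracles; CD(R, P) = 6. Halogen chemistry is homolytic, so this
  system permits open-shell atoms (`allowRadicals`); the E_tol = 20
  kcal/mol screen then removes the high-energy radical states, leaving the
  textbook HI + HCl + ICl corridor as the rank-1 path (total CD 8: two
  four-change steps, since with the no-undo rule no closed-shell
  two-change step exists from the reactants).
* **Claisen ester condensation** (2 ethyl acetate + ethoxide, charge −1).
  Active atoms: the α-carbon and one α-hydrogen of the first ester, the
  carbonyl carbon, carbonyl oxygen and ester oxygen of the second ester,
  and the ethoxide oxygen. The accepted mechanism — deprotonation to the
  enolate, C–C addition to the tetrahedral alkoxide, ethoxide expulsion —
  has total CD 4 = CD(R, P).
* **Cobalt-catalyzed hydroformylation** (HCo(CO)₃ + ethylene + CO + H₂ →
  propanal, catalyst regenerated). Eight active atoms (Co, the hydride,
  both ethylene carbons, the free-CO carbon and oxygen, both H₂ atoms);
  cobalt is the catalyst atom. `heckBreslowLike()` recognizes paths
  realizing the Heck–Breslow cycle through three graph milestones: olefin
  coordination, migratory insertion to the alkyl, and CO insertion to the
  acyl.

The active-atom sets are mechanistic choices made once: they are exactly
the atoms whose bonds change in the accepted mechanisms, plus the
carbonyl/CO oxygens that carry the reacting groups. Settings follow the
published protocol for these reactions: bond-change caps 2/2, uni/
bimolecular steps, Δ = 6, E_tol = 20 kcal/mol, top-50% path ranking.

## The energy surrogate, and what tests do and do not show

Electronic-structure backends (semiempirical, DFTB, DFT) attach through the
evaluator contract (`externalEvaluator`: one call per state with an SDF
payload, one line of output, kcal/mol). For self-contained operation
`bondEnergyEvaluator()` supplies a deterministic additive surrogate: minus
the sum of mean bond enthalpies over the assigned bond orders (e.g. C–H 99,
C=O 178, H–H 104 kcal/mol; unknown pairs fall back to 50 kcal/mol per bond
order). It is additive over molecules by construction and reproduces the
*ordering* "more/stronger bonds = more stable", but it knows nothing about
resonance, strain, solvation or metal electronic structure.

Consequently, counts downstream of the E_tol screen (survivor numbers,
network sizes, path counts) reflect the surrogate, not a quantum backend;
with the published semiempirical/DFTB energies the screen keeps a somewhat
different state set. The graph machinery upstream (enumeration,
deduplication, CD, path sampling) is exact and deterministic, which is what
the test suite pins down with brute-force oracles. Equally, passing tests
on the built-in systems do not certify real-system coverage: conformers,
stereoisomers and electronically distinct states sharing one connectivity
are all mapped to a single vertex by design.

## Numerical choices and determinism

* Atom order is input order and never changes; all tie-breaks are
  lexicographic on canonical keys or bond-order vectors, so two runs on the
  same input are byte-identical — no seeds are involved.
* Canonical-key spectra are rounded to 10⁻⁶ before stringification;
  collisions go through the exact isomorphism check, so the rounding cannot
  merge distinct states.
* `cdMin`'s branch-and-bound explores high-degree atoms first and starts
  from the identity-within-class mapping; the node budget (2×10⁵) marks
  results "feasible" instead of "optimal" when exceeded.
* Tie-inclusive path sampling caps Yen enumeration at 4096 paths per
  vertex with a warning; on dense networks a handful of far-from-corridor
  vertices can hit this cap.
* Problem sizes in the test suite: the interhalogen system runs to its
  fixed point (24 states) in about a second; the Claisen system (160
  states) in ~30 s; the hydroformylation system (280 states, with in-flight
  ellipse screening) in ~2–3 min. Pairwise-CD batteries use ≤ 8 permutable
  atoms where exhaustive permutation oracles stay enumerable.

## Known limitations

* The valence model covers common main-group elements and treats
  transition metals purely geometrically; exotic bonding (3-center bonds,
  bridging hydrides, hypervalent main-group species beyond S/P) is
  rejected, matching the screens' intent but excluding some real
  intermediates.
* Exhaustive tie enumeration can return many thousands of equidistant
  paths on dense networks — orders of magnitude more than a sampler that
  returns only a few shortest paths per vertex; rankings are still
  well-defined, but absolute path counts depend strongly on this
  convention.
* The scaffold-compatible CD reduction assumes states share their
  inactive bond structure (true for enumerated states by construction); a
  hand-built state pair violating this should use `cdMin` directly.
* No conformer or stereoisomer sampling, no solvent model, no
  transition-state search: energies enter only through the pluggable
  evaluator and threshold filters.
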