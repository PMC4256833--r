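---
title: "Atom mapping via cyclic transition-state constraint search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom mapping via cyclic transition-state constraint search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

A chemical reaction turns educt molecules into product molecules while every
atom persists, so there is a bijection — the *atom map* — between educt and
product atoms. itsmapr computes *chemically correct* atom maps: bijections
`m` that (i) preserve element labels and (ii) preserve the total bond
electrons of every atom. Both sides are modeled as undirected labeled graphs
with integer bond orders 1–3; non-bonding electron pairs sit on the vertices
(conceptually, the diagonal of the adjacency matrix) and are computed from
the element's valence-electron count, its formal charge and its bond-order
sum: `lp = (ve − charge − bos) / 2`. Writing `I` and `O` for the educt and
product adjacency matrices (lone pairs on the diagonal), condition (ii) says
every row of the reaction matrix `R = O − I∘m` sums to zero.

Correctness alone does not make a map chemically *plausible*: the changing
bonds must form a reasonable imaginary transition state (ITS). For
elementary reactions the ITS is a single cycle over 3–8 atoms along which
bond-order changes alternate. itsmapr therefore splits the search in two:

1. **Cycle identification (the CSP).** For a chosen *layout* — a cyclic
   pattern of edge changes `c_1..c_k` and per-vertex lone-pair changes
   `d_1..d_k` — a finite-domain constraint model over `2k` variables (the
   cycle positions in educts and in products) is solved by depth-first
   search with forward checking. Constraints: all-different per side,
   positionwise element equality, `lp(X^O_i) − lp(X^I_i) = d_i`, degree
   compatibility (an atom loses or gains at most one bond), and the exact
   bond-order change on every cycle edge. 0-change ("pseudo") edges must
   exist with equal positive order on both sides.
2. **Map extension (graph isomorphism).** Each CSP solution is an ITS
   *candidate*. Its cycle edges are relabeled `f` (formed), `b` (broken) or
   `p` (pseudo) in both matrices; all other entries are untouched. Non-ITS
   hydrogens are collapsed into their heavy atom's label (an absorbed-H
   count), which removes hydrogen-interchange symmetry and roughly halves
   the graphs. All color-preserving isomorphisms extending the pinned ITS
   correspondence are then enumerated with igraph's VF2 and expanded back to
   full bijections (absorbed hydrogens paired in ascending id order); every
   result is re-verified against conditions (i) and (ii). A candidate whose
   residual graphs are not isomorphic simply extends to nothing — it was not
   a true ITS.

The ITS correspondence is pinned (distinct vertex colors per cycle
position) before the isomorphism search. The `f`/`b` labels alone would let
VF2 remap symmetric ITS copies onto each other; pinning keeps candidate and
map counts interpretable, and non-consecutive cycle pairs ("chords") are
deliberately left unconstrained in the CSP — their unchanged-ness is exactly
what the edge-color equality of the isomorphism stage enforces.

## Basic versus extended model

The basic model above admits many candidates that never extend, mostly due
to interchangeable hydrogens. The extended model adds three ingredients:

* **Master hydrogens.** Per heavy atom only the lowest-id attached hydrogen
  stays in the variable domains (`sibling_hydrogen_removal()`); hydrogens of
  molecular H2 are never removed. The vertex order used for this choice is
  the package's parse order (non-hydrogens first, hydrogens grouped by
  parent).
* **Neighborhood signatures.** `N(v)` is the element of `v` plus the sorted
  multiset of "order+neighbor-element" strings of its bonds. The
  occurrence-wise difference of the educt and product signature multisets
  (`multiset_difference()`) lists local environments that *must* change, so
  their element labels (`its_label_requirements()`) become per-label
  cardinality lower bounds on the cycle, and the assigned cycle must carry
  the educt-unique (product-unique) signatures — checked at assignment
  completion, as a cheap n-ary filter.
* Signatures are computed on whatever representation the model sees:
  explicit hydrogens in the production pipeline (hydrogen counts are part of
  the local environment; e.g. amide-hydrolysis fixtures require an H in the
  cycle), hydrogen-suppressed when replicating the printed worked example,
  which omits hydrogens.

The extended model is the pipeline default (`run_mapping(mode =
"extended")`). This matters for screening claims: on the Diels-Alder worked
example the basic model yields 37 size-4 candidates, all spurious (the
product has no 4-ring, so none extends), while the extended model yields
none — the educt-unique signatures force the cycle onto the four reacting
carbons, which admit no alternating 4-cycle. The same holds for the
Meisenheimer fixture, where the basic model produces thousands of
hydrogen-shift candidates at even sizes; the extended model proves at once
that no homovalent cycle can host the required N and O labels (their
lone-pair counts change), so the ambivalent claim "no homovalent ITS, but an
odd pseudo-bond cycle maps it" is a statement about the extended model.

## Layout catalog

`figure2_catalog()` ships, all validated against the per-vertex electron
balance `c_{i−1} + c_i + d_i = 0`:

* homovalent alternating even cycles, k = 4, 6, 8 (edge changes
  −1, +1, …; all `d_i = 0`), the dominant case;
* pseudo-bond odd cycles, k = 3, 5, 7: edges alternate along the path, the
  closure is an unchanged pseudo bond between two oppositely charged
  vertices (`d = +1` and `−1`), plus the sign-flipped inverses;
* single-vertex redox odd cycles, k = 3, 5, 7 (± inverses): all edges
  alternate, which on an odd cycle forces two equal-signed changes to meet
  at one vertex, whose lone-pair count must change by ±2.

Two naturally-suggested odd variants are *not* encodable and are therefore
absent: a pseudo-bond odd cycle whose two special vertices have *equal*
lone-pair changes (interior alternation forces the pseudo-bond endpoints to
opposite changes), and a single changing vertex with `d = ±1` under full
alternation (balance forces ±2 there). The catalog is a plain-YAML format
(`read_layout_catalog()`/`write_layout_catalog()`), so additional layouts
can be supplied without touching code; `validate_layout()` gates every
entry. Bond-change magnitudes are fixed to 1 in the shipped catalog; the
model itself handles |c| up to 3.

## Symmetry accounting

A rotation-symmetric layout (the homovalent cycles are invariant under
rotation by two positions) would make the solver report every geometric
cycle many times. The ordering constraint `X^I_1 < X^I_i` keeps exactly one
representative: the anchor position is tied to the smallest educt vertex of
the cycle, and since the first edge must be bond-breaking, only one of the
two traversal directions survives *from that anchor*. Counts reported with
symmetry breaking on are therefore one per geometric ITS orientation-class,
which is what reproduces the published candidate counts exactly.

One accounting subtlety deserves a warning. With the ordering constraint
*disabled*, each geometric cycle is realized by `k` assignments, not `k/2`:
reversing the traversal of an even alternating cycle maps breaking edges to
breaking edges, so both directions satisfy `c_1 = −1` (from different start
vertices), giving `k/2` phase-preserving rotations × 2 directions. The
fixed first-edge phase alone does **not** fix the direction; it only does so
once the anchor vertex is fixed by the ordering constraint. Both the solver
and the independent brute-force oracle confirm the factor `k` (e.g. 432 vs
108 on the hydrogenation fixture at k = 4). Ambivalent layouts are anchored
by their own asymmetry (the position of the pseudo bond or the changing
vertex) and get no ordering constraint.

## Numerical and procedural choices

* **Hydrogen completion.** Standard valences H 1, B 3, C 4, N 3/5, O 2,
  P 3/5, S 2/4/6, halogens 1, charge-adjusted by ±1 per unit charge; the
  smallest target ≥ the current bond-order sum is used. Exceeding all
  targets is a hard "hypervalent" error; an odd non-bonding electron count
  is a hard "radical" error. Aromatic input is rejected (kekulized SMILES
  only — electron bookkeeping needs integer orders); stereochemistry and
  isotopes are rejected as out of scope.
* **Atom order.** Non-hydrogens in SMILES parse order, then hydrogens
  grouped by parent in parent order. This order is load-bearing: it defines
  master-hydrogen selection, the ordering constraint, and deterministic
  output.
* **Branching.** Smallest current domain first, ties by lowest variable
  index (educt side first); values: non-hydrogen atoms in ascending id, then
  hydrogens. Deterministic, so enumeration order is reproducible.
* **Absorbed-hydrogen expansion** pairs hydrogens in ascending id — any
  pairing is valid by symmetry, one must be chosen.
* **Degree semantics.** "Degree" is the count of distinct incident bonds
  (option `itsmapr.degree_semantics`, alternative `"bond_order_sum"`). The
  default reproduces all published candidate counts exactly; the switch was
  kept because the source description is ambiguous on this point.
* **Counting semantics.** Candidate counts are distinct `(X^I, X^O)`
  assignments with symmetry breaking on, explicit hydrogens, basic or
  extended model as stated.

## The synthetic generator

`plant_random_reaction()` builds a random valence-respecting educt graph
over C/N/O (60/20/20%), plants a k-cycle realizing a homovalent or
pseudo-bond layout (breaking edges present at order 1, occasionally 2;
formed edges absent; the pseudo bond present and unchanged; charges ±1 only
where the pseudo layout requires them), applies the layout to obtain the
products, completes hydrogens, permutes the product atom order, and records
the ground-truth map and candidate. Decoration bonds are added at an
expected 0.6 per heavy atom. It is deterministic per seed and restores the
caller's RNG state.

What it does and does not emulate: instances are small (tests use 7–10
heavy atoms, k ∈ {4, 6}, the sizes at which the exhaustive oracles are
feasible), frequently disconnected, ring-poor and aromatic-free, with
hydrogen fractions similar to small metabolites. Passing the planted
recovery suite demonstrates completeness of the search and extension
machinery under those conditions; it says nothing about runtime on
110-atom database reactions or about multi-step (fused-cycle) mechanisms,
which are out of scope. Recovery is checked through the extended pipeline:
on hydrogen-rich instances the basic model's candidate space explodes
combinatorially (millions of hydrogen-symmetric assignments) — the very
phenomenon the extended model was designed to remove — while the planted
heavy-atom cycle provably satisfies the extended constraints (only cycle
atoms change their signatures, so the containment and cardinality bounds
hold by construction).

## Problem sizes used by the shipped tests

The test suite runs the five benchmark reactions (14–44 atoms; full basic
enumeration up to ~194k candidates takes well under a second in the
compiled search core), exhaustive brute-force cross-checks on fixtures with
at most 16–18 atoms, 100 seeded planted-recovery instances, and exhaustive
bijection oracles on ≤ 12-atom fixtures. The whole suite completes in about
a minute on one CPU.

## Known limitations

* Kekulized, stereochemistry-free, radical-free input only; at most 64
  atoms per side in the compiled search core.
* The layout catalog covers single-cycle (elementary) mechanisms; fused
  multi-cycle ITS for multi-step reactions are not modeled.
* Atom maps are deduplicated per reaction as full bijections; maps that
  differ only by exchanging equivalent non-ITS hydrogens are already
  collapsed by construction, but symmetric educt/product automorphisms can
  still yield several genuinely distinct maps, all reported.
* The planted generator does not produce aromatic systems, charges beyond
  the pseudo-layout pattern, or reactions whose ITS breaks a bond of order
  3.
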