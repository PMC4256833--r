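# itsmapr

Chemically correct atom-atom mapping of elementary reactions by cyclic
imaginary-transition-state (ITS) search.

## The problem

Reaction databases give educts and products but rarely the atom map — the
bijection `m` between educt and product atoms that reveals which bonds
break and form. Optimization surrogates (maximum common subgraph variants)
often return chemically wrong maps because their objectives are not derived
from reaction principles. itsmapr instead searches directly for the
mechanism: a *chemically correct* atom map is a bijection with

1. `l(x) = l(m(x))` — element labels preserved, and
2. `R·1 = 0` for the reaction matrix `R = O − I∘m` — every atom's bond
   electrons (bond orders plus lone pairs on the diagonal) balance,

whose changing bonds form a cyclic ITS: for elementary homovalent
reactions an even alternating cycle of 4–8 atoms (bond orders change by
±1 around the cycle); for ambivalent reactions odd cycles with charged
vertices and an unchanged pseudo bond.

The two-stage algorithm: a finite-domain constraint model (basic or
extended with hydrogen symmetry breaking and neighborhood-multiset
cardinality bounds) enumerates ITS candidate cycles; each candidate's cycle
edges are relabeled formed/broken/pseudo, non-ITS hydrogens are collapsed,
and label-preserving graph isomorphisms extending the pinned cycle yield
the complete atom maps, emitted as atom-mapped SMILES. Audience: anyone
needing mechanism-consistent atom maps for metabolic network analysis,
reaction classification, or isotope-tracing study design.

## Worked example

Glyoxylate-forming cleavage (CO2 + tartronate semialdehyde giving two
glyoxylates, KEGG R00013):

```r
library(itsmapr)
r <- parse_reaction("C(=O)=O.C(C(=O)O)(C=O)O>>C(=O)(C=O)O.C(=O)(C=O)O",
                    id = "R00013")
r
#> reaction R00013: 14 educt atoms, 14 product atoms
res <- run_mapping(r, mode = "extended", output = "all")
res$table
#>        layout k candidates extendable maps_total maps_distinct
#> 1 homovalent4 4          4          0          0             0
#> 2 homovalent6 6         76          4          4             4
#> 3 homovalent8 8        164          4          4             4
res$minimal_k
#> [1] 6
cat(res$smiles[1])
#> homovalent6  6  [C:1](=[O:2])=[O:3].[C:4]([C:5](=[O:6])[O:7][H:12])([C:8](=[O:9])[H:13])([O:10][H:14])[H:11]>>[C:1](=[O:3])([C:8](=[O:9])[H:13])[O:2][H:14].[C:5](=[O:6])([C:4](=[O:10])[H:11])[O:7][H:12]
```

Reading the table: at k = 4 the extended constraint model leaves four ITS
candidates, none of which extends to a complete map (the residual graphs
are not isomorphic), so the smallest mechanism is a six-membered cycle:
CO2's carbon bonds to the aldehyde carbon, the central C–C bond and the
hydroxyl O–H break, the proton lands on a CO2 oxygen and the old hydroxyl
becomes a carbonyl. The four maps at k = 6 are the equivalent choices from
the two identical product molecules and the two equivalent CO2 oxygens.
The mapped SMILES carries one `:n` class per atom; educt atom `n` maps to
the product atom with the same class.

The basic (un-extended) model on the same reaction has 346 candidates at
k = 6 — the extended model's hydrogen symmetry breaking and
neighborhood-derived cardinality bounds do the pruning. Ambivalent
chemistry works through the odd-cycle catalog:

```r
res <- run_mapping(meisenheimer_reaction(), k_values = 3:8, layouts = "all",
                   mode = "extended", output = "first")
res$minimal_k   # 3 — no homovalent even cycle exists for this rearrangement
```

A thin command-line front end ships in `inst/cli/itsmap.R`:

```sh
Rscript inst/cli/itsmap.R map --reaction 'N.N(CCCCN)CCCCN>>C(CCN)CN.C(CCN)CN' --first
Rscript inst/cli/itsmap.R fixtures --table2
```

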