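---
title: "Fragment-based charge transfer: model, algorithms and design choices"
author: "fragcharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based charge transfer: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(fragcharge))
```

## The problem

Fixed-charge force fields need a partial charge on every atom. Deriving
those charges ab initio (ESP fits to DFT electron densities) is expensive
for large molecules, but most large molecules are built from substructures
that have been parametrized many times before. `fragcharge` implements the
re-use strategy: find every substructure of a query molecule that also
occurs — *in the same local chemical environment* — in a library of
previously parametrized molecules, transfer the stored charges from chosen
fragments, reconcile disagreements explicitly, and correct the final sum
to the molecule's integer net charge. Regions the library does not cover
are extracted, completed into small valid molecules, and handed on for
external parametrization.

## The matching model

A molecule is a labeled simple graph: nodes are atoms (element, formal
charge, optional partial charge), edges are covalent bonds with an order.
Hydrogens are always explicit; all matching is all-atom.

Two atoms are **k-compatible** when the subgraphs induced by their
*k-balls* — all atoms within `k` bonds — admit an isomorphism that maps
one atom onto the other and preserves every atom's label. A label is the
pair (element, degree), with the degree counted in the full molecule, so a
truncated neighborhood can never masquerade as a complete one. The shell
size `k` (default 3) controls how much context two atoms must share
before their charges are considered interchangeable: at `k = 0`
compatibility degenerates to label equality, and increasing `k` is
strictly more demanding, so compatibility at `k` implies compatibility at
every smaller shell.

A **fragment** is a connected set of query atoms mapped bijectively and
bond-preservingly (an induced common subgraph) onto atoms of one library
molecule, every mapped pair k-compatible, with one additional coherence
requirement: the core mapping must extend to a single label- and
adjacency-preserving witness on the union of the k-balls of its atoms.
Pairwise compatibility guarantees each atom a shell witness individually;
the fragment-level rule prevents stitching together witnesses that
contradict each other on shared shell atoms. Fragments are reported when
**maximal**: no compatible adjacent pair can be added without breaking
these invariants.

### Enumeration

All maximal fragments between two molecules are enumerated on the *pair
product graph*: vertices are k-compatible atom pairs; two vertices are
compatible (can coexist in one fragment) when they are injective and
their adjacency agrees in both molecules, and *c-adjacent* when adjacent
in both. Fragments are exactly the maximal consistent c-connected cliques
of this graph. The package recovers them as c-components of maximal plain
cliques, computed per c-connected component of the product graph with
igraph's pivoted Bron–Kerbosch implementation; each candidate is then
checked for a shell witness (a cheap forced-extension pass, falling back
to VF2 with the core pinned by colors) and for inextensibility.

Symmetric images are the enumerative hazard: the three hydrogens of a
methyl group can be matched to another methyl in 3! interchangeable ways,
and these choices multiply across groups. Degree-1 "twin" atoms (same
parent, same label) have identical k-balls, so the package enumerates
only order-preserving twin matchings and afterwards remaps every twin
pairing to the lexicographically smallest one; mappings sharing a query
core are collapsed to a single reported match. A brute-force oracle
(`bruteForceKMCF`) implements the same contract directly from the
definitions — hand-rolled breadth-first distances, backtracking
isomorphism, exhaustive growth — and the test suite checks agreement on
hundreds of randomized instances, including self-matches, which stress
the symmetry handling hardest.

## Charge assignment

Charges transfer per mapped atom, each transfer recorded with its
provenance (`library_id:atom`). An atom holding two or more *distinct*
candidate values (duplicates collapse on entry, so re-selecting a
fragment never reweights anything) is a **conflict**, resolved by one of
three policies: select one candidate, average the distinct values, or
set a manual value. Batch runs default to averaging.

The **residual charge** is `sum(assigned) − target`; uniform correction
subtracts `residual/N` from every atom, restoring the target to within
1e-6 e and doing nothing when applied again. The sign convention makes
the subtraction rule exact; the quantity itself is symmetric in use.

Optional **symmetrization** averages charges within topological
equivalence classes: neighborhood-label refinement run to a fixed point,
refined exactly by the orbits of the element-colored automorphism group
(BLISS, via igraph). Class means preserve the total charge.

The automated `greedyAssign` protocol replaces interactive fragment
selection: pick a seeded start atom, apply the largest fragment covering
it, and repeat on unparametrized atoms. Overlap with already-assigned
atoms is used only to break ties among the largest candidates — making
overlap-freedom an absolute preference lets small symmetric
cross-fragments (one phenyl ring matched onto another) defeat large
faithful fragments and contaminate the assignment. `multiStartAssign`
runs the protocol from several seeds and reports the per-atom standard
deviation across runs, the spread statistic used to judge assignment
consistency.

## Missing fragments

Atoms no fragment covers are grouped into connected cores, each extended
by its k-shell (the environment that must accompany the fragment for its
eventual parametrization to be transferable back). Overlapping regions
merge. Oversized regions are split recursively along bonds that lie on
no ring of the parent molecule, choosing at each step the cut whose two
sides are most balanced; a piece that cannot shrink without breaking a
ring is returned whole. The size limit (default 40 atoms, targeting
30–40) applies to the *capped* piece — the atoms it contains plus the
hydrogens capping will add — since that is the molecule a downstream
parametrization pipeline actually has to process.

Capping completes every dangling valence (bond-order deficit relative to
the element's valence target, raised to the atom's bond-order sum in the
parent for deliberately unsaturated inputs). Cap groups come from a
configurable table; the default is hydrogen-only, which is neutral and
apolar by construction, and caps are terminal so rings are never
altered. The combination of cap options is chosen by an exact
lexicographic integer optimisation — minimize heavy cap atoms, then
hydrogens, subject to exact valence completion — solved by depth-first
branch and bound with per-atom lower bounds; the suite verifies it
against exhaustive enumeration for up to six dangling atoms. With the
default table the optimum is forced; the optimiser exists so richer
tables (e.g. a methyl alternative, `inst/extdata/cap_rules_methyl.json`)
can be dropped in without code changes.

## Synthetic data: what it emulates and what it does not

The package ships four built-in structures (phenol, paracetamol,
N,2-diphenylacetamide and the 113-atom paclitaxel), encoded as SMILES
and parsed at load so the graphs are bit-stable with no binary assets.

`assignSyntheticCharges` draws per-atom charges uniformly from
(−0.6, 0.6) e — the magnitude range typical of ESP-fitted charges — and
shifts them to hit the integer target exactly. `makeSelfLibrary` covers
a charged molecule with `n` connected, overlapping cores (multi-source
BFS from maximin-spread seed atoms), extends each by its k-shell, and
caps each cut bond with one hydrogen carrying the removed neighbor's
charge. One hydrogen *per cut bond* — rather than per valence unit —
keeps boundary degrees identical to the parent, which is what guarantees
every core atom remains k-compatible with its own image; caps are
flagged in the library schema and ignored by charge transfer and
coverage accounting.

The recovery property — self-library plus greedy averaging reproduces
every charge to 1e-9 e with zero residual, and zero per-atom spread
across five starts — is the pipeline's end-to-end correctness check: it
shows the bookkeeping (matching, transfer, dedup, averaging,
redistribution) is exact. It deliberately does *not* show predictive
accuracy on real data: real libraries carry charges from *different*
molecules, where long-range effects and fit uncertainty make candidates
genuinely disagree (conflicts of a few hundredths to a few tenths of an
elementary charge are normal, and residuals grow accordingly). Random
synthetic charges also lack the element-wise structure of real ESP
charges, and the generator's libraries are always consistent with a
single parent — there is no analogue of selecting a fragment from a
molecule with the wrong net charge, the main failure mode interactive
use must guard against.

## Numerical and interface choices

* Atom ids are 0-based and stable; SDF atom-block order defines them.
* Bond orders are stored (aromatic = 4, valued 1.5 in valence sums) but
  ignored by matching labels — the matching criterion is element plus
  connectivity; orders matter for valence accounting and capping.
* Net-charge tolerance: 1e-6 e after redistribution, 0.5 e as a sanity
  bound before. Candidate values within 1e-12 e are one value.
* Library JSON round-trips write doubles at 17 significant digits, so
  write→read→write is bit-stable; charges in *reports* and annotated
  SDFs are rounded to 4 decimals, with full precision kept internally.
* Ranking is size-descending with deterministic tie-breaks (library id,
  then query atom ids); identical configuration and seed give
  byte-identical reports.
* Degenerate inputs: `k` beyond the diameter demands whole-component
  isomorphism; empty libraries, unresolved atoms, unknown ids and
  malformed records all raise early, named errors.
* Problem sizes in the test suite: oracle equivalence on 200 randomized
  pairs of up to 10 atoms at shells 0–3 (the oracle's exhaustive growth
  is exponential, so instances are capped at 400 atom pairs); recovery
  on all four fixtures up to paclitaxel's 113 atoms with libraries of
  1, 3 and 5 entries and three seeds each.

## Limitations

Matching uses (element, degree) labels; it does not consult
hybridization-aware atom types, stereochemistry or conformation (by
construction, matching is conformation-independent). The enumeration's
twin reduction covers degree-1 orbits; larger symmetric substituents are
handled by the collapse-per-core rule rather than suppressed during
search, which is adequate at these molecule sizes. The capping table is
hydrogen-only by default and makes no attempt to reproduce any specific
published cap-selection objective beyond the stated lexicographic one.
PDB input, topology-file emission, 2D depiction and any interaction with
external parametrization servers are out of scope.
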