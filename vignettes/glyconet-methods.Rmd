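---
title: "Rule-based construction of N-glycosylation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based construction of N-glycosylation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconet)
library(dplyr)
```

## The problem

N-linked glycans are branched oligosaccharides attached to asparagine
residues of secreted and membrane proteins. Unlike proteins, their structures
are not template-encoded: they emerge from a cascade of Golgi enzymes —
mannosidases that trim the Man9GlcNAc2 precursor, and glycosyltransferases
that then build complex antennae — each acting only on substrates that
satisfy its linkage and context specificity. The set of glycans a cell can
produce is therefore the closure of a starting structure under a finite set
of enzyme reaction rules. `glyconet` computes that closure: given a starting
glycan and a rule database, it constructs the reaction network whose nodes
are glycan species and whose edges are single enzymatic steps.

## Glycans as rooted trees

A glycan is a rooted tree of monosaccharide residues over the six-symbol
alphabet `M` (Man), `GN` (GlcNAc), `A` (Gal), `AN` (GalNAc), `F` (Fuc), `NN`
(Neu5Ac). The root is the reducing-end GlcNAc (the protein side is not
modelled; rule patterns end at the core GlcNAc). Each non-root residue
carries one linkage to its parent: an anomer (`a`/`b`) and an attachment
position (2, 3, 4 or 6). A position on a residue can hold at most one
substituent — this occupancy rule is what terminates many transferase
cascades (e.g. core fucosylation can happen once). Neu5Ac linkages written
`a3`/`a6` denote alpha2-3/alpha2-6; the carbon-2 origin is uniform and kept
implicit.

Text I/O uses LinearCode: children are written to the left of their parent,
the first branch as a plain chain and the rest in parentheses, e.g.
Man5GlcNAc2 is `Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN`.

**Canonical form.** Networks are deduplicated by a canonical LinearCode key:
children of every residue are ordered by (position ascending, canonical
subtree string ascending). Position-first ordering matches the field's
convention of writing the alpha3 arm before the alpha6 arm; since siblings
cannot share a position, the ordering is total on valid glycans and the
subtree-string tiebreak only matters for degenerate inputs. The key is
itself valid LinearCode and re-parses to the same tree, so two glycans are
isomorphic if and only if their keys are equal.

## The pattern dialect

Substrate specificity is expressed in an extended LinearCode dialect:

* a leading unbalanced `(` anchors the pattern at a **non-reducing
  terminal**: the leftmost explicit residue must match a leaf — this is how
  `(Ma2Ma` (a *terminal* Man-a2 on a Man) differs from an internal Ma2;
* `*` matches exactly one residue of any kind; `...` matches any descending
  chain of length ≥ 0 (and makes a leading anchor vacuous, since some leaf
  always lies above any residue);
* omitted linkage parts are unconstrained (`GNb` = GlcNAc beta-linked at any
  position);
* `!` after a symbol marks the **action target**: the residue removed by a
  hydrolase, or the acceptor to which a transferase attaches its residue.

Matching is subtree embedding: the subject may carry residues beyond the
pattern except where an anchor demands a leaf. Constraints form a small
boolean language over the glycan and the action target: `~`, `&`, `or`;
named atoms `Gnbis` (bisecting GlcNAc: a GN beta1-4 on the core beta-Man)
and `Ab` (any beta-Gal anywhere); branch atoms `X|Y` (pattern `X` occurs in
the branch rooted at core residue `Y`); target atoms `_X|Y` (the action
target lies in that branch) and `!`-marked patterns (the pattern must match
with its mark on the target).

The source framework describes enzyme specificity through eight predicate
slots; they map onto this encoding as: *substMinStruct* → the substrate
pattern; *substMaxStruct* → an exhaustion constraint (e.g. `~Ma2M`, "no
alpha1-2 Man left", making MGAT1 act on Man5 exactly);
*substNABranch/Struct/Residue* → negated atoms (`~Gnbis`, `~Ab`, negated
patterns); *targetBranch/targetNABranch* → branch and target atoms;
*isTerminalTarget* → the anchor and the `target_terminal` flag. Undefined
slots are vacuously true, so a rule is exactly the conjunction of what its
row specifies.

## The rule database

The bundled CSV holds 27 rules for 22 enzymes: two mannosidases (ManI,
ManII, each with two rules), the branching GlcNAc-transferases MGAT1–5 and
iGnT/IGNT, the galactosyltransferases b4GalT, b3GalT1, b3GALT6, c1GALT1 and
GalT-B, the sialyltransferases a3SiaT, a6SiaT and st3galI, the
fucosyltransferases FUT8, FUT1, FUT3 and a3FucT, and GalNAcT-A. Each row
carries the machine-readable pattern/constraint columns next to the source
cells verbatim (`*_printed`) and a `source_note` explaining any
normalization, so every interpretive step is inspectable:

```{r}
rules <- load_rule_db()
rules |> select(index, enzyme, ec, kind, substrate_pattern, constraint) |> print(n = 27)
```

A reaction event applies one rule at one site; a rule with several
admissible sites (ManI has three on Man9GlcNAc2 under the printed reading)
contributes one candidate product per site. Products and reactions are
deduplicated by canonical form and by (substrate, product, enzyme).

### Two documented readings of the damaged cells

Several source cells are garbled or underdetermined, and the per-enzyme
specificity tables they summarize are not machine-readable in the available
text. Three rules admit two defensible readings, both shipped:

* **ManI (rule 1).** The printed constraint `~*2Ma3(...Ma6)` reads as "the
  target is not the a2-Man on the Ma3 branch of the a6 arm" — the middle-arm
  mannose, which rule 2 removes only after the a3 arm is fully trimmed. The
  *curated* reading (default) enforces this, giving the ordered trimming
  Man9 → Man5 of the secretory pathway; the *printed* reading leaves rule 1
  unconstrained (any terminal a2-Man), giving the full 12-isomer trimming
  lattice.
* **ManII (rule 4).** The printed product `(Ma6` shows the parent Man
  *terminal* after removal, i.e. the a3-linked sibling is already gone: the
  curated reading makes the two ManII removals sequential (rule 3 before
  rule 4); the printed reading lets either act first.
* **FUT8 (rule 5).** The curated reading adds the biantennary-core
  requirement (`GNb2|Ma6`, i.e. after MGAT2) to the printed
  `GNb2|Ma3 & ~Gnbis & ~Ab`: hybrid glycans with an unprocessed alpha6 arm
  are poor FUT8 acceptors.

On the published benchmark (7 rounds from Man9GlcNAc2, all 27 rules) the
curated reading reproduces the published **structure** count exactly (31)
and the printed reading the published **reaction** count exactly (64); no
single reading reproduces both, and the package reports both rather than
blending them:

```{r}
m9 <- glycan_fixture("M9")
for (rd in c("curated", "printed")) {
  net <- forward_network_inference(m9, load_rule_db(reading = rd), max_rounds = 7)
  print(glance(net) |> mutate(reading = rd))
}
```

The companion comparison values for the older 11-enzyme model (rules 1–13;
14 structures / 26 reactions) are not reachable by this engine under any
reading we enumerated: 26 reactions over 14 species implies a convergence
density that breadth-first closure cannot produce at that size (each new
species contributes at least one reaction, and the mannose-trimming lattice
— the only early source of convergent edges — already needs more than 14
species). The same argument applies more strongly to the 8-enzyme model's
quoted 4 structures / 12 reactions, which no simple digraph can realize.
We conclude those comparison figures were carried over from the earlier
publications' own (differently-defined) tallies; this package reports what
the rules actually generate (21 structures / 25 reactions under the default
reading).

## Forward network inference

The network is built breadth-first. Round 0 contains the root(s); round *k*
applies every rule to every glycan first discovered in round *k − 1*. New
canonical keys join the network with round index *k*; rediscoveries only add
the new edge. Expansion stops at `max_rounds` or at the fixpoint where a
round yields nothing new. "First seven rounds" therefore means nodes with
round ≤ 7 and reactions discovered while expanding rounds ≤ 7.

There is no randomness anywhere: glycans are expanded in canonical-key
order and rules in index order, so repeated runs — and their file exports —
are byte-identical. Because iGnT + b4GalT can elongate poly-LacNAc chains
indefinitely, the network has no global fixpoint; a hard cap (`max_nodes`,
default 10,000) aborts runaway growth with a clear error. Reverse reactions
are out of scope: the reaction schemas are chemically reversible, but the
network is built in the biosynthetic direction only.

Two tally conventions are ambiguous in the source and both are emitted by
`network_stats()`: cumulative structures including the root
(`n_structures`, with `n_structures_new` per round), and two reaction
tallies (`n_reactions`, reactions discovered by round *r*; and
`n_reactions_closed`, reactions whose both endpoints lie within rounds ≤
*r*). The root for the benchmark runs is Man9GlcNAc2 alone; Man8GlcNAc2 (we
bundle the common B-isomer, missing the middle-arm terminal a2-Man) is also
provided and any other isomer can be given as LinearCode.

## What the tests cover, and with what

Fixtures are standard textbook structures (Man9/Man8/Man5GlcNAc2 and
hand-built complex-type intermediates), so the golden tests check real
glycobiology. The property tests use uniformly random residue trees (random
symbols, anomers and free positions, up to 12–15 residues) — deliberately
*harder* than biological glycans for canonicalization and matching, since
they include chemically impossible branchings; passing them therefore
supports the tree machinery in general, but says nothing about rule
*content* beyond what the golden and benchmark tests pin down. Three
independent oracles back the engine: an exhaustive generate-and-test
matcher (every injective pattern-to-subject assignment), a stack-based
traversal for residue queries, and a memoized depth-first reachability
search for the network closure. Problem sizes (1,000 canonicalization
cases, ~450 matcher-oracle comparisons, 7-round networks of ≤ 50 nodes)
keep the full suite under a minute while exercising every rule.

## Numerical and degenerate-input choices

* Addresses are position paths from the root; they are stable under
  canonicalization and readable in logs (`GN>GNb4>Mb4>Ma3`).
* `attach` refuses occupied positions; `detach` refuses non-leaves and the
  root; parsers reject unknown symbols and report character offsets.
* Tie-breaks: sites in canonical traversal order, rules by index; edge
  identity is (substrate, product, enzyme name), so the two ManI rules
  cannot double-count one trimming step.
* The bisecting GlcNAc blocks other enzymes only through explicit `~Gnbis`
  atoms; no implicit steric model is assumed.
* Both FUT3 rules (and a3FucT, whose printed row duplicates FUT3's type-2
  rule) are allowed wherever their patterns match; whether Lewis-a and
  Lewis-x modifications exclude each other on one glycan is not specified
  in the source and is left to position occupancy.
* st3galI's printed product cell names a type-2 Gal for a type-1 substrate;
  it is encoded as sialylation of the matched (type-1) Gal and flagged in
  the CSV.

## Limitations

The model is structural, not kinetic: no enzyme concentrations, rates or
Golgi compartment ordering, and no mass-spectrometry integration. Rule
semantics for the damaged source cells rest on the documented readings
above; users can supply their own CSV to test alternatives. Glycan size is
bounded only by memory, but the round cap is the intended control on
network growth.
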