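# glyconet

Rule-based construction of N-glycosylation reaction networks in R.

N-linked glycan structures are not encoded in the genome: they are produced
in the Golgi by a cascade of glycosidases and glycosyltransferases, each
acting only on substrates that satisfy its linkage and context specificity.
The set of glycans a cell can make is therefore the closure of a starting
structure (typically Man9GlcNAc2) under a finite set of enzyme reaction
rules. `glyconet` computes that closure: glycans are rooted residue trees
written in LinearCode (`Ma3(Ma6)Mb4GNb4GN` …), enzymes are rows of a
27-rule database covering 22 Golgi enzymes (mannosidases ManI/ManII,
MGAT1–5, iGnT/IGNT, four galactosyl-, three sialyl- and four
fucosyl-transferases, GalNAcT-A), and the network is built breadth-first
with canonical-form deduplication:

* substrate patterns use a small dialect — `(` anchors a non-reducing
  terminal, `*` one arbitrary residue, `...` an arbitrary chain, `!` marks
  the action target — matched by subtree embedding;
* constraints are boolean expressions over the glycan and the action site
  (`GNb2|Ma3 & ~Gnbis & ~Ab`: GlcNAc-beta2 on the core alpha3-Man, no
  bisecting GlcNAc, no galactose);
* a reaction event applies one rule at one admissible site; products and
  reactions are deduplicated by canonical LinearCode keys, and round *k* of
  the inference applies every rule to everything first seen in round
  *k − 1*.

The result is a `glycan_network` with tidy `nodes`/`edges` tibbles,
per-round summaries, pruning, `tidy()`/`glance()`/`autoplot()` methods, and
deterministic export to GraphML, SIF, DOT and CSV.

## Worked example

```r
library(glyconet)

rules <- load_rule_db()                       # bundled 27-rule database
net <- forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 7)
net
#> <glycan_network> 31 glycans, 36 reactions (7 rounds from 1 root)

network_stats(net)
#> # A tibble: 8 × 5
#>   round n_structures_new n_structures n_reactions n_reactions_closed
#>   <int>            <int>        <int>       <int>              <int>
#> 1     0                1            1           0                  0
#> 2     1                2            3           2                  2
#> 3     2                2            5           5                  5
#> 4     3                2            7           8                  8
#> 5     4                1            8          10                 10
#> 6     5                1            9          11                 11
#> 7     6                5           14          16                 16
#> 8     7               17           31          36                 36
```

Rounds 1–4 are the ordered mannose trimming Man9 → Man5 (two ManI rules),
round 5 is MGAT1 priming the core, and from round 6 the transferase cascade
fans out — 31 distinct glycan species and 36 single-enzyme reactions within
seven rounds. Individual steps are just as accessible:

```r
gngn <- parse_structure("GNb2Ma3(GNb2Ma6)Mb4GNb4GN")   # biantennary core
infer_products(gngn, rules[5, ])$product                # FUT8
#> [1] "GNb2Ma3(GNb2Ma6)Mb4GNb4(Fa6)GN"                  # core fucose added
```

`export_network(net, "graphml", "net.graphml")` writes the network for
Cytoscape-style tools, and a command-line front end wraps the same
pipeline: `inst/scripts/glyconet infer --root M9 --rules all --rounds 7
--format graphml --out net.graphml`.

Three source cells of the rule table are damaged; the database ships two
documented readings (`load_rule_db(reading = "curated")`, the default, and
`reading = "printed"`), compared in the methods vignette
(`vignettes/glyconet-methods.Rmd`).

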