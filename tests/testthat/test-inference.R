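test_that("infer_products generates one product per admissible site", {
  rules <- load_rule_db()
  # FUT8 on the biantennary core adds the a1-6 core fucose
  gngn <- parse_structure(GNGN_TEXT)
  p <- infer_products(gngn, rules[5, ])
  expect_identical(nrow(p), 1L)
  expect_true(pattern_matches_glycan(parse_pattern("GNb4(Fa6)GN"),
                                     p$glycan[[1]]))
  # ManI (printed reading) on M9: three distinct Man8 isomers
  printed <- load_rule_db(reading = "printed")
  p8 <- infer_products(glycan_fixture("M9"), printed[1, ])
  expect_identical(nrow(p8), 3L)
  expect_identical(dplyr::n_distinct(p8$product), 3L)
  for (g in p8$glycan) {
    expect_identical(unname(composition(g)[c("M", "GN")]), c(8L, 2L))
  }
  # non-matching rule yields an empty, well-typed tibble
  none <- infer_products(glycan(residue("GN")), rules[5, ])
  expect_identical(nrow(none), 0L)
  expect_named(none, c("product", "glycan", "enzyme", "rule_index", "site"))
})

test_that("forward inference handles trivial inputs and bad arguments", {
  rules <- load_rule_db()
  empty_rules <- rules[0, ]
  net <- forward_network_inference(glycan_fixture("M9"), empty_rules,
                                   max_rounds = 5)
  expect_identical(nrow(net$nodes), 1L)
  expect_identical(nrow(net$edges), 0L)
  expect_identical(net$nodes$round, 0L)

  net0 <- forward_network_inference(glycan_fixture("M9"), rules,
                                    max_rounds = 0)
  expect_identical(nrow(net0$nodes), 1L)

  expect_error(forward_network_inference(glycan_fixture("M9"), rules, -1),
               class = "glyconet_invalid_rounds")
  expect_error(forward_network_inference(list(), rules, 3),
               class = "glyconet_invalid_rounds")
  expect_error(
    forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 7,
                              max_nodes = 5),
    class = "glyconet_network_overflow")
})

test_that("forward inference matches the exhaustive reachability oracle", {
  rules <- load_rule_db()
  # toy rule sets, small depth: compare node and edge sets exactly
  toys <- list(select_rules(rules, "1-2"),
               select_rules(rules, c(6L, 12L, 13L)),
               select_rules(rules, c(5L, 8L)))
  roots <- list(glycan_fixture("M9"), glycan_fixture("Man5"),
                parse_structure(GNGN_TEXT))
  for (i in seq_along(toys)) {
    for (depth in c(1L, 3L)) {
      net <- forward_network_inference(roots[[i]], toys[[i]], depth)
      oracle <- oracle_reachable(roots[[i]], toys[[i]], depth)
      expect_identical(sort(net$nodes$key), oracle$nodes)
      got_edges <- sort(paste(net$edges$substrate, net$edges$product,
                              net$edges$enzyme, sep = "\r"))
      expect_identical(got_edges, oracle$edges)
      # round index equals the BFS depth of first discovery
      expect_identical(net$nodes$round[match(names(oracle$rounds),
                                             net$nodes$key)],
                       unname(as.integer(oracle$rounds)))
    }
  }
})

test_that("network invariants hold on the full 7-round run", {
  rules <- load_rule_db()
  net <- forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 7)
  nodes <- net$nodes
  edges <- net$edges
  # every edge endpoint is a node; no duplicate nodes or edges
  expect_true(all(edges$substrate %in% nodes$key))
  expect_true(all(edges$product %in% nodes$key))
  expect_identical(anyDuplicated(nodes$key), 0L)
  expect_identical(
    anyDuplicated(edges[, c("substrate", "product", "enzyme")]), 0L)
  # no self-loops; round(product) <= round(substrate) + 1
  expect_true(all(edges$substrate != edges$product))
  sub_round <- nodes$round[match(edges$substrate, nodes$key)]
  prod_round <- nodes$round[match(edges$product, nodes$key)]
  expect_true(all(prod_round <= sub_round + 1L))
  # composition changes by exactly +-1 in exactly one symbol along every edge
  comp_of <- function(k) composition(nodes$glycan[[match(k, nodes$key)]])
  for (i in seq_len(nrow(edges))) {
    d <- comp_of(edges$product[i]) - comp_of(edges$substrate[i])
    expect_identical(sum(abs(d)), 1L)
  }
})

test_that("prune_network filters nodes and their incident edges", {
  rules <- load_rule_db()
  net <- forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 7)
  # keep everything: identical network
  same <- prune_network(net, function(g, key) TRUE)
  expect_identical(same$nodes$key, net$nodes$key)
  expect_identical(nrow(same$edges), nrow(net$edges))
  # drop fucosylated glycans: no F remains, and no edge touches a dropped node
  nofuc <- prune_network(net, function(g, key) composition(g)[["F"]] == 0L)
  expect_true(all(vapply(nofuc$nodes$glycan,
                         function(g) composition(g)[["F"]] == 0L,
                         logical(1))))
  n_fuc <- sum(vapply(net$nodes$glycan,
                      function(g) composition(g)[["F"]] > 0L, logical(1)))
  expect_identical(nrow(nofuc$nodes), nrow(net$nodes) - n_fuc)
  expect_true(all(nofuc$edges$substrate %in% nofuc$nodes$key))
  expect_true(all(nofuc$edges$product %in% nofuc$nodes$key))
  # whitelist of just the root
  only_root <- prune_network(net, net$roots)
  expect_identical(nrow(only_root$nodes), 1L)
  expect_identical(nrow(only_root$edges), 0L)
  # a root may never be pruned
  expect_error(prune_network(net, function(g, key) FALSE),
               class = "glyconet_prune_root")
})

test_that("network_stats summarises rounds consistently", {
  rules <- load_rule_db()
  net <- forward_network_inference(glycan_fixture("M9"), rules[0, ],
                                   max_rounds = 5)
  s0 <- network_stats(net)
  expect_true(all(s0$n_structures == 1L))
  expect_true(all(s0$n_reactions == 0L))

  net7 <- forward_network_inference(glycan_fixture("M9"), rules,
                                    max_rounds = 7)
  s <- network_stats(net7, per_enzyme = TRUE)
  expect_identical(s$round, 0:7)
  # cumulative columns are non-decreasing and end at the network totals
  expect_true(all(diff(s$n_structures) >= 0L))
  expect_true(all(diff(s$n_reactions) >= 0L))
  expect_identical(s$n_structures[8], nrow(net7$nodes))
  expect_identical(s$n_reactions[8], nrow(net7$edges))
  expect_identical(sum(s$n_structures_new), nrow(net7$nodes))
  # per-enzyme cumulative counts sum to the reaction count in every round
  enz_cols <- setdiff(names(s), c("round", "n_structures_new", "n_structures",
                                  "n_reactions", "n_reactions_closed"))
  expect_identical(unname(rowSums(s[, enz_cols])), as.numeric(s$n_reactions))
  # closed tally never exceeds the discovered tally
  expect_true(all(s$n_reactions_closed <= s$n_reactions))
})

test_that("tidy and glance expose the network as tables", {
  rules <- load_rule_db()
  net <- forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 4)
  td <- tidy(net)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("substrate", "product", "enzyme", "ec", "rule_index",
                    "round", "substrate_round", "product_round") %in%
                    names(td)))
  expect_identical(nrow(td), nrow(net$edges))
  gl <- glance(net)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_glycans, nrow(net$nodes))
  expect_identical(gl$rounds, 4L)
})

test_that("autoplot returns a ggplot of the network", {
  rules <- load_rule_db()
  net <- forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 5)
  p <- ggplot2::autoplot(net)
  expect_s3_class(p, "ggplot")
})
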