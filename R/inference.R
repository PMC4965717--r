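# Forward network inference: breadth-first application of all rules to each
# round's newly discovered glycans, with canonical-form deduplication.

#' Infer all products of one rule on one glycan
#'
#' Applies the rule at every admissible site and returns the distinct
#' products (deduplicated by canonical form).
#'
#' @param g A `glycan`.
#' @param rule One rule (single-row `enzyme_rules` slice).
#' @return A tibble with columns `product` (canonical key), `glycan`
#'   (list-column), `enzyme`, `rule_index`, `site` (list-column of addresses).
#'   Zero rows when the rule does not apply.
#' @examples
#' rules <- load_rule_db()
#' infer_products(glycan_fixture("M9"), rules[1, ])  # three Man8 isomers
#' @export
infer_products <- function(g, rule) {
  r <- as_rule(rule)
  sites <- match_sites(r, g)
  if (length(sites) == 0L) {
    return(tibble(product = character(), glycan = list(),
                  enzyme = character(), rule_index = integer(),
                  site = list()))
  }
  prods <- lapply(sites, function(at) apply_rule(g, r, at))
  keys <- vapply(prods, canonical_form, character(1))
  keep <- !duplicated(keys)
  tibble(product = keys[keep], glycan = prods[keep],
         enzyme = r$enzyme, rule_index = r$index, site = sites[keep])
}

new_glycan_network <- function(nodes, edges, roots, params) {
  structure(list(nodes = nodes, edges = edges, roots = roots,
                 params = params),
            class = "glycan_network")
}

#' Forward network inference
#'
#' Builds the glycosylation reaction network reachable from the root
#' glycan(s) by breadth-first rule application: round `k` applies every rule
#' to every glycan first discovered in round `k - 1`; products not seen
#' before (by canonical form) join the network with round index `k`, and
#' every reaction becomes an edge (deduplicated by substrate, product and
#' enzyme name). Expansion stops at `max_rounds`, or earlier at the fixpoint
#' where a round generates no new glycan. With rules that can elongate
#' indefinitely (e.g. poly-LacNAc extension) the network has no fixpoint;
#' `max_nodes` aborts runaway growth.
#'
#' @param roots A `glycan`, a LinearCode string, or a list of either;
#'   round-0 members of the network.
#' @param rules An `enzyme_rules` tibble (possibly a subset from
#'   [select_rules()]).
#' @param max_rounds Number of expansion rounds (>= 0; 0 = roots only).
#' @param max_nodes Hard cap on network size; exceeding it is an error.
#' @return A `glycan_network`: list with `nodes` (tibble: `key`, `round`,
#'   `composition`, `glycan` list-column), `edges` (tibble: `substrate`,
#'   `product`, `enzyme`, `ec`, `rule_index`, `site`, `round`), `roots`,
#'   `params`. The output is deterministic: node and rule iteration order is
#'   fixed by canonical keys and rule index.
#' @examples
#' rules <- load_rule_db()
#' net <- forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 7)
#' glance(net)
#' @export
forward_network_inference <- function(roots, rules, max_rounds,
                                      max_nodes = 10000L) {
  max_rounds <- as.integer(max_rounds)
  if (is.na(max_rounds) || max_rounds < 0L) {
    abort("max_rounds must be a non-negative integer",
          class = "glyconet_invalid_rounds")
  }
  if (is_glycan(roots) || is.character(roots)) roots <- list(roots)
  if (length(roots) == 0L) {
    abort("at least one root glycan is required",
          class = "glyconet_invalid_rounds")
  }
  roots <- lapply(roots, function(r) {
    if (is.character(r)) parse_structure(r) else r
  })
  stopifnot(all(vapply(roots, is_glycan, logical(1))))

  glycans <- list()   # key -> glycan
  round_of <- integer(0)
  root_keys <- character(0)
  for (r in roots) {
    key <- canonical_form(r)
    if (!key %in% names(glycans)) {
      glycans[[key]] <- r
      round_of[key] <- 0L
      root_keys <- c(root_keys, key)
    }
  }

  edge_rows <- list()
  edge_seen <- character(0)
  frontier <- sort(names(glycans))
  rule_list <- lapply(seq_len(nrow(rules)), function(i) rule_row(rules, i))
  rule_list <- rule_list[order(vapply(rule_list, `[[`, integer(1), "index"))]

  round_k <- 0L
  while (round_k < max_rounds && length(frontier) > 0L) {
    round_k <- round_k + 1L
    next_frontier <- character(0)
    for (key in frontier) {
      g <- glycans[[key]]
      for (r in rule_list) {
        prods <- infer_products(g, r)
        for (i in seq_len(nrow(prods))) {
          pkey <- prods$product[i]
          if (identical(pkey, key)) next  # no self-loops
          if (!pkey %in% names(glycans)) {
            glycans[[pkey]] <- prods$glycan[[i]]
            round_of[pkey] <- round_k
            next_frontier <- c(next_frontier, pkey)
            if (length(glycans) > max_nodes) {
              abort(paste0("network exceeded max_nodes = ", max_nodes,
                           " at round ", round_k,
                           "; the rule set generates products indefinitely"),
                    class = "glyconet_network_overflow")
            }
          }
          ekey <- paste(key, pkey, r$enzyme, sep = "\r")
          if (!ekey %in% edge_seen) {
            edge_seen <- c(edge_seen, ekey)
            edge_rows[[length(edge_rows) + 1L]] <-
              tibble(substrate = key, product = pkey, enzyme = r$enzyme,
                     ec = r$ec, rule_index = r$index,
                     site = list(prods$site[[i]]), round = round_k)
          }
        }
      }
    }
    frontier <- sort(unique(next_frontier))
  }

  keys <- names(glycans)
  ord <- order(round_of[keys], keys)
  keys <- keys[ord]
  nodes <- tibble(
    key = keys,
    round = unname(round_of[keys]),
    composition = vapply(keys, function(k) composition_string(glycans[[k]]),
                         character(1), USE.NAMES = FALSE),
    glycan = unname(glycans[keys])
  )
  edges <- if (length(edge_rows) == 0L) {
    tibble(substrate = character(), product = character(),
           enzyme = character(), ec = character(), rule_index = integer(),
           site = list(), round = integer())
  } else {
    dplyr::arrange(dplyr::bind_rows(edge_rows), round, substrate, rule_index,
                   product)
  }
  new_glycan_network(nodes, edges, root_keys,
                     params = list(max_rounds = max_rounds,
                                   rounds_run = round_k,
                                   max_nodes = max_nodes,
                                   rules = rules$index))
}

#' @export
print.glycan_network <- function(x, ...) {
  cat("<glycan_network> ", nrow(x$nodes), " glycans, ", nrow(x$edges),
      " reactions (", x$params$rounds_run, " rounds from ",
      length(x$roots), " root", if (length(x$roots) > 1) "s", ")\n", sep = "")
  invisible(x)
}

#' Prune a glycan network
#'
#' Removes nodes failing `keep` together with their incident edges; used
#' e.g. to discard glycans that do not occur in the Golgi from an inferred
#' network. Roots may never be removed.
#'
#' @param net A `glycan_network`.
#' @param keep Either a predicate `function(glycan, key)` returning `TRUE`
#'   to keep a node, or a character vector whitelist of canonical keys.
#' @return The pruned `glycan_network`.
#' @examples
#' rules <- load_rule_db()
#' net <- forward_network_inference(glycan_fixture("M9"), rules, max_rounds = 7)
#' no_fuc <- prune_network(net, function(g, key) composition(g)[["F"]] == 0)
#' @export
prune_network <- function(net, keep) {
  stopifnot(inherits(net, "glycan_network"))
  if (is.character(keep)) {
    whitelist <- keep
    keep_fun <- function(g, key) key %in% whitelist
  } else {
    stopifnot(is.function(keep))
    keep_fun <- keep
  }
  ok <- vapply(seq_len(nrow(net$nodes)), function(i) {
    isTRUE(keep_fun(net$nodes$glycan[[i]], net$nodes$key[i]))
  }, logical(1))
  dropped_roots <- setdiff(net$roots, net$nodes$key[ok])
  if (length(dropped_roots) > 0L) {
    abort(paste0("prune predicate would remove root glycan(s): ",
                 paste(dropped_roots, collapse = ", ")),
          class = "glyconet_prune_root")
  }
  nodes <- net$nodes[ok, ]
  edges <- net$edges[net$edges$substrate %in% nodes$key &
                       net$edges$product %in% nodes$key, ]
  new_glycan_network(nodes, edges, net$roots, net$params)
}

#' Per-round network summary
#'
#' Summarises a network round by round: glycans first discovered in each
#' round, cumulative glycans, and cumulative reactions. Because the source
#' table's conventions are ambiguous on two points, both readings of each
#' are reported: `n_structures` counts all nodes with round <= r (including
#' the root) and `n_structures_new` only that round's discoveries;
#' `n_reactions` counts reactions discovered up to round r (substrate round
#' < r), while `n_reactions_closed` counts reactions whose two endpoints
#' both lie within rounds <= r.
#'
#' @param net A `glycan_network`.
#' @param per_enzyme If `TRUE`, add one column per enzyme with cumulative
#'   discovered-reaction counts (their row sums equal `n_reactions`).
#' @return A tibble with one row per round, from 0 to the last run round.
#' @export
network_stats <- function(net, per_enzyme = FALSE) {
  stopifnot(inherits(net, "glycan_network"))
  rounds <- 0:net$params$rounds_run
  node_round <- net$nodes$round
  edge_round <- net$edges$round
  prod_round <- net$nodes$round[match(net$edges$product, net$nodes$key)]
  sub_round <- net$nodes$round[match(net$edges$substrate, net$nodes$key)]
  out <- tibble(
    round = rounds,
    n_structures_new = vapply(rounds, function(r) sum(node_round == r),
                              integer(1)),
    n_structures = vapply(rounds, function(r) sum(node_round <= r),
                          integer(1)),
    n_reactions = vapply(rounds, function(r) sum(edge_round <= r), integer(1)),
    n_reactions_closed = vapply(rounds, function(r) {
      sum(pmax(prod_round, sub_round) <= r)
    }, integer(1))
  )
  if (per_enzyme) {
    for (enz in sort(unique(net$edges$enzyme))) {
      out[[enz]] <- vapply(rounds, function(r) {
        sum(edge_round <= r & net$edges$enzyme == enz)
      }, integer(1))
    }
  }
  out
}

# ---- broom-style accessors --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a glycan network into its edge table
#'
#' @param x A `glycan_network`.
#' @param ... Unused.
#' @return A tibble of reactions: `substrate`, `product`, `enzyme`, `ec`,
#'   `rule_index`, `round`, plus substrate/product rounds.
#' @export
tidy.glycan_network <- function(x, ...) {
  edges <- dplyr::select(x$edges, -"site")
  edges$substrate_round <- x$nodes$round[match(edges$substrate, x$nodes$key)]
  edges$product_round <- x$nodes$round[match(edges$product, x$nodes$key)]
  edges
}

#' One-row summary of a glycan network
#'
#' @param x A `glycan_network`.
#' @param ... Unused.
#' @return A one-row tibble: `n_glycans`, `n_reactions`, `n_enzymes_used`,
#'   `rounds`, `n_roots`.
#' @export
glance.glycan_network <- function(x, ...) {
  tibble(n_glycans = nrow(x$nodes), n_reactions = nrow(x$edges),
         n_enzymes_used = dplyr::n_distinct(x$edges$enzyme),
         rounds = x$params$rounds_run, n_roots = length(x$roots))
}

#' Plot a glycan network
#'
#' Draws the reaction network with glycans laid out left to right by
#' discovery round, edges coloured by catalysing enzyme.
#'
#' @param object A `glycan_network`.
#' @param label_nodes Label nodes with their composition (default) or not.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glycan_network <- function(object, label_nodes = TRUE, ...) {
  nodes <- object$nodes
  set.seed(1L)  # layout jitter only; network content is deterministic
  lay <- tibble(
    key = nodes$key,
    x = nodes$round,
    y = stats::ave(seq_len(nrow(nodes)), nodes$round,
                   FUN = function(i) seq_along(i) - (length(i) + 1) / 2)
  )
  edges <- object$edges
  seg <- dplyr::mutate(edges,
    x = lay$x[match(.data$substrate, lay$key)],
    y = lay$y[match(.data$substrate, lay$key)],
    xend = lay$x[match(.data$product, lay$key)],
    yend = lay$y[match(.data$product, lay$key)])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$enzyme),
      arrow = grid::arrow(length = grid::unit(2, "mm")), alpha = 0.7) +
    ggplot2::geom_point(data = lay, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::labs(x = "round", y = NULL, colour = "enzyme") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
  if (label_nodes) {
    lay$composition <- nodes$composition
    p <- p + ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$composition),
      size = 2.5, vjust = -1)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
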