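# Shared fixtures, random-tree generators and independent brute-force oracles.

M9_TEXT <- "Ma2Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN"
M8_TEXT <- "Ma2Ma2Ma3(Ma3(Ma2Ma6)Ma6)Mb4GNb4GN"
MAN5_TEXT <- "Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN"
GNM5_TEXT <- "GNb2Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN"
GNGN_TEXT <- "GNb2Ma3(GNb2Ma6)Mb4GNb4GN"  # biantennary core

SYMS <- c("M", "GN", "A", "AN", "F", "NN")
POSITIONS <- c(2L, 3L, 4L, 6L)

# Random glycan with n residues (uniform random attachment at free positions).
rand_glycan <- function(n) {
  g <- glycan(residue(sample(SYMS, 1)))
  for (i in seq_len(n - 1L)) {
    repeat {
      addrs <- find_residues(g)
      at <- addrs[[sample(length(addrs), 1)]]
      node <- glyconet:::get_node(g, at)
      taken <- vapply(node$kids, function(k) k$pos, integer(1))
      free <- setdiff(POSITIONS, taken)
      if (length(free) > 0L) {
        pos <- free[sample.int(length(free), 1)]
        g <- attach_residue(g, at, residue(sample(SYMS, 1),
                                           sample(c("a", "b"), 1), pos))
        break
      }
    }
  }
  g
}

# Write a glycan's tree with a RANDOM branch order at every node (valid
# LinearCode, but not canonical) so parsing it back exercises canonicalization.
write_shuffled <- function(g) {
  wr <- function(node) {
    tok <- node$sym
    if (!is.na(node$ano)) tok <- paste0(tok, node$ano, node$pos)
    if (length(node$kids) == 0L) return(tok)
    kids <- node$kids[sample(length(node$kids))]
    parts <- vapply(kids, wr, character(1))
    if (length(parts) > 1L) parts[-1L] <- paste0("(", parts[-1L], ")")
    paste0(paste0(parts, collapse = ""), tok)
  }
  wr(g$root)
}

# All LinearCode writings of g over every product of per-node branch
# permutations (used to verify canonical-form invariance exhaustively).
all_branch_writings <- function(g) {
  perms <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (p in perms(n - 1L)) for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
    out
  }
  wr <- function(node) {
    tok <- node$sym
    if (!is.na(node$ano)) tok <- paste0(tok, node$ano, node$pos)
    if (length(node$kids) == 0L) return(tok)
    kid_writes <- lapply(node$kids, wr)   # each: character vector of variants
    out <- character(0)
    for (p in perms(length(node$kids))) {
      combos <- expand.grid(lapply(kid_writes[p], identity),
                            stringsAsFactors = FALSE)
      for (ri in seq_len(nrow(combos))) {
        parts <- as.character(unlist(combos[ri, ]))
        if (length(parts) > 1L) parts[-1L] <- paste0("(", parts[-1L], ")")
        out <- c(out, paste0(paste0(parts, collapse = ""), tok))
      }
    }
    unique(out)
  }
  wr(g$root)
}

# Independent traversal oracle for find_residues: iterative stack walk.
oracle_find <- function(g, sym = NULL, ano = NULL, pos = NULL,
                        terminal_only = FALSE) {
  out <- list()
  stack <- list(list(node = g$root, at = integer(0)))
  while (length(stack) > 0L) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    node <- cur$node
    ok <- (is.null(sym) || identical(node$sym, sym)) &&
      (is.null(ano) || identical(node$ano, ano)) &&
      (is.null(pos) || identical(node$pos, as.integer(pos))) &&
      (!terminal_only || length(node$kids) == 0L)
    if (ok) out[[length(out) + 1L]] <- cur$at
    for (k in node$kids) {
      stack[[length(stack) + 1L]] <- list(node = k, at = c(cur$at, k$pos))
    }
  }
  out
}

# Independent generate-and-test matcher oracle: enumerate every injective
# assignment of (non-ellipsis) pattern nodes to subject residues that
# preserves the parent relation, then test all attribute/anchor conditions;
# finally apply the same specificity filter as the engine.
oracle_sites <- function(rule, g) {
  r <- glyconet:::as_rule(rule)
  # flatten pattern, parents before children, dropping ellipsis nodes
  pnodes <- list()
  flat <- function(node, parent) {
    if (node$sym == "...") return(invisible(NULL))
    pnodes[[length(pnodes) + 1L]] <<- list(node = node, parent = parent)
    me <- length(pnodes)
    for (k in node$kids) flat(k, me)
  }
  flat(r$substrate$root, 0L)
  # flatten subject
  snodes <- list()
  sflat <- function(node, at, parent) {
    snodes[[length(snodes) + 1L]] <<- list(node = node, at = at,
                                           parent = parent)
    me <- length(snodes)
    for (k in node$kids) sflat(k, c(at, k$pos), me)
  }
  sflat(g$root, integer(0), 0L)

  targets <- list()
  assign_next <- function(i, map) {
    if (i > length(pnodes)) {
      # complete assignment passed all checks: record target binding
      for (j in seq_along(pnodes)) {
        if (isTRUE(pnodes[[j]]$node$target)) {
          targets[[length(targets) + 1L]] <<- snodes[[map[j]]]$at
        }
      }
      return(invisible(NULL))
    }
    pn <- pnodes[[i]]$node
    for (s in seq_along(snodes)) {
      if (s %in% map) next
      sn <- snodes[[s]]$node
      if (pn$sym != "*" && pn$sym != sn$sym) next
      if (!is.na(pn$ano) && !identical(pn$ano, sn$ano)) next
      if (!is.na(pn$pos) && !identical(pn$pos, sn$pos)) next
      if (isTRUE(pn$anchored) && length(sn$kids) > 0L) next
      pp <- pnodes[[i]]$parent
      if (pp != 0L && snodes[[s]]$parent != map[pp]) next
      assign_next(i + 1L, c(map, s))
    }
  }
  assign_next(1L, integer(0))
  if (length(targets) == 0L) return(list())
  keys <- vapply(targets, function(a) paste(a, collapse = "/"), character(1))
  targets <- targets[!duplicated(keys)]
  ord <- order(vapply(targets, function(a) {
    paste(formatC(a, width = 2, flag = "0"), collapse = "/")
  }, character(1)))
  targets <- targets[ord]
  Filter(function(at) check_specificity(r, g, at), targets)
}

# Minimal substrate embeddings for the 27 rule rows (used by the per-row
# golden tests in both the module and acceptance suites).
golden <- tibble::tribble(
  ~index, ~substrate,
  1L, "Ma2Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN",
  2L, "Ma3(Ma2Ma3(Ma6)Ma6)Mb4GNb4GN",
  3L, "GNb2Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN",
  4L, "GNb2Ma3(Ma6Ma6)Mb4GNb4GN",
  5L, "GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
  6L, "Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN",
  7L, "GNb2Ma3(Ma6)Mb4GNb4GN",
  8L, "GNb2Ma3(Ma6)Mb4GNb4GN",
  9L, "GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
  10L, "GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
  11L, "GNb2Ma3(Ab4GNb2Ma6)Mb4GNb4GN",
  12L, "GNb2Ma3(Ma6)Mb4GNb4GN",
  13L, "Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  14L, "Ab4GNb3Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  15L, "Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  16L, "GNb2Ma3(Ma6)Mb4GNb4GN",
  17L, "Ab3GNb2Ma3(Ma6)Mb4GNb4GN",
  18L, "NNa3Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  19L, "Ab3GNb2Ma3(Ma6)Mb4GNb4GN",
  20L, "Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  21L, "Fa2Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  22L, "Fa2Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  23L, "Fa2Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  24L, "Ab4GNb2Ma3(Ma6)Mb4GNb4GN",
  25L, "Ab4Ab3AN",
  26L, "AN",
  27L, "Ab3GNb2Ma3(Ma6)Mb4GNb4GN"
)

# Independent exhaustive reachability oracle for forward inference:
# depth-limited recursion with a best-depth memo, no frontier bookkeeping.
oracle_reachable <- function(root, rules, max_depth) {
  best <- new.env(parent = emptyenv())
  edges <- new.env(parent = emptyenv())
  rule_rows <- lapply(seq_len(nrow(rules)), function(i) rules[i, ])
  visit <- function(g, d) {
    key <- canonical_form(g)
    prev <- get0(key, envir = best, ifnotfound = Inf)
    if (d >= prev) return(invisible(NULL))
    assign(key, d, envir = best)
    if (d == max_depth) return(invisible(NULL))
    for (r in rule_rows) {
      prods <- infer_products(g, r)
      for (i in seq_len(nrow(prods))) {
        if (identical(prods$product[i], key)) next
        ek <- paste(key, prods$product[i], r$enzyme, sep = "\r")
        assign(ek, TRUE, envir = edges)
        visit(prods$glycan[[i]], d + 1L)
      }
    }
  }
  visit(root, 0L)
  list(nodes = sort(ls(best)), edges = sort(ls(edges)),
       rounds = unlist(as.list(best)))
}
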