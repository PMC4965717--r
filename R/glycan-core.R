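#' @importFrom rlang abort warn `%||%`
#' @importFrom tibble tibble as_tibble
NULL

# Closed monosaccharide alphabet (LinearCode symbols):
# M = Man, GN = GlcNAc, A = Gal, AN = GalNAc, F = Fuc, NN = Neu5Ac.
GLYCO_SYMBOLS <- c("M", "GN", "A", "AN", "F", "NN")

# Attachment positions seen on N-glycans in this rule set. Sialic acid linkages
# written a3/a6 (for alpha2-3/alpha2-6) are stored as positions 3/6; the
# 2-carbon origin of Neu5Ac is implicit and uniform.
GLYCO_POSITIONS <- c(2L, 3L, 4L, 6L)

new_residue <- function(sym, ano = NA_character_, pos = NA_integer_,
                        kids = list()) {
  list(sym = sym, ano = ano, pos = as.integer(pos), kids = kids)
}

#' Create a residue
#'
#' A residue is one monosaccharide node of a glycan tree: a symbol from the
#' closed six-letter alphabet (`M`, `GN`, `A`, `AN`, `F`, `NN`), an anomeric
#' configuration (`"a"` or `"b"`) and the position on its parent it attaches
#' to (2, 3, 4 or 6). The root (reducing-end) residue of a glycan carries no
#' linkage.
#'
#' @param sym Monosaccharide symbol, one of `"M"`, `"GN"`, `"A"`, `"AN"`,
#'   `"F"`, `"NN"`.
#' @param ano Anomer, `"a"` (alpha) or `"b"` (beta); `NA` for a root residue.
#' @param pos Attachment position on the parent (2, 3, 4 or 6); `NA` for a
#'   root residue.
#' @return A residue object (plain list with fields `sym`, `ano`, `pos`,
#'   `kids`).
#' @examples
#' residue("F", "a", 6)
#' @export
residue <- function(sym, ano = NA, pos = NA) {
  sym <- as.character(sym)
  if (length(sym) != 1L || !sym %in% GLYCO_SYMBOLS) {
    abort(paste0("unknown monosaccharide symbol: ", sym),
          class = "glyconet_unknown_symbol")
  }
  ano <- as.character(ano)
  pos <- suppressWarnings(as.integer(pos))
  if (is.na(ano) != is.na(pos)) {
    abort("anomer and position must be given together (or both NA for a root)",
          class = "glyconet_bad_linkage")
  }
  if (!is.na(ano)) {
    if (!ano %in% c("a", "b")) {
      abort(paste0("anomer must be 'a' or 'b', got: ", ano),
            class = "glyconet_bad_linkage")
    }
    if (!pos %in% GLYCO_POSITIONS) {
      abort(paste0("attachment position must be one of 2,3,4,6, got: ", pos),
            class = "glyconet_bad_linkage")
    }
  }
  new_residue(sym, ano, pos)
}

# Recursively sort children into canonical order. Children of one node are
# ordered by (link position ascending, canonical subtree string ascending);
# since at most one child can occupy a position, the position alone already
# breaks all ties on valid glycans, but the subtree string keeps the order
# total on degenerate inputs.
sort_node <- function(node) {
  if (length(node$kids) == 0L) return(node)
  node$kids <- lapply(node$kids, sort_node)
  keys <- vapply(node$kids, node_string, character(1))
  pos <- vapply(node$kids, function(k) k$pos, integer(1))
  node$kids <- node$kids[order(pos, keys)]
  node
}

# LinearCode text of one (sub)tree, children assumed sorted.
node_string <- function(node) {
  tok <- node$sym
  if (!is.na(node$ano)) tok <- paste0(tok, node$ano, node$pos)
  if (length(node$kids) == 0L) return(tok)
  parts <- vapply(node$kids, node_string, character(1))
  if (length(parts) > 1L) {
    parts[-1L] <- paste0("(", parts[-1L], ")")
  }
  paste0(paste0(parts, collapse = ""), tok)
}

count_nodes <- function(node) {
  1L + sum(vapply(node$kids, count_nodes, integer(1)))
}

validate_node <- function(node, is_root = TRUE) {
  if (!node$sym %in% GLYCO_SYMBOLS) {
    abort(paste0("unknown monosaccharide symbol: ", node$sym),
          class = "glyconet_unknown_symbol")
  }
  if (is_root) {
    if (!is.na(node$ano) || !is.na(node$pos)) {
      abort("root residue must not carry a parent linkage",
            class = "glyconet_bad_linkage")
    }
  } else {
    if (is.na(node$ano) || is.na(node$pos)) {
      abort("non-root residue must carry exactly one (anomer, position) pair",
            class = "glyconet_bad_linkage")
    }
  }
  pos <- vapply(node$kids, function(k) as.integer(k$pos), integer(1))
  if (anyDuplicated(pos)) {
    abort("two children of one residue share an attachment position",
          class = "glyconet_occupied_position")
  }
  for (k in node$kids) validate_node(k, is_root = FALSE)
  invisible(TRUE)
}

#' Construct a glycan from a residue tree
#'
#' Wraps a residue tree into a `glycan` object, validating the tree (closed
#' alphabet, single parent linkage per residue, at most one substituent per
#' position) and putting branches into canonical order. Most users will
#' instead call [parse_structure()] on LinearCode text.
#'
#' @param root A residue tree built with [residue()], with children in the
#'   `kids` field.
#' @return A `glycan` object.
#' @seealso [parse_structure()], [canonical_form()]
#' @export
glycan <- function(root) {
  validate_node(root, is_root = TRUE)
  root <- sort_node(root)
  structure(list(root = root), class = "glycan")
}

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan> ", canonical_form(x), "\n", sep = "")
  comp <- composition(x)
  comp <- comp[comp > 0L]
  cat("  residues: ", sum(comp), "  (",
      paste0(names(comp), ":", comp, collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' @export
format.glycan <- function(x, ...) canonical_form(x)

is_glycan <- function(x) inherits(x, "glycan")

#' Canonical text form of a glycan
#'
#' Returns a deterministic LinearCode string that is identical for any two
#' trees related by branch-order permutation and distinct for non-isomorphic
#' trees. Branches of each residue are ordered by (position ascending,
#' canonical subtree string ascending), so e.g. the alpha3 arm is written
#' before the alpha6 arm. The key re-parses to the same glycan, making it a
#' safe deduplication key for network construction.
#'
#' @param g A `glycan`.
#' @return A single LinearCode string.
#' @examples
#' canonical_form(parse_structure("Ma6(Ma3)Mb4GNb4GN"))
#' @export
canonical_form <- function(g) {
  stopifnot(is_glycan(g))
  node_string(g$root)
}

#' Monosaccharide composition of a glycan
#'
#' Counts residues per monosaccharide symbol over the whole tree.
#'
#' @param g A `glycan`.
#' @return A named integer vector over the six-symbol alphabet; the sum equals
#'   the residue count of the glycan.
#' @examples
#' composition(glycan_fixture("M9"))  # M:9 GN:2
#' @export
composition <- function(g) {
  stopifnot(is_glycan(g))
  counts <- stats::setNames(integer(length(GLYCO_SYMBOLS)), GLYCO_SYMBOLS)
  walk <- function(node) {
    counts[node$sym] <<- counts[node$sym] + 1L
    for (k in node$kids) walk(k)
  }
  walk(g$root)
  counts
}

composition_string <- function(g) {
  comp <- composition(g)
  comp <- comp[comp > 0L]
  paste0(names(comp), comp, collapse = "")
}

n_residues <- function(g) count_nodes(g$root)

# ---- residue addresses ------------------------------------------------------
# A residue address is the integer vector of link positions walked from the
# root; integer(0) addresses the root itself. Positions are unique among the
# children of one residue, so the path is unambiguous and stable under
# canonicalization.

get_node <- function(g, at) {
  node <- g$root
  for (p in at) {
    hit <- NULL
    for (k in node$kids) if (k$pos == p) { hit <- k; break }
    if (is.null(hit)) {
      abort(paste0("no residue at address ", format_address(at)),
            class = "glyconet_address_not_found")
    }
    node <- hit
  }
  node
}

has_node <- function(g, at) {
  !inherits(try(get_node(g, at), silent = TRUE), "try-error")
}

#' Format a residue address
#'
#' Renders an address (integer vector of link positions from the root) as a
#' readable path such as `"GN>GNb4>Mb4>Ma3"`.
#'
#' @param at Integer vector address.
#' @param g Optionally, the glycan the address refers to; when given, residue
#'   symbols are included in the path.
#' @return A single string.
#' @export
format_address <- function(at, g = NULL) {
  if (is.null(g)) {
    if (length(at) == 0L) return("<root>")
    return(paste0("<root>/", paste0(at, collapse = "/")))
  }
  node <- g$root
  parts <- node$sym
  for (p in at) {
    hit <- NULL
    for (k in node$kids) if (k$pos == p) { hit <- k; break }
    if (is.null(hit)) abort(paste0("no residue at address ", format_address(at)),
                            class = "glyconet_address_not_found")
    node <- hit
    parts <- c(parts, paste0(node$sym, node$ano, node$pos))
  }
  paste0(parts, collapse = ">")
}

# Pure functional update of the node at `at` via function f(node).
modify_node <- function(node, at, f) {
  if (length(at) == 0L) return(f(node))
  p <- at[[1L]]
  for (i in seq_along(node$kids)) {
    if (node$kids[[i]]$pos == p) {
      node$kids[[i]] <- modify_node(node$kids[[i]], at[-1L], f)
      return(node)
    }
  }
  abort("no residue at address", class = "glyconet_address_not_found")
}

#' Attach a residue to a glycan
#'
#' Returns a new glycan with `new` attached to the residue addressed by `at`
#' (the input is unchanged). This is the structural primitive behind
#' glycosyltransferase action: one monosaccharide is transferred onto an
#' acceptor residue at a free position.
#'
#' @param g A `glycan`.
#' @param at Residue address (integer vector of link positions from the root;
#'   `integer(0)` is the root).
#' @param new A linked [residue()] (anomer and position must be set).
#' @return A new `glycan` with one more residue.
#' @examples
#' g <- parse_structure("GNb4GN")
#' canonical_form(attach_residue(g, integer(0), residue("F", "a", 6)))
#' @export
attach_residue <- function(g, at, new) {
  stopifnot(is_glycan(g))
  if (is.na(new$ano) || is.na(new$pos)) {
    abort("attached residue needs an (anomer, position) linkage",
          class = "glyconet_bad_linkage")
  }
  target <- get_node(g, at)
  occupied <- any(vapply(target$kids, function(k) k$pos == new$pos, logical(1)))
  if (occupied) {
    abort(paste0("position ", new$pos, " already substituted at ",
                 format_address(at, g)),
          class = "glyconet_occupied_position")
  }
  new$kids <- list()
  root <- modify_node(g$root, at, function(node) {
    node$kids <- c(node$kids, list(new))
    node
  })
  glycan(root)
}

#' Detach a terminal residue from a glycan
#'
#' Returns a new glycan with the leaf residue addressed by `at` removed (the
#' input is unchanged). This is the structural primitive behind glycosidase
#' action: hydrolases remove one terminal (non-reducing) monosaccharide.
#'
#' @param g A `glycan`.
#' @param at Address of a terminal (leaf) residue.
#' @return A new `glycan` with one fewer residue.
#' @export
detach_residue <- function(g, at) {
  stopifnot(is_glycan(g))
  if (length(at) == 0L) {
    abort("cannot detach the root (reducing-end) residue",
          class = "glyconet_nonterminal_removal")
  }
  node <- get_node(g, at)
  if (length(node$kids) > 0L) {
    abort(paste0("residue at ", format_address(at, g),
                 " is not terminal; only leaf residues can be removed"),
          class = "glyconet_nonterminal_removal")
  }
  parent_at <- at[-length(at)]
  p <- at[[length(at)]]
  root <- modify_node(g$root, parent_at, function(nd) {
    keep <- vapply(nd$kids, function(k) k$pos != p, logical(1))
    nd$kids <- nd$kids[keep]
    nd
  })
  glycan(root)
}

# Preorder traversal of addresses in canonical order.
all_addresses <- function(g) {
  out <- list()
  walk <- function(node, at) {
    out[[length(out) + 1L]] <<- at
    for (k in node$kids) walk(k, c(at, k$pos))
  }
  walk(g$root, integer(0))
  out
}

#' Find residues matching a query
#'
#' Scans the glycan in canonical (preorder) traversal order and returns the
#' addresses of residues matching the query. Any of `sym`, `ano`, `pos` may be
#' `NULL` to leave that attribute unconstrained.
#'
#' @param g A `glycan`.
#' @param sym Monosaccharide symbol to match, or `NULL`.
#' @param ano Anomer (`"a"`/`"b"`) to match, or `NULL`.
#' @param pos Attachment position to match, or `NULL`.
#' @param terminal_only If `TRUE`, only leaf (non-reducing terminal) residues
#'   are returned.
#' @return A list of integer-vector addresses (possibly empty).
#' @examples
#' length(find_residues(glycan_fixture("M9"), sym = "M", ano = "a", pos = 2,
#'                      terminal_only = TRUE))  # 3
#' @export
find_residues <- function(g, sym = NULL, ano = NULL, pos = NULL,
                          terminal_only = FALSE) {
  stopifnot(is_glycan(g))
  out <- list()
  walk <- function(node, at) {
    ok <- TRUE
    if (!is.null(sym) && !identical(node$sym, sym)) ok <- FALSE
    if (ok && !is.null(ano) && !identical(node$ano, ano)) ok <- FALSE
    if (ok && !is.null(pos) && !identical(node$pos, as.integer(pos))) ok <- FALSE
    if (ok && terminal_only && length(node$kids) > 0L) ok <- FALSE
    if (ok) out[[length(out) + 1L]] <<- at
    for (k in node$kids) walk(k, c(at, k$pos))
  }
  walk(g$root, integer(0))
  out
}
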