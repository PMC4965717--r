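# Subtree-embedding pattern matcher.
#
# A pattern matches rooted at a subject residue when symbols and specified
# linkage parts agree, every non-ellipsis pattern child can be assigned
# injectively to a distinct subject child (recursively), and every anchored
# pattern node maps to a subject leaf. Subject residues not covered by the
# pattern are allowed (containment semantics); ellipsis children impose
# nothing. The matcher returns the subject address bound to the pattern's
# '!'-marked node (or NA if the pattern has none).

# Match pattern node pn against subject node sn (at address s_at).
# Returns list(ok = TRUE/FALSE, target = address or NULL).
match_node <- function(pn, sn, s_at) {
  if (pn$sym == "...") return(list(ok = TRUE, target = NULL))
  if (pn$sym != "*" && pn$sym != sn$sym) return(list(ok = FALSE))
  if (!is.na(pn$ano) && !identical(pn$ano, sn$ano)) return(list(ok = FALSE))
  if (!is.na(pn$pos) && !identical(pn$pos, sn$pos)) return(list(ok = FALSE))
  if (isTRUE(pn$anchored) && length(sn$kids) > 0L) return(list(ok = FALSE))

  pkids <- Filter(function(k) k$sym != "...", pn$kids)
  target <- if (isTRUE(pn$target)) s_at else NULL

  if (length(pkids) == 0L) return(list(ok = TRUE, target = target))
  if (length(pkids) > length(sn$kids)) return(list(ok = FALSE))

  # Injective assignment of pattern children to subject children, with
  # backtracking. Subject children have unique positions, so a pattern child
  # with a specified position has at most one candidate.
  assign_kids <- function(i, used, tgt) {
    if (i > length(pkids)) return(list(ok = TRUE, target = tgt))
    pk <- pkids[[i]]
    for (j in seq_along(sn$kids)) {
      if (used[j]) next
      sk <- sn$kids[[j]]
      res <- match_node(pk, sk, c(s_at, sk$pos))
      if (res$ok) {
        used2 <- used; used2[j] <- TRUE
        out <- assign_kids(i + 1L, used2, tgt %||% res$target)
        if (out$ok) return(out)
      }
    }
    list(ok = FALSE)
  }
  assign_kids(1L, logical(length(sn$kids)), target)
}

# All rooted matches of `pattern` in `g`. Returns a list of
# list(at = root address of the match, target = bound target address or NULL).
pattern_matches <- function(pattern, g) {
  out <- list()
  walk <- function(node, at) {
    res <- match_node(pattern$root, node, at)
    if (res$ok) out[[length(out) + 1L]] <<- list(at = at, target = res$target)
    for (k in node$kids) walk(k, c(at, k$pos))
  }
  walk(g$root, integer(0))
  out
}

#' Test whether a pattern occurs on a glycan
#'
#' @param pattern A `glycan_pattern` from [parse_pattern()].
#' @param g A `glycan`.
#' @param at If given, the pattern must match rooted at this residue address;
#'   otherwise any rooting counts.
#' @return `TRUE` or `FALSE`.
#' @export
pattern_matches_glycan <- function(pattern, g, at = NULL) {
  stopifnot(inherits(pattern, "glycan_pattern"), is_glycan(g))
  if (!is.null(at)) {
    node <- get_node(g, at)
    return(match_node(pattern$root, node, as.integer(at))$ok)
  }
  length(pattern_matches(pattern, g)) > 0L
}

# ---- core-branch resolution -------------------------------------------------

# Address of the core beta-Man (root GN -> GN b4 -> M b4), or NULL.
core_mb4_address <- function(g) {
  r <- g$root
  if (r$sym != "GN") return(NULL)
  gn2 <- NULL
  for (k in r$kids) if (k$pos == 4L && k$sym == "GN" && k$ano == "b") gn2 <- k
  if (is.null(gn2)) return(NULL)
  for (k in gn2$kids) {
    if (k$pos == 4L && k$sym == "M" && k$ano == "b") return(c(4L, 4L))
  }
  NULL
}

# Address of a named core branch residue: "Mb4" (core beta-Man), "Ma3"/"Ma6"
# (its alpha3/alpha6 children). NULL when absent.
resolve_core_branch <- function(g, spec) {
  mb4 <- core_mb4_address(g)
  if (is.null(mb4)) return(NULL)
  if (spec == "Mb4") return(mb4)
  node <- get_node(g, mb4)
  want_pos <- if (spec == "Ma3") 3L else 6L
  for (k in node$kids) {
    if (k$pos == want_pos && k$sym == "M" && k$ano == "a") {
      return(c(mb4, want_pos))
    }
  }
  NULL
}

is_prefix_of <- function(prefix, x) {
  length(prefix) <= length(x) &&
    (length(prefix) == 0L || identical(as.integer(prefix),
                                       as.integer(x[seq_along(prefix)])))
}

# ---- constraint evaluation --------------------------------------------------

#' Evaluate a constraint on a glycan
#'
#' Evaluates a parsed constraint expression against a glycan, optionally in
#' the context of an action target (needed by target-context atoms such as
#' `~_Ma3|Mb4` or `!`-marked patterns).
#'
#' @param constraint A `glycan_constraint` from [parse_constraint()].
#' @param g A `glycan`.
#' @param target Optional residue address of the action site.
#' @return `TRUE` or `FALSE`.
#' @export
eval_constraint <- function(constraint, g, target = NULL) {
  stopifnot(inherits(constraint, "glycan_constraint"), is_glycan(g))
  eval_ast(constraint, g, target)
}

eval_ast <- function(ast, g, target) {
  switch(ast$op,
    true = TRUE,
    not = !eval_ast(ast$x, g, target),
    and = all(vapply(ast$xs, eval_ast, logical(1), g = g, target = target)),
    or = any(vapply(ast$xs, eval_ast, logical(1), g = g, target = target)),
    gnbis = {
      mb4 <- core_mb4_address(g)
      if (is.null(mb4)) FALSE else {
        node <- get_node(g, mb4)
        any(vapply(node$kids,
                   function(k) k$pos == 4L && k$sym == "GN" && k$ano == "b",
                   logical(1)))
      }
    },
    any_gal = length(find_residues(g, sym = "A", ano = "b")) > 0L,
    pattern_in = {
      b <- resolve_core_branch(g, ast$branch)
      if (is.null(b)) FALSE else {
        hits <- pattern_matches(ast$pattern, g)
        any(vapply(hits, function(h) is_prefix_of(b, h$at), logical(1)))
      }
    },
    target_in = {
      if (is.null(target)) {
        abort("constraint refers to the action target, but none was given",
              class = "glyconet_missing_target")
      }
      outer <- resolve_core_branch(g, ast$of)
      inner <- resolve_core_branch(g, ast$branch)
      !is.null(outer) && !is.null(inner) && is_prefix_of(outer, inner) &&
        is_prefix_of(inner, target)
    },
    pattern = {
      hits <- pattern_matches(ast$pattern, g)
      if (isTRUE(ast$target_bound)) {
        if (is.null(target)) {
          abort("constraint refers to the action target, but none was given",
                class = "glyconet_missing_target")
        }
        any(vapply(hits, function(h) {
          !is.null(h$target) && identical(as.integer(h$target),
                                          as.integer(target))
        }, logical(1)))
      } else {
        length(hits) > 0L
      }
    },
    abort(paste0("unknown constraint node: ", ast$op))
  )
}
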