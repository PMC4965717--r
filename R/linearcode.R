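# LinearCode reader/writer and the pattern dialect used by the rule database.
#
# Structure grammar (right to left): a residue is preceded by its children,
# the first child as a plain chain and further children in parentheses, e.g.
# "Ma3(Ma6)Mb4GNb4GN". Residue tokens are SYMBOL [anomer position], where the
# root (reducing-end) token is bare.
#
# The pattern dialect adds: a leading unbalanced "(" marking a non-reducing
# terminal anchor (the leftmost explicit residue must match a leaf); "*" for
# exactly one residue of any kind; "..." for any descending chain of >= 0
# residues (which absorbs the anchor); linkage parts may be omitted to leave
# them unconstrained; and "!" directly after a symbol marks the action target
# of a rule, e.g. "(M!a2M" (remove this Man) or "GNb4GN!" (attach here).

TOKEN_END_RE <- "(?:\\.\\.\\.|GN!?|AN!?|NN!?|M!?|A!?|F!?|\\*!?)(?:[ab][2-9]?)?$"
TOKEN_PARSE_RE <- "^(\\.\\.\\.|GN|AN|NN|M|A|F|\\*)(!?)([ab]?)([2-9]?)$"

lc_normalize <- function(text) {
  text <- gsub("…", "...", text)
  gsub("[[:space:]]+", "", text)
}

parse_token <- function(tok, offset, pattern = FALSE) {
  m <- regmatches(tok, regexec(TOKEN_PARSE_RE, tok))[[1]]
  if (length(m) == 0L) {
    abort(paste0("syntax error near character ", offset, ": '", tok, "'"),
          class = "glyconet_syntax_error")
  }
  sym <- m[2]; target <- nzchar(m[3]); ano <- m[4]; pos <- m[5]
  if (!pattern && (sym %in% c("*", "...") || target)) {
    abort(paste0("wildcard or target mark not allowed in a structure (character ",
                 offset, ")"), class = "glyconet_syntax_error")
  }
  node <- new_residue(sym,
                      if (nzchar(ano)) ano else NA_character_,
                      if (nzchar(pos)) as.integer(pos) else NA_integer_)
  node$target <- target
  node
}

# Split "prefix(group)(group)TOKEN" from the right; returns node.
parse_segment <- function(s, base, pattern = FALSE) {
  m <- regexpr(TOKEN_END_RE, s, perl = TRUE)
  if (m == -1L) {
    abort(paste0("syntax error near character ", base + nchar(s),
                 ": expected a residue token"),
          class = "glyconet_syntax_error")
  }
  tok <- substr(s, m, nchar(s))
  node <- parse_token(tok, base + m - 1L, pattern = pattern)
  rest <- substr(s, 1L, m - 1L)

  groups <- list()   # parenthesised sibling subtrees, right to left
  while (nzchar(rest) && substr(rest, nchar(rest), nchar(rest)) == ")") {
    depth <- 0L
    i <- nchar(rest)
    start <- NA_integer_
    while (i >= 1L) {
      ch <- substr(rest, i, i)
      if (ch == ")") depth <- depth + 1L
      if (ch == "(") {
        depth <- depth - 1L
        if (depth == 0L) { start <- i; break }
      }
      i <- i - 1L
    }
    if (is.na(start)) {
      abort(paste0("unbalanced parentheses near character ", base + nchar(rest)),
            class = "glyconet_syntax_error")
    }
    inner <- substr(rest, start + 1L, nchar(rest) - 1L)
    if (!nzchar(inner)) {
      abort(paste0("empty branch near character ", base + start),
            class = "glyconet_syntax_error")
    }
    groups <- c(list(parse_segment(inner, base + start, pattern = pattern)),
                groups)
    rest <- substr(rest, 1L, start - 1L)
  }

  kids <- list()
  if (nzchar(rest)) {
    kids <- list(parse_segment(rest, base, pattern = pattern))  # chain child
  }
  node$kids <- c(kids, groups)

  if (!pattern) {
    for (k in node$kids) {
      if (is.na(k$ano) || is.na(k$pos)) {
        abort(paste0("missing linkage on a non-root residue near character ",
                     base), class = "glyconet_syntax_error")
      }
    }
  }
  node
}

#' Parse a LinearCode glycan string
#'
#' Reads LinearCode text such as `"Ma3(Ma6)Mb4GNb4GN"` into a [glycan()]. The
#' rightmost residue token is the reducing-end root and carries no linkage;
#' every other residue is written as symbol + anomer + position (e.g. `Ma3` =
#' Man alpha1-3). The first branch of a residue is written as a plain chain,
#' further branches in parentheses. Branch order in the input is free; the
#' parsed glycan is held in canonical order.
#'
#' @param text A single LinearCode string.
#' @return A `glycan`.
#' @examples
#' parse_structure("GNb4(Fa6)GN")
#' @export
parse_structure <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- lc_normalize(text)
  if (!nzchar(s)) abort("empty glycan string", class = "glyconet_syntax_error")
  if (grepl("[^A-Za-z0-9()]", s)) {
    bad <- regexpr("[^A-Za-z0-9()]", s)
    abort(paste0("syntax error at character ", bad, ": '",
                 substr(s, bad, bad), "'"), class = "glyconet_syntax_error")
  }
  root <- parse_segment(s, 1L, pattern = FALSE)
  if (!is.na(root$ano) || !is.na(root$pos)) {
    abort("root (reducing-end) residue must not carry a linkage",
          class = "glyconet_syntax_error")
  }
  root$target <- NULL
  strip <- function(n) { n$target <- NULL; n$kids <- lapply(n$kids, strip); n }
  glycan(strip(root))
}

#' Write a glycan as canonical LinearCode
#'
#' Inverse of [parse_structure()]; always emits the canonical branch order, so
#' `write_structure(parse_structure(x))` is the canonical form of `x` and the
#' composition `write %then% parse %then% write` is idempotent.
#'
#' @param g A `glycan`.
#' @return A single LinearCode string, identical to [canonical_form()].
#' @export
write_structure <- function(g) canonical_form(g)

# ---- patterns ---------------------------------------------------------------

#' Parse a substrate/product pattern
#'
#' Parses the extended LinearCode dialect used by the enzyme rule database:
#'
#' * a leading unbalanced `"("` anchors the pattern at a non-reducing terminal:
#'   the leftmost explicit residue must match a leaf of the subject glycan;
#' * `"*"` matches exactly one residue of any symbol/linkage;
#' * `"..."` matches any descending chain of zero or more residues (and makes
#'   a leading anchor vacuous);
#' * anomer and/or position may be omitted to leave them unconstrained
#'   (e.g. `"GNb"` = GlcNAc beta-linked at any position);
#' * `"!"` directly after a symbol marks the rule's action target, e.g.
#'   `"(M!a2M"` (this Man is removed) or `"GNb4GN!"` (a residue is attached
#'   here).
#'
#' Matching is by subtree embedding: the subject may carry residues beyond the
#' pattern except where the anchor requires a leaf.
#'
#' @param text Pattern text.
#' @return A `glycan_pattern` object.
#' @examples
#' parse_pattern("(Ma2Ma")
#' parse_pattern("(...Ab4GNb")
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- lc_normalize(text)
  if (!nzchar(s)) abort("empty pattern", class = "glyconet_syntax_error")
  n_open <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  anchored <- FALSE
  if (n_open == n_close + 1L && substr(s, 1L, 1L) == "(") {
    anchored <- TRUE
    s <- substr(s, 2L, nchar(s))
  } else if (n_open != n_close) {
    abort("unbalanced parentheses in pattern", class = "glyconet_syntax_error")
  }
  root <- parse_segment(s, 1L, pattern = TRUE)
  if (anchored) {
    # The leftmost explicit residue in the text is reached by walking first
    # children; it must match a subject leaf. An ellipsis there absorbs the
    # anchor (any chain, possibly empty, up to a leaf always exists).
    mark <- function(n) {
      if (length(n$kids) == 0L) { if (n$sym != "...") n$anchored <- TRUE; return(n) }
      n$kids[[1L]] <- mark(n$kids[[1L]])
      n
    }
    root <- mark(root)
  }
  n_targets <- sum_targets(root)
  if (n_targets > 1L) {
    abort("a pattern may mark at most one action target ('!')",
          class = "glyconet_syntax_error")
  }
  structure(list(root = root, anchored = anchored, text = lc_normalize(text)),
            class = "glycan_pattern")
}

sum_targets <- function(node) {
  isTRUE(node$target) + sum(vapply(node$kids, sum_targets, integer(1)))
}

#' @export
print.glycan_pattern <- function(x, ...) {
  cat("<glycan_pattern> ", x$text,
      if (x$anchored) "  [terminal-anchored]" else "", "\n", sep = "")
  invisible(x)
}

# ---- constraints ------------------------------------------------------------

#' Parse a rule constraint expression
#'
#' Parses the boolean constraint dialect of the rule database. Operators, in
#' increasing binding strength: `or`, `&`, `~` (NOT; the typographic form
#' `$\thicksim$` is also accepted). Atoms:
#'
#' * `Gnbis` — a bisecting GlcNAc is present (a GN linked beta1-4 to the core
#'   beta-Man);
#' * `Ab` — any beta-linked Gal is present anywhere on the glycan;
#' * `X |Y` — pattern `X` occurs within the branch rooted at core residue `Y`
#'   (`Y` is one of `Mb4`, `Ma3`, `Ma6`, resolved on the
#'   Man-beta4-GlcNAc-beta4-GlcNAc core), e.g. `GNb2|Ma3`;
#' * `_X |Y` — the action target lies within branch `X` of `Y` (used negated:
#'   `~_Ma3|Mb4` = the target is not on the core alpha3-Man branch);
#' * any pattern text — the pattern must occur somewhere on the glycan; if it
#'   contains a `!` mark, the marked node must coincide with the action
#'   target (a target-context test).
#'
#' The empty string parses to an expression that is always true.
#'
#' @param text Constraint text (possibly empty or `NA`).
#' @return A `glycan_constraint` object.
#' @examples
#' parse_constraint("GNb2|Ma3 & ~Gnbis")
#' @export
parse_constraint <- function(text) {
  if (length(text) != 1L) abort("constraint must be a single string")
  if (is.na(text)) text <- ""
  s <- gsub("$\\thicksim$", "~", text, fixed = TRUE)
  s <- gsub("∼|˜", "~", s)
  s <- trimws(s)
  if (!nzchar(s)) {
    return(structure(list(op = "true", text = ""), class = "glycan_constraint"))
  }
  terms <- strsplit(s, "\\bor\\b")[[1]]
  parse_term <- function(t) {
    factors <- strsplit(t, "&", fixed = TRUE)[[1]]
    parse_factor <- function(f) {
      f <- trimws(f)
      neg <- 0L
      while (startsWith(f, "~")) {
        neg <- neg + 1L
        f <- trimws(substr(f, 2L, nchar(f)))
      }
      if (!nzchar(f)) abort("empty constraint atom",
                            class = "glyconet_syntax_error")
      atom <- parse_atom(f)
      if (neg %% 2L == 1L) atom <- list(op = "not", x = atom)
      atom
    }
    fs <- lapply(factors, parse_factor)
    if (length(fs) == 1L) fs[[1]] else list(op = "and", xs = fs)
  }
  ts <- lapply(terms, parse_term)
  ast <- if (length(ts) == 1L) ts[[1]] else list(op = "or", xs = ts)
  structure(c(ast, list(text = text)), class = "glycan_constraint")
}

CORE_BRANCH_SPECS <- c("Mb4", "Ma3", "Ma6")

parse_atom <- function(f) {
  f0 <- gsub("[[:space:]]+", "", f)
  if (f0 == "Gnbis") return(list(op = "gnbis"))
  if (f0 == "Ab") return(list(op = "any_gal"))
  if (grepl("^_", f0) && grepl("|", f0, fixed = TRUE)) {
    parts <- strsplit(substr(f0, 2L, nchar(f0)), "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% CORE_BRANCH_SPECS)) {
      abort(paste0("unknown constraint atom: ", f),
            class = "glyconet_unknown_atom")
    }
    return(list(op = "target_in", branch = parts[1], of = parts[2]))
  }
  if (grepl("|", f0, fixed = TRUE)) {
    parts <- strsplit(f0, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[2] %in% CORE_BRANCH_SPECS) {
      abort(paste0("unknown constraint atom: ", f),
            class = "glyconet_unknown_atom")
    }
    return(list(op = "pattern_in", pattern = parse_pattern(parts[1]),
                branch = parts[2]))
  }
  if (grepl("^[A-Za-z(*.]", f0)) {
    pat <- tryCatch(parse_pattern(f0), error = function(e) {
      abort(paste0("unknown constraint atom: ", f),
            class = "glyconet_unknown_atom")
    })
    return(list(op = "pattern", pattern = pat,
                target_bound = sum_targets(pat$root) == 1L))
  }
  abort(paste0("unknown constraint atom: ", f), class = "glyconet_unknown_atom")
}

#' @export
print.glycan_constraint <- function(x, ...) {
  cat("<glycan_constraint> ",
      if (identical(x$op, "true")) "(always true)" else x$text, "\n", sep = "")
  invisible(x)
}
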