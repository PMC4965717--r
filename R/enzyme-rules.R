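# The enzyme rule database and the substrate-specificity engine.
#
# Each rule row is one enzymatic capability: a substrate pattern with a marked
# action target, the residue transferred (for transferases), and a constraint
# expression. The eight substrate-specificity predicates of the source
# framework map onto this encoding as follows: substMinStruct -> the substrate
# pattern itself; substMaxStruct -> an exhaustion constraint (e.g. ~Ma2M for
# "no a1-2 Man left"); substNABranch/substNAStruct/substNAResidue -> negated
# pattern or named atoms (~Gnbis, ~Ab, ~...); targetBranch/targetNABranch ->
# branch-context atoms (X|Y, _X|Y); isTerminalTarget -> the terminal-anchor
# "(" and the target_terminal flag. Undefined predicates are vacuously true.

RULE_DB_COLS <- c("index", "enzyme", "ec", "kind", "substrate_pattern",
                  "product_pattern", "res_add", "link_add", "constraint",
                  "target_terminal", "substrate_printed", "product_printed",
                  "constraint_printed", "constraint_printed_machine",
                  "source_note")

#' Path of the bundled enzyme rule database
#'
#' @return Path to the package's 27-rule CSV.
#' @export
default_rule_path <- function() {
  system.file("extdata", "enzyme_rules.csv", package = "glyconet",
              mustWork = TRUE)
}

#' Load an enzyme rule database
#'
#' Reads a rule CSV (by default the bundled 27-rule database covering 22
#' Golgi enzymes), validates it, and compiles substrate/product patterns and
#' constraints. Columns: `index`, `enzyme`, `ec`, `kind`
#' (`transferase`/`hydrolase`), `substrate_pattern` (pattern dialect with a
#' `!` action-target mark), `product_pattern` (pattern the product must
#' embed), `res_add`/`link_add` (residue and linkage added by a transferase),
#' `constraint` (see [parse_constraint()]), `target_terminal` (require the
#' target to be a leaf), plus `*_printed` columns carrying the source cells
#' verbatim and a `source_note` documenting any normalization.
#'
#' A few source constraint cells are garbled or underdetermined, so the
#' database carries two documented readings (see the methods vignette):
#' `"curated"` (default) enforces the mannosidase trimming order implied by
#' the ManI constraint cell, makes the two ManII removals sequential, and
#' requires the biantennary core for FUT8; `"printed"` keeps only the
#' constraint cells exactly as printed (column
#' `constraint_printed_machine`, with `"none"` meaning no constraint).
#'
#' @param path CSV path; defaults to the bundled database.
#' @param reading `"curated"` (default) or `"printed"`; which documented
#'   reading of the ambiguous constraint cells to compile.
#' @return An `enzyme_rules` tibble with compiled `substrate` / `product` /
#'   `spec` list-columns.
#' @examples
#' rules <- load_rule_db()
#' nrow(rules)                     # 27
#' dplyr::n_distinct(rules$enzyme) # 22
#' @export
load_rule_db <- function(path = default_rule_path(),
                         reading = c("curated", "printed")) {
  reading <- match.arg(reading)
  raw <- readr::read_csv(path, col_types = readr::cols(
    index = readr::col_integer(),
    enzyme = readr::col_character(),
    ec = readr::col_character(),
    kind = readr::col_character(),
    substrate_pattern = readr::col_character(),
    product_pattern = readr::col_character(),
    res_add = readr::col_character(),
    link_add = readr::col_character(),
    constraint = readr::col_character(),
    target_terminal = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(RULE_DB_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("rule CSV is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "glyconet_bad_rule_db")
  }
  if (nrow(raw) == 0L) {
    warn("rule database is empty")
    return(structure(dplyr::mutate(raw,
                                   substrate = list(), product = list(),
                                   spec = list()),
                     class = c("enzyme_rules", class(raw))))
  }
  if (anyDuplicated(raw$index)) {
    abort("duplicate rule indices in rule database",
          class = "glyconet_bad_rule_db")
  }
  bad_kind <- !raw$kind %in% c("transferase", "hydrolase")
  if (any(bad_kind)) {
    abort(paste0("unknown enzyme kind in row ", which(bad_kind)[1], ": ",
                 raw$kind[bad_kind][1]),
          class = "glyconet_bad_rule_db")
  }
  rules <- raw
  if (reading == "printed") {
    alt <- rules$constraint_printed_machine
    use <- !is.na(alt)
    rules$constraint[use] <- ifelse(alt[use] == "none", NA_character_,
                                    alt[use])
  }
  rules$substrate <- vector("list", nrow(raw))
  rules$product <- vector("list", nrow(raw))
  rules$spec <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row_err <- function(e) {
      abort(paste0("rule database row ", raw$index[i], " (", raw$enzyme[i],
                   "): ", conditionMessage(e)),
            class = "glyconet_bad_rule_db")
    }
    tryCatch({
      sub <- parse_pattern(raw$substrate_pattern[i])
      if (sum_targets(sub$root) != 1L) {
        stop("substrate pattern must mark exactly one action target ('!')")
      }
      prod <- parse_pattern(raw$product_pattern[i])
      cons <- parse_constraint(rules$constraint[i] %||% "")
      if (raw$kind[i] == "transferase") {
        if (is.na(raw$res_add[i]) || is.na(raw$link_add[i])) {
          stop("transferase rule needs res_add and link_add")
        }
        link <- regmatches(raw$link_add[i],
                           regexec("^([ab])([2-9])$", raw$link_add[i]))[[1]]
        if (length(link) == 0L) stop("link_add must look like 'a6' or 'b2'")
        added <- residue(raw$res_add[i], link[2], as.integer(link[3]))
      } else {
        if (!is.na(raw$res_add[i]) || !is.na(raw$link_add[i])) {
          stop("hydrolase rule must not define res_add/link_add")
        }
        added <- NULL
      }
      rules$substrate[[i]] <- sub
      rules$product[[i]] <- prod
      rules$spec[[i]] <- list(constraint = cons, added = added,
                              target_terminal = isTRUE(raw$target_terminal[i]))
    }, error = row_err)
  }
  structure(rules, class = c("enzyme_rules", class(raw)))
}

#' Select rules by index range or enzyme name
#'
#' Accepts selections such as `"all"`, `"1-13"`, `"1,3,5-7"`, or
#' `"ManI,MGAT1"` and returns the matching subset of a rule database.
#'
#' @param rules An `enzyme_rules` tibble from [load_rule_db()].
#' @param selection A selection string, or an integer vector of rule indices.
#' @return The subset, still an `enzyme_rules` tibble.
#' @examples
#' select_rules(load_rule_db(), "1-13")
#' @export
select_rules <- function(rules, selection = "all") {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
  } else {
    stopifnot(is.character(selection), length(selection) == 1L)
    sel <- trimws(selection)
    if (identical(tolower(sel), "all")) return(rules)
    parts <- trimws(strsplit(sel, ",")[[1]])
    if (all(grepl("^[0-9]+(-[0-9]+)?$", parts))) {
      idx <- unlist(lapply(parts, function(p) {
        if (grepl("-", p)) {
          ab <- as.integer(strsplit(p, "-")[[1]])
          seq(ab[1], ab[2])
        } else as.integer(p)
      }))
    } else {
      unknown <- setdiff(parts, rules$enzyme)
      if (length(unknown) > 0L) {
        abort(paste0("unknown enzyme name(s): ",
                     paste(unknown, collapse = ", ")),
              class = "glyconet_unknown_enzyme")
      }
      return(rules[rules$enzyme %in% parts, ])
    }
  }
  unknown <- setdiff(idx, rules$index)
  if (length(unknown) > 0L) {
    abort(paste0("unknown rule index(es): ", paste(unknown, collapse = ", ")),
          class = "glyconet_unknown_enzyme")
  }
  rules[match(idx, rules$index), ]
}

rule_row <- function(rules, i) {
  list(index = rules$index[i], enzyme = rules$enzyme[i], ec = rules$ec[i],
       kind = rules$kind[i], substrate = rules$substrate[[i]],
       product = rules$product[[i]], spec = rules$spec[[i]])
}

#' Check rule specificity at a candidate site
#'
#' Evaluates everything beyond the bare substrate pattern: the
#' terminal-target requirement, position occupancy for transferases, and the
#' rule's constraint expression. Undefined parts are vacuously true.
#'
#' @param rule A single-row slice of an `enzyme_rules` tibble (or the list
#'   from an internal rule row).
#' @param g A `glycan`.
#' @param site Residue address of the candidate action target.
#' @return `TRUE` if the enzyme may act at `site`.
#' @export
check_specificity <- function(rule, g, site) {
  r <- as_rule(rule)
  node <- get_node(g, site)
  if (r$kind == "hydrolase" || r$spec$target_terminal) {
    if (length(node$kids) > 0L) return(FALSE)
  }
  if (r$kind == "transferase") {
    pos <- r$spec$added$pos
    if (any(vapply(node$kids, function(k) k$pos == pos, logical(1)))) {
      return(FALSE)
    }
  }
  eval_constraint(r$spec$constraint, g, target = site)
}

as_rule <- function(rule) {
  if (is.list(rule) && !is.null(rule$spec) && !is.data.frame(rule)) return(rule)
  if (inherits(rule, "data.frame")) {
    stopifnot(nrow(rule) == 1L)
    return(rule_row(rule, 1L))
  }
  abort("not an enzyme rule")
}

#' Find all sites where a rule applies
#'
#' Matches the rule's substrate pattern everywhere on the glycan and keeps
#' the action targets that pass [check_specificity()]. Sites are returned in
#' canonical traversal order; multi-site substrates (e.g. the three terminal
#' a1-2 mannoses of Man9GlcNAc2 for ManI) yield one site each.
#'
#' @param rule One rule (single-row `enzyme_rules` slice).
#' @param g A `glycan`.
#' @return A list of residue addresses (possibly empty).
#' @examples
#' rules <- load_rule_db()
#' match_sites(rules[1, ], glycan_fixture("M9"))
#' @export
match_sites <- function(rule, g) {
  r <- as_rule(rule)
  hits <- pattern_matches(r$substrate, g)
  targets <- lapply(hits, function(h) h$target)
  targets <- Filter(Negate(is.null), targets)
  if (length(targets) == 0L) return(list())
  keys <- vapply(targets, function(a) paste(a, collapse = "/"), character(1))
  targets <- targets[!duplicated(keys)]
  ord <- order(vapply(targets, function(a) {
    paste(formatC(a, width = 2, flag = "0"), collapse = "/")
  }, character(1)))
  targets <- targets[ord]
  Filter(function(at) check_specificity(r, g, at), targets)
}

#' Apply a rule at one site
#'
#' Executes a single reaction event: a transferase attaches its residue at
#' the site, a hydrolase removes the terminal residue at the site. The input
#' glycan is unchanged; a new product glycan is returned.
#'
#' @param g A `glycan`.
#' @param rule One rule.
#' @param site Residue address from [match_sites()].
#' @return The product `glycan`.
#' @export
apply_rule <- function(g, rule, site) {
  r <- as_rule(rule)
  if (r$kind == "transferase") {
    attach_residue(g, site, r$spec$added)
  } else {
    detach_residue(g, site)
  }
}
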