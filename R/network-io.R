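# Fixtures, network writers (GraphML/SIF/DOT/CSV) and the command-line
# front end.

GLYCAN_FIXTURES <- c(
  # High-mannose N-glycans. M9 = Man9GlcNAc2, the glycan entering the Golgi.
  M9 = "Ma2Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN",
  # M8 = Man8GlcNAc2, B-isomer (middle-arm terminal a1-2 Man removed), the
  # common ER-derived isomer; other isomers can be given as full LinearCode.
  M8 = "Ma2Ma2Ma3(Ma3(Ma2Ma6)Ma6)Mb4GNb4GN",
  # Man5 = Man5GlcNAc2, the MGAT1 acceptor.
  Man5 = "Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN"
)

#' Bundled glycan fixtures
#'
#' Returns one of the bundled standard N-glycans: `"M9"` (Man9GlcNAc2),
#' `"M8"` (Man8GlcNAc2, B-isomer) or `"Man5"` (Man5GlcNAc2).
#'
#' @param name Fixture name.
#' @return A `glycan`.
#' @examples
#' composition(glycan_fixture("M9"))
#' @export
glycan_fixture <- function(name) {
  if (length(name) != 1L || !name %in% names(GLYCAN_FIXTURES)) {
    abort(paste0("unknown fixture: ", paste(name, collapse = ", "),
                 " (available: ", paste(names(GLYCAN_FIXTURES),
                                        collapse = ", "), ")"),
          class = "glyconet_unknown_fixture")
  }
  parse_structure(GLYCAN_FIXTURES[[name]])
}

#' Export a glycan network to a standard graph format
#'
#' Writes the network with canonical LinearCode keys as node identifiers,
#' node attributes `round` and `composition`, and edge attributes `enzyme`,
#' `ec` and `rule_index`. Nodes and edges are written in sorted order, so
#' repeated exports of the same network are byte-identical.
#'
#' @param net A `glycan_network`.
#' @param format One of `"graphml"`, `"sif"`, `"dot"`, `"csv"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("graphml", "sif", "dot", "csv"),
                           path) {
  stopifnot(inherits(net, "glycan_network"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("cannot write to ", path, ": directory does not exist"),
          class = "glyconet_unwritable_path")
  }
  nodes <- dplyr::arrange(net$nodes, .data$round, .data$key)
  edges <- dplyr::arrange(net$edges, .data$substrate, .data$rule_index,
                          .data$product)
  switch(format,
    graphml = {
      gr <- igraph::graph_from_data_frame(
        d = data.frame(from = edges$substrate, to = edges$product,
                       enzyme = edges$enzyme, ec = edges$ec,
                       rule_index = edges$rule_index,
                       stringsAsFactors = FALSE),
        directed = TRUE,
        vertices = data.frame(name = nodes$key, round = nodes$round,
                              composition = nodes$composition,
                              stringsAsFactors = FALSE))
      igraph::write_graph(gr, path, format = "graphml")
    },
    sif = {
      lines <- paste(edges$substrate, edges$enzyme, edges$product, sep = "\t")
      writeLines(lines, path, sep = "\n")
    },
    dot = {
      q <- function(x) paste0("\"", x, "\"")
      lines <- c(
        "digraph glycan_network {",
        paste0("  ", q(nodes$key), " [round=", nodes$round, ", composition=",
               q(nodes$composition), "];"),
        paste0("  ", q(edges$substrate), " -> ", q(edges$product),
               " [label=", q(edges$enzyme), ", ec=", q(edges$ec), "];"),
        "}")
      writeLines(lines, path, sep = "\n")
    },
    csv = {
      readr::write_csv(dplyr::select(edges, -"site"), path, progress = FALSE)
    }
  )
  invisible(path)
}

# ---- command-line front end -------------------------------------------------

cli_message <- function(...) cat(..., "\n", sep = "")

cli_resolve_root <- function(root) {
  if (root %in% names(GLYCAN_FIXTURES)) return(glycan_fixture(root))
  tryCatch(parse_structure(root), error = function(e) {
    abort(paste0("unknown fixture or unparsable LinearCode: '", root,
                 "' (fixtures: ", paste(names(GLYCAN_FIXTURES),
                                        collapse = ", "), ")"),
          class = "glyconet_unknown_fixture")
  })
}

#' Command-line entry point
#'
#' Thin command-line front end over the package: `infer` runs forward
#' network inference and writes a network file, `stats` prints the per-round
#' table, `rules` lists the rule database, and `validate-rules` checks a
#' rule CSV. Invoked by the `inst/scripts/glyconet` wrapper; all work is
#' done by the exported package functions.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit code (0 on success), invisibly.
#' @examples
#' glyconet_cli(c("rules"))
#' @export
glyconet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: glyconet <command> [options]",
    "commands:",
    "  infer --root <fixture|LinearCode> [--rules all|1-13|names]",
    "        [--rounds N] [--max-nodes N] [--format graphml|sif|dot|csv]",
    "        [--out FILE] [--rule-db FILE]",
    "  stats --root <...> [--rules ...] [--rounds N] [--rule-db FILE]",
    "  rules [--rule-db FILE]",
    "  validate-rules [--rule-db FILE]",
    sep = "\n")
  if (length(args) == 0L) {
    cli_message(usage)
    return(invisible(2L))
  }
  cmd <- args[[1]]
  rest <- args[-1]
  opt <- list(root = "M9", rules = "all", rounds = 7L, `max-nodes` = 10000L,
              format = "graphml", out = NULL, `rule-db` = NULL)
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || !key %in% names(opt) ||
        i == length(rest)) {
      cli_message("error: bad argument '", rest[i], "'\n", usage)
      return(invisible(2L))
    }
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  result <- tryCatch({
    db_path <- opt$`rule-db` %||% default_rule_path()
    rules <- load_rule_db(db_path)
    if (cmd == "rules") {
      tab <- dplyr::select(as_tibble(rules), "index", "enzyme", "ec", "kind",
                           "substrate_pattern", "constraint")
      print(tab, n = Inf)
      0L
    } else if (cmd == "validate-rules") {
      cli_message("rule database OK: ", nrow(rules), " rules, ",
                  dplyr::n_distinct(rules$enzyme), " enzymes")
      0L
    } else if (cmd %in% c("infer", "stats")) {
      root <- cli_resolve_root(opt$root)
      rules <- select_rules(rules, opt$rules)
      net <- forward_network_inference(
        root, rules, max_rounds = as.integer(opt$rounds),
        max_nodes = as.integer(opt$`max-nodes`))
      print(network_stats(net), n = Inf)
      gl <- glance(net)
      cli_message("total: ", gl$n_glycans, " glycan structures, ",
                  gl$n_reactions, " reactions")
      if (cmd == "infer") {
        out <- opt$out %||% paste0("network.", opt$format)
        export_network(net, format = opt$format, path = out)
        cli_message("wrote ", out)
      }
      0L
    } else {
      cli_message("error: unknown command '", cmd, "'\n", usage)
      2L
    }
  }, error = function(e) {
    cli_message("error: ", conditionMessage(e))
    1L
  })
  invisible(result)
}
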