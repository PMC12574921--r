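# Network export/import.
#
# GraphML is written with xml2 at 17 significant digits so scores survive a
# round trip bit-exactly (igraph's own writer truncates the last bits);
# reading goes through igraph's GraphML parser. TSV export writes an edge
# table plus a .nodes.tsv sidecar (same precision) and a .config.json
# sidecar holding the scoring snapshot. SIF is a plain export with no
# round-trip guarantee (the format has no attributes).

fmt_num <- function(x) sprintf("%.17g", x)

#' Export a PPI network
#'
#' Writes the grouped, LIS-weighted network. Node `group` and edge `lis`,
#' `lia`, `round` are carried as attributes; the conventional edge `weight`
#' attribute equals `lis`. GraphML and TSV exports re-import losslessly via
#' [import_network()]; SIF keeps only the topology.
#'
#' @param net A `ppi_network` from [run_screen()].
#' @param path Output file; TSV export additionally writes
#'   `<stem>.nodes.tsv` and `<stem>.config.json` next to it.
#' @param format `"graphml"`, `"tsv"` or `"sif"`; default guessed from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("graphml", "tsv", "sif")) {
    abort(sprintf("Unknown network format '%s' (use graphml, tsv or sif).",
                  format), class = "lisnet_usage_error")
  }
  switch(format,
         graphml = write_network_graphml(net, path),
         tsv = write_network_tsv(net, path),
         sif = write_network_sif(net, path))
  invisible(path)
}

network_graph_attrs <- function(net) {
  cfg <- net$config
  list(bait = net$manifest$bait, pae_cutoff = cfg$pae_cutoff,
       tau_lis = cfg$tau_lis, tau_lia = cfg$tau_lia,
       aggregation = cfg$aggregation, lia_blocks = cfg$lia_blocks,
       pae_max = cfg$pae_max)
}

write_network_graphml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    list(id = "g_group", for_ = "node", name = "group", type = "string"),
    list(id = "e_lis", for_ = "edge", name = "lis", type = "double"),
    list(id = "e_lia", for_ = "edge", name = "lia", type = "double"),
    list(id = "e_round", for_ = "edge", name = "round", type = "long"),
    list(id = "e_weight", for_ = "edge", name = "weight", type = "double"))
  ga <- network_graph_attrs(net)
  for (nm in names(ga)) {
    keys[[length(keys) + 1L]] <- list(
      id = paste0("meta_", nm), for_ = "graph", name = nm,
      type = if (is.numeric(ga[[nm]])) "double" else "string")
  }
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k$id, "for" = k$for_,
                        "attr.name" = k$name, "attr.type" = k$type)
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "ppi",
                               edgedefault = "undirected")
  for (nm in names(ga)) {
    v <- ga[[nm]]
    xml2::xml_add_child(graph, "data",
                        if (is.numeric(v)) fmt_num(v) else as.character(v),
                        key = paste0("meta_", nm))
  }
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = net$nodes$id[i])
    xml2::xml_add_child(nd, "data", net$nodes$group[i], key = "g_group")
  }
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    ed <- xml2::xml_add_child(graph, "edge", source = e$from, target = e$to)
    xml2::xml_add_child(ed, "data", fmt_num(e$lis), key = "e_lis")
    xml2::xml_add_child(ed, "data", fmt_num(e$lia), key = "e_lia")
    xml2::xml_add_child(ed, "data", as.character(e$round), key = "e_round")
    xml2::xml_add_child(ed, "data", fmt_num(e$lis), key = "e_weight")
  }
  xml2::write_xml(doc, path)
}

tsv_sidecars <- function(path) {
  stem <- tools::file_path_sans_ext(path)
  list(nodes = paste0(stem, ".nodes.tsv"),
       config = paste0(stem, ".config.json"))
}

write_network_tsv <- function(net, path) {
  side <- tsv_sidecars(path)
  e <- net$edges
  edf <- data.frame(from = e$from, to = e$to, lis = fmt_num(e$lis),
                    lia = fmt_num(e$lia), round = e$round,
                    weight = fmt_num(e$lis))
  write.table(edf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(net$nodes), side$nodes, sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(network_graph_attrs(net), side$config,
                       auto_unbox = TRUE, digits = NA)
}

write_network_sif <- function(net, path) {
  lines <- if (nrow(net$edges) > 0) {
    paste(net$edges$from, "interacts", net$edges$to)
  } else {
    # isolated nodes are listed bare, per SIF convention
    character()
  }
  isolated <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
  writeLines(c(lines, isolated), path)
}

#' Import a PPI network written by [export_network()]
#'
#' Restores nodes, edges and the scoring configuration from a GraphML or
#' TSV export. The rebuilt object passes [validate_ppi_network()] and its
#' node and edge attribute sets equal the exported network's exactly.
#'
#' @param path File written by [export_network()].
#' @param format `"graphml"` or `"tsv"`; default guessed from the
#'   extension.
#' @return A `ppi_network`.
#' @export
import_network <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("graphml", "tsv")) {
    abort(sprintf("Cannot import format '%s' (use graphml or tsv).", format),
          class = "lisnet_usage_error")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ids <- igraph::V(g)$id %||% igraph::V(g)$name
    nodes <- tibble(id = ids, group = igraph::V(g)$group)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- if (nrow(el) > 0) {
      u <- ids[el[, 1]]; v <- ids[el[, 2]]
      # igraph orders undirected endpoints by vertex index; restore the
      # canonical lexicographic orientation used throughout
      tibble(from = pmin(u, v), to = pmax(u, v), lis = igraph::E(g)$lis,
             lia = igraph::E(g)$lia, round = as.integer(igraph::E(g)$round))
    } else empty_edges()
    ga <- igraph::graph_attr(g)
  } else {
    side <- tsv_sidecars(path)
    edf <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "numeric",
                                     "numeric", "integer", "numeric"))
    edges <- tibble(from = edf$from, to = edf$to, lis = edf$lis,
                    lia = edf$lia, round = as.integer(edf$round))
    ndf <- read.delim(side$nodes, stringsAsFactors = FALSE)
    nodes <- tibble(id = as.character(ndf$id), group = ndf$group)
    ga <- jsonlite::read_json(side$config, simplifyVector = TRUE)
  }
  config <- score_config(pae_cutoff = ga$pae_cutoff, tau_lis = ga$tau_lis,
                         tau_lia = ga$tau_lia, aggregation = ga$aggregation,
                         lia_blocks = ga$lia_blocks, pae_max = ga$pae_max)
  # node order: bait, then groups in discovery order (lexicographic in-group)
  nodes <- nodes[order(match(nodes$group,
                             c("bait", "group1", "group2", "group3")),
                       nodes$id), ]
  edges <- dplyr::arrange(edges, .data$round, .data$from, .data$to)
  counts <- table(factor(nodes$group,
                         levels = c("bait", "group1", "group2", "group3")))
  net <- structure(
    list(nodes = nodes, edges = edges, config = config,
         manifest = list(bait = ga$bait, imported_from = basename(path),
                         rounds = list(
                           round1 = list(n_passed = unname(counts[["group1"]])),
                           round2 = list(n_group2 = unname(counts[["group2"]])),
                           round3 = list(n_group3 = unname(counts[["group3"]]))))),
    class = "ppi_network")
  validate_ppi_network(net)
  net
}
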