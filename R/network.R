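#' Default hormone-to-pathway-node mapping
#'
#' Brassinosteroid regulation is attributed to the BES1/BZR1 transcription
#' factors and ABA regulation to ABI3/ABI4/ABI5.  Auxin regulation enters
#' the network through the two AFB groups via [infer_afb_edges()], not
#' through this map.
#'
#' @return named list: hormone -> character vector of upstream pathway nodes.
#' @export
default_pathway_map <- function() {
  list(brassinosteroid = c("BES1", "BZR1"),
       ABA = c("ABI3", "ABI4", "ABI5"))
}

#' Build the network node table
#'
#' Germination roles (positive / negative / unknown) are consumed from an
#' annotation table, never inferred from the data.
#'
#' @param gene_ids character vector of gene nodes.
#' @param annotation optional data frame with columns \code{gene_id} and
#'   \code{germination_class} in \code{c("promote", "inhibit", "either",
#'   "unknown")}; classes map to roles positive / negative / unknown /
#'   unknown.
#' @param extra_nodes additional non-gene nodes (AFB group and pathway
#'   nodes); roles default to unknown.
#' @return data frame \code{node_id}, \code{germination_role},
#'   \code{source_table}, sorted by node ID.
#' @export
network_nodes <- function(gene_ids, annotation = NULL,
                          extra_nodes = character()) {
  role <- rep("unknown", length(gene_ids))
  src <- rep("none", length(gene_ids))
  if (!is.null(annotation)) {
    stopifnot(all(c("gene_id", "germination_class") %in% names(annotation)))
    i <- match(gene_ids, annotation$gene_id)
    cls <- annotation$germination_class[i]
    role <- ifelse(is.na(cls), "unknown",
                   c(promote = "positive", inhibit = "negative",
                     either = "unknown", unknown = "unknown")[cls])
    src <- ifelse(is.na(cls), "none", "annotation")
  }
  nodes <- data.frame(node_id = c(gene_ids, extra_nodes),
                      germination_role = c(role,
                                           rep("unknown", length(extra_nodes))),
                      source_table = c(src, rep("topology",
                                                length(extra_nodes))),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
               collapse = ", "))
  nodes[order(nodes$node_id), , drop = FALSE]
}

#' Infer signed AFB-group -> gene edges from gradient logic
#'
#' An auxin-downregulated gene group receives a repression edge from the AFB
#' group whose FUN->CSC gradient is opposite to the gene group's gradient;
#' an auxin-upregulated group receives an activation edge from the AFB group
#' whose gradient matches.  The AFB1 group carries the down-gradient and the
#' AFB5 group the up-gradient, so e.g. auxin-down/up-gradient genes are
#' repressed by the AFB1 group and auxin-up/up-gradient genes activated by
#' the AFB5 group.  Edges are emitted per gene.
#'
#' @param grouping a \code{"gradient_grouping"} from [assign_groups()].
#' @param afb an \code{"afb_groups"} assignment (fixes which group node
#'   carries which gradient; the node names stay "AFB1-group"/"AFB5-group").
#' @return edge data frame \code{source}, \code{target}, \code{sign},
#'   \code{evidence}, sorted.
#' @export
infer_afb_edges <- function(grouping, afb) {
  stopifnot(inherits(grouping, "gradient_grouping"),
            inherits(afb, "afb_groups"))
  group_node <- c(down = "AFB1-group", up = "AFB5-group")
  rows <- lapply(grouping$groups, function(g) {
    if (!length(g$genes)) return(NULL)
    if (g$auxin_response == "down") {
      src_gradient <- setdiff(c("down", "up"), g$gradient)
      sign <- "repression"
    } else {
      src_gradient <- g$gradient
      sign <- "activation"
    }
    data.frame(source = group_node[[src_gradient]], target = g$genes,
               sign = sign,
               evidence = paste0("auxin-", g$auxin_response,
                                 ":gradient-", g$gradient),
               stringsAsFactors = FALSE)
  })
  sort_edges(do.call(rbind, rows))
}

#' Add hormone-regulon edges from upstream pathway nodes
#'
#' For each network gene found in a hormone regulon, emits one edge from
#' every pathway node mapped to that hormone, signed by the regulon
#' direction (up -> activation, down -> repression) and annotated with the
#' regulon's source as evidence.  Genes absent from all regulons get no
#' edge.
#'
#' @param node_ids character vector of gene node IDs in the network.
#' @param regulons list of [regulon()] objects (ABA/brassinosteroid).
#' @param pathway_map see [default_pathway_map()].
#' @return edge data frame as in [infer_afb_edges()].
#' @export
merge_hormone_edges <- function(node_ids, regulons,
                                pathway_map = default_pathway_map()) {
  hormones <- unique(vapply(regulons, `[[`, character(1), "hormone"))
  unmapped <- setdiff(hormones, names(pathway_map))
  if (length(unmapped))
    stop("pathway_map has no entry for hormone(s): ",
         paste(unmapped, collapse = ", "))
  rows <- lapply(regulons, function(reg) {
    hits <- intersect(node_ids, reg$genes)
    if (!length(hits)) return(NULL)
    sources <- pathway_map[[reg$hormone]]
    evidence <- paste0(reg$hormone, "-", reg$direction, ":", reg$source)
    do.call(rbind, lapply(sources, function(src) {
      tgt <- setdiff(hits, src)  # no self-edges
      if (!length(tgt)) return(NULL)
      data.frame(source = src, target = tgt,
                 sign = if (reg$direction == "up") "activation" else
                   "repression",
                 evidence = evidence, stringsAsFactors = FALSE)
    }))
  })
  sort_edges(do.call(rbind, rows))
}

#' @keywords internal
sort_edges <- function(edges) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), evidence = character(),
                        stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$target, edges$sign,
                       edges$evidence), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Export a signed network
#'
#' Writes the network in a Cytoscape-compatible format.  SIF uses the
#' interaction labels \code{activates} / \code{represses}; GraphML carries
#' the edge sign and node germination role as typed attributes; the TSV
#' option writes \code{nodes.tsv} and \code{edges.tsv}.  Nodes and edges are
#' sorted so repeated exports are byte-identical.
#'
#' @param nodes node table from [network_nodes()].
#' @param edges edge table.
#' @param path output file path (for \code{"tsv"}, a directory).
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @return the path(s) written, invisibly.
#' @export
export_network <- function(nodes, edges, path,
                           format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  dangling <- setdiff(unique(c(edges$source, edges$target)), nodes$node_id)
  if (length(dangling))
    stop("edge endpoint(s) missing from node table: ",
         paste(dangling, collapse = ", "))
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  edges <- sort_edges(edges)
  switch(format,
    sif = {
      verb <- ifelse(edges$sign == "activation", "activates", "represses")
      writeLines(if (nrow(edges)) paste(edges$source, verb, edges$target)
                 else character(), path)
      invisible(path)
    },
    graphml = {
      write_graphml(nodes, edges, path)
      invisible(path)
    },
    tsv = {
      np <- file.path(path, "nodes.tsv")
      ep <- file.path(path, "edges.tsv")
      write_tsv(nodes, np)
      write_tsv(edges, ep)
      invisible(c(np, ep))
    })
}

write_graphml <- function(nodes, edges, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  add_key <- function(id, dom, name) {
    k <- xml2::xml_add_child(doc, "key")
    xml2::xml_set_attrs(k, c(id = id, `for` = dom, attr.name = name,
                             attr.type = "string"))
  }
  add_key("d_role", "node", "germination_role")
  add_key("d_source", "node", "source_table")
  add_key("d_sign", "edge", "sign")
  add_key("d_evidence", "edge", "evidence")
  graph <- xml2::xml_add_child(doc, "graph", id = "SGN",
                               edgedefault = "directed")
  for (i in seq_len(nrow(nodes))) {
    n <- xml2::xml_add_child(graph, "node", id = nodes$node_id[i])
    d <- xml2::xml_add_child(n, "data", key = "d_role")
    xml2::xml_set_text(d, nodes$germination_role[i])
    d <- xml2::xml_add_child(n, "data", key = "d_source")
    xml2::xml_set_text(d, nodes$source_table[i])
  }
  for (i in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(graph, "edge", source = edges$source[i],
                             target = edges$target[i])
    d <- xml2::xml_add_child(e, "data", key = "d_sign")
    xml2::xml_set_text(d, edges$sign[i])
    d <- xml2::xml_add_child(e, "data", key = "d_evidence")
    xml2::xml_set_text(d, edges$evidence[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-read a GraphML network written by [export_network()]
#'
#' @param path a GraphML file.
#' @return list with \code{nodes} and \code{edges} data frames matching the
#'   layout written by [export_network()].
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  get_data <- function(node, key) {
    xml2::xml_text(xml2::xml_find_first(
      node, paste0("./g:data[@key='", key, "']"), ns))
  }
  node_els <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  nodes <- data.frame(
    node_id = xml2::xml_attr(node_els, "id"),
    germination_role = vapply(node_els, get_data, character(1), "d_role"),
    source_table = vapply(node_els, get_data, character(1), "d_source"),
    stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  edges <- data.frame(
    source = xml2::xml_attr(edge_els, "source"),
    target = xml2::xml_attr(edge_els, "target"),
    sign = vapply(edge_els, get_data, character(1), "d_sign"),
    evidence = vapply(edge_els, get_data, character(1), "d_evidence"),
    stringsAsFactors = FALSE)
  list(nodes = nodes[order(nodes$node_id), , drop = FALSE],
       edges = sort_edges(edges))
}

#' Load the germination-role annotation table
#'
#' Reads a TSV with columns \code{gene_id}, \code{subgroup},
#' \code{germination_class} (and optionally a free-text \code{function}
#' column).  A transcription of the published seed-germination subgroup
#' tables ships with the package under
#' \code{inst/extdata/germination_annotation.tsv}.
#'
#' @param path path to the TSV; default the shipped fixture.
#' @return data frame with canonicalized \code{gene_id}.
#' @export
load_annotation <- function(path = system.file("extdata",
                                               "germination_annotation.tsv",
                                               package = "gradientnet")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  stopifnot(all(c("gene_id", "subgroup", "germination_class") %in% names(tab)))
  tab$gene_id <- canonicalize_gene_id(tab$gene_id)
  if (anyNA(tab$gene_id)) stop("unparseable gene ID in annotation table")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene ID in annotation table")
  bad <- setdiff(tab$germination_class,
                 c("promote", "inhibit", "either", "unknown"))
  if (length(bad))
    stop("unknown germination_class value(s): ", paste(bad, collapse = ", "))
  tab
}
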