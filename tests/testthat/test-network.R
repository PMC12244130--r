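edge_fixture <- function() {
  prof <- make_profiles(
    c("At1g00010", "At1g00020", "At1g00030", "At1g00040"),
    fun = c(20, 20, 80, 80), csc = c(80, 80, 20, 20), dsc_raw = rep(5, 4))
  grouping <- assign_groups(
    prof,
    regulon(c("At1g00020", "At1g00040"), "auxin", "up"),
    regulon(c("At1g00010", "At1g00030"), "auxin", "down"))
  afb <- structure(list(afb1_group = c("TIR1", "AFB1", "AFB4"),
                        afb5_group = c("AFB2", "AFB3", "AFB5"),
                        derived_from_data = FALSE),
                   class = "afb_groups")
  list(grouping = grouping, afb = afb)
}

test_that("AFB edges follow the gradient-match rule with correct signs", {
  fx <- edge_fixture()
  edges <- infer_afb_edges(fx$grouping, fx$afb)
  get <- function(target) edges[edges$target == target, ]
  # auxin-down, up-gradient (G1): repressed by the down-gradient AFB1 group
  expect_equal(get("At1g00010")$source, "AFB1-group")
  expect_equal(get("At1g00010")$sign, "repression")
  # auxin-down, down-gradient (G2): repressed by the AFB5 group
  expect_equal(get("At1g00030")$source, "AFB5-group")
  expect_equal(get("At1g00030")$sign, "repression")
  # auxin-up, down-gradient (G3): activated by the AFB1 group
  expect_equal(get("At1g00040")$source, "AFB1-group")
  expect_equal(get("At1g00040")$sign, "activation")
  # auxin-up, up-gradient (G4): activated by the AFB5 group
  expect_equal(get("At1g00020")$source, "AFB5-group")
  expect_equal(get("At1g00020")$sign, "activation")
  # only group nodes appear as sources
  expect_true(all(edges$source %in% c("AFB1-group", "AFB5-group")))
})

test_that("hormone regulon edges map through pathway nodes per evidence", {
  genes <- c("At1g00010", "At1g00020", "At1g00030")
  regs <- list(
    regulon("At1g00010", "brassinosteroid", "down", source = "br-ds1"),
    regulon(c("At1g00010", "At1g00020"), "ABA", "up", source = "aba-ds1"))
  edges <- merge_hormone_edges(genes, regs)
  br <- edges[grepl("brassinosteroid", edges$evidence), ]
  expect_setequal(br$source, c("BES1", "BZR1"))
  expect_true(all(br$sign == "repression"))
  expect_true(all(br$target == "At1g00010"))
  aba <- edges[grepl("ABA", edges$evidence), ]
  expect_equal(nrow(aba), 6)  # 3 pathway nodes x 2 genes
  expect_true(all(aba$sign == "activation"))
  # a gene in two regulons gets edges with distinct evidence
  expect_gte(length(unique(edges$evidence[edges$target == "At1g00010"])), 2)
  # a gene in no regulon gets none
  expect_false("At1g00030" %in% edges$target)
  # unmapped hormone is a config error
  expect_error(merge_hormone_edges(genes, regs, pathway_map = list()),
               "pathway_map")
})

test_that("network export is validated, byte-stable and round-trips", {
  fx <- edge_fixture()
  edges <- infer_afb_edges(fx$grouping, fx$afb)
  genes <- sort(unique(edges$target))
  nodes <- network_nodes(genes, annotation = NULL,
                         extra_nodes = c("AFB1-group", "AFB5-group"))

  sif <- tempfile(fileext = ".sif")
  export_network(nodes, edges, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 4)
  expect_true("AFB5-group activates At1g00020" %in% lines)
  expect_true("AFB1-group represses At1g00010" %in% lines)

  gml <- tempfile(fileext = ".graphml")
  export_network(nodes, edges, gml, "graphml")
  back <- read_graphml(gml)
  expect_equal(back$nodes$node_id, nodes$node_id)
  expect_equal(back$edges[c("source", "target", "sign", "evidence")],
               edges[c("source", "target", "sign", "evidence")])

  # byte-identical on re-export, and on permuted edge input
  sif2 <- tempfile(); gml2 <- tempfile()
  export_network(nodes, edges[sample(nrow(edges)), ], sif2, "sif")
  export_network(nodes, edges[rev(seq_len(nrow(edges))), ], gml2, "graphml")
  expect_identical(readLines(sif), readLines(sif2))
  expect_identical(readLines(gml), readLines(gml2))

  # dangling endpoints rejected; empty edge set allowed
  expect_error(export_network(nodes[-1, ], edges, tempfile(), "sif"),
               "endpoint")
  empty <- export_network(nodes, edges[0, ], tempfile(), "sif")
  expect_length(readLines(empty), 0)
})

test_that("annotation fixture drives germination roles", {
  ann <- load_annotation()
  nodes <- network_nodes(c("At1g09090", "At4g30080", "At5g57560",
                           "At9g99999"), annotation = ann)
  role <- setNames(nodes$germination_role, nodes$node_id)
  expect_equal(unname(role["At1g09090"]), "positive")   # promotes
  expect_equal(unname(role["At4g30080"]), "negative")   # inhibits
  expect_equal(unname(role["At5g57560"]), "unknown")
  expect_equal(unname(role["At9g99999"]), "unknown")    # unannotated
})
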