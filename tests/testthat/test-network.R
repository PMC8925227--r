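# Regulatory-network assembly and export round trips.

five_node_inputs <- function() {
  delncs <- tibble::tibble(lnc_id = "lnc1", direction = "up")
  dems <- tibble::tibble(mirna_id = "mir1", direction = "down")
  common <- tibble::tibble(gene_id = c("g1", "g2"), n_cis_links = 1L,
                           n_trans_links = 1L, de_flag = c("up", "down"))
  attr(common, "links") <- list(
    cis = tibble::tibble(lnc_id = "lnc1", gene_id = c("g1", "g2"),
                         mode = "cis", distance = c(100L, 2000L)),
    trans = tibble::tibble(lnc_id = "lnc1", gene_id = c("g1", "g2"),
                           mode = "trans", r = c(0.99, -0.97))
  )
  mirna_links <- tibble::tibble(mirna_id = "mir1", lnc_id = "lnc1",
                                site_start = 10L, expectation = 0,
                                alignment = strrep("|", 21))
  enrichment <- tibble::tibble(
    term_id = c("GO:1", "GO:2"), name = c("t1", "t2"), namespace = "BP",
    k = c(2L, 1L), n = 2L, K = c(4L, 30L), N = 40L,
    pvalue = c(0.003, 0.6), qvalue = c(0.006, 0.6),
    significant = c(TRUE, FALSE)
  )
  term_map <- tibble::tibble(gene_id = c("g1", "g2", "g2"),
                             term_id = c("GO:1", "GO:1", "GO:2"))
  list(delncs = delncs, dems = dems, common = common,
       mirna_links = mirna_links, enrichment = enrichment,
       term_map = term_map)
}

test_that("the 1-miRNA/1-lncRNA/2-gene/1-term build has 5 nodes and 5 edges", {
  x <- five_node_inputs()
  net <- build_network(x$delncs, x$dems, x$common, x$mirna_links,
                       x$enrichment, x$term_map)
  expect_equal(nrow(net$nodes), 5L)
  expect_equal(nrow(net$edges), 5L)
  expect_equal(sum(net$edges$edge_type == "mirna_targets_lnc"), 1L)
  expect_equal(sum(net$edges$edge_type == "lnc_targets_gene"), 2L)
  expect_equal(sum(net$edges$edge_type == "gene_annotated_term"), 2L)
  # only terms with p < 0.05 appear
  expect_false("GO:2" %in% net$nodes$id)
  # cis + trans support collapses to mode "common"
  expect_true(all(net$edges$mode[net$edges$edge_type == "lnc_targets_gene"] ==
                    "common"))
})

test_that("regulation colors follow the up-red / down-green encoding", {
  x <- five_node_inputs()
  net <- build_network(x$delncs, x$dems, x$common, x$mirna_links,
                       x$enrichment, x$term_map)
  nodes <- net$nodes
  expect_equal(nodes$color[nodes$id == "lnc1"], "red")
  expect_equal(nodes$regulation[nodes$id == "lnc1"], "up")
  expect_equal(nodes$color[nodes$id == "mir1"], "green")
  expect_equal(nodes$color[nodes$id == "g2"], "green")
  expect_equal(nodes$color[nodes$id == "GO:1"], "blue")
})

test_that("dangling ids across input tables are rejected by name", {
  x <- five_node_inputs()
  bad_links <- dplyr::bind_rows(
    x$mirna_links,
    tibble::tibble(mirna_id = "mir1", lnc_id = "ghost", site_start = 1L,
                   expectation = 0, alignment = "|")
  )
  expect_error(
    build_network(x$delncs, x$dems, x$common, bad_links, x$enrichment,
                  x$term_map),
    "ghost"
  )
})

test_that("empty inputs give an empty but exportable network", {
  net <- build_network(
    tibble::tibble(lnc_id = character(), direction = character()),
    tibble::tibble(mirna_id = character(), direction = character()),
    tibble::tibble(gene_id = character(), de_flag = character()),
    tibble::tibble(mirna_id = character(), lnc_id = character(),
                   site_start = integer(), expectation = numeric(),
                   alignment = character()),
    tibble::tibble(term_id = character(), name = character(),
                   namespace = character(), k = integer(), n = integer(),
                   K = integer(), N = integer(), pvalue = numeric(),
                   qvalue = numeric(), significant = logical()),
    tibble::tibble(gene_id = character(), term_id = character())
  )
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)
  p <- withr::local_tempfile(fileext = ".sif")
  export_network(net, "sif", p)
  expect_equal(length(readLines(p)), 0L)
})

test_that("SIF has one line per edge; exports are byte-deterministic", {
  x <- five_node_inputs()
  net <- build_network(x$delncs, x$dems, x$common, x$mirna_links,
                       x$enrichment, x$term_map)
  p1 <- withr::local_tempfile(fileext = ".sif")
  p2 <- withr::local_tempfile(fileext = ".sif")
  export_network(net, "sif", p1)
  export_network(net, "sif", p2)
  lines <- readLines(p1)
  expect_equal(length(lines), nrow(net$edges))
  expect_true(all(grepl("^\\S+\t\\S+\t\\S+$", lines)))
  expect_identical(readLines(p2), lines)
  g1 <- withr::local_tempfile(fileext = ".graphml")
  g2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", g1)
  export_network(net, "graphml", g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("GraphML and TSV round trips preserve node and edge multisets", {
  x <- five_node_inputs()
  net <- build_network(x$delncs, x$dems, x$common, x$mirna_links,
                       x$enrichment, x$term_map)
  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", g)
  back <- import_network(g, "graphml")
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(
    sort(paste(back$nodes$id, back$nodes$node_type, back$nodes$regulation,
               back$nodes$color)),
    sort(paste(net$nodes$id, net$nodes$node_type, net$nodes$regulation,
               net$nodes$color))
  )
  expect_equal(
    sort(paste(back$edges$source, back$edges$edge_type, back$edges$target)),
    sort(paste(net$edges$source, net$edges$edge_type, net$edges$target))
  )
  d <- withr::local_tempdir()
  export_network(net, "tsv", d)
  back2 <- import_network(d, "tsv")
  expect_equal(as.data.frame(back2$edges)[c("source", "edge_type", "target")],
               as.data.frame(net$edges)[c("source", "edge_type", "target")])
  expect_setequal(back2$nodes$id, net$nodes$id)
})

test_that("every build keeps referential integrity", {
  ds <- small_dataset()
  res <- run_all(withr::local_tempdir(), config = small_config(seed = 12))
  net <- res$network
  expect_true(all(net$edges$source %in% net$nodes$id))
  expect_true(all(net$edges$target %in% net$nodes$id))
  expect_false(anyDuplicated(net$nodes$id) > 0)
  # DEM nodes have degree >= 1 (isolated nodes dropped)
  deg <- table(c(net$edges$source, net$edges$target))
  mirs <- net$nodes$id[net$nodes$node_type == "mirna"]
  expect_true(all(deg[mirs] >= 1))
})
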