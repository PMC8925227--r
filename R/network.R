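# Assembly and export of the lncRNA-mediated regulatory network: typed nodes
# (miRNA, lncRNA, gene, GO term, pathway) and directed typed edges
# (miRNA -> lncRNA -> gene -> term), with the conventional color encoding
# (up-regulated red, down-regulated green).

#' Build the regulatory network
#'
#' Nodes are the DE lncRNAs with at least one edge, DE miRNAs with at least
#' one link, all common-target genes, and significantly enriched terms
#' (raw `p < term_p`, both GO and pathway) covering at least one included
#' gene; isolated nodes are dropped. Edges are directed regulator ->
#' regulated: `mirna_targets_lnc` (with the site expectation),
#' `lnc_targets_gene` (mode cis / trans / common, with distance and r) and
#' `gene_annotated_term`.
#'
#' @param delncs Tibble `lnc_id`, `direction` (`up`/`down`).
#' @param dems Tibble `mirna_id`, `direction`.
#' @param common CommonTargetSet from [common_targets()] (its supporting
#'   links are taken from the `links` attribute).
#' @param mirna_links Tibble from [dem_delnc_links()].
#' @param enrichment Tibble from [hypergeom_enrich()].
#' @param term_map Tibble `gene_id`, `term_id` used to draw
#'   gene-to-term edges.
#' @param term_p Inclusion threshold for term nodes (default 0.05, raw p).
#' @return Object of class `regulatory_network`: list of `nodes`
#'   (`id`, `node_type`, `regulation`, `color`, `p`) and `edges`
#'   (`source`, `target`, `edge_type`, `mode`, `expectation`, `r`,
#'   `distance`), deterministically ordered.
#' @export
build_network <- function(delncs, dems, common, mirna_links, enrichment,
                          term_map, term_p = 0.05) {
  delncs <- as_tibble(delncs); dems <- as_tibble(dems)
  common <- as_tibble(common)
  links <- attr(common, "links")
  if (is.null(links)) links <- list(
    cis = tibble(lnc_id = character(), gene_id = character(),
                 distance = integer()),
    trans = tibble(lnc_id = character(), gene_id = character(), r = numeric())
  )
  mirna_links <- as_tibble(mirna_links)

  dangle <- c(
    setdiff(mirna_links$mirna_id, dems$mirna_id),
    setdiff(mirna_links$lnc_id, delncs$lnc_id),
    setdiff(c(links$cis$lnc_id, links$trans$lnc_id), delncs$lnc_id),
    setdiff(c(links$cis$gene_id, links$trans$gene_id), common$gene_id)
  )
  if (length(dangle) > 0) {
    abort(sprintf("dangling id(s) across network inputs: %s",
                  paste(head(unique(dangle), 10), collapse = ", ")))
  }

  # lncRNA -> gene edges, mode collapsed to cis / trans / common
  cis_pairs <- distinct(select(links$cis, "lnc_id", "gene_id"),
                        .data$lnc_id, .data$gene_id, .keep_all = TRUE)
  cis_pairs <- left_join(
    cis_pairs,
    distinct(links$cis, .data$lnc_id, .data$gene_id, .keep_all = TRUE) %>%
      select("lnc_id", "gene_id", dplyr::any_of("distance")),
    by = c("lnc_id", "gene_id")
  )
  trans_pairs <- distinct(links$trans, .data$lnc_id, .data$gene_id,
                          .keep_all = TRUE) %>%
    select("lnc_id", "gene_id", dplyr::any_of("r"))
  lg <- dplyr::full_join(cis_pairs, trans_pairs, by = c("lnc_id", "gene_id"))
  if (!"distance" %in% names(lg)) lg$distance <- NA_integer_
  if (!"r" %in% names(lg)) lg$r <- NA_real_
  lg$mode <- ifelse(!is.na(lg$distance) & !is.na(lg$r), "common",
                    ifelse(!is.na(lg$distance), "cis", "trans"))

  edges <- bind_rows(
    if (nrow(mirna_links) > 0) tibble(
      source = mirna_links$mirna_id, target = mirna_links$lnc_id,
      edge_type = "mirna_targets_lnc", mode = NA_character_,
      expectation = mirna_links$expectation, r = NA_real_,
      distance = NA_integer_
    ),
    if (nrow(lg) > 0) tibble(
      source = lg$lnc_id, target = lg$gene_id,
      edge_type = "lnc_targets_gene", mode = lg$mode,
      expectation = NA_real_, r = lg$r, distance = as.integer(lg$distance)
    )
  )

  enr <- as_tibble(enrichment)
  sig_terms <- enr[enr$pvalue < term_p, , drop = FALSE]
  tm <- distinct(as_tibble(term_map), .data$gene_id, .data$term_id)
  gt <- filter(tm, .data$term_id %in% sig_terms$term_id,
               .data$gene_id %in% common$gene_id)
  edges <- bind_rows(edges, if (nrow(gt) > 0) tibble(
    source = gt$gene_id, target = gt$term_id,
    edge_type = "gene_annotated_term", mode = NA_character_,
    expectation = NA_real_, r = NA_real_, distance = NA_integer_
  ))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(source = character(), target = character(),
                    edge_type = character(), mode = character(),
                    expectation = numeric(), r = numeric(),
                    distance = integer())
  }
  edges <- arrange(edges, .data$edge_type, .data$source, .data$target)

  color_of <- function(reg) {
    ifelse(reg == "up", "red", ifelse(reg == "down", "green", "black"))
  }
  nodes <- bind_rows(
    tibble(id = dems$mirna_id, node_type = "mirna",
           regulation = dems$direction %||% "none"),
    tibble(id = delncs$lnc_id, node_type = "lncrna",
           regulation = delncs$direction %||% "none"),
    tibble(id = common$gene_id, node_type = "gene",
           regulation = if ("de_flag" %in% names(common))
             as.character(ifelse(common$de_flag %in% c("up", "down"),
                                 common$de_flag, "none"))
           else rep("none", nrow(common))),
    if (nrow(sig_terms) > 0) tibble(
      id = sig_terms$term_id,
      node_type = ifelse(sig_terms$namespace == "pathway", "pathway",
                         "go_term"),
      regulation = "none", p = sig_terms$pvalue
    )
  )
  if (!"p" %in% names(nodes)) nodes$p <- NA_real_
  nodes$regulation[is.na(nodes$regulation)] <- "none"
  nodes$color <- color_of(nodes$regulation)
  nodes$color[nodes$node_type == "go_term"] <- "blue"
  nodes$color[nodes$node_type == "pathway"] <- "green"

  used <- unique(c(edges$source, edges$target))
  nodes <- filter(nodes, .data$id %in% used) %>%
    arrange(.data$node_type, .data$id)
  edges <- filter(edges, .data$source %in% nodes$id,
                  .data$target %in% nodes$id)

  net <- structure(list(nodes = nodes, edges = edges),
                   class = "regulatory_network")
  check_network(net)
  net
}

check_network <- function(net) {
  bad <- setdiff(c(net$edges$source, net$edges$target), net$nodes$id)
  if (length(bad) > 0) {
    abort(sprintf("edge endpoint(s) missing from nodes: %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  if (anyDuplicated(net$nodes$id)) {
    abort("duplicate node id(s) in network")
  }
  invisible(net)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes / %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$node_type)
    cat("  nodes:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes Cytoscape-compatible interchange files: SIF (one
#' `source<TAB>edge_type<TAB>target` line per edge), GraphML with all node
#' and edge attributes (via igraph), or a `nodes.tsv`/`edges.tsv` pair.
#' Output is byte-deterministic for a given network.
#'
#' @param net A `regulatory_network`.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @param path Output file path (for `"tsv"`: a directory receiving
#'   `nodes.tsv` and `edges.tsv`).
#' @return The path(s) written, invisibly.
#' @export
export_network <- function(net, format = c("sif", "graphml", "tsv"), path) {
  stopifnot(inherits(net, "regulatory_network"))
  format <- match.arg(format)
  check_network(net)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$edge_type,
                     net$edges$target)
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = as.data.frame(net$edges), directed = TRUE,
      vertices = as.data.frame(net$nodes)
    )
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  np <- file.path(path, "nodes.tsv"); ep <- file.path(path, "edges.tsv")
  readr::write_tsv(net$nodes, np, progress = FALSE)
  readr::write_tsv(net$edges, ep, progress = FALSE)
  invisible(c(np, ep))
}

#' Re-import an exported network
#'
#' Reads a GraphML file (or a nodes/edges TSV directory) back into a
#' `regulatory_network`, mainly to verify round-trip fidelity.
#'
#' @param path GraphML file or TSV directory.
#' @param format `"graphml"` or `"tsv"`.
#' @return A `regulatory_network`.
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
    nodes <- nodes[setdiff(names(nodes), "id")] %>%
      rename(id = "name")
    edges <- as_tibble(igraph::as_data_frame(g, what = "edges")) %>%
      rename(source = "from", target = "to")
  } else {
    nodes <- readr::read_tsv(file.path(path, "nodes.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    edges <- readr::read_tsv(file.path(path, "edges.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  }
  structure(
    list(nodes = arrange(as_tibble(nodes), .data$node_type, .data$id),
         edges = arrange(as_tibble(edges), .data$edge_type, .data$source,
                         .data$target)),
    class = "regulatory_network"
  )
}
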