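# Over-representation analysis of a foreground gene set against gene-to-term
# maps: exact hypergeometric upper tail, BH within namespace, and the
# asymmetric significance convention (GO at raw p < 0.05, pathways at
# q < 0.05).

#' Hypergeometric term enrichment
#'
#' For each term with at least one foreground gene, the upper-tail
#' hypergeometric probability of seeing `k` or more annotated genes among
#' the `n` foreground draws from a background of `N` genes of which `K`
#' carry the term. BH adjustment is applied within each namespace, so adding
#' pathway terms never changes GO q-values. GO namespaces (BP/CC/MF) are
#' called significant at raw `p < go_p`; pathways at adjusted `q < kegg_q`.
#'
#' @param foreground Character vector of gene ids (must be a subset of
#'   `background`, non-empty).
#' @param background Character vector of gene ids.
#' @param term_map Tibble `gene_id`, `term_id` and optionally `namespace`
#'   (`BP`/`CC`/`MF`/`pathway`; defaults to `"GO"`) and `name`.
#' @param go_p,kegg_q Significance thresholds (defaults 0.05).
#' @return Tibble `term_id`, `name`, `namespace`, `k`, `n`, `K`, `N`,
#'   `pvalue`, `qvalue`, `significant`, sorted by p within namespace.
#' @export
hypergeom_enrich <- function(foreground, background, term_map,
                             go_p = 0.05, kegg_q = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) abort("foreground is empty")
  extra <- setdiff(foreground, background)
  if (length(extra) > 0) {
    abort(sprintf("foreground gene(s) not in background: %s",
                  paste(head(extra, 10), collapse = ", ")))
  }
  tm <- as_tibble(term_map)
  if (!"namespace" %in% names(tm)) tm$namespace <- "GO"
  if (!"name" %in% names(tm)) tm$name <- tm$term_id
  tm <- filter(distinct(tm, .data$gene_id, .data$term_id,
                        .keep_all = TRUE),
               .data$gene_id %in% background)
  N <- length(background)
  n <- length(foreground)
  if (nrow(tm) == 0) {
    return(tibble(term_id = character(), name = character(),
                  namespace = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), pvalue = numeric(),
                  qvalue = numeric(), significant = logical()))
  }
  stats_tbl <- tm %>%
    group_by(.data$term_id, .data$namespace, .data$name) %>%
    summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% foreground),
      .groups = "drop"
    ) %>%
    filter(.data$k > 0) %>%
    mutate(
      n = n, N = N,
      pvalue = phyper(.data$k - 1, .data$K, N - .data$K, n,
                      lower.tail = FALSE)
    ) %>%
    group_by(.data$namespace) %>%
    mutate(qvalue = bh_adjust(.data$pvalue)) %>%
    ungroup() %>%
    mutate(
      significant = ifelse(.data$namespace == "pathway",
                           .data$qvalue < kegg_q, .data$pvalue < go_p)
    ) %>%
    arrange(.data$namespace, .data$pvalue, .data$term_id) %>%
    select("term_id", "name", "namespace", "k", "n", "K", "N",
           "pvalue", "qvalue", "significant")
  stats_tbl
}
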