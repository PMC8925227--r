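# Target prediction: cis by genomic window, trans by expression correlation,
# and the cis/trans/DE common-target intersection.

#' Predict cis target genes by genomic proximity
#'
#' A coding gene is a cis target of a lncRNA when both lie on the same
#' chromosome and their 1-based inclusive gap (0 on overlap, else
#' `later.start - earlier.end - 1`) is at most `window` (default 100 kb,
#' i.e. genes within 100 kb up- or downstream). Strand is ignored; the
#' boundary gap equal to `window` is included.
#'
#' @param de_lncs Tibble of lncRNAs (`transcript_id`, `chrom`, `start`,
#'   `end`).
#' @param genes [annotation_set()] (its coding genes are scanned) or a gene
#'   tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param window Maximum gap in bp (default 100000).
#' @return Tibble `lnc_id`, `gene_id`, `mode = "cis"`, `distance`.
#' @export
cis_targets <- function(de_lncs, genes, window = 100000) {
  gene_tbl <- if (inherits(genes, "annotation_set")) {
    filter(genes$genes, .data$biotype == "coding")
  } else {
    as_tibble(genes)
  }
  de_lncs <- as_tibble(de_lncs)
  if (nrow(de_lncs) == 0 || nrow(gene_tbl) == 0) {
    return(tibble(lnc_id = character(), gene_id = character(),
                  mode = character(), distance = integer()))
  }
  lnc_gr <- GenomicRanges::GRanges(
    de_lncs$chrom, IRanges::IRanges(de_lncs$start, de_lncs$end))
  gene_gr <- GenomicRanges::GRanges(
    gene_tbl$chrom, IRanges::IRanges(gene_tbl$start, gene_tbl$end))
  hits <- GenomicRanges::findOverlaps(lnc_gr, gene_gr, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  dist <- interval_gap(
    de_lncs$start[qi], de_lncs$end[qi],
    gene_tbl$start[si], gene_tbl$end[si]
  )
  tibble(
    lnc_id = de_lncs$transcript_id[qi],
    gene_id = gene_tbl$gene_id[si],
    mode = "cis",
    distance = as.integer(dist)
  ) %>% arrange(.data$lnc_id, .data$gene_id)
}

#' Predict trans target genes by expression correlation
#'
#' Pearson correlation of the raw FPKM vectors of each (lncRNA, gene) pair
#' across all samples; a link is emitted when `|r| >= r_min` (default 0.95).
#' Zero-variance features are skipped with a warning. With six samples no
#' p-value is attached to `r` — the threshold is purely on magnitude, so
#' treat trans links as hypotheses, not tests.
#'
#' @param lnc_ids,gene_ids Character vectors of feature ids present in
#'   `fpkm` (for genes, the id of the gene's transcript row or the gene
#'   itself, whichever indexes the FPKM table).
#' @param fpkm Tibble `feature_id` + sample columns (>= 3 samples).
#' @param r_min Minimum absolute correlation (default 0.95).
#' @param log2_transform Correlate `log2(FPKM + 1)` instead of raw FPKM.
#' @return Tibble `lnc_id`, `gene_id`, `mode = "trans"`, `r`.
#' @export
trans_targets <- function(lnc_ids, gene_ids, fpkm, r_min = 0.95,
                          log2_transform = FALSE) {
  m <- counts_matrix(fpkm)
  if (ncol(m) < 3) abort("trans prediction needs >= 3 samples")
  missing <- setdiff(c(lnc_ids, gene_ids), rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("feature(s) missing from fpkm: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  if (length(lnc_ids) == 0 || length(gene_ids) == 0) {
    return(tibble(lnc_id = character(), gene_id = character(),
                  mode = character(), r = numeric()))
  }
  if (log2_transform) m <- log2(m + 1)
  lm <- m[lnc_ids, , drop = FALSE]
  gm <- m[gene_ids, , drop = FALSE]
  l_var <- apply(lm, 1, stats::sd) > 0
  g_var <- apply(gm, 1, stats::sd) > 0
  if (any(!l_var) || any(!g_var)) {
    warn(sprintf(
      "skipping %d zero-variance feature(s) (undefined correlation)",
      sum(!l_var) + sum(!g_var)
    ))
  }
  lm <- lm[l_var, , drop = FALSE]; gm <- gm[g_var, , drop = FALSE]
  if (nrow(lm) == 0 || nrow(gm) == 0) {
    return(tibble(lnc_id = character(), gene_id = character(),
                  mode = character(), r = numeric()))
  }
  rmat <- cor(t(lm), t(gm))
  idx <- which(abs(rmat) >= r_min, arr.ind = TRUE)
  tibble(
    lnc_id = rownames(rmat)[idx[, 1]],
    gene_id = colnames(rmat)[idx[, 2]],
    mode = "trans",
    r = rmat[idx]
  ) %>% arrange(.data$lnc_id, .data$gene_id)
}

#' Intersect cis and trans targets with differential expression
#'
#' A gene is a common target when it has at least one cis link and at least
#' one trans link from differentially expressed lncRNAs and is itself
#' differentially expressed. Under `mode = "any_lnc"` (default) the two links
#' may come from different lncRNAs; under `mode = "same_lnc"` they must share
#' one.
#'
#' @param cis_links,trans_links Link tibbles from [cis_targets()] /
#'   [trans_targets()].
#' @param de_results DE table (`feature_id`, `de_flag`) for the genes; ids
#'   must match the link tables' `gene_id` (map transcript-level DE to genes
#'   beforehand if needed).
#' @param mode `"any_lnc"` or `"same_lnc"`.
#' @return Tibble `gene_id`, `n_cis_links`, `n_trans_links`, `de_flag`, with
#'   supporting link tables in the `links` attribute.
#' @export
common_targets <- function(cis_links, trans_links, de_results,
                           mode = c("any_lnc", "same_lnc")) {
  mode <- match.arg(mode)
  de <- as_tibble(de_results)
  de_genes <- de$feature_id[de$de_flag != "ns"]
  if (mode == "any_lnc") {
    genes <- intersect(intersect(unique(cis_links$gene_id),
                                 unique(trans_links$gene_id)), de_genes)
  } else {
    both <- dplyr::inner_join(
      distinct(select(as_tibble(cis_links), "lnc_id", "gene_id")),
      distinct(select(as_tibble(trans_links), "lnc_id", "gene_id")),
      by = c("lnc_id", "gene_id")
    )
    genes <- intersect(unique(both$gene_id), de_genes)
  }
  cis_sup <- filter(as_tibble(cis_links), .data$gene_id %in% genes)
  trans_sup <- filter(as_tibble(trans_links), .data$gene_id %in% genes)
  out <- tibble(gene_id = sort(genes)) %>%
    left_join(dplyr::count(cis_sup, .data$gene_id, name = "n_cis_links"),
              by = "gene_id") %>%
    left_join(dplyr::count(trans_sup, .data$gene_id, name = "n_trans_links"),
              by = "gene_id") %>%
    left_join(select(de, "feature_id", "de_flag"),
              by = c(gene_id = "feature_id"))
  attr(out, "links") <- list(cis = cis_sup, trans = trans_sup)
  attr(out, "mode") <- mode
  out
}
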