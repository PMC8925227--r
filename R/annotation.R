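# The in-memory annotation container: transcripts, exons and genes as
# tibbles of 1-based inclusive intervals. All downstream modules consume it.

#' Construct an annotation set
#'
#' Bundles transcript models, their exons and the derived gene spans into a
#' light container used throughout the pipeline. All coordinates are 1-based
#' inclusive; `length` is the sum of exon lengths (`end - start + 1`).
#'
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype` (one of `coding`, `known_lncRNA`,
#'   `candidate`, `novel_lncRNA`). `start`/`end`/`length`/`n_exons` are
#'   recomputed from `exons` when missing.
#' @param exons Tibble with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`; exons of one transcript must be non-overlapping.
#' @param genes Optional tibble `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `biotype`; derived as the union span of each gene's transcripts when
#'   absent.
#' @return An object of class `annotation_set`: a list of the three tibbles.
#' @export
annotation_set <- function(transcripts, exons, genes = NULL) {
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  if (nrow(transcripts) == 0 && nrow(exons) == 0) {
    empty_tx <- tibble(
      transcript_id = character(), gene_id = character(),
      biotype = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), length = integer(),
      n_exons = integer()
    )
    empty_genes <- tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), biotype = character()
    )
    return(structure(
      list(transcripts = empty_tx,
           exons = tibble(transcript_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer()),
           genes = if (is.null(genes)) empty_genes else as_tibble(genes)),
      class = "annotation_set"
    ))
  }
  if (nrow(exons) > 0) {
    check_strand(exons$strand, "exon strand")
    if (any(exons$start < 1) || any(exons$end < exons$start)) {
      abort("exon intervals must satisfy start >= 1 and end >= start")
    }
  }
  exons <- arrange(exons, .data$transcript_id, .data$start)
  spans <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      length = sum(.data$end - .data$start + 1L),
      n_exons = dplyr::n(),
      overlap_ok = all(diff(.data$start) > 0 &
        utils::head(.data$end, -1) < .data$start[-1]) || dplyr::n() == 1L,
      # aggregate the span last: these assignments shadow the exon columns
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) %>%
    select("transcript_id", "chrom", "strand", "start", "end", "length",
           "n_exons", "overlap_ok")
  if (!all(spans$overlap_ok)) {
    abort(sprintf(
      "overlapping exons within transcript(s): %s",
      paste(spans$transcript_id[!spans$overlap_ok], collapse = ", ")
    ))
  }
  missing_tx <- setdiff(spans$transcript_id, transcripts$transcript_id)
  if (length(missing_tx) > 0) {
    abort(sprintf("exons reference unknown transcript(s): %s",
                  paste(missing_tx, collapse = ", ")))
  }
  keep <- intersect(
    c("transcript_id", "gene_id", "biotype"), names(transcripts))
  transcripts <- transcripts[keep]
  if (is.null(transcripts$biotype)) transcripts$biotype <- "candidate"
  transcripts <- left_join(
    transcripts,
    select(spans, -"overlap_ok"),
    by = "transcript_id"
  )
  if (anyNA(transcripts$start)) {
    abort(sprintf(
      "transcript(s) without exons: %s",
      paste(transcripts$transcript_id[is.na(transcripts$start)], collapse = ", ")
    ))
  }
  if (is.null(genes)) {
    genes <- transcripts %>%
      group_by(.data$gene_id) %>%
      summarise(
        chrom = .data$chrom[1], strand = .data$strand[1],
        start = min(.data$start), end = max(.data$end),
        biotype = .data$biotype[1], .groups = "drop"
      )
  }
  structure(
    list(
      transcripts = arrange(transcripts, .data$chrom, .data$start,
                            .data$transcript_id),
      exons = arrange(exons, .data$chrom, .data$start, .data$transcript_id),
      genes = arrange(as_tibble(genes), .data$chrom, .data$start, .data$gene_id)
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d transcripts / %d exons / %d genes\n",
    nrow(x$transcripts), nrow(x$exons), nrow(x$genes)
  ))
  tab <- table(x$transcripts$biotype)
  if (length(tab)) {
    cat("  biotypes:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# GRanges views used by the interval machinery.
exon_granges <- function(ann, biotypes = NULL) {
  ex <- ann$exons
  tx <- ann$transcripts
  if (!is.null(biotypes)) {
    keep <- tx$transcript_id[tx$biotype %in% biotypes]
    ex <- filter(ex, .data$transcript_id %in% keep)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start, end = ex$end),
    strand = ex$strand
  )
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  gr
}

transcript_granges <- function(tbl) {
  gr <- GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start, end = tbl$end),
    strand = tbl$strand
  )
  id_col <- if ("transcript_id" %in% names(tbl)) "transcript_id" else "gene_id"
  S4Vectors::mcols(gr)$id <- tbl[[id_col]]
  gr
}

# Introns of each transcript (gaps between consecutive exons).
transcript_introns <- function(ann, biotypes = NULL) {
  ex <- ann$exons
  if (!is.null(biotypes)) {
    keep <- ann$transcripts$transcript_id[ann$transcripts$biotype %in% biotypes]
    ex <- filter(ex, .data$transcript_id %in% keep)
  }
  ex %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    filter(dplyr::n() > 1) %>%
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      intron_start = list(utils::head(.data$end, -1) + 1L),
      intron_end = list(.data$start[-1] - 1L),
      .groups = "drop"
    ) %>%
    tidyr::unnest(c("intron_start", "intron_end")) %>%
    rename(start = "intron_start", end = "intron_end") %>%
    filter(.data$end >= .data$start)
}
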