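# GFF3/GTF reading and writing. Parsing is delegated to rtracklayer after a
# cheap structural pre-validation pass so that malformed input is reported
# with its line number. Coordinates stay 1-based inclusive end to end and
# GFF3 is the only output dialect.

detect_gff_dialect <- function(lines) {
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) return("gff3")
  attrs <- vapply(strsplit(body[1], "\t", fixed = TRUE), function(f) {
    if (length(f) >= 9) f[9] else ""
  }, character(1))
  # GTF uses `key "value";`, GFF3 uses `key=value`
  if (grepl("\\w+ +\"", attrs) && !grepl("=", sub("\\\".*", "", attrs))) "gtf"
  else "gff3"
}

validate_gff_lines <- function(lines, path) {
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      abort(sprintf("%s: malformed line %d: expected 9 tab-separated fields, got %d",
                    path, i, length(f)))
    }
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      abort(sprintf("%s: malformed line %d: non-numeric coordinates", path, i))
    }
  }
  invisible(TRUE)
}

#' Read a GFF3 or GTF annotation into an annotation set
#'
#' The dialect is auto-detected from the attribute syntax. Exon features must
#' carry a transcript attribute (`Parent` in GFF3, `transcript_id` in GTF)
#' and an explicit strand; transcript spans are computed from the exons when
#' no transcript feature is present. A `biotype` attribute on transcript
#' features is preserved (`candidate` when absent).
#'
#' @param path Path to a GFF3/GTF file.
#' @return An [annotation_set()].
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  validate_gff_lines(lines, path)
  dialect <- detect_gff_dialect(lines)
  gr <- rtracklayer::import(path, format = dialect)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_exon <- type == "exon"
  if (!any(is_exon)) {
    return(annotation_set(
      tibble(transcript_id = character(), gene_id = character(),
             biotype = character()),
      tibble(transcript_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer())
    ))
  }
  if (dialect == "gtf") {
    tx_id <- as.character(mc$transcript_id[is_exon])
    gene_of_tx <- NULL
    gene_id <- as.character(mc$gene_id[is_exon])
  } else {
    if (is.null(mc$Parent)) {
      abort(sprintf("exon feature(s) without a transcript attribute in %s", path))
    }
    parents <- mc$Parent[is_exon]
    n_par <- S4Vectors::elementNROWS(parents)
    if (any(n_par == 0)) {
      abort(sprintf("exon feature(s) without a transcript attribute in %s", path))
    }
    tx_id <- as.character(unlist(parents))
    # transcript-level rows map transcripts to genes
    is_tx <- !is_exon & !is.na(mc$ID) & type != "gene"
    gene_of_tx <- setNames(
      vapply(mc$Parent[is_tx], function(p) {
        if (length(p)) as.character(p[1]) else NA_character_
      }, character(1)),
      as.character(mc$ID[is_tx])
    )
    gene_id <- unname(gene_of_tx[tx_id])
    gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]
  }
  if (anyNA(tx_id) || any(tx_id == "")) {
    abort(sprintf("exon feature(s) without a transcript attribute in %s", path))
  }
  strand <- as.character(BiocGenerics::strand(gr))[is_exon]
  if (any(!strand %in% c("+", "-"))) {
    abort(sprintf(
      "exon(s) with unknown strand '.' in %s (transcripts: %s)", path,
      paste(unique(tx_id[!strand %in% c("+", "-")]), collapse = ", ")
    ))
  }
  exons <- tibble(
    transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    strand = strand,
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon]
  )
  # biotype from transcript-level features when present
  biotype_col <- if ("biotype" %in% names(mc)) as.character(mc$biotype) else NULL
  tx_tbl <- distinct(tibble(transcript_id = tx_id, gene_id = gene_id))
  tx_tbl$biotype <- "candidate"
  if (!is.null(biotype_col)) {
    id_col <- if (dialect == "gtf") as.character(mc$transcript_id) else
      as.character(mc$ID)
    has_bt <- !is.na(biotype_col) & !is.na(id_col)
    bt <- setNames(biotype_col[has_bt], id_col[has_bt])
    hit <- tx_tbl$transcript_id %in% names(bt)
    tx_tbl$biotype[hit] <- unname(bt[tx_tbl$transcript_id[hit]])
  }
  annotation_set(tx_tbl, exons)
}

#' Write an annotation set as GFF3
#'
#' Emits gene, transcript and exon features with `ID`/`Parent` links and the
#' transcript `biotype` attribute, ordered by chromosome, start and
#' transcript id, so output is byte-deterministic for a given annotation.
#'
#' @param annotation An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  tx <- arrange(annotation$transcripts, .data$chrom, .data$start,
                .data$transcript_id)
  if (nrow(tx) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  genes <- annotation$genes %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
  ex <- annotation$exons %>%
    left_join(select(tx, "transcript_id", "gene_id", "biotype"),
              by = "transcript_id") %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)

  rows <- bind_rows(
    tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
           strand = genes$strand, type = "gene", ID = genes$gene_id,
           Parent = NA_character_, biotype = genes$biotype,
           ord_start = genes$start, tx = genes$gene_id, lvl = 1L),
    tibble(chrom = tx$chrom, start = tx$start, end = tx$end,
           strand = tx$strand, type = "transcript", ID = tx$transcript_id,
           Parent = tx$gene_id, biotype = tx$biotype,
           ord_start = tx$start, tx = tx$transcript_id, lvl = 2L),
    tibble(chrom = ex$chrom, start = ex$start, end = ex$end,
           strand = ex$strand, type = "exon", ID = NA_character_,
           Parent = ex$transcript_id, biotype = NA_character_,
           ord_start = ex$start, tx = ex$transcript_id, lvl = 3L)
  ) %>%
    arrange(.data$chrom, .data$ord_start, .data$tx, .data$lvl, .data$start)

  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  mc <- S4Vectors::DataFrame(
    source = "stresslnc",
    type = rows$type,
    ID = rows$ID,
    Parent = ifelse(is.na(rows$Parent), "", rows$Parent),
    biotype = rows$biotype
  )
  mc$Parent <- S4Vectors::splitAsList(
    rows$Parent[!is.na(rows$Parent)],
    factor(seq_len(nrow(rows))[!is.na(rows$Parent)],
           levels = seq_len(nrow(rows)))
  )
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings keeping the user-facing representation a
#' named character vector (DNA alphabet; U is accepted on read and stored
#' as T).
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  x <- Biostrings::readBStringSet(path)
  out <- toupper(chartr("Uu", "Tt", as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
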