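# lncRNA discovery: the ordered filter cascade (length -> coding-gene
# overlap / known-lncRNA rescue -> expression floor -> coding-potential
# consensus), the three-predictor coding-potential stand-in (ORF length,
# hexamer log-likelihood, protein-motif scan) and strand-aware positional
# classification.

#' Build hexamer log-likelihood tables
#'
#' Frequency tables of all 4096 hexamers from coding and non-coding training
#' sequences (overlapping windows, pseudocount-smoothed, each summing to 1).
#' When no non-coding training set is available the background defaults to
#' the uniform distribution, which keeps the score a signed KL-style contrast
#' against coding composition.
#'
#' @param coding_seqs Character vector of coding training sequences.
#' @param noncoding_seqs Optional non-coding training sequences.
#' @param pseudocount Added to every hexamer count before normalization.
#' @return List `coding`, `noncoding`: named numeric vectors over hexamers.
#' @export
build_hexamer_tables <- function(coding_seqs, noncoding_seqs = NULL,
                                 pseudocount = 0.5) {
  freq_of <- function(seqs) {
    x <- Biostrings::DNAStringSet(seqs)
    cnt <- colSums(Biostrings::oligonucleotideFrequency(x, width = 6L, step = 1L))
    f <- cnt + pseudocount
    f / sum(f)
  }
  coding <- freq_of(coding_seqs)
  noncoding <- if (is.null(noncoding_seqs)) {
    setNames(rep(1 / length(coding), length(coding)), names(coding))
  } else {
    freq_of(noncoding_seqs)
  }
  list(coding = coding, noncoding = noncoding)
}

# Longest forward-frame ORF (ATG..stop) in codons, counting start through the
# codon preceding the stop. N breaks an ORF.
longest_orf_codons <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    has_n <- grepl("N", codons, fixed = TRUE)
    open <- -1L
    for (i in seq_along(codons)) {
      if (has_n[i] || is_stop[i]) {
        if (open > 0 && is_stop[i]) best <- max(best, i - open)
        open <- -1L
      } else if (open < 0 && is_start[i]) {
        open <- i
      }
    }
  }
  best
}

hexamer_score <- function(seq, tables) {
  log_ratio <- log2(tables$coding / tables$noncoding)
  if (grepl("N", seq, fixed = TRUE)) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < 6) return(0)
    hex <- vapply(1:(n - 5L), function(i) paste(chars[i:(i + 5L)], collapse = ""),
                  character(1))
    hex <- hex[!grepl("N", hex, fixed = TRUE)]
    if (length(hex) == 0) return(0)
    return(mean(log_ratio[hex]))
  }
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq), width = 6L, step = 1L)
  if (sum(cnt) == 0) return(0)
  sum(cnt * log_ratio[names(cnt)]) / sum(cnt)
}

# Batched predictors over many sequences (one Biostrings call per step).
coding_potential_batch <- function(sequences, hexamer_tables, motifs,
                                   orf_min_codons = 100L) {
  sequences <- toupper(chartr("Uu", "Tt", sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) abort("sequence contains non-ACGTN symbols")
  has_n <- grepl("N", sequences, fixed = TRUE)
  log_ratio <- log2(hexamer_tables$coding / hexamer_tables$noncoding)

  hx <- numeric(length(sequences))
  if (any(!has_n)) {
    cnt <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(sequences[!has_n]), width = 6L, step = 1L)
    tot <- rowSums(cnt)
    hx[!has_n] <- ifelse(
      tot == 0, 0,
      as.numeric(cnt %*% log_ratio[colnames(cnt)]) / pmax(tot, 1))
  }
  if (any(has_n)) {
    hx[has_n] <- vapply(sequences[has_n], hexamer_score, numeric(1),
                        tables = hexamer_tables)
  }

  orf <- vapply(sequences, longest_orf_codons, integer(1), USE.NAMES = FALSE)

  motif <- rep(NA_character_, length(sequences))
  if (length(motifs) > 0) {
    aa3 <- lapply(0:2, function(frame) {
      lens <- ((nchar(sequences) - frame) %/% 3L) * 3L
      sub <- substr(sequences, frame + 1L, frame + pmax(lens, 0L))
      sub[lens < 3] <- ""
      as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAStringSet(sub), if.fuzzy.codon = "X", no.init.codon = TRUE
      )))
    })
    for (m in motifs) {
      hit <- grepl(m, aa3[[1]], fixed = TRUE) |
        grepl(m, aa3[[2]], fixed = TRUE) | grepl(m, aa3[[3]], fixed = TRUE)
      motif[is.na(motif) & hit] <- m
    }
  }

  orf_coding <- orf >= orf_min_codons
  hex_coding <- hx > 0
  dom_coding <- !is.na(motif)
  tibble(
    predictor_orf = ifelse(orf_coding, "coding", "noncoding"),
    orf_codons = orf,
    predictor_hexamer = ifelse(hex_coding, "coding", "noncoding"),
    hexamer_score = hx,
    predictor_domain = ifelse(dom_coding, "coding", "noncoding"),
    motif = motif,
    consensus = ifelse(orf_coding | hex_coding | dom_coding,
                       "coding", "noncoding")
  )
}

motif_hit <- function(seq, motifs) {
  if (length(motifs) == 0) return(NA_character_)
  n <- nchar(seq)
  for (frame in 0:2) {
    len <- ((n - frame) %/% 3L) * 3L
    if (len < 3) next
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(substr(seq, frame + 1L, frame + len)),
      if.fuzzy.codon = "X"
    )))
    for (m in motifs) {
      if (grepl(m, aa, fixed = TRUE)) return(m)
    }
  }
  NA_character_
}

#' Three-predictor coding-potential consensus
#'
#' Re-creates the three-tool consensus used in lncRNA pipelines with three
#' in-package predictors: longest forward-frame ORF length (coding if >=
#' `orf_min_codons`), mean hexamer log2 likelihood ratio (coding if > 0) and
#' a protein-motif scan over the three forward-frame translations (coding on
#' any hit). The consensus is `noncoding` only when all three predictors
#' agree on `noncoding` — the intersection logic of a three-set Venn.
#'
#' @param sequence Nucleotide string (A/C/G/T/N; N breaks ORFs and is skipped
#'   in hexamer scoring).
#' @param hexamer_tables From [build_hexamer_tables()].
#' @param motifs Character vector of protein motifs (may be empty).
#' @param orf_min_codons ORF-length threshold (default 100 codons).
#' @return One-row tibble with each predictor's call and score and the
#'   consensus call.
#' @export
coding_potential <- function(sequence, hexamer_tables,
                             motifs = stresslnc_motifs(),
                             orf_min_codons = 100L) {
  stopifnot(length(sequence) == 1L)
  coding_potential_batch(sequence, hexamer_tables, motifs, orf_min_codons)
}

#' Classify lncRNAs by genomic position
#'
#' Strand-aware positional classes with precedence antisense > intronic >
#' lincRNA: `antisense` if any lncRNA exon overlaps any coding-gene exon on
#' the opposite strand; else `intronic` if the lncRNA span is fully contained
#' within a single intron of a same-strand coding transcript; else
#' `lincRNA`.
#'
#' @param lncs Tibble of lncRNA transcripts (`transcript_id`, `chrom`,
#'   `strand`, `start`, `end`) or an [annotation_set()] whose candidates to
#'   classify.
#' @param genes An [annotation_set()] providing the coding gene models.
#' @param lnc_exons Optional exon tibble for the lncRNAs; defaults to their
#'   spans (single-exon assumption) or to the annotation's exons.
#' @return Tibble `transcript_id`, `class`.
#' @export
classify_lncrna <- function(lncs, genes, lnc_exons = NULL) {
  if (inherits(lncs, "annotation_set")) {
    if (is.null(lnc_exons)) lnc_exons <- lncs$exons
    lncs <- lncs$transcripts
  }
  lncs <- as_tibble(lncs)
  if (nrow(lncs) == 0) return(tibble(transcript_id = character(), class = character()))
  if (is.null(lnc_exons)) {
    lnc_exons <- select(lncs, "transcript_id", "chrom", "strand", "start", "end")
  }
  lnc_exons <- filter(lnc_exons, .data$transcript_id %in% lncs$transcript_id)

  coding_ex <- filter(
    genes$exons,
    .data$transcript_id %in%
      genes$transcripts$transcript_id[genes$transcripts$biotype == "coding"]
  )

  lnc_gr <- GenomicRanges::GRanges(
    lnc_exons$chrom, IRanges::IRanges(lnc_exons$start, lnc_exons$end),
    strand = lnc_exons$strand
  )
  cod_gr <- GenomicRanges::GRanges(
    coding_ex$chrom, IRanges::IRanges(coding_ex$start, coding_ex$end),
    strand = coding_ex$strand
  )
  # exon overlap on the opposite strand -> antisense
  hits <- GenomicRanges::findOverlaps(lnc_gr, cod_gr, ignore.strand = TRUE)
  opp <- as.character(BiocGenerics::strand(lnc_gr))[S4Vectors::queryHits(hits)] !=
    as.character(BiocGenerics::strand(cod_gr))[S4Vectors::subjectHits(hits)]
  antisense_ids <- unique(lnc_exons$transcript_id[
    S4Vectors::queryHits(hits)[opp]])

  # full containment in a single intron of a same-strand coding transcript
  introns <- transcript_introns(genes, biotypes = "coding")
  intronic_ids <- character(0)
  if (nrow(introns) > 0) {
    span_gr <- GenomicRanges::GRanges(
      lncs$chrom, IRanges::IRanges(lncs$start, lncs$end), strand = lncs$strand
    )
    int_gr <- GenomicRanges::GRanges(
      introns$chrom, IRanges::IRanges(introns$start, introns$end),
      strand = introns$strand
    )
    wh <- GenomicRanges::findOverlaps(span_gr, int_gr, type = "within",
                                      ignore.strand = FALSE)
    intronic_ids <- unique(lncs$transcript_id[S4Vectors::queryHits(wh)])
  }

  cls <- rep("lincRNA", nrow(lncs))
  cls[lncs$transcript_id %in% intronic_ids] <- "intronic"
  cls[lncs$transcript_id %in% antisense_ids] <- "antisense"
  tibble(transcript_id = lncs$transcript_id, class = cls)
}

#' The lncRNA identification filter cascade
#'
#' Ordered rule evaluation over every candidate transcript: (1) length >=
#' `min_length` (200 nt; single-exon transcripts are retained by default);
#' (2) same-strand exonic overlap with a coding gene rejects the candidate,
#' while overlap with the known-lncRNA track marks it `known_lncRNA`
#' (skipping the coding-potential step); (3) maximum FPKM over all samples
#' must reach `min_fpkm` (0.5); (4) the coding-potential consensus must be
#' `noncoding` for the survivors, which become `novel_lncRNA`. Each
#' transcript receives exactly one outcome and, if rejected, the first
#' failed rule. Surviving lncRNAs are positionally classified.
#'
#' @param annotation [annotation_set()] holding coding gene models
#'   (`biotype == "coding"`) and the candidate transcripts to screen.
#' @param known_lnc [annotation_set()] of the known-lncRNA track (may be
#'   empty).
#' @param fpkm Tibble `feature_id` + sample columns covering all candidates.
#' @param sequences Named character vector covering all candidates.
#' @param thresholds Named list overriding `min_length` (200), `min_fpkm`
#'   (0.5), `keep_single_exon` (TRUE), `orf_min_codons` (100).
#' @param hexamer_tables Optional [build_hexamer_tables()] output; trained on
#'   the annotation's coding transcript sequences when absent.
#' @param motifs Protein motif list for the domain predictor.
#' @return Tibble of class `filter_trace`: `transcript_id`, `outcome`
#'   (`known_lncRNA` / `novel_lncRNA` / `rejected`), `rejected_at`, `class`
#'   (positional class, `unclassified` for rejected transcripts).
#' @export
filter_cascade <- function(annotation, known_lnc, fpkm, sequences,
                           thresholds = list(), hexamer_tables = NULL,
                           motifs = stresslnc_motifs()) {
  th <- utils::modifyList(
    list(min_length = 200, min_fpkm = 0.5, keep_single_exon = TRUE,
         orf_min_codons = 100L),
    thresholds
  )
  tx <- annotation$transcripts
  cand <- filter(tx, .data$biotype %in% c("candidate", "novel_lncRNA",
                                          "known_lncRNA"))
  if (nrow(cand) == 0) {
    return(structure(
      tibble(transcript_id = character(), outcome = character(),
             rejected_at = character(), class = character()),
      class = c("filter_trace", "tbl_df", "tbl", "data.frame")
    ))
  }
  missing_fpkm <- setdiff(cand$transcript_id, fpkm$feature_id)
  missing_seq <- setdiff(cand$transcript_id, names(sequences))
  if (length(missing_fpkm) || length(missing_seq)) {
    abort(sprintf(
      "candidate transcript(s) missing from %s: %s",
      paste(c(if (length(missing_fpkm)) "fpkm",
              if (length(missing_seq)) "sequences"), collapse = " and "),
      paste(head(unique(c(missing_fpkm, missing_seq)), 10), collapse = ", ")
    ))
  }

  outcome <- rep(NA_character_, nrow(cand))
  rejected_at <- rep(NA_character_, nrow(cand))

  # rule 1: minimum length (single-exon transcripts retained by default)
  fail_len <- cand$length < th$min_length |
    (!th$keep_single_exon & cand$n_exons == 1L)
  rejected_at[fail_len] <- "min_length"

  # rule 2: same-strand exonic overlap with coding genes rejects;
  # overlap with the known-lncRNA track rescues as known
  cand_ex <- filter(annotation$exons, .data$transcript_id %in% cand$transcript_id)
  cand_gr <- GenomicRanges::GRanges(
    cand_ex$chrom, IRanges::IRanges(cand_ex$start, cand_ex$end),
    strand = cand_ex$strand
  )
  cod_gr <- exon_granges(annotation, biotypes = "coding")
  cod_hit <- GenomicRanges::findOverlaps(cand_gr, cod_gr, ignore.strand = FALSE)
  overlap_ids <- unique(cand_ex$transcript_id[S4Vectors::queryHits(cod_hit)])
  known_ids <- character(0)
  if (nrow(known_lnc$exons) > 0) {
    known_gr <- exon_granges(known_lnc)
    kn_hit <- GenomicRanges::findOverlaps(cand_gr, known_gr, ignore.strand = FALSE)
    known_ids <- unique(cand_ex$transcript_id[S4Vectors::queryHits(kn_hit)])
  }
  fail_ovl <- cand$transcript_id %in% overlap_ids & is.na(rejected_at)
  rejected_at[fail_ovl] <- "coding_overlap"
  is_known <- cand$transcript_id %in% known_ids & is.na(rejected_at)

  # rule 3: expression floor on the max FPKM over all samples
  fm <- counts_matrix(fpkm)
  max_fpkm <- apply(fm[match(cand$transcript_id, rownames(fm)), , drop = FALSE],
                    1, max)
  fail_fpkm <- max_fpkm < th$min_fpkm & is.na(rejected_at)
  rejected_at[fail_fpkm] <- "min_fpkm"
  is_known <- is_known & is.na(rejected_at)
  outcome[is_known] <- "known_lncRNA"

  # rule 4: coding-potential consensus for the remaining candidates
  pending <- which(is.na(outcome) & is.na(rejected_at))
  if (length(pending) > 0) {
    if (is.null(hexamer_tables)) {
      coding_seqs <- sequences[intersect(
        tx$transcript_id[tx$biotype == "coding"], names(sequences))]
      if (length(coding_seqs) == 0) {
        abort("no coding training sequences available; supply hexamer_tables")
      }
      hexamer_tables <- build_hexamer_tables(coding_seqs)
    }
    calls <- coding_potential_batch(
      sequences[cand$transcript_id[pending]], hexamer_tables, motifs,
      orf_min_codons = th$orf_min_codons
    )
    is_coding <- calls$consensus == "coding"
    rejected_at[pending[is_coding]] <- "coding_potential"
    outcome[pending[!is_coding]] <- "novel_lncRNA"
  }
  outcome[is.na(outcome)] <- "rejected"

  res <- tibble(
    transcript_id = cand$transcript_id,
    outcome = outcome,
    rejected_at = rejected_at,
    class = "unclassified"
  )
  kept <- res$outcome != "rejected"
  if (any(kept)) {
    cls <- classify_lncrna(
      cand[kept, ], annotation,
      lnc_exons = filter(annotation$exons,
                         .data$transcript_id %in% cand$transcript_id[kept])
    )
    res$class[kept] <- cls$class[match(res$transcript_id[kept],
                                       cls$transcript_id)]
  }
  structure(res, class = c("filter_trace", class(res)))
}

#' Structural summary of transcript cohorts
#'
#' Per-cohort fractions of transcripts per exon-count bin (1, 2, ...,
#' `>= 10`), per length bin, and counts per chromosome — the standard
#' lncRNA-vs-mRNA structural comparison.
#'
#' @param lncs,mrnas Tibbles with `transcript_id`, `chrom`, `length`,
#'   `n_exons` (e.g. slices of an annotation's transcripts). Both must be
#'   non-empty.
#' @param length_breaks Inner bin edges for transcript length (nt).
#' @return List of tibbles `exon_bins`, `length_bins` (fractions sum to 1
#'   per cohort), `chromosomes` (counts); class `lnc_structure_summary`.
#' @export
summarize_structure <- function(lncs, mrnas,
                                length_breaks = c(500, 1200)) {
  if (nrow(lncs) == 0 || nrow(mrnas) == 0) abort("both cohorts must be non-empty")
  cohorts <- list(lncRNA = as_tibble(lncs), mRNA = as_tibble(mrnas))
  exon_levels <- c(as.character(1:9), ">=10")
  brk <- c(0, length_breaks, Inf)
  len_levels <- sprintf(
    "%s-%s", c("<=", brk[2:(length(brk) - 1)] + 1)[
      seq_len(length(brk) - 1)], brk[-1])
  len_labels <- character(length(brk) - 1)
  for (i in seq_len(length(brk) - 1)) {
    len_labels[i] <- if (i == 1) sprintf("<=%g", brk[2])
    else if (i == length(brk) - 1) sprintf(">%g", brk[i])
    else sprintf("%g-%g", brk[i] + 1, brk[i + 1])
  }
  out_exon <- list(); out_len <- list(); out_chr <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    eb <- ifelse(co$n_exons >= 10, ">=10", as.character(co$n_exons))
    tab <- table(factor(eb, levels = exon_levels))
    out_exon[[nm]] <- tibble(
      cohort = nm, exon_bin = factor(exon_levels, levels = exon_levels),
      fraction = as.numeric(tab) / nrow(co)
    )
    lb <- cut(co$length, breaks = brk, labels = len_labels,
              include.lowest = TRUE)
    tabl <- table(lb)
    out_len[[nm]] <- tibble(
      cohort = nm, length_bin = factor(len_labels, levels = len_labels),
      fraction = as.numeric(tabl) / nrow(co)
    )
    tc <- table(co$chrom)
    out_chr[[nm]] <- tibble(
      cohort = nm, chrom = names(tc), n = as.integer(tc)
    )
  }
  structure(
    list(exon_bins = bind_rows(out_exon), length_bins = bind_rows(out_len),
         chromosomes = bind_rows(out_chr)),
    class = "lnc_structure_summary"
  )
}
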