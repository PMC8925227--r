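# Filter cascade, coding-potential consensus and positional classification.

uniform_tables <- function() {
  hex <- names(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString("ACGT"), width = 6L))
  u <- setNames(rep(1 / 4096, 4096), hex)
  list(coding = u, noncoding = u)
}

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

test_that("an embedded long ORF forces a coding consensus", {
  codons <- rep("GCT", 200)  # alanine run, no stops
  seq <- paste0(random_seq(30, 1), "ATG", paste(codons, collapse = ""), "TAA",
                random_seq(30, 2))
  call <- coding_potential(seq, uniform_tables(), motifs = character(0))
  expect_equal(call$predictor_orf, "coding")
  expect_gte(call$orf_codons, 200)
  expect_equal(call$consensus, "coding")
})

test_that("a quiet random sequence is called noncoding by all predictors", {
  # hexamer tables equal -> score exactly 0 -> noncoding by strict > 0
  seq <- random_seq(300, 3)
  call <- coding_potential(seq, uniform_tables(), motifs = character(0))
  expect_equal(call$hexamer_score, 0)
  expect_equal(call$predictor_hexamer, "noncoding")
  expect_lt(call$orf_codons, 100)
  expect_equal(call$consensus, "noncoding")
})

test_that("the domain predictor fires on an encoded motif", {
  ds <- small_dataset()
  coding_seq <- ds$sequences[[
    ds$annotation$transcripts$transcript_id[
      ds$annotation$transcripts$biotype == "coding"][1]]]
  call <- coding_potential(coding_seq, uniform_tables(),
                           motifs = stresslnc_motifs())
  expect_equal(call$predictor_domain, "coding")
})

test_that("consensus is noncoding only when all three predictors agree", {
  # flipping any single predictor to coding flips the consensus
  grid <- expand.grid(orf = c(FALSE, TRUE), hex = c(FALSE, TRUE),
                      dom = c(FALSE, TRUE))
  base <- random_seq(400, 4)
  tabs <- uniform_tables()
  for (i in seq_len(nrow(grid))) {
    seq <- base
    motifs <- character(0)
    if (grid$orf[i]) {
      seq <- paste0(substr(seq, 1, 30), "ATG", strrep("GCT", 150), "TAA",
                    substr(seq, 31, 400))
    }
    tt <- tabs
    if (grid$hex[i]) {
      # bias the coding table toward the sequence's own hexamers
      cnt <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAString(seq), width = 6L)
      tt$coding <- (cnt + 0.5) / sum(cnt + 0.5)
    }
    if (grid$dom[i]) {
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(substr(seq, 1, 399)), if.fuzzy.codon = "X")))
      motifs <- substr(aa, 5, 10)
    }
    call <- coding_potential(seq, tt, motifs = motifs)
    any_fired <- call$predictor_orf == "coding" ||
      call$predictor_hexamer == "coding" || call$predictor_domain == "coding"
    expect_equal(call$consensus == "coding", any_fired)
    if (grid$orf[i] || grid$hex[i] || grid$dom[i]) {
      expect_equal(call$consensus, "coding")
    }
  }
})

test_that("sequences with invalid symbols are rejected", {
  expect_error(coding_potential("ACGTXACGT", uniform_tables()), "non-ACGTN")
})

test_that("cascade rejections carry the first failed rule", {
  ds <- small_dataset()
  # too-short transcript -> min_length
  ids <- ds$annotation$transcripts
  short_id <- ids$transcript_id[ids$length < 200][1]
  trace <- filter_cascade(ds$annotation, ds$known_lnc, ds$fpkm, ds$sequences)
  expect_equal(trace$rejected_at[trace$transcript_id == short_id],
               "min_length")
  # silent transcript -> min_fpkm (max FPKM < 0.5)
  low_id <- ds$truth$transcripts$transcript_id[
    ds$truth$transcripts$violated_rule %in% "min_fpkm"][1]
  expect_equal(trace$rejected_at[trace$transcript_id == low_id], "min_fpkm")
  expect_lt(max(as.numeric(ds$fpkm[ds$fpkm$feature_id == low_id, -1])), 0.5)
})

test_that("the cascade partitions every candidate exactly once", {
  ds <- small_dataset()
  trace <- filter_cascade(ds$annotation, ds$known_lnc, ds$fpkm, ds$sequences)
  cand <- ds$annotation$transcripts$transcript_id[
    ds$annotation$transcripts$biotype == "candidate"]
  expect_setequal(trace$transcript_id, cand)
  expect_false(anyDuplicated(trace$transcript_id) > 0)
  expect_true(all(trace$outcome %in%
                    c("known_lncRNA", "novel_lncRNA", "rejected")))
  expect_true(all(is.na(trace$rejected_at) == (trace$outcome != "rejected")))
})

test_that("planted truth is recovered on the small synthetic dataset", {
  ds <- small_dataset()
  trace <- filter_cascade(ds$annotation, ds$known_lnc, ds$fpkm, ds$sequences)
  j <- merge(trace, ds$truth$transcripts, by = "transcript_id")
  lnc <- j[j$is_lnc, ]; dec <- j[!j$is_lnc, ]
  expect_true(all(lnc$outcome != "rejected"))
  expect_true(all(dec$outcome == "rejected"))
  expect_equal(dec$rejected_at, dec$violated_rule)
  # knowns rescued as known_lncRNA
  known <- j[j$known %in% TRUE, ]
  if (nrow(known) > 0) expect_true(all(known$outcome == "known_lncRNA"))
})

test_that("missing FPKM or sequences are reported with ids", {
  ds <- small_dataset()
  cand_id <- ds$annotation$transcripts$transcript_id[
    ds$annotation$transcripts$biotype == "candidate"][1]
  expect_error(
    filter_cascade(ds$annotation, ds$known_lnc,
                   ds$fpkm[ds$fpkm$feature_id != cand_id, ], ds$sequences),
    cand_id
  )
})

test_that("positional classification honors its definitions and precedence", {
  genes <- annotation_set(
    tibble::tibble(transcript_id = "gt1", gene_id = "g1", biotype = "coding"),
    tibble::tibble(transcript_id = "gt1", chrom = "chr1", strand = "+",
                   start = c(1000, 2000), end = c(1499, 2499))
  )
  # 1 bp opposite-strand exon overlap -> antisense
  lnc1 <- tibble::tibble(transcript_id = "l1", chrom = "chr1", strand = "-",
                         start = 700, end = 1000)
  expect_equal(classify_lncrna(lnc1, genes)$class, "antisense")
  # same-strand containment in the intron -> intronic
  lnc2 <- tibble::tibble(transcript_id = "l2", chrom = "chr1", strand = "+",
                         start = 1550, end = 1850)
  expect_equal(classify_lncrna(lnc2, genes)$class, "intronic")
  # opposite-strand containment in the intron, no exon overlap -> lincRNA
  lnc3 <- tibble::tibble(transcript_id = "l3", chrom = "chr1", strand = "-",
                         start = 1550, end = 1850)
  expect_equal(classify_lncrna(lnc3, genes)$class, "lincRNA")
  # far from any gene -> lincRNA
  lnc4 <- tibble::tibble(transcript_id = "l4", chrom = "chr1", strand = "+",
                         start = 52000, end = 52400)
  expect_equal(classify_lncrna(lnc4, genes)$class, "lincRNA")
  # antisense beats intronic: opposite strand, overlapping an exon while
  # also inside another gene's intron
  genes2 <- annotation_set(
    tibble::tibble(transcript_id = c("gt1", "gt2"), gene_id = c("g1", "g2"),
                   biotype = "coding"),
    dplyr::bind_rows(
      tibble::tibble(transcript_id = "gt1", chrom = "chr1", strand = "+",
                     start = c(1000, 5000), end = c(1499, 5499)),
      tibble::tibble(transcript_id = "gt2", chrom = "chr1", strand = "-",
                     start = c(900, 2000), end = c(1200, 2400))
    )
  )
  lnc5 <- tibble::tibble(transcript_id = "l5", chrom = "chr1", strand = "+",
                         start = 1600, end = 2100)
  expect_equal(classify_lncrna(lnc5, genes2)$class, "antisense")
})

test_that("classification agrees with the exhaustive interval-pair oracle", {
  n_cases <- 300
  set.seed(20)
  genes <- annotation_set(
    tibble::tibble(transcript_id = c("gt1", "gt2", "gt3"),
                   gene_id = c("g1", "g2", "g3"), biotype = "coding"),
    dplyr::bind_rows(
      tibble::tibble(transcript_id = "gt1", chrom = "chr1", strand = "+",
                     start = c(1000, 2000, 3000), end = c(1400, 2400, 3400)),
      tibble::tibble(transcript_id = "gt2", chrom = "chr1", strand = "-",
                     start = c(6000, 7000), end = c(6500, 7500)),
      tibble::tibble(transcript_id = "gt3", chrom = "chr2", strand = "+",
                     start = c(1000, 3000), end = c(1900, 3900))
    )
  )
  for (i in seq_len(n_cases)) {
    chrom <- sample(c("chr1", "chr2"), 1)
    strand <- sample(c("+", "-"), 1)
    start <- sample(1:9000, 1)
    len <- sample(50:1500, 1)
    lnc <- tibble::tibble(transcript_id = "lx", chrom = chrom,
                          strand = strand, start = start,
                          end = start + len - 1L)
    got <- classify_lncrna(lnc, genes)$class
    want <- classify_oracle(
      lnc, lnc, genes$transcripts, genes$exons
    )
    expect_equal(got, want,
                 label = sprintf("case %d (%s:%d-%d %s)", i, chrom, start,
                                 start + len - 1L, strand))
  }
})

test_that("structure summaries bin cohorts with unit totals", {
  lncs <- tibble::tibble(transcript_id = paste0("l", 1:10), chrom = "chr1",
                         length = 300, n_exons = 1)
  mrnas <- tibble::tibble(transcript_id = paste0("m", 1:3), chrom = "chr2",
                          length = c(250, 450, 1300), n_exons = c(2, 5, 12))
  s <- summarize_structure(lncs, mrnas, length_breaks = c(500, 1200))
  eb <- s$exon_bins[s$exon_bins$cohort == "lncRNA", ]
  expect_equal(eb$fraction[eb$exon_bin == "1"], 1)
  lb <- s$length_bins[s$length_bins$cohort == "mRNA", ]
  expect_equal(lb$fraction, c(2 / 3, 0, 1 / 3))
  expect_equal(sum(s$exon_bins$fraction[s$exon_bins$cohort == "mRNA"]), 1)
  mb <- s$exon_bins[s$exon_bins$cohort == "mRNA", ]
  expect_equal(mb$fraction[mb$exon_bin == ">=10"], 1 / 3)
  expect_error(summarize_structure(lncs[0, ], mrnas), "non-empty")
})

test_that("structure fractions sum to one over random cohorts", {
  set.seed(21)
  for (i in 1:100) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    lncs <- tibble::tibble(
      transcript_id = paste0("l", seq_len(n1)),
      chrom = sample(paste0("chr", 1:3), n1, TRUE),
      length = sample(200:5000, n1, TRUE), n_exons = sample(1:15, n1, TRUE))
    mrnas <- tibble::tibble(
      transcript_id = paste0("m", seq_len(n2)),
      chrom = sample(paste0("chr", 1:3), n2, TRUE),
      length = sample(200:5000, n2, TRUE), n_exons = sample(1:15, n2, TRUE))
    s <- summarize_structure(lncs, mrnas)
    agg <- tapply(s$exon_bins$fraction, s$exon_bins$cohort, sum)
    expect_equal(as.numeric(agg), c(1, 1), tolerance = 1e-12)
    aggl <- tapply(s$length_bins$fraction, s$length_bins$cohort, sum)
    expect_equal(as.numeric(aggl), c(1, 1), tolerance = 1e-12)
  }
})
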