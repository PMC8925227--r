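# Synthetic-data generator with planted ground truth: a toy multi-chromosome
# genome carrying coding genes with real ORFs, planted lncRNAs of each
# positional class, rule-violating decoys, negative-binomial counts with
# planted condition effects, embedded miRNA complementary sites and a planted
# over-represented annotation term. Every output is a pure function of the
# configuration (seed included).

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, STOP_CODONS)
}

# GC-biased codon weights give coding sequence a hexamer signature distinct
# from the uniform intergenic background.
codon_usage_weights <- function(codons) {
  gc <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
               numeric(1))
  (gc + 0.25)^2
}

# Fixed reverse-translation table (alphabetically first codon per residue).
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), unname(gc))
  vapply(split_codons, function(x) sort(x)[1], character(1))
}

#' Default protein motifs planted into coding sequences
#'
#' Used by the generator (planted into every coding ORF and ORF-carrying
#' decoy) and as the default motif list of the domain-scan coding-potential
#' predictor.
#' @export
stresslnc_motifs <- function() c("WDHEVLRQW", "MKTAYIAKQR")

random_bases <- function(n) c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)]

#' Simulation configuration
#'
#' Defines the synthetic study: a two-condition (control vs heat), three-
#' replicate design over a toy genome. Defaults mirror a heat-stress bulk
#' RNA-seq experiment at desk scale: lncRNA class counts follow the
#' lincRNA-dominated mix observed in maize (about 95% lincRNA), planted
#' effects are large (|log2FC| = 3, as typical of heat-shock responses), and
#' counts are negative binomial with common dispersion 0.1.
#'
#' @param seed Integer RNG seed; every generator output is a pure function of
#'   the full configuration.
#' @param n_chroms,chrom_length Chromosome count and length (bp).
#' @param n_coding_genes Multi-exon coding genes with real ORFs
#'   (start codon, >= 150 codons, stop).
#' @param n_lnc_per_class Named counts for planted `lincRNA`, `intronic`,
#'   `antisense` lncRNAs.
#' @param n_decoys Decoy transcripts, split evenly over the four violated
#'   rules (`min_length`, `coding_overlap`, `min_fpkm`, `coding_potential`).
#' @param frac_known Fraction of planted lincRNAs also emitted as the
#'   known-lncRNA annotation track.
#' @param n_replicates Replicates per condition.
#' @param nb_dispersion Common NB dispersion `phi` (0 = Poisson).
#' @param frac_de Fraction of expressed features with a planted condition
#'   effect.
#' @param planted_log2fc Planted effect size: heat mean = control mean x
#'   `2^planted_log2fc` (sign per planted direction).
#' @param prob_up Probability a planted effect is up-regulated.
#' @param baseline_range Baseline mean counts drawn log-uniform over this
#'   range (equal bounds give a constant, so `c(0, 0)` silences all features).
#' @param libsize_jitter Per-sample depth factors drawn uniformly within
#'   plus/minus this fraction of 1.
#' @param n_cis_pairs,n_trans_pairs,n_common_targets Planted lncRNA-gene
#'   relations; common targets are cis-proximal, trans-correlated and
#'   differentially expressed by construction.
#' @param trans_ratio Proportionality constant of planted trans pairs.
#' @param deterministic_counts If `TRUE`, counts equal rounded expectations
#'   (noise-free mode; planted trans pairs are exactly proportional).
#' @param n_mirnas,n_mirna_sites,mirna_length Mature miRNAs to generate and
#'   complementary sites to embed (site kinds cycle exact / one non-seed G:U
#'   wobble / one seed mismatch).
#' @param mirna_gu_pos,mirna_mismatch_pos miRNA positions (from its 5' end)
#'   perturbed in wobble / mismatch sites.
#' @param motifs Protein motifs planted into every ORF.
#' @param term_background_terms,term_planted_frac Background annotation-term
#'   pool size behaviour and the fraction of planted common-target genes
#'   carrying the planted enriched term.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 5L,
                              chrom_length = 4000000L,
                              n_coding_genes = 100L,
                              n_lnc_per_class = c(lincRNA = 230L, intronic = 6L,
                                                  antisense = 5L),
                              n_decoys = 200L,
                              frac_known = 0.1,
                              n_replicates = 3L,
                              nb_dispersion = 0.1,
                              frac_de = 0.2,
                              planted_log2fc = 3,
                              prob_up = 0.5,
                              baseline_range = c(10, 300),
                              libsize_jitter = 0.2,
                              n_cis_pairs = 30L,
                              n_trans_pairs = 20L,
                              n_common_targets = 10L,
                              trans_ratio = 2,
                              deterministic_counts = FALSE,
                              n_mirnas = 10L,
                              n_mirna_sites = 18L,
                              mirna_length = 21L,
                              mirna_gu_pos = 16L,
                              mirna_mismatch_pos = 3L,
                              motifs = stresslnc_motifs(),
                              term_background_terms = 1:3,
                              term_planted_frac = 0.8) {
  cfg <- as.list(environment())
  stopifnot(
    length(cfg$n_lnc_per_class) == 3,
    all(c("lincRNA", "intronic", "antisense") %in% names(cfg$n_lnc_per_class))
  )
  assert_scalar_number(cfg$nb_dispersion, "nb_dispersion", min = 0)
  assert_scalar_number(cfg$frac_de, "frac_de", min = 0)
  for (f in c("n_chroms", "chrom_length", "n_coding_genes", "n_decoys",
              "n_replicates", "n_cis_pairs", "n_trans_pairs",
              "n_common_targets", "n_mirnas", "n_mirna_sites")) {
    assert_scalar_number(cfg[[f]], f, min = 0)
  }
  if (any(cfg$n_lnc_per_class < 0)) abort("lncRNA class counts must be >= 0")
  if (cfg$mirna_length < 15) abort("mirna_length must be >= 15 nt")
  structure(cfg, class = "simulation_config")
}

# -- gene/transcript construction helpers ------------------------------------

build_cds <- function(pep_len, motifs, sense, w, aa_tab) {
  codons <- sample(sense, pep_len, replace = TRUE, prob = w)
  if (length(motifs) > 0) {
    motif <- motifs[[sample.int(length(motifs), 1L)]]
    aa <- strsplit(motif, "")[[1]]
    mc <- unname(aa_tab[aa])
    if (anyNA(mc)) abort(sprintf("motif '%s' contains a non-residue symbol", motif))
    if (length(mc) + 8 < pep_len) {
      pos <- sample.int(pep_len - length(mc) - 7L, 1L) + 3L
      codons[pos:(pos + length(mc) - 1L)] <- mc
    }
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

split_lengths <- function(total, k, min_len = 50L) {
  if (k == 1L) return(total)
  for (i in 1:60) {
    cuts <- sort(sample(seq.int(min_len, total - min_len), k - 1L))
    lens <- diff(c(0L, cuts, total))
    if (all(lens >= min_len)) return(lens)
  }
  base <- rep(total %/% k, k)
  base[k] <- base[k] + total %% k
  base
}

#' Simulate the toy genome, annotations and planted truth
#'
#' Lays out coding genes on an even grid per chromosome, then places planted
#' lincRNAs (intergenic, > 0 bp from any gene), intronic lncRNAs (fully
#' inside one intron of a same-strand host), antisense lncRNAs (overlapping a
#' host exon on the opposite strand) and the four decoy families, writes real
#' ORFs into the genome sequence, and assigns planted differential-expression
#' status and the planted cis / trans / common-target relations.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `annotation` ([annotation_set()] of coding
#'   genes plus candidates), `known_lnc` (annotation of the known-lncRNA
#'   track), `genome` (named character vector, one string per chromosome),
#'   `sequences` (named character vector of transcript sequences) and
#'   `truth` (list of truth tibbles).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  sense <- sense_codons()
  w <- codon_usage_weights(sense)
  aa_tab <- aa_codon_table()
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  genome <- lapply(chroms, function(ch) random_bases(cfg$chrom_length))
  names(genome) <- chroms

  exon_rows <- list()
  tx_rows <- list()
  seqs <- list()

  write_seq <- function(chrom, exon_starts, exon_ends, strand, tx_seq) {
    lens <- exon_ends - exon_starts + 1L
    genomic <- if (strand == "+") tx_seq else revcomp(tx_seq)
    chars <- strsplit(genomic, "")[[1]]
    off <- 0L
    for (i in seq_along(lens)) {
      genome[[chrom]][exon_starts[i]:exon_ends[i]] <<-
        chars[(off + 1L):(off + lens[i])]
      off <- off + lens[i]
    }
  }

  read_tx_seq <- function(chrom, exon_starts, exon_ends, strand) {
    parts <- vapply(seq_along(exon_starts), function(i) {
      paste(genome[[chrom]][exon_starts[i]:exon_ends[i]], collapse = "")
    }, character(1))
    s <- paste(parts, collapse = "")
    if (strand == "-") revcomp(s) else s
  }

  # ---- coding genes on an even grid ----------------------------------------
  per_chrom <- diff(round(seq(0, cfg$n_coding_genes, length.out = cfg$n_chroms + 1)))
  margin <- 20000L
  gene_info <- list()
  slot_tbl <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    slot_w <- (cfg$chrom_length - 2L * margin) %/% k
    if (slot_w < 25000L) {
      abort("chrom_length too small to place genes with cis-window margins; increase chrom_length or reduce n_coding_genes")
    }
    for (s in seq_len(k)) {
      gi <- gi + 1L
      gene_id <- sprintf("GENE%04d", gi)
      tx_id <- sprintf("MRNA%04d", gi)
      n_ex <- sample(3:7, 1L)
      pep_len <- sample(150:220, 1L)
      cds <- build_cds(pep_len, cfg$motifs, sense, w, aa_tab)
      utr5 <- paste(random_bases(sample(10:40, 1L)), collapse = "")
      utr3 <- paste(random_bases(sample(20:80, 1L)), collapse = "")
      tx_seq <- paste0(utr5, cds, utr3)
      tx_len <- nchar(tx_seq)
      exon_lens <- split_lengths(tx_len, n_ex)
      intron_lens <- sample(600:1800, n_ex - 1L, replace = TRUE)
      strand <- sample(c("+", "-"), 1L)
      start <- margin + (s - 1L) * slot_w + sample(0:2000, 1L)
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- start
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        ends[e] <- pos + exon_lens[e] - 1L
        pos <- ends[e] + 1L + if (e < n_ex) intron_lens[e] else 0L
      }
      write_seq(chroms[ci], starts, ends, strand, tx_seq)
      exon_rows[[tx_id]] <- tibble(
        transcript_id = tx_id, chrom = chroms[ci], strand = strand,
        start = starts, end = ends
      )
      tx_rows[[tx_id]] <- tibble(
        transcript_id = tx_id, gene_id = gene_id, biotype = "coding"
      )
      seqs[[tx_id]] <- tx_seq
      gene_info[[gene_id]] <- list(
        gene_id = gene_id, tx_id = tx_id, chrom = chroms[ci], strand = strand,
        start = starts[1], end = ends[n_ex],
        exon_starts = starts, exon_ends = ends,
        intron_starts = if (n_ex > 1) ends[-n_ex] + 1L else integer(0),
        intron_ends = if (n_ex > 1) starts[-1] - 1L else integer(0)
      )
      slot_tbl[[length(slot_tbl) + 1L]] <- list(
        chrom = chroms[ci], gene_id = gene_id,
        cursor = ends[n_ex] + sample(500:3000, 1L),
        limit = margin + s * slot_w - 500L
      )
    }
  }
  genes <- gene_info

  # ---- intergenic placement (round-robin over inter-gene slots) ------------
  n_slots <- length(slot_tbl)
  slot_ptr <- 0L
  place_intergenic <- function(len) {
    tried <- 0L
    while (tried < n_slots) {
      slot_ptr <<- (slot_ptr %% n_slots) + 1L
      tried <- tried + 1L
      sl <- slot_tbl[[slot_ptr]]
      # wide uniform gaps spread placements over the whole inter-gene span,
      # so only some lincRNAs fall inside the 100 kb cis window of a gene
      start <- sl$cursor + sample(2000:50000, 1L)
      if (start + len - 1L <= sl$limit) {
        slot_tbl[[slot_ptr]]$cursor <<- start + len
        return(list(chrom = sl$chrom, start = start, gene_id = sl$gene_id))
      }
    }
    abort("cannot place all transcripts; increase chrom_length or n_chroms")
  }

  lnc_counter <- 0L
  add_candidate <- function(prefix, chrom, strand, starts, ends,
                            planted_seq = NULL) {
    lnc_counter <<- lnc_counter + 1L
    tx_id <- sprintf("%s%04d", prefix, lnc_counter)
    if (!is.null(planted_seq)) {
      write_seq(chrom, starts, ends, strand, planted_seq)
    }
    exon_rows[[tx_id]] <<- tibble(
      transcript_id = tx_id, chrom = chrom, strand = strand,
      start = starts, end = ends
    )
    tx_rows[[tx_id]] <<- tibble(
      transcript_id = tx_id, gene_id = tx_id, biotype = "candidate"
    )
    seqs[[tx_id]] <<- read_tx_seq(chrom, starts, ends, strand)
    tx_id
  }

  truth_rows <- list()
  note_truth <- function(tx_id, class, is_lnc, violated = NA_character_,
                         host = NA_character_, slot_gene = NA_character_) {
    truth_rows[[tx_id]] <<- tibble(
      transcript_id = tx_id, true_class = class, is_lnc = is_lnc,
      violated_rule = violated, host_gene = host, slot_gene = slot_gene
    )
  }

  lincRNA_len <- function() {
    if (runif(1) < 0.97) sample(210:480, 1L) else sample(500:1500, 1L)
  }

  # planted lincRNAs
  for (i in seq_len(cfg$n_lnc_per_class[["lincRNA"]])) {
    len <- lincRNA_len()
    n_ex <- if (runif(1) < 0.92) 1L else 2L
    span <- len + if (n_ex == 2L) sample(300:800, 1L) else 0L
    loc <- place_intergenic(span)
    strand <- sample(c("+", "-"), 1L)
    if (n_ex == 1L) {
      starts <- loc$start; ends <- loc$start + len - 1L
    } else {
      l1 <- split_lengths(len, 2L, min_len = 80L)
      starts <- c(loc$start, loc$start + span - l1[2])
      ends <- c(loc$start + l1[1] - 1L, loc$start + span - 1L)
    }
    id <- add_candidate("LINC", loc$chrom, strand, starts, ends)
    note_truth(id, "lincRNA", TRUE, slot_gene = loc$gene_id)
  }

  # planted intronic lncRNAs (same-strand host, fully inside one intron)
  host_pool <- Filter(function(g) length(g$intron_starts) > 0, genes)
  for (i in seq_len(cfg$n_lnc_per_class[["intronic"]])) {
    len <- sample(210:400, 1L)
    ok <- FALSE
    for (try in 1:100) {
      g <- host_pool[[sample.int(length(host_pool), 1L)]]
      introns <- which(g$intron_ends - g$intron_starts + 1L >= len + 40L)
      if (length(introns) > 0) { ok <- TRUE; break }
    }
    if (!ok) abort("no intron large enough for a planted intronic lncRNA")
    iv <- introns[sample.int(length(introns), 1L)]
    room <- (g$intron_ends[iv] - g$intron_starts[iv] + 1L) - len
    s0 <- g$intron_starts[iv] + sample.int(room - 20L, 1L) + 10L
    id <- add_candidate("LNCI", g$chrom, g$strand, s0, s0 + len - 1L)
    note_truth(id, "intronic", TRUE, host = g$gene_id, slot_gene = g$gene_id)
  }

  # exon-overlapping placements (antisense lncRNAs, coding-overlap decoys)
  place_exon_overlap <- function(len, same_strand) {
    g <- genes[[sample.int(length(genes), 1L)]]
    e <- sample.int(length(g$exon_starts), 1L)
    ex_len <- g$exon_ends[e] - g$exon_starts[e] + 1L
    ov <- sample(30:min(len - 10L, ex_len), 1L)
    if (runif(1) < 0.5) {
      end <- g$exon_starts[e] + ov - 1L
      start <- end - len + 1L
    } else {
      start <- g$exon_ends[e] - ov + 1L
      end <- start + len - 1L
    }
    strand <- if (same_strand) g$strand else setdiff(c("+", "-"), g$strand)
    list(chrom = g$chrom, start = max(1L, start), end = end, strand = strand,
         gene_id = g$gene_id)
  }

  for (i in seq_len(cfg$n_lnc_per_class[["antisense"]])) {
    len <- sample(210:450, 1L)
    loc <- place_exon_overlap(len, same_strand = FALSE)
    id <- add_candidate("LNCA", loc$chrom, loc$strand, loc$start, loc$end)
    note_truth(id, "antisense", TRUE, host = loc$gene_id,
               slot_gene = loc$gene_id)
  }

  # decoys: each violates exactly one cascade rule
  n_per_decoy <- diff(round(seq(0, cfg$n_decoys, length.out = 5)))
  for (i in seq_len(n_per_decoy[1])) {        # too short
    len <- sample(80:199, 1L)
    loc <- place_intergenic(len)
    id <- add_candidate("DSHT", loc$chrom, sample(c("+", "-"), 1L),
                        loc$start, loc$start + len - 1L)
    note_truth(id, "decoy_short", FALSE, violated = "min_length",
               slot_gene = loc$gene_id)
  }
  for (i in seq_len(n_per_decoy[2])) {        # same-strand coding overlap
    len <- sample(210:450, 1L)
    loc <- place_exon_overlap(len, same_strand = TRUE)
    id <- add_candidate("DOVL", loc$chrom, loc$strand, loc$start, loc$end)
    note_truth(id, "decoy_coding_overlap", FALSE, violated = "coding_overlap",
               host = loc$gene_id, slot_gene = loc$gene_id)
  }
  for (i in seq_len(n_per_decoy[3])) {        # silent (fails the FPKM floor)
    len <- sample(210:400, 1L)
    loc <- place_intergenic(len)
    id <- add_candidate("DLOW", loc$chrom, sample(c("+", "-"), 1L),
                        loc$start, loc$start + len - 1L)
    note_truth(id, "decoy_low_fpkm", FALSE, violated = "min_fpkm",
               slot_gene = loc$gene_id)
  }
  for (i in seq_len(n_per_decoy[4])) {        # long-ORF intergenic decoy
    pep_len <- sample(120:140, 1L)
    cds <- build_cds(pep_len, cfg$motifs, sense, w, aa_tab)
    seq <- paste0(
      paste(random_bases(sample(10:30, 1L)), collapse = ""), cds,
      paste(random_bases(sample(10:40, 1L)), collapse = "")
    )
    len <- nchar(seq)
    loc <- place_intergenic(len)
    id <- add_candidate("DORF", loc$chrom, "+", loc$start,
                        loc$start + len - 1L, planted_seq = seq)
    note_truth(id, "decoy_orf", FALSE, violated = "coding_potential",
               slot_gene = loc$gene_id)
  }

  truth_tx <- bind_rows(truth_rows)
  # known-lncRNA track: a fraction of the planted lincRNAs
  linc_ids <- truth_tx$transcript_id[truth_tx$true_class == "lincRNA"]
  n_known <- round(cfg$frac_known * length(linc_ids))
  known_ids <- if (n_known > 0) sort(sample(linc_ids, n_known)) else character(0)
  truth_tx$known <- truth_tx$transcript_id %in% known_ids

  annotation <- annotation_set(bind_rows(tx_rows), bind_rows(exon_rows))

  known_lnc <- if (length(known_ids) > 0) {
    ktx <- filter(annotation$transcripts, .data$transcript_id %in% known_ids)
    kex <- filter(annotation$exons, .data$transcript_id %in% known_ids)
    kid <- setNames(sprintf("KNOWN%03d", seq_along(known_ids)), known_ids)
    ktx$transcript_id <- unname(kid[ktx$transcript_id])
    ktx$gene_id <- ktx$transcript_id
    ktx$biotype <- "known_lncRNA"
    kex$transcript_id <- unname(kid[kex$transcript_id])
    annotation_set(select(ktx, "transcript_id", "gene_id", "biotype"), kex)
  } else {
    annotation_set(
      tibble(transcript_id = character(), gene_id = character(),
             biotype = character()),
      tibble(transcript_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer())
    )
  }

  truth <- plant_de_truth(annotation, truth_tx, cfg)

  list(
    annotation = annotation,
    known_lnc = known_lnc,
    genome = vapply(genome, paste, character(1), collapse = ""),
    sequences = unlist(seqs),
    truth = truth
  )
}

# Planted differential expression and the cis/trans/common-target relations.
# Called inside simulate_genome's seeded scope.
plant_de_truth <- function(annotation, truth_tx, cfg) {
  tx <- annotation$transcripts
  expressed <- truth_tx$transcript_id[truth_tx$violated_rule %in% "min_fpkm" == FALSE]
  eligible <- tx$transcript_id[
    tx$biotype == "coding" |
      tx$transcript_id %in% truth_tx$transcript_id[truth_tx$is_lnc]
  ]
  de <- tibble(
    feature_id = tx$transcript_id,
    is_de = tx$transcript_id %in% eligible & runif(nrow(tx)) < cfg$frac_de,
    direction = NA_character_
  )
  de$direction[de$is_de] <- ifelse(runif(sum(de$is_de)) < cfg$prob_up,
                                   "up", "down")

  linc <- filter(truth_tx, .data$true_class == "lincRNA")
  # force enough DE lincRNAs to support the planted pair structure
  need <- max(cfg$n_common_targets + cfg$n_trans_pairs, cfg$n_cis_pairs)
  linc_ids <- linc$transcript_id
  forced <- head(linc_ids, min(need, length(linc_ids)))
  newly <- forced[!de$is_de[match(forced, de$feature_id)]]
  de$is_de[match(forced, de$feature_id)] <- TRUE
  de$direction[match(newly, de$feature_id)] <-
    ifelse(runif(length(newly)) < cfg$prob_up, "up", "down")

  slot_gene <- setNames(truth_tx$slot_gene, truth_tx$transcript_id)
  gene_tx <- setNames(
    tx$transcript_id[tx$biotype == "coding"],
    tx$gene_id[tx$biotype == "coding"]
  )

  # common targets: same lncRNA is cis-proximal and trans-correlated
  common_lncs <- head(forced, cfg$n_common_targets)
  common_genes <- unname(slot_gene[common_lncs])
  # remaining trans pairs: distinct lncs paired with arbitrary other genes
  trans_lncs <- forced[seq_len(min(length(forced),
    cfg$n_common_targets + cfg$n_trans_pairs))]
  trans_lncs <- setdiff(trans_lncs, common_lncs)
  other_genes <- setdiff(names(gene_tx), common_genes)
  trans_genes <- sample(other_genes, min(length(trans_lncs), length(other_genes)))
  trans_lncs <- trans_lncs[seq_along(trans_genes)]

  trans_pairs <- bind_rows(
    tibble(lnc_id = common_lncs, gene_id = common_genes, is_common = TRUE),
    tibble(lnc_id = trans_lncs, gene_id = trans_genes, is_common = FALSE)
  )
  trans_pairs$ratio <- cfg$trans_ratio

  # trans-paired genes inherit the lnc profile, hence its DE status
  pair_tx <- unname(gene_tx[trans_pairs$gene_id])
  lnc_idx <- match(trans_pairs$lnc_id, de$feature_id)
  gidx <- match(pair_tx, de$feature_id)
  de$is_de[gidx] <- de$is_de[lnc_idx]
  de$direction[gidx] <- de$direction[lnc_idx]

  de$log2fc <- ifelse(
    de$is_de, ifelse(de$direction == "up", cfg$planted_log2fc,
                     -cfg$planted_log2fc), 0
  )

  cis_lncs <- head(forced, min(cfg$n_cis_pairs, length(forced)))
  g <- annotation$genes
  cis_pairs <- tibble(
    lnc_id = cis_lncs,
    gene_id = unname(slot_gene[cis_lncs])
  )
  li <- match(cis_pairs$lnc_id, tx$transcript_id)
  ggi <- match(cis_pairs$gene_id, g$gene_id)
  cis_pairs$distance <- interval_gap(
    tx$start[li], tx$end[li], g$start[ggi], g$end[ggi]
  )

  list(
    transcripts = truth_tx,
    de = de,
    cis_pairs = cis_pairs,
    trans_pairs = select(trans_pairs, "lnc_id", "gene_id", "ratio", "is_common"),
    common_targets = tibble(
      gene_id = common_genes, lnc_id = common_lncs,
      feature_id = unname(gene_tx[common_genes])
    )
  )
}

#' Simulate negative-binomial counts with planted effects
#'
#' Counts are drawn per feature and sample as NB(mean, dispersion `phi`),
#' Poisson when `phi = 0`, or rounded expectations in noise-free mode.
#' Baseline means are log-uniform over `config$baseline_range`, scaled by a
#' per-sample depth factor; planted-DE features have heat means shifted by
#' `2^(+/- planted_log2fc)`; planted trans pairs share the lncRNA's mean
#' profile (scaled by `trans_ratio`) so their noise-free FPKM vectors are
#' exactly proportional.
#'
#' @param annotation An [annotation_set()] (feature lengths are taken from it).
#' @param truth Truth list from [simulate_genome()].
#' @param config The [simulation_config()].
#' @return A list: `counts` (tibble, `feature_id` + sample columns, with the
#'   `samples` attribute), `fpkm` (the exact FPKM implied by the counts and
#'   column-sum library sizes) and `means` (the expectation matrix).
#' @export
simulate_counts <- function(annotation, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 1L, {
    tx <- annotation$transcripts
    n_rep <- config$n_replicates
    sample_ids <- c(sprintf("PC%d", seq_len(n_rep)), sprintf("PH%d", seq_len(n_rep)))
    samples <- parse_sample_info(sample_ids)
    n_feat <- nrow(tx)

    rng <- config$baseline_range
    base <- if (rng[1] == rng[2]) rep(rng[1], n_feat) else
      exp(runif(n_feat, log(rng[1]), log(rng[2])))
    silent <- truth$transcripts$transcript_id[
      truth$transcripts$violated_rule %in% "min_fpkm"]
    base[tx$transcript_id %in% silent] <- 0

    depth <- runif(2L * n_rep, 1 - config$libsize_jitter,
                   1 + config$libsize_jitter)
    mu <- outer(base, depth)
    rownames(mu) <- tx$transcript_id
    colnames(mu) <- sample_ids

    de <- truth$de[match(tx$transcript_id, truth$de$feature_id), ]
    heat <- samples$condition == "heat"
    # heat mean = control mean x 2^log2fc; down-regulation is realized by
    # boosting the control side so planted effects stay mass-balanced
    # between conditions (no systematic library-size tilt)
    up_fc <- ifelse(de$is_de & de$log2fc > 0, 2^de$log2fc, 1)
    down_fc <- ifelse(de$is_de & de$log2fc < 0, 2^(-de$log2fc), 1)
    mu[, heat] <- mu[, heat] * up_fc
    mu[, !heat] <- mu[, !heat] * down_fc

    # planted trans pairs share the lncRNA profile
    tp <- truth$trans_pairs
    if (nrow(tp) > 0) {
      gene_tx <- setNames(
        tx$transcript_id[tx$biotype == "coding"],
        tx$gene_id[tx$biotype == "coding"]
      )
      gi <- match(unname(gene_tx[tp$gene_id]), rownames(mu))
      li <- match(tp$lnc_id, rownames(mu))
      mu[gi, ] <- tp$ratio * mu[li, , drop = FALSE]
    }

    if (config$deterministic_counts) {
      cnt <- round(mu)
      if (nrow(tp) > 0) cnt[gi, ] <- tp$ratio * cnt[li, , drop = FALSE]
    } else if (config$nb_dispersion == 0) {
      cnt <- matrix(rpois(length(mu), lambda = mu), nrow = n_feat,
                    dimnames = dimnames(mu))
    } else {
      cnt <- matrix(
        rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
        nrow = n_feat, dimnames = dimnames(mu)
      )
    }

    counts <- matrix_to_tibble(cnt)
    attr(counts, "samples") <- samples
    lengths <- tibble(feature_id = tx$transcript_id, length = tx$length)
    fpkm <- if (all(colSums(cnt) > 0)) {
      compute_fpkm(counts, lengths)
    } else {
      # a library with no fragments has no defined FPKM scale; report zeros
      z <- matrix_to_tibble(cnt * 0)
      attr(z, "samples") <- samples
      z
    }
    list(counts = counts, fpkm = fpkm, means = mu)
  })
}

#' Generate miRNAs and embed complementary sites in lncRNA sequences
#'
#' Each planted site embeds the exact reverse complement of a generated
#' miRNA at a recorded 1-based position of a differentially expressed
#' lncRNA; site kinds cycle through exact complement (expectation 0), one
#' non-seed G:U wobble (0.5) and one seed mismatch (2.0 under the default
#' scoring parameters).
#'
#' @param sequences Named character vector of transcript sequences.
#' @param truth Truth list from [simulate_genome()].
#' @param config The [simulation_config()].
#' @return List: `sequences` (with sites embedded), `mirnas` (named vector),
#'   `sites` (truth tibble `mirna_id`, `lnc_id`, `site_start`, `kind`,
#'   `expectation`) and `dems` (miRNA DE directions).
#' @export
plant_mirna_sites <- function(sequences, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 2L, {
    L <- config$mirna_length
    mirnas <- vapply(seq_len(config$n_mirnas), function(i) {
      s <- random_bases(L)
      # guarantee a wobble-capable base at the perturbation position
      s[config$mirna_gu_pos] <- sample(c("G", "T"), 1L)
      paste(s, collapse = "")
    }, character(1))
    names(mirnas) <- sprintf("MIR%03d", seq_len(config$n_mirnas))
    dems <- tibble(
      mirna_id = names(mirnas),
      direction = ifelse(runif(config$n_mirnas) < 0.5, "up", "down")
    )
    empty_sites <- tibble(
      mirna_id = character(), lnc_id = character(), site_start = integer(),
      kind = character(), expectation = numeric()
    )
    if (config$n_mirna_sites == 0 || config$n_mirnas == 0) {
      return(list(sequences = sequences, mirnas = mirnas, sites = empty_sites,
                  dems = dems))
    }
    is_de <- truth$de$feature_id[truth$de$is_de]
    lnc_ids <- truth$transcripts$transcript_id[truth$transcripts$is_lnc]
    hosts <- intersect(intersect(lnc_ids, is_de), names(sequences))
    hosts <- hosts[nchar(sequences[hosts]) >= L + 10L]
    if (length(hosts) == 0) {
      abort("no differentially expressed lncRNA is long enough to host a miRNA site")
    }
    n_sites <- min(config$n_mirna_sites, length(hosts))
    if (n_sites < config$n_mirna_sites) {
      warn(sprintf("only %d lncRNAs can host sites; planting %d of %d",
                   length(hosts), n_sites, config$n_mirna_sites))
    }
    chosen <- sample(hosts, n_sites)
    kinds <- rep(c("exact", "gu", "seed_mismatch"), length.out = n_sites)
    mirna_of <- rep(names(mirnas), length.out = n_sites)
    wc <- c(A = "T", C = "G", G = "C", T = "A")

    sites <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      lnc <- chosen[i]
      m <- mirnas[[mirna_of[i]]]
      site <- revcomp(m)
      kind <- kinds[i]
      expectation <- 0
      if (kind == "gu") {
        p <- config$mirna_gu_pos
        mb <- substr(m, p, p)
        gu_partner <- if (mb == "G") "T" else "G"
        j <- L - p + 1L
        substr(site, j, j) <- gu_partner
        expectation <- 0.5
      } else if (kind == "seed_mismatch") {
        p <- config$mirna_mismatch_pos
        mb <- substr(m, p, p)
        forbidden <- c(wc[[mb]], if (mb == "G") "T", if (mb == "T") "G")
        choicepool <- setdiff(c("A", "C", "G", "T"), forbidden)
        j <- L - p + 1L
        substr(site, j, j) <- sample(choicepool, 1L)
        expectation <- 2.0
      }
      pos <- sample.int(nchar(sequences[[lnc]]) - L + 1L, 1L)
      substr(sequences[[lnc]], pos, pos + L - 1L) <- site
      sites[[i]] <- tibble(
        mirna_id = mirna_of[i], lnc_id = lnc, site_start = pos,
        kind = kind, expectation = expectation
      )
    }
    list(sequences = sequences, mirnas = mirnas, sites = bind_rows(sites),
         dems = dems)
  })
}

#' Simulate the gene-to-term annotation map
#'
#' Every coding gene receives a few background GO terms and pathways drawn
#' from a synthetic pool; one planted GO term and one planted pathway are
#' assigned to `term_planted_frac` of the planted common-target genes (plus
#' two background genes) so the planted term is over-represented among the
#' common targets by construction.
#'
#' @inheritParams simulate_counts
#' @return List: `term_map` (tibble `gene_id`, `term_id`, `namespace`,
#'   `name`) and `planted` (tibble naming the planted term/pathway).
#' @export
simulate_term_map <- function(annotation, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 3L, {
    gene_ids <- annotation$genes$gene_id[annotation$genes$biotype == "coding"]
    pool <- tibble(
      term_id = c(sprintf("GO:S%06d", 1:30), sprintf("koS%05d", 1:10)),
      namespace = c(rep(c("BP", "CC", "MF"), each = 10), rep("pathway", 10))
    )
    if (length(gene_ids) == 0) {
      return(list(
        term_map = tibble(gene_id = character(), term_id = character(),
                          namespace = character(), name = character()),
        planted = tibble(term_id = character(), namespace = character())
      ))
    }
    rows <- lapply(gene_ids, function(g) {
      k <- sample(config$term_background_terms, 1L)
      idx <- sample.int(nrow(pool), k)
      tibble(gene_id = g, term_id = pool$term_id[idx],
             namespace = pool$namespace[idx])
    })
    term_map <- bind_rows(rows)

    planted <- tibble(
      term_id = c("GO:S900001", "koS90001"),
      namespace = c("BP", "pathway")
    )
    commons <- truth$common_targets$gene_id
    if (length(commons) > 0) {
      n_fg <- ceiling(config$term_planted_frac * length(commons))
      carriers <- c(
        commons[seq_len(n_fg)],
        sample(setdiff(gene_ids, commons), min(2L, length(gene_ids)))
      )
      term_map <- bind_rows(
        term_map,
        tidyr::crossing(tibble(gene_id = carriers), planted)
      )
    }
    term_map$name <- paste("synthetic term", term_map$term_id)
    term_map <- distinct(arrange(term_map, .data$gene_id, .data$term_id))
    list(term_map = term_map, planted = planted)
  })
}

#' Run the full generator and optionally write all artifacts
#'
#' Chains [simulate_genome()], [simulate_counts()], [plant_mirna_sites()] and
#' [simulate_term_map()], merging the truth tables. When `out_dir` is given,
#' writes `genome.fa`, `annotation.gff3`, `known_lnc.gff3`, `transcripts.fa`,
#' `mirna.fa`, `counts.tsv`, `fpkm.tsv`, `terms.tsv` and the `truth_*.tsv`
#' tables (all plain text, byte-deterministic for a given configuration).
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return The full dataset as a list (annotation, known_lnc, genome,
#'   sequences, mirnas, counts, fpkm, term_map, truth, config).
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  gen <- simulate_genome(config)
  cnt <- simulate_counts(gen$annotation, gen$truth, config)
  mir <- plant_mirna_sites(gen$sequences, gen$truth, config)
  trm <- simulate_term_map(gen$annotation, gen$truth, config)
  truth <- gen$truth
  truth$mirna_sites <- mir$sites
  truth$dems <- mir$dems
  truth$planted_terms <- trm$planted

  ds <- list(
    annotation = gen$annotation, known_lnc = gen$known_lnc,
    genome = gen$genome, sequences = mir$sequences, mirnas = mir$mirnas,
    counts = cnt$counts, fpkm = cnt$fpkm, term_map = trm$term_map,
    truth = truth, config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(ds$genome, p("genome.fa"))
    write_gff(ds$annotation, p("annotation.gff3"))
    write_gff(ds$known_lnc, p("known_lnc.gff3"))
    write_fasta(ds$sequences, p("transcripts.fa"))
    write_fasta(ds$mirnas, p("mirna.fa"))
    write_expression(ds$counts, p("counts.tsv"))
    write_expression(ds$fpkm, p("fpkm.tsv"))
    readr::write_tsv(ds$term_map, p("terms.tsv"), progress = FALSE)
    for (nm in names(truth)) {
      readr::write_tsv(truth[[nm]], p(sprintf("truth_%s.tsv", nm)),
                       progress = FALSE)
    }
  }
  ds
}
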