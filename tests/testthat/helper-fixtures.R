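# Shared fixtures: a small simulated dataset (cached per seed), a flat
# annotation-free count simulator for DE calibration checks, and brute-force
# oracles kept deliberately independent of the package's interval / p-value
# machinery.

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2, chrom_length = 800000,
         n_coding_genes = 10,
         n_lnc_per_class = c(lincRNA = 12, intronic = 3, antisense = 3),
         n_decoys = 12, n_cis_pairs = 3, n_trans_pairs = 2,
         n_common_targets = 2, n_mirnas = 3, n_mirna_sites = 4),
    list(...)
  )
  do.call(simulation_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function(seed = 1) {
  key <- paste0("small", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_dataset(small_config(seed))
  }
  .fixture_cache[[key]]
}

# Flat feature panel (no genome) for count-level simulations.
flat_panel <- function(n, seed, frac_de, baseline, lfc = 3, prob_up = 0.5,
                       dispersion = 0.1) {
  ids <- sprintf("f%04d", seq_len(n))
  ann <- annotation_set(
    tibble::tibble(transcript_id = ids, gene_id = ids, biotype = "candidate"),
    tibble::tibble(
      transcript_id = ids, chrom = "chr1", strand = "+",
      start = seq_len(n) * 2000L, end = seq_len(n) * 2000L + 999L
    )
  )
  cfg <- simulation_config(
    seed = seed, nb_dispersion = dispersion, frac_de = frac_de,
    planted_log2fc = lfc, prob_up = prob_up, baseline_range = baseline,
    n_cis_pairs = 0, n_trans_pairs = 0, n_common_targets = 0
  )
  is_de <- withr::with_seed(seed + 7, runif(n) < frac_de)
  dir <- withr::with_seed(seed + 8, ifelse(runif(n) < prob_up, "up", "down"))
  truth <- list(
    transcripts = tibble::tibble(
      transcript_id = ids, true_class = "flat", is_lnc = FALSE,
      violated_rule = NA_character_
    ),
    de = tibble::tibble(
      feature_id = ids, is_de = is_de,
      direction = ifelse(is_de, dir, NA_character_),
      log2fc = ifelse(is_de, ifelse(dir == "up", lfc, -lfc), 0)
    ),
    trans_pairs = tibble::tibble(
      lnc_id = character(), gene_id = character(), ratio = numeric(),
      is_common = logical()
    )
  )
  list(annotation = ann, truth = truth, config = cfg)
}

empty_annotation <- function() {
  annotation_set(
    tibble::tibble(transcript_id = character(), gene_id = character(),
                   biotype = character()),
    tibble::tibble(transcript_id = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer())
  )
}

# ---- independent oracles ---------------------------------------------------

intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

# Exhaustive interval-pair classification oracle (antisense > intronic >
# lincRNA), scanning every exon pair and every intron of every transcript.
classify_oracle <- function(lnc, lnc_exons, genes_tx, genes_exons) {
  for (tx in unique(genes_exons$transcript_id)) {
    ge <- genes_exons[genes_exons$transcript_id == tx, ]
    if (ge$chrom[1] != lnc$chrom) next
    if (ge$strand[1] != lnc$strand) {
      for (i in seq_len(nrow(ge))) {
        for (j in seq_len(nrow(lnc_exons))) {
          if (intervals_overlap(ge$start[i], ge$end[i],
                                lnc_exons$start[j], lnc_exons$end[j])) {
            return("antisense")
          }
        }
      }
    }
  }
  for (tx in unique(genes_exons$transcript_id)) {
    ge <- genes_exons[genes_exons$transcript_id == tx, ]
    ge <- ge[order(ge$start), ]
    if (ge$chrom[1] != lnc$chrom || ge$strand[1] != lnc$strand) next
    if (nrow(ge) < 2) next
    for (i in seq_len(nrow(ge) - 1)) {
      int_start <- ge$end[i] + 1
      int_end <- ge$start[i + 1] - 1
      if (int_end >= int_start && lnc$start >= int_start &&
            lnc$end <= int_end) {
        return("intronic")
      }
    }
  }
  "lincRNA"
}

# Brute-force all-pairs cis scan with the stated gap formula.
cis_oracle <- function(lncs, genes, window = 100000) {
  out <- list()
  for (i in seq_len(nrow(lncs))) {
    for (j in seq_len(nrow(genes))) {
      if (lncs$chrom[i] != genes$chrom[j]) next
      if (intervals_overlap(lncs$start[i], lncs$end[i],
                            genes$start[j], genes$end[j])) {
        gap <- 0
      } else if (genes$start[j] > lncs$end[i]) {
        gap <- genes$start[j] - lncs$end[i] - 1
      } else {
        gap <- lncs$start[i] - genes$end[j] - 1
      }
      if (gap <= window) {
        out[[length(out) + 1]] <- data.frame(
          lnc_id = lncs$transcript_id[i], gene_id = genes$gene_id[j],
          distance = gap
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(lnc_id = character(), gene_id = character(),
                      distance = numeric()))
  }
  do.call(rbind, out)
}

# Direct summation-formula Pearson correlation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# Exhaustive hypergeometric upper-tail enumeration.
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Default-scale pipeline run (the study conditions), cached across tests.
default_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_all(
      file.path(tempdir(), paste0("stresslnc_default_", seed)),
      config = simulation_config(seed = seed)
    )
  }
  .fixture_cache[[key]]
}
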