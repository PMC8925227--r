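# End-to-end orchestration: simulate (or load) -> identify -> classify -> DE
# -> targets -> enrichment -> miRNA links -> network, with a run manifest
# recording artifacts, hashes and the thresholds used.

#' Pipeline thresholds
#'
#' The analysis thresholds, defaulting to the standard printed criteria:
#' transcript length >= 200 nt, FPKM floor 0.5, DE at padj <= 0.05 and
#' |log2FC| >= 1, cis window 100 kb, trans |r| >= 0.95, GO p < 0.05, pathway
#' q < 0.05, miRNA expectation cutoff 5.0, network term inclusion p < 0.05.
#'
#' @param ... Named overrides of any threshold.
#' @return Named list of thresholds.
#' @export
pipeline_thresholds <- function(...) {
  utils::modifyList(
    list(min_length = 200, min_fpkm = 0.5, max_padj = 0.05, min_abs_lfc = 1,
         cis_window = 100000, trans_rmin = 0.95, go_p = 0.05, kegg_q = 0.05,
         mirna_cutoff = 5.0, term_p = 0.05),
    list(...)
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

load_pipeline_inputs <- function(input_dir) {
  need <- function(f, stage) {
    p <- file.path(input_dir, f)
    if (!file.exists(p)) {
      abort(sprintf("stage '%s' failed: required input missing: %s", stage, p))
    }
    p
  }
  annotation <- read_gff(need("annotation.gff3", "identify"))
  known_path <- file.path(input_dir, "known_lnc.gff3")
  known_lnc <- if (file.exists(known_path)) read_gff(known_path) else
    annotation_set(
      tibble(transcript_id = character(), gene_id = character(),
             biotype = character()),
      tibble(transcript_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer())
    )
  counts <- read_expression(need("counts.tsv", "de"))
  sequences <- read_fasta(need("transcripts.fa", "identify"))
  mirna_path <- file.path(input_dir, "mirna.fa")
  mirnas <- if (file.exists(mirna_path)) read_fasta(mirna_path) else character(0)
  terms_path <- file.path(input_dir, "terms.tsv")
  term_map <- if (file.exists(terms_path)) {
    readr::read_tsv(terms_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  dems_path <- file.path(input_dir, "truth_dems.tsv")
  dems <- if (file.exists(dems_path)) {
    readr::read_tsv(dems_path, show_col_types = FALSE, progress = FALSE)
  } else if (length(mirnas) > 0) {
    tibble(mirna_id = names(mirnas), direction = "none")
  } else {
    tibble(mirna_id = character(), direction = character())
  }
  list(annotation = annotation, known_lnc = known_lnc, counts = counts,
       sequences = sequences, mirnas = mirnas, term_map = term_map,
       dems = dems)
}

#' Run the full analysis end to end
#'
#' Executes the complete chain on either a freshly simulated dataset
#' (`simulate = TRUE`, the default) or on user files in `input_dir`
#' (`annotation.gff3`, optional `known_lnc.gff3`, `counts.tsv`,
#' `transcripts.fa`, optional `mirna.fa`, `terms.tsv`, `truth_dems.tsv`).
#' All stage outputs are written under `out_dir`, together with a manifest
#' recording every artifact's MD5 hash, row count and the thresholds used.
#' Any stage failure aborts with the stage name. With a fixed configuration
#' (seed included) every data artifact is byte-identical across runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config [simulation_config()] used when simulating.
#' @param thresholds [pipeline_thresholds()].
#' @param simulate Generate the synthetic dataset (otherwise read
#'   `input_dir`).
#' @param input_dir Directory of user inputs when `simulate = FALSE`.
#' @return Invisibly, a list with every stage result and the `manifest`
#'   tibble.
#' @export
run_all <- function(out_dir, config = simulation_config(),
                    thresholds = pipeline_thresholds(), simulate = TRUE,
                    input_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list()
  note <- function(stage, files, n_rows = NA_integer_) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, artifact = basename(files),
      md5 = unname(tools::md5sum(files)), n_rows = n_rows,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    )
  }
  th <- thresholds

  # -- simulate / load -------------------------------------------------------
  if (simulate) {
    data_dir <- file.path(out_dir, "data")
    ds <- run_stage("simulate", simulate_dataset(config, out_dir = data_dir))
    note("simulate", list.files(data_dir, full.names = TRUE))
    annotation <- ds$annotation; known_lnc <- ds$known_lnc
    counts <- ds$counts; sequences <- ds$sequences; mirnas <- ds$mirnas
    term_map <- ds$term_map; dems <- ds$truth$dems
  } else {
    if (is.null(input_dir)) abort("input_dir is required when simulate = FALSE")
    inp <- load_pipeline_inputs(input_dir)
    ds <- NULL
    annotation <- inp$annotation; known_lnc <- inp$known_lnc
    counts <- inp$counts; sequences <- inp$sequences; mirnas <- inp$mirnas
    term_map <- inp$term_map; dems <- inp$dems
  }

  tx <- annotation$transcripts
  lengths <- tibble(feature_id = tx$transcript_id, length = tx$length)
  fpkm <- run_stage("fpkm", compute_fpkm(counts, lengths))

  # -- identify + classify ---------------------------------------------------
  trace <- run_stage("identify", filter_cascade(
    annotation, known_lnc, fpkm, sequences,
    thresholds = list(min_length = th$min_length, min_fpkm = th$min_fpkm)
  ))
  trace_path <- file.path(out_dir, "filter_trace.tsv")
  readr::write_tsv(trace, trace_path, progress = FALSE)
  note("identify", trace_path, nrow(trace))

  lnc_ids <- trace$transcript_id[trace$outcome != "rejected"]
  lnc_tx <- filter(tx, .data$transcript_id %in% lnc_ids)
  lnc_ann <- annotation_set(
    mutate(select(lnc_tx, "transcript_id", "gene_id"),
           biotype = ifelse(
             .data$transcript_id %in%
               trace$transcript_id[trace$outcome == "known_lncRNA"],
             "known_lncRNA", "novel_lncRNA")),
    filter(annotation$exons, .data$transcript_id %in% lnc_ids)
  )
  lnc_gff <- file.path(out_dir, "lncrna.gff3")
  write_gff(lnc_ann, lnc_gff)
  note("classify", lnc_gff, nrow(lnc_tx))

  # -- differential expression ----------------------------------------------
  de_all <- run_stage("de", exact_test_de(
    counts, max_padj = th$max_padj, min_abs_lfc = th$min_abs_lfc))
  de_path <- file.path(out_dir, "de_results.tsv")
  readr::write_tsv(tidy(de_all), de_path, progress = FALSE)
  note("de", de_path, nrow(de_all))

  coding_tx <- filter(tx, .data$biotype == "coding")
  de_gene <- tidy(de_all) %>%
    filter(.data$feature_id %in% coding_tx$transcript_id) %>%
    mutate(gene_id = coding_tx$gene_id[
      match(.data$feature_id, coding_tx$transcript_id)])
  de_lnc <- filter(tidy(de_all), .data$feature_id %in% lnc_ids)
  delnc_ids <- de_lnc$feature_id[de_lnc$de_flag != "ns"]

  # -- targets ---------------------------------------------------------------
  targets <- run_stage("targets", {
    delnc_tbl <- filter(lnc_tx, .data$transcript_id %in% delnc_ids)
    cis <- cis_targets(delnc_tbl, annotation, window = th$cis_window)
    trans_tx <- trans_targets(delnc_ids, coding_tx$transcript_id, fpkm,
                              r_min = th$trans_rmin)
    trans <- mutate(trans_tx, gene_id = coding_tx$gene_id[
      match(.data$gene_id, coding_tx$transcript_id)])
    de_gene_flags <- select(
      rename(de_gene, feature_id2 = "feature_id", feature_id = "gene_id"),
      "feature_id", "de_flag")
    common <- common_targets(cis, trans, de_gene_flags, mode = "any_lnc")
    list(cis = cis, trans = trans, common = common)
  })
  cis_path <- file.path(out_dir, "cis_targets.tsv")
  trans_path <- file.path(out_dir, "trans_targets.tsv")
  common_path <- file.path(out_dir, "common_targets.tsv")
  readr::write_tsv(targets$cis, cis_path, progress = FALSE)
  readr::write_tsv(targets$trans, trans_path, progress = FALSE)
  readr::write_tsv(targets$common, common_path, progress = FALSE)
  note("targets", c(cis_path, trans_path, common_path),
       nrow(targets$common))

  # -- enrichment ------------------------------------------------------------
  enrichment <- if (!is.null(term_map) && nrow(targets$common) > 0) {
    run_stage("enrich", {
      gene_fpkm <- fpkm %>%
        filter(.data$feature_id %in% coding_tx$transcript_id)
      expressed <- apply(counts_matrix(gene_fpkm), 1, max) >= th$min_fpkm
      background <- unique(coding_tx$gene_id[
        match(gene_fpkm$feature_id[expressed], coding_tx$transcript_id)])
      background <- union(background, targets$common$gene_id)
      hypergeom_enrich(targets$common$gene_id, background, term_map,
                       go_p = th$go_p, kegg_q = th$kegg_q)
    })
  } else {
    tibble(term_id = character(), name = character(), namespace = character(),
           k = integer(), n = integer(), K = integer(), N = integer(),
           pvalue = numeric(), qvalue = numeric(), significant = logical())
  }
  enr_path <- file.path(out_dir, "enrichment.tsv")
  readr::write_tsv(enrichment, enr_path, progress = FALSE)
  note("enrich", enr_path, nrow(enrichment))

  # -- miRNA links -----------------------------------------------------------
  mirna_links <- if (length(mirnas) > 0 && length(delnc_ids) > 0) {
    run_stage("mirna", dem_delnc_links(
      dems, tibble(lnc_id = delnc_ids), mirnas, sequences,
      cutoff = th$mirna_cutoff))
  } else {
    tibble(mirna_id = character(), lnc_id = character(),
           site_start = integer(), expectation = numeric(),
           alignment = character())
  }
  mir_path <- file.path(out_dir, "mirna_lnc_links.tsv")
  readr::write_tsv(mirna_links, mir_path, progress = FALSE)
  note("mirna", mir_path, nrow(mirna_links))

  # -- network ---------------------------------------------------------------
  net <- run_stage("network", {
    delnc_dir <- tibble(
      lnc_id = delnc_ids,
      direction = de_lnc$de_flag[match(delnc_ids, de_lnc$feature_id)]
    )
    build_network(delnc_dir, dems, targets$common, mirna_links, enrichment,
                  term_map %||% tibble(gene_id = character(),
                                       term_id = character()),
                  term_p = th$term_p)
  })
  sif_path <- file.path(out_dir, "network.sif")
  gml_path <- file.path(out_dir, "network.graphml")
  export_network(net, "sif", sif_path)
  export_network(net, "graphml", gml_path)
  export_network(net, "tsv", out_dir)
  note("network", c(sif_path, gml_path, file.path(out_dir, "nodes.tsv"),
                    file.path(out_dir, "edges.tsv")), nrow(net$edges))

  manifest <- bind_rows(manifest)
  manifest$params <- paste(
    sprintf("%s=%s", names(th), vapply(th, format, character(1))),
    collapse = ";")
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)

  invisible(list(
    dataset = ds, annotation = annotation, fpkm = fpkm, trace = trace,
    lnc_annotation = lnc_ann, de = de_all, de_lnc = de_lnc,
    de_gene = de_gene, targets = targets, enrichment = enrichment,
    mirna_links = mirna_links, network = net, manifest = manifest,
    thresholds = th, out_dir = out_dir
  ))
}
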