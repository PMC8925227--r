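# cis / trans target prediction and the common-target intersection.

test_that("cis targets honor the stated gap formula and 100 kb boundary", {
  lnc <- tibble::tibble(transcript_id = "l1", chrom = "chr1",
                        start = 200000, end = 201000)
  genes <- tibble::tibble(
    gene_id = c("near", "boundary", "beyond", "otherchrom"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(150000, 301001, 301002, 150000),
    end = c(160000, 310000, 310001, 160000)
  )
  hits <- cis_targets(lnc, genes)
  expect_setequal(hits$gene_id, c("near", "boundary"))
  expect_equal(hits$distance[hits$gene_id == "near"], 39999L)
  # boundary: 301001 - 201000 - 1 = 100000, included by <=
  expect_equal(hits$distance[hits$gene_id == "boundary"], 100000L)
  # overlap -> distance 0
  ov <- cis_targets(lnc, tibble::tibble(gene_id = "ov", chrom = "chr1",
                                        start = 200500, end = 200600))
  expect_equal(ov$distance, 0L)
})

test_that("cis targets equal the brute-force all-pairs scan", {
  set.seed(50)
  for (rep in 1:10) {
    n_l <- sample(5:15, 1); n_g <- sample(5:15, 1)
    lncs <- tibble::tibble(
      transcript_id = paste0("l", seq_len(n_l)),
      chrom = sample(paste0("chr", 1:2), n_l, TRUE),
      start = sample(1:900000, n_l)
    )
    lncs$end <- lncs$start + sample(200:2000, n_l, TRUE)
    genes <- tibble::tibble(
      gene_id = paste0("g", seq_len(n_g)),
      chrom = sample(paste0("chr", 1:2), n_g, TRUE),
      start = sample(1:900000, n_g)
    )
    genes$end <- genes$start + sample(1000:10000, n_g, TRUE)
    got <- cis_targets(lncs, genes)
    want <- cis_oracle(lncs, genes)
    got_keys <- sort(paste(got$lnc_id, got$gene_id, got$distance))
    want_keys <- sort(paste(want$lnc_id, want$gene_id, want$distance))
    expect_equal(got_keys, want_keys)
  }
})

test_that("cis gap is symmetric and windows are monotone", {
  set.seed(51)
  lncs <- tibble::tibble(transcript_id = "l1", chrom = "chr1",
                         start = 5000, end = 6000)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 50000, end = 60000)
  d1 <- cis_targets(lncs, genes)$distance
  # swap roles: same gap
  d2 <- cis_targets(
    tibble::tibble(transcript_id = "g1", chrom = "chr1", start = 50000,
                   end = 60000),
    tibble::tibble(gene_id = "l1", chrom = "chr1", start = 5000, end = 6000)
  )$distance
  expect_equal(d1, d2)
  small <- cis_targets(lncs, genes, window = 50000)
  large <- cis_targets(lncs, genes, window = 200000)
  expect_true(all(paste(small$lnc_id, small$gene_id) %in%
                    paste(large$lnc_id, large$gene_id)))
})

test_that("trans targets threshold the Pearson correlation of FPKM", {
  fpkm <- tibble::tibble(
    feature_id = c("l1", "l2", "g1", "g2", "g3"),
    PC1 = c(1, 1, 2, 1, 4), PC2 = c(2, 2, 4, 2, 4), PC3 = c(3, 3, 6, 4, 4),
    PH1 = c(4, 4, 8, 8, 4), PH2 = c(5, 5, 10, 20, 4), PH3 = c(6, 6, 12, 50, 4)
  )
  expect_warning(
    links <- trans_targets(c("l1", "l2"), c("g1", "g2", "g3"), fpkm),
    "zero-variance"
  )
  # g1 = 2 x l1 -> r = 1
  expect_true("g1" %in% links$gene_id[links$lnc_id == "l1"])
  expect_equal(links$r[links$lnc_id == "l1" & links$gene_id == "g1"], 1)
  # constant g3 skipped entirely
  expect_false("g3" %in% links$gene_id)
})

test_that("the (1,2,3) vs (1,2,4) correlation matches the direct formula", {
  fpkm <- tibble::tibble(feature_id = c("l1", "g1"),
                         S1 = c(1, 1), S2 = c(2, 2), S3 = c(3, 4))
  links <- trans_targets("l1", "g1", fpkm)
  want <- 3 / sqrt(2 * 14 / 3)
  expect_equal(links$r, want, tolerance = 1e-12)
  expect_equal(pearson_oracle(c(1, 2, 3), c(1, 2, 4)), want, tolerance = 1e-12)
  expect_gte(links$r, 0.95)
})

test_that("trans r matches the Pearson oracle on random vectors", {
  set.seed(52)
  for (i in 1:20) {
    x <- rexp(6, 1 / 30); y <- x * 2 + rnorm(6, sd = 0.01)
    fpkm <- dplyr::bind_cols(
      tibble::tibble(feature_id = c("l", "g")),
      tibble::as_tibble(setNames(as.data.frame(rbind(x, y)), paste0("S", 1:6)))
    )
    links <- trans_targets("l", "g", fpkm, r_min = 0)
    expect_equal(links$r, pearson_oracle(x, y), tolerance = 1e-12)
    expect_equal(links$r, pearson_oracle(y, x), tolerance = 1e-12)
  }
})

test_that("trans prediction needs at least three samples", {
  fpkm <- tibble::tibble(feature_id = c("l", "g"), S1 = c(1, 2), S2 = c(2, 4))
  expect_error(trans_targets("l", "g", fpkm), ">= 3 samples")
})

test_that("lowering r_min never removes a trans link", {
  ds <- small_dataset()
  lnc_ids <- ds$truth$transcripts$transcript_id[ds$truth$transcripts$is_lnc][1:5]
  gene_ids <- ds$annotation$transcripts$transcript_id[
    ds$annotation$transcripts$biotype == "coding"]
  strict <- trans_targets(lnc_ids, gene_ids, ds$fpkm, r_min = 0.95)
  loose <- trans_targets(lnc_ids, gene_ids, ds$fpkm, r_min = 0.80)
  expect_true(all(paste(strict$lnc_id, strict$gene_id) %in%
                    paste(loose$lnc_id, loose$gene_id)))
})

test_that("common targets intersect cis, trans and DE correctly", {
  cis <- tibble::tibble(lnc_id = c("lA", "lA"), gene_id = c("g1", "g2"),
                        mode = "cis", distance = c(100L, 200L))
  trans <- tibble::tibble(lnc_id = c("lB", "lA"), gene_id = c("g1", "g3"),
                          mode = "trans", r = c(0.99, 0.97))
  de <- tibble::tibble(feature_id = c("g1", "g2", "g3"),
                       de_flag = c("up", "ns", "up"))
  any_lnc <- common_targets(cis, trans, de, mode = "any_lnc")
  # g1: cis from lA, trans from lB, DE -> member under any_lnc only
  expect_equal(any_lnc$gene_id, "g1")
  expect_equal(any_lnc$de_flag, "up")
  same_lnc <- common_targets(cis, trans, de, mode = "same_lnc")
  expect_equal(nrow(same_lnc), 0L)
  # g2 has both links under no mode (trans missing) and is ns anyway
  expect_false("g2" %in% any_lnc$gene_id)
  expect_error(common_targets(cis, trans, de, mode = "both"), "arg")
})

test_that("same_lnc common targets are a subset of any_lnc", {
  set.seed(53)
  for (i in 1:20) {
    lncs <- paste0("l", 1:4); genes <- paste0("g", 1:6)
    cis <- tibble::tibble(
      lnc_id = sample(lncs, 8, TRUE), gene_id = sample(genes, 8, TRUE),
      mode = "cis", distance = sample(0:1000, 8))
    trans <- tibble::tibble(
      lnc_id = sample(lncs, 8, TRUE), gene_id = sample(genes, 8, TRUE),
      mode = "trans", r = runif(8, 0.95, 1))
    de <- tibble::tibble(feature_id = genes,
                         de_flag = sample(c("up", "down", "ns"), 6, TRUE))
    a <- common_targets(cis, trans, de, mode = "any_lnc")
    s <- common_targets(cis, trans, de, mode = "same_lnc")
    expect_true(all(s$gene_id %in% a$gene_id))
    expect_true(all(a$de_flag != "ns"))
  }
})

test_that("planted common targets are fully recovered without noise", {
  cfg <- small_config(seed = 6, deterministic_counts = TRUE)
  ds <- simulate_dataset(cfg)
  tx <- ds$annotation$transcripts
  lnc_ids <- ds$truth$transcripts$transcript_id[ds$truth$transcripts$is_lnc]
  lnc_tbl <- tx[tx$transcript_id %in% lnc_ids, ]
  cis <- cis_targets(lnc_tbl, ds$annotation)
  gene_tx <- tx[tx$biotype == "coding", ]
  suppressWarnings(
    trans <- trans_targets(lnc_ids, gene_tx$transcript_id, ds$fpkm)
  )
  trans$gene_id <- gene_tx$gene_id[match(trans$gene_id, gene_tx$transcript_id)]
  de <- tibble::tibble(
    feature_id = gene_tx$gene_id,
    de_flag = ifelse(
      ds$truth$de$is_de[match(gene_tx$transcript_id,
                              ds$truth$de$feature_id)], "up", "ns")
  )
  common <- common_targets(cis, trans, de)
  expect_true(all(ds$truth$common_targets$gene_id %in% common$gene_id))
})
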