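# FPKM computation and replicate-correlation QC.

#' Compute FPKM from fragment counts
#'
#' `fpkm = counts * 1e9 / (length * library_size)` per feature and sample.
#' Library sizes default to the column sums of the counts table.
#'
#' @param counts Tibble `feature_id` + one numeric column per sample.
#' @param feature_lengths Tibble `feature_id`, `length` (nt) covering all
#'   features.
#' @param library_sizes Optional named numeric vector (per sample); defaults
#'   to column sums.
#' @return Tibble of the same shape holding FPKM values, `samples` attribute
#'   carried over.
#' @examples
#' counts <- tibble::tibble(feature_id = "t1", S1 = 100)
#' compute_fpkm(counts, tibble::tibble(feature_id = "t1", length = 1000),
#'              library_sizes = c(S1 = 1e6))   # FPKM 100
#' @export
compute_fpkm <- function(counts, feature_lengths, library_sizes = NULL) {
  m <- counts_matrix(counts)
  len <- feature_lengths$length[match(rownames(m), feature_lengths$feature_id)]
  if (anyNA(len)) {
    abort(sprintf("feature(s) missing from feature_lengths: %s",
                  paste(head(rownames(m)[is.na(len)], 5), collapse = ", ")))
  }
  if (any(len <= 0)) abort("feature lengths must be > 0")
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  lib <- library_sizes[colnames(m)]
  if (anyNA(lib) || any(lib <= 0)) {
    abort("library sizes must be positive and cover every sample")
  }
  fpkm <- m * 1e9 / outer(len, lib)
  out <- matrix_to_tibble(fpkm)
  attr(out, "samples") <- attr(counts, "samples")
  out
}

#' Pairwise replicate correlation (R squared)
#'
#' For every replicate pair within a condition, the squared Pearson
#' correlation of `log2(FPKM + 1)` across all features — the standard
#' repeatability check for a sequenced replicate set.
#'
#' @param fpkm Tibble `feature_id` + sample columns.
#' @param samples Optional samples tibble (`sample_id`, `condition`,
#'   `replicate`); parsed from column names when absent.
#' @param condition Optional single condition to restrict to.
#' @return Tibble `condition`, `sample_a`, `sample_b`, `r_squared`, with the
#'   minimum R squared in the `min_r_squared` attribute. Zero-variance
#'   replicates yield `NA` with a warning.
#' @export
replicate_correlation <- function(fpkm, samples = NULL, condition = NULL) {
  samples <- resolve_samples(fpkm, samples)
  if (!is.null(condition)) {
    samples <- filter(samples, .data$condition %in% .env$condition)
  }
  m <- log2(counts_matrix(fpkm)[, samples$sample_id, drop = FALSE] + 1)
  out <- list()
  for (cond in unique(samples$condition)) {
    ids <- samples$sample_id[samples$condition == cond]
    if (length(ids) < 2) abort(sprintf("condition '%s' has < 2 replicates", cond))
    prs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(prs))) {
      a <- m[, prs[1, k]]; b <- m[, prs[2, k]]
      r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warn(sprintf("zero-variance replicate in pair %s/%s; R squared undefined",
                     prs[1, k], prs[2, k]))
        NA_real_
      } else {
        cor(a, b)^2
      }
      out[[length(out) + 1L]] <- tibble(
        condition = cond, sample_a = prs[1, k], sample_b = prs[2, k],
        r_squared = r2
      )
    }
  }
  res <- bind_rows(out)
  attr(res, "min_r_squared") <- suppressWarnings(min(res$r_squared, na.rm = TRUE))
  res
}
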