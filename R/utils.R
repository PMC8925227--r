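# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Nucleotide complement on A/C/G/T character vectors (T == U throughout).
complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")[x])
}

revcomp <- function(seq) {
  vapply(seq, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    paste(rev(complement_base(chars)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}

# 1-based inclusive gap between two intervals on the same chromosome:
# 0 on overlap, otherwise later.start - earlier.end - 1.
interval_gap <- function(start1, end1, start2, end2) {
  gap <- pmax(start1, start2) - pmin(end1, end2) - 1L
  pmax(gap, 0L)
}

check_strand <- function(strand, what = "strand") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf(
      "%s must be '+' or '-'; found: %s",
      what, paste(unique(strand[bad]), collapse = ", ")
    ))
  }
  invisible(strand)
}

# Parse sample names like PC1..PC3 / PH1..PH3 into condition/replicate labels.

#' Parse sample names into condition and replicate labels
#'
#' Sample names are expected to carry a short condition prefix followed by a
#' replicate index (the `PC1..PC3` / `PH1..PH3` pattern of a paired
#' control/heat design). The prefix-to-condition map is configurable.
#'
#' @param sample_ids Character vector of sample names.
#' @param condition_map Named character vector mapping name prefixes to
#'   condition labels. Default `c(PC = "control", PH = "heat")`.
#' @return A tibble with columns `sample_id`, `condition`, `replicate`.
#' @examples
#' parse_sample_info(c("PC1", "PC2", "PC3", "PH1", "PH2", "PH3"))
#' @export
parse_sample_info <- function(sample_ids,
                              condition_map = c(PC = "control", PH = "heat")) {
  m <- regmatches(sample_ids, regexec("^([A-Za-z_]+)([0-9]+)$", sample_ids))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf(
      "cannot parse sample name(s): %s (expected <prefix><replicate>)",
      paste(sample_ids[bad], collapse = ", ")
    ))
  }
  prefix <- vapply(m, `[`, character(1), 2L)
  replicate <- as.integer(vapply(m, `[`, character(1), 3L))
  condition <- unname(condition_map[prefix])
  condition[is.na(condition)] <- prefix[is.na(condition)]
  tibble(sample_id = sample_ids, condition = condition, replicate = replicate)
}

# Resolve a samples tibble: take the one supplied or parse from column names.
resolve_samples <- function(counts, samples = NULL,
                            condition_map = c(PC = "control", PH = "heat")) {
  ids <- setdiff(names(counts), "feature_id")
  if (is.null(samples)) samples <- attr(counts, "samples")
  if (is.null(samples)) samples <- parse_sample_info(ids, condition_map)
  samples <- as_tibble(samples)
  if (!all(ids %in% samples$sample_id)) {
    abort("`samples` does not cover all count columns")
  }
  samples[match(ids, samples$sample_id), ]
}

counts_matrix <- function(counts) {
  stopifnot("feature_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  rownames(m) <- counts$feature_id
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m) {
  out <- as_tibble(as.data.frame(m))
  dplyr::bind_cols(tibble(feature_id = rownames(m)), out)
}
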