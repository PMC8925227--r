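# Expression-table I/O: wide TSV with a feature-id column and one column per
# sample, plus sample-metadata parsing from the PC/PH-style names.

#' Read a counts (or FPKM) table
#'
#' Expects a TSV whose header row names the samples and whose first column
#' holds feature ids. Condition and replicate labels are parsed from the
#' sample names (default: `PC` = control, `PH` = heat) and attached as the
#' `samples` attribute.
#'
#' @param path TSV file path.
#' @param integer_counts Require non-negative integers (set to `FALSE` when
#'   reading FPKM tables).
#' @param condition_map Passed to [parse_sample_info()].
#' @return A tibble `feature_id` + one numeric column per sample, with a
#'   `samples` attribute tibble (`sample_id`, `condition`, `replicate`).
#' @export
read_expression <- function(path, integer_counts = TRUE,
                            condition_map = c(PC = "control", PH = "heat")) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort(sprintf("%s: need a feature column plus samples", path))
  names(raw)[1] <- "feature_id"
  if (anyDuplicated(raw$feature_id)) {
    abort(sprintf("%s: duplicated feature id(s): %s", path,
                  paste(unique(raw$feature_id[duplicated(raw$feature_id)]),
                        collapse = ", ")))
  }
  out <- raw["feature_id"]
  for (col in names(raw)[-1]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("%s: missing or non-numeric value at feature '%s', sample '%s'",
                    path, raw$feature_id[bad[1]], col))
    }
    if (any(v < 0)) {
      abort(sprintf("%s: negative value in sample '%s'", path, col))
    }
    if (integer_counts && any(v != round(v))) {
      abort(sprintf("%s: non-integer count in sample '%s'", path, col))
    }
    out[[col]] <- v
  }
  samples <- tryCatch(
    parse_sample_info(names(out)[-1], condition_map),
    error = function(e) NULL
  )
  attr(out, "samples") <- samples
  out
}

#' Write an expression table as TSV
#'
#' @param expr Tibble `feature_id` + sample columns.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  out <- expr
  num <- vapply(out, is.numeric, logical(1))
  is_int <- vapply(out[num], function(x) all(x == round(x)), logical(1))
  for (col in names(out[num])[is_int]) out[[col]] <- as.integer(out[[col]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
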