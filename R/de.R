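# Differential expression: a negative-binomial conditional exact test on
# replicate group sums, with median-of-moments common dispersion and
# Benjamini-Hochberg adjustment. Features are flagged with the standard
# padj <= 0.05 and |log2FC| >= 1 criteria.

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around the step-up procedure
#' (`padj_(i) = min_{j >= i}(m * p_(j) / j)`, clipped to 1, mapped back to
#' input order), delegated to [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("p-values must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Common NB dispersion: per-feature method-of-moments estimates pooled within
# conditions, then the median over features with mean normalized count > 5.
# The pooled variance is divided by median(chisq_df)/df: the per-feature s^2
# is chi-square distributed with few degrees of freedom, whose median sits
# well below its mean, so the raw feature-median would underestimate phi and
# make the exact test anticonservative.
estimate_common_dispersion <- function(y, group, mean_floor = 5) {
  groups <- unique(group)
  n <- ncol(y)
  ss <- 0
  for (g in groups) {
    yg <- y[, group == g, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
  }
  df <- n - length(groups)
  if (df <= 0) return(0)
  s2 <- (ss / df) / (stats::qchisq(0.5, df) / df)
  mu <- rowMeans(y)
  phi <- pmax(0, (s2 - mu) / mu^2)
  keep <- mu > mean_floor & is.finite(phi)
  if (!any(keep)) return(0)
  median(phi[keep])
}

# Conditional exact p-value for one feature: both group sums NB with means
# proportional to replicate counts and sum-dispersion phi/n; the p-value sums
# P(a)P(b) over all splits a + b = total whose probability does not exceed
# that of the observed split (with the customary 1 + 1e-7 tie guard).
exact_nb_pvalue <- function(s1, s2, n1, n2, phi, enum_cap = 1e5) {
  total <- s1 + s2
  if (total == 0) return(1)
  mu <- total / (n1 + n2)
  if (total > enum_cap) {
    # normal approximation to the conditional distribution
    w <- n1 / (n1 + n2)
    v <- total * w * (1 - w) * (1 + phi * mu)
    z <- (abs(s1 - total * w) - 0.5) / sqrt(v)
    return(min(1, 2 * pnorm(-max(z, 0))))
  }
  a <- 0:total
  b <- total - a
  if (phi > 0) {
    lp <- dnbinom(a, size = n1 / phi, mu = mu * n1, log = TRUE) +
      dnbinom(b, size = n2 / phi, mu = mu * n2, log = TRUE)
  } else {
    lp <- dpois(a, lambda = mu * n1, log = TRUE) +
      dpois(b, lambda = mu * n2, log = TRUE)
  }
  lmax <- max(lp)
  p_all <- exp(lp - lmax)
  obs <- p_all[s1 + 1]
  sum(p_all[p_all <= obs * (1 + 1e-7)]) / sum(p_all)
}

#' Negative-binomial exact test for two-condition differential expression
#'
#' The procedure: (1) counts are normalized by scaling each sample to the
#' geometric mean of the library sizes and rounding; (2) a common dispersion
#' is estimated by pooled method of moments (median over well-expressed
#' features); (3) each feature's replicate-group sums are compared with a
#' conditional exact test under the NB model (Poisson when the dispersion is
#' 0; a normal approximation replaces full enumeration above `enum_cap`
#' total counts); (4) `log2fc = log2((S_H/n_H + c0) / (S_C/n_C + c0))` with
#' prior count `c0`; (5) BH adjustment; (6) features with
#' `padj <= max_padj` and `|log2fc| >= min_abs_lfc` are flagged up or down.
#'
#' @param counts Tibble `feature_id` + integer sample columns.
#' @param samples Optional samples tibble; parsed from column names when
#'   absent. The first condition level (control, if present) is the
#'   reference; `log2fc` is second vs first.
#' @param library_sizes Optional named per-sample totals; default column sums.
#' @param dispersion Optional fixed common dispersion (estimated when `NULL`).
#' @param max_padj,min_abs_lfc Significance criteria (defaults 0.05 and 1).
#' @param prior_count Prior count `c0` in the fold-change (default 0.5).
#' @param enum_cap Largest total count enumerated exactly.
#' @return A tibble of class `lnc_de`: `feature_id`, `log2fc`, `pvalue`,
#'   `padj`, `de_flag` (`up`/`down`/`ns`), with the estimated dispersion and
#'   design in attributes. [tidy()] returns the table, [glance()] a one-row
#'   summary, [autoplot()] a volcano plot.
#' @export
exact_test_de <- function(counts, samples = NULL, library_sizes = NULL,
                          dispersion = NULL, max_padj = 0.05,
                          min_abs_lfc = 1, prior_count = 0.5,
                          enum_cap = 1e5) {
  samples <- resolve_samples(counts, samples)
  m <- counts_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  conds <- unique(samples$condition)
  if (length(conds) != 2) abort("exactly two conditions are required")
  if ("control" %in% conds) conds <- c("control", setdiff(conds, "control"))
  g1 <- samples$sample_id[samples$condition == conds[1]]
  g2 <- samples$sample_id[samples$condition == conds[2]]
  if (length(g1) < 1 || length(g2) < 1) abort("each condition needs >= 1 replicate")

  if (is.null(library_sizes)) library_sizes <- colSums(m)
  lib <- library_sizes[colnames(m)]
  if (anyNA(lib) || any(lib <= 0)) abort("library sizes must be positive")
  sf <- exp(mean(log(lib))) / lib
  y <- round(sweep(m, 2, sf, `*`))

  group <- ifelse(colnames(y) %in% g1, conds[1], conds[2])
  phi <- dispersion %||%
    estimate_common_dispersion(y, group)

  s1 <- unname(rowSums(y[, group == conds[1], drop = FALSE]))
  s2 <- unname(rowSums(y[, group == conds[2], drop = FALSE]))
  n1 <- length(g1); n2 <- length(g2)

  pvalue <- vapply(seq_along(s1), function(i) {
    exact_nb_pvalue(s1[i], s2[i], n1, n2, phi, enum_cap)
  }, numeric(1))
  log2fc <- ifelse(
    s1 + s2 == 0, 0,
    log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  )
  padj <- bh_adjust(pvalue)
  de_flag <- dplyr::case_when(
    padj <= max_padj & log2fc >= min_abs_lfc ~ "up",
    padj <= max_padj & log2fc <= -min_abs_lfc ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble(
    feature_id = rownames(m), log2fc = log2fc, pvalue = pvalue,
    padj = padj, de_flag = de_flag
  )
  structure(
    out,
    class = c("lnc_de", class(out)),
    dispersion = phi,
    conditions = conds,
    n_replicates = c(n1, n2),
    criteria = c(max_padj = max_padj, min_abs_lfc = min_abs_lfc)
  )
}

#' @exportS3Method generics::tidy
tidy.lnc_de <- function(x, ...) {
  as_tibble(unclass(x)[c("feature_id", "log2fc", "pvalue", "padj", "de_flag")])
}

#' @exportS3Method generics::glance
glance.lnc_de <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_de = sum(x$de_flag != "ns"),
    n_up = sum(x$de_flag == "up"),
    n_down = sum(x$de_flag == "down"),
    dispersion = attr(x, "dispersion"),
    max_padj = attr(x, "criteria")[["max_padj"]],
    min_abs_lfc = attr(x, "criteria")[["min_abs_lfc"]]
  )
}
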