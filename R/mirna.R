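# miRNA -> lncRNA targeting by ungapped antiparallel complementarity with a
# psRNATarget-style expectation (penalty) score: Watson-Crick pair 0, G:U
# wobble 0.5, mismatch 1.0; penalties inside the seed region are multiplied;
# hits are reported up to a cutoff, lower expectation = stronger site.

score_window <- function(m_chars, t_chars) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  # miRNA position i (from its 5' end) pairs with the window base L - i + 1
  paired <- rev(t_chars)
  state <- ifelse(
    paired == unname(wc[m_chars]), "match",
    ifelse((m_chars == "G" & paired == "T") |
             (m_chars == "T" & paired == "G"), "gu", "mismatch")
  )
  state
}

#' Score miRNA complementarity sites on a lncRNA
#'
#' Slides an ungapped antiparallel window of miRNA length along the lncRNA.
#' At each offset every miRNA position is paired with its opposite target
#' base: Watson-Crick 0, G:U wobble `gu_penalty`, otherwise
#' `mismatch_penalty`; penalties at miRNA positions within `seed_range` are
#' multiplied by `seed_multiplier`. The expectation is the penalty sum; all
#' offsets with expectation <= `cutoff` are reported, best first, ties by
#' leftmost site. T and U are equivalent.
#'
#' @param mirna Mature miRNA sequence (15-30 nt, ACGU/ACGT).
#' @param lnc_seq Target lncRNA sequence (at least as long as the miRNA).
#' @param gu_penalty,mismatch_penalty,seed_range,seed_multiplier,cutoff
#'   Scoring parameters (defaults 0.5, 1.0, positions 2-13, 2.0, 5.0).
#' @return Tibble `site_start` (1-based 5' end of the window on the lncRNA),
#'   `expectation`, `alignment` (per-position states `|` match, `o` wobble,
#'   `x` mismatch, written 5'->3' of the miRNA).
#' @export
score_sites <- function(mirna, lnc_seq, gu_penalty = 0.5,
                        mismatch_penalty = 1.0, seed_range = 2:13,
                        seed_multiplier = 2.0, cutoff = 5.0) {
  mirna <- toupper(chartr("Uu", "Tt", mirna))
  lnc_seq <- toupper(chartr("Uu", "Tt", lnc_seq))
  if (nchar(mirna) < 15) abort("miRNA shorter than 15 nt")
  if (grepl("[^ACGT]", mirna) || grepl("[^ACGT]", lnc_seq)) {
    abort("sequences must contain only A/C/G/T/U symbols")
  }
  L <- nchar(mirna)
  if (L > nchar(lnc_seq)) abort("miRNA longer than the target sequence")
  m_chars <- strsplit(mirna, "", fixed = TRUE)[[1]]
  t_chars <- strsplit(lnc_seq, "", fixed = TRUE)[[1]]
  weights <- rep(1, L)
  weights[intersect(seed_range, seq_len(L))] <- seed_multiplier
  n_off <- nchar(lnc_seq) - L + 1L
  n_t <- length(t_chars)
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  # accumulate the expectation over miRNA positions: position i pairs with
  # target base (offset + L - i), a contiguous slice across all offsets
  expectation <- numeric(n_off)
  for (i in seq_len(L)) {
    slice <- t_chars[(L - i + 1L):(n_t - i + 1L)]
    pen <- ifelse(
      slice == wc[[m_chars[i]]], 0,
      ifelse((m_chars[i] == "G" & slice == "T") |
               (m_chars[i] == "T" & slice == "G"),
             gu_penalty, mismatch_penalty)
    )
    expectation <- expectation + pen * weights[i]
  }
  hits <- which(expectation <= cutoff)
  if (length(hits) == 0) {
    return(tibble(site_start = integer(), expectation = numeric(),
                  alignment = character()))
  }
  alignment <- vapply(hits, function(s) {
    state <- score_window(m_chars, t_chars[s:(s + L - 1L)])
    paste(c("|", "o", "x")[match(state, c("match", "gu", "mismatch"))],
          collapse = "")
  }, character(1))
  res <- tibble(site_start = hits, expectation = expectation[hits],
                alignment = alignment)
  arrange(res, .data$expectation, .data$site_start)
}

#' Predict regulatory links between DE miRNAs and DE lncRNAs
#'
#' One link per (miRNA, lncRNA) pair with at least one site at expectation
#' <= `cutoff`; the link carries the best (lowest-expectation, leftmost)
#' site.
#'
#' @param dems Tibble `mirna_id` (optionally `direction`).
#' @param delncs Tibble `lnc_id` (optionally `direction`).
#' @param mirna_seqs,lnc_seqs Named character vectors covering all ids.
#' @param ... Scoring parameters passed to [score_sites()].
#' @return Tibble `mirna_id`, `lnc_id`, `site_start`, `expectation`,
#'   `alignment`.
#' @export
dem_delnc_links <- function(dems, delncs, mirna_seqs, lnc_seqs, ...) {
  dems <- as_tibble(dems); delncs <- as_tibble(delncs)
  missing <- c(setdiff(dems$mirna_id, names(mirna_seqs)),
               setdiff(delncs$lnc_id, names(lnc_seqs)))
  if (length(missing) > 0) {
    abort(sprintf("sequence(s) missing for: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  out <- list()
  for (m in dems$mirna_id) {
    for (l in delncs$lnc_id) {
      if (nchar(mirna_seqs[[m]]) > nchar(lnc_seqs[[l]])) next
      hits <- score_sites(mirna_seqs[[m]], lnc_seqs[[l]], ...)
      if (nrow(hits) > 0) {
        out[[length(out) + 1L]] <- tibble(
          mirna_id = m, lnc_id = l,
          site_start = hits$site_start[1],
          expectation = hits$expectation[1],
          alignment = hits$alignment[1]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(mirna_id = character(), lnc_id = character(),
                  site_start = integer(), expectation = numeric(),
                  alignment = character()))
  }
  bind_rows(out) %>% arrange(.data$mirna_id, .data$lnc_id)
}
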