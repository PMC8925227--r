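---
title: "Methods: lncRNA discovery and heat-stress regulatory networks with stresslnc"
author: "stresslnc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery and heat-stress regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresslnc)
```

# Scope and model

`stresslnc` re-implements, as composable tested functions, a bulk RNA-seq
workflow for identifying heat-responsive long non-coding RNAs (lncRNAs) and
their regulatory context in a two-condition design with three biological
replicates per condition (control samples `PC1..PC3`, heat-stressed samples
`PH1..PH3`). The chain is:

1. **Discovery** — a filter cascade over assembled candidate transcripts;
2. **Classification** — strand-aware positional classes
   (lincRNA / intronic / antisense);
3. **Expression** — FPKM, replicate correlation, and a negative-binomial
   exact test for differential expression;
4. **Targeting** — cis targets by genomic window, trans targets by
   expression correlation, and their intersection with differential
   expression ("common targets");
5. **Enrichment** — hypergeometric over-representation of GO terms and
   pathways among the common targets;
6. **miRNA targeting** — complementarity expectation scoring between
   differentially expressed miRNAs and lncRNAs;
7. **Network** — assembly and export of the
   miRNA → lncRNA → gene → term regulatory network.

Because raw sequencing data are deliberately out of scope, a synthetic-data
generator with planted ground truth stands in for the upstream read
processing (QC, alignment, assembly). Every downstream stage is validated
against that planted truth.

# The filter cascade

Candidates are screened by ordered rules; a rejected transcript records the
*first* rule it failed, which makes every decision auditable:

1. `min_length` — keep transcripts ≥ 200 nt (the conventional lncRNA
   threshold). Single-exon transcripts are retained by default
   (`keep_single_exon = TRUE`); a switch is provided because several
   published pipelines drop them.
2. `coding_overlap` — reject candidates whose exons overlap a coding gene's
   exons *on the same strand*. Same-strand is essential: an antisense lncRNA
   by definition overlaps a gene on the opposite strand, so opposite-strand
   overlap must never reject. Candidates overlapping the known-lncRNA
   annotation track are rescued as `known_lncRNA` and skip the
   coding-potential step.
3. `min_fpkm` — require a maximum FPKM over all samples of ≥ 0.5
   (reliably expressed).
4. `coding_potential` — the remaining candidates must be called noncoding
   by the three-predictor consensus; survivors are `novel_lncRNA`.

Rule order follows the conventional flow (length → overlap → expression →
coding potential); evaluating coding potential last restricts the most
expensive predictors to the smallest candidate set and matches the usual
three-tool intersection applied to the final candidate pool.

## The coding-potential consensus

The published pipelines this package models use three external programs
(an ORF/feature-based classifier, an alignment-free composition index, and a
protein-domain scan). Those binaries cannot be bundled, so `stresslnc`
implements three *in-package stand-ins* that exercise the same decision
structure:

- **ORF length** — coding if the longest forward-frame ORF (`ATG` … stop)
  is ≥ 100 codons. `N` breaks an ORF.
- **Hexamer log-likelihood** — coding if the mean
  `log2(f_coding(h) / f_noncoding(h))` over all overlapping hexamers is
  strictly positive. Tables come from `build_hexamer_tables()`; by default
  the pipeline trains the coding table on the annotation's coding transcript
  sequences and uses a uniform background, making the score a signed
  KL-style contrast against coding composition. Hexamers containing `N` are
  skipped.
- **Domain scan** — coding if any motif from a protein-motif list is a
  substring of any of the three forward-frame translations.

The consensus is `noncoding` only when *all three* predictors agree —
the intersection logic of a three-set Venn diagram. This is an
interpretation choice: the alternative reading ("any predictor noncoding")
would let a single permissive predictor overrule the other two, which
contradicts the purpose of a consensus filter. Consequently the consensus is
monotone: flipping any single predictor from noncoding to coding can only
move the consensus toward coding (a property-tested invariant).

These stand-ins are *not* re-implementations of the external tools and make
no attempt to reproduce their scores; they are deliberately simple
predictors with the same interface and failure modes, sufficient to test the
cascade logic exactly.

# Positional classification

With precedence `antisense > intronic > lincRNA`:

- **antisense** — any lncRNA exon overlaps any coding exon on the opposite
  strand (1 bp suffices);
- **intronic** — the lncRNA span is fully contained within a *single*
  intron of a *same-strand* coding transcript. Partial intron overlap falls
  through to lincRNA (conservative convention);
- **lincRNA** — everything else. In particular, opposite-strand containment
  in an intron with no exon overlap is lincRNA, not antisense, because
  antisense is defined at the exon level. This is a documented convention,
  not an empirical claim.

The implementation uses `GenomicRanges` overlap machinery; the test suite
checks 100% agreement with an exhaustive interval-pair oracle on 1,000
random configurations.

# Differential expression

The DE stage is a self-contained negative-binomial conditional exact test
(pipelines of this kind typically run edgeR; re-implementing its
quantile-adjusted machinery is out of scope, so a defensible exact test
with the same significance criteria is provided and the stage is pluggable):

1. **Normalization** — each sample is scaled to the geometric mean of the
   library sizes (column sums by default) and rounded to integers. No
   trimmed-mean (TMM) step is applied.
2. **Common dispersion** — per-feature method-of-moments estimates
   `max(0, (s² − μ̄)/μ̄²)` with the variance pooled within conditions, then
   the median over features with mean normalized count > 5. The pooled
   variance is first divided by `qchisq(0.5, df)/df` (≈ 0.84 at 4 degrees
   of freedom): a per-feature variance estimate on so few replicates is
   χ²-distributed with a median well below its mean, so the raw feature
   median would underestimate φ by ~20% and make the exact test
   anticonservative; the median-unbiased correction restores type-I
   calibration (verified by simulation in the test suite). A single common φ is the
   most that 3-vs-3 replication supports honestly.
3. **Conditional exact test** — under the null both replicate-group sums
   are negative binomial with means proportional to replicate counts and
   sum-dispersion φ/n; conditioning on the total, the two-sided p-value sums
   the probabilities of all splits no more probable than the observed one
   (with the customary `1 + 1e-7` tie guard, so that with φ = 0 and equal
   library sizes the test reduces *exactly* to the two-sided exact binomial
   test). Totals above 100,000 use a normal approximation to the
   conditional distribution with continuity correction — at such totals the
   discrete enumeration and the approximation agree to far below the
   decision threshold.
4. **Fold change** — `log2((S_H/n_H + 0.5)/(S_C/n_C + 0.5))`; the 0.5 prior
   count avoids infinities when one group is all zeros.
5. **Criteria** — Benjamini–Hochberg adjustment, then `padj ≤ 0.05` and
   `|log2FC| ≥ 1` flag features up or down.

Calibration is verified by simulation: the empirical type-I error at nominal
0.05 on a 2,000-feature null panel (φ = 0.1) falls inside the exact binomial
99% interval, and planted log2FC = 3 effects at baseline mean 100 are
recovered with ≥ 90% power and correct signs.

# Target prediction

- **cis** — a coding gene is a cis target of a lncRNA if both are on the
  same chromosome and the 1-based inclusive gap
  (`later.start − earlier.end − 1`, 0 on overlap) is ≤ 100 kb. The window is
  measured from the lncRNA *span* (not its TSS), strand is ignored, and the
  boundary gap of exactly 100,000 is included.
- **trans** — Pearson correlation of raw FPKM vectors across all six
  samples, link emitted when |r| ≥ 0.95 (both signs). Raw FPKM (not
  log-transformed) is the default because the correlation is defined on the
  expression profiles as given; a `log2_transform` switch exists. **No
  p-value accompanies r**: with n = 6 samples, |r| ≥ 0.95 corresponds to a
  nominal p around 0.004 per pair, and tens of thousands of pairs are
  tested, so trans links are screening hypotheses, not inferences. The
  documentation and this vignette state this prominently.
- **common targets** — genes with ≥ 1 cis link and ≥ 1 trans link from DE
  lncRNAs that are themselves differentially expressed. The default
  `any_lnc` mode intersects at the gene level (the cis and trans links may
  come from different lncRNAs); `same_lnc` requires one lncRNA to support
  both. Gene-level intersection is the default because it reflects how
  common-target sets are reported in this literature.

# Enrichment

Plain exact hypergeometric upper-tail over-representation per term, with BH
adjustment *within namespace* (BP/CC/MF/pathway), so adding pathway
annotations never changes GO q-values. The significance convention is
asymmetric, mirroring how such results are reported: GO terms at raw
`p < 0.05`, pathways at adjusted `q < 0.05`; both thresholds are flags. A
length-bias (Wallenius) correction is deliberately **not** implemented: the
probability-weighting function it requires is not identified by anything in
scope here, and the planted-truth tests need the exact null. The background
defaults to all genes above the FPKM floor.

# miRNA–lncRNA expectation scoring

An ungapped antiparallel window of miRNA length slides along the lncRNA;
each miRNA position pairs with its opposite target base: Watson–Crick 0,
G:U wobble 0.5, mismatch 1.0, with penalties at miRNA positions 2–13 (the
seed-proximal region) doubled; the expectation is the penalty sum and sites
with expectation ≤ 5.0 are reported, best first. T ≡ U everywhere. This is a
simplified rendering of expectation scoring in plant small-RNA target
predictors: gaps/bulges and target-accessibility (UPE) scoring are
excluded — both would require alignment machinery that adds nothing to the
planted-truth tests — and every parameter is a flag.

# The regulatory network

Nodes are DE miRNAs, DE lncRNAs, common-target genes and significantly
enriched terms (`p < 0.05` raw, for both GO and pathway nodes — the
pathway q-rule applies to the enrichment report, not network inclusion);
isolated nodes are dropped. Edges are directed regulator → regulated
(miRNA → lncRNA → gene → term) — the direction is a convention of this
package, chosen for unambiguous downstream parsing. Up-regulation is stored
as node color `red`, down-regulation `green`, targets `black`, GO terms
`blue` and pathways `green`, so any viewer reproduces the conventional
encoding without further styling; no plotting is performed. Exports are SIF,
GraphML (via igraph) and a nodes/edges TSV pair, all byte-deterministic.

# The synthetic-data generator

`simulation_config()` defines the study; `simulate_dataset()` realizes it.
What it emulates, and the defaults (chosen once as a realistic desk-scale
rendering of a heat-stress experiment, with the reasoning given here):

- **Genome and genes** — 5 chromosomes × 4 Mb with 100 coding genes on an
  even grid (inter-gene spacing ≈ 400 kb). The spacing is deliberately
  larger than twice the 100 kb cis window so that cis targeting is
  *selective*: only lncRNAs that happen to fall near a gene produce cis
  links. Genes have 3–7 exons, introns of 0.6–1.8 kb, and real ORFs
  (start codon, 150–220 codons, stop) written into the genome sequence with
  GC-biased codon usage, so the hexamer predictor has a genuine signal.
  Protein motifs are encoded into every ORF for the domain predictor.
- **Planted lncRNAs** — 230 lincRNAs, 6 intronic, 5 antisense
  (≈ 95.4 / 2.5 / 2.1%, the lincRNA-dominated mix typical of plant lncRNA
  surveys, at a scale that still gives > 200 planted lncRNAs). Lengths are
  mostly 210–480 nt with a small long tail, and 92% are single-exon,
  matching the structural profile such surveys report. 10% of lincRNAs are
  also emitted as the known-lncRNA track.
- **Decoys** — 200, in four families of 50, each violating exactly one
  cascade rule: shorter than 200 nt; same-strand overlap with a coding
  exon; zero expression (fails the FPKM floor); and an intergenic
  transcript carrying a planted 120–140 codon ORF (fails coding potential).
- **Counts** — negative binomial with common dispersion φ = 0.1 (a typical
  biological-replicate value), baseline means log-uniform on [10, 300],
  per-sample depth factors within ±20%. 20% of expressed features carry a
  planted effect of |log2FC| = 3 (heat-shock responses are large),
  direction fair-coin. Down-regulation is realized by boosting the
  control-side mean (heat = control × 2^log2FC either way): with symmetric
  effects realized only on the heat side, the ×8 inductions add far more
  library mass than the ÷8 repressions remove, and the resulting
  condition-level library tilt (≈ 1.6×) would push null features past the
  |log2FC| ≥ 1 criterion after total-count normalization. The
  control-side-boost construction keeps expected library mass balanced, so
  the planted truth stays self-consistent under the package's own
  normalization. Narrowing the baseline range to [10, 300] serves the same
  end: no single feature dominates library mass.
- **Planted relations** — 10 common-target genes (the same lincRNA is
  cis-proximal, its expression profile shared with the gene at ratio 2, and
  both planted DE), plus 20 additional pure trans pairs and 30 recorded cis
  pairs. In noise-free mode (`deterministic_counts = TRUE`) counts equal
  expectations and planted trans pairs are *exactly* proportional (r = 1).
- **Annotation terms** — every gene draws 1–3 background terms from a pool
  of 30 GO terms and 10 pathways; one planted GO term and one planted
  pathway are assigned to 80% of the planted common targets plus two
  background genes, making the planted term over-represented among detected
  common targets by construction.
- **miRNAs** — 10 mature 21-nt miRNAs with 18 planted sites on DE lncRNAs,
  cycling exact complement (expectation 0), one non-seed G:U wobble (0.5)
  and one seed mismatch (2.0).

Everything is a pure function of the configuration, seed included; two runs
with the same configuration are byte-identical.

## What the generator does *not* emulate

No read-level simulation (no FASTQ, no sequencing-error or positional-bias
model), no isoform complexity beyond multi-exon structure, no GC or
length-dependent quantification bias, no batch effects, and sequence content
outside ORFs/motifs/sites is i.i.d. uniform. Passing tests therefore
demonstrate the *logic* of every stage against planted truth — they do not
certify performance on real libraries, where assembly artifacts, tagwise
dispersion and annotation noise dominate. The miRNA-site planting edits
transcript sequences after genome extraction, so `transcripts.fa` (not
`genome.fa`) is authoritative for sequence-level operations.

# Numerical and design choices

- Coordinates are 1-based inclusive everywhere (`length = end − start + 1`);
  GTF or GFF3 is auto-detected on input and GFF3 is the only output dialect.
  Exons with strand `.` are rejected because classification is strand-aware.
- Exact-test ties use the `1 + 1e-7` relative guard standard for exact
  binomial tests; BH is delegated to `stats::p.adjust` behind a validating
  wrapper; hypergeometric tails are `stats::phyper` (the test suite carries
  an independent enumeration oracle for all backgrounds up to N = 50).
- Zero-variance features are skipped with a warning in correlation-based
  steps (undefined r), never silently scored.
- A library with zero total counts has no FPKM scale; the generator reports
  zeros for that degenerate case.
- Problem sizes used by the test-suite calibration runs: 2,000-feature
  panels for type-I and power, 1,000 random configurations for each
  interval oracle, the full default study (541 candidates over a 20 Mb
  genome) for end-to-end checks. These sizes give the binomial confidence
  intervals quoted above while keeping the default test run quick.

# Known limitations

- Total-count normalization is sensitive to composition bias: a strongly
  asymmetric transcriptome shift between conditions (common under severe
  stress) biases null fold changes; robust normalizations (TMM,
  median-of-ratios) are intentionally out of scope.
- With 3 replicates, the common-dispersion estimator is noisy and slightly
  conservative or anticonservative depending on the mean range; calibration
  is verified at the defaults, not across all regimes.
- Trans targeting with six samples is a screen (see above), and the miRNA
  scorer's ungapped model cannot represent bulged duplexes.
- The enrichment stage takes annotations as given (no GO-DAG propagation,
  no live database access).
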