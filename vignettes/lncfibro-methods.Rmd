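---
title: "Methods: lncRNA discovery and prioritization in renal fibrosis"
author: "lncfibro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery and prioritization in renal fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncfibro)
```

## The scientific problem

Renal fibrosis is the common end stage of most chronic kidney diseases.
In the rat unilateral ureteral obstruction (UUO) model, obstruction of
one ureter drives TGF-β/Smad-mediated fibrogenesis in the obstructed
kidney within about two weeks, and comparing obstructed against
sham-operated animals is the standard way to find fibrosis-associated
transcripts. Long non-coding RNAs (lncRNAs) — transcripts longer than
200 nt without protein-coding capacity — are both candidate effectors
(several act in cis on neighboring genes, and some are direct Smad3
transcriptional targets) and candidate biomarkers, because fragments of
kidney-derived RNA are detectable in urine.

`lncfibro` implements the complete desk-side analysis for this design:
it identifies lncRNA candidates from an annotated transcriptome, calls
differential expression between UUO and Sham in two compartments (renal
tissue and urine), annotates dysregulated lncRNAs with nearby
protein-coding genes, prioritizes TGF-β pathway candidates by counting
Smad-binding elements in their promoters, intersects tissue and urine
results into concordant biomarker candidates, and quantifies qPCR
validation data by the Livak 2^−ΔΔCt method.

## Pipeline stages and their assumptions

### Consensus lncRNA filtering

A transcript is kept as a lncRNA candidate only if

1. its spliced (exonic) length exceeds 200 nt — read strictly, so a
   200-nt transcript is removed and a 201-nt one kept; and
2. **no** coding-potential predictor calls it coding (union removal:
   a transcript flagged by *any* predictor is discarded).

The union rule is deliberately conservative — it minimizes false
lncRNAs at the cost of discarding borderline transcripts — and is
monotone: adding a predictor can only shrink the candidate set (a
property the test suite checks on randomized call tables). External
coding-potential tools are not bundled; the module defines a predictor
interface (`transcript_id`, `score`, `is_coding`) with two built-ins:

* **ORF length** (`longest_orf_length`): longest ATG→stop open reading
  frame over the three forward frames (transcripts are stranded),
  length including the stop codon; coding if > 300 nt. 300 nt (100
  codons) is the conventional boundary below which random ORFs are
  common in non-coding sequence.
* **Hexamer bias** (`hexamer_bias_score`): mean log-likelihood ratio of
  in-frame hexamer frequencies under user-supplied coding vs non-coding
  tables; coding if > 0. No default tables ship with the package — they
  are organism-specific — so the default pipeline uses the ORF
  predictor alone.

### RPKM quantification and differential expression

Expression is quantified as RPKM, reads per kilobase of exon per
million reads:

$$\mathrm{rpkm}_{ij} = \frac{c_{ij} \cdot 10^9}{N_j \cdot L_i}$$

with count $c_{ij}$, library size $N_j$ (the column sum of the analyzed
matrix, stated in the output header rather than an external
mapped-read total) and exonic length $L_i$. The identity
$\sum_i \mathrm{rpkm}_{ij} L_i = 10^9$ holds for every sample and is
asserted in the tests to 10^−9 relative error.

Within one compartment, UUO is compared against Sham per transcript
with a two-sided Welch t-test on log2(RPKM + 0.25). With two groups a
one-way ANOVA and the t-test coincide; Welch's unequal-variance form is
the robust default. The 0.25 RPKM pseudocount keeps zero-expression
transcripts finite on the log scale and in the fold change
$\log_2((\bar{x}_{UUO}+0.25)/(\bar{x}_{Sham}+0.25))$. A transcript is
called significant iff |log2FC| ≥ 1 (inclusive) **and** p < 0.05
(strict), on raw p-values; Benjamini–Hochberg adjustment is available
as an option (`bh_correction`) but off by default, matching common
practice in small-n discovery screens. Degenerate inputs never produce
NaN: two constant equal groups give p = 1, constant unequal groups
p = 0.

With n = 3 per group the test is underpowered for subtle changes and
its type-I behaviour relies on approximate log-normality of NB counts;
the suite checks empirically that the full caller flags ≤ 7.5% of
transcripts under a global null (the fold-change gate makes the
realized rate far smaller).

### Cis-neighbor search

Many lncRNAs regulate transcription of nearby genes, so every
protein-coding gene whose span lies within ±100 kb of a dysregulated
lncRNA gene (both up- and down-regulated) is reported. Distance is the
gene-boundary gap between spans (0 for overlapping spans), not
TSS-to-TSS, and the 100 kb boundary is inclusive. Candidate pairs come
from an interval overlap query (IRanges) and an O(n·m) brute-force
comparator is kept in the test suite as the oracle; the two agree
exactly on randomized instances. Upstream/downstream labels are
assigned from the lncRNA's strand; unstranded lncRNAs fall back to "+"
with a warning.

### Promoter extraction and Smad3 motif scanning

Activated Smad3 binds the Smad-binding element, canonical sequence
CAGACA. For each up-regulated lncRNA gene the putative promoter is the
5 kb immediately upstream of the TSS: `[tss − 5000, tss)` on the plus
strand and `[tss + 1, tss + 5001)` reverse-complemented on the minus
strand, clipped (and flagged) at contig edges. For multi-isoform genes
the TSS is the most 5′ transcript start across isoforms — one promoter
per gene keeps the motif count well defined. Promoters are **not**
truncated when they overlap a neighboring gene; the window is defined
purely by distance.

The scan counts all exact, possibly overlapping occurrences
(CAGACAGACA counts 2) on the promoter's sense strand; `both_strands`
adds the reverse complement TGTCTG with antisense labels. The default
is sense-only because the single literal motif is the stated consensus;
Smad elements are double-stranded in reality, which is why the option
exists. "Conserved" motifs are interpreted as exact matches to the
canonical consensus — cross-species conservation scoring is out of
scope. The ambiguity code N never matches. A gene is prioritized as a
TGF-β pathway candidate iff its count is **strictly greater than 4**
(k = 5 passes, k = 4 fails). Scanning is restricted to up-regulated
lncRNAs by default (TGF-β *induces* its Smad3 targets);
`scan_all_dysregulated` widens it.

### Concordance and qPCR quantification

A urinary biomarker candidate must be significant in **both** tissue
and urine under identical cutoffs with the same direction of change;
near-misses are not rescued. qPCR validation uses the Livak method:
ΔCt = Ct_target − Ct_reference within a sample, ΔΔCt subtracts the
arithmetic mean ΔCt of the calibrator (Sham) group, fold = 2^−ΔΔCt.
By construction the calibrator group's geometric-mean fold is exactly
1. Group summaries report mean ± SD of per-sample folds (the bar-plot
convention) alongside the geometric mean, and significance comes from
a Welch t-test on ΔCt — the appropriate scale, since folds are
log-normal. Tissue assays normalize to a cellular reference gene
(GAPDH or 18S; the choice is a required input, never inferred), urine
assays to the exogenous cel-miR-39 spike-in, because no cellular
reference is reliable in a body fluid.

## The synthetic data generator

Every stage is testable without external data through a deterministic
generator that emulates the study design: 2 conditions × 2
compartments × 3 replicates. Its defaults are the package's reference
conditions:

| parameter | default | meaning |
|---|---|---|
| `n_lnc_genes` / `n_coding_genes` | 960 / 40 | 1000 transcripts total |
| `n_de_lnc_up` / `n_de_lnc_down` | 20 / 20 | tissue DE lncRNAs |
| `true_log2fc` | 2 | planted effect size |
| `baseline_mean` | 200 | NB mean in Sham |
| `nb_dispersion` | 0.05 | NB dispersion (var = μ + 0.05 μ²) |
| `replicates_per_group` | 3 | per condition and compartment |
| motif design | 6 × k∈5..10, 14 × k≤4 | planted CAGACA copies in up-lncRNA promoters |
| `neighbor_layout` | 25 pairs, gaps up to 100 kb | planted cis pairs (includes 99,999 and exactly 100,000) |
| urine design | 5 up + 2 down shared, 1 discordant, 10 urine-only | makes concordance non-trivial |

Counts are negative binomial rather than Poisson because overdispersion
between biological replicates is the rule in RNA-seq. Urine counts are
an independent draw with their own DE subset — the compartments are
separate libraries, not transformations of each other. One global seed
drives a named sub-stream per artifact (genome, tissue counts, urine
counts, qPCR) so any artifact can be regenerated independently;
identical config and seed give byte-identical files.

Three constructions make planted truth *exactly* recoverable:

* **Motif planting**: background CAGACA occurrences inside a designated
  promoter are disrupted (single-base substitutions) before the
  configured number of copies is planted at spaced positions, and the
  result is re-scanned until the sense-strand count is exact. Without
  disruption, a 5 kb random promoter would carry ~1.2 background
  copies and planted counts would be untestable.
* **Exact gaps**: each planted cis pair is laid out with its coding
  partner at an exact span gap from the lncRNA; all other gene blocks
  are separated by more than the 100 kb window so no unintended pair
  exists. The non-signal background lncRNAs are packed densely in
  their own region, far from every coding gene.
* **Composition control**: with only the signal genes present, 40
  planted changes at |log2FC| = 2 would shift column-sum library sizes
  enough to bias apparent fold changes (a real phenomenon — column-sum
  normalization is not robust to asymmetric DE). The default of 1000
  transcripts keeps the DE fraction small, as in real transcriptomes,
  so planted effects are recovered near their nominal size.

Coding transcripts carry a planted 456-nt ORF; lncRNA transcripts are
generated without any ATG so their ORF length is exactly 0. The first
lncRNA gene sits 3 kb from the contig start to exercise promoter
clipping.

What the generator does **not** model — and therefore what passing
tests do not demonstrate about real data: isoform structure beyond one
transcript per gene, GC/length biases, fragment-level degradation of
urinary RNA (urine libraries are treated as ordinary count libraries),
batch effects, and realistic hexamer composition. Parameter-recovery
results on this generator show the pipeline's logic is correct, not
that the biological discovery procedure has any particular sensitivity
on real libraries.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GTF I/O does
  the ±1 conversion at the boundary, so interval arithmetic is uniform.
* Counts are supported at transcript level; gene-level aggregation
  happens only where loci matter (cis search, promoters), via the gene
  span and the gene-level TSS.
* Ties and boundaries: |log2FC| cutoff inclusive, p cutoff strict,
  cis window inclusive, motif threshold strict, length threshold
  strict. Each boundary has a dedicated test.
* `too_short` takes precedence over `coding_by:` in removal reasons
  when both apply.
* The run report (`report.json`) deliberately contains no wall-clock
  timestamps so that re-running a configuration yields byte-identical
  artifacts; reproducibility is treated as more valuable than run
  metadata, which belongs in logs.
* Problem sizes in the shipped test suite are chosen to keep the whole
  suite under about a minute on one core: 1000-case motif-scan
  equivalence (sequences ≤ 2 kb), 100 randomized cis instances of up
  to 200 genes, the full 1000-transcript reference dataset for
  end-to-end truth recovery, a 2000-transcript null for type-I
  calibration, and 200 seeds for noisy qPCR recovery.

## Known limitations

* The DE caller is the classical RPKM + Welch-t recipe, not a count
  GLM; with n = 3 it has limited power near the fold-change cutoff and
  no shrinkage. This is intentional — the package reproduces that
  analysis recipe — but for new studies a negative-binomial GLM
  (DESeq2/edgeR) is the better tool, and the honest consequence is
  visible in our own acceptance runs: an occasional planted gene lands
  at p ≈ 0.05 and is missed.
* Raw p-values by default mean the discovery lists are screening
  output, not confirmatory statistics.
* The motif scanner is a literal-word counter, not a PWM; it cannot
  rank partial matches, and promoter choice (5 kb, gene-level TSS) is
  a convention, exposed as parameters rather than defended as optimal.
* qPCR quantification assumes perfect (2-fold per cycle) amplification
  efficiency; no Pfaffl correction or standard curves.
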