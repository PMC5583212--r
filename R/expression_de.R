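#' @title RPKM quantification and differential expression
#'
#' @description Expression is quantified as RPKM (reads per kilobase of
#' exon per million reads): \code{rpkm = c * 1e9 / (N * L)} with count
#' \code{c}, library size \code{N} (column sum of the analyzed matrix) and
#' exonic length \code{L}. Differential calls between UUO and Sham within
#' one compartment use a Welch two-sample t-test on log2(RPKM +
#' pseudocount) with the conventional cutoffs |log2FC| >= 1 (inclusive)
#' and p < 0.05 (strict), without multiple-testing correction by default.
#'
#' @name expression_de
NULL

#' Compute the RPKM matrix
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay, or a
#'   plain count matrix.
#' @param lengths Named numeric vector of exonic lengths (nt) covering
#'   every transcript in the matrix.
#' @return Numeric matrix of RPKM values, same dimnames as the counts.
#' @export
compute_rpkm <- function(se, lengths) {
  counts <- if (is(se, "SummarizedExperiment")) assay(se, "counts") else se
  ids <- rownames(counts)
  missing_len <- setdiff(ids, names(lengths))
  if (length(missing_len)) {
    stop("missing exonic length for transcript(s): ",
         paste(head(missing_len, 5), collapse = ", "))
  }
  L <- lengths[ids]
  if (any(L <= 0)) stop("non-positive exonic length")
  N <- colSums(counts)
  if (any(N <= 0)) stop("sample with zero library size")
  sweep(counts, 2, N, "/") * 1e9 / L
}

#' log2 fold change with pseudocount
#'
#' \code{log2((mean_case + pseudocount) / (mean_control + pseudocount))}.
#' The pseudocount (default 0.25 RPKM) keeps zero-expression transcripts
#' finite.
#'
#' @param mean_case,mean_control Mean RPKM per group (vectors allowed).
#' @param pseudocount Non-negative RPKM offset.
#' @return Numeric log2 fold change.
#' @export
log2_fold_change <- function(mean_case, mean_control, pseudocount = 0.25) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  log2((mean_case + pseudocount) / (mean_control + pseudocount))
}

#' Per-transcript Welch test on log2 RPKM
#'
#' Two-sided Welch t-test on log2(RPKM + pseudocount). With two groups
#' this coincides with a one-way ANOVA; Welch's form is used as the robust
#' default. Degenerate inputs never yield NaN: two constant, equal groups
#' give p = 1, constant but unequal groups give p = 0.
#'
#' @param rpkm_case,rpkm_control Numeric RPKM vectors, length >= 2 each.
#' @param pseudocount RPKM offset before the log transform.
#' @return p-value in [0, 1].
#' @export
per_transcript_test <- function(rpkm_case, rpkm_control, pseudocount = 0.25) {
  if (length(rpkm_case) < 2 || length(rpkm_control) < 2) {
    stop("each group needs at least 2 values")
  }
  welch_p(log2(rpkm_case + pseudocount), log2(rpkm_control + pseudocount))
}

#' Call differentially expressed transcripts
#'
#' Produces one record per transcript with group mean RPKMs, log2 fold
#' change (UUO over Sham), Welch p-value, direction and significance flag.
#' A transcript is significant iff |log2FC| >= \code{lfc_cutoff}
#' (inclusive) and p < \code{p_cutoff} (strict). Direction is \code{up} or
#' \code{down} for significant records and \code{none} otherwise.
#'
#' @param se \code{SummarizedExperiment} of counts for ONE compartment with
#'   \code{colData()$condition} in UUO/Sham; mixing compartments is an
#'   error.
#' @param lengths Named exonic lengths (nt).
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param pseudocount RPKM offset (default 0.25).
#' @param bh If TRUE, add a Benjamini-Hochberg adjusted p-value column and
#'   gate significance on it instead of the raw p-value.
#' @return data.frame of DE records, with attributes \code{n_up} and
#'   \code{n_down}.
#' @export
call_de <- function(se, lengths, lfc_cutoff = 1, p_cutoff = 0.05,
                    pseudocount = 0.25, bh = FALSE) {
  cd <- colData(se)
  if (length(unique(cd$compartment)) > 1) {
    stop("call_de expects a single compartment; got: ",
         paste(unique(cd$compartment), collapse = ", "))
  }
  case <- rownames(cd)[cd$condition == "UUO"]
  ctrl <- rownames(cd)[cd$condition == "Sham"]
  if (length(case) < 2 || length(ctrl) < 2) {
    stop("need >= 2 replicates per condition (UUO and Sham)")
  }
  rpkm <- compute_rpkm(se, lengths)
  mean_uuo <- rowMeans(rpkm[, case, drop = FALSE])
  mean_sham <- rowMeans(rpkm[, ctrl, drop = FALSE])
  lfc <- log2_fold_change(mean_uuo, mean_sham, pseudocount)
  p <- welch_p_rows(log2(rpkm[, case, drop = FALSE] + pseudocount),
                    log2(rpkm[, ctrl, drop = FALSE] + pseudocount))
  p_eff <- if (bh) stats::p.adjust(p, method = "BH") else p
  significant <- abs(lfc) >= lfc_cutoff & p_eff < p_cutoff
  direction <- ifelse(!significant, "none", ifelse(lfc > 0, "up", "down"))
  out <- data.frame(
    transcript_id = rownames(rpkm),
    mean_rpkm_uuo = unname(mean_uuo),
    mean_rpkm_sham = unname(mean_sham),
    log2fc = unname(lfc),
    p_value = p,
    direction = direction,
    significant = significant,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (bh) out$p_adj <- stats::p.adjust(p, method = "BH")
  attr(out, "n_up") <- sum(direction == "up")
  attr(out, "n_down") <- sum(direction == "down")
  out
}
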