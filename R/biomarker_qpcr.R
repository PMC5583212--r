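#' @title Tissue-urine concordance and ddCt qPCR quantification
#'
#' @description A urinary biomarker candidate is a lncRNA significantly
#' dysregulated in BOTH renal tissue and urine with the same direction of
#' change. qPCR validation uses the Livak 2^-ddCt method: per sample,
#' dCt = Ct_target - Ct_reference; ddCt subtracts the calibrator group's
#' mean dCt (Sham by default); fold change = 2^-ddCt. Body-fluid samples
#' are normalized to an exogenous spike-in (cel-miR-39) instead of a
#' cellular reference gene.
#'
#' @name biomarker_qpcr
NULL

#' Concordant tissue-urine biomarker candidates
#'
#' Intersects the transcripts significant in both compartments and flags
#' whether their directions agree. Only concordant transcripts form the
#' biomarker candidate set; discordant ones are reported with
#' \code{concordant = FALSE}.
#'
#' @param tissue_de,urine_de DE tables from \code{\link{call_de}}.
#' @return data.frame transcript_id, tissue_direction, urine_direction,
#'   concordant; attributes \code{n_concordant_up} / \code{n_concordant_down}.
#' @export
concordant_biomarkers <- function(tissue_de, urine_de) {
  tsig <- tissue_de[tissue_de$significant, c("transcript_id", "direction")]
  usig <- urine_de[urine_de$significant, c("transcript_id", "direction")]
  shared <- intersect(tsig$transcript_id, usig$transcript_id)
  out <- data.frame(
    transcript_id = shared,
    tissue_direction = tsig$direction[match(shared, tsig$transcript_id)],
    urine_direction = usig$direction[match(shared, usig$transcript_id)],
    stringsAsFactors = FALSE
  )
  out$concordant <- out$tissue_direction == out$urine_direction
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_concordant_up") <-
    sum(out$concordant & out$tissue_direction == "up")
  attr(out, "n_concordant_down") <-
    sum(out$concordant & out$tissue_direction == "down")
  out
}

#' Relative quantification by the 2^-ddCt method
#'
#' For every non-reference target: per-sample dCt = Ct_target -
#' Ct_reference (same sample); ddCt = dCt - mean(dCt over the calibrator
#' group); fold = 2^-ddCt. Group summaries report the arithmetic mean and
#' SD of per-sample folds (bar-plot convention) plus the geometric mean,
#' and a two-sided Welch t-test on dCt between groups supplies the
#' p-value.
#'
#' @param table Long-format data.frame with columns sample_id, group
#'   (UUO/Sham), gene, ct.
#' @param reference_gene Gene id used as the within-sample reference
#'   (e.g. GAPDH or 18S); required, never inferred.
#' @param calibrator_group Group whose mean dCt anchors ddCt (default
#'   "Sham"); needs >= 2 samples.
#' @param targets Optional subset of target genes (default: all
#'   non-reference genes in the table).
#' @return List with \code{records} (per-sample data.frame: target,
#'   sample_id, group, ct_target, ct_reference, delta_ct, delta_delta_ct,
#'   fold) and \code{summary} (per target x group: mean_fold, sd_fold,
#'   geo_mean_fold, p_value, normalization).
#' @export
delta_delta_ct <- function(table, reference_gene, calibrator_group = "Sham",
                           targets = NULL) {
  req <- c("sample_id", "group", "gene", "ct")
  if (!all(req %in% names(table))) {
    stop("qPCR table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(table$ct < 0)) stop("negative Ct value")
  ref <- table[table$gene == reference_gene, ]
  samples <- unique(table$sample_id)
  no_ref <- setdiff(samples, ref$sample_id)
  if (length(no_ref)) {
    stop("missing reference (", reference_gene, ") Ct for sample(s): ",
         paste(no_ref, collapse = ", "))
  }
  if (is.null(targets)) targets <- setdiff(unique(table$gene), reference_gene)
  groups <- unique(table$group)
  if (!calibrator_group %in% groups) {
    stop("calibrator group absent from table: ", calibrator_group)
  }

  records <- list()
  summaries <- list()
  for (tg in targets) {
    sub <- table[table$gene == tg, ]
    ct_ref <- ref$ct[match(sub$sample_id, ref$sample_id)]
    dct <- sub$ct - ct_ref
    cal <- sub$group == calibrator_group
    if (sum(cal) < 2) {
      stop("calibrator group needs >= 2 samples for target ", tg)
    }
    ddct <- dct - mean(dct[cal])
    fold <- 2^(-ddct)
    records[[tg]] <- data.frame(
      target = tg, sample_id = sub$sample_id, group = sub$group,
      ct_target = sub$ct, ct_reference = ct_ref, delta_ct = dct,
      delta_delta_ct = ddct, fold = fold, stringsAsFactors = FALSE
    )
    for (g in groups) {
      gi <- sub$group == g
      p <- if (g == calibrator_group) 1 else welch_p(dct[gi], dct[cal])
      summaries[[paste(tg, g)]] <- data.frame(
        target = tg, group = g,
        mean_fold = mean(fold[gi]), sd_fold = sd(fold[gi]),
        geo_mean_fold = 2^(-mean(ddct[gi])),
        p_value = p,
        normalization = reference_gene,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, records); rownames(records) <- NULL
  summary <- do.call(rbind, summaries); rownames(summary) <- NULL
  list(records = records, summary = summary)
}

#' Spike-in normalized ddCt quantification
#'
#' Identical math to \code{\link{delta_delta_ct}} with an exogenous
#' spike-in (default cel-miR-39) as the reference; intended for urine,
#' where no cellular reference gene is reliable. Errors listing the
#' affected samples if the spike is missing anywhere.
#'
#' @inheritParams delta_delta_ct
#' @param spike_id Spike-in identifier (default "cel-miR-39").
#' @return As \code{\link{delta_delta_ct}}; the summary's
#'   \code{normalization} column is tagged \code{spike:<id>}.
#' @export
spike_in_normalize <- function(table, spike_id = "cel-miR-39",
                               calibrator_group = "Sham", targets = NULL) {
  samples <- unique(table$sample_id)
  with_spike <- unique(table$sample_id[table$gene == spike_id])
  absent <- setdiff(samples, with_spike)
  if (length(absent)) {
    stop("spike-in ", spike_id, " missing in sample(s): ",
         paste(absent, collapse = ", "))
  }
  out <- delta_delta_ct(table, reference_gene = spike_id,
                        calibrator_group = calibrator_group,
                        targets = targets)
  out$summary$normalization <- paste0("spike:", spike_id)
  out
}
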