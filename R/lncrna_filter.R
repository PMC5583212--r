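#' @title Consensus lncRNA candidate filtering
#'
#' @description Transcripts are retained as lncRNA candidates only if they
#' are longer than a minimum spliced length (default 200 nt, strict) and no
#' coding-potential predictor calls them coding. The union-removal rule —
#' a transcript flagged by \emph{any} predictor is discarded — mirrors the
#' consensus filtering used with CPC/CNCI/Pfam/PhyloCSF in lncRNA surveys;
#' the external tools themselves are replaced by a pluggable predictor
#' interface with two built-ins (longest-ORF length and hexamer bias).
#'
#' @name lncrna_filter
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame length
#'
#' Scans the three forward frames (transcripts are stranded) for the
#' longest ORF starting at ATG and ending at the first in-frame stop codon
#' (TAA/TAG/TGA). The returned length is in nucleotides and includes the
#' stop codon; 0 if no complete ORF exists.
#'
#' @param sequence Transcript DNA string over A,C,G,T,N.
#' @return Integer length in nt.
#' @export
longest_orf_length <- function(sequence) {
  n <- nchar(sequence)
  if (n < 6) return(0L)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- substring(sequence, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stops <- which(codons %in% STOP_CODONS)
    if (length(atg) == 0 || length(stops) == 0) next
    for (a in atg) {
      s <- stops[stops > a]
      if (length(s) == 0) next
      len <- (s[1] - a + 1L) * 3L
      if (len > best) best <- len
    }
  }
  best
}

#' Hexamer usage bias score
#'
#' Mean log-likelihood ratio, over the in-frame hexamers of the sequence
#' (frame 0, step 3), of coding versus non-coding hexamer frequencies.
#' Positive scores indicate coding-like hexamer usage. Hexamers containing
#' non-ACGT characters are skipped; sequences shorter than 6 nt score 0.
#'
#' @param sequence Transcript DNA string.
#' @param coding_freq_table,noncoding_freq_table Named numeric vectors over
#'   all 4^6 hexamers with strictly positive entries summing to 1.
#' @return Numeric score (0 for degenerate input).
#' @export
hexamer_bias_score <- function(sequence, coding_freq_table,
                               noncoding_freq_table) {
  check_tab <- function(tab, what) {
    if (length(tab) != 4096 || is.null(names(tab))) {
      stop(what, " table must cover all 4096 hexamers")
    }
    if (any(tab <= 0)) stop(what, " table has non-positive entries")
    if (abs(sum(tab) - 1) > 1e-6) stop(what, " table must sum to 1")
  }
  check_tab(coding_freq_table, "coding")
  check_tab(noncoding_freq_table, "noncoding")
  n <- nchar(sequence)
  if (n < 6) return(0)
  starts <- seq(1L, n - 5L, by = 3L)
  hexamers <- substring(sequence, starts, starts + 5L)
  hexamers <- hexamers[grepl("^[ACGT]{6}$", hexamers)]
  if (length(hexamers) == 0) return(0)
  missing_hex <- setdiff(hexamers, names(coding_freq_table))
  if (length(missing_hex)) {
    stop("frequency table missing hexamer(s): ",
         paste(head(missing_hex, 3), collapse = ", "))
  }
  mean(log(coding_freq_table[hexamers] / noncoding_freq_table[hexamers]))
}

#' Built-in coding-potential predictors
#'
#' \code{orf_coding_calls} flags transcripts whose longest ORF exceeds
#' \code{threshold} nt (default 300). \code{hexamer_coding_calls} flags
#' transcripts whose hexamer bias score exceeds \code{threshold}
#' (default 0). Both return one \code{CodingCall} row per transcript.
#'
#' @param sequences Named character vector of spliced transcript sequences.
#' @param threshold Predictor-specific decision threshold.
#' @param coding_freq_table,noncoding_freq_table Hexamer frequency tables
#'   (see \code{\link{hexamer_bias_score}}).
#' @return data.frame with transcript_id, predictor_name, score, is_coding.
#' @export
orf_coding_calls <- function(sequences, threshold = 300) {
  score <- vapply(sequences, longest_orf_length, integer(1))
  data.frame(transcript_id = names(sequences),
             predictor_name = "orf_length",
             score = as.numeric(score),
             is_coding = score > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname orf_coding_calls
#' @export
hexamer_coding_calls <- function(sequences, coding_freq_table,
                                 noncoding_freq_table, threshold = 0) {
  score <- vapply(sequences, hexamer_bias_score, numeric(1),
                  coding_freq_table, noncoding_freq_table)
  data.frame(transcript_id = names(sequences),
             predictor_name = "hexamer_bias",
             score = score,
             is_coding = score > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus lncRNA candidate filter
#'
#' A transcript is removed if its spliced (exonic) length is at most
#' \code{min_length} nt — checked first, reason \code{too_short} — or if
#' any predictor calls it coding (reason \code{coding_by:<predictors>}).
#' The remainder form the lncRNA candidate set. "Longer than 200 nt" is
#' read strictly: a 200-nt transcript is removed, a 201-nt one kept.
#'
#' @param transcripts data.frame with transcript_id and exonic_length
#'   columns (e.g. \code{gene_models()$transcripts}).
#' @param calls data.frame of coding calls (one row per transcript x
#'   predictor); every transcript must have at least one call.
#' @param min_length Minimum exonic length in nt (strict; default 200).
#' @return List with \code{candidate_ids} (character vector) and
#'   \code{removed} (data.frame transcript_id, reason); together they
#'   partition the input transcript set.
#' @export
consensus_lnc_filter <- function(transcripts, calls, min_length = 200) {
  ids <- transcripts$transcript_id
  uncalled <- setdiff(ids, calls$transcript_id)
  if (length(uncalled)) {
    stop("transcript(s) without any predictor call: ",
         paste(head(uncalled, 5), collapse = ", "))
  }
  calls <- calls[calls$transcript_id %in% ids, , drop = FALSE]
  coding_by <- lapply(split(calls, calls$transcript_id), function(d) {
    sort(d$predictor_name[d$is_coding])
  })
  reason <- character(0)
  removed_ids <- character(0)
  candidates <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (transcripts$exonic_length[i] <= min_length) {
      removed_ids <- c(removed_ids, id)
      reason <- c(reason, "too_short")
    } else if (length(coding_by[[id]]) > 0) {
      removed_ids <- c(removed_ids, id)
      reason <- c(reason, paste0("coding_by:",
                                 paste(coding_by[[id]], collapse = ",")))
    } else {
      candidates <- c(candidates, id)
    }
  }
  list(candidate_ids = candidates,
       removed = data.frame(transcript_id = removed_ids, reason = reason,
                            stringsAsFactors = FALSE))
}
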