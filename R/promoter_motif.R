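#' @title Promoter extraction and Smad3 motif scanning
#'
#' @description Activated Smad3 binds DNA at Smad-binding elements with
#' canonical sequence CAGACA. This module extracts the 5 kb putative
#' promoter upstream of each gene's TSS (strand-aware, clipped at contig
#' boundaries), counts exact — possibly overlapping — motif occurrences on
#' the promoter's sense strand (optionally also the antisense strand), and
#' prioritizes genes whose promoter carries strictly more than a threshold
#' number of motifs (default: more than 4) as TGF-beta pathway candidates.
#'
#' @name promoter_motif
NULL

#' Extract a gene's putative promoter
#'
#' On the + strand the promoter is \code{[max(0, tss - length), tss)}; on
#' the - strand it is \code{[tss + 1, min(contig_length, tss + 1 + length))}
#' and the returned sequence is reverse-complemented, so position 0 of the
#' sequence is always the position farthest from the TSS in transcription
#' orientation. \code{clipped} is TRUE when a contig edge truncated the
#' window.
#'
#' @param gene One-row data.frame (or list) with gene_id, contig, strand,
#'   tss (as in \code{gene_models()$genes}).
#' @param genome \code{DNAStringSet} keyed by contig.
#' @param length Promoter length in nt (default 5000).
#' @return List with gene_id, contig, start, end (0-based half-open,
#'   genomic), strand, clipped, sequence.
#' @export
promoter_interval <- function(gene, genome, length = 5000) {
  contig <- as.character(gene$contig)
  if (!contig %in% names(genome)) {
    stop("contig not in genome: ", contig, " (gene ", gene$gene_id, ")")
  }
  clen <- nchar(as.character(genome[[contig]]))
  tss <- as.integer(gene$tss)
  if (gene$strand == "+") {
    start <- max(0L, tss - as.integer(length))
    end <- tss
  } else {
    start <- tss + 1L
    end <- min(clen, tss + 1L + as.integer(length))
  }
  if (end <= start) {
    stop("zero-length promoter for gene ", gene$gene_id,
         " (TSS at contig edge)")
  }
  seq <- as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
  if (gene$strand == "-") seq <- revcomp(seq)
  list(gene_id = gene$gene_id, contig = contig, start = start, end = end,
       strand = gene$strand, clipped = (end - start) < length,
       sequence = seq)
}

#' Scan a sequence for exact motif occurrences
#'
#' All (possibly overlapping) exact matches of \code{motif} on the given
#' sequence; with \code{include_reverse_complement}, matches of the
#' reverse-complement word are added with antisense labels. The ambiguity
#' code N never matches. Offsets are 0-based within the scanned sequence.
#'
#' @param sequence DNA string.
#' @param motif DNA word over A,C,G,T (default CAGACA, the Smad-binding
#'   element).
#' @param include_reverse_complement Also scan for the reverse complement
#'   (TGTCTG for the default motif)?
#' @return List with hit_positions (0-based, sorted), hit_strands
#'   ("sense"/"antisense") and k (total hit count).
#' @export
scan_motif <- function(sequence, motif = "CAGACA",
                       include_reverse_complement = FALSE) {
  if (nchar(motif) < 1 || grepl("[^ACGT]", motif)) {
    stop("motif must be a non-empty word over A,C,G,T")
  }
  if (nchar(sequence) < nchar(motif)) {
    return(list(hit_positions = integer(0), hit_strands = character(0),
                k = 0L))
  }
  subject <- DNAString(sequence)
  pos <- Biostrings::start(matchPattern(motif, subject)) - 1L
  strands <- rep("sense", length(pos))
  if (include_reverse_complement) {
    rc <- revcomp(motif)
    pos_rc <- Biostrings::start(matchPattern(rc, subject)) - 1L
    # the motif can be its own reverse complement; avoid double counting
    if (rc == motif) pos_rc <- integer(0)
    pos <- c(pos, pos_rc)
    strands <- c(strands, rep("antisense", length(pos_rc)))
  }
  ord <- order(pos, strands)
  list(hit_positions = as.integer(pos[ord]), hit_strands = strands[ord],
       k = length(pos))
}

#' Scan the promoters of a gene set for a motif
#'
#' Convenience wrapper: extracts each gene's promoter and scans it,
#' returning one row per gene with the hit count \code{k} and the
#' prioritization flag (\code{k > threshold}).
#'
#' @param genes data.frame of gene rows (gene_id, contig, strand, tss).
#' @param genome \code{DNAStringSet}.
#' @param motif Motif word (default CAGACA).
#' @param promoter_length Promoter window in nt (default 5000).
#' @param threshold Prioritization threshold on k (strict; default 4).
#' @param include_reverse_complement Scan both strands?
#' @return data.frame gene_id, contig, start, end, strand, clipped, k,
#'   prioritized, plus a list-column \code{hit_positions}.
#' @export
scan_promoters <- function(genes, genome, motif = "CAGACA",
                           promoter_length = 5000, threshold = 4,
                           include_reverse_complement = FALSE) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    prom <- promoter_interval(genes[i, ], genome, promoter_length)
    hits <- scan_motif(prom$sequence, motif, include_reverse_complement)
    data.frame(gene_id = prom$gene_id, contig = prom$contig,
               start = prom$start, end = prom$end, strand = prom$strand,
               clipped = prom$clipped, k = hits$k,
               prioritized = hits$k > threshold,
               hit_positions = I(list(hits$hit_positions)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prioritize TGF-beta candidate lncRNAs by motif count
#'
#' A gene is selected iff its promoter motif count is strictly greater
#' than \code{threshold}: with the default 4, k = 5 passes and k = 4 does
#' not ("more than 4 motifs").
#'
#' @param results data.frame with gene_id and k columns (one row per gene).
#' @param threshold Strict lower bound on k (default 4).
#' @return Character vector of prioritized gene ids.
#' @export
prioritize_tgfb_candidates <- function(results, threshold = 4) {
  if (anyDuplicated(results$gene_id)) {
    stop("duplicate gene ids in motif scan results")
  }
  results$gene_id[results$k > threshold]
}
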