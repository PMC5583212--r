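#' @title Cis-neighbor search around dysregulated lncRNA loci
#'
#' @description lncRNAs frequently act in cis on nearby genes. For each
#' dysregulated lncRNA gene this module reports every protein-coding gene
#' whose span lies within a window (default 100 kb, boundary inclusive) on
#' the same contig, together with the span-to-span gap distance and the
#' orientation relative to the lncRNA's strand. Candidate pairs are found
#' with an interval overlap query (IRanges) and distances recomputed
#' exactly; a brute-force all-pairs oracle is kept in the test suite.
#'
#' @name cis_neighbors
NULL

# Gap between two 0-based half-open spans; 0 when they overlap or touch.
span_distance <- function(start_a, end_a, start_b, end_b) {
  pmax(0, pmax(start_a, start_b) - pmin(end_a, end_b))
}

#' Find protein-coding neighbors of lncRNA genes
#'
#' @param lnc_genes,coding_genes data.frames with gene_id, contig, strand,
#'   start, end (0-based half-open spans), e.g. rows of
#'   \code{gene_models()$genes}.
#' @param window Maximum gap in nt (inclusive; default 100000).
#' @return data.frame with lnc_gene_id, coding_gene_id, distance and
#'   relation (\code{overlap}, \code{upstream}, \code{downstream}; assigned
#'   from the lncRNA's strand). Empty inputs yield an empty frame.
#' @export
find_cis_neighbors <- function(lnc_genes, coding_genes, window = 100000) {
  if (window <= 0) stop("window must be positive")
  empty <- data.frame(lnc_gene_id = character(), coding_gene_id = character(),
                      distance = numeric(), relation = character(),
                      stringsAsFactors = FALSE)
  if (nrow(lnc_genes) == 0 || nrow(coding_genes) == 0) return(empty)

  strand_lnc <- lnc_genes$strand
  if (any(!strand_lnc %in% c("+", "-"))) {
    warning("unstranded lncRNA gene(s); treating as '+'")
    strand_lnc[!strand_lnc %in% c("+", "-")] <- "+"
  }

  out <- list()
  for (ctg in intersect(unique(lnc_genes$contig), unique(coding_genes$contig))) {
    li <- which(lnc_genes$contig == ctg)
    ci <- which(coding_genes$contig == ctg)
    q <- IRanges(start = lnc_genes$start[li] + 1L, end = lnc_genes$end[li])
    s <- IRanges(start = coding_genes$start[ci] + 1L,
                 end = coding_genes$end[ci])
    hits <- findOverlaps(q, s, maxgap = window + 1L)
    if (length(hits) == 0) next
    i <- li[queryHits(hits)]
    j <- ci[subjectHits(hits)]
    d <- span_distance(lnc_genes$start[i], lnc_genes$end[i],
                       coding_genes$start[j], coding_genes$end[j])
    keep <- d <= window
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    if (length(i) == 0) next
    overlaps <- coding_genes$start[j] < lnc_genes$end[i] &
      lnc_genes$start[i] < coding_genes$end[j]
    # genomic side of the coding gene, then strand-aware relabelling
    left_of_lnc <- !overlaps &
      (coding_genes$end[j] <= lnc_genes$start[i] |
         coding_genes$start[j] < lnc_genes$start[i])
    relation <- ifelse(overlaps, "overlap",
                       ifelse(xor(left_of_lnc, strand_lnc[i] == "-"),
                              "upstream", "downstream"))
    out[[length(out) + 1L]] <- data.frame(
      lnc_gene_id = lnc_genes$gene_id[i],
      coding_gene_id = coding_genes$gene_id[j],
      distance = as.numeric(d),
      relation = relation,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$lnc_gene_id, res$coding_gene_id), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}
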