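#' @title Synthetic genome, annotation, counts and qPCR tables with planted truth
#'
#' @description Generates a deterministic toy dataset emulating the study
#' design the pipeline targets: 2 conditions (UUO vs Sham) x 2
#' compartments (renal tissue, urine) x 3 replicates of negative-binomial
#' transcript counts with planted log2 fold changes, CAGACA Smad-binding
#' elements planted at exact copy numbers in designated lncRNA promoters
#' (background occurrences are disrupted first so the planted count is the
#' exact sense-strand scan count), protein-coding genes placed at exact gap
#' distances from lncRNA loci, and Ct tables with reference genes and a
#' cel-miR-39 spike-in. One global seed drives a named sub-stream per
#' artifact (genome, tissue counts, urine counts, qPCR) so each can be
#' regenerated independently and byte-identically.
#'
#' @name synthetic_data
NULL

# geometry constants of the toy gene models (nt)
LNC_EXONS <- c(300L, 250L); LNC_INTRON <- 200L
PCG_EXONS <- c(500L, 400L); PCG_INTRON <- 300L
BLOCK_SPACER <- 101000L     # min gene-to-gene separation across blocks
FILLER_SPACER <- 1500L      # spacing inside the dense background region
CLIPPED_PROMOTER <- 3000L   # first lncRNA gets a contig-start-clipped promoter

#' Configuration for the synthetic dataset
#'
#' Defaults define the package's reference study conditions: 960 lncRNA
#' and 40 protein-coding genes (1000 transcripts); 20 lncRNAs up- and 20
#' down-regulated in tissue at |log2FC| = 2 (negative binomial, baseline
#' mean 200, dispersion 0.05, 3 replicates per group); promoters of the 20
#' up-regulated lncRNAs planted with 6 motif counts in 5..10 and 14 counts
#' of at most 4; 25 cis pairs at exact gaps up to the 100 kb boundary; a
#' urine compartment sharing 5 up- and 2 down-regulated lncRNAs with
#' tissue (plus one discordant and several urine-only changes). lncRNA
#' genes that carry planted signal (DE, motifs or cis pairs) occupy
#' isolated blocks separated by more than the 100 kb cis window; the
#' remaining non-DE background lncRNAs are packed densely in their own
#' region, far from every protein-coding gene, keeping the DE fraction
#' small so column-sum library normalization stays stable.
#'
#' @param seed Global integer seed.
#' @param n_contigs Number of contigs to spread gene blocks over.
#' @param contig_length Optional fixed contig length (nt); NULL sizes each
#'   contig automatically. Too small a value is an error suggesting a
#'   larger one.
#' @param n_coding_genes,n_lnc_genes Gene counts.
#' @param n_de_lnc_up,n_de_lnc_down,n_de_mrna Planted DE gene counts
#'   (tissue).
#' @param true_log2fc Planted effect size (log2).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_mean Expected count in the Sham group.
#' @param replicates_per_group Replicates per condition (default 3).
#' @param planted_motif_counts Named integer vector (lncRNA gene id ->
#'   intended CAGACA copies); NULL installs the default design above.
#' @param neighbor_layout data.frame(lnc, coding, gap) of planted cis
#'   pairs with exact span gaps; NULL installs the default 25 pairs.
#' @param urine_up_shared,urine_down_shared Planted concordant lncRNAs.
#' @param urine_discordant lncRNAs up in tissue but down in urine.
#' @param urine_only_up,urine_only_down lncRNAs dysregulated only in urine.
#' @param qpcr_true_folds Named positive vector (target -> fold) for the
#'   Ct table; NULL derives a default from the planted effects.
#' @param qpcr_noise_sd Gaussian Ct noise, cycles (default 0.15).
#' @param promoter_length Promoter window used for motif planting (nt).
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(seed = 1,
                             n_contigs = 1,
                             contig_length = NULL,
                             n_coding_genes = 40,
                             n_lnc_genes = 960,
                             n_de_lnc_up = 20,
                             n_de_lnc_down = 20,
                             n_de_mrna = 15,
                             true_log2fc = 2,
                             nb_dispersion = 0.05,
                             baseline_mean = 200,
                             replicates_per_group = 3,
                             planted_motif_counts = NULL,
                             neighbor_layout = NULL,
                             urine_up_shared = 5,
                             urine_down_shared = 2,
                             urine_discordant = 1,
                             urine_only_up = 7,
                             urine_only_down = 3,
                             qpcr_true_folds = NULL,
                             qpcr_noise_sd = 0.15,
                             promoter_length = 5000) {
  if (n_de_lnc_up + n_de_lnc_down > n_lnc_genes) {
    stop("n_de_lnc_up + n_de_lnc_down exceeds n_lnc_genes")
  }
  if (n_de_mrna > n_coding_genes) stop("n_de_mrna exceeds n_coding_genes")
  if (urine_up_shared + urine_discordant > n_de_lnc_up ||
      urine_down_shared > n_de_lnc_down ||
      urine_only_up + urine_only_down > n_lnc_genes - n_de_lnc_up - n_de_lnc_down) {
    stop("urine DE design inconsistent with gene counts")
  }
  lnc_ids <- sprintf("LNC%03d", seq_len(n_lnc_genes))
  pcg_ids <- sprintf("PCG%03d", seq_len(n_coding_genes))

  if (is.null(planted_motif_counts)) {
    up <- lnc_ids[seq_len(n_de_lnc_up)]
    k <- rep(0L, length(up))
    hi <- 5:10
    lo <- c(0L, 1L, 2L, 3L, 4L, 0L, 1L, 2L, 3L, 4L, 0L, 2L, 3L, 4L)
    k[seq_len(min(6, length(up)))] <- hi[seq_len(min(6, length(up)))]
    rest <- setdiff(seq_along(up), seq_len(min(6, length(up))))
    k[rest] <- rep(lo, length.out = length(rest))
    planted_motif_counts <- setNames(as.integer(k), up)
  }
  if (!all(names(planted_motif_counts) %in% lnc_ids)) {
    stop("planted_motif_counts keys must be lncRNA gene ids")
  }

  if (is.null(neighbor_layout)) {
    n_pairs <- min(25, n_de_lnc_up + n_de_lnc_down, n_coding_genes)
    gaps <- c(round(seq(1000, 95000, length.out = max(0, n_pairs - 2))),
              99999, 100000)[seq_len(n_pairs)]
    neighbor_layout <- data.frame(
      lnc = lnc_ids[seq_len(n_pairs)],
      coding = pcg_ids[seq_len(n_pairs)],
      gap = as.integer(gaps),
      stringsAsFactors = FALSE
    )
  }
  if (!all(neighbor_layout$lnc %in% lnc_ids) ||
      !all(neighbor_layout$coding %in% pcg_ids)) {
    stop("neighbor_layout references unknown gene ids")
  }
  if (any(neighbor_layout$gap < 0) || any(neighbor_layout$gap > 100000)) {
    stop("neighbor_layout gaps must be in [0, 100000]")
  }

  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = contig_length,
    n_coding_genes = n_coding_genes, n_lnc_genes = n_lnc_genes,
    n_de_lnc_up = n_de_lnc_up, n_de_lnc_down = n_de_lnc_down,
    n_de_mrna = n_de_mrna, true_log2fc = true_log2fc,
    nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
    replicates_per_group = replicates_per_group,
    planted_motif_counts = planted_motif_counts,
    neighbor_layout = neighbor_layout,
    urine_up_shared = urine_up_shared, urine_down_shared = urine_down_shared,
    urine_discordant = urine_discordant,
    urine_only_up = urine_only_up, urine_only_down = urine_only_down,
    qpcr_true_folds = qpcr_true_folds, qpcr_noise_sd = qpcr_noise_sd,
    promoter_length = promoter_length,
    lnc_ids = lnc_ids, pcg_ids = pcg_ids
  ), class = "synthetic_config")
}

# All overlapping occurrences (0-based) of a word in a string.
find_word <- function(seq, word) {
  m <- gregexpr(paste0("(?=", word, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Replace "ATG" trigrams until none remain (G -> C cannot re-create ATG),
# so the transcript has no start codon and zero ORF length.
strip_start_codons <- function(chars) {
  repeat {
    s <- paste(chars, collapse = "")
    occ <- find_word(s, "ATG")
    if (length(occ) == 0) return(chars)
    chars[occ + 3L] <- "C"
  }
}

# Force a promoter sequence (transcription orientation) to contain exactly
# k sense-strand copies of the motif: disrupt background occurrences, plant
# k copies at spaced positions, and iterate until the scan count is exact.
plant_motifs <- function(seq_chars, k, motif = "CAGACA") {
  len <- length(seq_chars)
  mlen <- nchar(motif)
  mchars <- strsplit(motif, "")[[1]]
  flip <- c(A = "T", C = "G", G = "C", T = "A", N = "A")
  planted <- if (k > 0) {
    round(seq(50, len - mlen - 10, length.out = max(k, 2)))[seq_len(k)]
  } else integer(0)
  planted_cols <- unlist(lapply(planted, function(p) p:(p + mlen - 1L)))
  for (iter in 1:200) {
    for (p in planted) seq_chars[(p + 1L):(p + mlen)] <- mchars
    occ <- find_word(paste(seq_chars, collapse = ""), motif)
    extra <- setdiff(occ, planted)
    if (length(extra) == 0 && length(occ) == k) return(seq_chars)
    for (e in extra) {
      cols <- e:(e + mlen - 1L)
      free <- setdiff(cols, planted_cols)
      if (length(free) == 0) stop("cannot disrupt motif occurrence at ", e)
      tgt <- free[ceiling(length(free) / 2)]
      seq_chars[tgt + 1L] <- flip[[seq_chars[tgt + 1L]]]
    }
  }
  stop("motif planting did not converge")
}

# Random spliced sequence for a coding transcript: carries one long ORF
# (ATG + 150 sense codons + TAA = 456 nt) well above the 300 nt call
# threshold of the built-in ORF predictor.
coding_transcript_seq <- function(total_len) {
  chars <- random_bases(total_len)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""), STOP_CODONS)
  body <- sample(sense, 150, replace = TRUE)
  orf <- unlist(strsplit(c("ATG", body, "TAA"), ""))
  at <- 101L
  chars[at:(at + length(orf) - 1L)] <- orf
  chars
}

#' Generate the synthetic genome, annotation and ground truth
#'
#' Lays out gene blocks deterministically (each lncRNA with its reserved
#' promoter zone and any planted cis partners at exact gaps; blocks
#' separated by >100 kb so no unintended cis pair exists), fills the
#' contigs with i.i.d. uniform background sequence, writes transcript
#' sequences into exons (lncRNA transcripts carry no ATG, protein-coding
#' transcripts carry a 456 nt ORF), and plants the configured CAGACA copy
#' numbers into designated promoters after disrupting background
#' occurrences. The first lncRNA is placed 3 kb from the contig start so
#' promoter clipping is exercised.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with \code{genome} (\code{DNAStringSet}), \code{models}
#'   (\code{\link{gene_models}}) and \code{truth} (planted DE sets, motif
#'   counts, cis pairs, urine design, qPCR folds, transcript table).
#' @export
generate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, "genome"))
  lnc_ids <- config$lnc_ids; pcg_ids <- config$pcg_ids
  lnc_strand <- rep(c("+", "-"), length.out = length(lnc_ids))
  pcg_strand <- rep(c("-", "+"), length.out = length(pcg_ids))
  names(pcg_strand) <- pcg_ids
  lnc_span <- sum(LNC_EXONS) + LNC_INTRON
  pcg_span <- sum(PCG_EXONS) + PCG_INTRON
  prom <- as.integer(config$promoter_length)

  layout <- config$neighbor_layout
  pairs_of <- split(layout, layout$lnc)
  paired_pcg <- layout$coding
  if (anyDuplicated(paired_pcg)) {
    stop("neighbor_layout must use each coding gene at most once")
  }
  unpaired_pcg <- setdiff(pcg_ids, paired_pcg)

  # planted design (needed up-front to decide which loci require isolation)
  L <- config$true_log2fc
  up <- lnc_ids[seq_len(config$n_de_lnc_up)]
  down <- lnc_ids[config$n_de_lnc_up + seq_len(config$n_de_lnc_down)]
  nonde <- setdiff(lnc_ids, c(up, down))
  urine_up <- c(up[seq_len(config$urine_up_shared)],
                nonde[seq_len(config$urine_only_up)])
  discordant <- up[config$urine_up_shared + seq_len(config$urine_discordant)]
  urine_down <- c(down[seq_len(config$urine_down_shared)], discordant,
                  nonde[config$urine_only_up + seq_len(config$urine_only_down)])

  # lncRNAs carrying planted signal get isolated blocks (> window away
  # from any coding gene); the rest are dense non-DE background
  isolated_lnc <- lnc_ids[lnc_ids %in% c(up, down, urine_up, urine_down,
                                         names(config$planted_motif_counts),
                                         layout$lnc)]
  filler_lnc <- setdiff(lnc_ids, isolated_lnc)

  # --- dry layout: one block per signal lncRNA (+ its partners), then
  # leftover coding genes, then the dense background; chunked over contigs
  blocks <- c(isolated_lnc, unpaired_pcg, filler_lnc)
  contig_of_block <- rep(seq_len(config$n_contigs),
                         each = ceiling(length(blocks) / config$n_contigs),
                         length.out = length(blocks))
  genes <- list()
  cursor <- rep(0L, config$n_contigs)
  last_filler <- rep(FALSE, config$n_contigs)
  first_lnc_done <- FALSE
  for (b in seq_along(blocks)) {
    id <- blocks[b]
    ctg <- contig_of_block[b]
    is_lnc <- id %in% lnc_ids
    if (is_lnc && id %in% filler_lnc) {
      spacing <- if (last_filler[ctg]) FILLER_SPACER else BLOCK_SPACER
      gstart <- cursor[ctg] + spacing
      genes[[id]] <- list(gene_id = id, contig = ctg,
                          strand = lnc_strand[match(id, lnc_ids)],
                          start = gstart, end = gstart + lnc_span,
                          kind = "lnc")
      cursor[ctg] <- gstart + lnc_span
      last_filler[ctg] <- TRUE
      next
    }
    last_filler[ctg] <- FALSE
    if (!is_lnc) {
      gstart <- cursor[ctg] + BLOCK_SPACER
      genes[[id]] <- list(gene_id = id, contig = ctg,
                          strand = pcg_strand[[id]],
                          start = gstart, end = gstart + pcg_span,
                          kind = "pcg")
      cursor[ctg] <- gstart + pcg_span
      next
    }
    strand <- lnc_strand[match(id, lnc_ids)]
    prs <- pairs_of[[id]]
    if (!is.null(prs)) {
      prs <- prs[order(prs$gap), , drop = FALSE]
      if (nrow(prs) > 1 && any(diff(prs$gap) <= pcg_span)) {
        stop("neighbor layout infeasible for ", id,
             ": gaps too close for non-overlapping coding genes")
      }
    }
    if (strand == "+") {
      clearance <- if (!first_lnc_done && cursor[ctg] == 0L)
        CLIPPED_PROMOTER else BLOCK_SPACER + prom
      gstart <- cursor[ctg] + clearance
      gend <- gstart + lnc_span
      cursor[ctg] <- gend
      if (!is.null(prs)) for (r in seq_len(nrow(prs))) {
        cstart <- gend + prs$gap[r]
        genes[[prs$coding[r]]] <- list(gene_id = prs$coding[r], contig = ctg,
                                       strand = pcg_strand[[prs$coding[r]]],
                                       start = cstart, end = cstart + pcg_span,
                                       kind = "pcg")
        cursor[ctg] <- max(cursor[ctg], cstart + pcg_span)
      }
    } else {
      # coding partners sit genomically left of the gene; promoter right
      max_reach <- if (is.null(prs)) 0L else max(prs$gap) + pcg_span
      gstart <- cursor[ctg] + BLOCK_SPACER + max_reach
      gend <- gstart + lnc_span
      if (!is.null(prs)) for (r in seq_len(nrow(prs))) {
        cend <- gstart - prs$gap[r]
        genes[[prs$coding[r]]] <- list(gene_id = prs$coding[r], contig = ctg,
                                       strand = pcg_strand[[prs$coding[r]]],
                                       start = cend - pcg_span, end = cend,
                                       kind = "pcg")
      }
      cursor[ctg] <- gend + prom
    }
    genes[[id]] <- list(gene_id = id, contig = ctg, strand = strand,
                        start = gstart, end = gstart + lnc_span,
                        kind = "lnc")
    first_lnc_done <- TRUE
  }
  needed <- cursor + 200L
  if (!is.null(config$contig_length)) {
    if (any(needed > config$contig_length)) {
      stop("cannot place genes without overlap; use contig_length >= ",
           max(needed))
    }
    needed <- rep(as.integer(config$contig_length), config$n_contigs)
  }
  contig_names <- sprintf("chrS%d", seq_len(config$n_contigs))

  # --- sequence synthesis
  contigs <- lapply(needed, random_bases)
  exon_rows <- list()
  tx_rows <- list()
  for (g in genes) {
    if (g$kind == "lnc") {
      exlen <- LNC_EXONS; intron <- LNC_INTRON
      tx_chars <- strip_start_codons(random_bases(sum(exlen)))
      biotype <- "lncRNA_candidate"
      tx_id <- sub("^LNC", "TLNC", g$gene_id)
    } else {
      exlen <- PCG_EXONS; intron <- PCG_INTRON
      tx_chars <- coding_transcript_seq(sum(exlen))
      biotype <- "protein_coding"
      tx_id <- sub("^PCG", "TPCG", g$gene_id)
    }
    genomic <- if (g$strand == "+") tx_chars else
      rev(chartr("ACGTN", "TGCAN", tx_chars))
    e1 <- c(g$start, g$start + exlen[1])
    e2 <- c(e1[2] + intron, e1[2] + intron + exlen[2])
    contigs[[g$contig]][(e1[1] + 1):e1[2]] <- genomic[seq_len(exlen[1])]
    contigs[[g$contig]][(e2[1] + 1):e2[2]] <- genomic[exlen[1] + seq_len(exlen[2])]
    ctg_name <- contig_names[g$contig]
    exon_rows[[g$gene_id]] <- data.frame(
      transcript_id = tx_id, gene_id = g$gene_id, contig = ctg_name,
      strand = g$strand, start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
      biotype = biotype, stringsAsFactors = FALSE
    )
    tx_rows[[g$gene_id]] <- data.frame(
      transcript_id = tx_id, gene_id = g$gene_id, biotype = biotype,
      stringsAsFactors = FALSE
    )
  }

  # --- plant promoter motifs (designated promoters only)
  motif_counts <- config$planted_motif_counts
  for (gid in names(motif_counts)) {
    g <- genes[[gid]]
    clen <- needed[g$contig]
    tss <- if (g$strand == "+") g$start else g$end - 1L
    if (g$strand == "+") {
      ps <- max(0L, tss - prom); pe <- tss
      window <- contigs[[g$contig]][(ps + 1):pe]
    } else {
      ps <- tss + 1L; pe <- min(clen, tss + 1L + prom)
      window <- rev(chartr("ACGTN", "TGCAN",
                           contigs[[g$contig]][(ps + 1):pe]))
    }
    window <- plant_motifs(window, motif_counts[[gid]])
    if (g$strand == "+") {
      contigs[[g$contig]][(ps + 1):pe] <- window
    } else {
      contigs[[g$contig]][(ps + 1):pe] <- rev(chartr("ACGTN", "TGCAN", window))
    }
  }

  genome <- DNAStringSet(vapply(contigs, paste, character(1), collapse = ""))
  names(genome) <- contig_names
  models <- gene_models(do.call(rbind, exon_rows))

  # --- ground truth
  n_up_m <- ceiling(config$n_de_mrna * 2 / 3)
  mrna_up <- pcg_ids[seq_len(n_up_m)]
  mrna_down <- pcg_ids[n_up_m + seq_len(config$n_de_mrna - n_up_m)]
  qpcr_folds <- config$qpcr_true_folds %||%
    setNames(c(2^L, 2^-L, 1), c(up[1], down[1], nonde[1]))

  gm <- models$genes
  cis_pairs <- config$neighbor_layout
  names(cis_pairs) <- c("lnc_gene_id", "coding_gene_id", "distance")
  truth <- structure(list(
    de_lnc_up = setNames(rep(L, length(up)), up),
    de_lnc_down = setNames(rep(-L, length(down)), down),
    de_mrna = setNames(c(rep(L, length(mrna_up)), rep(-L, length(mrna_down))),
                       c(mrna_up, mrna_down)),
    urine_lnc_up = setNames(rep(L, length(urine_up)), urine_up),
    urine_lnc_down = setNames(rep(-L, length(urine_down)), urine_down),
    concordant_up = up[seq_len(config$urine_up_shared)],
    concordant_down = down[seq_len(config$urine_down_shared)],
    discordant = discordant,
    motif_counts = motif_counts,
    cis_pairs = cis_pairs,
    qpcr_true_folds = qpcr_folds,
    transcripts = do.call(rbind, tx_rows)
  ), class = "ground_truth")
  rownames(truth$transcripts) <- NULL

  list(genome = genome, models = models, truth = truth)
}

# log2 fold change planted for a gene in a compartment ("tissue"/"urine").
planted_lfc <- function(truth, compartment) {
  if (compartment == "tissue") {
    c(truth$de_lnc_up, truth$de_lnc_down, truth$de_mrna)
  } else {
    c(truth$urine_lnc_up, truth$urine_lnc_down, truth$de_mrna)
  }
}

#' Simulate negative-binomial counts for one compartment
#'
#' Sham samples draw from NB(mean = baseline), UUO samples from
#' NB(mean = baseline * 2^log2FC) for planted DE genes (baseline
#' otherwise), with variance mu + dispersion * mu^2. The urine compartment
#' uses an independent random sub-stream and its own planted DE subset.
#'
#' @param truth \code{ground_truth} from
#'   \code{\link{generate_genome_and_annotation}}.
#' @param config \code{\link{synthetic_config}}.
#' @param compartment "tissue" or "urine".
#' @return \code{SummarizedExperiment} with a counts assay and full sample
#'   metadata.
#' @export
simulate_counts <- function(truth, config, compartment = c("tissue", "urine")) {
  compartment <- match.arg(compartment)
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  set.seed(sub_seed(config$seed, compartment))
  tx <- truth$transcripts
  lfc <- planted_lfc(truth, compartment)
  gene_lfc <- ifelse(tx$gene_id %in% names(lfc), lfc[tx$gene_id], 0)
  reps <- config$replicates_per_group
  conds <- rep(c("Sham", "UUO"), each = reps)
  sample_ids <- paste(compartment, conds, rep(seq_len(reps), 2), sep = "_")
  mu <- outer(rep(config$baseline_mean, nrow(tx)), rep(1, 2 * reps))
  mu[, conds == "UUO"] <- config$baseline_mean * 2^gene_lfc
  counts <- matrix(0L, nrow(tx), 2 * reps,
                   dimnames = list(tx$transcript_id, sample_ids))
  for (j in seq_len(ncol(counts))) {
    counts[, j] <- rnbinom(nrow(tx), mu = mu[, j],
                           size = 1 / config$nb_dispersion)
  }
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = conds, compartment = compartment,
                        replicate = rep(seq_len(reps), 2),
                        library_size = colSums(counts),
                        row.names = sample_ids),
    rowData = DataFrame(transcript_id = tx$transcript_id,
                        gene_id = tx$gene_id, biotype = tx$biotype,
                        row.names = tx$transcript_id)
  )
}

#' Simulate a global-null count matrix
#'
#' Convenience generator for calibration checks: \code{n_transcripts}
#' genes with no expression difference between UUO and Sham.
#'
#' @param n_transcripts Number of transcripts.
#' @param replicates Replicates per group.
#' @param baseline_mean,dispersion NB parameters.
#' @param seed Integer seed.
#' @return List with \code{se} (SummarizedExperiment, tissue compartment)
#'   and \code{lengths} (named vector, all 1000 nt).
#' @export
simulate_null_counts <- function(n_transcripts, replicates = 3,
                                 baseline_mean = 200, dispersion = 0.05,
                                 seed = 1) {
  if (dispersion <= 0) stop("dispersion must be positive")
  set.seed(sub_seed(seed, "null"))
  ids <- sprintf("NULL%05d", seq_len(n_transcripts))
  conds <- rep(c("Sham", "UUO"), each = replicates)
  sample_ids <- paste("tissue", conds, rep(seq_len(replicates), 2), sep = "_")
  counts <- matrix(rnbinom(n_transcripts * 2 * replicates,
                           mu = baseline_mean, size = 1 / dispersion),
                   n_transcripts, 2 * replicates,
                   dimnames = list(ids, sample_ids))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = conds, compartment = "tissue",
                        replicate = rep(seq_len(replicates), 2),
                        library_size = colSums(counts),
                        row.names = sample_ids)
  )
  list(se = se, lengths = setNames(rep(1000, n_transcripts), ids))
}

#' Simulate a qPCR Ct table
#'
#' Ct(gene, sample) = base Ct - log2(relative abundance) + Gaussian noise.
#' Targets carry their planted fold in UUO; the reference genes (GAPDH,
#' 18S) and the cel-miR-39 spike-in are constant across groups.
#'
#' @param truth \code{ground_truth} with \code{qpcr_true_folds}.
#' @param config \code{\link{synthetic_config}}.
#' @param noise_sd Ct noise in cycles (default from config; 0 gives exact
#'   fold recovery).
#' @return Long data.frame: sample_id, group, gene, ct.
#' @export
simulate_qpcr <- function(truth, config, noise_sd = config$qpcr_noise_sd) {
  folds <- truth$qpcr_true_folds
  if (any(folds <= 0)) stop("qPCR true fold must be positive")
  set.seed(sub_seed(config$seed, "qpcr"))
  reps <- config$replicates_per_group
  groups <- rep(c("Sham", "UUO"), each = reps)
  sample_ids <- paste(groups, rep(seq_len(reps), 2), sep = "_")
  base_ct <- c(setNames(rep(24, length(folds)), names(folds)),
               GAPDH = 18, `18S` = 10, `cel-miR-39` = 22)
  rows <- list()
  for (gene in names(base_ct)) {
    rel <- rep(1, length(sample_ids))
    if (gene %in% names(folds)) rel[groups == "UUO"] <- folds[[gene]]
    ct <- base_ct[[gene]] - log2(rel) + rnorm(length(sample_ids), 0, noise_sd)
    rows[[gene]] <- data.frame(sample_id = sample_ids, group = groups,
                               gene = gene, ct = ct,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the full synthetic dataset to disk
#'
#' Emits genome FASTA, annotation GTF, per-compartment count TSVs, a
#' combined sample sheet, the qPCR Ct TSV and the ground truth as JSON.
#' Same config (and seed) produces byte-identical files.
#'
#' @param config \code{\link{synthetic_config}}.
#' @param out_dir Output directory (created if needed).
#' @return List with \code{paths} (named file paths), \code{truth},
#'   \code{models} and \code{genome}.
#' @export
write_synthetic_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome_and_annotation(config)
  tissue <- simulate_counts(gen$truth, config, "tissue")
  urine <- simulate_counts(gen$truth, config, "urine")
  qpcr <- simulate_qpcr(gen$truth, config)

  paths <- c(genome = file.path(out_dir, "genome.fa"),
             gtf = file.path(out_dir, "annotation.gtf"),
             tissue_counts = file.path(out_dir, "counts_tissue.tsv"),
             urine_counts = file.path(out_dir, "counts_urine.tsv"),
             sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
             qpcr = file.path(out_dir, "qpcr_ct.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_fasta(gen$genome, paths[["genome"]])
  write_gtf(gen$models, paths[["gtf"]])

  dump_counts <- function(se, path) {
    tab <- data.frame(transcript_id = rownames(se), assay(se, "counts"),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dump_counts(tissue, paths[["tissue_counts"]])
  dump_counts(urine, paths[["urine_counts"]])

  sheet <- rbind(
    data.frame(sample = colnames(tissue), condition = colData(tissue)$condition,
               compartment = "tissue", replicate = colData(tissue)$replicate),
    data.frame(sample = colnames(urine), condition = colData(urine)$condition,
               compartment = "urine", replicate = colData(urine)$replicate)
  )
  write.table(sheet, paths[["sample_sheet"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(qpcr, paths[["qpcr"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_json <- gen$truth
  class(truth_json) <- NULL
  write_json(truth_json, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  list(paths = as.list(paths), truth = gen$truth, models = gen$models,
       genome = gen$genome)
}
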