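#' @title End-to-end pipeline orchestration
#'
#' @description Runs the full discovery-and-prioritization workflow from
#' files on disk: consensus lncRNA filtering, differential expression in
#' tissue and urine, cis-neighbor search around dysregulated lncRNA genes,
#' Smad3-motif promoter scanning of up-regulated lncRNAs with the
#' more-than-4-motifs prioritization rule, tissue-urine concordance, and
#' optional ddCt qPCR quantification. Every stage writes a plain-text
#' artifact and the run ends with a machine-readable JSON report whose
#' counts satisfy the pipeline's set inclusions (prioritized genes are
#' up-regulated lncRNA candidates; concordant biomarkers are significant
#' in both compartments; every cis pair's lncRNA is dysregulated).
#'
#' @name pipeline_cli
NULL

#' Build a validated pipeline configuration
#'
#' @param genome,gtf,tissue_counts,urine_counts,sample_sheet Input paths.
#' @param qpcr Optional long-format Ct table path (sample_id, group, gene,
#'   ct).
#' @param out_dir Output directory for stage artifacts.
#' @param min_lnc_length Minimum spliced lncRNA length, nt (strict;
#'   default 200).
#' @param orf_coding_threshold ORF-length predictor threshold, nt
#'   (default 300).
#' @param lfc_cutoff,p_cutoff DE cutoffs (|log2FC| >= 1 inclusive,
#'   p < 0.05 strict).
#' @param cis_window Cis-neighbor window, nt (default 100000, inclusive).
#' @param promoter_length Promoter window, nt (default 5000).
#' @param motif Motif word (default CAGACA).
#' @param motif_threshold Prioritization threshold on the motif count
#'   (strict >; default 4).
#' @param pseudocount RPKM pseudocount (default 0.25).
#' @param seed Seed echoed into the report.
#' @param both_strands Scan promoters on both strands?
#' @param bh_correction Use Benjamini-Hochberg adjusted p-values for
#'   significance?
#' @param scan_all_dysregulated Scan promoters of down-regulated lncRNAs
#'   too (default: up-regulated only)?
#' @param qpcr_reference Reference gene for tissue-style normalization.
#' @param qpcr_spike Optional spike-in id; when set, a spike-normalized
#'   summary is also produced.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(genome, gtf, tissue_counts, urine_counts,
                            sample_sheet, qpcr = NULL,
                            out_dir = tempfile("lncfibro_run_"),
                            min_lnc_length = 200, orf_coding_threshold = 300,
                            lfc_cutoff = 1, p_cutoff = 0.05,
                            cis_window = 100000, promoter_length = 5000,
                            motif = "CAGACA", motif_threshold = 4,
                            pseudocount = 0.25, seed = 1,
                            both_strands = FALSE, bh_correction = FALSE,
                            scan_all_dysregulated = FALSE,
                            qpcr_reference = "GAPDH", qpcr_spike = NULL) {
  cfg <- list(genome = genome, gtf = gtf, tissue_counts = tissue_counts,
              urine_counts = urine_counts, sample_sheet = sample_sheet,
              qpcr = qpcr, out_dir = out_dir,
              min_lnc_length = min_lnc_length,
              orf_coding_threshold = orf_coding_threshold,
              lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff,
              cis_window = cis_window, promoter_length = promoter_length,
              motif = motif, motif_threshold = motif_threshold,
              pseudocount = pseudocount, seed = seed,
              both_strands = both_strands, bh_correction = bh_correction,
              scan_all_dysregulated = scan_all_dysregulated,
              qpcr_reference = qpcr_reference, qpcr_spike = qpcr_spike)
  for (p in c("genome", "gtf", "tissue_counts", "urine_counts",
              "sample_sheet")) {
    if (!file.exists(cfg[[p]])) {
      stop("config validation: ", p, " file not found: ", cfg[[p]])
    }
  }
  if (!is.null(qpcr) && !file.exists(qpcr)) {
    stop("config validation: qpcr file not found: ", qpcr)
  }
  num <- c("min_lnc_length", "orf_coding_threshold", "lfc_cutoff", "p_cutoff",
           "cis_window", "promoter_length", "motif_threshold")
  for (p in num) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) {
      stop("config validation: ", p, " must be positive")
    }
  }
  if (pseudocount < 0) stop("config validation: pseudocount must be >= 0")
  if (grepl("[^ACGT]", motif) || !nzchar(motif)) {
    stop("config validation: motif must be a word over A,C,G,T")
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match \code{\link{pipeline_config}}
#'   arguments.
#' @return A validated \code{pipeline_config}.
#' @export
pipeline_config_from_yaml <- function(path) {
  do.call(pipeline_config, read_yaml(path))
}

stage_banner <- function(name) message("[lncfibro] stage: ", name)

#' Run the full pipeline
#'
#' Stage order: input parsing -> consensus lncRNA filter -> DE (tissue) ->
#' DE (urine) -> cis neighbors of all dysregulated lncRNA genes ->
#' promoter Smad3 scan of up-regulated lncRNA genes -> prioritization ->
#' tissue-urine concordance -> optional qPCR quantification. A failing
#' stage aborts with a stage-named error; all artifacts land in
#' \code{config$out_dir}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The run report (list), invisibly the same object written to
#'   \code{report.json}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  with_stage <- function(name, expr) {
    stage_banner(name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- with_stage("read-inputs", {
    genome <- read_fasta(config$genome)
    models <- read_gtf(config$gtf)
    tissue <- read_counts(config$tissue_counts, config$sample_sheet, models)
    urine <- read_counts(config$urine_counts, config$sample_sheet, models)
    list(genome = genome, models = models, tissue = tissue, urine = urine)
  })
  models <- inputs$models
  lengths <- setNames(models$transcripts$exonic_length,
                      models$transcripts$transcript_id)

  filt <- with_stage("lncrna-filter", {
    noncoding_pool <- models$transcripts[
      models$transcripts$biotype != "protein_coding", , drop = FALSE]
    seqs <- extract_transcript_sequences(models, inputs$genome)
    calls <- orf_coding_calls(seqs[noncoding_pool$transcript_id],
                              threshold = config$orf_coding_threshold)
    res <- consensus_lnc_filter(noncoding_pool, calls,
                                min_length = config$min_lnc_length)
    n_cand <- length(res$candidate_ids)
    status <- rbind(
      data.frame(transcript_id = res$candidate_ids,
                 status = rep("candidate", n_cand),
                 reason = rep("", n_cand), stringsAsFactors = FALSE),
      data.frame(transcript_id = res$removed$transcript_id,
                 status = rep("removed", nrow(res$removed)),
                 reason = res$removed$reason, stringsAsFactors = FALSE)
    )
    write.table(status, out("lnc_candidates.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res
  })
  candidates <- filt$candidate_ids

  de <- with_stage("differential-expression", {
    de_tissue <- call_de(inputs$tissue, lengths, config$lfc_cutoff,
                         config$p_cutoff, config$pseudocount,
                         bh = config$bh_correction)
    de_urine <- call_de(inputs$urine, lengths, config$lfc_cutoff,
                        config$p_cutoff, config$pseudocount,
                        bh = config$bh_correction)
    write.table(de_tissue, out("de_tissue.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(de_urine, out("de_urine.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(tissue = de_tissue, urine = de_urine)
  })

  tx2gene <- setNames(models$transcripts$gene_id,
                      models$transcripts$transcript_id)
  sig_tissue <- de$tissue[de$tissue$significant &
                            de$tissue$transcript_id %in% candidates, ]
  dysreg_lnc_genes <- unique(tx2gene[sig_tissue$transcript_id])
  up_lnc_genes <- unique(tx2gene[sig_tissue$transcript_id[
    sig_tissue$direction == "up"]])

  cis <- with_stage("cis-neighbors", {
    lnc_rows <- models$genes[models$genes$gene_id %in% dysreg_lnc_genes, ]
    coding_rows <- models$genes[models$genes$biotype == "protein_coding", ]
    pairs <- find_cis_neighbors(lnc_rows, coding_rows,
                                window = config$cis_window)
    write.table(pairs, out("cis_pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pairs
  })

  scan <- with_stage("smad-scan", {
    target_genes <- if (config$scan_all_dysregulated) dysreg_lnc_genes
                    else up_lnc_genes
    gene_rows <- models$genes[models$genes$gene_id %in% target_genes, ]
    if (nrow(gene_rows) == 0) {
      res <- data.frame(gene_id = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), clipped = logical(),
                        k = integer(), prioritized = logical())
    } else {
      res <- scan_promoters(gene_rows, inputs$genome, motif = config$motif,
                            promoter_length = config$promoter_length,
                            threshold = config$motif_threshold,
                            include_reverse_complement = config$both_strands)
    }
    if (nrow(res)) {
      write_bed(data.frame(contig = res$contig, start = res$start,
                           end = res$end, name = res$gene_id, score = res$k,
                           strand = res$strand), out("promoters.bed"))
      mlen <- nchar(config$motif)
      hit_rows <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
        pos <- res$hit_positions[[i]]
        if (length(pos) == 0) return(NULL)
        gstart <- if (res$strand[i] == "+") res$start[i] + pos
                  else res$end[i] - pos - mlen
        data.frame(contig = res$contig[i], start = gstart,
                   end = gstart + mlen, name = res$gene_id[i], score = 0,
                   strand = res$strand[i], stringsAsFactors = FALSE)
      }))
      if (!is.null(hit_rows)) write_bed(hit_rows, out("motif_hits.bed"))
    }
    write.table(res[, c("gene_id", "k", "prioritized")], out("smad_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  prioritized <- prioritize_tgfb_candidates(
    scan[, c("gene_id", "k")], threshold = config$motif_threshold)

  conc <- with_stage("concordance", {
    tis <- de$tissue[de$tissue$transcript_id %in% candidates, ]
    uri <- de$urine[de$urine$transcript_id %in% candidates, ]
    cc <- concordant_biomarkers(tis, uri)
    write.table(cc, out("concordant_biomarkers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cc
  })

  qpcr_summary <- NULL
  if (!is.null(config$qpcr)) {
    qpcr_summary <- with_stage("qpcr", {
      tab <- read.delim(config$qpcr, stringsAsFactors = FALSE,
                        check.names = FALSE)
      res <- delta_delta_ct(tab, reference_gene = config$qpcr_reference)
      if (!is.null(config$qpcr_spike)) {
        spike <- spike_in_normalize(tab, spike_id = config$qpcr_spike)
        res$summary <- rbind(res$summary, spike$summary)
        res$records <- rbind(res$records, spike$records)
      }
      write.table(res$records, out("qpcr_per_sample.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(res$summary, out("qpcr_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res$summary
    })
  }

  # internal consistency of the run
  scan_scope <- if (config$scan_all_dysregulated) dysreg_lnc_genes
                else up_lnc_genes
  stopifnot(all(prioritized %in% scan_scope),
            all(cis$lnc_gene_id %in% dysreg_lnc_genes),
            all(conc$transcript_id %in%
                  intersect(de$tissue$transcript_id[de$tissue$significant],
                            de$urine$transcript_id[de$urine$significant])))

  lnc_dir <- function(det) {
    sig <- det[det$significant & det$transcript_id %in% candidates, ]
    c(up = sum(sig$direction == "up"), down = sum(sig$direction == "down"))
  }
  report <- list(
    package_version = as.character(utils::packageVersion("lncfibro")),
    seed = config$seed,
    parameters = config[c("min_lnc_length", "orf_coding_threshold",
                          "lfc_cutoff", "p_cutoff", "cis_window",
                          "promoter_length", "motif", "motif_threshold",
                          "pseudocount", "both_strands", "bh_correction",
                          "scan_all_dysregulated")],
    n_transcripts = nrow(models$transcripts),
    n_lnc_candidates = length(candidates),
    tissue = list(n_up = attr(de$tissue, "n_up"),
                  n_down = attr(de$tissue, "n_down"),
                  n_lnc_up = unname(lnc_dir(de$tissue)["up"]),
                  n_lnc_down = unname(lnc_dir(de$tissue)["down"])),
    urine = list(n_up = attr(de$urine, "n_up"),
                 n_down = attr(de$urine, "n_down"),
                 n_lnc_up = unname(lnc_dir(de$urine)["up"]),
                 n_lnc_down = unname(lnc_dir(de$urine)["down"])),
    n_cis_pairs = nrow(cis),
    n_prioritized = length(prioritized),
    prioritized = as.list(prioritized),
    n_concordant = sum(conc$concordant),
    n_concordant_up = attr(conc, "n_concordant_up"),
    n_concordant_down = attr(conc, "n_concordant_down")
  )
  write_json(report, out("report.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  report$de_tissue <- de$tissue
  report$de_urine <- de$urine
  report$cis_pairs <- cis
  report$smad_scan <- scan
  report$concordance <- conc
  report$lnc_candidates <- candidates
  report$qpcr_summary <- qpcr_summary
  invisible(report)
}
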