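#' @title Annotation, genome and count-table input/output
#'
#' @description Readers and writers for the standard formats the pipeline
#' touches (FASTA, GTF, BED6, TSV count matrices). All internal coordinates
#' are 0-based half-open; the GTF boundary performs the +/-1 conversion so
#' interval arithmetic inside the package is uniform.
#'
#' @name io_formats
NULL

BIOTYPE_LEVELS <- c("protein_coding", "lncRNA_candidate", "other")

# Map GTF biotype attribute values onto the internal three-level scheme.
map_biotype <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("other", length(x))
  out[x == "protein_coding"] <- "protein_coding"
  out[x %in% c("lncrna", "lincrna", "lnc_rna", "lncrna_candidate")] <-
    "lncRNA_candidate"
  out
}

biotype_to_gtf <- function(x) {
  c(protein_coding = "protein_coding",
    lncRNA_candidate = "lncRNA",
    other = "misc_RNA")[x]
}

#' Assemble a gene_models object from exon-level tables
#'
#' A \code{gene_models} object groups transcripts under genes and carries
#' three data frames: \code{$genes} (gene_id, contig, strand, start, end,
#' tss, biotype), \code{$transcripts} (transcript_id, gene_id, contig,
#' strand, biotype, exonic_length) and \code{$exons} (transcript_id,
#' gene_id, contig, strand, start, end). Coordinates are 0-based half-open.
#' The TSS of a multi-isoform gene is the most 5' transcript start across
#' isoforms (strand-aware): span start on + and span end - 1 on -.
#'
#' @param exons data.frame with columns transcript_id, gene_id, contig,
#'   strand, start, end (0-based half-open) and optionally biotype.
#' @return A \code{gene_models} object.
#' @export
gene_models <- function(exons) {
  req <- c("transcript_id", "gene_id", "contig", "strand", "start", "end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols)) {
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("exon strand must be '+' or '-'")
  }
  if (any(exons$end <= exons$start)) {
    stop("exon with end <= start")
  }
  if (is.null(exons$biotype)) exons$biotype <- "other"
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  # per-transcript: sorted, non-overlapping exons; exonic length
  tx_split <- split(exons, exons$transcript_id)
  for (tx in tx_split) {
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)])) {
      stop("overlapping exons in transcript ", tx$transcript_id[1])
    }
    if (length(unique(tx$strand)) != 1 || length(unique(tx$contig)) != 1) {
      stop("inconsistent strand/contig in transcript ", tx$transcript_id[1])
    }
  }
  transcripts <- do.call(rbind, lapply(tx_split, function(tx) {
    data.frame(transcript_id = tx$transcript_id[1],
               gene_id = tx$gene_id[1],
               contig = tx$contig[1],
               strand = tx$strand[1],
               biotype = tx$biotype[1],
               exonic_length = sum(tx$end - tx$start),
               stringsAsFactors = FALSE)
  }))
  rownames(transcripts) <- NULL

  gene_split <- split(exons, exons$gene_id)
  genes <- do.call(rbind, lapply(gene_split, function(gx) {
    strand <- gx$strand[1]
    span_start <- min(gx$start)
    span_end <- max(gx$end)
    bt <- unique(gx$biotype)
    biotype <- if ("protein_coding" %in% bt) "protein_coding"
               else if ("lncRNA_candidate" %in% bt) "lncRNA_candidate"
               else "other"
    data.frame(gene_id = gx$gene_id[1],
               contig = gx$contig[1],
               strand = strand,
               start = span_start,
               end = span_end,
               tss = if (strand == "+") span_start else span_end - 1L,
               biotype = biotype,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  print(table(x$transcripts$biotype))
  invisible(x)
}

#' Read a GTF annotation into gene models
#'
#' Parses exon features of an Ensembl-style GTF (1-based, closed intervals)
#' and converts them to the internal 0-based half-open convention.
#' Transcript biotype is taken from the \code{transcript_biotype} (or
#' \code{gene_biotype}) attribute when present; unknown values map to
#' \code{"other"}.
#'
#' @param path Path to a GTF file.
#' @return A \code{\link{gene_models}} object.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("malformed GTF line ", i, " in ", path)
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[mcols(gr)$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  tx_id <- as.character(mcols(gr)$transcript_id)
  if (any(is.na(tx_id) | !nzchar(tx_id))) {
    stop("exon feature without transcript_id in ", path)
  }
  gene_id <- as.character(mcols(gr)$gene_id)
  bt_raw <- mcols(gr)$transcript_biotype %||% mcols(gr)$gene_biotype %||%
    rep(NA_character_, length(gr))
  exons <- data.frame(
    transcript_id = tx_id,
    gene_id = gene_id,
    contig = as.character(seqnames(gr)),
    strand = as.character(strand(gr)),
    start = start(gr) - 1L,   # 1-based closed -> 0-based half-open
    end = end(gr),
    biotype = map_biotype(bt_raw),
    stringsAsFactors = FALSE
  )
  gene_models(exons)
}

#' Write gene models to a GTF file
#'
#' Emits exon features only (sufficient to round-trip through
#' \code{\link{read_gtf}}), converting back to 1-based closed coordinates.
#'
#' @param models A \code{\link{gene_models}} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  gr <- GRanges(
    seqnames = ex$contig,
    ranges = IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  mcols(gr)$source <- "lncfibro"
  mcols(gr)$type <- "exon"
  mcols(gr)$gene_id <- ex$gene_id
  mcols(gr)$transcript_id <- ex$transcript_id
  mcols(gr)$transcript_biotype <- unname(biotype_to_gtf(ex$biotype))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path Path to a FASTA file.
#' @return A \code{Biostrings::DNAStringSet}, uppercased, with contig names
#'   truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  seqs <- readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig name in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs
}

#' Write a genome FASTA
#'
#' @param seqs Named character vector or \code{DNAStringSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(unlist(seqs))
  writeXStringSet(seqs, path)
  invisible(path)
}

normalize_condition <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- c(uuo = "UUO", sham = "Sham")[key]
  if (any(is.na(out))) {
    stop("unknown condition value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected UUO or Sham)")
  }
  unname(out)
}

normalize_compartment <- function(x) {
  key <- tolower(trimws(as.character(x)))
  if (!all(key %in% c("tissue", "urine"))) {
    stop("unknown compartment value(s): ",
         paste(unique(x[!key %in% c("tissue", "urine")]), collapse = ", "))
  }
  key
}

#' Read a transcript count matrix with its sample sheet
#'
#' The count TSV has a \code{transcript_id} column plus one integer column
#' per sample; the sample sheet maps each sample to condition (UUO/Sham,
#' case-insensitive), compartment (tissue/urine) and replicate. Library
#' size is computed per sample as the column sum and stored in
#' \code{colData()$library_size}.
#'
#' @param path Count matrix TSV.
#' @param sample_sheet_path Sample sheet TSV with columns sample,
#'   condition, compartment, replicate.
#' @param annotation Optional \code{\link{gene_models}}; transcripts absent
#'   from it are retained but flagged \code{unannotated} in \code{rowData()}
#'   with a warning.
#' @return A \code{SummarizedExperiment} with a \code{counts} assay.
#' @export
read_counts <- function(path, sample_sheet_path, annotation = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"transcript_id" %in% names(tab)) {
    stop("count table lacks a transcript_id column: ", path)
  }
  ids <- tab$transcript_id
  mat <- as.matrix(tab[setdiff(names(tab), "transcript_id")])
  if (any(is.na(mat)) || any(mat < 0) || any(mat != floor(mat))) {
    stop("counts must be non-negative integers in ", path)
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids

  sheet <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  req <- c("sample", "condition", "compartment", "replicate")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  }
  missing_samples <- setdiff(colnames(mat), sheet$sample)
  if (length(missing_samples)) {
    stop("samples missing from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  }
  sheet <- sheet[match(colnames(mat), sheet$sample), , drop = FALSE]
  cd <- DataFrame(
    condition = normalize_condition(sheet$condition),
    compartment = normalize_compartment(sheet$compartment),
    replicate = sheet$replicate,
    library_size = colSums(mat),
    row.names = colnames(mat)
  )
  rd <- DataFrame(transcript_id = ids, row.names = ids)
  if (!is.null(annotation)) {
    rd$unannotated <- !(ids %in% annotation$transcripts$transcript_id)
    if (any(rd$unannotated)) {
      warning(sum(rd$unannotated),
              " transcript(s) absent from the annotation, flagged unannotated")
    }
  }
  SummarizedExperiment(assays = list(counts = mat), colData = cd,
                       rowData = rd)
}

#' Write intervals as BED6
#'
#' @param intervals data.frame with columns contig, start, end, name,
#'   score, strand (0-based half-open, the native BED convention).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end)) {
    stop("BED interval with start >= end")
  }
  cols <- c("contig", "start", "end", "name", "score", "strand")
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED6 path.
#' @return data.frame with contig, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("contig", "start", "end", "name", "score", "strand")
  tab
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts, yielding each transcript's sequence
#' in transcription orientation.
#'
#' @param models A \code{\link{gene_models}} object.
#' @param genome A \code{DNAStringSet} keyed by contig name.
#' @return Named character vector of spliced sequences.
#' @export
extract_transcript_sequences <- function(models, genome) {
  genome_chr <- setNames(as.character(genome), names(genome))
  out <- vapply(split(models$exons, models$exons$transcript_id), function(tx) {
    contig <- genome_chr[[tx$contig[1]]]
    if (is.null(contig)) stop("contig not in genome: ", tx$contig[1])
    pieces <- substring(contig, tx$start + 1L, tx$end)
    s <- paste(pieces, collapse = "")
    if (tx$strand[1] == "-") s <- revcomp(s)
    s
  }, character(1))
  out
}
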