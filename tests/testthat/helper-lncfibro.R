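# Shared fixtures and independent brute-force oracles.

# --- oracles -----------------------------------------------------------

# All-offsets substring comparison; 0-based positions of exact matches.
bf_scan <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(integer(0))
  idx <- seq_len(n - m + 1)
  which(substring(seq, idx, idx + m - 1) == motif) - 1L
}

# O(n*m) all-pairs cis search on gene span tables.
bf_cis <- function(lnc, coding, window = 100000) {
  rows <- list()
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(coding))) {
      if (lnc$contig[i] != coding$contig[j]) next
      d <- max(0, max(lnc$start[i], coding$start[j]) -
                 min(lnc$end[i], coding$end[j]))
      if (d > window) next
      rows[[length(rows) + 1]] <- data.frame(
        lnc_gene_id = lnc$gene_id[i], coding_gene_id = coding$gene_id[j],
        distance = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(lnc_gene_id = character(), coding_gene_id = character(),
                      distance = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lnc_gene_id, out$coding_gene_id), ]
  rownames(out) <- NULL
  out
}

# Independent ORF oracle: walk codons from every ATG.
bf_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  if (n < 6) return(best)
  for (i in seq_len(n - 5)) {
    if (substring(seq, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      cod <- substring(seq, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2 - i + 1L)
        break
      }
      j <- j + 3
    }
  }
  best
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random gene-span table on a single contig.
rand_gene_table <- function(n, prefix, contig = "chr1", max_pos = 4e5) {
  start <- sample.int(max_pos, n)
  len <- sample(200:5000, n, replace = TRUE)
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
             contig = contig, strand = sample(c("+", "-"), n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# --- synthetic configs scaled for tests --------------------------------

tiny_synth_config <- function(seed = 7, ...) {
  synthetic_config(
    seed = seed, n_lnc_genes = 24, n_coding_genes = 6,
    n_de_lnc_up = 4, n_de_lnc_down = 4, n_de_mrna = 2,
    urine_up_shared = 2, urine_down_shared = 1, urine_discordant = 1,
    urine_only_up = 2, urine_only_down = 1, ...
  )
}

small_synth_config <- function(seed = 11, ...) {
  synthetic_config(
    seed = seed, n_lnc_genes = 150, n_coding_genes = 12,
    n_de_lnc_up = 8, n_de_lnc_down = 8, n_de_mrna = 4,
    urine_up_shared = 3, urine_down_shared = 2, urine_discordant = 1,
    urine_only_up = 3, urine_only_down = 2, ...
  )
}

# Build a SummarizedExperiment count container directly.
make_se <- function(counts, condition, compartment = "tissue",
                    replicate = NULL) {
  if (is.null(replicate)) replicate <- seq_along(condition)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      condition = condition, compartment = compartment,
      replicate = replicate, library_size = colSums(counts),
      row.names = colnames(counts))
  )
}

# Tiny GTF text writer for parser tests.
write_gtf_lines <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon <- function(contig, start1, end1, strand, gene, tx,
                     biotype = "lncRNA") {
  sprintf(paste0('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                 'transcript_id "%s"; transcript_biotype "%s";'),
          contig, start1, end1, strand, gene, tx, biotype)
}
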