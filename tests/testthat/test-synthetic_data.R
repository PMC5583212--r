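test_that("the generator is fully deterministic in (config, seed)", {
  cfg <- tiny_synth_config(seed = 5)
  d1 <- write_synthetic_dataset(cfg, file.path(tempdir(), "detA"))
  d2 <- write_synthetic_dataset(cfg, file.path(tempdir(), "detB"))
  for (f in names(d1$paths)) {
    expect_equal(unname(tools::md5sum(d1$paths[[f]])),
                 unname(tools::md5sum(d2$paths[[f]])), info = f)
  }
  d3 <- write_synthetic_dataset(tiny_synth_config(seed = 6),
                                file.path(tempdir(), "detC"))
  expect_false(tools::md5sum(d1$paths$genome) == tools::md5sum(d3$paths$genome))
})

test_that("planted cis gaps are measurable exactly from the emitted GTF", {
  layout <- data.frame(lnc = c("LNC001", "LNC002", "LNC003"),
                       coding = c("PCG001", "PCG002", "PCG003"),
                       gap = c(99999L, 100000L, 500L),
                       stringsAsFactors = FALSE)
  cfg <- tiny_synth_config(neighbor_layout = layout)
  gen <- generate_genome_and_annotation(cfg)
  path <- tempfile(fileext = ".gtf")
  write_gtf(gen$models, path)
  genes <- read_gtf(path)$genes
  for (r in seq_len(nrow(layout))) {
    a <- genes[genes$gene_id == layout$lnc[r], ]
    b <- genes[genes$gene_id == layout$coding[r], ]
    gap <- max(0, max(a$start, b$start) - min(a$end, b$end))
    expect_equal(gap, layout$gap[r], info = layout$lnc[r])
  }
  # truth mirrors the layout
  expect_equal(gen$truth$cis_pairs$distance, layout$gap)
})

test_that("designated promoters carry no unintended motifs", {
  counts <- setNames(c(0L, 0L, 3L), sprintf("LNC%03d", 1:3))
  cfg <- tiny_synth_config(seed = 19, planted_motif_counts = counts)
  gen <- generate_genome_and_annotation(cfg)
  genes <- gen$models$genes
  scan <- scan_promoters(genes[genes$gene_id %in% names(counts), ],
                         gen$genome)
  expect_equal(setNames(scan$k, scan$gene_id)[names(counts)],
               setNames(as.integer(counts), names(counts)))
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  sim <- simulate_null_counts(2000, replicates = 3, baseline_mean = 200,
                              dispersion = 1e-6, seed = 2)
  x <- as.vector(SummarizedExperiment::assay(sim$se, "counts"))
  expect_equal(var(x) / mean(x), 1, tolerance = 0.05)
  expect_error(simulate_null_counts(10, dispersion = 0), "positive")
})

test_that("planted effect sizes are recovered without bias", {
  set.seed(123)
  n <- 500
  case <- matrix(rnbinom(n * 3, mu = 200 * 2^2, size = 1 / 0.05), n)
  ctrl <- matrix(rnbinom(n * 3, mu = 200, size = 1 / 0.05), n)
  lfc <- log2_fold_change(rowMeans(case), rowMeans(ctrl))
  expect_equal(mean(lfc), 2, tolerance = 0.25)
})

test_that("urine and tissue counts are independent draws with own truth", {
  cfg <- tiny_synth_config(seed = 9)
  gen <- generate_genome_and_annotation(cfg)
  t1 <- simulate_counts(gen$truth, cfg, "tissue")
  u1 <- simulate_counts(gen$truth, cfg, "urine")
  expect_false(identical(SummarizedExperiment::assay(t1, "counts")[, 1],
                         SummarizedExperiment::assay(u1, "counts")[, 1]))
  # regenerating one compartment alone reproduces it exactly
  t2 <- simulate_counts(gen$truth, cfg, "tissue")
  expect_identical(SummarizedExperiment::assay(t1, "counts"),
                   SummarizedExperiment::assay(t2, "counts"))
  expect_error(
    simulate_counts(gen$truth, synthetic_config(nb_dispersion = 0)),
    "positive")
})

test_that("noiseless qPCR simulation inverts to the planted folds", {
  cfg <- tiny_synth_config(seed = 15)
  gen <- generate_genome_and_annotation(cfg)
  tab <- simulate_qpcr(gen$truth, cfg, noise_sd = 0)
  folds <- gen$truth$qpcr_true_folds
  res <- delta_delta_ct(tab, reference_gene = "GAPDH",
                        targets = names(folds))
  uuo <- res$summary[res$summary$group == "UUO", ]
  expect_equal(setNames(uuo$mean_fold, uuo$target)[names(folds)],
               folds, tolerance = 1e-12)
  spike <- spike_in_normalize(tab, targets = names(folds))
  suuo <- spike$summary[spike$summary$group == "UUO", ]
  expect_equal(setNames(suuo$mean_fold, suuo$target)[names(folds)],
               folds, tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_lnc_genes = 10, n_de_lnc_up = 8,
                                n_de_lnc_down = 8), "exceeds")
  expect_error(tiny_synth_config(
    neighbor_layout = data.frame(lnc = "LNC001", coding = "NOPE",
                                 gap = 10L)), "unknown gene ids")
  expect_error(tiny_synth_config(
    neighbor_layout = data.frame(lnc = "LNC001", coding = "PCG001",
                                 gap = 100001L)), "100000")
  cfg <- tiny_synth_config(contig_length = 1000)
  expect_error(generate_genome_and_annotation(cfg), "contig_length")
})
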