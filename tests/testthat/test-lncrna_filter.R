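test_that("longest ORF length matches hand-checked cases", {
  expect_equal(longest_orf_length("ATGAAATAG"), 9)
  expect_equal(longest_orf_length("CCCCCC"), 0)
  expect_equal(longest_orf_length("ATGTAA"), 6)
  expect_equal(longest_orf_length(""), 0)
  # ORF must be in-frame: stop out of frame does not terminate
  expect_equal(longest_orf_length("ATGATAAGCTAA"), 12)
})

test_that("longest ORF agrees with a codon-walking oracle", {
  set.seed(42)
  for (i in 1:300) {
    s <- rand_dna(sample(10:200, 1))
    expect_equal(longest_orf_length(s), bf_orf(s), info = s)
  }
})

test_that("hexamer bias score follows the log-ratio definition", {
  hexamers <- apply(expand.grid(rep(list(c("A","C","G","T")), 6)),
                    1, paste, collapse = "")
  u <- setNames(rep(1/4096, 4096), hexamers)
  expect_equal(hexamer_bias_score("ACGTACGTACGT", u, u), 0)
  expect_equal(hexamer_bias_score("ACGTA", u, u), 0)

  coding <- u
  coding["AAAAAA"] <- 2 * u[["AAAAAA"]]
  others <- setdiff(hexamers, c("AAAAAA"))
  coding[others] <- coding[others] - u[["AAAAAA"]] / length(others)
  expect_equal(sum(coding), 1)
  # 12 nt of A: in-frame hexamers at offsets 0,3,6 are all AAAAAA
  expect_equal(hexamer_bias_score("AAAAAAAAAAAA", coding, u), log(2))

  bad <- u[-1]
  expect_error(hexamer_bias_score("ACGTACGTACGT", bad, u), "4096")
})

test_that("union-removal consensus rule and length boundary are exact", {
  tx <- data.frame(
    transcript_id = c("short", "edge200", "edge201", "coded", "clean"),
    exonic_length = c(150, 200, 201, 500, 500),
    stringsAsFactors = FALSE)
  calls <- expand.grid(
    transcript_id = tx$transcript_id,
    predictor_name = c("p1", "p2", "p3", "p4"),
    stringsAsFactors = FALSE)
  calls$score <- 0
  calls$is_coding <- FALSE
  # one of four predictors flags "coded"; "short" is flagged by all four
  calls$is_coding[calls$transcript_id == "coded" &
                    calls$predictor_name == "p2"] <- TRUE
  calls$is_coding[calls$transcript_id == "short"] <- TRUE

  res <- consensus_lnc_filter(tx, calls, min_length = 200)
  expect_setequal(res$candidate_ids, c("edge201", "clean"))
  rem <- setNames(res$removed$reason, res$removed$transcript_id)
  expect_equal(rem[["short"]], "too_short")  # precedence over coding_by
  expect_equal(rem[["edge200"]], "too_short")
  expect_equal(rem[["coded"]], "coding_by:p2")

  expect_error(consensus_lnc_filter(tx, calls[calls$transcript_id != "clean", ]),
               "without any predictor call")
})

test_that("filter partitions the input and is monotone in predictors", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    tx <- data.frame(transcript_id = sprintf("t%02d", 1:n),
                     exonic_length = sample(100:600, n, replace = TRUE),
                     stringsAsFactors = FALSE)
    preds <- c("a", "b", "c")
    calls <- expand.grid(transcript_id = tx$transcript_id,
                         predictor_name = preds, stringsAsFactors = FALSE)
    calls$score <- runif(nrow(calls))
    calls$is_coding <- calls$score > 0.7

    res_all <- consensus_lnc_filter(tx, calls)
    # partition: candidates and removed cover the input, disjointly
    expect_setequal(c(res_all$candidate_ids, res_all$removed$transcript_id),
                    tx$transcript_id)
    expect_length(intersect(res_all$candidate_ids,
                            res_all$removed$transcript_id), 0)
    # monotonicity: dropping a predictor can only grow the candidate set
    res_two <- consensus_lnc_filter(tx,
                                    calls[calls$predictor_name != "c", ])
    expect_true(all(res_all$candidate_ids %in% res_two$candidate_ids))
  }
})

test_that("built-in predictors recover planted coding/non-coding structure", {
  cfg <- tiny_synth_config()
  gen <- generate_genome_and_annotation(cfg)
  seqs <- extract_transcript_sequences(gen$models, gen$genome)
  calls <- orf_coding_calls(seqs, threshold = 300)
  res <- consensus_lnc_filter(gen$models$transcripts, calls)
  lnc_tx <- gen$models$transcripts$transcript_id[
    gen$models$transcripts$biotype == "lncRNA_candidate"]
  pcg_tx <- gen$models$transcripts$transcript_id[
    gen$models$transcripts$biotype == "protein_coding"]
  expect_setequal(res$candidate_ids, lnc_tx)
  expect_setequal(res$removed$transcript_id, pcg_tx)
  expect_true(all(grepl("^coding_by:", res$removed$reason)))
})
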