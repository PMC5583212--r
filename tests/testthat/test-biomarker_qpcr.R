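make_ct <- function(dct_sham, dct_uuo, target = "T1", ref = "GAPDH",
                    ref_ct = 20) {
  n1 <- length(dct_sham); n2 <- length(dct_uuo)
  samples <- c(paste0("S", seq_len(n1)), paste0("U", seq_len(n2)))
  groups <- c(rep("Sham", n1), rep("UUO", n2))
  rbind(
    data.frame(sample_id = samples, group = groups, gene = target,
               ct = ref_ct + c(dct_sham, dct_uuo), stringsAsFactors = FALSE),
    data.frame(sample_id = samples, group = groups, gene = ref,
               ct = ref_ct, stringsAsFactors = FALSE)
  )
}

test_that("ddCt arithmetic matches the Livak hand calculation", {
  # calibrator mean dCt = 6, treated dCt = 4 -> ddCt = -2, fold = 4
  tab <- make_ct(dct_sham = c(6, 6, 6), dct_uuo = c(4, 4, 4))
  res <- delta_delta_ct(tab, reference_gene = "GAPDH")
  uuo <- res$records[res$records$group == "UUO", ]
  expect_equal(uuo$delta_delta_ct, rep(-2, 3))
  expect_equal(uuo$fold, rep(4, 3))
  sham <- res$records[res$records$group == "Sham", ]
  expect_equal(sham$fold, rep(1, 3))  # samples at the calibrator mean

  flat <- make_ct(dct_sham = c(5, 5, 5), dct_uuo = c(5, 5, 5))
  rflat <- delta_delta_ct(flat, reference_gene = "GAPDH")
  expect_equal(rflat$records$fold, rep(1, 6))
  expect_equal(rflat$summary$p_value, c(1, 1))
})

test_that("calibrator geometric-mean fold is exactly 1", {
  set.seed(44)
  for (i in 1:10) {
    tab <- make_ct(dct_sham = rnorm(4, 6, 0.5), dct_uuo = rnorm(3, 4, 0.5))
    res <- delta_delta_ct(tab, reference_gene = "GAPDH")
    cal <- res$records[res$records$group == "Sham", ]
    expect_equal(exp(mean(log(cal$fold))), 1, tolerance = 1e-12)
    # reciprocal identity: swapping the calibrator inverts the group fold
    swapped <- delta_delta_ct(tab, reference_gene = "GAPDH",
                              calibrator_group = "UUO")
    g1 <- res$summary$geo_mean_fold[res$summary$group == "UUO"]
    g2 <- swapped$summary$geo_mean_fold[swapped$summary$group == "Sham"]
    expect_equal(g1 * g2, 1, tolerance = 1e-12)
  }
})

test_that("qPCR input contracts are enforced", {
  tab <- make_ct(c(6, 6), c(4, 4))
  expect_error(delta_delta_ct(tab[tab$gene != "GAPDH", ], "GAPDH"),
               "missing reference")
  bad <- tab; bad$ct[1] <- -1
  expect_error(delta_delta_ct(bad, "GAPDH"), "negative Ct")
  one <- make_ct(6, c(4, 4))
  expect_error(delta_delta_ct(one, "GAPDH"), ">= 2 samples")
})

test_that("spike-in normalization cancels global Ct shifts", {
  tab <- make_ct(c(6, 6.2, 5.8), c(4.1, 4, 3.9), ref = "cel-miR-39")
  base <- spike_in_normalize(tab)
  shifted <- tab
  shifted$ct[shifted$gene == "cel-miR-39"] <-
    shifted$ct[shifted$gene == "cel-miR-39"] + 1
  res <- spike_in_normalize(shifted)
  expect_equal(res$records$delta_ct, base$records$delta_ct - 1)
  expect_equal(res$records$delta_delta_ct, base$records$delta_delta_ct)
  expect_equal(res$records$fold, base$records$fold)
  expect_match(res$summary$normalization[1], "spike:cel-miR-39")

  missing <- tab[!(tab$gene == "cel-miR-39" & tab$sample_id == "U2"), ]
  expect_error(spike_in_normalize(missing), "U2")
})

test_that("concordance requires significance in both compartments", {
  de_row <- function(id, dir, sig = TRUE) {
    data.frame(transcript_id = id, mean_rpkm_uuo = 1, mean_rpkm_sham = 1,
               log2fc = ifelse(dir == "up", 2, -2) * sig, p_value = 0.01,
               direction = ifelse(sig, dir, "none"), significant = sig,
               stringsAsFactors = FALSE)
  }
  tissue <- rbind(de_row("a", "up"), de_row("b", "down"), de_row("c", "up"),
                  de_row("e", "up", sig = FALSE))
  urine <- rbind(de_row("a", "up"), de_row("b", "up"), de_row("d", "down"),
                 de_row("e", "up"))
  cc <- concordant_biomarkers(tissue, urine)
  expect_setequal(cc$transcript_id, c("a", "b"))  # c, d, e not in both
  expect_true(cc$concordant[cc$transcript_id == "a"])
  expect_false(cc$concordant[cc$transcript_id == "b"])
  expect_equal(attr(cc, "n_concordant_up"), 1)
  expect_equal(attr(cc, "n_concordant_down"), 0)
  expect_equal(nrow(concordant_biomarkers(tissue[0, ], urine)), 0)
})

test_that("concordance equals brute-force set logic on random instances", {
  set.seed(55)
  dirs <- c("up", "down")
  for (i in 1:20) {
    ids <- sprintf("t%02d", 1:30)
    mk <- function() {
      sig <- sample(c(TRUE, FALSE), 30, replace = TRUE)
      d <- ifelse(sig, sample(dirs, 30, replace = TRUE), "none")
      data.frame(transcript_id = ids, log2fc = 0, p_value = 0,
                 direction = d, significant = sig, stringsAsFactors = FALSE)
    }
    tis <- mk(); uri <- mk()
    cc <- concordant_biomarkers(tis, uri)
    both <- intersect(tis$transcript_id[tis$significant],
                      uri$transcript_id[uri$significant])
    expect_setequal(cc$transcript_id, both)
    for (id in both) {
      expect_equal(cc$concordant[cc$transcript_id == id],
                   tis$direction[tis$transcript_id == id] ==
                     uri$direction[uri$transcript_id == id])
    }
  }
})
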