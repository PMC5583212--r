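test_that("RPKM follows c * 1e9 / (N * L) and its conservation identity", {
  counts <- matrix(c(10, 999990), ncol = 1,
                   dimnames = list(c("t1", "t2"), "s1"))
  lengths <- c(t1 = 1000, t2 = 5000)
  rpkm <- compute_rpkm(counts, lengths)
  expect_equal(rpkm["t1", "s1"], 10)  # c=10, N=1e6, L=1000

  counts2 <- matrix(c(0, 100, 50, 25), 2,
                    dimnames = list(c("t1", "t2"), c("a", "b")))
  rpkm2 <- compute_rpkm(counts2, c(t1 = 300, t2 = 700))
  expect_equal(rpkm2["t1", "a"], 0)
  # doubling a sample's counts leaves its RPKM unchanged (N doubles too)
  expect_equal(compute_rpkm(counts2 * 2L, c(t1 = 300, t2 = 700)), rpkm2)

  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rpois(60, 50) + 1, 10)
    rownames(m) <- sprintf("t%02d", 1:10)
    colnames(m) <- sprintf("s%d", 1:6)
    L <- setNames(sample(200:3000, 10), rownames(m))
    r <- compute_rpkm(m, L)
    tot <- colSums(r * L)
    expect_true(all(abs(tot - 1e9) / 1e9 < 1e-9))
  }

  expect_error(compute_rpkm(counts, c(t1 = 1000)), "t2")
})

test_that("log2 fold change is antisymmetric with a guarded pseudocount", {
  expect_equal(log2_fold_change(8, 2, pseudocount = 0), 2)
  expect_equal(log2_fold_change(7, 7), 0)
  expect_equal(log2_fold_change(12, 3), -log2_fold_change(3, 12))
  expect_error(log2_fold_change(1, 1, pseudocount = -0.1), "non-negative")
})

test_that("Welch test on log2 RPKM matches stats::t.test and is NaN-free", {
  expect_equal(per_transcript_test(c(4, 4, 4), c(4, 4, 4)), 1)
  expect_equal(per_transcript_test(c(4, 4, 4), c(9, 9, 9)), 0)
  expect_lt(per_transcript_test(c(100, 110, 95), c(10, 12, 9)), 0.01)
  expect_error(per_transcript_test(c(1, 2), 5), "at least 2")

  set.seed(13)
  for (i in 1:25) {
    x <- rlnorm(sample(3:6, 1), 3, 1)
    y <- rlnorm(sample(3:6, 1), 3.5, 1)
    ours <- per_transcript_test(x, y, pseudocount = 0.25)
    ref <- t.test(log2(x + 0.25), log2(y + 0.25))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("DE caller applies inclusive lfc and strict p cutoffs", {
  # balanced library sizes so RPKM ratios equal count ratios exactly
  case <- c(400, 396, 204, 19000)  # filler row balances each column
  counts <- cbind(
    s1 = c(400, 396, 204, 19000), s2 = c(404, 400, 202, 18994),
    s3 = c(396, 392, 206, 19006),
    c1 = c(200, 200, 200, 19400), c2 = c(202, 202, 202, 19394),
    c3 = c(198, 198, 198, 19406))
  rownames(counts) <- c("exact2", "below2", "flat", "filler")
  expect_equal(unique(colSums(counts)), 20000)
  se <- make_se(counts, condition = rep(c("UUO", "Sham"), each = 3))
  L <- setNames(rep(1000, 4), rownames(counts))
  de <- call_de(se, L, pseudocount = 0)
  rec <- setNames(split(de, seq_len(nrow(de))), de$transcript_id)

  expect_equal(rec$exact2$log2fc, 1)          # ratio exactly 2
  expect_true(rec$exact2$significant)          # lfc cutoff is inclusive
  expect_equal(rec$exact2$direction, "up")
  expect_lt(rec$below2$p_value, 0.05)
  expect_lt(rec$below2$log2fc, 1)              # ratio 1.98 -> ~0.986
  expect_false(rec$below2$significant)         # fold-change gate holds
  expect_equal(rec$flat$direction, "none")

  # direction labels are consistent
  expect_true(all(de$direction[de$significant] %in% c("up", "down")))
  expect_true(all(de$direction[!de$significant] == "none"))
  expect_true(all(de$log2fc[de$direction == "up"] > 0))
})

test_that("swapping condition labels swaps up and down calls exactly", {
  sim <- simulate_null_counts(50, seed = 3)
  counts <- SummarizedExperiment::assay(sim$se, "counts")
  counts[1:5, 4:6] <- counts[1:5, 4:6] * 5L   # planted shift in UUO
  se1 <- make_se(counts, condition = rep(c("Sham", "UUO"), each = 3))
  se2 <- make_se(counts, condition = rep(c("UUO", "Sham"), each = 3))
  de1 <- call_de(se1, sim$lengths)
  de2 <- call_de(se2, sim$lengths)
  expect_equal(attr(de1, "n_up"), attr(de2, "n_down"))
  expect_equal(attr(de1, "n_down"), attr(de2, "n_up"))
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-12)
})

test_that("mixing compartments or missing replicates is refused", {
  counts <- matrix(10L, 4, 4,
                   dimnames = list(sprintf("t%d", 1:4), sprintf("s%d", 1:4)))
  se <- make_se(counts, condition = c("UUO", "UUO", "Sham", "Sham"),
                compartment = c("tissue", "urine", "tissue", "urine"))
  L <- setNames(rep(100, 4), rownames(counts))
  expect_error(call_de(se, L), "single compartment")
  se2 <- make_se(counts[, 1:3], condition = c("UUO", "Sham", "Sham"))
  expect_error(call_de(se2, setNames(rep(100, 4), rownames(counts))),
               ">= 2 replicates")
})
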