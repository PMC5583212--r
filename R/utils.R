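# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named random stream from the global
# seed, so each synthetic artifact (genome, tissue counts, urine counts,
# qPCR) can be regenerated independently. Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  offsets <- c(genome = 101L, tissue = 211L, urine = 307L, qpcr = 401L,
               null = 503L)
  if (!stream %in% names(offsets)) {
    stop("unknown random stream: ", stream)
  }
  as.integer((as.numeric(seed) %% 1e6) * 2011 + offsets[[stream]])
}

# Random DNA as a character vector of single bases (uppercase).
random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# Reverse complement of a plain character string (ACGTN alphabet).
revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Welch two-sample t-test returning a p-value that is never NaN:
# zero pooled variance collapses to p = 1 (equal means) or p = 0 (unequal).
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    return(if (mx == my) 1 else 0)
  }
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Row-wise Welch p-values for two matrices with matched rows.
welch_p_rows <- function(xmat, ymat) {
  nx <- ncol(xmat); ny <- ncol(ymat)
  mx <- rowMeans(xmat); my <- rowMeans(ymat)
  vx <- rowSums((xmat - mx)^2) / (nx - 1)
  vy <- rowSums((ymat - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  p <- rep(1, nrow(xmat))
  deg <- se2 == 0
  p[deg & mx != my] <- 0
  ok <- !deg
  if (any(ok)) {
    tstat <- (mx[ok] - my[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 / ((vx[ok] / nx)^2 / (nx - 1) + (vy[ok] / ny)^2 / (ny - 1))
    p[ok] <- 2 * stats::pt(-abs(tstat), df)
  }
  p
}
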