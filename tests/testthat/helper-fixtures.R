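# Shared fixture builders; everything is generated in code.

# Small sample sheet: nLakes lakes x 2 ecotypes x nPer individuals.
makeSamples <- function(nLakes = 2, nPer = 5, nLineages = 1) {
  lakes <- paste0("lk", seq_len(nLakes))
  lin <- rep(paste0("lin", seq_len(nLineages)),
             each = ceiling(nLakes / nLineages))[seq_len(nLakes)]
  df <- expand.grid(lake = lakes,
                    ecotype = c("planktivorous", "benthivorous"),
                    idx = seq_len(nPer), stringsAsFactors = FALSE)
  df <- df[order(df$lake, df$ecotype), ]
  df$lineage <- lin[match(df$lake, lakes)]
  df$id <- sprintf("i%03d", seq_len(nrow(df)))
  df$forkLength <- 200
  rownames(df) <- NULL
  df[, c("id", "lake", "lineage", "ecotype", "forkLength")]
}

# Expression matrix with planted correlated blocks driven by latent factors.
# Returns genes x samples plus the block membership.
makeBlockExpression <- function(nBlocks = 3, blockSize = 30, nNoise = 200,
                                nSamples = 40, withinR = 0.8, seed = 1) {
  set.seed(seed)
  nG <- nBlocks * blockSize + nNoise
  E <- matrix(rnorm(nG * nSamples), nG, nSamples)
  lambda <- sqrt(withinR)
  blocks <- rep(c(seq_len(nBlocks), 0),
                c(rep(blockSize, nBlocks), nNoise))
  for (bl in seq_len(nBlocks)) {
    f <- rnorm(nSamples)
    sel <- blocks == bl
    E[sel, ] <- lambda * matrix(f, sum(sel), nSamples, byrow = TRUE) +
      sqrt(1 - withinR) * matrix(rnorm(sum(sel) * nSamples),
                                 sum(sel), nSamples)
  }
  rownames(E) <- sprintf("g%04d", seq_len(nG))
  list(expr = E, blocks = setNames(blocks, rownames(E)))
}

# Independent re-derivation of the Weir & Cockerham (1984) estimator for two
# populations at one locus, written directly from the published component
# formulas; serves as the oracle for the vectorized implementation.
wcOracle <- function(gA, gB) {
  r <- 2
  n <- c(length(gA), length(gB))
  p <- c(sum(gA) / (2 * n[1]), sum(gB) / (2 * n[2]))
  h <- c(mean(gA == 1), mean(gB == 1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar / 4))
  bb <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a / (a + bb + cc)
}

# Exhaustive permutations of 1..n (n small).
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1)) for (i in seq_len(n)) {
    q <- integer(n)
    q[i] <- n
    q[-i] <- p
    out[[length(out) + 1]] <- q
  }
  out
}
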