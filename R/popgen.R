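## Per-group per-locus summaries used by the Weir-Cockerham machinery.
.groupSummary <- function(G) {
  n <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * n)
  h <- colSums(G == 1, na.rm = TRUE) / n
  list(n = n, p = p, h = h)
}

## Weir & Cockerham (1984) variance components a, b, c for two groups,
## vectorized over loci. Inputs are per-locus sample sizes (diploids),
## alternate-allele frequencies and observed heterozygote frequencies.
.wcComponents <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

.resolveRows <- function(ids, genotypes) {
  if (is.logical(ids)) which(ids)
  else if (is.character(ids)) match(ids, rownames(genotypes))
  else as.integer(ids)
}

#' Per-locus and genome-wide Weir-Cockerham Fst
#'
#' Computes the Weir & Cockerham (1984) theta-hat per locus from the
#' variance components a (among populations), b (among individuals within
#' populations) and c (within individuals), estimated from genotype counts
#' with observed heterozygote frequencies. The genome-wide estimate is the
#' ratio of sums `sum(a) / sum(a+b+c)`. Negative per-locus values are
#' retained (not clipped), so downstream quantiles and Z-standardization are
#' unbiased.
#'
#' @param genotypes matrix individuals x loci of dosages 0/1/2, NA missing.
#' @param groupA,groupB row indices, logicals or sample ids; must not
#'   overlap.
#' @param loci optional data.frame with chrom and pos (and other columns)
#'   carried into the scan.
#' @param pair label for the comparison.
#' @return An [FstScan-class]. Loci with fewer than 2 non-missing genotypes
#'   in either group, or no variation, get NA.
#' @export
wcFst <- function(genotypes, groupA, groupB, loci = NULL, pair = "A-B") {
  ia <- .resolveRows(groupA, genotypes)
  ib <- .resolveRows(groupB, genotypes)
  if (length(intersect(ia, ib))) stop("groups must not overlap")
  sa <- .groupSummary(genotypes[ia, , drop = FALSE])
  sb <- .groupSummary(genotypes[ib, , drop = FALSE])
  ok <- sa$n >= 2 & sb$n >= 2
  comp <- .wcComponents(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  den <- comp$a + comp$b + comp$c
  fst <- ifelse(ok & abs(den) > 1e-300, comp$a / den, NA_real_)
  usable <- ok & is.finite(comp$a) & is.finite(den) & abs(den) > 1e-300
  meanFst <- sum(comp$a[usable]) / sum(den[usable])
  if (is.null(loci))
    loci <- data.frame(snp = colnames(genotypes) %||%
                         paste0("snp", seq_len(ncol(genotypes))),
                       chrom = NA_character_, pos = NA_integer_)
  tab <- data.frame(loci, fst = fst, zfst = NA_real_, outlierEmp = NA,
                    zfstSignificant = NA, zfstReported = NA,
                    outlierPerm = NA)
  new("FstScan", loci = tab, meanFst = meanFst, permNull95 = NA_real_,
      pair = pair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical-quantile Fst outliers and Z-standardization
#'
#' Flags loci whose Fst lies strictly above the scan's 95th percentile
#' (`outlierEmp`), computes `ZFst = (Fst - mean) / sd` and flags ZFst > 4 as
#' significant and ZFst > 3 as reported.
#'
#' @param scan an [FstScan-class] with >= 20 loci with finite Fst.
#' @param quantile empirical outlier quantile (default 0.95).
#' @return The scan with outlier columns filled.
#' @export
fstOutliersEmpirical <- function(scan, quantile = 0.95) {
  f <- scan@loci$fst
  if (sum(is.finite(f)) < 20) stop("need >= 20 loci with finite Fst")
  q <- stats::quantile(f, quantile, na.rm = TRUE, names = FALSE)
  z <- (f - mean(f, na.rm = TRUE)) / sd(f, na.rm = TRUE)
  scan@loci$outlierEmp <- !is.na(f) & f > q
  scan@loci$zfst <- z
  scan@loci$zfstSignificant <- !is.na(z) & z > 4
  scan@loci$zfstReported <- !is.na(z) & z > 3
  scan
}

#' Neutral (non-outlier) locus set
#'
#' @param scan an [FstScan-class] after [fstOutliersEmpirical()].
#' @return Character vector of locus names not flagged as empirical
#'   outliers (NA-Fst loci excluded).
#' @export
neutralMask <- function(scan) {
  if (all(is.na(scan@loci$outlierEmp)))
    stop("run fstOutliersEmpirical() first")
  with(scan@loci, snp[!is.na(fst) & !outlierEmp])
}

#' Fst outliers against a permuted-panmixia null
#'
#' Builds a null Fst distribution by randomly re-assigning ecotype labels to
#' individuals within each lake (sample sizes preserved), recomputing the
#' per-locus Fst each time and pooling all permuted values into a single
#' null distribution. Loci whose empirical Fst exceeds the pooled null's
#' 95th percentile are flagged (`outlierPerm`).
#'
#' @param scan the empirical [FstScan-class] for the pair.
#' @param genotypes,groupA,groupB as in [wcFst()].
#' @param lake lake label per individual (row) of `genotypes`; permutation
#'   swaps labels only within lakes.
#' @param nPerm number of label permutations.
#' @param seed integer seed (required).
#' @param quantile null quantile (default 0.95).
#' @param perLocus if TRUE use a per-locus null quantile instead of the
#'   pooled distribution.
#' @return The scan with `outlierPerm` and `permNull95` filled.
#' @export
fstOutliersPermuted <- function(scan, genotypes, groupA, groupB, lake,
                                nPerm = 1000, seed, quantile = 0.95,
                                perLocus = FALSE) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(as.integer(seed))
  ia <- .resolveRows(groupA, genotypes)
  ib <- .resolveRows(groupB, genotypes)
  rows <- c(ia, ib)
  isB <- c(rep(FALSE, length(ia)), rep(TRUE, length(ib)))
  lk <- lake[rows]
  G <- genotypes[rows, , drop = FALSE]
  nullMat <- if (perLocus)
    matrix(NA_real_, nPerm, ncol(G)) else NULL
  pooled <- numeric(0)
  for (p in seq_len(nPerm)) {
    lab <- isB
    for (l in unique(lk)) {
      sel <- which(lk == l)
      lab[sel] <- sample(isB[sel])
    }
    f <- wcFst(G, which(!lab), which(lab))@loci$fst
    if (perLocus) nullMat[p, ] <- f else pooled <- c(pooled, f[!is.na(f)])
  }
  f <- scan@loci$fst
  if (perLocus) {
    thr <- apply(nullMat, 2, stats::quantile, probs = quantile,
                 na.rm = TRUE)
    scan@loci$outlierPerm <- !is.na(f) & f > thr
    scan@permNull95 <- stats::median(thr, na.rm = TRUE)
  } else {
    thr <- stats::quantile(pooled, quantile, names = FALSE)
    scan@loci$outlierPerm <- !is.na(f) & f > thr
    scan@permNull95 <- thr
  }
  scan
}

#' Per-site and per-population nucleotide diversity
#'
#' Per site, `pi = k (n - k) / choose(n, 2)` with n the number of non-missing
#' allele copies and k the alternate-allele count: the mean pairwise
#' difference among the sampled haplotypes. Population pi is the mean over
#' all scored sites (sites with fewer than 2 allele copies are skipped).
#'
#' @param genotypes matrix individuals x loci of dosages.
#' @param pop population label per individual.
#' @return A [DiversityResult-class].
#' @export
nucleotideDiversity <- function(genotypes, pop) {
  pop <- as.character(pop)
  pops <- unique(pop)
  sitePi <- matrix(NA_real_, ncol(genotypes), length(pops),
                   dimnames = list(colnames(genotypes), pops))
  for (pp in pops) {
    G <- genotypes[pop == pp, , drop = FALSE]
    if (nrow(G) < 2) stop("population ", pp, " has < 2 individuals")
    n <- 2 * colSums(!is.na(G))
    k <- colSums(G, na.rm = TRUE)
    pi <- ifelse(n >= 2, k * (n - k) / (n * (n - 1) / 2), NA_real_)
    sitePi[, pp] <- pi
  }
  popPi <- colMeans(sitePi, na.rm = TRUE)
  new("DiversityResult", popPi = popPi, sitePi = sitePi)
}

#' Per-locus diversity difference between two populations
#'
#' `deltaPi = pi_pop2 - pi_pop1` per locus, conventionally oriented with
#' pop1 = planktivorous so negative values mean diversity loss in the
#' derived ecotype.
#'
#' @param div a [DiversityResult-class].
#' @param pop2,pop1 population names.
#' @return Named numeric vector per locus.
#' @export
deltaPi <- function(div, pop2, pop1) {
  div@sitePi[, pop2] - div@sitePi[, pop1]
}

#' Resampling test of outlier/DEG sharing between two comparisons
#'
#' Draws `|A|` and `|B|` features with replacement from the universe
#' `nResample` times, and takes the mean number of shared (distinct)
#' features as the expected sharing under independence. Significance is a
#' two-sample proportion test of the observed vs expected shared counts
#' against the universe size.
#'
#' @param setA,setB character vectors of features, subsets of `universe`.
#' @param universe all features the sets were drawn from.
#' @param nResample number of resampling rounds (default 10000).
#' @param level feature level label: "snp", "contig" or "gene".
#' @param seed integer seed (required).
#' @return A [SharingResult-class].
#' @export
sharingTest <- function(setA, setB, universe, nResample = 10000,
                        level = c("snp", "contig", "gene"), seed) {
  level <- match.arg(level)
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (!length(universe)) stop("universe must be non-empty")
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  set.seed(as.integer(seed))
  obs <- length(intersect(setA, setB))
  nA <- length(setA); nB <- length(setB); U <- length(universe)
  shared <- integer(nResample)
  if (nA > 0 && nB > 0) {
    for (r in seq_len(nResample)) {
      a <- unique(sample(universe, nA, replace = TRUE))
      b <- unique(sample(universe, nB, replace = TRUE))
      shared[r] <- length(intersect(a, b))
    }
  }
  expected <- mean(shared)
  expRound <- round(expected)
  p <- if (obs == expRound) 1 else
    suppressWarnings(prop.test(c(obs, expRound), c(U, U))$p.value)
  new("SharingResult", observed = as.integer(obs), expected = expected,
      resampleQuantiles = stats::quantile(shared, c(.025, .5, .975)),
      p = p, level = level, nResample = as.integer(nResample),
      universeSize = as.integer(U), sizeA = as.integer(nA),
      sizeB = as.integer(nB))
}

#' Linkage-disequilibrium decay with physical distance
#'
#' r2 is the squared Pearson correlation of dosage vectors
#' (pairwise-complete); pairs are restricted to the same chromosome and
#' binned by distance. In focal mode only (focal locus, any locus) pairs are
#' used, giving decay with distance from Fst outliers.
#'
#' @param genotypes matrix individuals x loci of dosages.
#' @param loci data.frame with chrom, pos aligned with columns.
#' @param maxDist maximum pair distance (bp).
#' @param nBins number of equal-width distance bins.
#' @param focal optional character/integer set of focal loci.
#' @return An [LdResult-class].
#' @export
ldDecay <- function(genotypes, loci, maxDist = 1e6, nBins = 20,
                    focal = NULL) {
  if (is.character(focal)) focal <- match(focal, loci$snp)
  breaks <- seq(0, maxDist, length.out = nBins + 1)
  dAll <- numeric(0); r2All <- numeric(0)
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    if (length(idx) < 2) next
    v <- apply(genotypes[, idx, drop = FALSE], 2, var, na.rm = TRUE)
    idx <- idx[!is.na(v) & v > 0]
    if (length(idx) < 2) next
    cm <- suppressWarnings(
      cor(genotypes[, idx, drop = FALSE], use = "pairwise.complete.obs"))^2
    pos <- loci$pos[idx]
    dm <- abs(outer(pos, pos, "-"))
    keep <- upper.tri(dm) & dm > 0 & dm <= maxDist
    if (!is.null(focal)) {
      isFocal <- idx %in% focal
      keep <- keep & (outer(isFocal, isFocal, "|"))
    }
    dAll <- c(dAll, dm[keep])
    r2All <- c(r2All, cm[keep])
  }
  bin <- cut(dAll, breaks, include.lowest = TRUE)
  ok <- !is.na(r2All)
  bins <- data.frame(
    distLo = breaks[-length(breaks)], distHi = breaks[-1],
    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    meanR2 = as.numeric(tapply(r2All[ok], bin[ok], mean)[levels(bin)]),
    medianR2 = as.numeric(tapply(r2All[ok], bin[ok], median)[levels(bin)]),
    nPairs = as.integer(table(bin[ok])[levels(bin)]))
  new("LdResult", bins = bins, focal = !is.null(focal))
}

.blockJackknife <- function(num, den = NULL, blockSize) {
  L <- length(num)
  nBlocks <- floor(L / blockSize)
  ratio <- !is.null(den)
  full <- if (ratio) sum(num) / sum(den) else mean(num)
  if (nBlocks < 5) {
    warning("fewer than 5 jackknife blocks; Z not computed")
    return(list(value = full, Z = NA_real_, se = NA_real_,
                nBlocks = as.integer(nBlocks)))
  }
  blk <- rep(seq_len(nBlocks), each = blockSize, length.out = L)
  est <- vapply(seq_len(nBlocks), function(b) {
    keep <- blk != b
    if (ratio) sum(num[keep]) / sum(den[keep]) else mean(num[keep])
  }, 0)
  se <- sqrt((nBlocks - 1) / nBlocks * sum((est - mean(est))^2))
  list(value = full, Z = full / se, se = se,
       nBlocks = as.integer(nBlocks))
}

#' Patterson's D (ABBA-BABA) statistic
#'
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` over loci, with
#' `ABBA = (1-p1) p2 p3 (1-p4)` and `BABA = p1 (1-p2) p3 (1-p4)` from
#' alternate-allele frequencies in populations P1, P2, P3 and outgroup P4.
#' Z-score by leave-one-block-out jackknife.
#'
#' @param p1,p2,p3,p4 per-locus allele frequencies.
#' @param blockSize loci per jackknife block (default 200).
#' @return An [IntrogressionStats-class].
#' @export
pattersonD <- function(p1, p2, p3, p4, blockSize = 200) {
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  ok <- is.finite(abba) & is.finite(baba)
  abba <- abba[ok]; baba <- baba[ok]
  if (sum(abba + baba) == 0) stop("D undefined: ABBA + BABA sums to zero")
  jk <- .blockJackknife(abba - baba, abba + baba, blockSize)
  new("IntrogressionStats", stat = "D", value = jk$value, Z = jk$Z,
      se = jk$se, blockSize = as.integer(blockSize), nBlocks = jk$nBlocks)
}

#' f3 three-population statistic
#'
#' `f3(C; A, B) = mean[(c - a)(c - b)] - bias`, where the bias term corrects
#' for sampling noise in the target population C: per locus
#' `h_c / (2 n_c)` with `h_c` the unbiased heterozygosity
#' `2 c (1 - c) 2n_c / (2n_c - 1)` and `n_c` the number of diploid
#' individuals. A significantly negative value (jackknife Z <= -3) signals
#' that C is admixed between sources related to A and B.
#'
#' @param a,b,cc per-locus allele frequencies in A, B and target C.
#' @param nC diploid sample size(s) of C (scalar or per locus).
#' @param blockSize loci per jackknife block.
#' @param biasCorrection apply the within-C sampling-bias term.
#' @return An [IntrogressionStats-class].
#' @export
f3Stat <- function(a, b, cc, nC, blockSize = 200, biasCorrection = TRUE) {
  if (biasCorrection) {
    if (missing(nC)) stop("nC required for the bias correction")
    if (any(nC < 2)) stop("nC must be >= 2")
  }
  t0 <- (cc - a) * (cc - b)
  if (biasCorrection) {
    hc <- 2 * cc * (1 - cc) * (2 * nC) / (2 * nC - 1)
    t0 <- t0 - hc / (2 * nC)
  }
  ok <- is.finite(t0)
  jk <- .blockJackknife(t0[ok], NULL, blockSize)
  new("IntrogressionStats", stat = "f3", value = jk$value, Z = jk$Z,
      se = jk$se, blockSize = as.integer(blockSize), nBlocks = jk$nBlocks)
}

#' Impute missing genotypes by per-population mean dosage
#'
#' A documented simple scheme: each missing dosage is replaced by the mean
#' dosage of its population at that locus; a locus fully missing within a
#' population falls back to the global mean with a warning. Reports the
#' Pearson correlation between per-locus allele frequencies before and
#' after imputation as a sanity measure.
#'
#' @param genotypes matrix individuals x loci of dosages.
#' @param pop population label per individual.
#' @return list: `genotypes` (no missing values, fractional dosages),
#'   `freqCorrelation`.
#' @export
imputeMissing <- function(genotypes, pop) {
  pop <- as.character(pop)
  before <- colMeans(genotypes, na.rm = TRUE) / 2
  out <- genotypes
  globalMean <- colMeans(genotypes, na.rm = TRUE)
  usedGlobal <- FALSE
  for (pp in unique(pop)) {
    sel <- pop == pp
    G <- out[sel, , drop = FALSE]
    m <- colMeans(G, na.rm = TRUE)
    allMiss <- !is.finite(m)
    if (any(allMiss)) { m[allMiss] <- globalMean[allMiss]; usedGlobal <- TRUE }
    miss <- which(is.na(G), arr.ind = TRUE)
    if (nrow(miss)) G[miss] <- m[miss[, 2]]
    out[sel, ] <- G
  }
  if (usedGlobal)
    warning("locus fully missing in a population: global mean used")
  after <- colMeans(out) / 2
  fc <- if (sd(before) == 0 || sd(after) == 0) 1 else cor(before, after)
  list(genotypes = out, freqCorrelation = fc)
}

#' Genotype quality-control filters
#'
#' Applies, in order: per-population presence (locus scored in at least
#' `perPopPresence` of individuals within a population, in at least
#' `popFraction` of populations), global minor-allele frequency, maximum
#' observed heterozygosity, Hardy-Weinberg equilibrium (chi-square, 1 df;
#' P > `hweAlpha` required in at least `popFraction` of populations), and
#' one SNP per contig (first by position).
#'
#' @param genotypes matrix individuals x loci.
#' @param loci data.frame with snp, chrom, pos, contig.
#' @param pop population label per individual.
#' @param perPopPresence,popFraction,maf,maxHet,hweAlpha,oneSnpPerLocus
#'   thresholds.
#' @return list: `genotypes`, `loci` (filtered), `removed` (named counts
#'   per filter), `kept` (number of surviving loci). Empty output is an
#'   error naming the first exhausted filter.
#' @export
genotypeQC <- function(genotypes, loci, pop, perPopPresence = 0.66,
                       popFraction = 2 / 3, maf = 0.05, maxHet = 0.5,
                       hweAlpha = 0.05, oneSnpPerLocus = TRUE) {
  pop <- as.character(pop)
  pops <- unique(pop)
  needPops <- ceiling(popFraction * length(pops))
  keep <- rep(TRUE, ncol(genotypes))
  removed <- c(presence = 0L, maf = 0L, heterozygosity = 0L, hwe = 0L,
               oneSnpPerLocus = 0L)
  checkEmpty <- function(filterName) {
    if (!any(keep))
      stop("no loci left after filter: ", filterName)
  }

  presOk <- matrix(FALSE, length(pops), ncol(genotypes))
  hweOk <- matrix(FALSE, length(pops), ncol(genotypes))
  for (i in seq_along(pops)) {
    G <- genotypes[pop == pops[i], , drop = FALSE]
    n <- colSums(!is.na(G))
    presOk[i, ] <- n / nrow(G) >= perPopPresence
    n0 <- colSums(G == 0, na.rm = TRUE)
    n1 <- colSums(G == 1, na.rm = TRUE)
    n2 <- colSums(G == 2, na.rm = TRUE)
    p <- (n1 + 2 * n2) / (2 * pmax(n, 1))
    e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
    chi <- rep(0, ncol(G))
    for (oe in list(list(n0, e0), list(n1, e1), list(n2, e2))) {
      term <- ifelse(oe[[2]] > 1e-12, (oe[[1]] - oe[[2]])^2 / oe[[2]],
                     ifelse(oe[[1]] > 0, Inf, 0))
      chi <- chi + term
    }
    hweOk[i, ] <- pchisq(chi, 1, lower.tail = FALSE) > hweAlpha
  }
  f <- colSums(presOk) >= needPops
  removed["presence"] <- sum(keep & !f); keep <- keep & f
  checkEmpty("presence")

  p <- colMeans(genotypes, na.rm = TRUE) / 2
  f <- !is.na(p) & pmin(p, 1 - p) >= maf
  removed["maf"] <- sum(keep & !f); keep <- keep & f
  checkEmpty("maf")

  het <- colMeans(genotypes == 1, na.rm = TRUE)
  f <- !is.na(het) & het <= maxHet
  removed["heterozygosity"] <- sum(keep & !f); keep <- keep & f
  checkEmpty("heterozygosity")

  f <- colSums(hweOk) >= needPops
  removed["hwe"] <- sum(keep & !f); keep <- keep & f
  checkEmpty("hwe")

  if (oneSnpPerLocus) {
    ord <- order(loci$contig, loci$pos)
    firstIdx <- ord[!duplicated(loci$contig[ord])]
    f <- seq_len(ncol(genotypes)) %in% firstIdx
    removed["oneSnpPerLocus"] <- sum(keep & !f); keep <- keep & f
    checkEmpty("oneSnpPerLocus")
  }
  list(genotypes = genotypes[, keep, drop = FALSE],
       loci = loci[keep, , drop = FALSE], removed = removed,
       kept = sum(keep))
}

#' Per-population allele-frequency matrix
#'
#' Alternate-allele frequencies per population over all loci; the feature
#' matrix used for genetic trajectory analysis (populations as rows,
#' PCA-reduced downstream).
#'
#' @param genotypes matrix individuals x loci.
#' @param pop population label per individual.
#' @return matrix populations x loci of frequencies in [0, 1].
#' @export
alleleFreqMatrix <- function(genotypes, pop) {
  pop <- as.character(pop)
  t(vapply(unique(pop), function(pp) {
    G <- genotypes[pop == pp, , drop = FALSE]
    colMeans(G, na.rm = TRUE) / 2
  }, numeric(ncol(genotypes))))
}
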