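toyLoci <- function(n, chrom = "chr1", contig = NULL) {
  data.frame(snp = paste0("s", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * 1000,
             contig = contig %||% paste0("c", seq_len(n)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Weir-Cockerham Fst matches the independent component oracle", {
  gA <- c(0, 0, 1, 1, 2)
  gB <- c(1, 2, 2, 2, 2)
  G <- rbind(matrix(gA, 5, 1), matrix(gB, 5, 1))
  sc <- wcFst(G, 1:5, 6:10)
  expect_equal(fstTable(sc)$fst, wcOracle(gA, gB), tolerance = 1e-12)
  expect_equal(fstTable(sc)$fst, 0.353448275862, tolerance = 1e-9)
  # random genotype draws against the oracle, locus by locus
  set.seed(12)
  for (rep in 1:20) {
    a <- sample(0:2, 6, replace = TRUE)
    b <- sample(0:2, 7, replace = TRUE)
    if (var(c(a, b)) == 0) next
    sc <- wcFst(rbind(matrix(a, 6, 1), matrix(b, 7, 1)), 1:6, 7:13)
    expect_equal(fstTable(sc)$fst, wcOracle(a, b), tolerance = 1e-10)
  }
})

test_that("fixed differences give Fst 1; identical tables give <= 0", {
  G <- rbind(matrix(0, 5, 2), matrix(2, 5, 2))
  expect_equal(fstTable(wcFst(G, 1:5, 6:10))$fst, c(1, 1))
  G2 <- rbind(matrix(c(0, 1, 2, 1, 0), 5, 1),
              matrix(c(0, 1, 2, 1, 0), 5, 1))
  expect_lte(fstTable(wcFst(G2, 1:5, 6:10))$fst, 0)
  expect_error(wcFst(G, 1:5, 5:10), "overlap")
})

test_that("genome-wide ratio-of-sums lies within per-locus range and is
          invariant to locus order and allele swap", {
  set.seed(3)
  G <- matrix(rbinom(20 * 50, 2, runif(50, 0.2, 0.8)), 20, 50, byrow = TRUE)
  sc <- wcFst(G, 1:10, 11:20)
  f <- fstTable(sc)$fst
  expect_gte(genomeFst(sc), min(f, na.rm = TRUE))
  expect_lte(genomeFst(sc), max(f, na.rm = TRUE))
  perm <- sample(50)
  expect_equal(genomeFst(wcFst(G[, perm], 1:10, 11:20)), genomeFst(sc))
  expect_equal(genomeFst(wcFst(2 - G, 1:10, 11:20)), genomeFst(sc),
               tolerance = 1e-12)
})

test_that("nucleotide diversity equals mean pairwise haplotype difference", {
  # 2 diploids, one het, one hom ref: n = 4 alleles, k = 1 -> pi = 0.5
  G <- matrix(c(1, 0), 2, 1)
  d <- nucleotideDiversity(G, c("p", "p"))
  expect_equal(unname(d@sitePi[1, "p"]), 0.5)
  # monomorphic -> 0
  G2 <- matrix(2, 3, 2)
  expect_equal(unname(nucleotideDiversity(G2, rep("p", 3))@popPi["p"]), 0)
  # identical pops -> deltaPi 0 everywhere
  G3 <- rbind(matrix(c(0, 1, 2), 3, 4), matrix(c(0, 1, 2), 3, 4))
  d3 <- nucleotideDiversity(G3, rep(c("a", "b"), each = 3))
  expect_equal(unname(deltaPi(d3, "b", "a")), rep(0, 4))
})

test_that("empirical outliers follow the strict 95th-percentile rule", {
  set.seed(5)
  fst <- runif(100)
  sc <- new("FstScan",
            loci = data.frame(toyLoci(100), fst = fst, zfst = NA_real_,
                              outlierEmp = NA, zfstSignificant = NA,
                              zfstReported = NA, outlierPerm = NA),
            meanFst = mean(fst), permNull95 = NA_real_, pair = "t")
  sc <- fstOutliersEmpirical(sc)
  expect_equal(sum(fstTable(sc)$outlierEmp), 5)
  expect_equal(sort(fst[fstTable(sc)$outlierEmp], decreasing = TRUE),
               sort(fst, decreasing = TRUE)[1:5])
  # ties at a constant -> none strictly above
  sc@loci$fst <- rep(0.1, 100)
  expect_equal(sum(fstTable(fstOutliersEmpirical(sc))$outlierEmp), 0)
  # ZFst flags match direct standardization
  sc@loci$fst <- rnorm(100, 0.1, 0.02)
  sc <- fstOutliersEmpirical(sc)
  z <- (sc@loci$fst - mean(sc@loci$fst)) / sd(sc@loci$fst)
  expect_equal(sum(fstTable(sc)$zfstSignificant), sum(z > 4))
  expect_equal(sum(fstTable(sc)$zfstReported), sum(z > 3))
  expect_setequal(neutralMask(sc),
                  fstTable(sc)$snp[!fstTable(sc)$outlierEmp])
})

test_that("QC filters apply the stated thresholds", {
  set.seed(6)
  n <- 24
  pop <- rep(c("p1", "p2", "p3"), each = 8)
  # a fixed near-HWE genotype block per population (p = 0.375, observed
  # het 0.5) passes presence, MAF, heterozygosity and HWE deterministically
  hwCol <- function() rep(c(0, 0, 0, 1, 1, 1, 1, 2), 3)
  G <- vapply(1:6, function(i) hwCol(), numeric(n))
  colnames(G) <- paste0("s", 1:6)
  G[, 3] <- c(1, rep(0, n - 1))      # MAF ~0.02 -> removed by MAF
  G[sample(n, 12), 4] <- NA          # present in 50% -> presence filter
  G[, 5] <- 1                        # all het -> heterozygosity + HWE
  loci <- toyLoci(6)
  qc <- genotypeQC(G, loci, pop, oneSnpPerLocus = FALSE)
  expect_false("s3" %in% qc$loci$snp)
  expect_false("s4" %in% qc$loci$snp)
  expect_false("s5" %in% qc$loci$snp)
  expect_gt(qc$removed["maf"] + qc$removed["presence"] +
              qc$removed["heterozygosity"] + qc$removed["hwe"], 0)
  # an all-passing matrix comes back identical
  G2 <- vapply(1:5, function(i) hwCol(), numeric(n))
  colnames(G2) <- paste0("s", 1:5)
  qc2 <- genotypeQC(G2, toyLoci(5), pop, oneSnpPerLocus = FALSE)
  expect_identical(qc2$genotypes, G2)
  expect_true(all(qc2$removed == 0))
  # one SNP per contig keeps the first by position
  loci3 <- toyLoci(4, contig = c("cA", "cA", "cB", "cB"))
  qc3 <- genotypeQC(G2[, 1:4], loci3, pop)
  expect_equal(qc3$loci$snp, c("s1", "s3"))
})

test_that("sharing expectation matches |A||B|/|U| and edge cases", {
  U <- paste0("u", 1:1000)
  A <- sample(U, 50)
  B <- sample(U, 50)
  sh <- sharingTest(A, B, U, nResample = 4000, level = "snp", seed = 3)
  # closed form: E|overlap| ~ |A||B|/|U| = 2.5 (with-replacement dedup
  # shrinks both sets slightly; allow 3 MC s.e. plus that bias)
  expect_lt(abs(sh@expected - 2.5), 0.35)
  shEmpty <- sharingTest(character(), character(), U, nResample = 100,
                         level = "snp", seed = 1)
  expect_equal(shEmpty@observed, 0L)
  expect_equal(shEmpty@p, 1)
  expect_error(sharingTest(A, B, character(), seed = 1), "universe")
  # complete overlap in a large universe is highly significant
  U2 <- paste0("u", 1:10000)
  A2 <- sample(U2, 20)
  sh2 <- sharingTest(A2, A2, U2, nResample = 500, level = "snp", seed = 5)
  expect_lt(sh2@p, 0.001)
})

test_that("permuted-null outliers flag about 5% under panmixia", {
  # panmictic pair: essentially no drift between the two ecotype groups
  cfg <- synthConfig(nLineages = 1, lakesPerLineage = 1, nPerGroup = 25,
                     nSnps = 1000, nGenes = 30, nDeGenes = 0, nEqtl = 0,
                     nAssocSnps = 0, sharedEffectScale = 0,
                     driftF = 0.001, missingRate = 0, seed = 41)
  b <- simulateStudy(cfg)
  s <- studySamples(b)
  ia <- which(s$ecotype == "planktivorous")
  ib <- which(s$ecotype == "benthivorous")
  sc <- wcFst(genotypeMatrix(b), ia, ib, loci = lociTable(b))
  sc <- fstOutliersEmpirical(sc)
  sc <- fstOutliersPermuted(sc, genotypeMatrix(b), ia, ib, lake = s$lake,
                            nPerm = 200, seed = 43)
  rate <- mean(fstTable(sc)$outlierPerm, na.rm = TRUE)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("weak real differentiation inflates permuted-null sharing
          relative to the empirical-quantile rule", {
  # drift without selection: every locus is somewhat differentiated, so
  # many loci exceed the panmixia null while the empirical rule always
  # flags exactly the top 5%
  cfg <- synthConfig(nLineages = 1, lakesPerLineage = 1, nPerGroup = 25,
                     nSnps = 600, nGenes = 30, nDeGenes = 0, nEqtl = 0,
                     nAssocSnps = 0, sharedEffectScale = 0,
                     driftF = 0.05, missingRate = 0, seed = 47)
  b <- simulateStudy(cfg)
  s <- studySamples(b)
  ia <- which(s$ecotype == "planktivorous")
  ib <- which(s$ecotype == "benthivorous")
  sc <- wcFst(genotypeMatrix(b), ia, ib, loci = lociTable(b))
  sc <- fstOutliersEmpirical(sc)
  sc <- fstOutliersPermuted(sc, genotypeMatrix(b), ia, ib, lake = s$lake,
                            nPerm = 100, seed = 49)
  expect_gte(sum(fstTable(sc)$outlierPerm, na.rm = TRUE),
             sum(fstTable(sc)$outlierEmp, na.rm = TRUE))
})

test_that("LD decay r2 matches direct correlation arithmetic", {
  g1 <- c(0, 1, 2, 1, 0, 2)
  g2 <- c(0, 1, 1, 2, 0, 2)
  G <- cbind(g1, g2)
  colnames(G) <- c("s1", "s2")
  ld <- ldDecay(G, toyLoci(2), maxDist = 5000, nBins = 5)
  row <- ld@bins[!is.na(ld@bins$meanR2), ]
  expect_equal(row$meanR2, 0.5625, tolerance = 1e-10)
  # duplicated locus -> r2 = 1
  G2 <- cbind(s1 = g1, s2 = g1)
  ld2 <- ldDecay(G2, toyLoci(2), maxDist = 5000, nBins = 5)
  expect_equal(ld2@bins$meanR2[!is.na(ld2@bins$meanR2)], 1)
  # independent loci: mean r2 ~ 1/n
  set.seed(9)
  n <- 50
  G3 <- matrix(rbinom(n * 80, 2, 0.5), n, 80)
  colnames(G3) <- paste0("s", 1:80)
  ld3 <- ldDecay(G3, toyLoci(80), maxDist = 1e5, nBins = 1)
  expect_lt(abs(ld3@bins$meanR2[1] - 1 / n), 0.01)
})

test_that("Patterson's D follows the worked arithmetic and symmetries", {
  # three loci with p = (0,1,1,0), (0,1,1,0), (1,0,1,0):
  # ABBA = 1, 1, 0 ; BABA = 0, 0, 1 -> D = (2 - 1) / (2 + 1) = 1/3
  p1 <- c(0, 0, 1); p2 <- c(1, 1, 0); p3 <- c(1, 1, 1); p4 <- c(0, 0, 0)
  d <- suppressWarnings(pattersonD(p1, p2, p3, p4, blockSize = 1))
  expect_equal(d@value, 1 / 3, tolerance = 1e-12)
  # p1 = p2 -> D = 0
  set.seed(10)
  p <- runif(100, 0.1, 0.9)
  d0 <- pattersonD(p, p, runif(100), runif(100, 0, 0.3), blockSize = 20)
  expect_equal(d0@value, 0, tolerance = 1e-12)
  # swapping P1 and P2 flips the sign
  q1 <- runif(200, 0.1, 0.9); q2 <- runif(200, 0.1, 0.9)
  q3 <- runif(200, 0.1, 0.9); q4 <- runif(200, 0, 0.3)
  dA <- pattersonD(q1, q2, q3, q4, blockSize = 40)
  dB <- pattersonD(q2, q1, q3, q4, blockSize = 40)
  expect_equal(dA@value, -dB@value, tolerance = 1e-12)
  expect_error(pattersonD(c(0, 0), c(0, 0), c(0, 0), c(1, 1)), "undefined")
})

test_that("introgression plants a positive D with strong Z", {
  set.seed(11)
  L <- 20000
  pa <- runif(L, 0.05, 0.95)
  drift <- function(p, F) rbeta(L, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  p3 <- drift(pa, 0.1)
  p1 <- drift(pa, 0.1)
  p2 <- 0.8 * drift(pa, 0.1) + 0.2 * p3   # P3 -> P2 admixture, f = 0.2
  p4 <- drift(pa, 0.02)
  d <- pattersonD(p1, p2, p3, p4, blockSize = 200)
  expect_gt(d@value, 0)
  expect_gte(d@Z, 3)
})

test_that("f3 matches arithmetic and detects the admixture sign", {
  f <- f3Stat(0.2, 0.8, 0.5, nC = 1000, blockSize = 1,
              biasCorrection = FALSE)
  expect_equal(suppressWarnings(f@value), -0.09, tolerance = 1e-12)
  # c exactly intermediate -> negative mean
  set.seed(13)
  a <- runif(500, 0.1, 0.9)
  b <- runif(500, 0.1, 0.9)
  f2 <- f3Stat(a, b, (a + b) / 2, nC = 1e6, blockSize = 100)
  expect_lt(f2@value, 0)
  expect_equal(f2@value, mean(((b - a) / 2) * ((a - b) / 2)),
               tolerance = 1e-4)
  # independent drift of C from the (A,B) ancestor -> f3 > 0
  pa <- runif(5000, 0.2, 0.8)
  drift <- function(p, F) rbeta(length(p), p * (1 - F) / F,
                                (1 - p) * (1 - F) / F)
  f3 <- f3Stat(drift(pa, 0.05), drift(pa, 0.05), drift(pa, 0.2), nC = 50,
               blockSize = 500)
  expect_gt(f3@value, 0)
})

test_that("imputation fills missing dosages sensibly", {
  set.seed(14)
  G <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30)
  pop <- rep(c("a", "b"), each = 20)
  # no missing -> identity
  r0 <- imputeMissing(G, pop)
  expect_identical(r0$genotypes, G)
  expect_equal(r0$freqCorrelation, 1)
  # 5% MCAR -> frequencies essentially preserved
  G1 <- G
  G1[runif(length(G1)) < 0.05] <- NA
  r1 <- imputeMissing(G1, pop)
  expect_false(anyNA(r1$genotypes))
  expect_gt(r1$freqCorrelation, 0.99)
  # fully missing population falls back to the global mean
  G2 <- G
  G2[pop == "a", 1] <- NA
  expect_warning(r2 <- imputeMissing(G2, pop), "global mean")
  expect_equal(unname(r2$genotypes[1, 1]), mean(G2[pop == "b", 1]))
})
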