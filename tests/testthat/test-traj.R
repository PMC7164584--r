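# Build a trajectory set from hand-placed group means plus optional noise.
plantedTraj <- function(vecs, nPer = 10, sdNoise = 0, seed = 1, base = 5) {
  set.seed(seed)
  nP <- length(vecs)
  d <- length(vecs[[1]])
  s <- do.call(rbind, lapply(seq_len(nP), function(i)
    data.frame(lake = paste0("lk", i), lineage = "lin1",
               ecotype = rep(c("planktivorous", "benthivorous"),
                             each = nPer))))
  X <- matrix(base, nrow(s), d)
  for (i in seq_len(nP)) {
    sel <- s$lake == paste0("lk", i) & s$ecotype == "benthivorous"
    X[sel, ] <- X[sel, ] + matrix(vecs[[i]], sum(sel), d, byrow = TRUE)
  }
  X <- X + matrix(rnorm(length(X), 0, sdNoise), nrow(X), ncol(X))
  list(scores = X, samples = s)
}

test_that("angles and length differences follow vector arithmetic", {
  pt <- plantedTraj(list(c(1, 1), c(1, 0), c(0, 1), c(-1, 0)))
  tr <- computeTrajectories(pt$scores, pt$samples)
  th <- trajectoryAngles(tr)
  expect_equal(th["lk1:benthivorous", "lk2:benthivorous"], 45,
               tolerance = 1e-10)
  expect_equal(th["lk2:benthivorous", "lk3:benthivorous"], 90,
               tolerance = 1e-10)
  expect_equal(th["lk2:benthivorous", "lk4:benthivorous"], 180,
               tolerance = 1e-10)
  expect_equal(tr@dL["lk1:benthivorous", "lk2:benthivorous"], sqrt(2) - 1,
               tolerance = 1e-10)
  # identical vectors
  pt2 <- plantedTraj(list(c(1, 2), c(1, 2)))
  tr2 <- computeTrajectories(pt2$scores, pt2$samples)
  # acos near its boundary limits precision to ~sqrt(machine eps)
  expect_lt(abs(trajectoryAngles(tr2)[1, 2]), 1e-5)
  expect_equal(tr2@dL[1, 2], 0, tolerance = 1e-10)
})

test_that("zero-length trajectories give NA angles with a warning", {
  pt <- plantedTraj(list(c(0, 0), c(1, 0)))
  expect_warning(tr <- computeTrajectories(pt$scores, pt$samples),
                 "identical centroids")
  expect_true(is.na(trajectoryAngles(tr)[1, 2]))
})

test_that("theta is invariant to rotation; L scales with the data", {
  pt <- plantedTraj(list(c(1, 0.5), c(0.2, 1)), sdNoise = 0.1, seed = 3)
  tr1 <- computeTrajectories(pt$scores, pt$samples)
  a <- pi / 5
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  tr2 <- computeTrajectories(pt$scores %*% R, pt$samples)
  expect_equal(trajectoryAngles(tr1), trajectoryAngles(tr2),
               tolerance = 1e-8)
  tr3 <- computeTrajectories(pt$scores * 3, pt$samples)
  expect_equal(trajectoryLengths(tr3), 3 * trajectoryLengths(tr1),
               tolerance = 1e-8)
})

test_that("permutation p-values are deterministic given a seed", {
  pt <- plantedTraj(list(c(1, 0), c(0.8, 0.3)), sdNoise = 0.5, seed = 5)
  tr <- computeTrajectories(pt$scores, pt$samples)
  p1 <- trajectoryPermutationTest(tr, pt$scores, pt$samples, nPerm = 99,
                                  seed = 11)
  p2 <- trajectoryPermutationTest(tr, pt$scores, pt$samples, nPerm = 99,
                                  seed = 11)
  expect_identical(p1@pTheta, p2@pTheta)
  expect_identical(p1@pDL, p2@pDL)
  expect_error(trajectoryPermutationTest(tr, pt$scores, pt$samples,
                                         nPerm = 99), "seed")
})

test_that("degenerate null: zero residuals and identical vectors give p = 1", {
  pt <- plantedTraj(list(c(1, 0), c(1, 0)), sdNoise = 0)
  tr <- computeTrajectories(pt$scores, pt$samples)
  expect_equal(trajectoryAngles(tr)[1, 2], 0)
  tr <- trajectoryPermutationTest(tr, pt$scores, pt$samples, nPerm = 99,
                                  seed = 1)
  expect_equal(tr@pTheta[1, 2], 1)
})

test_that("planted antiparallel vectors attain the minimum p-value", {
  pt <- plantedTraj(list(c(1, 0, 0), c(-1, 0, 0)), nPer = 15,
                    sdNoise = 0.005, seed = 7)
  tr <- computeTrajectories(pt$scores, pt$samples)
  tr <- trajectoryPermutationTest(tr, pt$scores, pt$samples, nPerm = 999,
                                  seed = 13)
  expect_gt(trajectoryAngles(tr)[1, 2], 179)
  expect_equal(tr@pTheta[1, 2], 1 / 1000)
})

test_that("null permutation p-values are uniform", {
  set.seed(99)
  ps <- replicate(200, {
    pt <- plantedTraj(list(c(0, 0, 0), c(0, 0, 0)), nPer = 8, sdNoise = 1,
                      seed = sample.int(1e6, 1))
    tr <- suppressWarnings(computeTrajectories(pt$scores, pt$samples))
    tr <- trajectoryPermutationTest(tr, pt$scores, pt$samples, nPerm = 99,
                                    seed = sample.int(1e6, 1))
    tr@pTheta[1, 2]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("replicated flags and the group contrast behave as constructed", {
  # lk1/lk2: benthivorous pairs; lk3: piscivorous pair -> comparisons
  # within {1,2} replicated, others not
  s <- rbind(makeSamples(nLakes = 2, nPer = 5),
             within(makeSamples(nLakes = 1, nPer = 5), {
               lake <- "lk3"
               ecotype[ecotype == "benthivorous"] <- "piscivorous"
             }))
  s$id <- sprintf("i%03d", seq_len(nrow(s)))
  set.seed(4)
  X <- matrix(rnorm(nrow(s) * 3), nrow(s), 3)
  tr <- computeTrajectories(X, s)
  expect_true(tr@replicated["lk1:benthivorous", "lk2:benthivorous"])
  expect_false(tr@replicated["lk1:benthivorous", "lk3:piscivorous"])
})

test_that("the Wilcoxon contrast equals exact rank enumeration", {
  # replicated angles {10, 20}; non-replicated {100, 110, 120}:
  # all replicated < all non-replicated, W = 0,
  # exact two-sided p = 2 * 1 / choose(5, 2) = 0.2
  pairs <- data.frame(pair = paste0("p", 1:4), lake = paste0("lk", 1:4),
                      lineage = "lin1", ecoFrom = "planktivorous",
                      ecoTo = c("benthivorous", "benthivorous",
                                "piscivorous", "piscivorous"),
                      type = c("bp", "bp", "pp", "pp"),
                      stringsAsFactors = FALSE)
  nP <- 4
  th <- matrix(0, nP, nP, dimnames = list(pairs$pair, pairs$pair))
  th[1, 2] <- th[2, 1] <- 10          # replicated (bp-bp)
  th[3, 4] <- th[4, 3] <- 20          # replicated (pp-pp)
  th[1, 3] <- th[3, 1] <- 100
  th[1, 4] <- th[4, 1] <- 110
  th[2, 3] <- th[3, 2] <- 120
  th[2, 4] <- th[4, 2] <- 115
  rep <- outer(pairs$type, pairs$type, "==")
  diag(rep) <- NA
  dimnames(rep) <- dimnames(th)
  dL <- th * 0
  tr <- new("TrajectorySet", pairs = pairs, vectors = matrix(0, 4, 2),
            L = rep(0, 4), theta = th, dL = dL, pTheta = th * NA,
            pDL = th * NA, replicated = rep, nPerm = 0L)
  gc <- groupContrast(tr)
  # exact enumeration: replicated {10,20} vs non-replicated
  # {100,110,120,115}: p = 2 * 1/choose(6,2) = 2/15
  expect_equal(gc$p, 2 / choose(6, 2), tolerance = 1e-10)
  expect_equal(gc$difference, mean(c(100, 110, 120, 115)) - 15)
})

test_that("parallel generator yields smaller replicated angles", {
  cfg <- synthConfig(ecotypesPerLake = 3, nLineages = 1,
                     lakesPerLineage = 3, nPerGroup = 25,
                     sharedEffectScale = 0.1, lakeNoiseScale = 0.005,
                     nSnps = 20, nGenes = 30, nDeGenes = 0, nEqtl = 0,
                     seed = 17)
  b <- simulateStudy(cfg)
  s <- studySamples(b)
  ct <- sizeCorrectTraits(traitMatrix(b), s$forkLength, s$lake, s$ecotype,
                          s$lineage)
  tr <- computeTrajectories(log10(correctedTraits(ct)), s)
  gc <- groupContrast(tr)
  expect_lt(gc$meanReplicated, gc$meanNonReplicated)
})
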