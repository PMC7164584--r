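#' @import methods
#' @importFrom stats anova aov coef complete.cases cor cor.test cov lm
#'   lm.fit median model.matrix na.omit p.adjust pchisq pf prcomp pt
#'   quantile rbeta rbinom rnbinom rnorm runif sd setNames t.test var
#'   wilcox.test rlnorm chisq.test prop.test terms qnorm
#' @importFrom utils head read.csv read.delim write.csv
NULL

#' Configuration for the synthetic study generator
#'
#' Holds every tunable of [simulateStudy()]: study design (lineages, lakes,
#' ecotypes, individuals per group), trait architecture (shared ecotype effect,
#' lake-specific deviation, allometric slopes, residual noise), genetic
#' architecture (Balding-Nichols drift, ecotype-associated allele-frequency
#' shifts), expression architecture (negative-binomial counts, planted
#' differential expression and cis-eQTL), and the coupling between ecosystem
#' size and the direction of divergence.
#'
#' @slot nLineages number of glacial lineages.
#' @slot lakesPerLineage number of lakes per lineage.
#' @slot ecotypesPerLake 2 (planktivorous + benthivorous) or 3 (+ piscivorous).
#' @slot nPerGroup individuals per lake-by-ecotype group.
#' @slot nTraits number of linear traits (default 7).
#' @slot nSnps number of biallelic SNPs.
#' @slot nGenes number of genes in the count matrix.
#' @slot sharedEffectScale norm of the lineage-shared ecotype effect vector on
#'   log10 traits.
#' @slot lakeNoiseScale per-trait s.d. of lake-specific deviations of the
#'   effect vector; 0 gives perfect parallelism.
#' @slot allometrySlopes per-trait allometric slope b.
#' @slot traitNoiseSd residual s.d. of log10 trait values.
#' @slot driftF Balding-Nichols divergence of each population from the
#'   ancestral allele frequencies, in (0,1).
#' @slot nAssocSnps number of SNPs with a planted ecotype frequency shift.
#' @slot assocDelta total ecotype allele-frequency shift at associated SNPs.
#' @slot missingRate MCAR missing-genotype rate.
#' @slot nDeGenes number of genes with a planted ecotype expression shift.
#' @slot deLog2fc planted log2 fold change (shared across lakes).
#' @slot nbDispersion negative-binomial dispersion alpha (var = mu + alpha mu^2).
#' @slot nEqtl number of genes given a planted cis-eQTL.
#' @slot eqtlBeta additive log2 expression effect per alternate allele.
#' @slot ecosystemCoupling in [0,1]; correlation between ecosystem-size
#'   distance and the rotation of lake effect vectors.
#' @slot seed RNG seed; same seed + config reproduces the bundle exactly.
#' @export
setClass("SynthConfig", representation(
  nLineages = "integer", lakesPerLineage = "integer",
  ecotypesPerLake = "integer", nPerGroup = "integer", nTraits = "integer",
  nSnps = "integer", nGenes = "integer",
  sharedEffectScale = "numeric", lakeNoiseScale = "numeric",
  allometrySlopes = "numeric", traitNoiseSd = "numeric",
  driftF = "numeric", nAssocSnps = "integer", assocDelta = "numeric",
  missingRate = "numeric", nDeGenes = "integer", deLog2fc = "numeric",
  nbDispersion = "numeric", nEqtl = "integer", eqtlBeta = "numeric",
  ecosystemCoupling = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  cnt <- c(nLineages = object@nLineages, lakesPerLineage = object@lakesPerLineage,
           nPerGroup = object@nPerGroup, nTraits = object@nTraits,
           nSnps = object@nSnps, nGenes = object@nGenes)
  if (any(cnt < 1L)) msg <- c(msg, "all design counts must be >= 1")
  if (!object@ecotypesPerLake %in% c(2L, 3L))
    msg <- c(msg, "ecotypesPerLake must be 2 or 3")
  sc <- c(object@sharedEffectScale, object@lakeNoiseScale, object@traitNoiseSd,
          object@assocDelta, object@deLog2fc, object@nbDispersion,
          object@eqtlBeta)
  if (any(sc < 0)) msg <- c(msg, "scales must be >= 0")
  if (object@driftF <= 0 || object@driftF >= 1)
    msg <- c(msg, "driftF must lie in (0,1)")
  if (object@ecosystemCoupling < 0 || object@ecosystemCoupling > 1)
    msg <- c(msg, "ecosystemCoupling must lie in [0,1]")
  if (object@missingRate < 0 || object@missingRate >= 0.5)
    msg <- c(msg, "missingRate must lie in [0, 0.5)")
  if (length(object@allometrySlopes) != object@nTraits)
    msg <- c(msg, "allometrySlopes must have one entry per trait")
  if (object@nAssocSnps > object@nSnps)
    msg <- c(msg, "nAssocSnps cannot exceed nSnps")
  if (object@nDeGenes + object@nEqtl > object@nGenes)
    msg <- c(msg, "nDeGenes + nEqtl cannot exceed nGenes")
  if (length(msg)) msg else TRUE
})

#' A linked synthetic (or real) study
#'
#' The five linked tables of one multi-lake, multi-lineage ecotype study, plus
#' the generator's ground truth when simulated.
#'
#' @slot samples data.frame: id, lake, lineage, ecotype, forkLength (mm).
#' @slot traits matrix individuals x traits, measured values (mm).
#' @slot genotypes matrix individuals x SNPs of dosages 0/1/2 with NA missing.
#' @slot loci data.frame per SNP: chrom, pos (1-based), contig, assoc flag.
#' @slot counts matrix genes x individuals of non-negative integer read counts.
#' @slot genes data.frame per gene: chrom, pos, de flag, eqtlSnp (index or NA).
#' @slot env data.frame per lake: lake, maxDepth (m), surfaceArea (km2).
#' @slot truth list of planted effect vectors and flags (empty for real data).
#' @export
setClass("StudyBundle", representation(
  samples = "data.frame", traits = "matrix", genotypes = "matrix",
  loci = "data.frame", counts = "matrix", genes = "data.frame",
  env = "data.frame", truth = "list"))

setValidity("StudyBundle", function(object) {
  msg <- character()
  n <- nrow(object@samples)
  if (!all(c("id", "lake", "lineage", "ecotype", "forkLength") %in%
           colnames(object@samples)))
    msg <- c(msg, "samples must have id, lake, lineage, ecotype, forkLength")
  if (anyDuplicated(object@samples$id))
    msg <- c(msg, "sample ids must be unique")
  if (nrow(object@traits) != n) msg <- c(msg, "traits rows != samples")
  if (nrow(object@genotypes) != n) msg <- c(msg, "genotype rows != samples")
  if (ncol(object@counts) != n) msg <- c(msg, "count columns != samples")
  g <- object@genotypes
  if (length(g) && !all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotype dosages must be 0/1/2 or NA")
  cc <- object@counts
  if (length(cc) && (any(cc < 0) || any(cc != round(cc))))
    msg <- c(msg, "counts must be non-negative integers")
  ne <- tapply(object@samples$ecotype, object@samples$lake,
               function(x) length(unique(x)))
  if (length(ne) && any(ne < 2)) msg <- c(msg, "each lake needs >= 2 ecotypes")
  if (length(msg)) msg else TRUE
})

#' Size-corrected linear traits
#'
#' @slot Y matrix of size-adjusted trait values on the original mm scale.
#' @slot M matrix of raw measured values (mm).
#' @slot L individual fork lengths (mm).
#' @slot b matrix lineage x trait of common allometric slopes.
#' @slot Lm named vector of lineage mean fork lengths (mm).
#' @slot dropped integer count of records rejected for non-positive values.
#' @export
setClass("CorrectedTraits", representation(
  Y = "matrix", M = "matrix", L = "numeric", b = "matrix", Lm = "numeric",
  dropped = "integer"))

setValidity("CorrectedTraits", function(object) {
  msg <- character()
  ok <- is.finite(object@M) & !is.na(object@M)
  if (any(!is.finite(object@Y[ok]))) msg <- c(msg, "Y must be finite where M observed")
  if (any(!is.finite(object@b))) msg <- c(msg, "slopes must be finite")
  if (any(object@Lm <= 0)) msg <- c(msg, "Lm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Principal component analysis result
#'
#' Thin wrapper around the spectral decomposition with a deterministic sign
#' convention (largest-magnitude loading of each component positive) and the
#' smallest number of leading components whose cumulative explained variance
#' exceeds one half (`k50`), the retention rule used throughout the pipeline.
#'
#' @slot scores individuals x components.
#' @slot loadings variables x components.
#' @slot explained fraction of variance per component.
#' @slot k50 smallest k with cumulative explained variance > 0.5.
#' @slot center,scale the centring/scaling vectors applied.
#' @slot imputed number of missing cells mean-imputed before decomposition.
#' @export
setClass("PcaResult", representation(
  scores = "matrix", loadings = "matrix", explained = "numeric",
  k50 = "integer", center = "numeric", scale = "numeric", imputed = "integer"))

#' Trajectory set: divergence vectors, lengths, angles
#'
#' One row per sympatric ecotype pair; the divergence vector v points from the
#' planktivorous centroid to the other ecotype's centroid in the retained
#' score space. Pairwise angles theta (degrees) and length differences dL are
#' square symmetric matrices over pairs; permutation p-values are attached by
#' [trajectoryPermutationTest()].
#'
#' @slot pairs data.frame: pair, lake, lineage, ecoFrom, ecoTo, type.
#' @slot vectors matrix pairs x dimensions of centroid differences.
#' @slot L vector of trajectory lengths per pair.
#' @slot theta,dL symmetric matrices of pairwise angles (deg) and |L_i - L_j|.
#' @slot pTheta,pDL permutation p-value matrices (NA before testing).
#' @slot replicated logical matrix: TRUE where the two pairs contrast the same
#'   ecotype combination (replicated comparison).
#' @slot nPerm number of permutations used (0 before testing).
#' @export
setClass("TrajectorySet", representation(
  pairs = "data.frame", vectors = "matrix", L = "numeric",
  theta = "matrix", dL = "matrix", pTheta = "matrix", pDL = "matrix",
  replicated = "matrix", nPerm = "integer"))

setValidity("TrajectorySet", function(object) {
  msg <- character()
  th <- object@theta
  if (any(th < -1e-9 | th > 180 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "angles must lie in [0, 180] degrees")
  if (any(abs(th - t(th)) > 1e-9, na.rm = TRUE))
    msg <- c(msg, "theta must be symmetric")
  if (any(object@dL < -1e-12, na.rm = TRUE)) msg <- c(msg, "dL must be >= 0")
  if (any(object@L < 0)) msg <- c(msg, "lengths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-locus Weir-Cockerham Fst scan
#'
#' @slot loci data.frame: chrom, pos, fst, zfst, outlierEmp (above empirical
#'   95th percentile), zfstSignificant (ZFst > 4), zfstReported (ZFst > 3),
#'   outlierPerm (above permuted-panmixia 95th percentile; NA before
#'   [fstOutliersPermuted()]).
#' @slot meanFst genome-wide ratio-of-sums estimate sum(a)/sum(a+b+c).
#' @slot permNull95 95th percentile of the pooled permutation null (NA before
#'   permutation).
#' @slot pair character naming the two groups compared.
#' @export
setClass("FstScan", representation(
  loci = "data.frame", meanFst = "numeric", permNull95 = "numeric",
  pair = "character"))

setValidity("FstScan", function(object) {
  f <- object@loci$fst
  if (any(f < -1 - 1e-9 | f > 1 + 1e-9, na.rm = TRUE))
    "per-locus Fst must lie in [-1, 1]" else TRUE
})

#' Nucleotide diversity per population
#'
#' @slot popPi named vector: mean per-site pi over variant sites per population.
#' @slot sitePi matrix loci x populations of per-site pi (NA where < 2 alleles).
#' @export
setClass("DiversityResult", representation(
  popPi = "numeric", sitePi = "matrix"))

#' Resampling-based sharing test result
#'
#' @slot observed observed shared feature count.
#' @slot expected mean shared count over resamples drawn with replacement.
#' @slot resampleQuantiles summary quantiles of the resample distribution.
#' @slot p proportion-test p-value (observed vs expected against universe size).
#' @slot level feature level: "snp", "contig" or "gene".
#' @slot nResample,universeSize,sizeA,sizeB bookkeeping.
#' @export
setClass("SharingResult", representation(
  observed = "integer", expected = "numeric", resampleQuantiles = "numeric",
  p = "numeric", level = "character", nResample = "integer",
  universeSize = "integer", sizeA = "integer", sizeB = "integer"))

#' D / f3 introgression statistics with block-jackknife Z
#'
#' @slot stat "D" or "f3".
#' @slot value the statistic.
#' @slot Z block-jackknife Z-score.
#' @slot se jackknife standard error.
#' @slot blockSize loci per jackknife block; @slot nBlocks number of blocks.
#' @export
setClass("IntrogressionStats", representation(
  stat = "character", value = "numeric", Z = "numeric", se = "numeric",
  blockSize = "integer", nBlocks = "integer"))

#' Binned linkage-disequilibrium decay
#'
#' @slot bins data.frame: distLo, distHi, mid, meanR2, medianR2, nPairs.
#' @slot focal TRUE when pairs were restricted to (outlier, any).
#' @export
setClass("LdResult", representation(bins = "data.frame", focal = "logical"))

setValidity("LdResult", function(object) {
  r2 <- object@bins$meanR2
  if (any(r2 < -1e-9 | r2 > 1 + 1e-9, na.rm = TRUE))
    "r2 must lie in [0, 1]" else TRUE
})

#' Partial redundancy analysis result
#'
#' @slot loadings features x constrained axes.
#' @slot z z-standardized loadings (mean 0, sd 1 per axis).
#' @slot candidates feature names with |z| > zCut on any constrained axis.
#' @slot explained fraction of conditioned variance captured by the
#'   constrained axes.
#' @slot p permutation pseudo-F p-value; @slot F observed pseudo-F.
#' @slot nPerm permutations; @slot zCut candidate threshold.
#' @slot siteScores samples x axes.
#' @export
setClass("RdaResult", representation(
  loadings = "matrix", z = "matrix", candidates = "character",
  explained = "numeric", p = "numeric", F = "numeric", nPerm = "integer",
  zCut = "numeric", siteScores = "matrix"))

setValidity("RdaResult", function(object) {
  msg <- character()
  if (ncol(object@z) > 0 && nrow(object@z) > 1) {
    m <- colMeans(object@z); s <- apply(object@z, 2, sd)
    if (any(abs(m) > 1e-6) || any(abs(s - 1) > 1e-6))
      msg <- c(msg, "z-scores must have mean 0 and sd 1 per axis")
  }
  if (!all(object@candidates %in% rownames(object@loadings)))
    msg <- c(msg, "candidates must be a subset of features")
  if (object@explained < -1e-9 || object@explained > 1 + 1e-9)
    msg <- c(msg, "explained fraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Co-expression module set
#'
#' @slot assignment named character: module label per gene ("unassigned" for
#'   genes in no module).
#' @slot eigengenes matrix samples x modules; each column is the unit-norm
#'   first principal component of its module, oriented to positive mean
#'   loading.
#' @slot minSize minimum module size enforced.
#' @slot moduleTrait data.frame of module-trait correlations (filled by
#'   [moduleTraitCorrelation()]).
#' @export
setClass("ModuleSet", representation(
  assignment = "character", eigengenes = "matrix", minSize = "integer",
  moduleTrait = "data.frame"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  tab <- table(object@assignment[object@assignment != "unassigned"])
  if (length(tab) && any(tab < object@minSize))
    msg <- c(msg, "every module must reach the minimum size")
  if (ncol(object@eigengenes) > 0) {
    nrm <- sqrt(colSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "eigengenes must be unit norm")
  }
  if (length(msg)) msg else TRUE
})

#' cis-eQTL mapping result
#'
#' @slot records data.frame: gene, snp, distance, beta, t, p, fdr.
#' @slot window cis window in bp.
#' @slot fdrLevels the FDR thresholds reported (0.1 and 0.05).
#' @export
setClass("EqtlResult", representation(
  records = "data.frame", window = "numeric", fdrLevels = "numeric"))

setValidity("EqtlResult", function(object) {
  msg <- character()
  r <- object@records
  if (nrow(r) && any(r$distance > object@window))
    msg <- c(msg, "every record must lie within the cis window")
  if (nrow(r) && (any(r$fdr < 0 | r$fdr > 1)))
    msg <- c(msg, "FDR must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Ecosystem-size axis (lake PC1) and pairwise distances
#'
#' @slot table data.frame: lake, maxDepth, surfaceArea, pc1.
#' @slot dist symmetric matrix of |PC1_i - PC1_j| between lakes.
#' @slot explained fraction of variance on PC1.
#' @export
setClass("EcosystemPC", representation(
  table = "data.frame", dist = "matrix", explained = "numeric"))

setValidity("EcosystemPC", function(object) {
  msg <- character()
  d <- object@dist
  if (any(abs(d - t(d)) > 1e-9)) msg <- c(msg, "distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "distance diagonal must be zero")
  if (object@explained < 0.5 - 1e-9)
    msg <- c(msg, "PC1 of two variables must explain >= 50%")
  if (length(msg)) msg else TRUE
})
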