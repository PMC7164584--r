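## Deterministic per-stage seed derived from the global seed; kept below
## 2^31 - 1.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) * 7907L + sum(utf8ToInt(stage))) %% 2147483629L
}

.writeCsv <- function(x, dir, name) {
  write.csv(x, file.path(dir, name), row.names = FALSE)
}

#' Run the full parallel-divergence pipeline on a study bundle
#'
#' Executes, in order: trait size correction, PCA and variance partitioning
#' (morpho); phenotypic trajectory analysis with permutation tests (traj);
#' genotype QC, per-pair Fst scans with empirical and permuted-null
#' outliers, nucleotide diversity and outlier sharing (popgen); partial RDA
#' per lineage with cross-lineage candidate sharing and the genetic
#' trajectory analyses (assoc); expression normalization, per-lake
#' differential expression, DEG sharing, expression RDA, variance filter,
#' co-expression modules with module-trait correlations and cis-eQTL
#' (expr); and the ecosystem-size Mantel/regression battery (integrate).
#' All randomness derives from `seed` via fixed per-stage offsets; a rerun
#' with the same inputs and seed reproduces every output file byte for
#' byte.
#'
#' @param bundle a [StudyBundle-class], or a directory path readable by
#'   [readStudyBundle()].
#' @param outDir output directory for stage CSV/JSON artifacts.
#' @param seed global integer seed.
#' @param stages subset of c("morpho","traj","popgen","assoc","expr",
#'   "integrate"); earlier stages a later one needs are run regardless.
#' @param nPermTraj,nPermFst,nPermRda,nPermMantel permutation counts.
#' @param nResample resampling rounds for sharing tests.
#' @param outlierQuantile,zCut,cisWindow,eqtlFdr,degFdr,varFraction,
#'   minCountPerLake,moduleMinSize,moduleCutHeight,moduleMergeDist
#'   thresholds, defaulting to the study's standard values.
#' @return (invisibly) list of stage results plus `manifest` (file MD5
#'   hashes, seeds, thresholds).
#' @export
runPipeline <- function(bundle, outDir, seed = 1L,
                        stages = c("morpho", "traj", "popgen", "assoc",
                                   "expr", "integrate"),
                        nPermTraj = 199, nPermFst = 99, nPermRda = 199,
                        nPermMantel = 999, nResample = 1000,
                        outlierQuantile = 0.95, zCut = 2, cisWindow = 1e6,
                        eqtlFdr = 0.1, degFdr = 0.05, varFraction = 0.10,
                        minCountPerLake = 20, moduleMinSize = 25,
                        moduleCutHeight = 0.992, moduleMergeDist = 0.25) {
  if (is.character(bundle)) bundle <- readStudyBundle(bundle)
  stopifnot(is(bundle, "StudyBundle"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  thresholds <- list(nPermTraj = nPermTraj, nPermFst = nPermFst,
                     nPermRda = nPermRda, nPermMantel = nPermMantel,
                     nResample = nResample,
                     outlierQuantile = outlierQuantile, zCut = zCut,
                     cisWindow = cisWindow, eqtlFdr = eqtlFdr,
                     degFdr = degFdr, varFraction = varFraction,
                     minCountPerLake = minCountPerLake,
                     moduleMinSize = moduleMinSize,
                     moduleCutHeight = moduleCutHeight,
                     moduleMergeDist = moduleMergeDist)
  s <- studySamples(bundle)
  pairSpec <- defaultPairSpec(s)

  ## ---- morpho ----
  ct <- sizeCorrectTraits(traitMatrix(bundle), s$forkLength, s$lake,
                          s$ecotype, s$lineage)
  pcaP <- runPca(correctedTraits(ct), center = TRUE, scale = TRUE)
  eta <- do.call(rbind, lapply(colnames(correctedTraits(ct)), function(tn) {
    r <- suppressMessages(traitAnovaEta2(correctedTraits(ct)[, tn], s))
    data.frame(trait = tn, term = names(r$eta2), eta2 = r$eta2,
               p = r$p, parallelDominant = r$parallelDominant,
               row.names = NULL)
  }))
  res$morpho <- list(corrected = ct, pca = pcaP, eta2 = eta)
  .writeCsv(data.frame(id = s$id, correctedTraits(ct), check.names = FALSE),
            outDir, "corrected_traits.csv")
  .writeCsv(eta, outDir, "trait_eta2.csv")
  .writeCsv(data.frame(id = s$id,
                       pcaScores(pcaP)[, seq_len(min(6, ncol(pcaScores(pcaP)))),
                                       drop = FALSE], check.names = FALSE),
            outDir, "trait_pca_scores.csv")

  ## ---- traj (phenotypic, on size-corrected traits) ----
  trajP <- computeTrajectories(correctedTraits(ct), s, pairSpec)
  trajP <- trajectoryPermutationTest(trajP, correctedTraits(ct), s,
                                     nPerm = nPermTraj,
                                     seed = .stageSeed(seed, "traj"))
  res$traj <- trajP
  .writeCsv(.trajLong(trajP), outDir, "trajectories_phenotype.csv")

  ## ---- popgen ----
  pops <- paste(s$lake, s$ecotype, sep = ".")
  qc <- genotypeQC(genotypeMatrix(bundle), lociTable(bundle), pops)
  scans <- list()
  for (i in seq_len(nrow(pairSpec))) {
    ia <- which(s$lake == pairSpec$lake[i] &
                  s$ecotype == pairSpec$ecoFrom[i])
    ib <- which(s$lake == pairSpec$lake[i] & s$ecotype == pairSpec$ecoTo[i])
    pr <- paste0(pairSpec$lake[i], ":", pairSpec$ecoTo[i])
    sc <- wcFst(qc$genotypes, ia, ib, loci = qc$loci, pair = pr)
    sc <- fstOutliersEmpirical(sc, outlierQuantile)
    sc <- fstOutliersPermuted(sc, qc$genotypes, ia, ib, lake = s$lake,
                              nPerm = nPermFst,
                              seed = .stageSeed(seed, paste0("fst", i)),
                              quantile = outlierQuantile)
    scans[[pr]] <- sc
  }
  div <- nucleotideDiversity(qc$genotypes, pops)
  sharing <- NULL
  if (length(scans) >= 2) {
    oA <- with(fstTable(scans[[1]]), snp[outlierEmp %in% TRUE])
    oB <- with(fstTable(scans[[2]]), snp[outlierEmp %in% TRUE])
    sharing <- sharingTest(oA, oB, qc$loci$snp, nResample = nResample,
                           level = "snp",
                           seed = .stageSeed(seed, "sharing"))
  }
  res$popgen <- list(qc = qc, scans = scans, diversity = div,
                     sharing = sharing)
  allScan <- do.call(rbind, lapply(names(scans), function(nm)
    data.frame(pair = nm, fstTable(scans[[nm]]))))
  .writeCsv(allScan, outDir, "fst_scans.csv")
  .writeCsv(data.frame(population = names(div@popPi), pi = div@popPi),
            outDir, "diversity.csv")

  ## neutral SNPs: outliers in no pair
  outAny <- Reduce(`|`, lapply(scans, function(sc)
    fstTable(sc)$outlierEmp %in% TRUE))
  neutralSnps <- qc$loci$snp[!outAny]

  ## ---- assoc ----
  imp <- imputeMissing(qc$genotypes, pops)
  lineages <- unique(s$lineage)
  rdas <- list()
  for (li in lineages) {
    sel <- s$lineage == li
    rdas[[li]] <- partialRda(imp$genotypes[sel, , drop = FALSE],
                             s$ecotype[sel],
                             data.frame(lake = s$lake[sel]),
                             nPerm = nPermRda,
                             seed = .stageSeed(seed, paste0("rda", li)),
                             zCut = zCut)
  }
  crossShare <- if (length(rdas) >= 2)
    crossLineageCandidates(rdas[[1]], rdas[[2]], qc$loci$snp,
                           nResample = nResample,
                           seed = .stageSeed(seed, "rdacross"))
  else NULL
  res$assoc <- list(rda = rdas, cross = crossShare)
  candAll <- unique(unlist(lapply(rdas, candidateFeatures)))
  .writeCsv(do.call(rbind, lapply(names(rdas), function(li)
    data.frame(lineage = li, snp = rownames(rdas[[li]]@z),
               z = rdas[[li]]@z[, 1],
               candidate = rownames(rdas[[li]]@z) %in%
                 candidateFeatures(rdas[[li]]), row.names = NULL))),
    outDir, "rda_candidates.csv")

  ## genetic trajectories: neutral and candidate SNP PC spaces
  trajGn <- trajRda <- NULL
  if (length(neutralSnps) >= 2) {
    pcaGn <- runPca(imp$genotypes[, neutralSnps, drop = FALSE])
    trajGn <- computeTrajectories(pcaGn, s, pairSpec)
  }
  if (length(candAll) >= 2) {
    pcaRda <- runPca(imp$genotypes[, candAll, drop = FALSE])
    trajRda <- computeTrajectories(pcaRda, s, pairSpec)
  }

  ## ---- expr ----
  keep <- filterGenes(countMatrix(bundle), s$lake, minCountPerLake)
  counts <- countMatrix(bundle)[keep, , drop = FALSE]
  genes <- geneTable(bundle)[keep, , drop = FALSE]
  nrm <- normalizeCounts(counts)
  de <- lapply(unique(s$lake), function(lk)
    differentialExpression(nrm$normalized, s, lk, fdr = degFdr))
  names(de) <- unique(s$lake)
  degSets <- lapply(de, function(d) d$gene[d$significant])
  degShare <- if (length(degSets) >= 2)
    degSharing(degSets[[1]], degSets[[2]], genes$gene,
               nResample = nResample, seed = .stageSeed(seed, "degshare"))
  else NULL
  rdaGex <- partialRda(t(nrm$normalized), s$ecotype,
                       data.frame(lake = s$lake, lineage = s$lineage),
                       nPerm = nPermRda,
                       seed = .stageSeed(seed, "rdagex"), zCut = zCut)
  canGex <- candidateFeatures(rdaGex)
  vf <- ecotypeVarianceFilter(nrm$normalized, s, varFraction)
  netGenes <- names(vf$keep)[vf$keep]
  modules <- NULL
  if (length(netGenes) >= 2) {
    modules <- coexpressionModules(nrm$normalized[netGenes, , drop = FALSE],
                                   cutHeight = moduleCutHeight,
                                   minSize = moduleMinSize,
                                   mergeDist = moduleMergeDist)
    modules <- moduleTraitCorrelation(modules, s)
  }
  eqtl <- cisEqtl(nrm$normalized, genes, imp$genotypes, qc$loci,
                  data.frame(lake = s$lake, lineage = s$lineage),
                  window = cisWindow, fdrLevels = c(eqtlFdr, 0.05))
  res$expr <- list(normalized = nrm, de = de, degSharing = degShare,
                   rda = rdaGex, varianceFilter = vf, modules = modules,
                   eqtl = eqtl)
  .writeCsv(do.call(rbind, lapply(names(de), function(lk)
    data.frame(lake = lk, de[[lk]]))), outDir, "differential_expression.csv")
  .writeCsv(eqtlRecords(eqtl), outDir, "cis_eqtl.csv")
  if (!is.null(modules) && nrow(modules@moduleTrait))
    .writeCsv(modules@moduleTrait, outDir, "module_trait.csv")

  ## expression trajectories
  pcaGex <- runPca(t(nrm$normalized))
  trajGex <- computeTrajectories(pcaGex, s, pairSpec)
  trajCanGex <- if (length(canGex) >= 2)
    computeTrajectories(runPca(t(nrm$normalized[canGex, , drop = FALSE])),
                        s, pairSpec)
  else NULL

  ## ---- integrate ----
  eco <- ecosystemPc(lakeEnvironment(bundle))
  fstNeut <- vapply(names(scans), function(nm)
    .neutralGenomeFst(qc$genotypes, s, pairSpec[match(nm, names(scans)), ],
                      neutralSnps), 0)
  tv <- traitVarianceByLake(ct, s)
  report <- predictabilityReport(
    trajP = trajP, trajGn = trajGn, trajRda = trajRda, trajGex = trajGex,
    trajCanGex = trajCanGex, fstNeut = fstNeut, popPi = div@popPi,
    popLake = setNames(s$lake[match(names(div@popPi), pops)],
                       names(div@popPi)),
    eco = eco, traitVarByLake = tv, nPerm = nPermMantel,
    seed = .stageSeed(seed, "integrate"))
  res$integrate <- list(eco = eco, report = report, fstNeut = fstNeut,
                        traitVariance = tv)
  .writeCsv(report, outDir, "predictability_report.csv")
  jsonlite::write_json(
    list(ecosystem = eco@table,
         report = report),
    file.path(outDir, "integrate.json"), auto_unbox = TRUE, digits = NA)

  ## ---- manifest ----
  files <- sort(list.files(outDir, full.names = TRUE,
                           pattern = "\\.(csv|json)$"))
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(files)
  manifest <- list(seed = seed, thresholds = thresholds,
                   stageSeeds = vapply(
                     c("traj", "sharing", "rdagex", "degshare", "integrate"),
                     function(st) .stageSeed(seed, st), 0),
                   hashes = as.list(hashes))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

## Genome-wide ratio-of-sums Fst for one pair restricted to neutral loci.
.neutralGenomeFst <- function(genotypes, s, pairRow, neutralSnps) {
  ia <- which(s$lake == pairRow$lake & s$ecotype == pairRow$ecoFrom)
  ib <- which(s$lake == pairRow$lake & s$ecotype == pairRow$ecoTo)
  G <- genotypes[, colnames(genotypes) %in% neutralSnps, drop = FALSE]
  genomeFst(wcFst(G, ia, ib))
}

.trajLong <- function(trajset) {
  pr <- trajectoryPairs(trajset)$pair
  n <- length(pr)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(pairA = pr[ij[, 1]], pairB = pr[ij[, 2]],
             theta = trajset@theta[ij], dL = trajset@dL[ij],
             pTheta = trajset@pTheta[ij], pDL = trajset@pDL[ij],
             replicated = trajset@replicated[ij])
}
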