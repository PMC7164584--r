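#' Accessors for study bundles and result objects
#'
#' Standard slot accessors; user code should use these rather than `@`.
#'
#' @param object an S4 object from this package.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("studySamples", function(object) standardGeneric("studySamples"))
#' @rdname accessors
#' @export
setGeneric("traitMatrix", function(object) standardGeneric("traitMatrix"))
#' @rdname accessors
#' @export
setGeneric("genotypeMatrix", function(object) standardGeneric("genotypeMatrix"))
#' @rdname accessors
#' @export
setGeneric("lociTable", function(object) standardGeneric("lociTable"))
#' @rdname accessors
#' @export
setGeneric("countMatrix", function(object) standardGeneric("countMatrix"))
#' @rdname accessors
#' @export
setGeneric("geneTable", function(object) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("lakeEnvironment", function(object) standardGeneric("lakeEnvironment"))
#' @rdname accessors
#' @export
setGeneric("studyTruth", function(object) standardGeneric("studyTruth"))
#' @rdname accessors
#' @export
setGeneric("correctedTraits", function(object) standardGeneric("correctedTraits"))
#' @rdname accessors
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))
#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("k50", function(object) standardGeneric("k50"))
#' @rdname accessors
#' @export
setGeneric("trajectoryPairs", function(object) standardGeneric("trajectoryPairs"))
#' @rdname accessors
#' @export
setGeneric("trajectoryLengths", function(object) standardGeneric("trajectoryLengths"))
#' @rdname accessors
#' @export
setGeneric("trajectoryAngles", function(object) standardGeneric("trajectoryAngles"))
#' @rdname accessors
#' @export
setGeneric("fstTable", function(object) standardGeneric("fstTable"))
#' @rdname accessors
#' @export
setGeneric("genomeFst", function(object) standardGeneric("genomeFst"))
#' @rdname accessors
#' @export
setGeneric("candidateFeatures", function(object) standardGeneric("candidateFeatures"))
#' @rdname accessors
#' @export
setGeneric("moduleAssignment", function(object) standardGeneric("moduleAssignment"))
#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(object) standardGeneric("moduleEigengenes"))
#' @rdname accessors
#' @export
setGeneric("eqtlRecords", function(object) standardGeneric("eqtlRecords"))

#' @rdname accessors
setMethod("studySamples", "StudyBundle", function(object) object@samples)
#' @rdname accessors
setMethod("traitMatrix", "StudyBundle", function(object) object@traits)
#' @rdname accessors
setMethod("genotypeMatrix", "StudyBundle", function(object) object@genotypes)
#' @rdname accessors
setMethod("lociTable", "StudyBundle", function(object) object@loci)
#' @rdname accessors
setMethod("countMatrix", "StudyBundle", function(object) object@counts)
#' @rdname accessors
setMethod("geneTable", "StudyBundle", function(object) object@genes)
#' @rdname accessors
setMethod("lakeEnvironment", "StudyBundle", function(object) object@env)
#' @rdname accessors
setMethod("studyTruth", "StudyBundle", function(object) object@truth)
#' @rdname accessors
setMethod("correctedTraits", "CorrectedTraits", function(object) object@Y)
#' @rdname accessors
setMethod("pcaScores", "PcaResult", function(object) object@scores)
#' @rdname accessors
setMethod("pcaLoadings", "PcaResult", function(object) object@loadings)
#' @rdname accessors
setMethod("explainedVariance", "PcaResult", function(object) object@explained)
#' @rdname accessors
setMethod("k50", "PcaResult", function(object) object@k50)
#' @rdname accessors
setMethod("trajectoryPairs", "TrajectorySet", function(object) object@pairs)
#' @rdname accessors
setMethod("trajectoryLengths", "TrajectorySet", function(object) object@L)
#' @rdname accessors
setMethod("trajectoryAngles", "TrajectorySet", function(object) object@theta)
#' @rdname accessors
setMethod("fstTable", "FstScan", function(object) object@loci)
#' @rdname accessors
setMethod("genomeFst", "FstScan", function(object) object@meanFst)
#' @rdname accessors
setMethod("candidateFeatures", "RdaResult", function(object) object@candidates)
#' @rdname accessors
setMethod("moduleAssignment", "ModuleSet", function(object) object@assignment)
#' @rdname accessors
setMethod("moduleEigengenes", "ModuleSet", function(object) object@eigengenes)
#' @rdname accessors
setMethod("eqtlRecords", "EqtlResult", function(object) object@records)

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nLineages, "lineage(s) x",
      object@lakesPerLineage, "lake(s) x", object@ecotypesPerLake,
      "ecotypes x", object@nPerGroup, "fish\n")
  cat("  ", object@nTraits, "traits |", object@nSnps, "SNPs (",
      object@nAssocSnps, "assoc ) |", object@nGenes, "genes (",
      object@nDeGenes, "DE,", object@nEqtl, "eQTL)\n")
  cat("  driftF =", object@driftF, "| ecosystemCoupling =",
      object@ecosystemCoupling, "| seed =", object@seed, "\n")
})

setMethod("show", "StudyBundle", function(object) {
  s <- object@samples
  cat("StudyBundle:", nrow(s), "individuals,",
      length(unique(s$lake)), "lakes,",
      length(unique(s$lineage)), "lineage(s)\n")
  cat("  traits:", ncol(object@traits), "| SNPs:", ncol(object@genotypes),
      "| genes:", nrow(object@counts), "\n")
  cat("  ecotypes:", paste(sort(unique(s$ecotype)), collapse = ", "), "\n")
})

setMethod("show", "TrajectorySet", function(object) {
  cat("TrajectorySet:", nrow(object@pairs), "ecotype pairs,",
      ncol(object@vectors), "dimensions\n")
  cat("  mean angle:", round(mean(object@theta[upper.tri(object@theta)],
                                  na.rm = TRUE), 2), "deg | mean L:",
      round(mean(object@L), 4), "\n")
  if (object@nPerm > 0)
    cat("  permutation p-values attached (", object@nPerm, "permutations )\n")
})

setMethod("show", "FstScan", function(object) {
  cat("FstScan [", object@pair, "]:", nrow(object@loci), "loci\n")
  cat("  genome-wide Fst (ratio of sums):", signif(object@meanFst, 4), "\n")
  cat("  empirical outliers:", sum(object@loci$outlierEmp, na.rm = TRUE))
  if (!is.na(object@permNull95))
    cat(" | permuted-null outliers:", sum(object@loci$outlierPerm, na.rm = TRUE))
  cat("\n")
})

setMethod("show", "RdaResult", function(object) {
  cat("RdaResult:", nrow(object@loadings), "features,",
      ncol(object@loadings), "constrained axis/axes\n")
  cat("  explained (conditioned):", signif(object@explained, 4),
      "| pseudo-F p =", signif(object@p, 4), "(", object@nPerm, "perms )\n")
  cat("  candidates (|z| >", object@zCut, "):", length(object@candidates), "\n")
})

setMethod("show", "SharingResult", function(object) {
  cat("SharingResult (", object@level, "): observed", object@observed,
      "vs expected", signif(object@expected, 4), "\n")
  cat("  proportion-test p =", signif(object@p, 4), "(",
      object@nResample, "resamples, universe", object@universeSize, ")\n")
})

setMethod("show", "ModuleSet", function(object) {
  tab <- table(object@assignment[object@assignment != "unassigned"])
  cat("ModuleSet:", length(tab), "modules over",
      length(object@assignment), "genes\n")
  if (length(tab)) print(tab)
})

setMethod("show", "EqtlResult", function(object) {
  r <- object@records
  cat("EqtlResult:", nrow(r), "tested gene-SNP pairs within",
      object@window / 1e6, "Mb\n")
  for (lv in object@fdrLevels)
    cat("  significant at FDR <", lv, ":", sum(r$fdr < lv), "\n")
})

setMethod("show", "IntrogressionStats", function(object) {
  cat(object@stat, "=", signif(object@value, 5), "| Z =",
      signif(object@Z, 4), "(", object@nBlocks, "blocks of",
      object@blockSize, "loci )\n")
})

setMethod("show", "EcosystemPC", function(object) {
  cat("EcosystemPC:", nrow(object@table), "lakes; PC1 explains",
      round(100 * object@explained, 1), "%\n")
})
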