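#' Build a synthetic-study configuration
#'
#' Defaults describe a small two-lineage study with three lakes per lineage,
#' two sympatric ecotypes per lake (planktivorous and benthivorous) and 20
#' fish per group: the replicated-ecotype-pair design under which every
#' downstream stage of the pipeline is exercised. Trait effects act on the
#' log10 scale; `sharedEffectScale = 0.06` corresponds to roughly a 15%
#' proportional shift of an affected trait.
#'
#' @param nLineages,lakesPerLineage,ecotypesPerLake,nPerGroup study design.
#' @param nTraits,nSnps,nGenes data dimensions.
#' @param sharedEffectScale norm of the lineage-shared ecotype effect on
#'   log10 traits.
#' @param lakeNoiseScale scale of lake-specific deviations of the effect
#'   vector (0 = perfect parallelism).
#' @param allometrySlopes per-trait allometric slope b (recycled to nTraits).
#' @param traitNoiseSd residual s.d. of log10 trait values.
#' @param driftF Balding-Nichols drift of each population from the ancestral
#'   allele frequency.
#' @param nAssocSnps,assocDelta planted ecotype-associated SNPs and their
#'   total between-ecotype frequency shift.
#' @param missingRate MCAR missing-genotype rate.
#' @param nDeGenes,deLog2fc planted differentially expressed genes and their
#'   log2 fold change (shared across lakes).
#' @param nbDispersion negative-binomial dispersion (var = mu + alpha mu^2).
#' @param nEqtl,eqtlBeta planted cis-eQTL genes and the additive log2 effect
#'   per alternate allele.
#' @param ecosystemCoupling in [0,1]: how strongly the rotation of each
#'   lake's effect vector follows the lake's ecosystem-size score.
#' @param seed integer RNG seed.
#' @return A [SynthConfig-class] object.
#' @export
synthConfig <- function(nLineages = 2L, lakesPerLineage = 3L,
                        ecotypesPerLake = 2L, nPerGroup = 20L, nTraits = 7L,
                        nSnps = 2000L, nGenes = 3000L,
                        sharedEffectScale = 0.06, lakeNoiseScale = 0.015,
                        allometrySlopes = seq(0.8, 1.2,
                                              length.out = nTraits),
                        traitNoiseSd = 0.02, driftF = 0.05,
                        nAssocSnps = 20L, assocDelta = 0.3,
                        missingRate = 0.05, nDeGenes = 50L, deLog2fc = 2,
                        nbDispersion = 0.05, nEqtl = 10L, eqtlBeta = 1,
                        ecosystemCoupling = 0.5, seed = 1L) {
  new("SynthConfig",
      nLineages = as.integer(nLineages),
      lakesPerLineage = as.integer(lakesPerLineage),
      ecotypesPerLake = as.integer(ecotypesPerLake),
      nPerGroup = as.integer(nPerGroup), nTraits = as.integer(nTraits),
      nSnps = as.integer(nSnps), nGenes = as.integer(nGenes),
      sharedEffectScale = sharedEffectScale, lakeNoiseScale = lakeNoiseScale,
      allometrySlopes = rep_len(allometrySlopes, nTraits),
      traitNoiseSd = traitNoiseSd, driftF = driftF,
      nAssocSnps = as.integer(nAssocSnps), assocDelta = assocDelta,
      missingRate = missingRate, nDeGenes = as.integer(nDeGenes),
      deLog2fc = deLog2fc, nbDispersion = nbDispersion,
      nEqtl = as.integer(nEqtl), eqtlBeta = eqtlBeta,
      ecosystemCoupling = ecosystemCoupling, seed = as.integer(seed))
}

.ecotypeNames <- c("planktivorous", "benthivorous", "piscivorous")

# Rotate vector u by angle alpha in the plane spanned by u and w
# (w orthonormal to u); identity when alpha = 0 or u = 0.
.rotateInPlane <- function(u, w, alpha) {
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(u)
  e1 <- u / nu
  w <- w - sum(w * e1) * e1
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(u)
  e2 <- w / nw
  nu * (cos(alpha) * e1 + sin(alpha) * e2)
}

#' Simulate a multi-lake, multi-lineage ecotype study
#'
#' Generates all five linked tables of a replicated sympatric-ecotype study
#' with planted, recorded ground truth. Populations drift from ancestral
#' allele frequencies under a Balding-Nichols model; traits follow allometric
#' growth plus a lineage-shared ecotype effect vector, a lake-specific
#' deviation and Gaussian noise; counts are negative-binomial with ecotype
#' log-fold changes shared across lakes and an additive dosage term for eQTL
#' genes; each lake's effect-vector rotation tracks its ecosystem-size score
#' with weight `ecosystemCoupling`.
#'
#' Measured trait values are built as
#' `log10 M = log10 Ytrue - b (log10 Lm - log10 L)` so that
#' [sizeCorrectTraits()] can invert the allometry exactly at zero noise.
#'
#' @param config a [SynthConfig-class] from [synthConfig()].
#' @return A [StudyBundle-class] with the `truth` slot recording every
#'   planted signal.
#' @examples
#' bundle <- simulateStudy(synthConfig(nSnps = 100, nGenes = 50, seed = 7))
#' bundle
#' @export
simulateStudy <- function(config) {
  validObject(config)
  set.seed(config@seed)
  K <- config@ecotypesPerLake
  ecos <- .ecotypeNames[seq_len(K)]
  lineages <- paste0("lineage", seq_len(config@nLineages))
  lakes <- unlist(lapply(seq_len(config@nLineages), function(i)
    paste0("lake", i, letters[seq_len(config@lakesPerLineage)])))
  lakeLineage <- rep(lineages, each = config@lakesPerLineage)
  names(lakeLineage) <- lakes
  nLakes <- length(lakes)

  ## lake environment: depth and area log-correlated, so PC1 is a clean
  ## ecosystem-size axis
  logDepth <- rnorm(nLakes, log(30), 0.6)
  logArea <- 0.8 * (logDepth - log(30)) + rnorm(nLakes, log(4), 0.4)
  env <- data.frame(lake = lakes, maxDepth = exp(logDepth),
                    surfaceArea = exp(logArea))
  if (nLakes >= 3) {
    zPc1 <- as.numeric(scale(prcomp(scale(cbind(logDepth, logArea)))$x[, 1]))
    # orient so larger lakes score higher
    if (cor(zPc1, logDepth + logArea) < 0) zPc1 <- -zPc1
  } else zPc1 <- rep(0, nLakes)

  ## samples
  samples <- do.call(rbind, lapply(seq_along(lakes), function(li)
    do.call(rbind, lapply(ecos, function(e)
      data.frame(lake = lakes[li], lineage = lakeLineage[li], ecotype = e,
                 stringsAsFactors = FALSE)))))
  samples <- samples[rep(seq_len(nrow(samples)), each = config@nPerGroup), ]
  rownames(samples) <- NULL
  samples$id <- sprintf("ind%04d", seq_len(nrow(samples)))
  samples <- samples[, c("id", "lake", "lineage", "ecotype")]
  n <- nrow(samples)

  ## fork length (mm): lineage means differ; within-lineage lognormal spread
  linMeanL <- setNames(seq(180, 240, length.out = config@nLineages), lineages)
  log10L <- rnorm(n, log10(linMeanL[samples$lineage]), 0.05)
  samples$forkLength <- 10^log10L

  ## effect vectors: shared per lineage-wide ecotype contrast, rotated and
  ## perturbed per lake; rotation angle tracks ecosystem PC1
  P <- config@nTraits
  uB <- rnorm(P); uB <- uB / sqrt(sum(uB^2)) * config@sharedEffectScale
  uP <- rnorm(P); uP <- uP - sum(uP * uB) * uB / max(sum(uB^2), 1e-12)
  if (sqrt(sum(uP^2)) > 0)
    uP <- uP / sqrt(sum(uP^2)) * config@sharedEffectScale
  w <- rnorm(P)
  # typical angular deviation the additive noise alone would cause
  rotScale <- if (config@sharedEffectScale > 0)
    atan2(config@lakeNoiseScale * sqrt(P), config@sharedEffectScale) else 0
  cpl <- config@ecosystemCoupling
  alpha <- rotScale * (cpl * zPc1 + sqrt(max(0, 1 - cpl^2)) * rnorm(nLakes))
  effB <- t(vapply(seq_len(nLakes), function(li)
    .rotateInPlane(uB, w, alpha[li]) +
      rnorm(P, 0, config@lakeNoiseScale / 2), numeric(P)))
  effP <- t(vapply(seq_len(nLakes), function(li)
    .rotateInPlane(uP, w, alpha[li]) +
      rnorm(P, 0, config@lakeNoiseScale / 2), numeric(P)))
  rownames(effB) <- rownames(effP) <- lakes

  ## traits (mm): log10 Ytrue = log10 base + ecotype effect + noise, then
  ## allometric growth towards measured values
  base <- runif(P, 0.7, 1.6)   # log10 mm of trait baselines
  li <- match(samples$lake, lakes)
  effect <- matrix(0, n, P)
  effect[samples$ecotype == "benthivorous", ] <-
    effB[li[samples$ecotype == "benthivorous"], , drop = FALSE]
  if (K == 3)
    effect[samples$ecotype == "piscivorous", ] <-
      effP[li[samples$ecotype == "piscivorous"], , drop = FALSE]
  log10Ytrue <- matrix(base, n, P, byrow = TRUE) + effect +
    matrix(rnorm(n * P, 0, config@traitNoiseSd), n, P)
  LmReal <- tapply(samples$forkLength, samples$lineage, mean)
  b <- config@allometrySlopes
  log10M <- log10Ytrue - outer(log10(LmReal[samples$lineage]) - log10L, b)
  traits <- 10^log10M
  colnames(traits) <- paste0("T", seq_len(P))
  rownames(traits) <- samples$id

  ## genotypes: Balding-Nichols drift per population; planted shifts at
  ## associated SNPs applied around the lake frequency
  S <- config@nSnps
  pAnc <- runif(S, 0.05, 0.95)
  Fst <- config@driftF
  sh <- (1 - Fst) / Fst
  pops <- interaction(samples$lake, samples$ecotype, drop = TRUE)
  popTab <- unique(data.frame(pop = as.character(pops), lake = samples$lake,
                              ecotype = samples$ecotype))
  assocIdx <- if (config@nAssocSnps > 0) sort(sample.int(S, config@nAssocSnps))
              else integer()
  isAssoc <- seq_len(S) %in% assocIdx
  popFreq <- matrix(0, nrow(popTab), S, dimnames = list(popTab$pop, NULL))
  lakeFreqAssoc <- matrix(0, nLakes, S)
  for (lk in seq_len(nLakes))
    lakeFreqAssoc[lk, ] <- rbeta(S, pAnc * sh, (1 - pAnc) * sh)
  for (pi in seq_len(nrow(popTab))) {
    f <- rbeta(S, pAnc * sh, (1 - pAnc) * sh)
    if (any(isAssoc)) {
      lk <- match(popTab$lake[pi], lakes)
      shift <- if (popTab$ecotype[pi] == "planktivorous")
        -config@assocDelta / 2 else config@assocDelta / 2
      f[isAssoc] <- pmin(0.99, pmax(0.01, lakeFreqAssoc[lk, isAssoc] + shift))
    }
    popFreq[pi, ] <- f
  }
  genotypes <- matrix(rbinom(n * S, 2L,
                             popFreq[as.character(pops), , drop = FALSE]),
                      n, S)
  if (config@missingRate > 0)
    genotypes[runif(n * S) < config@missingRate] <- NA
  rownames(genotypes) <- samples$id
  colnames(genotypes) <- sprintf("snp%05d", seq_len(S))

  nChrom <- 4L
  snpChrom <- sort(rep_len(seq_len(nChrom), S))
  snpPos <- integer(S)
  for (ch in seq_len(nChrom)) {
    k <- sum(snpChrom == ch)
    snpPos[snpChrom == ch] <- sort(sample.int(60e6, k))
  }
  loci <- data.frame(snp = colnames(genotypes),
                     chrom = paste0("chr", snpChrom), pos = snpPos,
                     contig = sprintf("ctg%05d", seq_len(S)),
                     assoc = isAssoc, stringsAsFactors = FALSE)

  ## expression: NB counts with per-individual size factors, planted DE and
  ## cis-eQTL genes
  G <- config@nGenes
  mu <- rlnorm(G, log(100), 1)
  sf <- rlnorm(n, 0, 0.15)
  deIdx <- if (config@nDeGenes > 0)
    sort(sample.int(G, config@nDeGenes)) else integer()
  eqtlGene <- if (config@nEqtl > 0)
    sort(sample(setdiff(seq_len(G), deIdx), config@nEqtl)) else integer()
  eqtlSnp <- if (config@nEqtl > 0) sample.int(S, config@nEqtl) else integer()
  log2mu <- matrix(log2(mu), G, n)
  nonPlank <- samples$ecotype != "planktivorous"
  log2mu[deIdx, nonPlank] <- log2mu[deIdx, nonPlank] + config@deLog2fc
  if (length(eqtlGene)) {
    dos <- genotypes[, eqtlSnp, drop = FALSE]
    for (k in seq_along(eqtlGene)) {
      d <- dos[, k]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      log2mu[eqtlGene[k], ] <- log2mu[eqtlGene[k], ] +
        config@eqtlBeta * (d - 1)
    }
  }
  muMat <- 2^log2mu * matrix(sf, G, n, byrow = TRUE)
  counts <- if (config@nbDispersion > 0)
    matrix(rnbinom(G * n, mu = muMat, size = 1 / config@nbDispersion), G, n)
  else matrix(stats::rpois(G * n, muMat), G, n)
  rownames(counts) <- sprintf("gene%05d", seq_len(G))
  colnames(counts) <- samples$id

  geneChrom <- sample.int(nChrom, G, replace = TRUE)
  genePos <- sample.int(60e6, G, replace = TRUE)
  if (length(eqtlGene)) {
    geneChrom[eqtlGene] <- snpChrom[eqtlSnp]
    genePos[eqtlGene] <- pmax(1L, as.integer(
      snpPos[eqtlSnp] + round(runif(length(eqtlSnp), -5e5, 5e5))))
  }
  genes <- data.frame(gene = rownames(counts),
                      chrom = paste0("chr", geneChrom), pos = genePos,
                      de = seq_len(G) %in% deIdx,
                      eqtlSnp = NA_integer_, stringsAsFactors = FALSE)
  genes$eqtlSnp[eqtlGene] <- eqtlSnp

  truth <- list(
    effectBenthic = effB,
    effectPiscivorous = if (K == 3) effP else NULL,
    sharedEffect = uB, allometrySlopes = b, lineageMeanL = LmReal,
    assocSnps = loci$snp[assocIdx], deGenes = rownames(counts)[deIdx],
    eqtl = if (length(eqtlGene))
      data.frame(gene = rownames(counts)[eqtlGene],
                 snp = colnames(genotypes)[eqtlSnp],
                 stringsAsFactors = FALSE)
    else data.frame(gene = character(), snp = character()),
    ecosystemScore = setNames(zPc1, lakes),
    rotationAngle = setNames(alpha, lakes))

  new("StudyBundle", samples = samples, traits = traits,
      genotypes = genotypes, loci = loci, counts = counts, genes = genes,
      env = env, truth = truth)
}

#' Flat table of all planted signals in a synthetic study
#'
#' @param bundle a [StudyBundle-class] from [simulateStudy()].
#' @return data.frame with columns `type` ("assoc_snp", "de_gene", "eqtl"),
#'   `feature` and `partner` (the SNP of an eQTL gene, else NA); zero rows
#'   for a null study.
#' @export
truthReport <- function(bundle) {
  tr <- studyTruth(bundle)
  out <- rbind(
    if (length(tr$assocSnps))
      data.frame(type = "assoc_snp", feature = tr$assocSnps,
                 partner = NA_character_),
    if (length(tr$deGenes))
      data.frame(type = "de_gene", feature = tr$deGenes,
                 partner = NA_character_),
    if (nrow(tr$eqtl))
      data.frame(type = "eqtl", feature = tr$eqtl$gene,
                 partner = tr$eqtl$snp))
  if (is.null(out))
    out <- data.frame(type = character(), feature = character(),
                      partner = character())
  rownames(out) <- NULL
  out
}
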