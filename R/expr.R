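#' Median-of-ratios normalization of a count matrix
#'
#' Size factor per sample = median over genes of the ratio of its count to
#' the per-gene geometric mean across samples (genes with any zero count are
#' excluded from the reference); factors are rescaled to geometric mean 1.
#' Normalized values are `log2(count / sizeFactor + 1)`.
#'
#' @param counts matrix genes x samples of non-negative integers.
#' @return list: `normalized` (log2 matrix, same shape), `sizeFactors`
#'   (named, geometric mean 1), `counts`.
#' @export
normalizeCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  zeroSamp <- colSums(counts) == 0
  if (any(zeroSamp))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zeroSamp], collapse = ", "))
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos))
    stop("need at least one gene with all-positive counts")
  logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
  sf <- apply(counts[allPos, , drop = FALSE], 2, function(cc)
    exp(median(log(cc) - logGeo)))
  sf <- sf / exp(mean(log(sf)))
  norm <- log2(sweep(counts, 2, sf, "/") + 1)
  list(normalized = norm, sizeFactors = sf, counts = counts)
}

#' Filter genes by minimum total count per lake
#'
#' Keeps genes whose summed raw count reaches `minPerLake` within every
#' lake.
#'
#' @param counts matrix genes x samples.
#' @param lake lake label per sample (column).
#' @param minPerLake minimum per-lake total (default 20).
#' @return logical vector per gene (TRUE = keep); warns when empty.
#' @export
filterGenes <- function(counts, lake, minPerLake = 20) {
  lake <- as.character(lake)
  perLake <- vapply(unique(lake), function(lk)
    rowSums(counts[, lake == lk, drop = FALSE]), numeric(nrow(counts)))
  keep <- rowSums(perLake >= minPerLake) == length(unique(lake))
  if (!any(keep)) warning("no genes pass the per-lake count filter")
  keep
}

#' Per-lake differential expression between sympatric ecotypes
#'
#' A defined, self-contained test: per gene, a Welch t-test on normalized
#' log2 values between the two ecotypes within one lake, with
#' Benjamini-Hochberg correction across genes within the lake. Fold changes
#' are oriented derived ecotype minus planktivorous (the trajectory
#' convention). Genes without residual variance are reported with p = NA.
#'
#' @param normalized matrix genes x samples of log2 values.
#' @param samples data.frame per column: lake, ecotype.
#' @param lake the lake to analyse.
#' @param ecoFrom,ecoTo the ecotype pair (default planktivorous vs the
#'   lake's other ecotype).
#' @param fdr significance threshold on BH-adjusted p (default 0.05).
#' @return data.frame per gene: log2fc, t, p, fdr, significant.
#' @export
differentialExpression <- function(normalized, samples, lake,
                                   ecoFrom = "planktivorous", ecoTo = NULL,
                                   fdr = 0.05) {
  sel <- samples$lake == lake
  ecos <- unique(samples$ecotype[sel])
  if (length(ecos) < 2) stop("lake ", lake, " has a single ecotype")
  if (is.null(ecoTo)) ecoTo <- setdiff(ecos, ecoFrom)[1]
  iF <- which(sel & samples$ecotype == ecoFrom)
  iT <- which(sel & samples$ecotype == ecoTo)
  if (length(iF) < 2 || length(iT) < 2)
    stop("need at least 2 individuals per ecotype")
  if (length(iF) < 3 || length(iT) < 3)
    warning("fewer than 3 individuals per ecotype: low power")
  A <- normalized[, iT, drop = FALSE]
  B <- normalized[, iF, drop = FALSE]
  mT <- rowMeans(A); mF <- rowMeans(B)
  vT <- apply(A, 1, var); vF <- apply(B, 1, var)
  nT <- ncol(A); nF <- ncol(B)
  seq2 <- vT / nT + vF / nF
  tstat <- ifelse(seq2 > 0, (mT - mF) / sqrt(seq2), NA_real_)
  df <- seq2^2 / ((vT / nT)^2 / (nT - 1) + (vF / nF)^2 / (nF - 1))
  p <- 2 * pt(-abs(tstat), df)
  out <- data.frame(gene = rownames(normalized), log2fc = mT - mF,
                    t = tstat, p = p, fdr = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$fdr) & out$fdr < fdr
  out
}

#' Sharing of differentially expressed genes between two comparisons
#'
#' Delegates to [sharingTest()] at the gene level.
#'
#' @param degA,degB character vectors of DEG names.
#' @param universe all genes tested in both comparisons.
#' @param nResample,seed as in [sharingTest()].
#' @return A [SharingResult-class].
#' @export
degSharing <- function(degA, degB, universe, nResample = 10000, seed) {
  sharingTest(degA, degB, universe, nResample = nResample, level = "gene",
              seed = seed)
}

#' Genes whose expression variance is dominated by ecotype
#'
#' Per gene, a fixed-effects ANOVA `expression ~ ecotype + lake`
#' partitions the total sum of squares; the ecotype fraction is the Type-II
#' ecotype sum of squares over the total. Genes exceeding `threshold`
#' (default 10%) are retained for network construction.
#'
#' @param normalized matrix genes x samples.
#' @param samples data.frame per column: ecotype, lake.
#' @param threshold minimum ecotype variance fraction.
#' @return list: `fraction` (named per gene), `keep` (logical).
#' @export
ecotypeVarianceFilter <- function(normalized, samples, threshold = 0.10) {
  eco <- factor(samples$ecotype)
  lk <- factor(samples$lake)
  if (nlevels(eco) < 2 || nlevels(lk) < 2)
    stop("need >= 2 ecotypes and >= 2 lakes")
  Xfull <- model.matrix(~ eco + lk)
  Xlake <- model.matrix(~ lk)
  qf <- qr(Xfull); ql <- qr(Xlake)
  Yt <- t(normalized)
  rFull <- Yt - qr.fitted(qf, Yt)
  rLake <- Yt - qr.fitted(ql, Yt)
  ssEco <- colSums(rLake^2) - colSums(rFull^2)
  Yc <- scale(Yt, center = TRUE, scale = FALSE)
  ssTot <- colSums(Yc^2)
  frac <- ifelse(ssTot > 0, ssEco / ssTot, 0)
  names(frac) <- rownames(normalized)
  list(fraction = frac, keep = frac > threshold)
}

.eigengene <- function(M) {
  # M: samples x member genes, standardized columns; unit-norm PC1 oriented
  # to positive mean loading
  Ms <- scale(M)
  Ms[!is.finite(Ms)] <- 0
  sv <- svd(Ms, nu = 1, nv = 1)
  e <- sv$u[, 1]
  if (mean(sv$v[, 1]) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Detect co-expression modules by static tree cut
#'
#' Network topology: adjacency `|Pearson r|^softPower` between genes,
#' dissimilarity `1 - adjacency`, average-linkage hierarchical clustering,
#' static cut at `cutHeight`, clusters below `minSize` discarded
#' (unassigned), then iterative merging of modules whose eigengenes are
#' closer than `mergeDist` in correlation distance (1 - r). Module labels
#' are ordered by size (M1 largest), making results invariant to gene
#' input order.
#'
#' @param normalized matrix genes x samples (typically restricted to
#'   ecotype-associated genes).
#' @param softPower adjacency exponent (default 6).
#' @param cutHeight static cut height on the dendrogram (default 0.992).
#' @param minSize minimum module size (default 25).
#' @param mergeDist eigengene correlation-distance merge threshold
#'   (default 0.25).
#' @return A [ModuleSet-class].
#' @export
coexpressionModules <- function(normalized, softPower = 6,
                                cutHeight = 0.992, minSize = 25,
                                mergeDist = 0.25) {
  v <- apply(normalized, 1, var)
  ok <- !is.na(v) & v > 0
  if (sum(ok) < 2) stop("need >= 2 genes with variance")
  E <- t(normalized[ok, , drop = FALSE])   # samples x genes
  adj <- abs(cor(E))^softPower
  diss <- 1 - adj
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cutHeight)
  assignment <- setNames(rep("unassigned", nrow(normalized)),
                         rownames(normalized))
  sizes <- table(cl)
  keepCl <- names(sizes)[sizes >= minSize]
  modGenes <- lapply(keepCl, function(k) colnames(E)[cl == as.integer(k)])
  # merge modules with similar eigengenes
  repeat {
    if (length(modGenes) < 2) break
    eg <- vapply(modGenes, function(g) .eigengene(E[, g, drop = FALSE]),
                 numeric(nrow(E)))
    dm <- 1 - cor(eg)
    diag(dm) <- Inf
    if (min(dm) >= mergeDist) break
    ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    modGenes[[ij[1]]] <- c(modGenes[[ij[1]]], modGenes[[ij[2]]])
    modGenes[[ij[2]]] <- NULL
  }
  if (length(modGenes)) {
    ord <- order(vapply(modGenes, length, 0L), decreasing = TRUE)
    modGenes <- modGenes[ord]
    names(modGenes) <- paste0("M", seq_along(modGenes))
    for (m in names(modGenes)) assignment[modGenes[[m]]] <- m
    eg <- vapply(modGenes, function(g) .eigengene(E[, g, drop = FALSE]),
                 numeric(nrow(E)))
    rownames(eg) <- rownames(E)
  } else {
    eg <- matrix(numeric(0), nrow(E), 0,
                 dimnames = list(rownames(E), NULL))
  }
  new("ModuleSet", assignment = assignment, eigengenes = eg,
      minSize = as.integer(minSize), moduleTrait = data.frame())
}

#' Correlate module eigengenes with ecotype and lake
#'
#' Pearson correlation of each module eigengene with the numeric ecotype
#' code (planktivorous 0, derived 1) and with each lake indicator (the
#' strongest lake correlation is reported), with Benjamini-Hochberg
#' correction across all module x variable tests.
#'
#' @param modules a [ModuleSet-class].
#' @param samples data.frame per sample: ecotype, lake (aligned with the
#'   eigengene rows).
#' @param fdr significance threshold (default 0.05).
#' @return The module set with `moduleTrait` filled: module, variable, r,
#'   p, fdr, significant.
#' @export
moduleTraitCorrelation <- function(modules, samples, fdr = 0.05) {
  eg <- moduleEigengenes(modules)
  if (!ncol(eg)) {
    modules@moduleTrait <- data.frame()
    return(modules)
  }
  eco <- as.numeric(samples$ecotype != "planktivorous")
  lakes <- sort(unique(samples$lake))
  rows <- list()
  for (m in colnames(eg)) {
    ct <- cor.test(eg[, m], eco)
    rows[[length(rows) + 1]] <- data.frame(module = m, variable = "ecotype",
                                           r = unname(ct$estimate),
                                           p = ct$p.value)
    lakeR <- vapply(lakes, function(lk)
      suppressWarnings(cor(eg[, m], as.numeric(samples$lake == lk))), 0)
    best <- lakes[which.max(abs(lakeR))]
    ct <- cor.test(eg[, m], as.numeric(samples$lake == best))
    rows[[length(rows) + 1]] <- data.frame(module = m, variable = "lake",
                                           r = unname(ct$estimate),
                                           p = ct$p.value)
  }
  tab <- do.call(rbind, rows)
  tab$fdr <- p.adjust(tab$p, "BH")
  tab$significant <- tab$fdr < fdr
  modules@moduleTrait <- tab
  modules
}

#' cis-eQTL mapping with lake and lineage covariates
#'
#' For every gene-SNP pair on the same chromosome within `window` bp, fits
#' normalized expression on additive dosage plus lake and lineage dummies
#' by least squares and t-tests the dosage coefficient; Benjamini-Hochberg
#' correction across all tested pairs. Monomorphic SNPs are skipped.
#'
#' @param normalized matrix genes x samples.
#' @param genes data.frame per gene: gene, chrom, pos.
#' @param genotypes matrix samples x SNPs of dosages (imputed; no missing).
#' @param loci data.frame per SNP: snp, chrom, pos.
#' @param covariates data.frame per sample: lake, lineage (either may be
#'   constant and is then dropped).
#' @param window maximum gene-SNP distance in bp (default 1e6).
#' @param fdrLevels FDR thresholds to report (default 0.1 and 0.05).
#' @return An [EqtlResult-class].
#' @export
cisEqtl <- function(normalized, genes, genotypes, loci, covariates,
                    window = 1e6, fdrLevels = c(0.1, 0.05)) {
  covariates <- as.data.frame(covariates)
  covariates[] <- lapply(covariates, factor)
  covariates <- covariates[, vapply(covariates, nlevels, 0L) >= 2,
                           drop = FALSE]
  X0 <- if (ncol(covariates))
    model.matrix(~ ., covariates) else
      matrix(1, ncol(normalized), 1)
  q0 <- qr(X0)
  n <- ncol(normalized)
  ## residualize expression and dosage on the covariates once; the dosage
  ## t-statistic from the residualized simple regression is identical to
  ## the full multiple-regression t with df = n - rank - 1
  Er <- t(normalized) - qr.fitted(q0, t(normalized))
  Gr <- genotypes - qr.fitted(q0, genotypes)
  dfres <- n - q0$rank - 1
  recs <- list()
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    si <- which(loci$chrom == ch)
    if (!length(gi) || !length(si)) next
    for (g in gi) {
      d <- abs(loci$pos[si] - genes$pos[g])
      sTest <- si[d <= window]
      dTest <- d[d <= window]
      if (!length(sTest)) next
      y <- Er[, g]
      X <- Gr[, sTest, drop = FALSE]
      sxx <- colSums(X^2)
      mono <- apply(genotypes[, sTest, drop = FALSE], 2, var) == 0
      sxy <- as.numeric(crossprod(X, y))
      beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
      ssRes <- sum(y^2) - beta^2 * sxx
      sigma2 <- ssRes / dfres
      tstat <- beta / sqrt(sigma2 / sxx)
      p <- 2 * pt(-abs(tstat), dfres)
      keep <- !mono & sxx > 0 & is.finite(p)
      if (!any(keep)) next
      recs[[length(recs) + 1]] <- data.frame(
        gene = genes$gene[g], snp = loci$snp[sTest][keep],
        distance = dTest[keep], beta = beta[keep], t = tstat[keep],
        p = p[keep], stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(), snp = character(), distance = numeric(),
               beta = numeric(), t = numeric(), p = numeric())
  records$fdr <- p.adjust(records$p, "BH")
  rownames(records) <- NULL
  new("EqtlResult", records = records, window = window,
      fdrLevels = fdrLevels)
}
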