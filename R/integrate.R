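#' Ecosystem-size axis from lake depth and area
#'
#' PC1 of the z-standardized log-free variables (maximum depth, surface
#' area), oriented so larger lakes score higher; pairwise lake distances
#' are the absolute PC1 differences.
#'
#' @param env data.frame: lake, maxDepth (m), surfaceArea (km2).
#' @return An [EcosystemPC-class].
#' @export
ecosystemPc <- function(env) {
  if (nrow(env) < 3) stop("need at least 3 lakes")
  if (any(is.na(env$maxDepth)) || any(is.na(env$surfaceArea)))
    stop("missing depth or area")
  if (any(env$maxDepth <= 0) || any(env$surfaceArea <= 0))
    stop("depth and area must be positive")
  X <- scale(cbind(depth = env$maxDepth, area = env$surfaceArea))
  pc <- prcomp(X)
  s <- pc$x[, 1]
  if (cor(s, env$maxDepth + env$surfaceArea) < 0) s <- -s
  expl <- pc$sdev[1]^2 / sum(pc$sdev^2)
  d <- abs(outer(s, s, "-"))
  dimnames(d) <- list(env$lake, env$lake)
  new("EcosystemPC",
      table = data.frame(lake = env$lake, maxDepth = env$maxDepth,
                         surfaceArea = env$surfaceArea, pc1 = as.numeric(s)),
      dist = d, explained = expl)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower-triangle entries; significance by
#' permuting the object labels of the second matrix, with a one-sided
#' (positive-association) p-value by default.
#'
#' @param matA,matB symmetric matrices with matching labelled dimensions,
#'   >= 4 objects.
#' @param nPerm permutations (default 999).
#' @param seed integer seed (required).
#' @param alternative "greater" (default) or "two.sided".
#' @return list: r, p, nPerm, n (objects), alternative.
#' @export
mantelTest <- function(matA, matB, nPerm = 999, seed,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("a seed is required for reproducibility")
  matA <- as.matrix(matA); matB <- as.matrix(matB)
  if (!identical(dim(matA), dim(matB)))
    stop("matrices must have the same dimensions")
  if (nrow(matA) < 4) stop("need at least 4 objects")
  if (!is.null(rownames(matA)) && !is.null(rownames(matB))) {
    if (!identical(rownames(matA), rownames(matB)))
      stop("object labels must match")
  }
  set.seed(as.integer(seed))
  lt <- lower.tri(matA)
  ok <- is.finite(matA[lt]) & is.finite(matB[lt])
  r <- suppressWarnings(cor(matA[lt][ok], matB[lt][ok]))
  if (!is.finite(r))
    return(list(r = NA_real_, p = NA_real_, nPerm = nPerm, n = nrow(matA),
                alternative = alternative))
  n <- nrow(matA)
  ge <- 0L
  for (p in seq_len(nPerm)) {
    pe <- sample.int(n)
    Bp <- matB[pe, pe]
    okp <- is.finite(matA[lt]) & is.finite(Bp[lt])
    rp <- suppressWarnings(cor(matA[lt][okp], Bp[lt][okp]))
    if (!is.finite(rp)) next
    if (alternative == "greater") {
      if (rp >= r) ge <- ge + 1L
    } else if (abs(rp) >= abs(r)) ge <- ge + 1L
  }
  list(r = r, p = (1 + ge) / (nPerm + 1), nPerm = nPerm, n = n,
       alternative = alternative)
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: slope, intercept, r2, p (two-sided slope test), n.
#' @export
olsRegression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0) stop("x has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, p = sm$coefficients[2, 4], n = length(x))
}

## Distance matrix between ecotype pairs on the ecosystem axis: the PC1
## distance between the pairs' lakes.
.pairEcosystemDist <- function(trajset, eco) {
  lakes <- trajectoryPairs(trajset)$lake
  d <- eco@dist[lakes, lakes, drop = FALSE]
  dimnames(d) <- list(trajectoryPairs(trajset)$pair,
                      trajectoryPairs(trajset)$pair)
  d
}

## Align a second trajectory set's matrices to a reference pair ordering.
.alignedMatrix <- function(trajset, what, refPairs) {
  m <- slot(trajset, what)
  common <- intersect(refPairs, rownames(m))
  if (length(common) < 4) return(NULL)
  m[common, common, drop = FALSE]
}

#' The integrated predictability report
#'
#' Assembles the pre-registered battery of twelve correlation and
#' regression analyses linking phenotypic, genetic and expression
#' divergence with each other and with ecosystem size: Mantel tests between
#' angle matrices (phenotype vs neutral-genetic, vs ecotype-associated
#' genetic, vs ecotype-associated expression; phenotype vs expression
#' length differences), regressions (phenotypic trajectory length on
#' neutral Fst, nucleotide diversity on ecosystem PC1, mean within-lake
#' trait variance on ecosystem PC1) and Mantel tests against ecosystem
#' distance (phenotypic, neutral-genetic and associated-genetic angles;
#' expression angles and length differences). Analyses whose inputs are
#' missing are reported as not computed, never silently dropped.
#'
#' @param trajP,trajGn,trajRda,trajGex,trajCanGex [TrajectorySet-class]
#'   objects for phenotypes, neutral SNPs, ecotype-associated SNPs, all
#'   expression and ecotype-associated expression (any may be NULL).
#' @param fstNeut named numeric: genome-wide neutral Fst per ecotype pair
#'   (names matching `trajP` pairs).
#' @param popPi named numeric: nucleotide diversity per population.
#' @param popLake named character: lake of each population in `popPi`.
#' @param eco an [EcosystemPC-class].
#' @param traitVarByLake named numeric: mean within-lake pooled variance of
#'   size-corrected traits.
#' @param nPerm Mantel permutations.
#' @param seed integer seed.
#' @return data.frame: analysis, type, statistic, value, p, n, computed.
#' @export
predictabilityReport <- function(trajP, trajGn = NULL, trajRda = NULL,
                                 trajGex = NULL, trajCanGex = NULL,
                                 fstNeut = NULL, popPi = NULL,
                                 popLake = NULL, eco = NULL,
                                 traitVarByLake = NULL, nPerm = 999,
                                 seed = 1L) {
  seed <- as.integer(seed)
  refPairs <- trajectoryPairs(trajP)$pair
  rows <- list()
  addRow <- function(analysis, type, statistic, value, p, n, computed) {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, type = type, statistic = statistic,
      value = value, p = p, n = n, computed = computed)
  }
  mantelRow <- function(name, mA, mB, off) {
    if (is.null(mA) || is.null(mB)) {
      addRow(name, "mantel", "r", NA_real_, NA_real_, NA_integer_, FALSE)
    } else {
      common <- intersect(rownames(mA), rownames(mB))
      if (length(common) < 4) {
        addRow(name, "mantel", "r", NA_real_, NA_real_, NA_integer_, FALSE)
      } else {
        mt <- mantelTest(mA[common, common], mB[common, common],
                         nPerm = nPerm, seed = seed + off)
        addRow(name, "mantel", "r", mt$r, mt$p, length(common), TRUE)
      }
    }
  }
  regRow <- function(name, x, y) {
    if (is.null(x) || is.null(y) || sum(is.finite(x) & is.finite(y)) < 3) {
      addRow(name, "regression", "r2", NA_real_, NA_real_, NA_integer_,
             FALSE)
    } else {
      rg <- olsRegression(x, y)
      addRow(name, "regression", "r2", rg$r2, rg$p, rg$n, TRUE)
    }
  }
  thP <- trajectoryAngles(trajP)
  dlP <- trajP@dL

  mantelRow("thetaP~thetaGn", thP,
            if (!is.null(trajGn)) .alignedMatrix(trajGn, "theta", refPairs),
            1L)
  mantelRow("thetaP~thetaRDA", thP,
            if (!is.null(trajRda)) .alignedMatrix(trajRda, "theta", refPairs),
            2L)
  mantelRow("thetaP~thetaCanGEx", thP,
            if (!is.null(trajCanGex))
              .alignedMatrix(trajCanGex, "theta", refPairs), 3L)
  mantelRow("dLP~dLGEx", dlP,
            if (!is.null(trajGex)) .alignedMatrix(trajGex, "dL", refPairs),
            4L)

  if (!is.null(fstNeut)) {
    common <- intersect(refPairs, names(fstNeut))
    regRow("LP~FstNeut", trajectoryLengths(trajP)[common], fstNeut[common])
  } else regRow("LP~FstNeut", NULL, NULL)
  if (!is.null(popPi) && !is.null(popLake) && !is.null(eco)) {
    pc1 <- setNames(eco@table$pc1, eco@table$lake)
    regRow("pi~ecosystemPC1", pc1[popLake[names(popPi)]], popPi)
  } else regRow("pi~ecosystemPC1", NULL, NULL)
  if (!is.null(traitVarByLake) && !is.null(eco)) {
    pc1 <- setNames(eco@table$pc1, eco@table$lake)
    regRow("traitVar~ecosystemPC1", pc1[names(traitVarByLake)],
           traitVarByLake)
  } else regRow("traitVar~ecosystemPC1", NULL, NULL)

  ecoD <- if (!is.null(eco)) .pairEcosystemDist(trajP, eco) else NULL
  mantelRow("thetaP~ecosystemDist", thP, ecoD, 5L)
  mantelRow("thetaGn~ecosystemDist",
            if (!is.null(trajGn)) .alignedMatrix(trajGn, "theta", refPairs),
            ecoD, 6L)
  mantelRow("thetaRDA~ecosystemDist",
            if (!is.null(trajRda)) .alignedMatrix(trajRda, "theta", refPairs),
            ecoD, 7L)
  mantelRow("thetaGEx~ecosystemDist",
            if (!is.null(trajGex)) .alignedMatrix(trajGex, "theta", refPairs),
            ecoD, 8L)
  mantelRow("dLGEx~ecosystemDist",
            if (!is.null(trajGex)) .alignedMatrix(trajGex, "dL", refPairs),
            ecoD, 9L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean within-lake pooled variance of size-corrected traits
#'
#' For each lake, the pooled (within-ecotype) variance of each corrected
#' trait, averaged over traits: a summary of standing phenotypic variation
#' used in the ecosystem-size regressions.
#'
#' @param ct a [CorrectedTraits-class].
#' @param samples data.frame: lake, ecotype per individual.
#' @return named numeric per lake.
#' @export
traitVarianceByLake <- function(ct, samples) {
  Y <- correctedTraits(ct)
  vapply(unique(samples$lake), function(lk) {
    sel <- samples$lake == lk
    grp <- samples$ecotype[sel]
    v <- vapply(seq_len(ncol(Y)), function(j) {
      ssw <- 0; dfw <- 0
      for (e in unique(grp)) {
        y <- Y[sel, j][grp == e]
        y <- y[is.finite(y)]
        if (length(y) > 1) {
          ssw <- ssw + sum((y - mean(y))^2)
          dfw <- dfw + length(y) - 1
        }
      }
      if (dfw > 0) ssw / dfw else NA_real_
    }, 0)
    mean(v, na.rm = TRUE)
  }, 0)
}
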