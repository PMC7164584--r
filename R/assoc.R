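## Predictor coding for ecotype: numeric passthrough, 0/1 for two ecotypes,
## and two indicator contrasts for three (benthivorous-vs-rest and
## piscivorous-vs-rest), which yields the RDA1 + RDA2 geometry of
## three-ecotype designs.
.ecotypePredictor <- function(ecotype) {
  if (is.numeric(ecotype)) return(cbind(eco = ecotype))
  ec <- as.character(ecotype)
  lv <- sort(unique(ec))
  if (length(lv) == 2) {
    ref <- if ("planktivorous" %in% lv) "planktivorous" else lv[1]
    return(cbind(eco = as.numeric(ec != ref)))
  }
  if (length(lv) == 3) {
    x1 <- as.numeric(ec == "benthivorous")
    x2 <- as.numeric(ec == "piscivorous")
    return(cbind(benthic = x1, piscivore = x2))
  }
  stop("ecotype must have 2 or 3 levels")
}

#' Partial redundancy analysis for ecotype association
#'
#' Constrained ordination of a multivariate response (genotype dosages or
#' normalized expression) on ecotype, conditioning on lake (and optionally
#' lineage): response and predictor are first residualized on the condition
#' dummies, the residual response is regressed on the residual predictor,
#' and the constrained axes are the principal axes of the fitted values.
#' Feature loadings are z-standardized per axis; features with |z| above
#' `zCut` (default 2, a two-tailed 5% rule) are candidates. Significance is
#' a permutation test of the pseudo-F statistic obtained by permuting rows
#' of the residualized predictor.
#'
#' @param response matrix samples x features (dosages centered internally;
#'   supply normalized values for expression).
#' @param ecotype numeric codes (e.g. planktivorous 0, benthivorous 1), or
#'   a factor/character vector (2 levels coded 0/1; 3 levels coded as two
#'   indicator contrasts giving RDA1 and RDA2).
#' @param condition data.frame of conditioning factors (lake, lineage).
#' @param nPerm permutations for the pseudo-F test.
#' @param seed integer seed (required).
#' @param zCut candidate threshold on |z|.
#' @return An [RdaResult-class].
#' @export
partialRda <- function(response, ecotype, condition, nPerm = 999, seed,
                       zCut = 2) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(as.integer(seed))
  Y <- as.matrix(response)
  n <- nrow(Y)
  X <- .ecotypePredictor(ecotype)
  if (nrow(X) != n) stop("ecotype length must match response rows")
  condition <- as.data.frame(condition)
  condition[] <- lapply(condition, factor)
  if (any(vapply(condition, nlevels, 0L) < 2))
    stop("condition factors must be non-constant")
  Z <- model.matrix(~ ., condition)
  if (n < ncol(Z) + 2)
    stop("need at least ", ncol(Z) + 2, " samples for ", ncol(Z),
         " condition dummies")
  keep <- apply(Y, 2, function(col) var(col) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant feature(s) dropped")
    Y <- Y[, keep, drop = FALSE]
  }
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("f", seq_len(ncol(Y)))
  Y <- scale(Y, center = TRUE, scale = FALSE)

  qz <- qr(Z)
  Yr <- Y - qr.fitted(qz, Y)
  Xr <- X - qr.fitted(qz, X)
  qx <- qr(Xr)
  q1 <- qx$rank
  fit <- qr.fitted(qx, Yr)
  sv <- svd(fit, nu = min(q1, n), nv = min(q1, ncol(Y)))
  nAxes <- min(q1, sum(sv$d > max(sv$d) * 1e-10))
  nAxes <- max(nAxes, 1L)
  U <- sv$u[, seq_len(nAxes), drop = FALSE]
  V <- sv$v[, seq_len(nAxes), drop = FALSE]
  Dv <- sv$d[seq_len(nAxes)]
  # orient each axis so its site scores correlate positively with the
  # (first) ecotype predictor column
  for (k in seq_len(nAxes)) {
    cc <- suppressWarnings(cor(U[, k], Xr[, 1]))
    if (!is.na(cc) && cc < 0) { U[, k] <- -U[, k]; V[, k] <- -V[, k] }
  }
  loadings <- sweep(V, 2, Dv, "*")
  rownames(loadings) <- colnames(Y)
  colnames(loadings) <- paste0("RDA", seq_len(nAxes))
  siteScores <- sweep(U, 2, Dv, "*")
  rownames(siteScores) <- rownames(Y)
  colnames(siteScores) <- colnames(loadings)

  ssFit <- sum(Dv^2)
  ssTot <- sum(Yr^2)
  ssRes <- ssTot - sum(fit^2)
  df1 <- q1
  df2 <- n - q1 - qr(cbind(Z))$rank
  Fobs <- (ssFit / df1) / (ssRes / df2)
  ge <- 0L
  for (p in seq_len(nPerm)) {
    Xp <- Xr[sample.int(n), , drop = FALSE]
    qp <- qr(Xp)
    fp <- qr.fitted(qp, Yr)
    ssF <- sum(fp^2)
    Fp <- (ssF / df1) / ((ssTot - ssF) / df2)
    if (Fp >= Fobs) ge <- ge + 1L
  }
  pval <- (1 + ge) / (nPerm + 1)

  z <- apply(loadings, 2, function(l) (l - mean(l)) / sd(l))
  dimnames(z) <- dimnames(loadings)
  cand <- rownames(z)[apply(abs(z) > zCut, 1, any)]
  new("RdaResult", loadings = loadings, z = z, candidates = cand,
      explained = sum(fit^2) / ssTot, p = pval, F = Fobs,
      nPerm = as.integer(nPerm), zCut = zCut, siteScores = siteScores)
}

#' Cross-lineage sharing of RDA candidates
#'
#' Tests whether more candidate features are shared across two independent
#' analyses (e.g. the two glacial lineages) than expected by chance, via
#' the same resampling machinery as outlier sharing, plus a chi-square test
#' of the 2x2 candidate/non-candidate cross-classification over the
#' universe.
#'
#' @param rdaA,rdaB [RdaResult-class] objects over the same feature
#'   universe.
#' @param universe all features tested in both analyses.
#' @param nResample resampling rounds for the sharing test.
#' @param seed integer seed (required).
#' @return list: `sharing` (a [SharingResult-class]), `chisqP`, `table`
#'   (the 2x2 contingency table).
#' @export
crossLineageCandidates <- function(rdaA, rdaB, universe, nResample = 10000,
                                   seed) {
  cA <- candidateFeatures(rdaA)
  cB <- candidateFeatures(rdaB)
  if (!all(cA %in% universe) || !all(cB %in% universe))
    stop("candidate sets must come from the common universe")
  sh <- sharingTest(cA, cB, universe, nResample = nResample, level = "snp",
                    seed = seed)
  inA <- universe %in% cA
  inB <- universe %in% cB
  tab <- table(inA = factor(inA, c(FALSE, TRUE)),
               inB = factor(inB, c(FALSE, TRUE)))
  chi <- if (length(cA) && length(cB))
    suppressWarnings(chisq.test(tab)$p.value) else 1
  list(sharing = sh, chisqP = chi, table = tab)
}
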